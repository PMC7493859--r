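# Neural-network layer kernels: forward and backward passes in base R
# matrix algebra. Batched activations are 3-D arrays (N, L, C): sample,
# position, channel. All layers here are deterministic given their inputs;
# stochasticity (dropout masks, weight init) draws from R's global RNG so a
# single set.seed() governs a whole training run.

# ---- shape algebra -------------------------------------------------------

# output length of a same-padded stride-1 convolution is the input length;
# total zero padding k-1 split floor/ceil between left and right
same_pad <- function(kernel) {
  c(left = (kernel - 1L) %/% 2L, right = kernel %/% 2L)
}

pool_out_len <- function(L, size = 2L, stride = 2L) {
  if (L < size) stopf("pooling window (%d) exceeds input length (%d)", size, L)
  (L - size) %/% stride + 1L
}

# ---- initializers --------------------------------------------------------

glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

orthogonal_init <- function(nrow, ncol) {
  a <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  qr_a <- qr(a)
  q <- qr.Q(qr_a)
  # fix signs so the distribution is uniform over orthogonal matrices
  q <- q %*% diag(sign(diag(qr.R(qr_a))), ncol(q))
  q[seq_len(nrow), seq_len(ncol), drop = FALSE]
}

# ---- 1-D convolution (same padding, stride 1) ----------------------------
# X: (N, L, C_in); W: (k * C_in, F) with rows ordered tap-major (tap 1
# channels 1..C, tap 2 channels 1..C, ...); b: length F.

conv1d_forward <- function(X, W, b, kernel) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; cin <- d[3L]
  f <- ncol(W)
  pad <- same_pad(kernel)
  Lp <- L + pad["left"] + pad["right"]
  Xp <- array(0, dim = c(n, Lp, cin))
  Xp[, (pad["left"] + 1L):(pad["left"] + L), ] <- X
  # im2col: M is (n * L, kernel * cin)
  M <- matrix(0, nrow = n * L, ncol = kernel * cin)
  for (t in seq_len(kernel)) {
    slab <- Xp[, t:(t + L - 1L), , drop = FALSE]
    dim(slab) <- c(n * L, cin)
    M[, ((t - 1L) * cin + 1L):(t * cin)] <- slab
  }
  Z <- M %*% W
  Z <- sweep(Z, 2L, b, "+")
  Y <- Z
  dim(Y) <- c(n, L, f)
  list(out = Y, cache = list(M = M, W = W, kernel = kernel, dims = d, pad = pad))
}

conv1d_backward <- function(dY, cache) {
  d <- cache$dims; n <- d[1L]; L <- d[2L]; cin <- d[3L]
  kernel <- cache$kernel; pad <- cache$pad
  f <- ncol(cache$W)
  dZ <- dY
  dim(dZ) <- c(n * L, f)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, cache$W)      # (n*L, k*cin)
  Lp <- L + pad["left"] + pad["right"]
  dXp <- array(0, dim = c(n, Lp, cin))
  for (t in seq_len(kernel)) {
    slab <- dM[, ((t - 1L) * cin + 1L):(t * cin), drop = FALSE]
    dim(slab) <- c(n, L, cin)
    dXp[, t:(t + L - 1L), ] <- dXp[, t:(t + L - 1L), , drop = FALSE] + slab
  }
  dX <- dXp[, (pad["left"] + 1L):(pad["left"] + L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- ReLU ----------------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

# ---- max pooling (size 2, stride 2, floor semantics) ---------------------

maxpool_forward <- function(X, size = 2L, stride = 2L) {
  stopifnot(size == 2L, stride == 2L)  # the only configuration used
  d <- dim(X); n <- d[1L]; L <- d[2L]; ch <- d[3L]
  Lo <- pool_out_len(L, size, stride)
  A <- X[, seq.int(1L, by = 2L, length.out = Lo), , drop = FALSE]
  B <- X[, seq.int(2L, by = 2L, length.out = Lo), , drop = FALSE]
  takeA <- A >= B
  list(out = pmax(A, B),
       cache = list(takeA = takeA, L = L, dims_out = c(n, Lo, ch)))
}

maxpool_backward <- function(dY, cache) {
  n <- cache$dims_out[1L]; Lo <- cache$dims_out[2L]; ch <- cache$dims_out[3L]
  dX <- array(0, dim = c(n, cache$L, ch))
  dX[, seq.int(1L, by = 2L, length.out = Lo), ] <- dY * cache$takeA
  dX[, seq.int(2L, by = 2L, length.out = Lo), ] <- dY * !cache$takeA
  dX
}

# ---- dropout (inverted scaling; train-time only) -------------------------

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  mask <- array(stats::runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- LSTM (sequence output) ----------------------------------------------
# Gate equations (forget f, input i, output o, candidate g):
#   f_t = sigmoid(W^f x_t + U^f h_{t-1} + b^f)
#   i_t = sigmoid(W^i x_t + U^i h_{t-1} + b^i)
#   o_t = sigmoid(W^o x_t + U^o h_{t-1} + b^o)
#   s_t = f_t * s_{t-1} + i_t * tanh(W^c x_t + U^c h_{t-1} + b^c)
#   h_t = tanh(s_t) * o_t
# Weights are packed column-blocks [i | f | g | o]: W (d, 4u), U (u, 4u),
# b (4u). The layer returns every h_t (sequence output), shape (N, T, u).

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(X, W, U, b) {
  d <- dim(X); n <- d[1L]; T_ <- d[2L]; din <- d[3L]
  u <- ncol(U) %/% 4L
  X2 <- X; dim(X2) <- c(n * T_, din)
  XW <- sweep(X2 %*% W, 2L, b, "+")     # (n*T, 4u), input part of all steps
  idx <- list(i = 1:u, f = (u + 1L):(2L * u),
              g = (2L * u + 1L):(3L * u), o = (3L * u + 1L):(4L * u))
  H <- array(0, dim = c(n, T_, u))
  gates <- array(0, dim = c(n, T_, 4L * u))   # post-activation i, f, g, o
  Cst <- array(0, dim = c(n, T_, u))          # cell states s_t
  h_prev <- matrix(0, n, u)
  c_prev <- matrix(0, n, u)
  for (t in seq_len(T_)) {
    rows <- seq.int((t - 1L) * n + 1L, t * n)  # X2 rows for step t? see below
    # X2 linearization is (n, T, d) -> element (i, t, c) at i + n(t-1) + nT(c-1),
    # so rows of X2 for step t are (t-1)*n + 1 .. t*n
    Z <- XW[rows, , drop = FALSE] + h_prev %*% U
    it <- sigmoid(Z[, idx$i, drop = FALSE])
    ft <- sigmoid(Z[, idx$f, drop = FALSE])
    gt <- tanh(Z[, idx$g, drop = FALSE])
    ot <- sigmoid(Z[, idx$o, drop = FALSE])
    c_t <- ft * c_prev + it * gt
    h_t <- ot * tanh(c_t)
    H[, t, ] <- h_t
    Cst[, t, ] <- c_t
    gates[, t, idx$i] <- it; gates[, t, idx$f] <- ft
    gates[, t, idx$g] <- gt; gates[, t, idx$o] <- ot
    h_prev <- h_t; c_prev <- c_t
  }
  list(out = H,
       cache = list(X = X, H = H, Cst = Cst, gates = gates, W = W, U = U,
                    idx = idx, dims = d, u = u))
}

lstm_backward <- function(dH, cache) {
  d <- cache$dims; n <- d[1L]; T_ <- d[2L]; din <- d[3L]
  u <- cache$u; idx <- cache$idx
  W <- cache$W; U <- cache$U
  dZ_all <- array(0, dim = c(n, T_, 4L * u))
  dh_next <- matrix(0, n, u)
  dc_next <- matrix(0, n, u)
  for (t in rev(seq_len(T_))) {
    it <- matrix(cache$gates[, t, idx$i], n, u)
    ft <- matrix(cache$gates[, t, idx$f], n, u)
    gt <- matrix(cache$gates[, t, idx$g], n, u)
    ot <- matrix(cache$gates[, t, idx$o], n, u)
    c_t <- matrix(cache$Cst[, t, ], n, u)
    c_prev <- if (t > 1L) matrix(cache$Cst[, t - 1L, ], n, u) else matrix(0, n, u)
    tc <- tanh(c_t)
    dh <- matrix(dH[, t, ], n, u) + dh_next
    do_ <- dh * tc
    dc <- dh * ot * (1 - tc^2) + dc_next
    df <- dc * c_prev
    di <- dc * gt
    dg <- dc * it
    dc_next <- dc * ft
    dZ <- cbind(di * it * (1 - it),
                df * ft * (1 - ft),
                dg * (1 - gt^2),
                do_ * ot * (1 - ot))
    dZ_all[, t, ] <- dZ
    dh_next <- dZ %*% t(U)
  }
  dZ2 <- dZ_all; dim(dZ2) <- c(n * T_, 4L * u)
  X2 <- cache$X; dim(X2) <- c(n * T_, din)
  dW <- crossprod(X2, dZ2)
  db <- colSums(dZ2)
  # dU accumulates h_{t-1} dZ_t over t >= 2 (h_0 = 0 contributes nothing)
  Hprev <- array(0, dim = c(n, T_, u))
  if (T_ > 1L) Hprev[, 2:T_, ] <- cache$H[, 1:(T_ - 1L), , drop = FALSE]
  H2 <- Hprev; dim(H2) <- c(n * T_, u)
  dU <- crossprod(H2, dZ2)
  dX <- dZ2 %*% t(W)
  dim(dX) <- c(n, T_, din)
  list(dX = dX, dW = dW, dU = dU, db = db)
}

# ---- dense ---------------------------------------------------------------

dense_forward <- function(X, W, b) {
  Z <- sweep(X %*% W, 2L, b, "+")
  list(out = Z, cache = list(X = X, W = W))
}

dense_backward <- function(dZ, cache) {
  list(dX = tcrossprod(dZ, cache$W),
       dW = crossprod(cache$X, dZ),
       db = colSums(dZ))
}

# flatten (N, L, C) position-major: position 1 channels 1..C, position 2, ...
flatten_forward <- function(X) {
  d <- dim(X)
  Y <- aperm(X, c(1L, 3L, 2L))   # (N, C, L) so that position varies slowest
  dim(Y) <- c(d[1L], d[2L] * d[3L])
  # note: after aperm, column index runs channel-fastest => position-major
  list(out = Y, cache = d)
}

flatten_backward <- function(dY, dims) {
  dX <- dY
  dim(dX) <- c(dims[1L], dims[3L], dims[2L])
  aperm(dX, c(1L, 3L, 2L))
}
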