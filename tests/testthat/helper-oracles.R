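# Independent oracles used across the test suite. These re-derive expected
# values from first principles and never call the implementation paths they
# check.

# AUC as exhaustive pairwise concordance: P(score+ > score-) + 0.5 P(tie)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Direct evaluation of the receptive-field sum
#   y_k = sum_{u = -n..n} w_u * x_{k - u},   k = n+1 .. d-n  (1-based interior)
# for a single neuron scanning a single-channel signal.
conv_receptive_field_oracle <- function(x, w_by_u) {
  n <- (length(w_by_u) - 1L) %/% 2L
  d <- length(x)
  u_vals <- -n:n
  vapply((n + 1L):(d - n), function(k) {
    sum(w_by_u * x[k - u_vals])
  }, numeric(1))
}

# Step-by-step LSTM per the gate equations, with per-gate (u x d) and (u x u)
# weight matrices and column-vector states:
#   f_t = sigmoid(Wf x + Uf h + bf); i_t, o_t alike;
#   s_t = f_t * s_{t-1} + i_t * tanh(Wc x + Uc h + bc);  h_t = tanh(s_t) * o_t
lstm_gate_oracle <- function(X_steps, Wf, Wi, Wo, Wc, Uf, Ui, Uo, Uc,
                             bf, bi, bo, bc) {
  sig <- function(z) 1 / (1 + exp(-z))
  u <- nrow(Wf)
  h <- matrix(0, u, 1)
  s <- matrix(0, u, 1)
  H <- matrix(NA_real_, length(X_steps), u)
  for (t in seq_along(X_steps)) {
    x <- matrix(X_steps[[t]], ncol = 1)
    f <- sig(Wf %*% x + Uf %*% h + bf)
    i <- sig(Wi %*% x + Ui %*% h + bi)
    o <- sig(Wo %*% x + Uo %*% h + bo)
    s <- f * s + i * tanh(Wc %*% x + Uc %*% h + bc)
    h <- tanh(s) * o
    H[t, ] <- h
  }
  H
}

# closed-form trainable-parameter counts
count_conv <- function(kernel, c_in, filters) kernel * c_in * filters + filters
count_lstm <- function(u, d) 4 * (u * d + u * u + u)
count_dense <- function(n_in, n_out) n_in * n_out + n_out

# random ACGT strings
random_seqs <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# small config for fast model tests
tiny_model_config <- function(L = 24L) {
  model_config(input_length = L, conv1_filters = 4L, conv1_kernel = 3L,
               lstm_units = 3L, conv2_filters = 4L, conv2_kernel = 4L,
               dense_units = 6L, dropout_rate = 0.5)
}

tiny_dataset <- function(n_per_class = 20L, L = 24L, seed = 5L, strength = 1,
                         motif_prob = 1) {
  simulate_dataset(simulation_config(n_per_class = n_per_class, length = L,
                                     periodic_strength = strength,
                                     motif_prob = motif_prob, seed = seed))
}
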