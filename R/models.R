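#' Architecture hyperparameters
#'
#' All tunable sizes of the hybrid network and its two baselines. The
#' defaults reproduce the published reference structure exactly: a shared
#' Conv1D(50 filters, kernel 5) feature extractor, a 50-unit sequence-output
#' LSTM path, a Conv1D(50 filters, kernel 10) path, and a 370-unit dense
#' head, with 50% dropout and L2 weight decay lambda = 1e-3 on convolution
#' and dense kernels.
#'
#' @param input_length Sequence length in bp (default 147).
#' @param input_channels Input channels; 4 for one-hot DNA.
#' @param conv1_filters,conv1_kernel,conv1_stride Shared feature-extraction
#'   convolution (stride must be 1; convolutions are same-padded).
#' @param pool_size,pool_stride Max-pooling window and stride (both 2).
#' @param lstm_units Hidden units of the sequence-output LSTM path.
#' @param conv2_filters,conv2_kernel,conv2_stride Convolutional-path
#'   convolution.
#' @param dense_units Width of the first dense layer.
#' @param dropout_rate Dropout rate in \[0, 1), applied after each pooling
#'   layer, after the LSTM, and after the first dense layer (training only).
#' @param l2_lambda L2 penalty coefficient on convolution and dense kernel
#'   weights (biases and LSTM weights are not penalized).
#' @param l2_on Character vector naming the penalized weight groups;
#'   the default penalizes convolution and dense kernels only.
#' @return A list of class `nucnet_model_config`.
#' @export
model_config <- function(input_length = 147L,
                         input_channels = 4L,
                         conv1_filters = 50L, conv1_kernel = 5L, conv1_stride = 1L,
                         pool_size = 2L, pool_stride = 2L,
                         lstm_units = 50L,
                         conv2_filters = 50L, conv2_kernel = 10L, conv2_stride = 1L,
                         dense_units = 370L,
                         dropout_rate = 0.5,
                         l2_lambda = 1e-3,
                         l2_on = c("conv", "dense")) {
  stopifnot(is_count(input_length), is_count(input_channels),
            is_count(conv1_filters), is_count(conv1_kernel),
            is_count(lstm_units), is_count(conv2_filters),
            is_count(conv2_kernel), is_count(dense_units),
            is.numeric(dropout_rate), dropout_rate >= 0, dropout_rate < 1,
            is.numeric(l2_lambda), l2_lambda >= 0)
  if (conv1_stride != 1L || conv2_stride != 1L) {
    stopf("only stride-1 convolutions are supported (shape-preserving, same padding)")
  }
  if (pool_size != 2L || pool_stride != 2L) {
    stopf("only 2/2 max pooling is supported")
  }
  structure(list(input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv1_stride = 1L,
                 pool_size = 2L, pool_stride = 2L,
                 lstm_units = as.integer(lstm_units),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_kernel = as.integer(conv2_kernel),
                 conv2_stride = 1L,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 l2_lambda = l2_lambda,
                 l2_on = l2_on),
            class = "nucnet_model_config")
}

# derived shape chain for an architecture; errors if pooling degenerates
model_shapes <- function(cfg, architecture) {
  L <- cfg$input_length
  L1 <- L                                   # same-padded conv
  Lp1 <- pool_out_len(L1)                   # 147 -> 73
  shp <- list(L = L, conv1 = L1, pool1 = Lp1)
  if (architecture %in% c("corenup", "convnet")) {
    shp$conv2 <- Lp1                        # same-padded conv
    shp$pool2 <- pool_out_len(Lp1)          # 73 -> 36
    shp$flat_conv <- shp$pool2 * cfg$conv2_filters
  }
  if (architecture %in% c("corenup", "lstm")) {
    shp$lstm <- Lp1                         # sequence output, one h_t per step
    shp$flat_lstm <- Lp1 * cfg$lstm_units
  }
  shp$concat <- switch(architecture,
                       corenup = shp$flat_lstm + shp$flat_conv,
                       convnet = shp$flat_conv,
                       lstm    = shp$flat_lstm)
  shp
}

init_params <- function(cfg, architecture) {
  shp <- model_shapes(cfg, architecture)
  cin <- cfg$input_channels
  p <- list()
  p$conv1_W <- glorot_uniform(cfg$conv1_kernel * cin, cfg$conv1_filters,
                              fan_in = cfg$conv1_kernel * cin,
                              fan_out = cfg$conv1_kernel * cfg$conv1_filters)
  p$conv1_b <- rep(0, cfg$conv1_filters)
  if (architecture %in% c("corenup", "lstm")) {
    u <- cfg$lstm_units; d <- cfg$conv1_filters
    p$lstm_W <- glorot_uniform(d, 4L * u)
    p$lstm_U <- do.call(cbind, lapply(1:4, function(i) orthogonal_init(u, u)))
    b <- rep(0, 4L * u)
    b[(u + 1L):(2L * u)] <- 1           # forget-gate bias starts open
    p$lstm_b <- b
  }
  if (architecture %in% c("corenup", "convnet")) {
    p$conv2_W <- glorot_uniform(cfg$conv2_kernel * cfg$conv1_filters,
                                cfg$conv2_filters,
                                fan_in = cfg$conv2_kernel * cfg$conv1_filters,
                                fan_out = cfg$conv2_kernel * cfg$conv2_filters)
    p$conv2_b <- rep(0, cfg$conv2_filters)
  }
  p$dense1_W <- glorot_uniform(shp$concat, cfg$dense_units)
  p$dense1_b <- rep(0, cfg$dense_units)
  p$out_W <- glorot_uniform(cfg$dense_units, 1L)
  p$out_b <- 0
  p
}

# which parameter matrices carry the L2 penalty
l2_param_names <- function(cfg, params) {
  groups <- list(conv = c("conv1_W", "conv2_W"),
                 dense = c("dense1_W", "out_W"),
                 lstm_input = "lstm_W",
                 lstm_recurrent = "lstm_U")
  nm <- unlist(groups[intersect(cfg$l2_on, names(groups))], use.names = FALSE)
  intersect(nm, names(params))
}

build_model <- function(architecture, cfg, seed = NULL) {
  params <- with_seed(seed, init_params(cfg, architecture))
  model <- structure(list(architecture = architecture, cfg = cfg,
                          params = params,
                          shapes = model_shapes(cfg, architecture)),
                     class = "nucnet_model")
  model
}

#' Build the hybrid convolutional-recurrent network
#'
#' Topology: Conv1D (same padding, ReLU) -> MaxPool(2,2) -> Dropout, then two
#' parallel paths on the pooled features — a sequence-output LSTM (-> Dropout
#' -> Flatten) and a second Conv1D (ReLU) -> MaxPool(2,2) -> Dropout ->
#' Flatten — concatenated and classified by Dense(ReLU) -> Dropout ->
#' Dense(1, sigmoid). With default sizes the shape chain is
#' 147 -> 147x50 -> 73x50 -> \{LSTM 73x50 (flatten 3650), conv 73x50 -> 36x50
#' (flatten 1800)\} -> concat 5450 -> 370 -> 1.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return A list of class `nucnet_model` with elements `architecture`,
#'   `cfg`, `params` (named weight arrays), `shapes`, and a `summary`
#'   accessor via [count_parameters()] / [network_summary()].
#' @examples
#' m <- build_corenup(model_config(), seed = 1)
#' count_parameters(m)$grand_total  # 2063541
#' @export
build_corenup <- function(cfg = model_config(), seed = NULL) {
  build_model("corenup", cfg, seed)
}

#' Build the purely convolutional baseline
#'
#' Two stacked convolution blocks (same-padded Conv1D -> ReLU -> MaxPool(2,2)
#' -> Dropout) followed by Flatten and the same dense head as the hybrid
#' network: the hybrid architecture without its recurrent path.
#'
#' @inheritParams build_corenup
#' @return A `nucnet_model`.
#' @export
build_convnet_baseline <- function(cfg = model_config(), seed = NULL) {
  build_model("convnet", cfg, seed)
}

#' Build the convolution-plus-LSTM baseline
#'
#' A single convolution block feeding a sequence-output LSTM, then Dropout,
#' Flatten and the dense head: the hybrid architecture without its second
#' convolutional path.
#'
#' @inheritParams build_corenup
#' @return A `nucnet_model`.
#' @export
build_lstm_baseline <- function(cfg = model_config(), seed = NULL) {
  build_model("lstm", cfg, seed)
}

#' @export
print.nucnet_model <- function(x, ...) {
  s <- count_parameters(x)
  cat(sprintf("<nucnet_model> architecture '%s', input %dx%d, %s trainable parameters\n",
              x$architecture, x$cfg$input_length, x$cfg$input_channels,
              format(s$grand_total, big.mark = ",")))
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

# Forward pass; returns probabilities and (optionally) the caches needed for
# backprop. Dropout draws from the current RNG stream when training = TRUE.
network_forward <- function(model, X, training = FALSE, keep_cache = training) {
  p <- model$params; cfg <- model$cfg; arch <- model$architecture
  rate <- cfg$dropout_rate
  cc <- list()
  c1 <- conv1d_forward(X, p$conv1_W, p$conv1_b, cfg$conv1_kernel)
  r1 <- relu_forward(c1$out)
  p1 <- maxpool_forward(r1$out)
  d1 <- dropout_forward(p1$out, rate, training)
  trunk <- d1$out
  feats <- NULL
  if (arch %in% c("corenup", "lstm")) {
    ls <- lstm_forward(trunk, p$lstm_W, p$lstm_U, p$lstm_b)
    dl <- dropout_forward(ls$out, rate, training)
    fl <- flatten_forward(dl$out)
    feats <- fl$out
    cc$lstm <- ls$cache; cc$drop_lstm <- dl$cache; cc$flat_lstm <- fl$cache
  }
  if (arch %in% c("corenup", "convnet")) {
    c2 <- conv1d_forward(trunk, p$conv2_W, p$conv2_b, cfg$conv2_kernel)
    r2 <- relu_forward(c2$out)
    p2 <- maxpool_forward(r2$out)
    d2 <- dropout_forward(p2$out, rate, training)
    f2 <- flatten_forward(d2$out)
    feats <- if (is.null(feats)) f2$out else cbind(feats, f2$out)
    cc$conv2 <- c2$cache; cc$relu2 <- r2$cache; cc$pool2 <- p2$cache
    cc$drop_conv <- d2$cache; cc$flat_conv <- f2$cache
  }
  h1 <- dense_forward(feats, p$dense1_W, p$dense1_b)
  rh <- relu_forward(h1$out)
  dh <- dropout_forward(rh$out, rate, training)
  o  <- dense_forward(dh$out, p$out_W, p$out_b)
  prob <- as.vector(sigmoid(o$out))
  if (!keep_cache) return(list(prob = prob))
  cc$conv1 <- c1$cache; cc$relu1 <- r1$cache; cc$pool1 <- p1$cache
  cc$drop1 <- d1$cache
  cc$dense1 <- h1$cache; cc$relu_h <- rh$cache; cc$drop_h <- dh$cache
  cc$out <- o$cache
  list(prob = prob, cache = cc)
}

# Backprop of mean binary cross-entropy: dz_out = (p - y) / N at the output
# pre-activation. Returns gradients named like model$params (L2 not included;
# the optimizer adds it).
network_backward <- function(model, cache, prob, y) {
  arch <- model$architecture
  n <- length(y)
  dz <- matrix((prob - y) / n, ncol = 1L)
  g <- list()
  bo <- dense_backward(dz, cache$out)
  g$out_W <- bo$dW; g$out_b <- bo$db
  dd <- dropout_backward(bo$dX, cache$drop_h)
  dd <- relu_backward(dd, cache$relu_h)
  b1 <- dense_backward(dd, cache$dense1)
  g$dense1_W <- b1$dW; g$dense1_b <- b1$db
  dfeat <- b1$dX
  d_trunk <- 0
  if (arch %in% c("corenup", "lstm")) {
    nl <- prod(cache$flat_lstm[2:3])
    d_fl <- dfeat[, seq_len(nl), drop = FALSE]
    d_lstm_out <- flatten_backward(d_fl, cache$flat_lstm)
    d_lstm_out <- dropout_backward(d_lstm_out, cache$drop_lstm)
    bl <- lstm_backward(d_lstm_out, cache$lstm)
    g$lstm_W <- bl$dW; g$lstm_U <- bl$dU; g$lstm_b <- bl$db
    d_trunk <- d_trunk + bl$dX
    offset <- nl
  } else offset <- 0L
  if (arch %in% c("corenup", "convnet")) {
    nc <- prod(cache$flat_conv[2:3])
    d_fc <- dfeat[, offset + seq_len(nc), drop = FALSE]
    d_c <- flatten_backward(d_fc, cache$flat_conv)
    d_c <- dropout_backward(d_c, cache$drop_conv)
    d_c <- maxpool_backward(d_c, cache$pool2)
    d_c <- relu_backward(d_c, cache$relu2)
    b2 <- conv1d_backward(d_c, cache$conv2)
    g$conv2_W <- b2$dW; g$conv2_b <- b2$db
    d_trunk <- d_trunk + b2$dX
  }
  d_trunk <- dropout_backward(d_trunk, cache$drop1)
  d_trunk <- maxpool_backward(d_trunk, cache$pool1)
  d_trunk <- relu_backward(d_trunk, cache$relu1)
  bc1 <- conv1d_backward(d_trunk, cache$conv1)
  g$conv1_W <- bc1$dW; g$conv1_b <- bc1$db
  g[names(model$params)]
}

# mean BCE; probabilities clipped away from 0/1 for finite logs
bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

l2_penalty <- function(model) {
  nm <- l2_param_names(model$cfg, model$params)
  model$cfg$l2_lambda * sum(vapply(model$params[nm],
                                   function(w) sum(w * w), numeric(1)))
}

#' Predict class probabilities from a built network
#'
#' Runs the forward pass with dropout disabled. Predictions are invariant to
#' batch partitioning: a sequence gets the same probability whether predicted
#' alone or inside any batch.
#'
#' @param model A `nucnet_model` (see [build_corenup()]).
#' @param x A one-hot array `(N, L, 4)`, a `nucnet_dataset`, or a character
#'   vector of sequences.
#' @param batch_size Sequences per forward pass.
#' @return Numeric vector of probabilities in \[0, 1\], one per sequence.
#' @export
predict_network <- function(model, x, batch_size = 256L) {
  X <- if (is.array(x) && length(dim(x)) == 3L) x else one_hot_encode(x)
  if (dim(X)[2L] != model$cfg$input_length) {
    stopf("input length mismatch: expected %d, got %d",
          model$cfg$input_length, dim(X)[2L])
  }
  if (dim(X)[3L] != model$cfg$input_channels) {
    stopf("input channels mismatch: expected %d, got %d",
          model$cfg$input_channels, dim(X)[3L])
  }
  n <- dim(X)[1L]
  out <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- network_forward(model, X[idx, , , drop = FALSE],
                                training = FALSE, keep_cache = FALSE)$prob
  }
  out
}

# ---- summaries -----------------------------------------------------------

n_params <- function(x) if (is.null(x)) 0L else length(x)

#' Per-layer and per-path parameter accounting
#'
#' Counts trainable parameters by direct enumeration of the model's weight
#' arrays and reports every layer's output shape, grouped into the network's
#' processing paths (feature extraction, LSTM, convolutional, dense).
#'
#' @param model A `nucnet_model`.
#' @return An object of class `nucnet_summary`: list with `architecture`,
#'   `layers` (data frame: path, layer, kernel, units, stride, output_dim,
#'   params), `path_totals` (named numeric) and `grand_total`.
#' @examples
#' s <- count_parameters(build_corenup(model_config(), seed = 1))
#' s$path_totals
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "nucnet_model"))
  cfg <- model$cfg; p <- model$params; shp <- model$shapes
  arch <- model$architecture
  f1 <- cfg$conv1_filters
  row <- function(path, layer, kernel, units, stride, outdim, params) {
    data.frame(path = path, layer = layer, kernel = kernel, units = units,
               stride = stride, output_dim = outdim, params = params,
               stringsAsFactors = FALSE)
  }
  dims <- function(l, c) sprintf("%dx%d", l, c)
  rows <- list(
    row("Feature extraction", "Conv1D", cfg$conv1_kernel, f1, 1L,
        dims(shp$conv1, f1), n_params(p$conv1_W) + n_params(p$conv1_b)),
    row("Feature extraction", "MaxPool1D", NA, NA, 2L, dims(shp$pool1, f1), 0L),
    row("Feature extraction",
        sprintf("Dropout %d%%", round(100 * cfg$dropout_rate)),
        NA, NA, NA, dims(shp$pool1, f1), 0L))
  if (arch %in% c("corenup", "lstm")) {
    u <- cfg$lstm_units
    rows <- c(rows, list(
      row("LSTM path", "LSTM", NA, u, NA, dims(shp$lstm, u),
          n_params(p$lstm_W) + n_params(p$lstm_U) + n_params(p$lstm_b)),
      row("LSTM path", sprintf("Dropout %d%%", round(100 * cfg$dropout_rate)),
          NA, NA, NA, dims(shp$lstm, u), 0L),
      row("LSTM path", "Flatten", NA, NA, NA, as.character(shp$flat_lstm), 0L)))
  }
  if (arch %in% c("corenup", "convnet")) {
    f2 <- cfg$conv2_filters
    rows <- c(rows, list(
      row("Convolutional path", "Conv1D", cfg$conv2_kernel, f2, 1L,
          dims(shp$conv2, f2), n_params(p$conv2_W) + n_params(p$conv2_b)),
      row("Convolutional path", "MaxPool1D", NA, NA, 2L, dims(shp$pool2, f2), 0L),
      row("Convolutional path",
          sprintf("Dropout %d%%", round(100 * cfg$dropout_rate)),
          NA, NA, NA, dims(shp$pool2, f2), 0L),
      row("Convolutional path", "Flatten", NA, NA, NA,
          as.character(shp$flat_conv), 0L)))
  }
  rows <- c(rows, list(
    if (arch == "corenup")
      row("Dense path", "Concatenate", NA, NA, NA, as.character(shp$concat), 0L),
    row("Dense path", "Dense", NA, cfg$dense_units, NA,
        dims(cfg$dense_units, 1L),
        n_params(p$dense1_W) + n_params(p$dense1_b)),
    row("Dense path", sprintf("Dropout %d%%", round(100 * cfg$dropout_rate)),
        NA, NA, NA, dims(cfg$dense_units, 1L), 0L),
    row("Dense path", "Dense", NA, 1L, NA, "1x1",
        n_params(p$out_W) + n_params(p$out_b))))
  layers <- do.call(rbind, Filter(Negate(is.null), rows))
  path_map <- c("Feature extraction" = "feature_extraction",
                "LSTM path" = "lstm_path",
                "Convolutional path" = "conv_path",
                "Dense path" = "dense_path")
  path_totals <- vapply(split(layers$params, path_map[layers$path]), sum, numeric(1))
  # keep canonical order
  path_totals <- path_totals[intersect(unname(path_map), names(path_totals))]
  structure(list(architecture = arch, layers = layers,
                 path_totals = path_totals,
                 grand_total = sum(layers$params)),
            class = "nucnet_summary")
}

#' @rdname count_parameters
#' @export
network_summary <- count_parameters

#' @export
print.nucnet_summary <- function(x, ...) {
  cat(sprintf("Network architecture: %s\n", x$architecture))
  tab <- x$layers
  tab$params <- format(tab$params, big.mark = ",")
  for (p in unique(tab$path)) {
    cat(sprintf("\n%s\n", p))
    sub <- tab[tab$path == p, c("layer", "kernel", "units", "stride",
                                "output_dim", "params")]
    print(sub, row.names = FALSE, na.print = "-")
  }
  cat("\nParameters per path\n")
  for (nm in names(x$path_totals)) {
    cat(sprintf("  %-20s %s\n", nm, format(x$path_totals[[nm]], big.mark = ",")))
  }
  cat(sprintf("  %-20s %s\n", "TOTAL", format(x$grand_total, big.mark = ",")))
  invisible(x)
}

# ---- save / load ---------------------------------------------------------

#' Save or load a fitted or built model
#'
#' Writes the weights to a single portable RDS file with a JSON sidecar
#' describing the architecture and configuration.
#'
#' @param model A `nucnet_model` or fitted `nucnet` object.
#' @param path Output path for the weights file; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `write_nucnet` invisibly returns `path`; `read_nucnet` returns the
#'   restored object.
#' @export
write_nucnet <- function(model, path) {
  stopifnot(inherits(model, c("nucnet_model", "nucnet")))
  saveRDS(model, path)
  cfg <- if (inherits(model, "nucnet")) model$model_cfg else model$cfg
  side <- list(class = class(model)[1L],
               architecture = model$architecture,
               config = unclass(cfg),
               package_version = as.character(utils::packageVersion("nucnet")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_nucnet
#' @export
read_nucnet <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- readRDS(path)
  stopifnot(inherits(obj, c("nucnet_model", "nucnet")))
  obj
}
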