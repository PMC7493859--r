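#' Training hyperparameters
#'
#' The reference protocol: Adam (learning rate 3e-4) on mean binary
#' cross-entropy plus the L2 weight penalty, at most 200 epochs, early
#' stopping when the validation loss fails to strictly decrease for 5
#' consecutive epochs, a stratified random 10% validation split, and a 0.5
#' decision threshold.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment coefficients (conventional values).
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Consecutive non-improving validation epochs
#'   tolerated before stopping.
#' @param validation_fraction Fraction of the training set held out for the
#'   validation loss (stratified).
#' @param batch_size Minibatch size.
#' @param decision_threshold Probability threshold for the positive class.
#' @param restore_best When `TRUE`, the weights from the best-validation
#'   epoch are restored after stopping (off by default).
#' @param seed Integer seed governing the validation split, epoch shuffling
#'   and dropout masks.
#' @return A list of class `nucnet_train_config`.
#' @export
train_config <- function(learning_rate = 3e-4,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         max_epochs = 200L,
                         early_stop_patience = 5L,
                         validation_fraction = 0.10,
                         batch_size = 32L,
                         decision_threshold = 0.5,
                         restore_best = FALSE,
                         seed = 1L) {
  stopifnot(is.numeric(learning_rate), learning_rate >= 0,
            is_count(max_epochs), is_count(early_stop_patience),
            is.numeric(validation_fraction),
            validation_fraction > 0, validation_fraction < 1,
            is_count(batch_size),
            is.numeric(decision_threshold),
            decision_threshold > 0, decision_threshold < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 decision_threshold = decision_threshold,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "nucnet_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * (state$m[[nm]] / bc1) /
        (sqrt(state$v[[nm]] / bc2) + cfg$epsilon)
  }
  list(params = params, state = state)
}

# stratified index split: returns list(train=, val=)
validation_split <- function(labels, fraction) {
  val <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    n_val <- round(length(idx) * fraction)
    if (n_val >= 1L) val <- c(val, sample(idx, n_val))
  }
  if (length(val) == 0L) {
    stopf("validation split is empty; increase the dataset or validation_fraction")
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Train a network on a labeled dataset
#'
#' Minibatch Adam on mean binary cross-entropy plus the model's L2 weight
#' penalty. A stratified random `validation_fraction` of the data is held out;
#' after each epoch the validation cross-entropy is computed with dropout
#' disabled, and training stops early when it has failed to strictly decrease
#' for `early_stop_patience` consecutive epochs. Fully reproducible from
#' `cfg$seed`.
#'
#' @param model A `nucnet_model` (its weights are the starting point).
#' @param ds A `nucnet_dataset` containing both classes.
#' @param cfg A [train_config()].
#' @param X Optional pre-encoded one-hot array for `ds` (saves re-encoding).
#' @param verbose Print one line per epoch.
#' @return A list of class `nucnet_trained`: `model` (weights updated),
#'   `log` (data frame epoch/train_loss/val_loss), `stopped_epoch`,
#'   `best_epoch`, `train_ids` (sequence ids seen by the optimizer,
#'   including the validation split).
#' @export
train_network <- function(model, ds, cfg = train_config(), X = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "nucnet_model"), inherits(ds, "nucnet_dataset"))
  if (ds$length != model$cfg$input_length) {
    stopf("dataset length %d does not match model input length %d",
          ds$length, model$cfg$input_length)
  }
  if (any(ds$class_counts == 0L)) {
    stopf("training set must contain both classes")
  }
  if (is.null(X)) X <- one_hot_encode(ds)
  y <- ds$label
  with_seed(cfg$seed, {
    sp <- validation_split(y, cfg$validation_fraction)
    Xtr <- X[sp$train, , , drop = FALSE]; ytr <- y[sp$train]
    Xva <- X[sp$val, , , drop = FALSE]; yva <- y[sp$val]
    if (length(unique(ytr)) < 2L) stopf("training split lost a class; dataset too small")
    n_tr <- length(ytr)
    state <- adam_init(model$params)
    lambda <- model$cfg$l2_lambda
    l2_names <- l2_param_names(model$cfg, model$params)
    log_rows <- vector("list", cfg$max_epochs)
    best_val <- Inf; best_epoch <- 0L; wait <- 0L
    best_params <- NULL
    stopped <- cfg$max_epochs
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      epoch_loss <- 0
      for (start in seq.int(1L, n_tr, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
        xb <- Xtr[idx, , , drop = FALSE]; yb <- ytr[idx]
        fw <- network_forward(model, xb, training = TRUE)
        g <- network_backward(model, fw$cache, fw$prob, yb)
        if (lambda > 0) {
          for (nm in l2_names) g[[nm]] <- g[[nm]] + 2 * lambda * model$params[[nm]]
        }
        st <- adam_step(model$params, g, state, cfg)
        model$params <- st$params; state <- st$state
        epoch_loss <- epoch_loss + bce_loss(fw$prob, yb) * length(yb)
      }
      train_loss <- epoch_loss / n_tr + l2_penalty(model)
      val_prob <- predict_network(model, Xva, batch_size = cfg$batch_size)
      val_loss <- bce_loss(val_prob, yva)
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                      val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        train_loss, val_loss))
      }
      if (val_loss < best_val) {
        best_val <- val_loss; best_epoch <- epoch; wait <- 0L
        if (cfg$restore_best) best_params <- model$params
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) { stopped <- epoch; break }
      }
    }
    if (cfg$restore_best && !is.null(best_params)) model$params <- best_params
    structure(list(model = model,
                   log = do.call(rbind, Filter(Negate(is.null), log_rows)),
                   stopped_epoch = min(stopped, cfg$max_epochs),
                   best_epoch = best_epoch,
                   train_ids = ds$id),
              class = "nucnet_trained")
  })
}

#' Partition a dataset into cross-validation folds
#'
#' Fold sizes differ by at most one; with `stratified = TRUE` (default) each
#' class is dealt round-robin so per-fold class counts also differ from
#' proportional by at most one. Deterministic from `seed`.
#'
#' @param ds A `nucnet_dataset` (or an integer/binary label vector).
#' @param k Number of folds (>= 2).
#' @param stratified Preserve class proportions per fold.
#' @param seed Integer seed.
#' @return A list of class `nucnet_folds`: `k`, `assignments` (fold index
#'   per sequence), `stratified`.
#' @export
make_folds <- function(ds, k = 20L, stratified = TRUE, seed = 1L) {
  labels <- if (inherits(ds, "nucnet_dataset")) ds$label else as.integer(ds)
  n <- length(labels)
  if (!is_count(k) || k < 2L) stopf("k must be an integer >= 2")
  if (k > n) stopf("k (%d) exceeds dataset size (%d)", k, n)
  if (stratified && any(table(factor(labels, levels = 0:1)) < k)) {
    stopf("stratified folding needs at least k members of each class")
  }
  assignments <- integer(n)
  with_seed(seed, {
    if (stratified) {
      ptr <- 0L  # continue round-robin across classes so totals differ <= 1
      for (cls in c(1L, 0L)) {
        idx <- which(labels == cls)
        idx <- idx[sample.int(length(idx))]
        folds <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
        assignments[idx] <- folds
        ptr <- (ptr + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      assignments[idx] <- ((seq_len(n) - 1L) %% k) + 1L
    }
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 stratified = isTRUE(stratified)),
            class = "nucnet_folds")
}

#' k-fold cross-validation of a network
#'
#' For each fold: build a fresh model, train on the remaining folds with the
#' given protocol, score the held-out fold and compute accuracy, sensitivity,
#' specificity, Matthews correlation and ROC AUC. Reports per-fold values and
#' mean +/- standard deviation aggregates.
#'
#' @param ds A `nucnet_dataset`.
#' @param folds A [make_folds()] plan (default: 20 stratified folds seeded
#'   from `train_cfg$seed`).
#' @param architecture One of `"corenup"`, `"convnet"`, `"lstm"`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param trainer Optional override: a `function(train_ds, fold_seed)`
#'   returning a scoring `function(test_ds) -> probabilities`. When supplied,
#'   `architecture`/`model_cfg`/`train_cfg` training is bypassed (used for
#'   protocol tests with stub classifiers).
#' @return An object of class `nucnet_cv`: list with `per_fold` (data frame:
#'   fold, acc, sens, spec, mcc, auc), `mean`, `sd` (named numeric vectors)
#'   and `k`.
#' @export
cross_validate <- function(ds, folds = NULL, architecture = "corenup",
                           model_cfg = model_config(), train_cfg = train_config(),
                           trainer = NULL) {
  stopifnot(inherits(ds, "nucnet_dataset"))
  if (is.null(folds)) folds <- make_folds(ds, 20L, TRUE, train_cfg$seed)
  stopifnot(inherits(folds, "nucnet_folds"),
            length(folds$assignments) == length(ds$seq))
  if (is.null(trainer)) {
    trainer <- function(train_ds, fold_seed) {
      cfg_f <- train_cfg; cfg_f$seed <- fold_seed
      model <- build_model(architecture, model_cfg, seed = fold_seed)
      fit <- train_network(model, train_ds, cfg_f)
      function(test_ds) predict_network(fit$model, test_ds)
    }
  }
  rows <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$assignments == f)
    train_ds <- ds[-test_idx]
    test_ds <- ds[test_idx]
    score <- trainer(train_ds, train_cfg$seed + f)
    prob <- score(test_ds)
    m <- evaluate_scores(prob, test_ds$label, train_cfg$decision_threshold)
    rows[[f]] <- data.frame(fold = f, t(m))
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("acc", "sens", "spec", "mcc", "auc")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metrics]),
                 sd = vapply(per_fold[metrics], stats::sd, numeric(1)),
                 k = folds$k),
            class = "nucnet_cv")
}

#' @export
print.nucnet_cv <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold cross-validation (mean +/- sd over folds)\n", x$k))
  for (m in names(x$mean)) {
    cat(sprintf("  %-5s %.*f +/- %.*f\n", toupper(m), digits, x$mean[[m]],
                digits, x$sd[[m]]))
  }
  invisible(x)
}

#' Bootstrap resampling evaluation on a held-out pool
#'
#' Draws `n_samples` samples of `sample_size` sequences each, with
#' replacement, from a test pool disjoint from the training data, and
#' computes the ROC AUC for each draw; the summary statistic is the mean AUC
#' over draws. A draw containing a single class (AUC undefined) is redrawn
#' and the event logged via `message()`.
#'
#' @param score_fn A fitted `nucnet` object, a `nucnet_model`, or a
#'   `function(dataset) -> probabilities`.
#' @param pool A `nucnet_dataset` test pool.
#' @param n_samples Number of bootstrap draws (default 100).
#' @param sample_size Sequences per draw (default 100).
#' @param seed Integer seed; the full list of AUCs is reproducible from it.
#' @param train_ids Character vector of ids used in training; an id overlap
#'   with the pool is an error. Extracted automatically from fitted objects
#'   that record them.
#' @return A list of class `nucnet_resample`: `auc` (length `n_samples`),
#'   `mean_auc`, `sd_auc`, `n_redrawn`.
#' @export
resample_evaluate <- function(score_fn, pool, n_samples = 100L,
                              sample_size = 100L, seed = 1L,
                              train_ids = NULL) {
  stopifnot(inherits(pool, "nucnet_dataset"))
  if (inherits(score_fn, "nucnet")) {
    train_ids <- train_ids %||% score_fn$train_ids
    object <- score_fn
    score_fn <- function(d) predict(object, d)
  } else if (inherits(score_fn, "nucnet_model")) {
    model <- score_fn
    score_fn <- function(d) predict_network(model, d)
  }
  stopifnot(is.function(score_fn))
  if (!is.null(train_ids) && length(intersect(train_ids, pool$id)) > 0L) {
    stopf("test pool overlaps the training set: %d shared id(s)",
          length(intersect(train_ids, pool$id)))
  }
  n_pool <- length(pool$seq)
  if (n_pool < sample_size) {
    stopf("pool size (%d) smaller than sample_size (%d)", n_pool, sample_size)
  }
  scores <- score_fn(pool)   # score the pool once; draws reuse the scores
  stopifnot(length(scores) == n_pool)
  with_seed(seed, {
    aucs <- numeric(n_samples)
    redrawn <- 0L
    for (s in seq_len(n_samples)) {
      repeat {
        idx <- sample.int(n_pool, sample_size, replace = TRUE)
        if (length(unique(pool$label[idx])) == 2L) break
        redrawn <- redrawn + 1L
        message(sprintf("resample_evaluate: draw %d had a single class; redrawn", s))
      }
      aucs[s] <- roc_auc(scores[idx], pool$label[idx])$auc
    }
    structure(list(auc = aucs, mean_auc = mean(aucs),
                   sd_auc = stats::sd(aucs), n_redrawn = redrawn),
              class = "nucnet_resample")
  })
}

#' @export
print.nucnet_resample <- function(x, ...) {
  cat(sprintf("Bootstrap evaluation: %d draws, mean AUC %.3f +/- %.3f\n",
              length(x$auc), x$mean_auc, x$sd_auc))
  invisible(x)
}
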