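#' Fit a nucleosome-vs-linker sequence classifier
#'
#' The package's front-end fitting function. Builds the requested network
#' architecture, trains it with the standard protocol (Adam on binary
#' cross-entropy with L2 weight decay, stratified validation split, early
#' stopping on validation loss) and returns a fitted-model object with the
#' usual accessor methods (`print`, `summary`, `predict`, `coef`, `fitted`,
#' `residuals`, `plot`).
#'
#' @param data A `nucnet_dataset` (see [labeled_dataset()], [read_dataset()]
#'   or [simulate_dataset()]).
#' @param architecture `"corenup"` (hybrid convolutional-recurrent, the
#'   default), `"convnet"` (two convolution blocks) or `"lstm"`
#'   (convolution + recurrent path only).
#' @param model A [model_config()].
#' @param training A [train_config()].
#' @param seed Convenience override: when non-`NULL`, replaces
#'   `training$seed` and seeds the weight initialization.
#' @param verbose Print per-epoch losses.
#' @return An object of class `nucnet`: list with `architecture`, `model_cfg`,
#'   `train_cfg`, `params` (trained weights), `log` (per-epoch losses),
#'   `stopped_epoch`, `best_epoch`, `fitted_values` (training-data
#'   probabilities, dropout off), `y` (labels), `train_ids`, `call`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(simulation_config(n_per_class = 60, length = 60,
#'                                          seed = 3))
#' fit <- nucnet(ds, model = model_config(input_length = 60, conv1_filters = 8,
#'                                        lstm_units = 8, conv2_filters = 8,
#'                                        dense_units = 16),
#'               training = train_config(max_epochs = 3), seed = 1)
#' fit
#' head(predict(fit, ds))
#' }
#' @export
nucnet <- function(data, architecture = c("corenup", "convnet", "lstm"),
                   model = model_config(), training = train_config(),
                   seed = NULL, verbose = FALSE) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(data, "nucnet_dataset"))
  if (!is.null(seed)) training$seed <- as.integer(seed)
  net <- build_model(architecture, model, seed = training$seed)
  fit <- train_network(net, data, training, verbose = verbose)
  fitted_values <- predict_network(fit$model, data)
  structure(list(architecture = architecture,
                 model_cfg = model, train_cfg = training,
                 params = fit$model$params,
                 log = fit$log,
                 stopped_epoch = fit$stopped_epoch,
                 best_epoch = fit$best_epoch,
                 fitted_values = fitted_values,
                 y = data$label,
                 train_ids = fit$train_ids,
                 call = match.call()),
            class = "nucnet")
}

# rebuild the nucnet_model view of a fitted object (for predict_network etc.)
as_model <- function(object) {
  structure(list(architecture = object$architecture, cfg = object$model_cfg,
                 params = object$params,
                 shapes = model_shapes(object$model_cfg, object$architecture)),
            class = "nucnet_model")
}

#' @export
print.nucnet <- function(x, ...) {
  s <- count_parameters(as_model(x))
  cat("Nucleosome-linker sequence classifier\n")
  cat(sprintf("  architecture: %s (%s trainable parameters)\n", x$architecture,
              format(s$grand_total, big.mark = ",")))
  cat(sprintf("  input: %d bp one-hot sequences\n", x$model_cfg$input_length))
  cat(sprintf("  training: stopped at epoch %d (best validation at epoch %d)\n",
              x$stopped_epoch, x$best_epoch))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final losses: train %.4f, validation %.4f\n",
              last$train_loss, last$val_loss))
  acc <- accuracy(confusion(x$fitted_values, x$y, x$train_cfg$decision_threshold))
  cat(sprintf("  training-set accuracy at threshold %.2f: %.3f\n",
              x$train_cfg$decision_threshold, acc))
  invisible(x)
}

#' Predict method for fitted classifiers
#'
#' @param object A fitted `nucnet` object.
#' @param newdata A `nucnet_dataset`, a character vector of sequences, or a
#'   one-hot array `(N, L, 4)`.
#' @param type `"response"` for probabilities (default) or `"class"` for 0/1
#'   labels at `threshold`.
#' @param threshold Decision threshold for `type = "class"`; defaults to the
#'   fitted object's training threshold.
#' @param batch_size Sequences per forward pass.
#' @param ... Ignored.
#' @return Numeric vector of probabilities, or integer 0/1 labels.
#' @export
predict.nucnet <- function(object, newdata, type = c("response", "class"),
                           threshold = NULL, batch_size = 256L, ...) {
  type <- match.arg(type)
  prob <- predict_network(as_model(object), newdata, batch_size = batch_size)
  if (type == "response") return(prob)
  threshold <- threshold %||% object$train_cfg$decision_threshold
  as.integer(prob >= threshold)
}

#' @export
coef.nucnet <- function(object, ...) object$params

#' @export
fitted.nucnet <- function(object, ...) object$fitted_values

#' @export
residuals.nucnet <- function(object, ...) object$y - object$fitted_values

#' @export
summary.nucnet <- function(object, ...) {
  structure(list(network = count_parameters(as_model(object)),
                 log = object$log,
                 stopped_epoch = object$stopped_epoch,
                 best_epoch = object$best_epoch,
                 train_metrics = evaluate_scores(object$fitted_values, object$y,
                                                 object$train_cfg$decision_threshold)),
            class = "summary.nucnet")
}

#' @export
print.summary.nucnet <- function(x, ...) {
  print(x$network)
  cat(sprintf("\nTraining stopped at epoch %d (best validation epoch %d)\n",
              x$stopped_epoch, x$best_epoch))
  cat("Training-set metrics:\n")
  for (m in names(x$train_metrics)) {
    cat(sprintf("  %-5s %.3f\n", toupper(m), x$train_metrics[[m]]))
  }
  invisible(x)
}

#' Plot training and validation loss curves
#'
#' @param x A fitted `nucnet` object.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.nucnet <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "b", pch = c(1, 2), lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = c("training", "validation"),
                   col = c("steelblue", "firebrick"), pch = c(1, 2), lty = 1,
                   bty = "n")
  invisible(x)
}
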