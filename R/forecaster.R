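#' Forecaster hyperparameters
#'
#' One shared configuration for all three feature sets — the comparison is
#' only fair if the network is identical and untuned across inputs. The
#' defaults: a single LSTM layer of 32 hidden units, dropout 0.2 on the
#' final hidden state, sigmoid output, class-weighted binary cross-entropy,
#' Adam at 1e-3, batch 64, at most 100 epochs with early stopping on
#' validation loss (patience 10).
#'
#' @param hidden Hidden units in the recurrent layer.
#' @param dropout Dropout rate on the final hidden state during training.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param class_weight Weight classes inversely to prevalence.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return A `forecaster_config` object.
#' @export
forecaster_config <- function(hidden = 32L, dropout = 0.2,
                              learning_rate = 1e-3, batch_size = 64L,
                              max_epochs = 100L, patience = 10L,
                              class_weight = TRUE, seed = 1L) {
  stopifnot(hidden >= 1, dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weight = isTRUE(class_weight),
                 seed = as.integer(seed)),
            class = "forecaster_config")
}

#' Train the LSTM exacerbation-event forecaster
#'
#' Trains a masked variable-length-sequence LSTM classifier on the training
#' samples, monitoring the validation samples each epoch; training stops
#' when validation loss has not improved for `config$patience` epochs and
#' the best-validation weights are kept. Class imbalance is handled by
#' weighting the loss inversely to class prevalence in the training set.
#' With a fixed seed the run is fully deterministic (single-threaded).
#'
#' @param train_samples,val_samples `forecast_samples` objects.
#' @param config A [forecaster_config()].
#' @return An `lstm_forecaster`: list with `weights`, `config`,
#'   `n_features`, `history` (per-epoch train/validation loss),
#'   `best_epoch`.
#' @export
train_forecaster <- function(train_samples, val_samples,
                             config = forecaster_config()) {
  tr <- pack_samples(train_samples)
  va <- pack_samples(val_samples)
  if (dim(tr$x)[1] != dim(va$x)[1]) {
    stop("train and validation feature counts differ", call. = FALSE)
  }
  n_pos <- sum(tr$y == 1)
  n_neg <- sum(tr$y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("training labels contain a single class; cannot train", call. = FALSE)
  }
  if (config$class_weight) {
    n <- n_pos + n_neg
    w_pos <- n / (2 * n_pos)
    w_neg <- n / (2 * n_neg)
  } else {
    w_pos <- w_neg <- 1
  }
  fit <- .lstm_train(tr$x, tr$mask, as.numeric(tr$y),
                     va$x, va$mask, as.numeric(va$y),
                     config$hidden, config$dropout, config$learning_rate,
                     config$batch_size, config$max_epochs, config$patience,
                     w_pos, w_neg, config$seed)
  structure(list(weights = fit$weights,
                 config = config,
                 n_features = dim(tr$x)[1],
                 class_weights = c(pos = w_pos, neg = w_neg),
                 history = data.frame(epoch = seq_along(fit$train_loss),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss),
                 best_epoch = fit$best_epoch,
                 epochs_run = fit$epochs_run),
            class = "lstm_forecaster")
}

#' @export
print.lstm_forecaster <- function(x, ...) {
  cat("<lstm_forecaster> ", x$config$hidden, " hidden units, ",
      x$n_features, " features/day; trained ", x$epochs_run,
      " epoch(s), best validation loss at epoch ", x$best_epoch, "\n",
      sep = "")
  invisible(x)
}

#' Predict exacerbation-event probabilities
#'
#' @param object A trained `lstm_forecaster`.
#' @param samples A `forecast_samples` object built with the same feature
#'   set the model was trained on.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\], one per sample, in
#'   sample order.
#' @export
predict.lstm_forecaster <- function(object, samples, ...) {
  if (!length(samples$windows)) {
    return(numeric(0))
  }
  pk <- pack_samples(samples)
  if (dim(pk$x)[1] != object$n_features) {
    stop("sample feature count (", dim(pk$x)[1],
         ") does not match the model (", object$n_features, ")",
         call. = FALSE)
  }
  as.numeric(.lstm_predict(object$weights, pk$x, pk$mask,
                           object$config$batch_size))
}
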