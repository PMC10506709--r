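#' Train the 1-D CNN with early stopping on validation F1
#'
#' Minibatch RMSprop on (optionally class-weighted) binary cross-entropy.
#' After every epoch the validation F1 at threshold 0.5 is computed; the
#' best-scoring weights are checkpointed and training stops once `patience`
#' consecutive epochs bring no improvement (or at `max_epochs`). All
#' randomness (shuffling, dropout) runs under the config seed, so repeated
#' runs from the same initialized model reproduce identical histories.
#'
#' @param model A [build_cnn()] model (its initialized weights are the
#'   starting point; the input object is not modified).
#' @param train Labeled `window_dataset` used for gradient updates.
#' @param validation Non-empty labeled `window_dataset` scored each epoch.
#' @param class_weights Optional class-weight tibble from
#'   [compute_class_weights()] (or a named numeric vector with names `"0"`
#'   and `"1"`); the SMOTE-free route to class balance.
#' @param verbose Print one line per epoch.
#' @return An object of class `cnn1d_fit`: list with `model` (best
#'   checkpoint), `history` (tibble: epoch, loss, val_loss, val_precision,
#'   val_recall, val_f1), `best_epoch` and `best_val_f1`.
#' @export
train_cnn <- function(model, train, validation, class_weights = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn1d"), inherits(train, "window_dataset"),
            inherits(validation, "window_dataset"))
  cfg <- model$config
  if (n_windows(train) == 0L) abort("Empty training set.")
  if (n_windows(validation) == 0L) {
    abort("Empty validation set: early stopping is undefined.")
  }
  if (train$width != model$width || train$dim != model$dim) {
    abort(sprintf("Training windows are %d x %d but the model expects %d x %d",
                  train$width, train$dim, model$width, model$dim))
  }
  if (anyNA(train$y) || anyNA(validation$y)) {
    abort("Training and validation labels must be known (0/1).")
  }

  wts <- c("0" = 1, "1" = 1)
  if (!is.null(class_weights)) {
    if (is.data.frame(class_weights)) {
      wts <- setNames(class_weights$weight, as.character(class_weights$class))
    } else {
      wts <- class_weights
    }
    if (!all(c("0", "1") %in% names(wts))) {
      abort("`class_weights` must provide weights for classes 0 and 1.")
    }
  }
  sw_all <- unname(wts[as.character(train$y)])

  N <- n_windows(train)
  weights <- model$weights
  opt <- rmsprop_init(weights)
  best <- list(f1 = -Inf, epoch = 0L, weights = weights)
  wait <- 0L
  hist <- vector("list", cfg$max_epochs)

  run <- with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(N)
      epoch_loss <- 0
      for (start in seq.int(1L, N, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, N)]
        Xb <- train$X[idx, , , drop = FALSE]
        yb <- train$y[idx]
        swb <- sw_all[idx]
        fwd <- cnn_forward(weights, cfg, Xb, training = TRUE,
                           keep_cache = TRUE)
        grads <- cnn_backward(weights, cfg, fwd, yb, swb)
        step <- rmsprop_step(weights, grads, opt, lr = cfg$learning_rate)
        weights <- step$weights
        opt <- step$state
        epoch_loss <- epoch_loss + bce_loss(fwd$prob, yb, swb) * length(idx)
      }
      val <- predict_scores(weights, cfg, validation$X)
      vm <- evaluate_predictions(validation$y, val, threshold = 0.5)
      val_f1 <- if (is.na(vm$f1)) 0 else vm$f1
      hist[[epoch]] <- tibble(
        epoch = epoch,
        loss = epoch_loss / N,
        val_loss = bce_loss(val, validation$y, rep(1, length(val))),
        val_precision = vm$precision, val_recall = vm$recall,
        val_f1 = val_f1
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val F1 %.4f",
                        epoch, epoch_loss / N, val_f1))
      }
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, epoch = epoch, weights = weights)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) break
      }
    }
    list(best = best, hist = dplyr::bind_rows(hist))
  })

  out_model <- model
  out_model$weights <- run$best$weights
  structure(
    list(model = out_model, history = run$hist,
         best_epoch = run$best$epoch, best_val_f1 = run$best$f1),
    class = "cnn1d_fit"
  )
}

# batched forward pass without dropout
predict_scores <- function(weights, cfg, X, chunk = 512L) {
  N <- dim(X)[1]
  if (N == 0L) return(numeric(0))
  out <- numeric(N)
  for (start in seq.int(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    out[idx] <- cnn_forward(weights, cfg, X[idx, , , drop = FALSE])$prob
  }
  out
}

#' @export
print.cnn1d_fit <- function(x, ...) {
  cat(sprintf(
    "<cnn1d_fit> %d epochs run, best epoch %d (validation F1 %.4f)\n",
    nrow(x$history), x$best_epoch, x$best_val_f1
  ))
  invisible(x)
}

#' Score windows with a fitted (or fresh) model
#'
#' @param object A `cnn1d_fit` (uses the best checkpoint) or `cnn1d`.
#' @param newdata A `window_dataset` (or N x width x D array).
#' @param threshold Decision threshold on the sigmoid score (default 0.5);
#'   a window is called a hotspot when `score >= threshold`.
#' @param ... Unused.
#' @return A tibble with the window `meta` columns (when available) plus
#'   `score` in \[0, 1\] and integer `label`.
#' @export
predict.cnn1d <- function(object, newdata, threshold = 0.5, ...) {
  if (inherits(newdata, "window_dataset")) {
    if (newdata$width != object$width || newdata$dim != object$dim) {
      abort(sprintf("Windows are %d x %d but the model expects %d x %d",
                    newdata$width, newdata$dim, object$width, object$dim))
    }
    X <- newdata$X
    meta <- newdata$meta
  } else {
    X <- newdata
    if (length(dim(X)) != 3L || dim(X)[2] != object$width ||
        dim(X)[3] != object$dim) {
      abort("`newdata` must be an N x width x D array matching the model.")
    }
    meta <- NULL
  }
  score <- predict_scores(object$weights, object$config, X)
  res <- tibble(score = score, label = as.integer(score >= threshold))
  if (!is.null(meta)) res <- dplyr::bind_cols(meta, res)
  res
}

#' @rdname predict.cnn1d
#' @export
predict.cnn1d_fit <- function(object, newdata, threshold = 0.5, ...) {
  predict(object$model, newdata, threshold = threshold, ...)
}

#' @export
tidy.cnn1d_fit <- function(x, ...) x$history

#' @export
glance.cnn1d_fit <- function(x, ...) {
  tibble(
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_f1 = x$best_val_f1,
    n_params = x$model$n_params
  )
}

#' Plot a training history
#'
#' Training/validation loss and validation F1 by epoch, with the checkpointed
#' best epoch marked.
#'
#' @param object A `cnn1d_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn1d_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$history[c("epoch", "loss", "val_loss", "val_f1")],
    -"epoch", names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL,
                  title = "1-D CNN training history") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @inheritParams roc_curve
#' @return A ggplot object annotated with the AUC.
#' @export
plot_roc <- function(truth, score) {
  rc <- roc_curve(truth, score)
  auc <- roc_auc(truth, score)
  ggplot2::ggplot(rc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", auc)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC") +
    ggplot2::theme_minimal()
}
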