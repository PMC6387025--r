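## har_cnn(): the single fitting entry point for both the 11-way recognition
## network and the per-exercise binary counting networks.

#' Fit a convolutional window classifier
#'
#' Trains the convolutional architecture of [model_spec()] on a pool of
#' labeled windows with plain stochastic gradient descent on the
#' cross-entropy loss. Batches are sampled i.i.d. uniformly with replacement
#' from the pool. If a validation pool is given, training stops early once
#' the validation loss has not improved for `control$patience` epochs and
#' the best-validation-loss weights are returned.
#'
#' @param x Window pool: array `W x channels x n` (or a `window_set`).
#' @param y Labels, length `n` (factor or character).
#' @param spec A [model_spec()].
#' @param control A [train_control()].
#' @param validation Optional list with elements `x` and `y`: held-out pool
#'   used for early stopping.
#' @param classes Optional class levels (defaults to sorted unique `y`).
#' @param verbose Print per-epoch progress.
#' @return Object of class `har_cnn` with elements `params` (weights),
#'   `spec`, `control`, `classes`, `norm` (per-channel standardization),
#'   `history` (per-epoch losses), `best_epoch`, `input_shape`.
#' @export
har_cnn <- function(x, y, spec = model_spec(), control = train_control(),
                    validation = NULL, classes = NULL, verbose = FALSE) {
  if (inherits(x, "window_set")) x <- x$data
  stopifnot(is.array(x), length(dim(x)) == 3L)
  y <- as.character(y)
  n <- dim(x)[3]
  if (n < 1L) stop("empty training pool", call. = FALSE)
  if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(y))
  if (!all(y %in% classes)) stop("labels outside the class set", call. = FALSE)
  y_idx <- match(y, classes)
  if (!is.null(control$seed)) set.seed(control$seed)

  norm <- NULL
  if (spec$input_norm) {
    mu <- apply(x, 2, mean)
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ < 1e-8] <- 1
    norm <- list(mu = mu, sd = sd_)
    x <- sweep(sweep(x, 2, mu, "-"), 2, sd_, "/")
  }
  input_shape <- dim(x)[1:2]
  params <- init_cnn_params(spec, input_shape, length(classes))

  has_val <- !is.null(validation)
  if (has_val) {
    xv <- if (inherits(validation$x, "window_set")) validation$x$data else validation$x
    if (!is.null(norm)) xv <- sweep(sweep(xv, 2, norm$mu, "-"), 2, norm$sd, "/")
    yv_idx <- match(as.character(validation$y), classes)
    if (anyNA(yv_idx)) stop("validation labels outside the class set", call. = FALSE)
  }

  bpe <- control$batches_per_epoch
  if (is.null(bpe)) bpe <- max(1L, as.integer(ceiling(n / control$batch_size)))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    tl <- 0
    for (b in seq_len(bpe)) {
      idx <- sample_training_batch(n, control$batch_size)
      Xb <- x[, , idx, drop = FALSE]
      fw <- cnn_forward(params, spec, Xb, training = TRUE, keep_cache = TRUE)
      loss <- cross_entropy(fw$prob, y_idx[idx])
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d batch %d (learning rate %g)",
                     epoch, b, control$learning_rate), call. = FALSE)
      }
      tl <- tl + loss
      grads <- cnn_backward(params, spec, fw, y_idx[idx])
      params <- sgd_update(params, grads, control$learning_rate)
    }
    tl <- tl / bpe
    vl <- NA_real_; va <- NA_real_
    if (has_val) {
      pv <- predict_engine(params, spec, xv)
      vl <- cross_entropy(pv, yv_idx)
      va <- mean(max.col(pv, ties.method = "first") == yv_idx)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl, val_acc = va))
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f  val %.4f  acc %.4f\n",
                  epoch, tl, vl, va))
    }
    if (has_val && stale >= control$patience) break
  }
  if (has_val && best$epoch > 0L) {
    params <- best$params
  } else {
    best$epoch <- nrow(history)
  }
  structure(list(params = params, spec = spec, control = control,
                 classes = classes, norm = norm, history = history,
                 best_epoch = best$epoch, input_shape = input_shape,
                 call = match.call()),
            class = "har_cnn")
}

## forward in evaluation mode, chunked to bound memory
predict_engine <- function(params, spec, x, chunk = 64L) {
  n <- dim(x)[3]
  K <- params$n_classes
  P <- matrix(0, n, K)
  at <- 1L
  while (at <= n) {
    hi <- min(n, at + chunk - 1L)
    P[at:hi, ] <- cnn_forward(params, spec, x[, , at:hi, drop = FALSE])$prob
    at <- hi + 1L
  }
  P
}

#' Predict from a fitted window classifier
#'
#' @param object A fitted [har_cnn()].
#' @param x Windows: array `W x channels x n` or a `window_set`.
#' @param type `"class"` for argmax labels (ties to the lowest class index)
#'   or `"prob"` for the full probability matrix.
#' @param ... Unused.
#' @return Character vector of labels or a numeric probability matrix whose
#'   rows sum to 1.
#' @export
predict.har_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(x, "window_set")) x <- x$data
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (!all(dim(x)[1:2] == object$input_shape)) {
    stop(sprintf("window shape (%d, %d) does not match model input (%d, %d)",
                 dim(x)[1], dim(x)[2],
                 object$input_shape[1], object$input_shape[2]), call. = FALSE)
  }
  if (!is.null(object$norm)) {
    x <- sweep(sweep(x, 2, object$norm$mu, "-"), 2, object$norm$sd, "/")
  }
  P <- predict_engine(object$params, object$spec, x)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' @export
print.har_cnn <- function(x, ...) {
  cat(sprintf("<har_cnn> %d-class window classifier, input %d x %d\n",
              length(x$classes), x$input_shape[1], x$input_shape[2]))
  print(x$spec)
  cat(sprintf("  %s parameters, trained %d epochs (best epoch %d)\n",
              format(count_params(x$params), big.mark = ","),
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' @export
summary.har_cnn <- function(object, ...) {
  h <- object$history
  cat("Classes:", paste(object$classes, collapse = ", "), "\n")
  print(object)
  cat(sprintf("  final train loss %.4f", h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_loss))) {
    cat(sprintf(", best val loss %.4f (acc %.4f) at epoch %d",
                min(h$val_loss, na.rm = TRUE),
                h$val_acc[object$best_epoch], object$best_epoch))
  }
  cat("\n")
  invisible(object)
}

#' @export
coef.har_cnn <- function(object, ...) object$params[c("conv", "dense")]

#' Plot the training history
#'
#' @param x A fitted [har_cnn()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.har_cnn <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", ylim = ylim, ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
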