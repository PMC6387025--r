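## Architecture and training configuration. Recognition defaults: five
## convolutional layers with
## 100/75/25/25/75 filters, a (15, 3) first kernel applied with a vertical
## stride of 3 (one sensor-axis triplet per step, so axes of different
## sensors are never mixed), dropout 0.5, two fully connected layers, and a
## softmax output. Training: batch size 30, plain SGD at learning rate 1e-4,
## cross-entropy loss, at most 100 epochs with early stopping.

#' Convolutional architecture specification
#'
#' The same base architecture serves exercise recognition (one model,
#' 10 exercises + null) and repetition counting (one binary model per
#' exercise). The first layer convolves a (`kernel_time`, 3) kernel with
#' vertical stride 3 over the stacked channels, producing one feature column
#' per sensor; deeper layers convolve (`kernel_time`, 1) kernels along time
#' with valid padding and no pooling.
#'
#' @param filters Integer vector of filter counts, one per convolutional
#'   layer (default `c(100, 75, 25, 25, 75)`).
#' @param kernel_time Temporal kernel extent in samples (default 15).
#' @param dense Widths of the fully connected hidden layers before the
#'   softmax output (default 128; the output layer is added automatically).
#' @param extra_dense If `TRUE`, append two extra dense layers of half the
#'   last hidden width (a counting-model variant).
#' @param dropout Dropout rate applied to the flattened features and each
#'   dense hidden activation during training (default 0.5).
#' @param activation `"relu"` or `"elu"`.
#' @param input_norm If `TRUE` (default), standardize each channel by the
#'   training pool mean and standard deviation.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(filters = c(100, 75, 25, 25, 75), kernel_time = 15,
                       dense = 128, extra_dense = FALSE, dropout = 0.5,
                       activation = c("relu", "elu"), input_norm = TRUE) {
  activation <- match.arg(activation)
  filters <- as.integer(filters)
  stopifnot(length(filters) >= 1L, all(filters >= 1L),
            kernel_time >= 1L, all(dense >= 1L),
            dropout >= 0, dropout < 1)
  dense <- as.integer(dense)
  if (isTRUE(extra_dense)) {
    dense <- c(dense, rep(max(1L, dense[length(dense)] %/% 2L), 2L))
  }
  structure(list(filters = filters, kernel_time = as.integer(kernel_time),
                 dense = dense, dropout = dropout, activation = activation,
                 input_norm = isTRUE(input_norm)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(paste0("<model_spec> %d conv layers (filters %s, kernel (%d, 3)",
                     " stride 3 then (%d, 1)), dense %s, dropout %.2f, %s\n"),
              length(x$filters), paste(x$filters, collapse = "/"),
              x$kernel_time, x$kernel_time,
              paste(x$dense, collapse = "/"), x$dropout, x$activation))
  invisible(x)
}

#' Training configuration
#'
#' @param batch_size Windows per SGD batch (default 30); batches are drawn
#'   i.i.d. uniformly with replacement from the training pool.
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param max_epochs Maximum number of epochs (default 100).
#' @param patience Early-stopping patience in epochs on validation loss
#'   (default 10); ignored when no validation pool is supplied.
#' @param batches_per_epoch Batches per epoch; default
#'   `ceiling(n_pool / batch_size)`.
#' @param seed Optional integer seed fixing initialization, batch sampling
#'   and dropout; identical seeds give identical training histories.
#' @return Object of class `train_control`.
#' @export
train_control <- function(batch_size = 30, learning_rate = 1e-4,
                          max_epochs = 100, patience = 10,
                          batches_per_epoch = NULL, seed = NULL) {
  stopifnot(batch_size >= 1L, learning_rate > 0, max_epochs >= 1L,
            patience >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batches_per_epoch = batches_per_epoch,
                 seed = seed),
            class = "train_control")
}
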