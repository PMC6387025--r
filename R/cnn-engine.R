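## Numerical engine for the convolutional networks. Convolutions are
## evaluated as sums of offset matrix products (one GEMM per temporal kernel
## offset), which keeps all heavy lifting inside BLAS. Activations are laid
## out as matrices of (time, sensor-column, window) rows by feature columns,
## so the deeper (k, 1) convolutions treat each sensor column of each window
## as an independent sequence with shared weights.

act_forward <- function(Z, activation) {
  if (activation == "relu") {
    Z[Z < 0] <- 0
    Z
  } else {                                   # elu, alpha = 1
    neg <- Z < 0
    Z[neg] <- exp(Z[neg]) - 1
    Z
  }
}

## derivative of the activation expressed through the post-activation value A
act_grad <- function(A, activation) {
  if (activation == "relu") {
    (A > 0) + 0
  } else {
    G <- matrix(1, nrow(A), ncol(A))
    neg <- A < 0
    G[neg] <- A[neg] + 1
    G
  }
}

## He-scaled Gaussian initialization
init_cnn_params <- function(spec, input_shape, n_classes) {
  W_len <- input_shape[1]; C <- input_shape[2]
  if (C %% 3L != 0L) {
    stop("channel count must be divisible by 3 (sensor-axis triplets)",
         call. = FALSE)
  }
  k <- spec$kernel_time
  H <- W_len
  conv <- vector("list", length(spec$filters))
  fin <- 3L
  for (l in seq_along(spec$filters)) {
    fout <- spec$filters[l]
    H <- H - k + 1L
    if (H < 1L) {
      stop(sprintf("window of %d samples too short for %d conv layers of kernel %d",
                   W_len, length(spec$filters), k), call. = FALSE)
    }
    conv[[l]] <- list(
      W = array(stats::rnorm(k * fin * fout, sd = sqrt(2 / (k * fin))),
                dim = c(k, fin, fout)),
      b = numeric(fout))
    fin <- fout
  }
  S <- C %/% 3L
  d_in <- H * S * fin
  dense <- vector("list", length(spec$dense) + 1L)
  widths <- c(spec$dense, n_classes)
  for (l in seq_along(widths)) {
    dense[[l]] <- list(
      W = matrix(stats::rnorm(d_in * widths[l], sd = sqrt(2 / d_in)),
                 d_in, widths[l]),
      b = numeric(widths[l]))
    d_in <- widths[l]
  }
  list(conv = conv, dense = dense, H_out = H, S = S,
       input_shape = input_shape, n_classes = n_classes)
}

count_params <- function(params) {
  sum(vapply(c(params$conv, params$dense),
             function(p) length(p$W) + length(p$b), numeric(1)))
}

## Forward pass on a batch X (array W x C x B). Returns output probabilities
## and, if keep_cache, everything backward() needs.
cnn_forward <- function(params, spec, X, training = FALSE, keep_cache = FALSE) {
  d <- dim(X)
  H <- d[1]; C <- d[2]; B <- d[3]
  S <- C %/% 3L
  k <- spec$kernel_time
  n_blocks <- S * B
  ## rows ordered (t, s, b), columns = the 3 axes of one sensor
  M <- matrix(aperm(array(X, c(H, 3L, S, B)), c(1L, 3L, 4L, 2L)), ncol = 3L)
  convs <- list()
  for (l in seq_along(params$conv)) {
    p <- params$conv[[l]]
    fout <- dim(p$W)[3]
    Z <- cpp_conv_fwd(M, p$W, H, k, fout, n_blocks)
    Z <- Z + rep(p$b, each = nrow(Z))
    A <- act_forward(Z, spec$activation)
    if (keep_cache) convs[[l]] <- list(M_in = M, A = A, H_in = H)
    M <- A
    H <- H - k + 1L
  }
  ## flatten (t, s, f) per window
  F_L <- ncol(M)
  Xf <- t(matrix(aperm(array(M, c(H, S, B, F_L)), c(1L, 2L, 4L, 3L)),
                 ncol = B))
  denses <- list()
  A <- Xf
  drop_masks <- list()
  if (training && spec$dropout > 0) {
    m <- matrix((stats::runif(length(A)) >= spec$dropout) / (1 - spec$dropout),
                nrow(A), ncol(A))
    A <- A * m
    drop_masks$flat <- m
  }
  n_dense <- length(params$dense)
  for (l in seq_len(n_dense - 1L)) {
    p <- params$dense[[l]]
    Z <- A %*% p$W + rep(p$b, each = nrow(A))
    Ah <- act_forward(Z, spec$activation)
    if (training && spec$dropout > 0) {
      m <- matrix((stats::runif(length(Ah)) >= spec$dropout) / (1 - spec$dropout),
                  nrow(Ah), ncol(Ah))
      if (keep_cache) denses[[l]] <- list(A_in = A, A_out = Ah, mask = m)
      Ah <- Ah * m
    } else if (keep_cache) {
      denses[[l]] <- list(A_in = A, A_out = Ah, mask = NULL)
    }
    A <- Ah
  }
  p <- params$dense[[n_dense]]
  logits <- A %*% p$W + rep(p$b, each = nrow(A))
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits)
  P <- P / rowSums(P)
  out <- list(prob = P)
  if (keep_cache) {
    out$cache <- list(convs = convs, Xf = Xf, drop_flat = drop_masks$flat,
                      denses = denses, A_last = A, H_L = H, S = S, B = B,
                      F_L = F_L, n_blocks = n_blocks)
  }
  out
}

## Backward pass; y_idx are 1-based class indices for the batch.
cnn_backward <- function(params, spec, fw, y_idx) {
  cache <- fw$cache
  B <- cache$B
  P <- fw$prob
  dZ <- P
  dZ[cbind(seq_len(B), y_idx)] <- dZ[cbind(seq_len(B), y_idx)] - 1
  dZ <- dZ / B
  n_dense <- length(params$dense)
  grads <- list(conv = vector("list", length(params$conv)),
                dense = vector("list", n_dense))
  A_in <- if (n_dense > 1L) {
    d <- cache$denses[[n_dense - 1L]]
    if (is.null(d$mask)) d$A_out else d$A_out * d$mask
  } else {
    if (is.null(cache$drop_flat)) cache$Xf else cache$Xf * cache$drop_flat
  }
  grads$dense[[n_dense]] <- list(dW = crossprod(A_in, dZ), db = colSums(dZ))
  dA <- dZ %*% t(params$dense[[n_dense]]$W)
  for (l in rev(seq_len(n_dense - 1L))) {
    d <- cache$denses[[l]]
    if (!is.null(d$mask)) dA <- dA * d$mask
    dZ <- dA * act_grad(d$A_out, spec$activation)
    A_in <- if (l > 1L) {
      prev <- cache$denses[[l - 1L]]
      if (is.null(prev$mask)) prev$A_out else prev$A_out * prev$mask
    } else {
      if (is.null(cache$drop_flat)) cache$Xf else cache$Xf * cache$drop_flat
    }
    grads$dense[[l]] <- list(dW = crossprod(A_in, dZ), db = colSums(dZ))
    dA <- dZ %*% t(params$dense[[l]]$W)
  }
  if (!is.null(cache$drop_flat)) dA <- dA * cache$drop_flat
  ## un-flatten back to ((t, s, b) rows x F) layout
  dM <- matrix(aperm(array(t(dA), c(cache$H_L, cache$S, cache$F_L, B)),
                     c(1L, 2L, 4L, 3L)), ncol = cache$F_L)
  k <- spec$kernel_time
  for (l in rev(seq_along(params$conv))) {
    cv <- cache$convs[[l]]
    p <- params$conv[[l]]
    fin <- dim(p$W)[2]; fout <- dim(p$W)[3]
    dZ <- dM * act_grad(cv$A, spec$activation)
    grads$conv[[l]] <- list(
      dW = cpp_conv_bwd_w(cv$M_in, dZ, cv$H_in, k, cache$n_blocks),
      db = colSums(dZ))
    if (l > 1L) {
      dM <- cpp_conv_bwd_x(dZ, p$W, cv$H_in, k, fin, cache$n_blocks)
    }
  }
  grads
}

sgd_update <- function(params, grads, lr) {
  for (l in seq_along(params$conv)) {
    params$conv[[l]]$W <- params$conv[[l]]$W - lr * grads$conv[[l]]$dW
    params$conv[[l]]$b <- params$conv[[l]]$b - lr * grads$conv[[l]]$db
  }
  for (l in seq_along(params$dense)) {
    params$dense[[l]]$W <- params$dense[[l]]$W - lr * grads$dense[[l]]$dW
    params$dense[[l]]$b <- params$dense[[l]]$b - lr * grads$dense[[l]]$db
  }
  params
}

cross_entropy <- function(P, y_idx) {
  -mean(log(pmax(P[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}
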