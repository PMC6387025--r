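## Subject-grouped evaluation: all data of one participant lands entirely in
## either the training or the test side of every fold, plus the counting
## error metrics (MAE, MRE, |e| buckets).

#' Subject-grouped k-fold plan
#'
#' Participants (never windows) are partitioned into `k` near-equal groups;
#' each group serves once as the test side. Deterministic given `seed`.
#'
#' @param participants Character vector of participant ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the participant shuffle.
#' @return Object of class `fold_plan`: list of `list(train, test)` id
#'   vectors, with attribute `scheme`.
#' @export
grouped_kfold <- function(participants, k = 5, seed = 1) {
  participants <- unique(as.character(participants))
  n <- length(participants)
  if (n < k) stop(sprintf("need at least %d participants for %d folds", k, k),
                  call. = FALSE)
  perm <- withr_seed(seed, sample(participants))
  grp <- sort(rep(seq_len(k), length.out = n))          # near-equal sizes
  folds <- lapply(seq_len(k), function(i) {
    test <- perm[grp == i]
    list(train = setdiff(participants, test), test = test)
  })
  structure(folds, scheme = sprintf("kfold%d", k), class = "fold_plan")
}

## evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Leave-one-subject-out plan
#'
#' One fold per participant; maximizes training data for the per-exercise
#' counting models.
#'
#' @param participants Character vector of participant ids.
#' @return A `fold_plan` with one fold per participant.
#' @export
loso_folds <- function(participants) {
  participants <- unique(as.character(participants))
  if (length(participants) < 2L) {
    stop("LOSO needs at least 2 participants", call. = FALSE)
  }
  folds <- lapply(participants, function(p) {
    list(train = setdiff(participants, p), test = p)
  })
  structure(folds, scheme = "loso", class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s: %d folds, test sizes %s\n", attr(x, "scheme"),
              length(x),
              paste(vapply(x, function(f) length(f$test), integer(1)),
                    collapse = "/")))
  invisible(x)
}

#' Accuracy and row-normalized confusion matrix
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Class order of the confusion matrix (default: union).
#' @return List with `accuracy` and `confusion` (rows = truth, normalized to
#'   sum to 1 for observed classes) and `counts` (raw counts).
#' @export
accuracy_and_confusion <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred lengths differ", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  counts <- table(factor(truth, classes), factor(pred, classes))
  counts <- matrix(counts, length(classes), length(classes),
                   dimnames = list(truth = classes, pred = classes))
  rs <- rowSums(counts)
  confusion <- counts / ifelse(rs == 0, 1, rs)
  list(accuracy = mean(truth == pred), confusion = confusion, counts = counts)
}

#' Repetition-counting error metrics
#'
#' Mean absolute error, mean relative error and the fractions of sets whose
#' count is off by 0, 1, 2 or more than 2 repetitions. Sets with a zero true
#' count are excluded from the MRE with a warning. Sets whose exercise was
#' not recognized (`NA` prediction) are excluded from all metrics and
#' reported in `n_not_recognized`.
#'
#' @param pred,truth Integer vectors of predicted and true counts per set.
#' @return Object of class `counting_metrics`: list with `mae`, `mre`
#'   (fraction), `buckets` (named fractions `e0`, `e1`, `e2`, `gt2`), `n`,
#'   `n_not_recognized`.
#' @export
counting_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ", call. = FALSE)
  }
  nr <- is.na(pred)
  pred <- pred[!nr]; truth <- truth[!nr]
  e <- abs(pred - truth)
  if (any(truth == 0)) {
    warning("sets with zero true count excluded from MRE", call. = FALSE)
  }
  buckets <- c(e0 = mean(e == 0), e1 = mean(e == 1), e2 = mean(e == 2),
               gt2 = mean(e > 2))
  structure(list(mae = mean(e),
                 mre = mean((e / truth)[truth > 0]),
                 buckets = buckets, n = length(e),
                 n_not_recognized = sum(nr)),
            class = "counting_metrics")
}

#' @export
print.counting_metrics <- function(x, ...) {
  cat(sprintf("<counting_metrics> %d sets: MAE %.2f, MRE %.1f%%,", x$n,
              x$mae, 100 * x$mre))
  cat(sprintf(" |e|=0: %.1f%%, |e|=1: %.1f%%, |e|=2: %.1f%%, |e|>2: %.1f%%",
              100 * x$buckets["e0"], 100 * x$buckets["e1"],
              100 * x$buckets["e2"], 100 * x$buckets["gt2"]))
  if (x$n_not_recognized > 0) cat(sprintf(" (%d n.r.)", x$n_not_recognized))
  cat("\n")
  invisible(x)
}
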