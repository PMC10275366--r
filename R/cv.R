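## deterministic stratified fold assignment: within each class, indices are
## shuffled with the seed and dealt round-robin over folds
stratified_folds <- function(y, folds, seed) {
  y <- as_group_factor(y)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (folds == length(y)) return(seq_along(y))   # leave-one-out
  small <- table(y) < folds
  if (any(small))
    stop("class smaller than fold count: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  assignment <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Cross-validated predictive ability (Q2Y) of an OPLS-DA model
#'
#' Stratified K-fold cross-validation: scaling parameters and the model are
#' re-estimated inside each training fold, out-of-fold samples are predicted,
#' and Q2Y = 1 - PRESS / SS with the class code centered by each fold's
#' training mean.
#'
#' @param x samples-by-features matrix.
#' @param y two-level class labels.
#' @param folds number of folds (default 7; `folds = n` gives leave-one-out).
#' @param n_orth orthogonal components per fold model.
#' @param scaling scaling method (re-estimated per fold).
#' @param seed seed for the stratified fold shuffle.
#' @return an `opls_cv` object: `q2y`, `folds`, per-sample `assignment` and
#'   out-of-fold `predicted` (centered scale).
#' @export
cross_validate <- function(x, y, folds = 7L, n_orth = 1L, scaling = "uv",
                           seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as_group_factor(y)
  assignment <- stratified_folds(y, folds, seed)
  y01 <- as.numeric(y) - 1
  pred <- rep(NA_real_, length(y))
  yc <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    test <- assignment == f
    fit <- opls_da(x[!test, , drop = FALSE], y[!test],
                   n_orth = n_orth, scaling = scaling)
    pred[test] <- predict(fit, x[test, , drop = FALSE])
    yc[test] <- y01[test] - fit$y_mean
  }
  q2y <- 1 - sum((yc - pred)^2) / sum(yc^2)
  structure(list(q2y = q2y, folds = as.integer(folds),
                 assignment = assignment, predicted = pred,
                 centered_y = yc, seed = as.integer(seed)),
            class = "opls_cv")
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation: Q2Y = %.3f\n",
              x$folds, x$q2y))
  invisible(x)
}

#' Label-permutation test for an OPLS-DA Q2Y
#'
#' Permutes class labels across the whole cohort `n_perm` times, re-runs the
#' full cross-validation for each permutation, and reports the empirical
#' p-value `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations (>= 20).
#' @return an `opls_permutation` object: `observed` Q2Y, `null` vector,
#'   `p`, `seed`.
#' @export
permutation_test <- function(x, y, n_perm = 99L, folds = 7L, n_orth = 1L,
                             scaling = "uv", seed = 1L) {
  if (n_perm < 20L) stop("need at least 20 permutations", call. = FALSE)
  x <- as_feature_matrix(x)
  y <- as_group_factor(y)
  observed <- cross_validate(x, y, folds = folds, n_orth = n_orth,
                             scaling = scaling, seed = seed)$q2y
  set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(length(y)))
  null <- vapply(seq_len(n_perm), function(i) {
    cross_validate(x, y[perms[, i]], folds = folds, n_orth = n_orth,
                   scaling = scaling, seed = seed)$q2y
  }, numeric(1L))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed Q2Y = %.3f, null mean = %.3f, p = %.4g (%d perms)\n",
    x$observed, mean(x$null), x$p, x$n_perm))
  invisible(x)
}
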