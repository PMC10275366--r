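#' Principal component analysis of a feature panel
#'
#' Thin SVD on the scaled matrix: orthonormal loadings, scores = scaled X
#' times loadings, per-component explained-variance fractions.
#'
#' @param x samples-by-features matrix.
#' @param k number of components, `1 <= k <= min(n - 1, features)`.
#' @param scaling scaling method passed to [scale_matrix()].
#' @return object of class `phen_pca`: `loadings` (features x k, orthonormal),
#'   `scores` (n x k), `explained` (fractions, non-increasing), `scaling`.
#' @export
fit_pca <- function(x, k = 2L, scaling = "uv") {
  x <- as_feature_matrix(x)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k < 1L || k > kmax)
    stop("k must be in 1..", kmax, call. = FALSE)
  sc <- scale_matrix(x, scaling)
  sv <- svd(sc$x)
  expl <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  scores <- sc$x %*% loadings
  structure(list(k = as.integer(k), loadings = loadings, scores = scores,
                 explained = expl[seq_len(k)], singular_values = sv$d,
                 scaling = sc$params),
            class = "phen_pca")
}

#' @export
print.phen_pca <- function(x, ...) {
  cat("PCA:", x$k, "components;",
      "explained variance:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}
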