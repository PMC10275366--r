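#' Column scaling for multivariate modelling
#'
#' Centers every column and divides by a method-dependent divisor: 1 for
#' `"center"`, the column SD for `"uv"` (unit variance), the square root of
#' the SD for `"pareto"`.
#'
#' @param x samples-by-features numeric matrix (>= 2 rows).
#' @param method scaling method.
#' @return list with `x` (scaled matrix) and `params` (list with `method`,
#'   per-feature `means` and `divisors`), reusable via [apply_scaling()].
#' @export
scale_matrix <- function(x, method = c("uv", "pareto", "center")) {
  x <- as_feature_matrix(x)
  method <- match.arg(method)
  if (nrow(x) < 2L) stop("scaling needs at least 2 samples", call. = FALSE)
  means <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (method != "center" && any(sds == 0))
    stop("constant feature under ", method, " scaling: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  divisors <- switch(method,
                     center = rep(1, ncol(x)),
                     uv = sds,
                     pareto = sqrt(sds))
  names(divisors) <- colnames(x)
  xs <- sweep(sweep(x, 2L, means, "-"), 2L, divisors, "/")
  list(x = xs,
       params = list(method = method, means = means, divisors = divisors))
}

#' @rdname scale_matrix
#' @param params scaling parameters from a previous [scale_matrix()] call.
#' @export
apply_scaling <- function(x, params) {
  x <- as_feature_matrix(x)
  sweep(sweep(x[, names(params$means), drop = FALSE], 2L, params$means, "-"),
        2L, params$divisors, "/")
}
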