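#' Orthogonal partial least squares discriminant analysis (OPLS-DA)
#'
#' Fits a two-class OPLS-DA model with one predictive component and
#' `n_orth` orthogonal components by the orthogonal-filtering recursion:
#' the predictive weight is `w = X'y / ||X'y||` on the scaled matrix; each
#' orthogonal component takes `p = X't/(t't)` with `t = Xw`, removes the
#' predictive direction `w_orth = p - (w'p) w` (normalized), forms
#' `t_orth = X w_orth` and its loading, and deflates
#' `X <- X - t_orth p_orth'`.  The final predictive component is computed on
#' the deflated matrix.  By construction every `t_orth` is orthogonal to the
#' centered class code and to the predictive score.
#'
#' Class labels are encoded 0/1 in factor-level order (control = 0, burn = 1
#' for the default levels) and centered; class calls threshold predictions at
#' the centered midpoint.
#'
#' @param x samples-by-features matrix (n >= 6), or a model formula.
#' @param y two-level factor (or coercible) of class labels.
#' @param n_orth number of orthogonal components (>= 0, < n - 2).
#' @param scaling scaling method (see [scale_matrix()]); unit-variance
#'   scaling is the default for quantified panels, `"center"` is conventional
#'   for full-resolution spectra.
#' @param ... passed between methods.
#' @return an object of class `opls_da` with components `w` (unit predictive
#'   weight), `p` (predictive loading), `t_pred` (predictive scores),
#'   `w_orth`/`p_orth`/`t_orth` (matrices, one column per orthogonal
#'   component), `b` (regression scalar from `t_pred` to centered y), `r2x`,
#'   `r2y`, `scaling`, `y_map`, and the training data.
#' @examples
#' cfg <- default_sim_config()
#' ds <- simulate_cohort(cfg, seed = 1)
#' fit <- opls_da(combined_panel(ds), ds$samples$group, n_orth = 1)
#' fit
#' @export
opls_da <- function(x, ...) UseMethod("opls_da")

#' @rdname opls_da
#' @export
opls_da.default <- function(x, y, n_orth = 1L, scaling = "uv", ...) {
  x <- as_feature_matrix(x)
  y <- as_group_factor(y)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (n < 6L) stop("OPLS-DA needs at least 6 samples", call. = FALSE)
  if (any(table(y) == 0L))
    stop("both classes must be present", call. = FALSE)
  if (n_orth < 0L || n_orth >= n - 2L)
    stop("n_orth must satisfy 0 <= n_orth < n - 2", call. = FALSE)

  sc <- scale_matrix(x, scaling)
  Xs <- sc$x
  y01 <- as.numeric(y) - 1           # first level -> 0, second -> 1
  ybar <- mean(y01)
  yc <- y01 - ybar

  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  p <- ncol(Xs)
  Xd <- Xs
  W_o <- P_o <- matrix(0, p, 0L)
  T_o <- matrix(0, n, 0L)
  for (k in seq_len(n_orth)) {
    t <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- pl - sum(w * pl) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break              # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  t_pred <- drop(Xd %*% w)
  p_pred <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  b <- sum(t_pred * yc) / sum(t_pred^2)

  ssx <- sum(Xs^2)
  modeled <- sum(t_pred^2) * sum(p_pred^2)
  if (ncol(T_o))
    modeled <- modeled + sum(colSums(T_o^2) * colSums(P_o^2))
  r2x <- min(modeled / ssx, 1)
  r2y <- 1 - sum((yc - b * t_pred)^2) / sum(yc^2)

  rownames(W_o) <- rownames(P_o) <- colnames(Xs)
  structure(list(
    w = stats::setNames(w, colnames(Xs)),
    p = stats::setNames(p_pred, colnames(Xs)),
    t_pred = stats::setNames(t_pred, rownames(x)),
    w_orth = W_o, p_orth = P_o, t_orth = T_o,
    n_orth = ncol(T_o), b = b,
    r2x = r2x, r2y = r2y,
    scaling = sc$params,
    y_map = stats::setNames(c(0, 1), levels(y)),
    y_mean = ybar, y = y,
    x = x, x_scaled = Xs
  ), class = "opls_da")
}

#' @rdname opls_da
#' @param formula a formula such as `group ~ .`; the response is the class
#'   label, the right-hand side selects predictor columns of `data`.
#' @param data a data frame.
#' @export
opls_da.formula <- function(formula, data, n_orth = 1L, scaling = "uv", ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as.matrix(mf[, -1L, drop = FALSE])
  opls_da.default(x, y, n_orth = n_orth, scaling = scaling, ...)
}

#' @export
print.opls_da <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive +", x$n_orth, "orthogonal component(s)\n")
  cat(sprintf("  R2X = %.3f, R2Y = %.3f\n", x$r2x, x$r2y))
  cat("  classes:", paste(names(x$y_map), x$y_map, sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.opls_da <- function(object, ...) {
  co <- coef(object)
  out <- list(model = object,
              r2x = object$r2x, r2y = object$r2y,
              n_orth = object$n_orth,
              top = co[order(-abs(co$loading)), ][seq_len(min(10L, nrow(co))), ])
  class(out) <- "summary.opls_da"
  out
}

#' @export
print.summary.opls_da <- function(x, ...) {
  print(x$model)
  cat("Top features by |predictive loading|:\n")
  print(x$top, digits = 3)
  invisible(x)
}

#' @export
coef.opls_da <- function(object, ...) {
  bs <- backscale_loadings(object)
  data.frame(feature = names(object$w), weight = as.numeric(object$w),
             loading = as.numeric(object$p),
             backscaled_loading = bs$backscaled,
             cor_t_pred = bs$correlation, row.names = NULL)
}

#' Predict from an OPLS-DA model
#'
#' New data is scaled with the training parameters, orthogonal components are
#' filtered out sequentially, and the predictive score is regressed onto the
#' centered class code.  Class calls threshold the prediction at the centered
#' midpoint between the two class codes.
#'
#' @param object an `opls_da` model.
#' @param newdata samples-by-features matrix with the training features.
#' @param type `"response"` for the centered numeric prediction, `"class"`
#'   for class labels, `"scores"` for the predictive/orthogonal scores.
#' @param ... unused.
#' @export
predict.opls_da <- function(object, newdata = object$x,
                            type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  Xn <- apply_scaling(newdata, object$scaling)
  T_o <- matrix(0, nrow(Xn), object$n_orth)
  for (k in seq_len(object$n_orth)) {
    t_o <- drop(Xn %*% object$w_orth[, k])
    Xn <- Xn - tcrossprod(t_o, object$p_orth[, k])
    T_o[, k] <- t_o
  }
  t_pred <- drop(Xn %*% object$w)
  yhat <- object$b * t_pred
  if (type == "scores")
    return(list(t_pred = t_pred, t_orth = T_o))
  if (type == "response") return(yhat)
  midpoint <- 0.5 - object$y_mean
  lab <- ifelse(yhat > midpoint, names(object$y_map)[2L], names(object$y_map)[1L])
  factor(lab, levels = names(object$y_map))
}

#' @export
fitted.opls_da <- function(object, ...) predict(object, object$x)

#' @export
residuals.opls_da <- function(object, ...) {
  yc <- object$y_map[as.character(object$y)] - object$y_mean
  as.numeric(yc) - predict(object, object$x)
}

#' @export
plot.opls_da <- function(x, ...) {
  t_o <- if (x$n_orth >= 1L) x$t_orth[, 1L] else seq_along(x$t_pred)
  cols <- c("#2166ac", "#b2182b")[as.integer(x$y)]
  graphics::plot(x$t_pred, t_o, col = cols, pch = 19,
                 xlab = "t_pred (predictive)",
                 ylab = if (x$n_orth >= 1L) "t_orth (orthogonal)" else "index",
                 main = "OPLS-DA scores", ...)
  graphics::legend("topright", legend = names(x$y_map), col = c("#2166ac",
                   "#b2182b"), pch = 19, bty = "n")
  invisible(x)
}

#' Back-scaled loadings and score correlations
#'
#' Returns, per feature, the predictive loading multiplied by the feature's
#' scaling divisor (back-scaled to the measurement scale, for spectral-style
#' loading display) and the Pearson correlation between the raw feature and
#' the predictive score.
#'
#' @param model a fitted `opls_da` model (training data is stored).
#' @return data frame with `feature`, `backscaled` and `correlation`.
#' @export
backscale_loadings <- function(model) {
  stopifnot(inherits(model, "opls_da"))
  divisors <- model$scaling$divisors
  corr <- as.numeric(stats::cor(model$x, model$t_pred))
  data.frame(feature = names(model$p),
             backscaled = as.numeric(model$p) * as.numeric(divisors),
             correlation = corr, row.names = NULL)
}
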