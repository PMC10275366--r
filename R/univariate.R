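#' Cliff's delta effect size
#'
#' Nonparametric effect size
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`; ties contribute
#' zero.  Computed through the rank-sum (Mann-Whitney) identity
#' `delta = 2 U / (n_x n_y) - 1` with mid-rank tie handling, which is exact
#' and O(n log n).
#'
#' @param x,y non-empty numeric vectors (NAs dropped); for burn-vs-control
#'   tables `x` is the burn group.
#' @return delta in \[-1, 1\].
#' @examples
#' cliffs_delta(c(1, 2, 3), c(4, 5, 6))  # -1
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ## 2u - n_x n_y is the integer win-loss count, so the division is exact
  (2 * u - length(x) * length(y)) / (length(x) * length(y))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_(j >= i) p_(j) m / j`, clipped at 1 and mapped back to input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p numeric p-values in \[0, 1\] (NAs passed through).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Two-group comparison of a feature panel
#'
#' Per feature: group means/SDs, two-sided Student's t (pooled variance by
#' default, Welch behind `welch = TRUE`), Benjamini-Hochberg q-values over
#' all features within the panel, and Cliff's delta (burn vs control).
#' Missing values are handled complete-case per feature; features with fewer
#' than 2 complete observations in a group are excluded and reported via the
#' `"excluded"` attribute (with a message).  Rows are sorted by |delta|
#' descending.
#'
#' @param panel samples-by-features matrix or data frame.
#' @param group two-level labels aligned with rows (levels control, burn).
#' @param welch use the Welch t-test instead of pooled variance.
#' @param panel_kind optional panel tag recorded per row.
#' @return an `effect_table` data frame: `feature`, `panel`, `control_mean`,
#'   `control_sd`, `burn_mean`, `burn_sd`, `t`, `p`, `q`, `delta`.
#' @export
compare_groups <- function(panel, group, welch = FALSE, panel_kind = NA_character_) {
  panel <- as_feature_matrix(panel)
  group <- as_group_factor(group)
  if (length(group) != nrow(panel))
    stop("group labels must align with panel rows", call. = FALSE)
  ctrl <- levels(group)[1L]; burn <- levels(group)[2L]
  feats <- colnames(panel)

  ok <- vapply(feats, function(f) {
    v <- panel[, f]
    sum(!is.na(v[group == ctrl])) >= 2L && sum(!is.na(v[group == burn])) >= 2L
  }, logical(1L))
  if (any(!ok))
    message("excluding features with < 2 complete observations in a group: ",
            paste(feats[!ok], collapse = ", "))
  feats <- feats[ok]

  rows <- lapply(feats, function(f) {
    xb <- panel[group == burn, f]; xc <- panel[group == ctrl, f]
    xb <- xb[!is.na(xb)]; xc <- xc[!is.na(xc)]
    tt <- if (stats::sd(xb) == 0 && stats::sd(xc) == 0) {
      ## degenerate constant inputs: t.test refuses; define t = 0 when the
      ## groups coincide, +/-Inf otherwise
      d <- mean(xb) - mean(xc)
      list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
           p.value = if (d == 0) 1 else 0)
    } else {
      stats::t.test(xb, xc, var.equal = !welch)
    }
    data.frame(feature = f, panel = panel_kind,
               control_mean = mean(xc), control_sd = stats::sd(xc),
               burn_mean = mean(xb), burn_sd = stats::sd(xb),
               t = unname(tt$statistic), p = tt$p.value,
               delta = cliffs_delta(xb, xc))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(-abs(out$delta)),
             c("feature", "panel", "control_mean", "control_sd",
               "burn_mean", "burn_sd", "t", "p", "q", "delta")]
  rownames(out) <- NULL
  attr(out, "excluded") <- setdiff(colnames(panel), feats)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @export
print.effect_table <- function(x, ...) {
  cat("Effect table:", nrow(x), "features (sorted by |Cliff's delta|)\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Glutamine:glutamate ratio per sample
#'
#' @param panel metabolite panel (samples x features) containing both analytes.
#' @param group optional two-level labels for group summaries.
#' @param glutamine,glutamate column names of the two analytes.
#' @return list with `ratio` (named per-sample vector; samples with zero or
#'   missing denominator excluded and reported), and, when `group` is given,
#'   `group_means` and `group_sds`.
#' @export
glutamine_glutamate_ratio <- function(panel, group = NULL,
                                      glutamine = "Glutamine",
                                      glutamate = "Glutamate") {
  panel <- as_feature_matrix(panel)
  for (a in c(glutamine, glutamate))
    if (!a %in% colnames(panel))
      stop("analyte column missing: ", a, call. = FALSE)
  gln <- panel[, glutamine]; glu <- panel[, glutamate]
  bad <- is.na(gln) | is.na(glu) | glu <= 0
  if (any(bad))
    message("excluding samples with missing or non-positive glutamate: ",
            paste(rownames(panel)[bad], collapse = ", "))
  ratio <- gln[!bad] / glu[!bad]
  out <- list(ratio = ratio, excluded = rownames(panel)[bad])
  if (!is.null(group)) {
    g <- as_group_factor(group)[!bad]
    m <- tapply(ratio, g, mean); s <- tapply(ratio, g, stats::sd)
    out$group_means <- stats::setNames(as.numeric(m), names(m))
    out$group_sds <- stats::setNames(as.numeric(s), names(s))
  }
  out
}

#' Eruption-plot coordinates
#'
#' Joins, per feature shared by the effect table and the OPLS-DA model, the
#' univariate Cliff's delta (x), the model's predictive loading (y) and the
#' FDR-adjusted p-value (colour), flagging features significant at
#' `q < q_cut`.
#'
#' @param effect an `effect_table` from [compare_groups()].
#' @param model a fitted [opls_da()] model.
#' @param q_cut significance gate (default 0.05).
#' @return an `eruption_table` data frame: `feature`, `delta`, `loading`,
#'   `q`, `significant`.
#' @export
eruption <- function(effect, model, q_cut = 0.05) {
  stopifnot(inherits(effect, "effect_table"), inherits(model, "opls_da"))
  shared <- intersect(effect$feature, names(model$p))
  if (!length(shared))
    stop("effect table and model share no features", call. = FALSE)
  eff <- effect[match(shared, effect$feature), ]
  out <- data.frame(feature = shared,
                    delta = eff$delta,
                    loading = as.numeric(model$p[shared]),
                    q = eff$q,
                    significant = eff$q < q_cut,
                    row.names = NULL)
  class(out) <- c("eruption_table", "data.frame")
  out
}

#' @export
plot.eruption_table <- function(x, ...) {
  cols <- ifelse(x$significant, "#b2182b", "grey60")
  graphics::plot(x$delta, x$loading, pch = 19, col = cols,
                 xlab = "Cliff's delta", ylab = "predictive loading (t_pred)",
                 main = "Eruption plot", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  sig <- which(x$significant)
  if (length(sig))
    graphics::text(x$delta[sig], x$loading[sig], x$feature[sig],
                   pos = 3, cex = 0.6)
  invisible(x)
}
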