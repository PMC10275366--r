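`%||%` <- function(a, b) if (is.null(a)) b else a

## trapezoidal rule on an ascending grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

## x must be a numeric samples-x-features matrix with dimnames
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric samples-by-features matrix", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

## two-level group factor with control first, burn second
as_group_factor <- function(group, levels = NULL) {
  if (is.factor(group)) {
    group <- droplevels(group)
    if (nlevels(group) != 2L)
      stop("group labels must form a two-level factor", call. = FALSE)
    return(group)
  }
  u <- unique(as.character(group))
  if (length(u) != 2L)
    stop("group labels must form a two-level factor, got: ",
         paste(u, collapse = ", "), call. = FALSE)
  if (is.null(levels)) {
    levels <- if (all(sort(u) == sort(c("control", "burn")))) c("control", "burn")
              else sort(u)
  }
  factor(as.character(group), levels = levels)
}
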