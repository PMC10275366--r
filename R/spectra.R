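#' Spectrum set container
#'
#' Holds a shared chemical-shift axis (stored high-to-low ppm, the NMR display
#' convention), a samples-by-points intensity matrix, unique sample ids and an
#' experiment-mode tag (`"standard"`, `"cpmg"` or `"jedi"`).
#'
#' @param ppm strictly monotonic numeric axis (ascending input is reversed).
#' @param intensities numeric matrix, samples x points, all finite.
#' @param sample_ids unique sample identifiers (defaults to rownames).
#' @param mode experiment-mode tag.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(ppm, intensities, sample_ids = rownames(intensities),
                         mode = "standard") {
  ppm <- as.numeric(ppm)
  if (is.data.frame(intensities)) intensities <- as.matrix(intensities)
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = 1L)
  d <- diff(ppm)
  if (length(ppm) < 2L || !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotonic", call. = FALSE)
  if (ncol(intensities) != length(ppm))
    stop("axis length (", length(ppm), ") must equal intensity columns (",
         ncol(intensities), ")", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("all intensities must be finite", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (d[1L] > 0) {             # store descending
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  }
  rownames(intensities) <- sample_ids
  structure(list(ppm = ppm, intensities = intensities,
                 sample_ids = sample_ids, mode = mode),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("Spectrum set (", x$mode, "): ", length(x$sample_ids), " samples, ",
      length(x$ppm), " points, ", signif(min(x$ppm), 4), "-",
      signif(max(x$ppm), 4), " ppm\n", sep = "")
  invisible(x)
}

#' Read / write spectra as CSV
#'
#' Format: an optional leading comment `# mode: <mode>`, then a header row
#' `sample_id,<ppm values>`, then one row per sample.  Values are written with
#' 17 significant digits so a write-read round trip is lossless.
#'
#' @param path CSV file path.
#' @return `read_spectra` returns a [spectrum_set()].
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  mode <- "standard"
  is_comment <- grepl("^#", lines)
  mline <- grep("^#\\s*mode:", lines, value = TRUE)
  if (length(mline)) mode <- trimws(sub("^#\\s*mode:", "", mline[1L]))
  lines <- lines[!is_comment]
  if (length(lines) < 2L) stop("spectra CSV has no data rows", call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  ppm <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(ppm)) stop("non-numeric ppm axis in header", call. = FALSE)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("non-monotonic ppm axis in header row", call. = FALSE)
  n_fields <- length(header)
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  ids <- character(length(rows))
  mat <- matrix(NA_real_, length(rows), length(ppm))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_fields)
      stop("ragged row for sample '", rows[[i]][1L], "' (row ", i + 1L,
           "): expected ", n_fields, " fields, got ", length(rows[[i]]),
           call. = FALSE)
    ids[i] <- rows[[i]][1L]
    mat[i, ] <- as.numeric(rows[[i]][-1L])
  }
  spectrum_set(ppm, mat, ids, mode = mode)
}

#' @rdname read_spectra
#' @param set a [spectrum_set()].
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  fmt <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode: ", set$mode), con)
  writeLines(paste(c("sample_id", fmt(set$ppm)), collapse = ","), con)
  for (i in seq_along(set$sample_ids))
    writeLines(paste(c(set$sample_ids[i], fmt(set$intensities[i, ])),
                     collapse = ","), con)
  invisible(path)
}

#' Normalize spectra
#'
#' `"total-area"` scales each spectrum to unit intensity sum.  `"pqn"`
#' (probabilistic quotient normalization) divides each spectrum by the median
#' of its pointwise quotients to the pointwise-median reference spectrum; the
#' estimated quotients (dilution factors) are attached as attribute
#' `"quotients"`.  `"none"` returns the input.
#'
#' @param set a [spectrum_set()].
#' @param method normalization method.
#' @return a normalized [spectrum_set()].
#' @export
normalize_spectra <- function(set, method = c("total-area", "pqn", "none")) {
  stopifnot(inherits(set, "spectrum_set"))
  method <- match.arg(method)
  if (method == "none") return(set)
  X <- set$intensities
  zero <- rowSums(abs(X)) == 0
  if (any(zero))
    stop("all-zero spectrum for sample: ",
         paste(set$sample_ids[zero], collapse = ", "), call. = FALSE)
  if (method == "total-area") {
    out <- set
    out$intensities <- X / rowSums(X)
    return(out)
  }
  ## pqn
  if (nrow(X) < 2L)
    stop("pqn needs at least 2 samples for the median reference", call. = FALSE)
  ref <- apply(X, 2L, stats::median)
  keep <- ref != 0
  if (!any(keep)) stop("pqn reference spectrum is all zero", call. = FALSE)
  q <- apply(X[, keep, drop = FALSE], 1L, function(row)
    stats::median(row / ref[keep]))
  out <- set
  out$intensities <- X / q
  attr(out, "quotients") <- stats::setNames(q, set$sample_ids)
  out
}

#' Integrate a spectral window
#'
#' Trapezoidal integral of each spectrum over `[lo, hi]` ppm (both bounds
#' inclusive; the descending display axis is converted to ascending
#' internally).  Grid points falling inside the window are used; the window
#' must overlap the axis with at least two points.
#'
#' @param set a [spectrum_set()].
#' @param lo,hi window bounds in ppm, `lo < hi`.
#' @return named numeric vector of per-sample integrals.
#' @export
integrate_region <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  ppm <- rev(set$ppm)                       # ascending
  X <- set$intensities[, rev(seq_along(set$ppm)), drop = FALSE]
  eps <- 1e-12
  idx <- which(ppm >= lo - eps & ppm <= hi + eps)
  if (length(idx) < 2L)
    stop("window [", lo, ", ", hi, "] ppm does not overlap the axis",
         call. = FALSE)
  vals <- apply(X[, idx, drop = FALSE], 1L, function(y) trapz(ppm[idx], y))
  stats::setNames(as.numeric(vals), set$sample_ids)
}

#' Default glycoprotein / phospholipid integration windows
#'
#' Conventional windows for the composite inflammation and phospholipid
#' signals: GlycA 2.00-2.05 ppm, GlycB 2.06-2.10 ppm, SPC 3.20-3.30 ppm.
#' All are configurable wherever regions are accepted.
#'
#' @return named list of `c(lo, hi)` ppm pairs.
#' @export
default_regions <- function() {
  list(GlycA = c(2.00, 2.05), GlycB = c(2.06, 2.10), SPC = c(3.20, 3.30))
}

#' @rdname integrate_region
#' @param regions named list of `c(lo, hi)` windows.
#' @return `region_integrals` returns a samples-by-regions matrix.
#' @export
region_integrals <- function(set, regions = default_regions()) {
  vapply(regions, function(w) integrate_region(set, w[1L], w[2L]),
         numeric(length(set$sample_ids)))
}

#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Correlates the intensity at a driver point against every point of the
#' spectrum across samples.  The requested driver ppm snaps to the apex of
#' the mean spectrum: the local maximum nearest the request within +/- 0.02
#' ppm (falling back to the window's intensity maximum if the window contains
#' no strict local maximum).  Pearson correlation on intensities (the classic
#' formulation), plus the covariance trace.
#'
#' @param set a [spectrum_set()] with at least 4 samples.
#' @param driver requested driver position (ppm).
#' @param window half-width of the apex search window (ppm).
#' @return a `stocsy_result`: list with `driver_ppm` (apex actually used),
#'   `requested_ppm`, `ppm`, `r` and `cov` vectors.
#' @export
stocsy <- function(set, driver, window = 0.02) {
  stopifnot(inherits(set, "spectrum_set"))
  if (length(set$sample_ids) < 4L)
    stop("STOCSY needs at least 4 samples", call. = FALSE)
  ppm <- set$ppm
  X <- set$intensities
  win <- which(abs(ppm - driver) <= window)
  if (!length(win))
    stop("driver ", driver, " ppm is outside the axis", call. = FALSE)
  mu <- colMeans(X)
  n <- length(ppm)
  is_max <- function(i) {
    (i == 1L || mu[i] >= mu[i - 1L]) && (i == n || mu[i] >= mu[i + 1L]) &&
      ((i > 1L && mu[i] > mu[i - 1L]) || (i < n && mu[i] > mu[i + 1L]))
  }
  apices <- win[vapply(win, is_max, logical(1L))]
  idx <- if (length(apices)) apices[which.min(abs(ppm[apices] - driver))]
         else win[which.max(mu[win])]
  x <- X[, idx]
  if (stats::sd(x) == 0)
    stop("zero-variance driver column at ", signif(ppm[idx], 5), " ppm",
         call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  cv <- as.numeric(stats::cov(x, X))
  r <- ifelse(sds > 0, cv / (stats::sd(x) * sds), NA_real_)
  r <- pmin(pmax(r, -1), 1)
  r[idx] <- 1                              # self-correlation, by definition
  structure(list(driver_ppm = ppm[idx], requested_ppm = driver,
                 ppm = ppm, r = r, cov = cv),
            class = "stocsy_result")
}

#' @export
print.stocsy_result <- function(x, ...) {
  top <- order(-abs(x$r))[seq_len(min(5L, length(x$r)))]
  cat("STOCSY from apex at", signif(x$driver_ppm, 5), "ppm (requested",
      signif(x$requested_ppm, 5), "ppm)\n")
  cat("  strongest |r| at ppm:",
      paste(signif(x$ppm[top], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Write a STOCSY trace as CSV (ppm, r, covariance)
#'
#' @param result a `stocsy_result`.
#' @param path output CSV path.
#' @export
write_stocsy <- function(result, path) {
  stopifnot(inherits(result, "stocsy_result"))
  utils::write.csv(data.frame(ppm = result$ppm, r = result$r,
                              covariance = result$cov),
                   path, row.names = FALSE)
  invisible(path)
}

## peak basis evaluated on an axis: Lorentzian for sharp peaks (linewidth =
## FWHM, unit peak height), Gaussian for broad envelopes (linewidth = SD)
peak_shape <- function(ppm, center, linewidth, shape) {
  if (shape == "sharp") {
    g <- linewidth / 2
    g^2 / ((ppm - center)^2 + g^2)
  } else {
    exp(-(ppm - center)^2 / (2 * linewidth^2))
  }
}

#' Simulate NMR spectra from a dataset's metabolite panel
#'
#' Each sample's spectrum is the sum over configured peak templates of
#' (concentration x relative amplitude x mode visibility) peaks — Lorentzian
#' for sharp resonances, Gaussian for broad lipid envelopes — plus Gaussian
#' noise.  The three modes emulate pulse-sequence editing as pure attenuation:
#' `"cpmg"` attenuates macromolecule envelopes, `"jedi"` suppresses small
#' molecules and lipids while retaining the GlycA/GlycB/SPC composites.
#'
#' @param dataset a `phenome_dataset` with a metabolite panel (from
#'   [simulate_cohort()]).
#' @param mode experiment mode: `"standard"`, `"cpmg"` or `"jedi"`.
#' @param seed integer seed for the noise.
#' @param ppm axis (default descending 6.0 to 0.4 ppm, 0.002 ppm step).
#' @param noise_sd Gaussian noise SD; defaults to the config's value.
#' @param config simulation config carrying the templates; defaults to the
#'   config attached to the dataset.
#' @return a [spectrum_set()] tagged with `mode`.
#' @export
simulate_spectra <- function(dataset, mode = c("standard", "cpmg", "jedi"),
                             seed = 1L, ppm = NULL, noise_sd = NULL,
                             config = attr(dataset, "config")) {
  stopifnot(inherits(dataset, "phenome_dataset"))
  mode <- match.arg(mode)
  if (is.null(config)) stop("no simulation config available", call. = FALSE)
  if (is.null(ppm)) ppm <- seq(6.0, 0.4, by = -0.002)
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  conc <- get_panel(dataset, "metabolite")
  tpl <- config$templates
  missing_feat <- setdiff(tpl$feature, colnames(conc))
  if (length(missing_feat))
    stop("metabolite panel lacks template features: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  vis <- tpl[[paste0("vis_", mode)]]
  B <- t(vapply(seq_len(nrow(tpl)), function(k)
    peak_shape(ppm, tpl$center[k], tpl$linewidth[k], tpl$shape[k]),
    numeric(length(ppm))))
  Ceff <- conc[, tpl$feature, drop = FALSE] *
    rep(tpl$amplitude * vis, each = nrow(conc))
  Y <- Ceff %*% B
  set.seed(as.integer(seed))
  if (noise_sd > 0)
    Y <- Y + matrix(rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y))
  spectrum_set(ppm, Y, dataset$samples$sample_id, mode = mode)
}
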