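#' Simulate a two-group plasma phenotyping cohort
#'
#' Draws `n_control` + `n_burn` samples from a Gaussian copula: latent normals
#' with the group's configured correlation matrix are transformed through each
#' feature's moment-matched positive marginal (quantile transform, equivalent
#' to redrawing negative values from the conditional distribution — no point
#' mass at zero).  The result is a `phenome_dataset` holding the metabolite,
#' lipoprotein and cytokine panels on an identical ordered sample list.
#' Identical `(config, n, seed)` give bit-identical datasets.
#'
#' @param config a [sim_config()].
#' @param n_burn,n_control group sizes (each >= 3).
#' @param seed integer random seed.
#' @return a `phenome_dataset`: list with `samples` (data frame of `sample_id`
#'   and two-level `group` factor, control first), `panels` (named list of
#'   samples-by-features matrices with a `units` attribute) and `spectra`
#'   (empty list; see [simulate_spectra()]).
#' @examples
#' ds <- simulate_cohort(default_sim_config(), n_burn = 36, n_control = 21, seed = 1)
#' nrow(ds$samples)  # 57
#' @export
simulate_cohort <- function(config, n_burn = config$n_burn,
                            n_control = config$n_control, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_burn < 3L || n_control < 3L)
    stop("need at least 3 samples per group", call. = FALSE)
  set.seed(as.integer(seed))
  p <- nrow(config$features)

  draw_group <- function(n, group) {
    R <- config$corr[[group]]
    L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, p)))
    Z <- matrix(rnorm(n * p), n, p) %*% L
    U <- pnorm(Z)
    X <- matrix(NA_real_, n, p, dimnames = list(NULL, config$features$name))
    for (j in seq_len(p))
      X[, j] <- marginal_quantile(U[, j], config$marginals[[group]][[j]])
    X
  }

  Xc <- draw_group(n_control, "control")
  Xb <- draw_group(n_burn, "burn")
  ids <- c(sprintf("control_%02d", seq_len(n_control)),
           sprintf("burn_%02d", seq_len(n_burn)))
  X <- rbind(Xc, Xb)
  rownames(X) <- ids
  samples <- data.frame(
    sample_id = ids,
    group = factor(rep(c("control", "burn"), c(n_control, n_burn)),
                   levels = c("control", "burn")))

  panels <- lapply(split(seq_len(p), config$features$panel), function(idx) {
    m <- X[, idx, drop = FALSE]
    attr(m, "units") <- stats::setNames(config$features$unit[idx],
                                        config$features$name[idx])
    m
  })
  panels <- panels[intersect(c("metabolite", "lipoprotein", "cytokine"),
                             names(panels))]

  structure(list(samples = samples, panels = panels, spectra = list()),
            class = "phenome_dataset", config = config, seed = as.integer(seed))
}

#' @export
print.phenome_dataset <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("Phenome dataset: ", nrow(x$samples), " samples (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n", sep = "")
  for (k in names(x$panels))
    cat("  panel ", k, ": ", ncol(x$panels[[k]]), " features\n", sep = "")
  if (length(x$spectra))
    cat("  spectra:", paste(names(x$spectra), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a feature panel from a dataset
#'
#' @param dataset a `phenome_dataset`.
#' @param kind panel kind(s); `get_panel` returns one panel,
#'   `combined_panel` column-binds several.
#' @return a samples-by-features numeric matrix.
#' @export
get_panel <- function(dataset, kind = c("metabolite", "lipoprotein", "cytokine")) {
  stopifnot(inherits(dataset, "phenome_dataset"))
  kind <- match.arg(kind)
  if (is.null(dataset$panels[[kind]]))
    stop("dataset has no '", kind, "' panel", call. = FALSE)
  dataset$panels[[kind]]
}

#' @rdname get_panel
#' @param kinds panel kinds to combine, in order.
#' @export
combined_panel <- function(dataset,
                           kinds = c("metabolite", "lipoprotein", "cytokine")) {
  stopifnot(inherits(dataset, "phenome_dataset"))
  kinds <- intersect(kinds, names(dataset$panels))
  if (!length(kinds)) stop("no matching panels", call. = FALSE)
  do.call(cbind, lapply(kinds, function(k) dataset$panels[[k]]))
}

## panel kind of each feature in a dataset, as a named character vector
feature_panels <- function(dataset) {
  unlist(lapply(names(dataset$panels), function(k)
    stats::setNames(rep(k, ncol(dataset$panels[[k]])),
                    colnames(dataset$panels[[k]]))))
}

#' Simulate cohorts from a configuration (stats::simulate method)
#'
#' @param object a [sim_config()].
#' @param nsim number of cohorts.
#' @param seed integer; cohort `i` uses `seed + i - 1`.
#' @param ... passed to [simulate_cohort()] (`n_burn`, `n_control`).
#' @return a list of `phenome_dataset`s (a single dataset if `nsim = 1`).
#' @export
simulate.sim_config <- function(object, nsim = 1, seed = 1L, ...) {
  out <- lapply(seq_len(nsim), function(i)
    simulate_cohort(object, seed = as.integer(seed) + i - 1L, ...))
  if (nsim == 1L) out[[1L]] else out
}

#' Write the feature panels of a dataset to CSV files
#'
#' One CSV per panel (`<prefix><kind>.csv`), samples in rows with `sample_id`
#' and `group` columns first.
#'
#' @param dataset a `phenome_dataset`.
#' @param prefix path prefix for the output files.
#' @return invisibly, the paths written.
#' @export
write_panels <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "phenome_dataset"))
  paths <- character(0)
  for (k in names(dataset$panels)) {
    df <- data.frame(sample_id = dataset$samples$sample_id,
                     group = as.character(dataset$samples$group),
                     dataset$panels[[k]], check.names = FALSE)
    path <- paste0(prefix, k, ".csv")
    utils::write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a feature panel CSV (samples x features with group labels)
#'
#' Expects the layout written by [write_panels()]: a `sample_id` column, a
#' `group` column, then one numeric column per feature.
#'
#' @param path CSV file path.
#' @return a list with `values` (samples-by-features matrix), `sample_id` and
#'   `group` (factor).
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("panel CSV must have 'sample_id' and 'group' columns", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE])
  rownames(m) <- df$sample_id
  list(values = m, sample_id = df$sample_id, group = as_group_factor(df$group))
}
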