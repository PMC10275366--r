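#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: either a
#' simulation block (config, group sizes) or input panel CSV paths, plus
#' scaling choices, cross-validation settings, significance thresholds,
#' network criteria, integration regions and STOCSY drivers.  All randomness
#' flows from the single root `seed`, expanded deterministically per stage.
#'
#' @param out_dir output directory (created on run).
#' @param seed root integer seed.
#' @param simulation list: `config` (a [sim_config()]; default
#'   [default_sim_config()]), `n_burn`, `n_control`.
#' @param input optional list of panel CSV paths (named by panel kind) read
#'   with [read_panel()]; when given, the simulation block is ignored.
#' @param scaling list: `panels` and `spectra` scaling methods.
#' @param cv list: `folds`, `n_orth`, `permutations`.
#' @param thresholds list: `alpha`, `q_cut` — both in (0, 1].
#' @param network list: `alpha`, `min_abs_rho`, `correction`,
#'   `force_include` (nodes always kept, e.g. IL-6/IL-8).
#' @param regions named integration windows (see [default_regions()]).
#' @param stocsy_drivers numeric driver positions in ppm.
#' @param modes spectral experiment modes to simulate and model.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("phenomet_run_"),
                            seed = 1L,
                            simulation = list(),
                            input = NULL,
                            scaling = list(),
                            cv = list(),
                            thresholds = list(),
                            network = list(),
                            regions = default_regions(),
                            stocsy_drivers = c(acetoacetate = 2.27),
                            modes = c("standard", "cpmg", "jedi")) {
  simulation <- utils::modifyList(
    list(config = NULL, n_burn = 36L, n_control = 21L), simulation)
  scaling <- utils::modifyList(list(panels = "uv", spectra = "center"), scaling)
  cv <- utils::modifyList(list(folds = 7L, n_orth = 1L, permutations = 99L), cv)
  thresholds <- utils::modifyList(list(alpha = 0.05, q_cut = 0.05), thresholds)
  network <- utils::modifyList(
    list(alpha = 0.05, min_abs_rho = 0, correction = "none",
         force_include = c("IL-6", "IL-8")), network)
  if (!(thresholds$q_cut > 0 && thresholds$q_cut <= 1))
    stop("q_cut must lie in (0, 1]", call. = FALSE)
  for (a in c(thresholds$alpha, network$alpha))
    if (!(a >= 0 && a <= 1))
      stop("alpha must lie in [0, 1]", call. = FALSE)
  if (cv$folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (!is.null(input)) {
    missing <- !vapply(unlist(input), file.exists, logical(1L))
    if (any(missing))
      stop("input files not found: ",
           paste(unlist(input)[missing], collapse = ", "), call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation, input = input, scaling = scaling,
                 cv = cv, thresholds = thresholds, network = network,
                 regions = regions, stocsy_drivers = stocsy_drivers,
                 modes = modes),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Serializes the scalar fields (paths, seed, scaling, CV, thresholds,
#' network criteria, regions, drivers, modes) as a flat YAML document; the
#' simulation config object itself is rebuilt from [default_sim_config()]
#' unless the YAML names input files.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$regions <- lapply(y$regions, as.numeric)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$simulation$config <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

## Semantic hash of a pipeline config: canonical JSON of the semantic fields
## (out_dir excluded; the embedded sim_config is reduced to its numeric
## content) -> md5.  Changes iff a semantic field changes.
config_hash <- function(config) {
  semantic <- unclass(config)
  semantic$out_dir <- NULL
  if (!is.null(semantic$simulation$config)) {
    sc <- semantic$simulation$config
    semantic$simulation$config <- list(
      features = sc$features, corr = sc$corr, templates = sc$templates,
      noise_sd = sc$noise_sd, n_burn = sc$n_burn, n_control = sc$n_control)
  }
  js <- jsonlite::serializeJSON(semantic, digits = 15)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

## per-stage seed derivation from the root seed (documented, deterministic,
## < 2^31): seed_i = (root * 48271 + 1000003 * i) mod (2^31 - 1)
stage_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + 1000003 * i) %% (2^31 - 1))
}

#' Run the end-to-end phenotyping pipeline
#'
#' Stages: `simulate` (or ingest) the cohort and its spectra; `univariate`
#' effect tables per panel plus the glutamine:glutamate ratio; `opls` models
#' (combined quantified panels plus one per spectral mode) with stratified
#' cross-validated Q2Y and label-permutation p; `stocsy` traces for the
#' configured drivers; `network` per-group correlation networks over the
#' differential feature set plus forced includes, with a differential report;
#' and a run `manifest` (config hash, stage seeds, outputs, package version).
#' Each stage logs a START/END pair to stderr and `run.log`; a failing stage
#' aborts with a stage-named error and is flagged in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the principal in-memory results
#'   (`dataset`, `effects`, `models`, `stocsy`, `networks`, `comparison`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("panels", "models", "networks", "stocsy", "report"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  logf <- function(...) {
    line <- paste0(...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  manifest <- list(package = "phenomet",
                   version = as.character(utils::packageVersion("phenomet")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = list(), outputs = character(0))
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    logf("START ", name)
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      logf("FAIL ", name, ": ", conditionMessage(e))
      manifest$stages[[name]] <<- "failed"
      manifest$partial <<- TRUE
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "report", "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    logf("END ", name)
    ok
  }

  run_stage("simulate", function() {
    if (!is.null(config$input)) {
      panels <- lapply(config$input, read_panel)
      first <- panels[[1L]]
      ds <- structure(list(
        samples = data.frame(sample_id = first$sample_id, group = first$group),
        panels = lapply(panels, `[[`, "values"), spectra = list()),
        class = "phenome_dataset")
    } else {
      sim_cfg <- config$simulation$config %||% default_sim_config()
      ds <- simulate_cohort(sim_cfg, n_burn = config$simulation$n_burn,
                            n_control = config$simulation$n_control,
                            seed = stage_seed(config$seed, 1L))
      for (m in config$modes)
        ds$spectra[[m]] <- simulate_spectra(ds, mode = m,
                                            seed = stage_seed(config$seed, 1L))
    }
    write_panels(ds, file.path(config$out_dir, "panels", ""))
    for (m in names(ds$spectra))
      write_spectra(ds$spectra[[m]],
                    file.path(config$out_dir, "panels",
                              paste0("spectra_", m, ".csv")))
    state$dataset <- ds
  })

  run_stage("univariate", function() {
    ds <- state$dataset
    state$effects <- lapply(stats::setNames(nm = names(ds$panels)), function(k) {
      eff <- compare_groups(ds$panels[[k]], ds$samples$group, panel_kind = k)
      utils::write.csv(eff, file.path(config$out_dir, "panels",
                                      paste0("effects_", k, ".csv")),
                       row.names = FALSE)
      eff
    })
    if (all(c("Glutamine", "Glutamate") %in%
            colnames(ds$panels$metabolite %||% matrix(0, 0, 0)))) {
      state$ratio <- glutamine_glutamate_ratio(ds$panels$metabolite,
                                               ds$samples$group)
    }
  })

  run_stage("opls", function() {
    ds <- state$dataset
    y <- ds$samples$group
    fit_one <- function(xmat, scaling, label, seed_offset) {
      fit <- opls_da(xmat, y, n_orth = config$cv$n_orth, scaling = scaling)
      cv <- cross_validate(xmat, y, folds = config$cv$folds,
                           n_orth = config$cv$n_orth, scaling = scaling,
                           seed = stage_seed(config$seed, seed_offset))
      perm <- permutation_test(xmat, y, n_perm = config$cv$permutations,
                               folds = config$cv$folds,
                               n_orth = config$cv$n_orth, scaling = scaling,
                               seed = stage_seed(config$seed, seed_offset))
      list(label = label, fit = fit, cv = cv, perm = perm)
    }
    models <- list(panels = fit_one(combined_panel(ds), config$scaling$panels,
                                    "combined-panels", 3L))
    for (m in names(ds$spectra))
      models[[m]] <- fit_one(ds$spectra[[m]]$intensities,
                             config$scaling$spectra, paste0("spectra-", m), 3L)
    summary_df <- do.call(rbind, lapply(models, function(mo)
      data.frame(model = mo$label, r2x = mo$fit$r2x, r2y = mo$fit$r2y,
                 q2y = mo$cv$q2y, permutation_p = mo$perm$p)))
    utils::write.csv(summary_df,
                     file.path(config$out_dir, "models", "opls_summary.csv"),
                     row.names = FALSE)
    state$models <- models
    eff_all <- do.call(rbind, lapply(state$effects, function(e) {
      class(e) <- "data.frame"; e
    }))
    er <- eruption(structure(eff_all, class = c("effect_table", "data.frame")),
                   models$panels$fit, q_cut = config$thresholds$q_cut)
    utils::write.csv(er, file.path(config$out_dir, "models", "eruption.csv"),
                     row.names = FALSE)
    state$eruption <- er
  })

  run_stage("stocsy", function() {
    ds <- state$dataset
    if (is.null(ds$spectra$standard)) {
      state$stocsy <- list()
      return(invisible())
    }
    state$stocsy <- lapply(seq_along(config$stocsy_drivers), function(i) {
      res <- stocsy(ds$spectra$standard, config$stocsy_drivers[i])
      nm <- names(config$stocsy_drivers)[i] %||%
        sprintf("%.2fppm", config$stocsy_drivers[i])
      write_stocsy(res, file.path(config$out_dir, "stocsy",
                                  paste0("stocsy_", nm, ".csv")))
      res
    })
  })

  run_stage("network", function() {
    ds <- state$dataset
    sig <- unique(unlist(lapply(state$effects, function(e)
      e$feature[e$q < config$thresholds$q_cut])))
    nodes <- union(sig, intersect(config$network$force_include,
                                  unlist(lapply(ds$panels, colnames))))
    if (!length(nodes)) nodes <- config$network$force_include
    nets <- lapply(stats::setNames(nm = levels(ds$samples$group)), function(g) {
      cm <- correlation_matrix(ds, group = g, features = nodes)
      net <- build_network(cm, alpha = config$network$alpha,
                           min_abs_rho = config$network$min_abs_rho,
                           correction = config$network$correction)
      export_network(net, file.path(config$out_dir, "networks",
                                    paste0("network_", g, ".csv")),
                     format = "edgelist")
      export_network(net, file.path(config$out_dir, "networks",
                                    paste0("network_", g, ".graphml")),
                     format = "graphml")
      net
    })
    cmp <- compare_networks(nets[[2L]], nets[[1L]])
    utils::write.csv(cmp$degrees,
                     file.path(config$out_dir, "networks",
                               "differential_degrees.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(network = names(cmp$n_edges),
                                group = cmp$groups, edges = cmp$n_edges,
                                top_node = cmp$top_node),
                     file.path(config$out_dir, "networks",
                               "differential_summary.csv"),
                     row.names = FALSE)
    state$networks <- nets
    state$comparison <- cmp
  })

  run_stage("report", function() {
    manifest$outputs <<- list.files(config$out_dir, recursive = TRUE)
    manifest$stage_seeds <<- stats::setNames(
      lapply(1:3, function(i) stage_seed(config$seed, i)),
      paste0("stage_", 1:3))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "report", "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(dataset = state$dataset, effects = state$effects,
                 ratio = state$ratio, models = state$models,
                 eruption = state$eruption, stocsy = state$stocsy,
                 networks = state$networks, comparison = state$comparison,
                 manifest = manifest, out_dir = config$out_dir))
}
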