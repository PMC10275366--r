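#' Simulation configuration for two-group plasma phenotyping cohorts
#'
#' A `sim_config` bundles everything the cohort simulator needs: per-feature
#' group summaries (control/burn mean and SD, panel kind, units), one
#' inter-feature latent correlation matrix per group, spectral peak templates
#' with per-experiment-mode visibility multipliers, the spectral noise level
#' and default group sizes.  Marginal distributions are moment-matched at
#' construction time (see the methods vignette), and both correlation matrices
#' are repaired to the nearest positive-semidefinite correlation matrix;
#' construction fails if repair would move any entry by more than 0.2.
#'
#' @param features data frame with columns `name`, `panel`
#'   (`"metabolite"`, `"lipoprotein"` or `"cytokine"`), `control_mean`,
#'   `control_sd`, `burn_mean`, `burn_sd`, `unit`.
#' @param corr_control,corr_burn square latent (Gaussian-copula) correlation
#'   matrices over all features, in `features$name` order.
#' @param templates data frame of spectral peaks: `feature`, `center` (ppm),
#'   `linewidth` (FWHM, ppm), `amplitude` (relative), `shape` (`"sharp"` =
#'   Lorentzian or `"broad"` = Gaussian envelope), and visibility multipliers
#'   `vis_standard`, `vis_cpmg`, `vis_jedi` in \[0, 1\].
#' @param noise_sd spectral Gaussian noise SD (intensity units).
#' @param n_burn,n_control default group sizes.
#' @param reference optional list of printed reference tables carried along as
#'   metadata (not simulated).
#' @return an object of class `sim_config`.
#' @seealso [default_sim_config()], [simulate_cohort()], [configured_effects()]
#' @export
sim_config <- function(features, corr_control, corr_burn, templates,
                       noise_sd = 0.002, n_burn = 36L, n_control = 21L,
                       reference = NULL) {
  needed <- c("name", "panel", "control_mean", "control_sd",
              "burn_mean", "burn_sd", "unit")
  if (!all(needed %in% names(features)))
    stop("features must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(features$name))
    stop("duplicated feature names in config", call. = FALSE)
  if (!all(features$panel %in% c("metabolite", "lipoprotein", "cytokine")))
    stop("unknown panel kind in features", call. = FALSE)
  if (any(features$control_sd <= 0) || any(features$burn_sd <= 0))
    stop("all configured SDs must be > 0", call. = FALSE)
  if (any(features$control_mean <= 0) || any(features$burn_mean <= 0))
    stop("all configured means must be > 0 (concentrations)", call. = FALSE)

  p <- nrow(features)
  for (nm in c("corr_control", "corr_burn")) {
    R <- get(nm)
    if (!is.matrix(R) || nrow(R) != p || ncol(R) != p)
      stop(nm, " must be a ", p, "x", p, " matrix", call. = FALSE)
    if (max(abs(R - t(R))) > 1e-10)
      stop(nm, " must be symmetric", call. = FALSE)
    if (max(abs(diag(R) - 1)) > 1e-10)
      stop(nm, " must have a unit diagonal", call. = FALSE)
    if (max(abs(R)) > 1)
      stop(nm, " entries must lie in [-1, 1]", call. = FALSE)
  }

  tneeded <- c("feature", "center", "linewidth", "amplitude", "shape",
               "vis_standard", "vis_cpmg", "vis_jedi")
  if (!all(tneeded %in% names(templates)))
    stop("templates must have columns: ", paste(tneeded, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(templates$feature, features$name)
  if (length(unknown))
    stop("spectral templates reference undeclared features: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  if (!all(templates$shape %in% c("sharp", "broad")))
    stop("template shape must be 'sharp' or 'broad'", call. = FALSE)
  vis <- as.matrix(templates[, c("vis_standard", "vis_cpmg", "vis_jedi")])
  if (any(vis < 0 | vis > 1))
    stop("mode-visibility multipliers must lie in [0, 1]", call. = FALSE)

  repair <- function(R, nm) {
    Rr <- nearest_psd(R)
    dmax <- max(abs(Rr - R))
    if (dmax > 0.2)
      stop("non-repairable ", nm, " correlation matrix: PSD projection moved ",
           "an entry by ", signif(dmax, 3), " (> 0.2)", call. = FALSE)
    dimnames(Rr) <- list(features$name, features$name)
    Rr
  }

  marginals <- list(
    control = mapply(fit_marginal, features$control_mean, features$control_sd,
                     SIMPLIFY = FALSE),
    burn = mapply(fit_marginal, features$burn_mean, features$burn_sd,
                  SIMPLIFY = FALSE))
  names(marginals$control) <- names(marginals$burn) <- features$name

  structure(list(
    features = features,
    corr = list(control = repair(corr_control, "control"),
                burn = repair(corr_burn, "burn")),
    templates = templates,
    noise_sd = noise_sd,
    n_burn = as.integer(n_burn),
    n_control = as.integer(n_control),
    marginals = marginals,
    reference = reference
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cohort simulation configuration\n")
  tab <- table(x$features$panel)
  cat("  features: ", nrow(x$features), " (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("  spectral templates:", nrow(x$templates), "peaks for",
      length(unique(x$templates$feature)), "features\n")
  cat("  default cohort: ", x$n_burn, " burn / ", x$n_control, " control\n",
      sep = "")
  invisible(x)
}

## block assignment helper: symmetric fill, diagonal preserved
set_block <- function(R, rows, cols, value) {
  R[rows, cols] <- value
  R[cols, rows] <- value
  diag(R) <- 1
  R
}

default_features <- function() {
  met <- data.frame(
    name = c("Glutamine", "Alanine", "GlycA", "Creatine", "Phenylalanine",
             "Glucose", "GlycB", "3-hydroxybutyrate", "Glutamate",
             "Pyruvate", "Acetoacetate", "Acetone", "SPC",
             "lipid-CH3", "lipid-CH2"),
    panel = "metabolite",
    control_mean = c(0.503, 0.278, 4386, 0.046, 0.034, 4.607, 986,
                     0.086, 0.213, 0.068, 0.042, 0.028, 420, 1.00, 1.80),
    control_sd   = c(0.090, 0.058, 480,  0.017, 0.043, 0.962, 110,
                     0.278, 0.108, 0.020, 0.020, 0.012, 60, 0.20, 0.40),
    burn_mean    = c(0.638, 0.348, 4518, 0.054, 0.039, 4.966, 1087,
                     0.061, 0.101, 0.078, 0.036, 0.025, 395, 0.95, 1.70),
    burn_sd      = c(0.100, 0.095, 500,  0.009, 0.020, 1.179, 174,
                     0.299, 0.077, 0.024, 0.018, 0.011, 65, 0.22, 0.42),
    unit = c(rep("mmol/L", 2), "a.u.", rep("mmol/L", 3), "a.u.",
             rep("mmol/L", 5), "a.u.", "a.u.", "a.u.")
  )
  lip <- data.frame(
    name = c("L6CH", "L6PL", "L6PN", "L6AB", "L6FC", "L6TG",
             "L5CH", "L5AB", "L5PN", "L5PL", "LDPN", "LDAB", "H2A2",
             "L5FC", "H4TG", "L1TG", "V5PL", "V5CH", "L4TG", "V5FC"),
    panel = "lipoprotein",
    control_mean = c(11.86, 7.46, 174.52, 9.60, 3.80, 2.50,
                     7.66, 5.37, 97.70, 4.72, 790.10, 43.45, 2.89,
                     3.01, 3.02, 3.83, 1.26, 0.84, 1.33, 0.64),
    control_sd   = c(3.39, 1.69, 46.07, 2.53, 0.94, 0.58,
                     2.34, 1.56, 28.44, 1.16, 181.46, 9.98, 0.63,
                     0.63, 0.60, 1.34, 0.34, 0.34, 0.42, 0.23),
    burn_mean    = c(17.61, 10.16, 248.11, 13.65, 5.14, 3.15,
                     10.41, 7.06, 128.34, 5.92, 935.38, 51.45, 3.15,
                     3.60, 2.75, 3.20, 1.07, 0.63, 1.07, 0.41),
    burn_sd      = c(4.24, 2.21, 60.73, 3.34, 1.09, 0.92,
                     2.58, 1.69, 30.78, 1.29, 167.27, 9.20, 0.87,
                     0.65, 0.78, 1.28, 0.50, 0.48, 0.57, 0.26),
    unit = ifelse(grepl("PN$", c("L6CH", "L6PL", "L6PN", "L6AB", "L6FC", "L6TG",
                                 "L5CH", "L5AB", "L5PN", "L5PL", "LDPN", "LDAB",
                                 "H2A2", "L5FC", "H4TG", "L1TG", "V5PL", "V5CH",
                                 "L4TG", "V5FC")),
                  "nmol/L", "mg/dL")
  )
  ## cytokines: reported burn/control fold changes for TNF-a (1.31), IL-2
  ## (1.18), IL-7 (1.63), IFN-g (1.18); IL-6/IL-8 carry a modest sustained
  ## elevation; remaining cytokines are null.  Control levels are typical
  ## paediatric plasma immunoassay values (pg/mL) with ~50% CV.
  cnames <- c("GM-CSF", "IFN-g", "IL-1B", "IL-2", "IL-5", "IL-6", "IL-7",
              "IL-8", "IL-10", "IL-12p70", "IL-13", "IL-17A", "TNF-a")
  cmean <- c(1.5, 6.0, 0.8, 1.2, 1.0, 2.5, 4.0, 8.0, 2.0, 1.5, 2.0, 3.0, 5.0)
  csd   <- c(0.75, 3.0, 0.40, 0.60, 0.50, 1.25, 2.0, 4.0, 1.0, 0.75, 1.0, 1.5, 2.2)
  fold  <- c(1.00, 1.18, 1.00, 1.18, 1.00, 1.10, 1.63, 1.10, 1.00, 1.00, 1.00,
             1.05, 1.31)
  cyt <- data.frame(
    name = cnames, panel = "cytokine",
    control_mean = cmean, control_sd = csd,
    burn_mean = cmean * fold, burn_sd = csd * fold,
    unit = "pg/mL")
  rbind(met, lip, cyt)
}

default_corr <- function(features) {
  nm <- features$name
  p <- length(nm)
  base <- diag(p)
  dimnames(base) <- list(nm, nm)

  l6 <- c("L6CH", "L6PL", "L6PN", "L6AB", "L6FC", "L6TG")
  l5 <- c("L5CH", "L5AB", "L5PN", "L5PL", "L5FC")
  v5 <- c("V5PL", "V5CH", "V5FC")
  ld <- c("LDPN", "LDAB")
  ket <- c("3-hydroxybutyrate", "Acetoacetate", "Acetone")
  cyt <- features$name[features$panel == "cytokine"]

  R <- base
  ## shared biochemistry (both groups)
  R <- set_block(R, ket, ket, 0.80)
  R <- set_block(R, "Pyruvate", ket, 0.30)
  R["Glutamine", "Glutamate"] <- R["Glutamate", "Glutamine"] <- -0.50
  R <- set_block(R, "Pyruvate", "Alanine", 0.40)
  R <- set_block(R, "Pyruvate", "Glucose", 0.30)
  R <- set_block(R, "Glucose", "GlycA", 0.25)
  R <- set_block(R, "GlycA", "GlycB", 0.70)
  R <- set_block(R, "SPC", c("lipid-CH3", "lipid-CH2"), 0.40)
  R <- set_block(R, "lipid-CH3", "lipid-CH2", 0.60)
  R <- set_block(R, l6, l6, 0.80)
  R <- set_block(R, l5, l5, 0.80)
  R <- set_block(R, l5, l6, 0.50)
  R <- set_block(R, ld, ld, 0.80)
  R <- set_block(R, ld, c(l5, l6), 0.45)
  R <- set_block(R, v5, v5, 0.85)
  R <- set_block(R, "L1TG", "L4TG", 0.50)
  R <- set_block(R, c("lipid-CH3", "lipid-CH2"), c(ld, "L1TG"), 0.30)
  R <- set_block(R, cyt, cyt, 0.30)

  control <- R
  ## control-specific immune/metabolic couplings (sparser overall)
  control <- set_block(control, "GlycA", c("IL-7", "IL-10", "GM-CSF"), -0.35)
  control <- set_block(control, "GlycB",
                       c("IFN-g", "IL-13", "IL-17A", "IL-6", "TNF-a"), 0.35)
  control <- set_block(control, "GlycB", c("Glutamine", "Alanine", "Creatine"),
                       0.35)
  control <- set_block(control, c(l5, l6), cyt, -0.15)
  control <- set_block(control, v5, c("IL-2", "IL-10", "IL-12p70"), 0.25)
  control <- set_block(control, "Glucose", c("IL-5", "IL-7", "IL-12p70"), 0.30)
  control <- set_block(control, "H4TG", c("GM-CSF", "IL-1B", "IL-5"), 0.30)

  burn <- R
  ## burn-specific dense positive cytokine couplings with glycoproteins,
  ## small-dense LDL and amino acids; negative with VLDL-5
  burn <- set_block(burn, c("GlycA", "GlycB"),
                    c("IL-2", "IL-6", "IL-10", "IL-13", "TNF-a", "IFN-g"), 0.45)
  burn <- set_block(burn, l6, cyt, 0.32)
  burn <- set_block(burn, l5, cyt, 0.25)
  burn <- set_block(burn, c(l5, l6), c("IL-7", "IL-12p70"), 0.40)
  burn <- set_block(burn, v5, cyt, -0.32)
  burn <- set_block(burn, c("Alanine", "Creatine"), cyt, 0.22)
  ## phenylalanine as the burn-group hub: clearly the highest-degree node,
  ## linked to LDL/VLDL parameters, TNF-a/IL-6/IL-8 and the amino-acid/
  ## ketone axis (strengths kept jointly realisable with the blocks)
  burn <- set_block(burn, "Phenylalanine",
                    c(l6, "L5PN", "L5CH", "TNF-a", "IL-6", "IL-8"), 0.45)
  burn <- set_block(burn, "Phenylalanine", v5, -0.35)
  burn <- set_block(burn, "Phenylalanine", c("Alanine", "Creatine"), 0.45)
  burn <- set_block(burn, "Phenylalanine", "Glutamate", -0.35)
  burn <- set_block(burn, "Phenylalanine", "3-hydroxybutyrate", -0.35)

  list(control = control, burn = burn)
}

default_templates <- function() {
  ## amplitudes are scaled so concentration x amplitude gives comparable
  ## peak heights across panels (GlycA/GlycB/SPC are large a.u. integrals)
  sharp <- function(feature, center, amplitude, linewidth = 0.004,
                    cpmg = 1, jedi = 0.05)
    data.frame(feature = feature, center = center, linewidth = linewidth,
               amplitude = amplitude, shape = "sharp",
               vis_standard = 1, vis_cpmg = cpmg, vis_jedi = jedi)
  rbind(
    sharp("Glucose", 5.23, 0.38), sharp("Glucose", 3.47, 1.00),
    sharp("Glucose", 3.72, 0.80), sharp("Glucose", 3.89, 0.40),
    sharp("Alanine", 1.48, 1.00),
    sharp("Glutamine", 2.45, 0.70), sharp("Glutamine", 2.14, 0.60),
    sharp("Glutamate", 2.35, 0.70), sharp("Glutamate", 3.75, 0.30),
    sharp("Creatine", 3.04, 1.00), sharp("Creatine", 3.93, 0.70),
    sharp("Phenylalanine", 3.12, 1.00),
    sharp("Pyruvate", 2.37, 1.00),
    sharp("3-hydroxybutyrate", 1.20, 1.00),
    sharp("3-hydroxybutyrate", 2.31, 0.40),
    sharp("3-hydroxybutyrate", 4.16, 0.30),
    sharp("Acetoacetate", 2.27, 1.00), sharp("Acetoacetate", 3.43, 0.30),
    sharp("Acetone", 2.22, 1.00),
    sharp("GlycA", 2.03, 2.5e-4, linewidth = 0.020, cpmg = 0.7, jedi = 1),
    sharp("GlycB", 2.08, 5.0e-4, linewidth = 0.020, cpmg = 0.7, jedi = 1),
    sharp("SPC", 3.22, 2.0e-3, linewidth = 0.025, cpmg = 0.4, jedi = 1),
    data.frame(feature = c("lipid-CH3", "lipid-CH2"),
               center = c(0.90, 1.30), linewidth = c(0.10, 0.12),
               amplitude = c(1.0, 1.0), shape = "broad",
               vis_standard = 1, vis_cpmg = 0.15, vis_jedi = 0.08)
  )
}

#' Default simulation configuration at the study's conditions
#'
#' Builds the default two-group cohort configuration: 15 metabolite-panel
#' features (the quantified analytes plus the ketone bodies, pyruvate, the
#' GlycA/GlycB glycoprotein and SPC phospholipid composite integrals and two
#' broad lipid envelopes), 20 lipoprotein subfraction parameters, 13 plasma
#' cytokines with their reported burn/control fold changes, group-specific
#' latent correlation structure (denser cytokine-lipoprotein-metabolite
#' coupling in the burn group, with phenylalanine as the burn hub), spectral
#' peak templates for three experiment modes (standard 1D, CPMG, JEDI), and
#' default group sizes of 36 burn / 21 control.
#'
#' @return a [sim_config()] object.
#' @examples
#' cfg <- default_sim_config()
#' cfg$features[cfg$features$name == "Glutamine", ]
#' @export
default_sim_config <- function() {
  features <- default_features()
  corr <- default_corr(features)
  ratio_row <- data.frame(
    name = "Glutamine: glutamate ratio",
    control_mean = 2.190, control_sd = 2.762,
    burn_mean = 5.565, burn_sd = 3.595)
  ## noise gives the major resonances SNR ~ 100 and the minor ketone peaks
  ## SNR ~ 10, typical of plasma 1D acquisitions
  sim_config(features, corr$control, corr$burn, default_templates(),
             noise_sd = 0.002, n_burn = 36L, n_control = 21L,
             reference = list(derived = ratio_row))
}

#' Null-effect variant of a simulation configuration
#'
#' Replaces every burn-group marginal (mean and SD) and the burn correlation
#' matrix with the control ones, so the two simulated groups are exchangeable
#' and every configured standardized effect is zero.  Used for Q2Y and FDR
#' calibration.
#'
#' @param config a [sim_config()].
#' @return a [sim_config()] with no group effect.
#' @export
null_effect_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$features
  f$burn_mean <- f$control_mean
  f$burn_sd <- f$control_sd
  sim_config(f, config$corr$control, config$corr$control, config$templates,
             noise_sd = config$noise_sd, n_burn = config$n_burn,
             n_control = config$n_control, reference = config$reference)
}

#' Model-implied effect sizes and Spearman targets of a configuration
#'
#' `configured_effects()` returns, per feature, the population Cliff's delta
#' (burn vs control) implied by the fitted marginal distributions, computed by
#' numeric integration — the generator's ground-truth effect size that sample
#' deltas estimate.  `configured_spearman()` maps a group's latent correlation
#' matrix to the Spearman correlations the Gaussian copula induces.
#'
#' @param config a [sim_config()].
#' @return a data frame with `name`, `panel` and `delta`.
#' @export
configured_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  delta <- mapply(marginal_delta, config$marginals$burn,
                  config$marginals$control)
  data.frame(name = config$features$name, panel = config$features$panel,
             delta = as.numeric(delta), row.names = NULL)
}

#' @rdname configured_effects
#' @param group `"control"` or `"burn"`.
#' @export
configured_spearman <- function(config, group = c("control", "burn")) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  latent_to_spearman(config$corr[[group]])
}
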