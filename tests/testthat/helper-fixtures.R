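# Shared fixtures, built once per test run.

default_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- default_sim_config()
    cfg
  }
})

null_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- null_effect_config(default_cfg())
    cfg
  }
})

# tiny three-feature config for fast generator tests
tiny_cfg <- function(rho = 0.6, burn_shift = c(1, 0, 0), noise_sd = 0.001) {
  feats <- data.frame(
    name = c("A", "B", "C"),
    panel = "metabolite",
    control_mean = c(1.0, 2.0, 3.0), control_sd = c(0.2, 0.4, 0.5),
    burn_mean = c(1.0, 2.0, 3.0) + burn_shift * c(0.2, 0.4, 0.5),
    burn_sd = c(0.2, 0.4, 0.5),
    unit = "mmol/L")
  R <- diag(3); R[1, 2] <- R[2, 1] <- rho
  tpl <- data.frame(feature = c("A", "B", "C"),
                    center = c(1.0, 2.0, 3.0), linewidth = 0.004,
                    amplitude = 1, shape = "sharp",
                    vis_standard = 1, vis_cpmg = 1, vis_jedi = 0.05)
  sim_config(feats, R, R, tpl, noise_sd = noise_sd)
}

# ketone-recovery config: default structure with moderate-CV (0.3) ketone
# marginals so the copula correlation survives to the intensity scale
ketone_cfg <- function() {
  cfg <- default_cfg()
  feats <- cfg$features
  for (nm in c("3-hydroxybutyrate", "Acetoacetate", "Acetone")) {
    i <- which(feats$name == nm)
    feats$control_sd[i] <- 0.3 * feats$control_mean[i]
    feats$burn_sd[i] <- 0.3 * feats$burn_mean[i]
  }
  sim_config(feats, cfg$corr$control, cfg$corr$burn, cfg$templates,
             noise_sd = cfg$noise_sd)
}

ppm_index <- function(set, target) which.min(abs(set$ppm - target))
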