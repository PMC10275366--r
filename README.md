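# phenomet

Multi-platform plasma phenotyping for two-group (burn-injury vs control)
immunometabolic studies: OPLS-DA with cross-validated Q²Y and permutation
testing, Cliff's-delta effect tables with Benjamini–Hochberg FDR control,
eruption-plot coordinates, STOCSY, and per-group weighted-node Spearman
correlation networks integrating metabolite, lipoprotein-subfraction and
cytokine panels. A Gaussian-copula cohort simulator with NMR peak templates
(standard 1D / CPMG / JEDI attenuation modes) provides data with known
structure so the whole pipeline is testable without clinical data.

It is written for analysts of quantified plasma NMR panels (e.g. metabolite
and lipoprotein-subfraction tables plus immunoassay cytokines) who need the
standard chemometric toolchain of this literature in reproducible, tested R.

## The core model

`opls_da()` fits a two-class OPLS-DA model: with scaled X and centered 0/1
class code y,

    w = Xᵀy / ‖Xᵀy‖            (predictive weight)
    t = Xw,  p = Xᵀt / tᵀt     (scores, loading)
    w⊥ ∝ p − (wᵀp)w,  t⊥ = Xw⊥, X ← X − t⊥p⊥ᵀ   (orthogonal filtering)

so each orthogonal score t⊥ is exactly uncorrelated with the class and with
the predictive score t_pred. Predictive ability is the stratified K-fold
cross-validated Q²Y = 1 − PRESS/SS on out-of-fold predictions, validated by
whole-cohort label permutation. Univariate effects use Cliff's delta
δ = P(x_burn > x_control) − P(x_burn < x_control) (computed exactly via the
Mann–Whitney identity) with BH q-values per panel; networks connect
significant features by within-group Spearman correlations (p < α), with
node weight = degree.

## Worked example

```r
library(phenomet)

cfg <- default_sim_config()                 # study conditions: Table-style
ds  <- simulate_cohort(cfg, n_burn = 36, n_control = 21, seed = 1)
ds
#> Phenome dataset: 57 samples (control = 21, burn = 36)
#>   panel metabolite: 15 features
#>   panel lipoprotein: 20 features
#>   panel cytokine: 13 features

X <- combined_panel(ds); y <- ds$samples$group
head(as.data.frame(compare_groups(X, y))[,
     c("feature", "control_mean", "burn_mean", "delta", "p", "q")], 5)
#>     feature control_mean burn_mean  delta        p        q
#> 1      L6CH       12.106   17.7123  0.693 2.84e-06 6.81e-05
#> 2 Glutamate        0.220    0.0958 -0.690 1.69e-06 6.81e-05
#> 3      L6PN      170.533  246.1684  0.630 2.15e-05 3.44e-04
#> 4      L6PL        7.694   10.1257  0.587 1.00e-04 9.64e-04
#> 5 Glutamine        0.523    0.6258  0.571 8.88e-05 9.64e-04

fit <- opls_da(X, y, n_orth = 1)
fit
#> OPLS-DA model: 1 predictive + 1 orthogonal component(s)
#>   R2X = 0.285, R2Y = 0.670
#>   classes: control = 0, burn = 1
cross_validate(X, y, folds = 7, seed = 2)
#> Stratified 7-fold cross-validation: Q2Y = 0.362
permutation_test(X, y, n_perm = 99, folds = 7, seed = 3)
#> Permutation test: observed Q2Y = 0.424, null mean = -0.516, p = 0.01 (99 perms)

nb <- build_network(correlation_matrix(ds, "burn"),    alpha = 0.05)
nc <- build_network(correlation_matrix(ds, "control"), alpha = 0.05)
compare_networks(nb, nc)
#> Network comparison: burn (211 edges) vs control (152 edges)
#>   top node by degree: L6PL vs LDPN
```

Reading: the small-dense LDL-6 parameters and glutamate carry the largest
effect sizes (δ ≈ ±0.7, q ≪ 0.05, elevation in burn except glutamate, which
is depleted); the combined-panel OPLS-DA separates the groups with a
cross-validated Q²Y well above its permutation null (p = 0.01); and the
burn-group correlation network is substantially denser than the control
network — the qualitative immune–metabolic coupling contrast the package is
built around.

The end-to-end pipeline (simulation or CSV panels in, effect tables, model
summaries, STOCSY traces, networks and a run manifest out) is
`run_pipeline(pipeline_config(out_dir = "out", seed = 1))`, also available
as a shell command via `inst/scripts/phenomet-pipeline.R`. See the methods
vignette (`vignettes/phenomet-methods.Rmd`) for the models, defaults and
their rationale.

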