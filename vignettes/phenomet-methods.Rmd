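---
title: "Models and methods in phenomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phenomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomet)
```

phenomet analyses two-group ("burn" vs "control") plasma phenotyping data
measured on three molecular panels — quantified low-molecular-weight
metabolites, lipoprotein subfraction parameters and plasma cytokines — plus
optional full-resolution ^1^H NMR spectra acquired under three pulse-sequence
modes (standard 1D, CPMG spin-echo, JEDI). This vignette explains the models
the package implements, the choices made where the design was genuinely open,
and what the built-in simulator does and does not emulate.

## The cohort simulator

The simulator exists so that every downstream stage — effect tables, OPLS-DA
cross-validation, STOCSY, correlation networks — can be exercised and
calibrated on data with *known* structure. It is a first-class, tested
component, not a fixture.

**Marginals.** Each feature in each group is described by a mean and SD
(`default_sim_config()` carries the published group summaries for 20
lipoprotein parameters and the quantified metabolite panel, the 13 cytokines
with their reported burn/control fold changes, and plausible values for the
remaining panel members). Concentrations must be positive, so each
(feature, group) marginal is a *moment-matched* positive distribution:

* a zero-truncated normal whose location/scale are solved numerically so the
  *truncated* distribution reproduces the target mean and SD exactly —
  feasible whenever the target CV is below ~0.85 (the family's limit is
  CV → 1);
* a moment-matched lognormal for the heavy-tailed features above that limit
  (3-hydroxybutyrate, with CV > 3, and control-group phenylalanine).

Sampling uses the quantile transform, which is exactly equivalent to
redrawing negative values from the conditional distribution: there is no
point mass at zero and the configured moments are population identities.
One consequence worth knowing: ratio statistics whose denominator is a
truncated normal with large CV (the glutamine:glutamate per-sample ratio)
acquire a heavy right tail that real plasma data does not show — real
glutamate is evidently bounded away from zero in a way a two-moment summary
cannot encode. Interpret simulated per-sample ratios accordingly.

**Dependence.** A Gaussian copula couples the features: latent normals with
a group-specific correlation matrix are pushed through the marginal
quantiles. Monotone marginal transforms leave rank statistics alone, so the
Spearman correlation induced by a latent correlation $r$ is the classical
$(6/\pi)\arcsin(r/2)$; `configured_spearman()` exposes these targets and
`configured_effects()` integrates the marginals numerically to give the
population Cliff's delta of every feature — the ground truth that sample
deltas estimate.

The two latent matrices encode the study's qualitative contrast: both groups
share biochemical blocks (a ketone-body block at 0.8, glutamine–glutamate
antagonism at −0.5, tight within-class lipoprotein blocks, a baseline
cytokine block), while the burn matrix adds dense positive couplings between
cytokines, the glycoprotein signals (GlycA/GlycB), and small-dense LDL
(L5/L6) parameters, negative couplings of cytokines with VLDL-5, and a
phenylalanine hub wired to LDL/VLDL parameters, TNF-α/IL-6/IL-8 and the
amino-acid/ketone axis. Hand-specified block matrices are usually not
positive semidefinite; both matrices are repaired by iterated eigenvalue
clipping (floor $10^{-8}$) with rescaling to a unit diagonal, and
construction *fails* if repair moves any entry by more than 0.2. The default
matrices are repaired by at most ≈0.18; the realised (post-repair) matrices
are the ones `configured_spearman()` reports, so recovery tests are anchored
to what the generator actually samples. A hub constraint worth noting: a
unit-diagonal correlation matrix cannot give one node strong links to many
mutually uncorrelated partners (the row becomes infeasible), so hub
prominence in the default configuration is a statement about *mean* degree,
decisive only at large n.

**Spectra.** Each sample's spectrum on a descending 6.0–0.4 ppm axis (0.002
ppm step) is a sum over peak templates of concentration × relative amplitude
× mode-visibility, with Lorentzian lineshapes for sharp resonances, Gaussian
envelopes for the two broad lipid signals, and i.i.d. Gaussian noise. The
default noise SD (0.002) puts the major resonances at SNR ≈ 100 and the
minor ketone peaks at SNR ≈ 10, typical of plasma 1D acquisitions. The three
experiment modes are emulated *only* as attenuation multipliers in [0, 1]:
CPMG attenuates the macromolecular envelopes (0.15) and partially the
glycoprotein/SPC composites; JEDI suppresses small molecules (0.05) and
lipid envelopes (0.08) while retaining GlycA/GlycB/SPC. No acquisition
physics, J-coupling, multiplet structure, baseline or shimming artefacts are
modelled, and multiplets are single effective peaks — so passing tests say
nothing about peak alignment or deconvolution on real spectra. Note the
3-hydroxybutyrate methyl doublet at 1.20 ppm rides on the broad lipid-CH2
envelope exactly as in real plasma; correlation analyses should probe the
clean 4.16 ppm resonance instead.

## Spectral processing

* **Normalization**: total-area (each spectrum sums to 1) and probabilistic
  quotient normalization (division by the median quotient to the pointwise
  median reference spectrum; estimated dilution factors are returned).
  Normalization is optional — the paper-style analyses run on quantified
  panels — and `none` is the default in the pipeline.
* **Region integration**: trapezoidal integrals over inclusive ppm windows.
  The published analyses use GlycA/GlycB/SPC integrals without printing the
  bounds; the defaults (GlycA 2.00–2.05, GlycB 2.06–2.10, SPC 3.20–3.30 ppm)
  are the conventional windows and are configurable everywhere.
* **STOCSY**: Pearson correlation (the classic covariance/correlation
  formulation, not Spearman) of a driver point against every spectral point.
  The requested driver ppm snaps to the apex of the mean spectrum — the
  nearest local maximum within ±0.02 ppm — because driving "from the apex"
  needs a concrete apex-finding rule; the apex actually used is recorded in
  the result, and the self-correlation at the driver is 1 by definition.

## Scaling, PCA and OPLS-DA

Scaling is re-estimated wherever a model is fitted: unit-variance (UV)
scaling is the default for quantified panels, mean-centering for
full-resolution spectra — the common chemometric practice when the source
analysis does not state its scaling. Pareto scaling is available.

`opls_da()` fits one predictive component plus `n_orth` orthogonal
components by orthogonal filtering: with scaled $X$ and centered 0/1 class
code $y_c$,

$$ w = X^\top y_c / \lVert X^\top y_c \rVert, \quad
   t = Xw, \quad p = X^\top t / t^\top t, $$

each orthogonal component removes the predictive direction from the loading,
$w_\perp \propto p - (w^\top p)\,w$, forms $t_\perp = X w_\perp$ and its
loading, and deflates $X \leftarrow X - t_\perp p_\perp^\top$; the final
predictive component is computed on the deflated matrix. By construction
every $t_\perp$ is exactly orthogonal to $y_c$ and to $t_{pred}$, and with
`n_orth = 0` the model *is* the first PLS1 component (a property the test
suite checks against an independent NIPALS implementation). `n_orth = 1` is
the default — the published score plots show exactly one orthogonal
component. R²X is the modelled fraction of scaled-X variance; R²Y the
fraction of $y_c$ variance captured by the single regression of $y_c$ on
$t_{pred}$.

**Cross-validated Q²Y.** Stratified K-fold (default 7-fold, one round,
seeded): scaling and the model are re-estimated inside each training fold
and $Q^2Y = 1 - \sum(y_c - \hat y)^2 / \sum y_c^2$ over out-of-fold
predictions, with $y_c$ centered by each fold's training mean. The source
analyses do not state their CV scheme, and Q²Y depends on it — treat
published Q²Y values as qualitative anchors. Leave-one-out (`folds = n`) is
supported and deterministic. The label-permutation test permutes the class
labels across the whole cohort, re-runs the full cross-validation per
permutation and reports $p = (1 + \#\{Q^2_{null} \ge Q^2_{obs}\}) /
(1 + n_{perm})$.

A note on PCA: published PCA figures sometimes carry Y-statistics (R²Y,
Q²Y), which are undefined for an unsupervised model; `fit_pca()` reports
per-component explained X-variance only.

## Univariate analysis

Per feature: two-sided Student's t with pooled variance ("Student's t test"
as stated; Welch is available behind a flag), Benjamini–Hochberg q-values
computed *within one panel* (the published metabolite and lipoprotein tables
are evidently corrected separately; no cross-panel family is formed — the
exact family membership behind the published q-values cannot be
reconstructed, so the package documents its own choice rather than forcing
agreement), and Cliff's delta computed exactly through the Mann–Whitney
identity with mid-rank ties. Tables are ranked by |δ| as in the published
convention. Missing values are complete-case per feature; features with
fewer than two complete observations in a group are excluded and reported.

The eruption table joins each feature's Cliff's delta (x), its OPLS-DA
predictive loading (y) and its q-value (colour), flagging the q < 0.05 set —
the same gate used to select network nodes.

## Correlation networks

Within one study group only: pairwise-complete Spearman correlation with
mid-rank ties; p-values from the t approximation on n − 2 degrees of freedom,
or the exact permutation null when fewer than 10 pairs are available. Nodes
are the differential (q < 0.05) features plus forced includes (IL-6 and IL-8
by default, following their reported sustained association with burn
injury); the node universe is shared between the two group networks so they
compare directly. Edges require p < α with α = 0.05 unadjusted by default —
the published display convention — with an FDR-corrected edge mode available
because the source is ambiguous between node-level q and edge-level p; an
optional |ρ| floor is off by default. Node weight is the degree. The
differential report gives per-node degree in each group, degree differences,
edges unique to each network and the top-ranked node. Published per-node
degree counts depend on the unstated edge rule and are therefore qualitative
anchors, not targets.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/ingest → univariate → OPLS (+ permutation)
→ STOCSY → networks → report. All randomness descends from one root seed
expanded deterministically per stage (`seed_i = (48271·root + 1000003·i)
mod (2^31 − 1)`), so identical configurations give byte-identical CSV
outputs. The run manifest records a semantic config hash (canonical JSON →
MD5) that changes iff a semantic field changes, per-stage status, and the
output inventory; each stage logs one START/END pair and failures abort with
a stage-named error.

## Problem sizes and what the tests show

The test suite calibrates the statistics at the sizes the methods are meant
for: effect-size recovery and network contrasts on 100 cohorts of 36 + 21
samples; Q²Y null calibration on 100 cohorts of 50 + 50; permutation-p
uniformity over 200 repetitions of 99 permutations; moment/correlation
recovery on cohorts of 2000 per group; STOCSY recovery at 200 samples over
20 seeds (using a moderate-CV ketone configuration, since heavy-tailed
marginals attenuate intensity-scale Pearson correlations below their latent
targets — an attenuation the package treats as real, not as error). Passing
these tests demonstrates statistical correctness of the machinery on data
satisfying the generator's assumptions — Gaussian-copula dependence,
two-moment marginals, attenuation-only spectral editing. Real plasma data
violate all three in places (non-normal marginals beyond two moments,
nonlinear dependence, baseline/alignment artefacts), so published values
should be reproduced from deposited tables with the ingestion path
(`read_panel()` → `compare_groups()`), not expected from the simulator.

## Known limitations

* The simulator cannot reproduce published Cliff's deltas *and* published
  means/SDs simultaneously: a two-moment marginal fixes the population delta
  (e.g. glutamine's configured moments imply δ ≈ 0.68 while the observed
  clinical value is 0.53), reflecting non-normality of the clinical data.
  Recovery tests are therefore anchored to the generator's own implied
  effects.
* Only two-class discrimination; no multi-class OPLS-DA, O2-PLS or VIP
  scores.
* No peak alignment, baseline correction, binning or reference
  deconvolution; spectra are assumed aligned on a shared axis.
* Network inference is marginal correlation, not partial correlation or a
  graphical model; forced includes and significance gates are the only node
  selection mechanisms.
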