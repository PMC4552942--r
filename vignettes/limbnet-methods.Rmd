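---
title: "Models and methods behind limbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind limbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbnet)
```

# The scientific problem

Mouse limb development is driven by two successive gene regulatory
networks: an early stage network (ESN, limb outgrowth, ~E9.5–E11) built
around the Fgf10/AER-Fgf epithelial–mesenchymal loop and the
Shh–Grem1–Bmp4 feedback system, and a late stage network (LSN,
expansion and elongation, ~E11–E13) in which Fgf10 has dropped out,
Hox A/D genes have become targets of AER-Fgf and Gli3R signalling, and
an unidentified repressor of *Grem1* ("Repressor X") participates.
`limbnet` models both networks as ODE systems, screens their robustness
to perturbation, and provides the statistical machinery to relate
network robustness to expression variation among individuals (qPCR-style
data) and among species (ortholog expression matrices), including a
synthetic-data generator so the whole pipeline runs without external
data.

# The ODE model family

Each gene's activity level \(x_g\) (dimensionless, roughly 0–2) obeys

\[
\frac{dx_g}{dt} \;=\; \Big[\,b_g + \sum_{l \in \mathrm{in}(g)} a_l\,
h_l(x_{src(l)})\Big]\; \prod_{m \in \mathrm{gates}(g)}
\frac{K_m^{n_m}}{K_m^{n_m} + x_{src(m)}^{n_m}} \;-\; d_g\, x_g ,
\]

where each incoming regulatory link contributes its own additive Hill
production term — increasing \(h(x) = x^n/(K^n + x^n)\) for activation,
decreasing \(h(x) = K^n/(K^n + x^n)\) for repression — and a gate link
multiplies the gene's whole production by a repression factor. The only
gate in the default topologies is Repressor X acting on *Grem1* in the
LSN. Decay is first order with \(d_g = 1\), so time is measured in
units of the common protein lifetime and steady-state levels equal net
production.

Two modelling conventions deserve comment:

* **Additive repression.** A "repressive" link can enter additively as
  a *decreasing* production term: the target is produced through a
  pathway that is active in the absence of the repressor. This is how
  Grem1⊣Bmp4 behaves in both networks — Bmp4's production collapses to
  its basal level when the link is removed, rather than rising to a
  maximum, which is what a multiplicative-repression reading would
  predict. The additive family is the only one consistent with the
  reference steady-state tables shipped in `reference_screen()`
  (e.g. removing Grem1→Bmp4 *lowers* Bmp4; removing the Repressor
  X→Grem1 gate *raises* Grem1 to ~1.9).
* **Link removal deletes the link's mathematical element.** An additive
  term is dropped (its neutral element is 0); a gate factor reverts to
  1 (its neutral element). `remove_link()` implements exactly this.

# Calibration of the default parameters

Measured rate constants for these networks are not available, so
`default_parameters()` ships constants calibrated by least squares
against the reference screen tables: the unaltered steady state of each network (held to ±0.01 per
gene) and the complete pattern of ≥10% expression changes across all 11
(ESN) and 12 (LSN) single-link removals (held cell-for-cell, with an
8.5%/11.5% hinge margin around the 10% boundary so the pattern is not
knife-edge). Fitting proceeded in two stages: per-gene nonlinear
regressions of each gene's production function on the reference rows
(possible because, at steady state with \(d_g = 1\), each gene's level
equals its production evaluated at the other genes' levels), followed
by a global Levenberg–Marquardt refinement through full coupled solves.
Each solve in the refinement and in the production screens integrates
from the mid-scale initial state (all genes at 1.0), so the calibration
also guarantees that the *reachable* equilibria — not just algebraic
fixed points — reproduce the reference pattern. A few fitted Hill
exponents are steep (up to ~44 on Gli3R⊣Grem1's Bmp4 response and ~17
on HoxAD→Shh); these act as calibrated switches and are kept as fitted.
The perturbed-row *values* were used only as soft guidance: where the
reference table's printed value and its own ≥10% flag disagree (the
ESN "Fgf10 to AER-Fgfs" removal prints a Gli3R change of +23% yet no
flag), the flag pattern wins and the printed value is not matched.

The LSN is bistable: removing either leg of the Bmp4/AER-Fgf loop tips
the system into a collapsed attractor in which AER-Fgfs, Shh, Hox and
Repressor X are essentially off — visible in the screen as rows in
which every readout is flagged. The default initial condition (all
genes at 1.0) is configurable precisely because of this multistability.

# The two robustness screens

**Link-removal screen** (`screen_links()`): every link is removed in
turn, one per simulation, and each gene is flagged when its new steady
state differs from the unaltered one by 10% *or more* of the unaltered
value (relative rule, boundary counted as affected; an absolute-change
mode is available). With the calibrated models the screen flags 14 of
77 readouts in the ESN and 52 of 84 in the LSN — the early network is
substantially more robust.

**Parameter-sensitivity screen** (`screen_parameters()`): every
positive parameter is tested one at a time over a multiplier grid
(default ×0.5, ×0.75, ×1.25, ×1.5, ×2 of baseline). A gene's
*affects-others* percentage is the fraction of its own parameter's runs
that flag at least one other gene; its *is-affected* percentage is the
fraction of other genes' runs that flag it. The tested values in the
original study's supplementary material are not available, and the
percentages depend strongly on the grid (halving or doubling the
production rate of a constitutive driver like ESN HoxAD flags its
targets essentially always), so the default grid reproduces the
qualitative contrast between the networks but not the study's printed
percentages; the grid is a plain tibble argument and can be replaced.

**Impact/sensitivity spaces.** `gene_space()` condenses a link-removal
screen to one point per gene. The default impact coordinate is the
*mean* number of other genes flagged per removal of one of the gene's
outgoing links; the sensitivity coordinate is the number of removal
simulations that flag the gene (the screen's column total). This is the
convention under which the published quadrant structure reproduces:
all ESN genes in the lower-left quadrant, LSN Bmp4/Gli3R upper right,
Hox A/D near the centre, and Repressor X alone in the lower left.
Union-over-removals and simultaneous-removal impact modes are provided
as alternatives (a distinct-gene union count pushes ESN HoxAD to 5 of
6, which contradicts the published placement — one reason the mean is
the default). Quadrants split each axis at half its maximum; pass
`axis_max` to place two networks on a shared scale. Percentage spaces
(`sensitivity_space()`) use fixed 0–100 axes split at 50%.

# Among-individual variation

The expression table format is one row per (gene, embryo): litter,
Wanek stage (1–15; stages 1–4 form the early group ES, 5–8 the late
group LS) and a scaled expression level. The variation measure is the
coefficient of variation, sample SD divided by mean. The *replicate*
unit for CoV is one Wanek stage within a stage group — four replicate
CoVs per group — matching a resampling design in which the early and
late samples have fixed sizes; a per-litter replicate mode is
available.

Three tests are provided: Bartlett's homogeneity test across genes on
mean-standardized levels (k − 1 df), a one-way litter ANOVA per gene
(litters − 1 df), and a Monte-Carlo shuffle test
(`mc_cov_shuffle_test()`) for the LS − ES difference in mean replicate
CoV: all replicate CoVs are pooled, two samples of the original sizes
are drawn with replacement, and the p-value is the proportion of
replicates whose null difference is at least the observed one, with an
add-one correction so p ∈ [1/(reps+1), 1] and two runs with one seed
agree exactly.

# Among-species conservation and divergence

An ortholog matrix is genes × species (the study design is 6,583 genes
by bat, mouse, opossum and pig, one matrix per stage). Conservation is
the mean of all pairwise Spearman coefficients (average-rank ties).
`subsample_conservation()` draws `n_sets` random gene subsets per
intensity (fractions 0.5–1.0 by default), applies the *same* subset to
both stages within a draw (paired design, minimizing subset-induced
variance in the stage comparison; an unpaired mode exists) and compares
the two score distributions per intensity with Welch's t-test.
Per-gene divergence (`gene_divergence()`) is the SD of the gene's
mean-standardized expression across species (sample SD by default, a
population-SD switch is provided); the lowest and highest SD quartiles
are labelled top-25% conserved / divergent. Spearman-based conservation
is invariant to monotone transforms of a species' values, but the
divergence SD is not scale-free across species, so inputs should be
comparably normalized across species.

# Variation–divergence correlation

`pearson_r()` correlates per-gene CoV with per-gene divergence;
`bootstrap_significance()` resamples genes (their CoV–divergence pair
jointly — the only resampling unit that keeps the pairing meaningful)
and reports the proportion of bootstrap correlations ≤ 0 as the
significance measure for a positive observed correlation. The
complementary proportion (R ≥ 0) is also reported: a literal
"proportion ≥ 0" reading would sit near 1 for any clearly positive
correlation and cannot serve as a small p-like quantity, so the lower
tail is the operative measure. Degenerate replicates are redrawn and
tallied.

# The synthetic generators

`generate_qpcr_table()` emulates the study design: 71 embryos from 9
litters spread evenly over Wanek stages 1–8, litters forming
consecutive age groups (litter and stage covary, as when litters are
collected at increasing gestational ages). Levels are
mean × litter-multiplier × lognormal noise; both multipliers are
mean-one lognormals, the litter effect with CoV `litter_effect_sd`
(default 0.3 — strong enough that litter membership explains variance,
as a heritable component should) and the noise dispersion set so the
within-litter CoV equals the gene's configured target. The default
panel uses the five shared network genes with their measured stage-group
means and CoVs, plus a beta-actin control.

`generate_ortholog_matrices()` builds both stage matrices from one
latent log-expression vector plus species-specific noise whose per-gene
scale is lognormal (or user-supplied); a single mixing weight per stage
is found by bisection (fixed draws, 40 iterations) so the realized mean
pairwise Spearman hits the stage target (defaults 0.5667 / 0.5612) to
±0.01, with a loud error when a target is unreachable. High-noise
genes are thereby the planted divergent genes, and a supplied scale
vector lets callers couple divergence to a CoV profile.

What the generators deliberately do not emulate: qPCR chemistry
(efficiencies, standard curves — levels are taken as already scaled),
read-count noise or normalization of the RNA-seq summaries,
phylogenetic structure among the four species (species noise is
exchangeable), and any litter-by-gene interaction. Passing tests
therefore demonstrate that the statistics recover planted structure
under these idealizations, not that the study's biological conclusions
are reproduced from raw data.

# Test and pipeline problem sizes

The test suite validates the resampling machinery at sizes chosen to
make Monte-Carlo assertions stable: 1,000 null datasets for the shuffle
test's type-I rate, 100 generator seeds for the planted-conservation
detection (500 subsets of a 500-gene universe at 90% intensity), 300
datasets for the bootstrap-null calibration, and 100 seeds for full
pipeline recovery (300-gene matrices). `run_pipeline()` defaults to a
demonstration scale (1,000 genes, 200 subsets, 2,000 resamples) and
scales to the study sizes by argument. On the recovery test's noise
floor: with five assayed genes and four species, each divergence SD
estimate carries three degrees of freedom, so the five-point
correlation recovers its planted positive sign in about 88% of seeds —
a property of the study design, not of the estimators.

# Known limitations

* The ODE constants are calibrated to reproduce published steady-state
  behaviour, not measured rate constants; individual parameter values
  (especially the steep Hill exponents) should not be interpreted
  biochemically.
* Sensitivity-screen percentages depend on the tested grid; only the
  qualitative early/late contrast is stable.
* The conservation pipeline treats species as exchangeable; no
  phylogenetic correction is applied to the correlation of divergence
  with variation.
* Bartlett's test assumes approximate normality of the standardized
  levels; with strongly lognormal data its type-I behaviour is
  liberal, which is why the shuffle test, not Bartlett, carries the
  stage comparison.
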