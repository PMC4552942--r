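# limbnet

Gene-network models and expression-variation statistics for mammalian
limb development.

`limbnet` is for developmental and evolutionary biologists who want to
ask how the *structure* of a gene regulatory network shapes the
*variation* of its genes' expression — among individual embryos within
a population, and among species over evolutionary time. It implements
the complete computational pipeline around the mouse limb system:

1. **ODE models of the early (ESN) and late (LSN) stage limb
   networks.** Seven genes each (AER-Fgfs, Bmp4, Gli3R, Grem1, HoxAD,
   Shh, plus Fgf10 early / an unidentified Repressor X late). Each
   gene follows
   `dx_g/dt = [b_g + Σ_l a_l h_l(x_src)] · Π_m K_m^n/(K_m^n + x_m^n) − d_g x_g`,
   with one additive Hill term per incoming link (increasing for
   activation, decreasing for repression) and multiplicative gates for
   repressors of whole production pathways. Default constants are
   calibrated so both unaltered networks reproduce their reference
   steady states to ±0.01.
2. **Robustness screens.** `screen_links()` removes each regulatory
   interaction in turn and flags every gene whose steady state moves by
   ≥10% (14/77 readouts affected in the ESN vs 52/84 in the LSN — the
   early network is far more robust); `screen_parameters()` does the
   same over a one-at-a-time parameter multiplier grid. `gene_space()`
   and `sensitivity_space()` condense either screen into per-gene
   impact-vs-sensitivity coordinates with quadrant labels.
3. **Among-individual variation.** Coefficient-of-variation summaries
   by gene and stage group (Wanek stages 1–4 = early, 5–8 = late),
   Bartlett's variance-homogeneity test, a per-gene litter ANOVA
   (heritability signal), and a Monte-Carlo shuffle test for the
   late-minus-early CoV difference.
4. **Among-species conservation.** Mean pairwise Spearman conservation
   of ortholog expression matrices, a 500-set gene-subsampling
   comparison between stages, and per-gene mean-standardized divergence
   with top-quartile classification.
5. **Variation–divergence link.** Pearson correlation of per-gene CoV
   against divergence with gene-level bootstrap significance.
6. **Synthetic data.** Generators for the staged qPCR table (71 embryos,
   9 litters, litter effects, stage-dependent CoVs) and for paired
   ortholog matrices with a tunable conservation target, so every
   statistical stage is testable with known ground truth.

## Worked example

```r
library(limbnet)

topo   <- build_topology("ESN")
params <- default_parameters("ESN")

ss <- find_steady_state(topo, params)
round(ss$state, 3)
#> AER-Fgfs     Bmp4    Fgf10    Gli3R    Grem1    HoxAD      Shh
#>    1.979    0.011    1.976    0.013    1.988    1.798    1.973

scr <- screen_links(topo, params)
glance(scr)
#> # A tibble: 1 × 7
#>   stage n_links n_genes total_affected total_cells affected_fraction threshold
#>   <chr>   <int>   <int>          <int>       <int>             <dbl>     <dbl>
#> 1 ESN        11       7             14          77             0.182       0.1
```

The steady state is the unaltered ESN expression profile: the
AER-Fgf/Fgf10 loop and Shh sit high (~2), Bmp4 and Gli3R are repressed
to near zero, HoxAD is constitutive. The screen says that of the
77 possible (link-removal × gene) readouts only 14 change by ≥10% —
the quantitative sense in which the early network is robust. Running
the same two calls on `"LSN"` yields 52 of 84 affected readouts.

Downstream, on synthetic data:

```r
tab  <- generate_qpcr_table(seed = 1)
covs <- summarize_cov(stage_cov_summaries(tab))
head(covs, 4)
#> # A tibble: 4 × 4
#>   gene  group n_replicates mean_cov
#>   <chr> <chr>        <int>    <dbl>
#> 1 Actb  ES               4    0.684
#> 2 Actb  LS               4    0.807
#> 3 Bmp4  ES               4    0.442
#> 4 Bmp4  LS               4    0.811
```

Each `mean_cov` averages four per-Wanek-stage replicate CoVs; the
late-stage values exceed the early ones for the model genes, which
`mc_cov_shuffle_test()` turns into a p-value. `run_pipeline()` chains
all six stages (models → screens → variation → conservation →
correlation) into one reproducible, seed-stamped bundle.

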