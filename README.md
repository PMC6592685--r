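# kassoc

Detection and mass-action quantification of circulating T cell:monocyte
complexes in flow cytometry, with the companion transcriptomic
contamination signature for sorted T-cell RNA-seq.

## The problem

PBMC acquisitions contain CD3+CD14+ events that are not staining artefacts
but tightly bound T cell:monocyte pairs. They pass conventional
pulse-geometry doublet exclusion (their FSC/SSC area, height and width look
like large singlets), they co-sort with T cells (planting a monocyte gene
module into sorted-T-cell RNA-seq), and their abundance tracks immune
perturbation. `kassoc` provides the full analysis stack for studying them:

* a **generative simulator** of per-event cytometry data in which complexes
  form by mass action at a known association constant, with imaging-flow
  brightfield features and truth labels for every event;
* a **hierarchical gating engine** (interval / threshold / rectangle /
  polygon / quadrant gates under arcsinh display transforms) and the
  canonical complex-detection strategy `tm_strategy()`;
* the **association constant** of complex formation and its model fit.
  With `f_c`, `f_T`, `f_M` the frequencies of complexes, singlet T cells
  and singlet monocytes on a common live-singlet denominator,

  `Ka = f_c / (f_T · f_M)`

  corrects the raw complex frequency for partner abundance; across a
  constant-affinity cohort, `f_c = Ka · f_T · f_M` and `mass_action()`
  fits the through-origin line together with the Spearman correlation.
  Per-subset constants (CD4 / CD8 / DNEG / DPOS) use subset-resolved gates;
* an **imaging-flow doublet score** (`bf_area / bf_aspect_ratio`, greater
  for doublets) with Youden-calibrated classification, and an exhaustive
  rectangular-gate screen demonstrating that no conventional scatter gate
  separates complexes from monocyte singlets while the brightfield score
  does;
* **nonparametric cohort statistics** (paired Wilcoxon signed-rank,
  Mann-Whitney, tie-corrected Spearman), exact in small samples;
* the **monocyte-contamination signature** for sorted-T-cell TPM matrices:
  top-100 variable genes, co-expressed module extraction
  (average-linkage on `1 − Spearman ρ`), PC1 module score, and correlation
  of the score with the gated CD14+ event fraction.

## Worked example

Simulate one subject at a true association constant of 2, gate with the
canonical strategy, and estimate Ka:

```r
library(kassoc)

cfg <- flow_sim_config(n_events = 100000, ka_true = 2, seed = 42)
tab <- simulate_subject_events(cfg)
tab
#> <event_table> 100000 events, 16 channels (+ truth_label)
#>   channels: FSC_A, FSC_H, FSC_W, SSC_A, SSC_H, SSC_W, CD3, CD14, CD4, CD8, CD45RA, CCR7, CD45, viability, bf_area, bf_aspect_ratio
#>   truth: singlet:other=65995, dead=9799, debris=7970, singlet:mono=5152, ...

res <- apply_strategy(tab, tm_strategy())
ka_from_gating(res)
#> <ka_result> subset all: Ka = 1.963 (f_complex = 0.01521, f_T = 0.1216, f_M = 0.06372)
```

The gated estimate (1.96) recovers the generative constant (2): about 1.5%
of live singlet events are complexes, which is `Ka · f_T · f_M` for the
realized singlet fractions. Across a cohort, the mass-action model fits the
complex frequency on the frequency product:

```r
design <- data.frame(subject_id = sprintf("h%02d", 1:20))
recs <- simulate_cohort(design, flow_sim_config(n_events = 50000, ka_true = 2),
                        subject_sd = 0.2, events = "table", seed = 7)
d <- do.call(rbind, lapply(recs, function(r)
  as.data.frame(ka_from_gating(apply_strategy(r$events, tm_strategy()),
                               subject_id = r$subject_id))))
fit <- mass_action(f_complex ~ f_T : f_M, d)
fit
#> Mass-action fit (through origin):
#>   f_complex ~ f_T:f_M
#>   Ka = 1.989 (SE 0.0172), n = 20 subjects
#>   Spearman rho = 0.982 (p = 6.48e-06)
```

The slope estimates the cohort constant; `coef()`, `summary()`,
`predict()`, `plot()`, `residuals()` and `simulate()` behave as for any
fitted model. Printed count pairs convert to percentages with the exact
fraction retained:

```r
proportion_percent(30, 105)
#> 30 of 105 = 29% (exact 0.2857)
```

See the vignette (`vignettes/complex-association.Rmd`) for the generative
model, the gating strategy, the denominator convention behind Ka, and the
signature procedure.

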