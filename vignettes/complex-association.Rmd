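---
title: "Quantifying circulating T cell:monocyte complexes by mass action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circulating T cell:monocyte complexes by mass action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kassoc)
```

## The problem

A fraction of the events recorded in any PBMC flow-cytometry acquisition are
not single cells but tightly bound cell pairs. CD3+CD14+ events — carrying
both the T-cell and the monocyte lineage marker — are predominantly intact
T cell:monocyte complexes that survive sample processing and, critically,
survive conventional doublet exclusion: their forward/side-scatter pulse
area, height and width look like those of large singlets, so the usual
A-vs-H singlet gate does not remove them. A second CD3+CD14mid population
consists of single T cells carrying CD14+ monocyte debris, and sits in the
lymphocyte scatter gate.

Two consequences matter for routine immunology:

1. **Sorting contamination.** Complexes and debris-bound T cells co-sort
   with T cells. In bulk RNA-seq of sorted memory CD4+ T cells this
   produces a coherent block of monocyte-associated genes among the most
   variable genes, driven by the per-sample contamination fraction.
2. **A biological signal.** The abundance of complexes is not noise: it
   tracks immune perturbation (infection, vaccination) once corrected for
   the abundance of the two partner populations.

This package implements both analysis layers plus the synthetic data needed
to validate them: a generative event-level simulator, a hierarchical gating
engine, the association-constant statistic with a through-origin model fit
and nonparametric cohort comparisons, an imaging-flow doublet score, and
the transcriptomic contamination-signature procedure.

## The association constant

Let `f_c`, `f_T`, `f_M` be the frequencies of complexes, singlet T cells and
singlet monocytes on a common denominator. Under mass action the expected
complex frequency is proportional to the collision rate `f_T * f_M`, so

    Ka = f_c / (f_T * f_M)

is an abundance-corrected readout of the propensity of T cells and
monocytes to be found in complex — the analogue of a chemical association
constant. In a cohort with constant affinity, `f_c` is a linear function of
`f_T * f_M` through the origin, and `mass_action()` estimates the cohort Ka
as the through-origin least-squares slope alongside the Spearman rank
correlation of the two quantities. The origin constraint is physical: with
either partner absent, no complexes can form. Per-subset constants
(`CD4`, `CD8`, `DNEG`, `DPOS`) use the same denominator with subset-resolved
complex and singlet T frequencies.

### Denominator convention

Whether `f_T` and `f_M` should include the cells bound inside complexes is
genuinely ambiguous in routine practice. This package fixes the convention
that makes the estimator consistent with the generative model: all three
frequencies are fractions of the **live non-complex singlet events**, and
`f_T`, `f_M` count singlet cells only. `ka_from_gating()` exposes
`include_complexes` to switch the denominator to all live singlet-gateable
events. Two properties of the statistic are worth knowing:

* Ka is *denominator-dependent*: diluting the denominator with a
  non-participating population (factor `c` more events) multiplies every
  frequency by `1/c` and hence Ka by `c`, because the numerator scales once
  and the denominator product twice. Comparisons are only meaningful on a
  fixed gating denominator; the test suite pins this exact law.
* For the global estimate, CD3+CD14mid debris-bound events are counted into
  `f_T` (they are single T cells); subset estimates use the clean
  CD3+CD14- subsets, which undercounts `f_T` by the debris-binding rate
  (2% by default) uniformly across subsets, leaving subset *ratios*
  unaffected.

## The event simulator

`flow_sim_config()` + `simulate_subject_events()` generate one subject's
acquisition: singlets of each population (four CD4 memory subsets, CD8,
DNEG, DPOS T cells, classical monocytes, other lymphocytes), debris, dead
cells, debris-bound CD14mid T cells, and complexes. Given the realized
singlet pool of size `L` with fractions `f_s` and `f_M`, each T subset
contributes `C_s ~ Binomial(L, Ka_s * f_s * f_M)` complex events — so the
estimator's input frequencies match the generative ones and parameter
recovery is well-posed. Configurations whose implied complex fraction
exceeds `min(f_T, f_M)` are rejected as infeasible. Complexes are strictly
pairs; occasional triplets seen in imaging data are not modelled because
only the pairwise constant is quantified.

Key modelling choices, all config-exposed:

* **Markers.** Log-normal intensities per population; positive markers at
  1000 arbitrary units (sdlog 0.35), negative at 10 (sdlog 0.5). Complexes
  carry CD3/CD4/CD8/CD45RA/CCR7 from the T member and CD14 at the full
  monocyte level; debris-bound T cells carry CD14 at 15% of the monocyte
  location (the CD14mid level is not quantified in real data; 15% is an
  explicit package choice, as is the 2% default debris-binding rate).
* **Scatter.** Pulse height is a tight proportional band around area
  (`H = 0.95 A` with 5% log-noise), the basis of the singlet gate.
  `pulse_overlap` interpolates complex pulse geometry between a
  monocyte-like singlet draw (`0`, the default — encoding the empirical
  finding that conventional A/H/W cannot separate complexes) and a
  classical additive doublet signature (`1`: summed areas and widths,
  near-max height, which the singlet gate then removes).
* **Imaging.** Brightfield area is log-normal per population and additive
  for complexes; aspect ratio is Beta(40, 3) for single cells (near-round)
  and Beta(8, 6) for complexes. The doublet score is
  `bf_area / bf_aspect_ratio`, larger for doublets. (Figure legends in the
  source literature sometimes write the ratio the other way round; the
  direction here follows the stated inequality — greater for doublets.)
* **Composition.** The default composition puts `f_T ~ 0.12` and
  `f_M ~ 0.06` of the live singlet pool. These are deliberately below
  typical PBMC T-cell fractions: the recovery studies exercise association
  constants up to 5, and the feasibility bound `Ka * f_T * f_M <= f_M`
  caps `Ka * f_T` at 1. Since the absolute scale of Ka in real cohorts is
  not recoverable (it depends on the instrument gating denominator), only
  relative structure is meaningful, and the default conditions are chosen
  so every exercised Ka level is feasible with margin under inter-subject
  variability.
* **Cohorts.** `simulate_cohort()` draws per-subject effects once — a
  logistic-normal composition perturbation (sd 0.2) and optionally a
  log-normal Ka multiplier (mean 1) — and reuses them across timepoints,
  modelling the within-subject stability of the constant; design-level
  `ka_scale` applies condition effects such as halving after treatment.

What the simulator does **not** model: fluorescence spillover and
compensation artefacts, instrument drift, acquisition-time complex breakup,
triplets, and the continuous morphological detail of imaging cytometry.
Passing recovery tests therefore demonstrate internal consistency of the
estimators under the stated generative assumptions, not performance on any
particular instrument's data.

## The gating engine

Gates (`interval`, `threshold`, `rectangle`, `polygon`, `quadrant`) are
evaluated under per-channel display transforms — arcsinh with cofactor 150
for fluorescence (a standard cytometry choice; the transform is a named
config field because source gating figures never state one), identity for
scatter. Boundary conventions are fixed for determinism and
oracle-testability: lower bounds inclusive, upper exclusive; polygon
membership by the even-odd rule with on-edge points included; quadrant `+`
means `>=` the split, so the four children partition the parent exactly.
The engine is verified against brute-force per-event evaluation on random
geometry.

`tm_strategy()` ships the canonical complex-detection tree: live →
singlet (FSC_H/FSC_A band, chosen so complexes pass at >= 99% under the
default geometry) → CD3 x CD14 quadrant → CD14hi complexes vs CD14mid
debris-bound T cells (split at the arcsinh midpoint of the two generative
CD14 levels; real data require user calibration) → CD4 x CD8 and
CD45RA x CCR7 quadrants within complexes and within T cells. An optional
CD45-SSC pre-gate can be inserted; it leaves the complex frequency
essentially unchanged, as it should when complexes are CD45+.

### Why the pulse-geometry benchmark compares complexes to monocytes

`scatter_gate_screen()` scores every axis-aligned rectangle over the 15
pairs of scatter channels as a binary classifier of complexes against
**monocyte singlets**, using balanced accuracy. Complexes-vs-all-singlets
would be the wrong benchmark: complexes sit inside the monocyte scatter
cloud, so any gate that selects that cloud trivially attains high balanced
accuracy against a mostly-lymphocyte background without separating
complexes from the cells they actually resemble. The operational question
for doublet exclusion is whether any conventional gate removes complexes
*without removing monocytes* — and at `pulse_overlap = 0` none does
(AUC stays near 0.5), while the brightfield score separates the same two
event classes nearly perfectly.

## The contamination signature

`simulate_expression()` plants the discovery problem: per-sample TPM is the
mixture `(1 - c) * T_profile + c * M_profile` with log-normal noise
(sdlog 0.2), where `c ~ Uniform(0, 0.05)` is the monocyte-contamination
fraction and a 22-gene module has monocyte profiles 2^7 to 2^11 above the
T baseline — the magnitude regime of canonical monocyte markers, and the
regime in which a contamination module is detectable at all; substantially
smaller fold differences leave the weakest module genes uncorrelated at
this noise level.

The discovery procedure is deliberately simple and fully deterministic:

1. `top_variable_genes()` — the 100 genes with the highest variance of
   `log2(TPM + 1)` (log stabilization because TPM is heavy-tailed; raw
   variance and CV are available), ties broken lexicographically.
2. `extract_coexpression_module()` — average-linkage clustering on
   `1 - Spearman rho`; clusters are the branches below height
   `1 - rho_min`, and the module is the largest cluster with mean
   intra-cluster rho >= `rho_min` (default 0.6). Cutting at the threshold
   height matters: qualifying on the mean alone would let uncorrelated
   genes free-ride on a strong block. The exact criterion that delimited
   the module in the original sorted-cell data is not published; this
   reconstruction is calibrated on synthetic data only.
3. `module_score()` — PC1 of the z-scored module expression (the module
   eigengene), sign-fixed to correlate positively with mean module
   expression. PC1 is computed jointly across all samples.
4. `correlate_score_with_gate()` — Spearman correlation of the score with
   the measured CD14+ event fraction of the same sorted samples.

On synthetic data the pipeline recovers the planted module and the
contamination ordering almost perfectly; in real sorted-cell data the
analogous correlation is substantially weaker, because real contamination
has biological and technical covariates the mixture model does not
emulate. The synthetic benchmark validates the procedure, not the effect
size to expect in practice.

## Statistics

Cohort comparisons use the Wilcoxon signed-rank test for within-subject
(timepoint) contrasts and the Mann-Whitney test otherwise, exact for group
sizes below 25 without ties and normal-approximate with tie and continuity
correction beyond; both are verified against exhaustive enumeration for all
designs with n <= 8. Two-sided by default. No multiple-testing correction
is applied — comparisons are reported per test, as is conventional for
figure-level asterisks; apply `p.adjust(..., "holm")` to the reported
p-values when a family-wise guarantee is needed. Undefined Ka values
(zero partner frequencies) are flagged and excluded pairwise, never
imputed.

## Workflow entry points and reproducibility

This package's users drive it from R, so the orchestration layer is three
functions rather than a shell tool: `run_simulate()` (YAML cohort config →
event CSVs + truth sidecar), `run_analyze()` (events → per-subject Ka
table, mass-action fit, designed comparisons) and `run_signature()`
(TPM TSV + gated fractions → module, scores, correlation report). Every
run writes a manifest (command, config hash, seed, package version), seeds
are explicit arguments everywhere, and identical config + seed reproduces
byte-identical outputs.

## Problem sizes used in validation

The bundled validation studies use 50 subjects x 100,000 events per
association-constant level for recovery, a 59-subject cohort at 50,000
events for the linearity fit, 100 replicates for the subset-ordering and
module-recovery rates, and 200 replicates of the 15-pair treatment design
for power — sizes at which binomial noise on the rarest population (DNEG
complexes) is a few percent, small relative to the effects being recovered.
The paired power study runs on the simulator's latent count layer
(`events = "counts"`), which is the same generative model without
materializing per-event channels.

## Known limitations

* Ka is reported on the package's own denominator convention; absolute
  values are not comparable across different gating strategies (the `1/c`
  scaling above) — only within-cohort and within-subject contrasts are.
* The CD14hi/CD14mid split and all default gate positions are calibrated
  to the default generative models; real acquisitions need per-panel
  calibration.
* FCS ingestion requires an external reader; delimited text with a header
  of channel names is the supported interchange format.
* The debris-binding rate and CD14mid level are package choices where the
  source data is qualitative; both are config fields and their defaults
  are stated above.
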