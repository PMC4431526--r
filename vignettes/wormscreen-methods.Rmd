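---
title: "Hit calling for reproductive-fitness RNAi screens: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit calling for reproductive-fitness RNAi screens: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscreen)
library(dplyr)
```

## The screening problem

A synthetic-lethal RNAi screen in *C. elegans* compares two strains well by
well: a viable deletion mutant (here the kinesin-5 mutant *bmk-1(ok391)*) and
its wild-type control, both carrying a pharyngeal GFP marker so that adults
(parents) and larvae (progeny) can be counted automatically. Each well of a
96-well plate receives a few L1 larvae and bacteria expressing a
gene-specific dsRNA; four days later the well is imaged and counted. Genes
whose knockdown reduces viability much more in the mutant than in the
wild-type background are candidate synthetic-lethal interactors.

`wormscreen` implements the full analysis from per-well parent/progeny
counts to a final, replicate-supported hit list, together with a simulator
that generates complete screens with known planted effects.

## The fitness statistic

**Reproductive fitness** of a well is progeny per parent,
$RF = \frac{\text{progeny}}{\text{parents}}$ (`compute_rf()`). Wells with
fewer than 2 or more than 12 parents are set to not-determined (ND): outside
that window the progeny count is no longer linear in the number of parents.
Both endpoints are valid (the window is a closed interval). ND is represented
as `NA` throughout, and no downstream operation ever turns an ND back into a
number.

**Plate normalization** (`normalize_plate()`) divides every measurement on a
physical assay plate by the median RF of that plate's *sample* wells.
One physical plate is one library plate × strain × technical replicate —
the two strains and the two technical replicates are pipetted as separate
assay plates, so each gets its own median. Control wells are normalized by
the sample median like any other measurement but never contribute to it.
Consequences that the test suite checks as invariants:

* the median of the normalized sample wells on every normalizable plate is
  exactly 1;
* rescaling all counts on a plate by any constant leaves every normalized
  value, and hence every ratio, unchanged;
* a plate whose sample median is zero, or that has no defined sample well,
  is flagged unnormalizable and all of its values become ND.

Normalization happens **before** technical-replicate averaging, so plate
effects are removed at the measurement level. `summarize_technical()` then
averages the two technical replicates; when only one replicate worked, its
value is used as is; two ND replicates stay ND.

**The RF ratio** (`compute_rf_ratio()`) divides the mutant strain's averaged
RF by the wild type's. With this orientation a knockdown that is
specifically deleterious in the mutant gives a ratio below 1, so the
enhancer rules below point downward. The published description of the two
strain stocks is internally inconsistent about which stock label is the
mutant; the package therefore fixes the orientation by the *semantics*
(enhancers ≤ 0.5) and exposes an `orientation` flag for users who need the
reciprocal convention. Swapping orientation maps every defined ratio r to
1/r, which the tests verify.

**Lethality** in the wild-type background is `1 - RF` on the normalized
scale, clamped to [0, 1] (`compute_lethality()`). The plate median is the
only internal viability reference, so normalized fitness 1 is treated as
typical viability; there is no absolute brood-size standard in the data.

## Hit calling

Two classification rules coexist, with deliberately different boundary
semantics:

* **Primary screen** (`classify_primary()`): enhancer when ratio ≤ 0.5,
  suppressor when ratio ≥ 1.5, both *inclusive*. Clones with more than 90%
  wild-type lethality (strict) are excluded before any ratio decision —
  a ratio of two near-zero numbers is noise. Exclusion precedes
  classification, including the suppressor rule.
* **Secondary screen** (`classify_at_cutoff()`): at a cut-off of c percent,
  enhancer when ratio is *strictly* below 1 − c/100 (45% → ratio < 0.55),
  suppressor strictly above 1 + c/100. The suppressor side has no published
  formula; symmetry with the enhancer side mirrors the primary 0.5/1.5 pair
  and is this package's choice.

**Cut-off calibration** (`calibrate_cutoff()`) evaluates the candidate grid
(default 40–70% in steps of 5) against the control distributions: the
predicted false-positive rate at cut-off c is the fraction of negative
controls (empty vector, *hil-5*) strictly below 1 − c/100, and the predicted
false-negative rate is the fraction of positive controls (*dli-1*) at or
above it. Only *dli-1* defines the FN rate; *plk-1* is an RNAi-efficacy
control that kills both strains and carries no strain-specific signal. The
chosen cut-off minimizes |FP − FN| over the grid, and a tie goes to the
smaller (more sensitive) cut-off — the tie rule is unspecified in the
original analysis and is fixed here once. FP is non-increasing and FN
non-decreasing along the grid, which the suite checks against a brute-force
counting oracle.

**Replicate agreement** (`summarize_replicates()`): a clone is a final hit
when it classifies as enhancer in at least 2 of the 3 biological
replicates. ND counts as non-enhancer — a hit needs positive evidence in two
experiments, not merely the absence of contrary evidence. Clones that are
enhancer in at least one experiment are partitioned into the 7 regions of
the three-set Venn diagram; the region counts must sum to the size of that
union. Finally `collapse_to_genes()` deduplicates clones that share a
primary target (the final gene list can be one shorter than the clone list,
as when two library wells carry the same targeting sequence).

## The synthetic screen generator

`generate_screen()` draws a complete screen from an explicit generative
model so that every pipeline stage can be tested against known truth:

* parent counts: Poisson(7), truncated to 0–15 by default — deliberately
  wider than the 2–12 quality window, so a realistic few percent of wells
  become ND;
* expected progeny: parents × baseline brood (30) × wild-type viability ×
  strain multiplier (mutant only) × a log-normal plate effect
  (sd 0.15 on the log scale, one draw per physical plate);
* observed progeny: negative binomial around that mean with size
  parameter 10. Counts from whole broods are overdispersed relative to
  Poisson (worm-to-worm variation, development timing), and the pipeline
  must be robust to that, which is why the generator is NB by design;
* planted effects: 5% enhancers with mutant/wild-type multipliers uniform
  on 0.1–0.4, 2% suppressors (multipliers 1.6–2.5), and 2% genes lethal in
  both strains (viability 2–8%) whose only purpose is to exercise the
  high-lethality exclusion;
* controls follow the column-1 roster; each plate's *dli-1* wells get a
  multiplier drawn once from the enhancer-effect distribution, so
  control-based FP/FN predictions are exchangeable with the samples;
* technical replicates share the gene effect but draw independent counts
  and plate effects; biological replicates redraw plate effects only.

What the generator does *not* emulate: well-to-well contamination, bacterial
growth failures, edge effects, image-segmentation errors, and the
developmental-delay mechanism (a delayed larva is simply an undetected
progeny, i.e. a reduced viability multiplier). Passing recovery tests
therefore demonstrate that the statistics and thresholds behave as designed
under a realistic noise model, not that any particular biological screen is
error-free.

## Parameter recovery

The recovery experiment simulated by the test suite and by
`scripts/acceptance.R` uses 10 screens of 10 plates × 88 genes with the
defaults above (11,520 wells each: 2 strains × 3 biological × 2 technical
replicates). Each screen is pushed through `run_secondary()` — calibration
on pooled controls, per-experiment classification at the chosen cut-off,
2-of-3 agreement, gene collapsing — and `evaluate_recovery()` scores the
final genes against the planted truth. Pooled over the 10 screens the
pipeline reaches sensitivity above 0.99 and FDR below 0.10, the modal chosen
cut-off is 45%, and the control-predicted FP/FN rates track the realized
per-experiment sample rates within about one percentage point, comfortably
inside the ±5-point band the design asks for. These problem sizes keep the
whole experiment in the tens of seconds on one core.

The two-stage flow (primary selection on a single biological replicate, then
secondary on the selected clones) is also implemented (`run_primary()`).
Note that re-arraying only selected clones enriches hit plates with true
enhancers, which biases the sample median of mutant-strain plates downward
and costs sensitivity; with only ~17 selected clones per plate the median is
also noisier (the pipeline warns below 10 defined sample wells per plate).
This is a property of median normalization on hit plates, not of the
implementation.

## Numerical and design choices

* ND is `NA_real_`; on disk it is the token `ND` (case-insensitive on read);
  unparseable numeric cells are read as ND, never as zero.
* Well coordinates accept `B8`/`B08` and are canonicalized to `B08`.
* Control wells are excluded from the plate median (the normalization is
  defined "across the sample wells"); whether the original analysis included
  them is unstated, and this package fixes the sample-only convention.
* Calibration drops ND control ratios with a logged count and errors only
  when a control set is empty after dropping.
* The cut-off grid must be strictly increasing; ties in |FP − FN| go to the
  smallest cut-off.
* Determinism: a `screen_config()` seed fixes the entire screen; the
  pipeline itself is deterministic, so identical inputs give byte-identical
  outputs.

## Limitations

* The exclusion rule and the suppressor rule interact in an order the
  original description leaves open; here exclusion always wins. Suppressors
  are classified but never taken forward to agreement analysis.
* Reproducing the historical screen's headline counts requires its deposited
  raw data tables; the package reproduces the *rules* and demonstrates them
  on simulated screens and deposited-style tables.
* The simulator's negative-binomial size parameter is shared across wells;
  real screens likely have heavier-tailed, well-specific noise.
```{r session}
sessionInfo()
```
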