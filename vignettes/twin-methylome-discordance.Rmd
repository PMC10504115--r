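---
title: "Discriminating monozygotic twins by recurrent methylation discordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating monozygotic twins by recurrent methylation discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindmc)
```

## The problem

Monozygotic (MZ) twins carry the same genomic sequence, so the STR markers
used in forensic identification cannot distinguish them. DNA methylation
diverges between MZ twins over life — environment, stochastic drift and
disease all leave marks — and that divergence is measurable on methylation
arrays as a difference in average-beta values (the methylated fraction of a
CpG, in [0, 1]). `twindmc` implements the cohort analysis that turns paired
twin methylomes into a ranked panel of candidate discriminating markers.

## The procedure

Given a normalized beta matrix (probes x samples), an optional detection
p-value matrix, and a sample sheet binding samples into pairs:

1. **Detection masking.** An entry is kept only when its detection p-value
   is strictly below `alpha` (default 0.05); everything else becomes
   missing. Masking is per entry, not per probe; probes incomplete after
   masking are excluded later at the selection stage (the complete-case
   default, relaxable via `min_pair_fraction`).
2. **Per-pair delta-beta.** For each pair, the signed difference
   `beta_A - beta_B` per probe. The member labels A/B are arbitrary, so
   every downstream count and selection uses the absolute difference;
   swapping labels only negates the signed column.
3. **Per-pair DMC calling.** A probe is a differentially methylated CpG
   (DMC) for a pair when its absolute difference is *strictly greater*
   than 0.05 on the beta scale. Per-pair counts feed two cohort-level
   checks: a pooled-variance Student t test of counts between male and
   female pairs (expected null) and a Pearson correlation of counts with
   pair age (expected positive — methylomes drift apart with time).
4. **Recurrent-DMC selection.** A probe is a *recurrent* DMC when
   (1) the standard deviation of its beta values across all samples
   exceeds 0.05 (a variability filter, sample SD with n-1 denominator),
   and (2) its mean absolute within-pair difference across pairs exceeds
   0.05. Both comparisons are strict.
5. **Enrichment.** Selected probes are compared with the non-selected
   background over eight gene-structure categories (TSS1500, TSS200,
   1stExon, Body, Intergenic, ExonBnd, 3'UTR, 5'UTR) and six CpG-island
   relations (Island, N/S Shore, N/S Shelf, OpenSea) with a Pearson
   chi-square, no continuity correction; per-category 2x2 tests give each
   enrichment a direction.
6. **Replication and ranking.** A second cohort analyzed identically
   yields a replication set; the overlap is ranked by the mean of the two
   cohorts' mean absolute differences and the top 20 become the candidate
   marker panel.

### Interpretation choices

Two phrases in the selection rule are genuinely ambiguous, and the package
fixes defaults while exposing the alternative:

* *Which SD?* Criterion (1) is taken as the SD of beta across all 2n
  samples, because unlike criterion (2) it carries no "between twins"
  qualifier; `sd_mode = "pair_deltas"` switches to the SD of the signed
  within-pair differences across pairs.
* *Signed or absolute difference?* Criterion (2) uses the mean of
  |delta-beta|. The divergence direction is arbitrary per pair, so signed
  means cancel across pairs and would systematically miss recurrent
  discordance; the table still reports the signed mean alongside.

Student's pooled-variance t is the default (Welch behind a flag) and both
selection thresholds are strict inequalities, matching the "greater than
0.05" convention used throughout.

## The synthetic cohort generator

Array data for real twin cohorts is large and access-controlled, so the
package ships a generator whose output has the statistical structure the
analysis assumes, with known ground truth:

* **Bimodal baselines.** Probe baselines are drawn 45% low (0.05–0.15),
  10% intermediate (0.25–0.75), 45% high (0.85–0.95), mimicking the
  bimodal methylome an array measures.
* **Planted recurrent DMCs** (`n_recurrent`, default 500 of 20,000)
  diverge by `delta_effect` (default 0.10, jittered multiplicatively, sign
  random per pair) in a configurable fraction of pairs (default all).
  Planted probes draw their baseline from the intermediate component: a
  0.1 divergence is not realizable at beta 0.05 on a bounded scale, and
  real recurrent DMCs of that magnitude necessarily sit at intermediate
  methylation.
* **Within-pair noise** is zero-mean with SD
  `noise_sd * (1 + age_gamma * age)`. Defaults (`noise_sd = 0.017`,
  `age_gamma = 0.02`/yr, ages uniform on 18–65) make the per-pair DMC
  count span roughly 3–17% of probes from the youngest to the oldest
  pairs, the range observed in blood EPIC data of adult twin cohorts, and
  give the positive age trend the analysis should detect. Sex is assigned
  per pair and never read when drawing betas.
* **Between-pair variability** (`between_sd = 0.03`): each pair shares a
  baseline shift on the beta scale. Real CpGs vary between unrelated
  individuals, not only within pairs; without this term the
  cross-sample-SD filter would see planted probes hovering at its
  threshold, which is an artifact of an over-clean simulation rather than
  a property of the method.
* **Bounded-scale mechanics.** All perturbations are applied on the logit
  scale, scaled by the local derivative `1/(mu(1-mu))` so that a nominal
  beta-scale offset keeps its magnitude after the inverse transform;
  final values are clipped to [0.001, 0.999] as a guard only. This keeps
  betas in range without the distortion hard clipping would cause near
  the bounds.
* **Detection failures** are uniform at rate `detp_fail_rate` (default
  0.001; with 94 samples this leaves ~91% of probes complete, so the
  complete-case selection default still sees most of the array).

What the generator does *not* emulate: cell-type composition shifts, batch
effects, probe cross-reactivity, and SNP-affected probes. Tests passing on
synthetic cohorts therefore validate the *selection machinery* — that the
two-criterion filter recovers probes with genuine recurrent divergence at
the stated thresholds — not robustness to those real-data artifacts.

```{r example}
co <- generate_cohort(sim_config(n_pairs = 12, n_probes = 2000,
                                 n_recurrent = 80, seed = 42))
beta <- apply_detection_mask(co$beta, co$detp, alpha = 0.05)
deltas <- compute_pair_deltas(beta, co$sheet)
summary_tbl <- call_pair_dmcs(deltas, threshold = 0.05)
range(summary_tbl$dmc_count)
age_count_correlation(summary_tbl)$estimate

rec <- select_recurrent_dmcs(beta, deltas)
recovery_report(rec, co$truth)[c("sensitivity", "fdp")]
```

## Numerical and design notes

* **Thresholds** all default to 0.05 on the beta scale (detection alpha,
  per-pair delta, cross-sample SD, mean delta) and are recorded in every
  output header so deviations are auditable.
* **Ties and ordering.** Selection tables sort by descending mean
  absolute difference with probe-ID tiebreak; marker panels likewise by
  rank score. Re-running any stage, or the whole pipeline, on the same
  inputs is byte-identical — there are no timestamps or unordered hashes
  in any output.
* **Ranking rule.** The panel score is the arithmetic mean of the two
  cohorts' mean absolute differences; `"min"` (worst cohort, the
  conservative choice for assay design) and `"discovery"` are available.
  When both cohorts agree probe-wise the rules coincide.
* **Degenerate inputs.** Zero pooled variance with equal means gives
  t = 0, p = 1; constant age or counts make the correlation an error
  rather than a NaN; categories absent from both groups are dropped from
  the chi-square with a warning; an empty replication overlap is a
  warning at replication and an error at ranking.
* **Problem sizes.** The validation suite exercises cohorts up to 47
  pairs x 20,000 probes with 500 planted markers — large enough that
  binomial noise on recovery rates is small, while a full run of the test
  suite stays under a minute.

## Limitations

The per-pair DMC stage applies no multiple-testing correction, matching
the descriptive use of those counts; the recurrent selector is a fixed
double threshold, not a significance procedure, and its false-discovery
behavior under correlated probes (CpG blocks) is not modeled by the
independent-probe simulation. Replication requires both cohorts to share
the probe universe of one array platform. Coordinates are carried through
from the manifest (1-based) without any liftover or region arithmetic.
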