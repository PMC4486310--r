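---
title: "Integrating miRNA and mRNA time-series expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating miRNA and mRNA time-series expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcouple)
```

## The problem

MicroRNAs repress target mRNAs post-transcriptionally, and in many
systems repression is visible as degradation of the target transcript.
Sequence-based target predictors (TargetScan, miRanda, PicTar, Diana
MicroT and their kin) are sensitive but notoriously unspecific; paired
expression profiling of miRNAs and mRNAs over the same samples offers an
orthogonal, context-specific filter. `miRcouple` implements the classic
two-evidence integration for a small time-course design — two conditions
(a transfected clone versus its parental line), three time points, two
replicate arrays each, so 12 arrays per platform:

1. probe filtering (intensity and IQR),
2. per-day moderated-t differential expression (DE) with BH FDR,
3. per-day Pearson correlation of every DE miRNA against every DE gene
   probe,
4. union of sequence-based predictions over several databases,
5. intersection of the two evidence streams into miRNA–gene *couples*,
6. per-day bipartite network analysis of the couples.

The motivating application is an osteosarcoma differentiation model
(Saos-2 cells re-expressing CD99 and driven towards the osteoblastic
phenotype), but nothing in the code is specific to it beyond the curated
example tables in `inst/extdata`.

## Stage-by-stage model

### Probe filters

A probe is removed when its raw-scale intensity (`2^log2`) is at or
below 100 in at least 75% of samples, and then when its IQR of log2
values is at or below the median of all per-feature IQRs. Both
boundaries are inclusive, exactly as the rules are conventionally
stated. Two choices here were genuinely open and are fixed as follows:

* **Quartile convention.** IQRs use linear interpolation between order
  statistics (R's type 7), so tests can assert exact values.
* **Filter order.** The median of IQRs is computed over the features
  that survive the intensity filter, i.e. the filters apply in the
  order they are listed. The IQR rule is deliberately *not* idempotent
  (re-application shifts the median), which is why
  `preprocess_expression()` applies it exactly once.
* **miRNA platform.** Only "low or not expressed" filtering is
  conventionally specified for miRNA arrays; we apply the same
  intensity rule with a configurable threshold (default 100) and no IQR
  filter.

### Differential expression

`fit_moderated_t()` fits one cell-means model over all six
condition-by-day groups and pools the residual variance across the whole
series (residual df `12 − 6 = 6`), rather than fitting three separate
2-vs-2 comparisons that would leave 2 df each. Variances are shrunk by
empirical Bayes: the prior `(d0, s0²)` is estimated by moment matching
of `log s²` against the log-F distribution, with the trigamma inverse
solved by Newton iteration to 1e-8 — the standard closed-form approach
for moderated t-statistics. The per-day statistic is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{\overline{x}_{T,d} - \overline{x}_{P,d}}
             {\tilde s_g\sqrt{1/n_1 + 1/n_2}},\quad
  \mathrm{df} = d_0 + d_g,$$

with BH adjustment within each day's contrast (per-day reporting makes
per-contrast adjustment the natural scope). The limits `d0 → ∞` (fully
pooled) and `d0 = 0` (ordinary t) are exposed for testing and reduce to
the expected closed forms. Features with exactly zero residual variance
are flagged and receive the shrunken prior variance instead of an
infinite statistic.

Significance defaults: genes at `|logFC| ≥ 0.585` (fold change 1.5) and
adjusted `p ≤ 0.05`; miRNAs at `|logFC| ≥ 0.485` (fold change 1.4) and
**raw** `p ≤ 0.01`. The miRNA rule is conventionally stated without the
"after multiple test correction" clause that accompanies the gene rule,
so raw p is the default and `mir_use_adjusted = TRUE` gives the stricter
reading.

### Correlation screen

For each day, every DE miRNA is correlated (Pearson) against every DE
gene probe over that day's four paired arrays; significance requires
`|r| ≥ 0.7` and asymptotic `p ≤ 0.05` (both inclusive; positive and
negative correlations are both retained, since positive miRNA–target
correlations are biologically documented). Correlation is kept at probe
level on purpose: multiple significant correlations per gene may exist
and are only collapsed at the reporting stage. No multiplicity
correction is applied; the high `|r|` cut-off is the type-I-error
control.

A caveat worth stating plainly: with `n = 4` the t-based asymptotic
p-value reaches 0.05 only around `|r| ≈ 0.95`, so the `p ≤ 0.05` clause
dominates the `|r| ≥ 0.7` clause. Published tables produced by this
class of pipeline nevertheless report significant couples with `|r|`
near 0.81, so the effective sample scope or p formula used there is not
always recoverable. We therefore expose both interpretations:
`sample_scope = "per_day"` (default) or `"all_samples"`, and
`cor_p_method = "t"` (default) or `"fisher_z"`. Defaults follow the
literal per-day reading.

### Prediction union and intersection

Predictions are supplied as per-database (miR, gene) tables; a couple
enters the union when listed in at least `min_databases = 1` databases,
with no score threshold. Identifiers match case-insensitively with the
`hsa-` prefix stripped; star strands (`miR-425*`) stay distinct. DE
miRNAs absent from every database yield zero couples and are surfaced
as "no prediction coverage" rather than an error. The intersection
keeps probe-level significant correlations whose couple is predicted;
`collapse_probes()` then retains, per (miR, gene, day), the probe with
the largest `|r|`, breaking exact ties by the smallest probe ID (and
saying so). A couple's sign is the sign of the retained probe's
correlation. Per-day counts deduplicate couples within the day; the
"total" over days is union-style, so a couple significant at two days
is counted once.

### Networks

Each day's couples form a bipartite graph (miRNA nodes vs gene nodes,
no self-loops, parallel evidence collapsed). Freeman degree
centralization

$$C = \frac{\sum_i (d_{\max} - d_i)}{(n-1)(n-2)}$$

is used because it is exactly 1 for a star and 0 for any regular graph,
matching how hub-dominated subnetworks are conventionally described; it
is algebraically the NetworkAnalyzer form `(n/(n−2))(d_max/(n−1) −
density)`. Components are reported per connected subnetwork, largest
first, and centralization is computed per component. Sign and edge
multiplicity are ignored by the topology metrics. Export formats are
SIF (for interactive viewers) and GraphML (lossless round trip).

### Downstream

Over-representation uses the plain one-sided hypergeometric upper tail
with BH adjustment across sets and an adjusted-p cut-off of 0.1; the
"modified" Fisher test of commercial pathway suites is proprietary, so
the open hypergeometric form is substituted — a documented semantic
difference. The background universe is the array's gene list. PCA
ordination operates on feature-centred log2 values of a chosen probe
subset (typically one day's DE probes), with external reference
profiles included simply as extra matrix columns and no batch
correction.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions so that the whole
pipeline can be benchmarked without any external download: 12 samples
per platform (2 conditions × 3 days × 2 replicates), 2000 probes over
1500 genes (some genes carry 2–3 probes), 150 miRNAs of which 12 are
regulated, with 5–50 targets each. Regulated miRNAs carry a per-day
condition effect of magnitude 0.6–1.6 log2 units on a random non-empty
subset of days (mostly up-regulated, probability 0.8); each target gene
moves by `beta` times its miRNA's realized deviation with the couple's
sign, and 80% of regulated targets are down-regulated — the canonical
repression picture. Gene-level baselines span 7–12 log2 units with a
small common day drift (SD 0.3) and residual noise `sigma = 0.25`;
10% of genes are planted at raw intensity ≤ 100 and 5% as near-flat, so
both probe filters are exercised, and neither class is ever a
regulation target. Four synthetic databases list each true couple with
probability 0.7 and add false pairs at a rate of 0.001 of the non-true
pair space.

Where the array study this emulates reports no effect-size or noise
magnitudes, the defaults above were chosen once as realistic for
rma-scale microarray data (log2 noise SD in the 0.1–0.3 range,
detectable but not trivial effects) and are not revisited; they
reproduce the qualitative structure — ~80% down-regulated DE genes,
recoverable couples — rather than any quantitative target.

What the generator does **not** emulate: probe-level array physics,
background correction or normalization artefacts (matrices are born
normalized, matching the pipeline's entry point), miRNAs that switch
direction across days, and probes mapping to several genes. Passing
tests therefore demonstrate the pipeline's correctness and statistical
behaviour under the stated generative model, not performance on raw
array data.

One empirical subtlety the generator exposed: with `beta = 0` (no
regulation) the few probes *falsely* called DE at a day are, by
selection, strongly condition-separated there, and so correlate
strongly with truly DE miRNAs over that day's four arrays — the raw
correlation screen does not obey a naive 0.05-per-pair budget after DE
selection. The end-to-end couple count still does, because the
prediction intersection admits a false couple only when it is also
(falsely) listed in a database; the null-budget test in the suite is
stated on the pipeline's output for exactly this reason.

## Ground truth and scoring

The truth ledger (regulated miRNAs and genes per day, true couples with
sign) is written alongside the synthetic data but never read by the
pipeline. `evaluate_recovery()` scores reported couples per day:
precision is the fraction of reported couples that are planted couples;
recall is the fraction of planted couples, among those whose miRNA and
gene are both truly regulated that day, that were reported. An empty
report has undefined precision (NA) and zero recall; a day with no
truly regulated couples has undefined recall.

## Numerical choices and degenerate inputs

* Trigamma inversion: Newton, tolerance 1e-8, with asymptotic starts
  for extreme arguments.
* `|r| = 1` maps to `p = 0`; `r = 0` is "positive" by convention and
  never significant.
* Constant expression vectors are skipped with a warning in the
  correlation screen (and are an error for the scalar `pearson_r()`).
* Probe-collapse ties: smallest probe ID, logged.
* Single-feature matrices are a degenerate-input error for the IQR
  filter; `frac` outside (0, 1] is a parameter error; a correlation
  `r_min` above 1 is allowed and simply selects nothing (useful for
  null-configuration runs).
* Determinism: one global RNG stream per dataset, consumed in a fixed
  documented order (structure → baselines → miRNA plan → couples →
  expression → databases), so a seed fully determines every output
  byte.

## Problem sizes used by the test suite

The suite exercises full-size synthetic datasets (2000 probes) for the
end-to-end and recovery checks — 20 seeds for the recovery averages and
the beta-monotonicity property, 100 small-scale replicates for the
Monte-Carlo sign and null checks, 2000 random graphs for the
centralization property — sizes chosen so the whole suite completes in
well under a minute per heavy block while keeping Monte-Carlo noise far
from the asserted margins.

## Known limitations

* With two replicates per cell, per-day correlations rest on four
  points; the screen is a high-threshold filter, not an estimator, and
  per-couple `r` values should be read qualitatively.
* The moderated-t model assumes a common variance prior across the
  series; strong mean–variance trends would call for an
  intensity-dependent prior, which is out of scope.
* Gene-level prediction tables are expanded to probes via a one-to-one
  probe→gene map; probes hitting several genes are not modelled.
* The hypergeometric enrichment is an open substitute for proprietary
  "modified" Fisher variants; p-values are not comparable across the
  two.
* Published hub-subnetwork centralization values can only be reproduced
  when the corresponding edge list is available; the package instead
  guarantees the metric's exact values on canonical topologies.
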