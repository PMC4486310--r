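# miRcouple

Integration of paired microRNA and mRNA expression time series by
**expression correlation** and **sequence-based target prediction**, for
two-condition, multi-day array designs (e.g. a transfected clone versus
its parental cell line profiled at days 0, 7 and 14 with two replicates
each).

MicroRNAs repress their targets post-transcriptionally, and repression
often shows up as degradation of the target mRNA. Sequence predictors
(TargetScan, miRanda, PicTar, Diana MicroT, …) are sensitive but
unspecific; expression anticorrelation over the same samples is
context-specific but noisy. `miRcouple` intersects the two evidence
streams into miRNA–gene **couples** and analyses them as per-day
bipartite regulatory networks. The pipeline, for each day *d*:

1. **Filter probes**: drop features with raw intensity `2^log2 ≤ 100` in
   ≥ 75 % of samples, then features with IQR ≤ median IQR.
2. **Differential expression**: per-day moderated *t* on a pooled
   6-group linear model, with empirical-Bayes variance shrinkage
   `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, BH-adjusted within day.
   Genes: `|logFC| ≥ 0.585` (fold change 1.5), adjusted `p ≤ 0.05`;
   miRNAs: `|logFC| ≥ 0.485` (fold change 1.4), raw `p ≤ 0.01`.
3. **Correlation screen**: Pearson *r* of every DE miRNA × DE probe over
   that day's paired arrays; significant when `|r| ≥ 0.7` and asymptotic
   `p ≤ 0.05` (t transform, `df = n − 2`); no multiplicity correction.
4. **Prediction union**: couples listed in ≥ 1 database, no score
   threshold, restricted to DE features.
5. **Intersection**: significant **and** predicted; probes collapsed per
   (miR, gene, day) to the most-correlated probe.
6. **Networks**: per-day bipartite graphs; connected subnetworks;
   Freeman degree centralization `C = Σ(d_max − d_i)/((n−1)(n−2))`
   (1 for a star, 0 for regular graphs); SIF/GraphML export.
   Downstream: hypergeometric gene-set over-representation and PCA
   ordination.

A synthetic-data generator plants regulated miRNAs, signed couples and
filter-fodder probes under a ground-truth ledger, so precision and
recall of the whole pipeline are measurable end to end.

## Worked example

Curated tables from a published osteosarcoma CD99-differentiation time
course ship with the package. Applying the miRNA thresholds to the DE
table:

```r
library(miRcouple)
sig <- call_significant(example_mir_de(), lfc_min = 0.485,
                        p_max = 0.01, use_adjusted = FALSE)
table(sig$day, sig$direction)
#>       down up
#>   0      1  6
#>   7      3  1
#>   14     2 14
```

7, 4 and 16 miRNAs pass at days 0/7/14; at day 14, 14 of 16 are
up-regulated. Summarising the final integrated couple table:

```r
s <- summarize_couples(example_integrated_couples())
c(s$n_couples, s$n_mirs, s$n_single_target)
#> [1] 62  9  5
head(s$per_mir, 3)
#>              mir n_couples n_positive n_negative
#> 1    hsa-miR-34a        24          7         17
#> 2    hsa-miR-26b        22         20          2
#> 3 hsa-miR-342-3p         9          8          1
```

62 couples across 9 miRNAs; 5 miRNAs have a single target; the miR-34a
hub holds 24 couples, 17 of them negative (canonical repression), while
miR-26b's couples are mostly positive. A full synthetic run with
recovery scoring:

```r
ds  <- generate_dataset(sim_config(seed = 1))
run <- run_pipeline(ds$gene, ds$mir, ds$design, ds$predictions,
                    pipeline_config(), truth = ds$truth)
run$recovery
#>       day n_reported n_relevant precision    recall
#> 1       0        124        190 0.9919355 0.6473684
#> 2       7        187        268 0.9893048 0.6902985
#> 3      14        142        233 0.9929577 0.6051502
#> 4 overall        289        350 0.9861592 0.8142857
```

`run$summary` prints the per-stage count tables (DE features,
correlations computed/significant with sign split, predictions,
couples), `run$networks` holds the per-day graphs, and
`pipeline_config(out_dir = ...)` persists every intermediate as TSV.

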