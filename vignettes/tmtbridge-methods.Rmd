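---
title: "Multi-batch TMT quantification with reference-pool bridging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-batch TMT quantification with reference-pool bridging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Isobaric TMT10plex labelling quantifies ten samples per mass-spectrometry
run through reporter-ion intensities. Experiments larger than ten samples
must be split into several runs ("batches"), and reporter intensities are
only comparable within a run: ionization efficiency, labelling efficiency
and instrument drift imprint a batch signature on every channel. The
design `tmtbridge` targets is the bridging design used in salivary
proteomics: every batch carries, besides its experimental samples, one
pooled unstimulated reference channel per participant, made from the same
pooled material in every batch. These pools anchor all cross-batch
comparisons.

`tmtbridge` implements the complete analysis path from a searched PSM
(peptide-spectrum match) table to differential-abundance calls:

1. **Filtering** — PSMs that are unassigned, have a missing or zero
   reporter intensity in any declared channel, or exceed the q-value
   threshold are removed (counts per rule are logged).
2. **Sum scaling** — within each batch, every channel is multiplied by
   (mean column total) / (column total), equalizing total reporter signal
   across channels; this corrects loading/labelling differences.
3. **Reference-pool normalization** — every peptide row is divided by the
   geometric mean of its two pool-channel values, so each peptide is
   expressed relative to pooled unstimulated saliva and its pool geomean
   is exactly 1.
4. **Roll-up** — peptides are grouped by primary accession (the first
   accession listed by the search engine) and the protein intensity is
   the geometric mean of its peptide intensities per channel.
5. **Batch integration** — batches are concatenated on the proteins
   present in all of them and corrected with a parametric empirical-Bayes
   location/scale model (below).
6. **Cross-batch variability** — a pool-normalized PCA distance statistic
   that needs no protein intersection (below).
7. **Clustering** — PCA of the corrected matrix or of per-condition
   geometric means, with the cluster count chosen by x-means and
   assignments by k-means.
8. **Differential abundance** — geomean fold changes versus the pools and
   one-sample t-tests, with up/down calls and optional GO
   over-representation.

Everything is exercised end-to-end on a synthetic-data generator with
known ground truth, so each stage's behaviour is testable without any
external download.

## The empirical-Bayes batch model

On log2 intensities, the model assumes each protein $g$ in batch $i$ is
shifted by an additive batch effect $\gamma_{ig}$ and has its variance
inflated by a multiplicative factor $\delta_{ig}^2$. The algorithm:

1. standardizes each protein by its grand mean and pooled variance;
2. estimates $\hat\gamma_{ig}$ (mean of the standardized residuals per
   batch) and $\hat\delta_{ig}^2$ (their per-batch variance);
3. fits batch-level hyperpriors by the method of moments — a normal prior
   on $\gamma$ and an inverse-gamma prior on $\delta^2$;
4. iterates the conditional posterior means $\gamma^*_{ig}$,
   $\delta^{2*}_{ig}$ to convergence (absolute change below $10^{-6}$,
   at most 500 iterations; non-convergence is flagged on the returned
   model, not an error);
5. subtracts $\gamma^*$, divides by $\delta^*$, and de-standardizes.

Matrices are stored on the linear scale; the log transform is internal.
Shrinkage always moves $\gamma^*$ toward the batch prior mean — this
contract is asserted entry-wise in the test suite. Two degenerate cases
get explicit treatment: if all $\hat\delta$ of a batch coincide, the
moment-matched inverse-gamma prior collapses to a point mass and
$\delta^*=\hat\delta$ is used directly; proteins with zero variance
inside some batch are excluded from the EB machinery entirely and
corrected by location only (they are listed on the model object).

No condition covariates enter the standardization — the workflow this
package reproduces used none. A practical consequence, visible in the
synthetic experiments, is that regulated proteins' within-batch variance
absorbs part of the condition effect, so the scale step *attenuates*
their fold changes by roughly 10–20% under the default simulation. The
package therefore also exposes the concatenated, uncorrected matrix, and
fold-change recovery is characterized on it; significance and direction
of calls survive the correction essentially unchanged.

## The pool-relative distance statistic

The empirical-Bayes correction can only use proteins observed in *every*
batch, which in the emulated design discards roughly two thirds of the
proteome. The complementary statistic avoids intersection entirely: PCA
is computed on each uncorrected batch separately (log2, mean-centered
per protein, no unit-variance scaling), and for every sample the
Euclidean distance to *its own participant's* unstimulated pool is
measured in the first two score dimensions, then divided by the distance
between the batch's two pools. Because the pools are aliquots of the
same pooled material in every batch, their mutual distance captures that
batch's intrinsic scale, and the ratio is comparable across batches.
Three properties pin the statistic down, and all are tested:

* the two pools expressed relative to themselves are exactly 1;
* multiplying a batch's entire log2 matrix by a constant changes raw
  distances but not relative ones;
* the mean relative distance responds monotonically to an injected
  condition shift.

Two score dimensions are the default (the statistic mirrors what a
2-D PCA plot shows); `n_components` is configurable, and PCA
sign/rotation ambiguity is irrelevant because only distances are used.
If the two pools coincide in score space the reference is degenerate and
the batch is rejected with an error rather than returning unstable
ratios.

## Clustering

k-means uses Lloyd's algorithm with k-means++ seeding, 10 restarts by
default, keeping the restart with the lowest within-cluster sum of
squares; given a seed the result is deterministic, and the WCSS trace of
the winning run is non-increasing (asserted per run). x-means chooses the
cluster count: starting from `k_min`, every centroid is tentatively split
in two by a local 2-means, and a split is kept when it improves the
Bayesian Information Criterion under a spherical-Gaussian model with a
shared per-dimension variance. The search records every configuration it
visits and returns the one with the best *global* BIC — the recorded-best
rule protects against locally attractive splits of a genuine single
Gaussian. With `k_min == k_max` the function reduces exactly to k-means
with the same seed. Agreement between a grouping (e.g. participant) and
the clustering is summarized as the fraction of each group in its modal
cluster, with ties broken toward the lowest cluster index.

## Differential abundance

Reference normalization makes the unstimulated level 1 by construction,
so a condition's fold change is the geometric mean of its normalized
sample values over both participants (equivalently, the ratio of the
condition geomean to the pool geomean — both forms are computed and agree
on clean data). Significance is a two-sided one-sample t-test of the log2
values against 0, pooling both participants' replicates (n = 6 in the
emulated geometry); proteins with zero variance get a missing p-value. A
protein is called *up* when p < 0.05 and its fold change reaches 1.5,
*down* when p < 0.05 and the fold change is at most 0.667. The
thresholds are a reconstruction from the magnitudes the bridged design
is powered for (the smallest spiked up-regulation is 1.52 and the
down-regulations span 0.43–0.66), not a universal rule; both thresholds
and the alpha gate are arguments. Benjamini–Hochberg adjusted p-values
are reported alongside but do not gate the default call. Note that a
true fold change sitting *on* a threshold (1.52 vs 1.5) is called "up"
in only about half of replicate experiments even by a perfect estimator
— direction and significance, not the threshold call, are the stable
recovery quantities at that effect size. GO over-representation uses the
one-sided hypergeometric tail with BH adjustment over tested terms.

## The synthetic-data generator

The generator emulates the study geometry: 6 batches x 10 channels, two
participants, eight mouth-rinse conditions (vehicle at two
concentrations, three TRP-channel agonists at two concentrations each)
with three repeats, and two pooled unstimulated reference channels per
batch. Intensities are built multiplicatively on the log2 scale —
protein baseline (N(16, 1.5²)) + peptide ionization offset (N(0, 0.7²))
+ condition log2 fold change + batch shift + noise — and exponentiated,
matching the geomean-based statistics downstream. Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 200 | per-batch identified sets of ~160–180 and a ~60–80 protein six-batch intersection, the observed study geometry |
| `protein_dropout_rate` | 0.17 | probability a protein goes undetected in a batch; 0.83⁶ ≈ 0.32 of proteins survive all six batches |
| spike fold changes | 1.52, 1.72, 1.81, 2.15, 0.52 | the regulated range observed for salivary cystatins and immunoglobulins |
| `noise_sd` | 0.25 log2 | within-condition reporter variability; no published estimate exists for this design, so this is a free choice made once |
| `batch_location_sd` | 0.5 log2 | batch shifts large enough that correction is necessary and measurable |
| `batch_scale_range` | 0.8–1.25 | mild per-batch variance inflation |
| `missing_channel_rate` | 0.05 | PSMs with ≥1 blanked reporter channel (filtered out, as in the source workflow) |
| `unassigned_rate` | 0.02 | accession-less PSMs |
| `flagged_q_rate` | 0.02 | PSMs with q-values above 0.05 (q ~ U(0.05, 1); clean PSMs draw q ~ U(0, 0.05)) |

The design generator places every condition on its own dedicated
channel(s) whenever that layout fits, as the canonical 10plex table does.
This is not cosmetic: if two replicates of a condition shared a batch,
they would share that batch's pool-noise after reference normalization
and be positively correlated, inflating the t-test's type-I error
(measured: ~0.072 under free scattering vs ~0.051 balanced).

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: inter-individual proteome
differences (both simulated participants share baselines and responses,
so participant clustering structure is absent by construction); ratio
compression from co-isolation interference; TMT label isotopic
impurities; intensity-dependent missingness (missingness is uniform at
random at channel level); and peptide-level disagreement within a
protein beyond independent noise. Conclusions about those phenomena need
real data.

## Numerical choices and degenerate inputs

* Zero intensities are treated as missing and the PSM removed — geomean
  and log2 are undefined at 0.
* Peptides with a zero pool value cannot be reference-normalized and are
  dropped (logged), rather than poisoning a whole channel.
* Sum scaling rejects a channel with zero total.
* The EB solver converges on absolute parameter change < 1e-6 (cap 500);
  protein-matrix round-trips hold to 12 significant digits; PCA is
  delegated to a dense SVD and checked against a direct
  eigendecomposition at 1e-8.
* x-means refuses to split clusters with fewer than 3 points (the
  pooled-variance estimator needs R − K ≥ 1), and a configuration with
  essentially zero residual variance is treated as unsplittable.
* Matrix states (`raw → sum_scaled → ref_normalized → concatenated →
  combat_corrected`) only move forward; readers and the pipeline refuse
  out-of-order transitions.

One deliberate tension is worth spelling out: sum scaling equalizes
*total* channel signal, so a genuinely regulated protein's contribution
to its condition's total is partially absorbed, compressing fold changes
by roughly the regulated share of total signal. In the zero-noise limit
the spiked ratio is recovered *exactly* only when sum scaling is skipped
(`quantify_batches(..., sum_scaling = FALSE)`); with the default 200
proteins and 5 spikes per condition the compression is well under 1% and
immaterial. The flag exists because which variant the original workflow
used is not documented.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances chosen to exercise every code path while keeping a full run in
well under a minute of compute per file: 200-protein simulations for
recovery and intersection checks (25–100 seeds where a rate is
estimated), a 2 000-protein single simulation for the null calibration,
50 proteins x 60 samples for the EB oracle comparison, and 60-point
planted clouds for cluster-count recovery.

## Worked example

```{r, eval = FALSE}
library(tmtbridge)

cfg <- default_pipeline_config(out_dir = "run1", seed = 42)
res <- run_pipeline(cfg)

res$filter_log               # PSMs removed per rule
res$corrected                # protein_matrix [combat_corrected]
summarize_by_condition(res$distances)
subset(res$differential, call != "none")
```

Each stage is also exported on its own (`generate_design()`,
`simulate_psm_table()`, `filter_psms()`, `sum_scale()`,
`normalize_to_reference()`, `rollup_proteins()`, `intersect_proteins()`,
`combat_correct()`, `per_batch_pca()`, `relative_distance()`,
`condition_geomeans()`, `xmeans_cluster()`, `fold_change()`,
`test_regulation()`, `go_enrichment()`), so the pipeline can be
re-entered at any point with real PSM tables read by
`read_psm_table()` against a design from `read_batch_design()`.

## Known limitations

* Protein inference is primary-accession grouping only; no parsimony or
  shared-peptide apportioning.
* Missing values are handled by intersection before batch correction; no
  imputation.
* The t-test pools participants; per-participant or paired testing is a
  straightforward variation but is not the default.
* The parametric EB variant only; no non-parametric mode.
* q-values are taken as given from the upstream search; no FDR
  re-estimation.
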