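---
title: "Drug mode-of-action networks from replicate treatment profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug mode-of-action networks from replicate treatment profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Connectivity-map style screens treat a cancer cell line with hundreds of
small molecules and record an expression profile per treatment. Querying
such a corpus with a disease or treatment profile nominates compounds with
similar effects — or, in *reverse* mode, compounds whose effect opposes a
tumor profile and are therefore therapeutic candidates. Three practical
obstacles limit the naive approach: profiles of the same compound on
*different* cell lines disagree, so pooling cell lines mixes cell-line
effects into drug effects; a sizable minority of replicate samples are
outliers that do not reproduce their siblings; and most compounds have only
two or three replicates, too few for t-statistics. `monet` implements a
pipeline built around these constraints for a single cell line: per-drug
signature selection with a replicate-consistency statistic, agreement-based
replicate quality control, a signature-based drug–drug distance, clustering
into modes of action (MoAs) at an empirically calibrated threshold, and
two-level (MoA, then drug) query ranking.

## From intensities to fold changes

When starting from background-adjusted probe intensities (absolute log2
scale) the preprocessing chain is:

1. `quantile_normalize()` on the untreated vehicle samples (every column is
   mapped onto the cross-column mean of order statistics; ties get the mean
   of their reference positions).
2. `rank_invariant_normalize()` of each treated sample against the vehicle
   baseline — the per-gene median of the vehicles. Genes whose rank moves by
   at most `rank_tolerance` (default 0.05, as a fraction of the gene count)
   between sample and baseline, excluding the extreme 5% of the baseline
   distribution at each tail, anchor a monotone piecewise-linear map
   (isotonic regression plus interpolation; linear extrapolation from the
   outer 10% of anchor points beyond their range). Fewer than 50 anchors
   triggers a median-shift fallback with a warning.
3. `median_polish_summarize()` collapses probes to one value per gene and
   sample: two-way median polish per gene block, at most 10 sweeps or a
   relative residual change below 1e-6; the per-sample summary is the
   overall plus column effect.
4. `assemble_fold_change()` subtracts, per treated sample, the per-gene
   median of its vehicle group (same batch and cell line). Everything
   downstream operates on these log2 fold changes.

The tolerances in step 2 and 3 are package choices: the rank-invariant
criterion and smoother are named but not parameterized in the methods
literature this design follows.

## The consistency statistic and its empirical null

Replicate fold-change profiles are standardized by their own standard
deviation across genes, `z = x / sd(x)` (no centering; fold changes are
already centered at zero by construction). For a gene with standardized
values `z_x`, `z_y` in two replicates, the consistency statistic is

```
R = z_x * z_y - |z_x - z_y|
```

`R` is large only when both replicates move the gene strongly, in the same
direction, by a similar amount; a discordant pair is penalized by both the
negative product and the magnitude gap. Because two or three replicates
cannot support a parametric null, the null distribution of `R` ("this gene
is not consistently differentially expressed") is sampled empirically:
`build_null()` draws random sample pairs from *different* drugs, reads a
random gene from each pair, and pools `n_draws` statistics. P-values are
upper-tail with an add-one correction, `p = (1 + #{R_null >= R}) / (n + 1)`.

Cross-drug pairing (rather than resampling within replicates) is the
package's reading of an ambiguous prescription: within-drug pairs carry
exactly the signal being tested, so they cannot represent the null. The
choice has one caveat to keep in mind on small corpora: if most drug pairs
share a mode of action — say a demo corpus with two MoAs — the cross-drug
null itself contains consistent pairs and becomes conservative, shrinking
signatures. The null is well calibrated when truly related drug pairs are a
small minority, which is the regime of any realistic screen (hundreds of
drugs, MoAs of a handful each).

A pair's signature (`select_pair_signature()`) keeps genes with
`p < alpha` (default `alpha = 0.001`, i.e. p < 0.1%) whose standardized
values agree in sign; the direction is `sign(z_x + z_y)`. A drug's
signature (`select_drug_signature()`) is the intersection of all its
pairwise signatures; the gene direction comes from the mean standardized
value and the reported p-value is the worst pairwise p. Drugs with one
sample (`single_sample`) or an empty intersection (`no_signature`) are
flagged and excluded downstream — the first round of quality control.

## Replicate quality control

For drugs with more than three samples (smaller drugs pass through), the
pairwise *agreement* of two replicates is the size of their pair signature
divided by the chance expectation `n_genes * alpha`. Two unrelated samples
score about 1 by construction; true replicates score many times that.
`filter_drug_samples()` iteratively removes the sample with the lowest mean
agreement to the others while any remaining pair falls below
`min_agreement`, stopping at two samples; a failing final pair removes the
whole drug. Ties are broken by removing the lexicographically larger sample
id, making the procedure deterministic.

`min_agreement` defaults to 2 — twice the chance count. The ceiling of the
agreement score is about `signature_size * recall / (n_genes * alpha)`
(with a 50-gene signature among 10,000 genes at `alpha = 0.001`, at most
about 5), so a floor must sit well below that ceiling yet well above the
chance level of 1; 2 separates the two regimes with a symmetric margin and,
unlike a higher fixed floor, does not silently couple the rule to the
signature size of the corpus at hand.

## Drug distance, background threshold, MoA network

Each surviving drug is summarized by its consensus profile — the per-gene
median fold change over QC-passed samples — with `var(a)` the variance of
that consensus across genes. For drugs `a`, `b` with signature gene sets of
size `n` and `m`:

```
S_ab = 1/2 * [ (1/n) * sum_{i in sig(a)} dir_i * b_i / var(b)
             + (1/m) * sum_{j in sig(b)} dir_j * a_j / var(a) ]
D_ab = D_max - S_ab,   D_max = max off-diagonal S
```

Each drug's signature is read out, direction-adjusted, in the other drug's
profile; the `D_max` convention makes the most similar pair sit at distance
0. Two deliberate readings: the readout is direction-adjusted (an unsigned
sum would score a shared *down*-signature as dissimilar), with
`signed = FALSE` available for the literal unsigned form; and the
denominator is the variance, as printed in the source method, not the
standard deviation.

Whether two drugs share a MoA is a hypothesis test against the population
distance distribution `p_b(D)`: the threshold is the lower-tail `p = 0.01`
quantile, and drug pairs closer than that are candidate same-MoA pairs.
`background_threshold()` estimates `p_b` two ways:

* `"pooled"` — the empirical quantile of all off-diagonal distances. This
  is exact when related pairs are a negligible fraction of all pairs (the
  large-corpus regime: with ~500 drugs in ~100 MoAs, same-MoA pairs are
  under 1% of pairs).
* `"reflected"` — the null component estimated by reflecting the upper half
  of the pooled distances around their median. Related pairs contaminate
  only the lower tail (they are closer than chance by definition), and the
  null distance of unrelated pairs is approximately symmetric, being a
  normalized sum of many weak gene readouts. `run_moa_pipeline()` defaults
  to this estimator because on compact corpora — including validation
  datasets with a few dozen drugs in a handful of MoAs, where same-MoA
  pairs exceed 10% of all pairs — the pooled quantile lands *inside* the
  related-pair mode and fragments every MoA.

MoAs are the clusters of average-linkage hierarchical clustering on `D` cut
at the threshold; singleton MoAs are expected and meaningful. Average
linkage is the package default for this correlation-like distance (the
linkage is configurable; the source method does not state one). Within each
MoA, drug pairs under the threshold form the intra-MoA edges; the MoA
center is the drug with the highest betweenness centrality on that
unweighted subgraph (ties: alphabetically first drug). Two MoAs are linked
when their closest member pair is under the threshold — the minimum, not
the average, because average linkage can leave two clusters unmerged at the
cut while a sub-threshold member pair still witnesses a secondary
relationship. MoA labels are assigned by each cluster's alphabetically
first member, so they do not depend on input order.

## Querying

A query is a log2 fold-change profile (a treated sample for MoA
identification, a tumor profile for therapeutic screening). Each network
drug's score is the mean direction-adjusted query value over its signature
genes present in the query (`drug_query_score()`); the query is not
rescaled, since every ranking below is invariant to positive scaling. A
MoA's score is the mean of its member drug scores (`aggregate = "max"` is
available; the mean is the default because a MoA claims a shared effect,
not a best-member effect). `similar` mode sorts MoAs and drugs within MoAs
by descending score; `reverse` mode by ascending score, so the compounds
most opposed to the query lead. Global ranks run down the MoA-grouped
list, mirroring the two-level report layout of connectivity-map style
tools. All ties break alphabetically, which makes reverse ranking of a
query *identical* to similar ranking of its negation — a property the test
suite asserts exactly. Queries must cover at least half of the network's
signature genes; drugs with no scorable gene are reported at the bottom
with a reason code rather than dropped.

## The synthetic generator

`generate_dataset()` emulates the structure the pipeline assumes: each MoA
owns a signature gene set with random up/down directions (optionally
overlapping between consecutive MoAs); every replicate sample of a drug in
that MoA is the signature pattern at `effect_size` noise-SD units plus
i.i.d. Gaussian noise; with probability `outlier_rate` a sample is replaced
by pure noise and recorded in the ground truth. `generate_probe_dataset()`
adds per-gene baselines, per-probe affinities and vehicle columns to
exercise the normalization chain. `generate_query()` emits a noisy
(anti-)aligned query for retrieval tests.

Defaults — 10,000 genes, 6 MoAs of 5 drugs, 3 replicates per drug, 50-gene
signatures at 5 noise-SD units, unit noise, 10% outliers — are the study
conditions used throughout the validation suite; the signature-recovery
checks use 2 replicates and the QC checks 6 replicates at effect 4, with
20–100 seeded repetitions per property. What the generator deliberately
omits: gene–gene correlation (real expression noise is structured),
heavy-tailed and batch-structured noise, dose dependence, and any probe
chemistry. Passing tests therefore demonstrate that the statistics and
algorithms do what they claim under their own model assumptions — planted
signatures are recovered, outliers removed, MoAs re-identified, queries
retrieved — not that real microarray data satisfies those assumptions.

## Numerical conventions and degenerate inputs

* Empirical p-values use the add-one convention and are never zero.
* All empirical quantiles interpolate linearly between order statistics
  (R's default type 7).
* An all-zero (zero-variance) profile yields an empty pair signature;
  `z_scale()` itself refuses zero-variance input.
* A degenerate background (all pairwise distances equal) returns that value
  as the threshold with a warning.
* Fewer than 10 off-diagonal distances refuse background estimation; fewer
  than 2 drugs refuse null construction.
* Deterministic tie-breaks everywhere: lexicographic in QC removal, MoA
  centers, ranking; the seeded generator and null are bit-reproducible, and
  seeded internals restore the caller's RNG state.

## Limitations

The pipeline inherits the method's core assumptions: signatures are
direction-consistent gene sets (no magnitude shrinkage or moderation, no
multiple-testing correction beyond the raw p < 0.1% cutoff — deliberately,
as the method predates and avoids FDR machinery); the distance sees only
signature genes; and the cross-drug null requires a corpus where most drug
pairs are unrelated. Identifier mapping between query and corpus is exact
string matching after whitespace trimming; harmonizing platforms is the
caller's job. Probe-level preprocessing assumes background-adjusted
intensities and does not re-implement RMA background correction.
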