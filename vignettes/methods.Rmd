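---
title: "Methods: site-aware multimodal classification of ADHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-aware multimodal classification of ADHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ADHD is diagnosed behaviorally; a quantitative aid would need to find
signal in structural and functional brain measurements that survives the
journey from group-level statistics to individual prediction. The ADHD-200
setting makes that concrete: eight research sites contribute training
cohorts with very different class compositions (two sites have *only*
typically developing children; one site measures no IQ; one contributes no
training data at all), and a classifier must predict TD vs. ADHD, plus the
ADHD subtype (combined vs. inattentive), for held-out children.

`adhdml` implements the full pipeline for this problem — feature
extraction, feature ranking, externally cross-validated subset selection,
per-site RBF-SVM classifiers with cross-site alignment, modality voting,
and competition-style scoring — together with a synthetic multi-site
cohort generator so every stage is testable without any imaging download.

# Feature extraction

**Connectivity matrices.** Pairwise Pearson correlation between ROI time
series, Fisher z-transformed (`atanh`), with `|r|` capped at `1 - 1e-7` so
perfect correlations stay finite. The matrix is symmetric, so the lower
triangle supplies the edge features: `R(R-1)/2` of them (79,800 for a
400-ROI functional atlas). Constant series cannot be correlated; their
rows are zeroed with a warning rather than erroring, because degenerate
series do occur at mask edges in real preprocessed data.

**Nodal power spectra.** One-sided amplitude spectrum per ROI
(`sqrt(Re^2 + Im^2)` per DFT bin). No detrending or windowing is applied —
the upstream preprocessing the features emulate has already detrended —
and the raw amplitude rather than a density is used. Whether amplitude or
squared power is the right per-bin feature is genuinely ambiguous in this
design space; amplitude is the default and the exponent is an argument.

**Voxelwise maps.** Global connectivity is each voxel's mean Fisher-z
correlation with every other in-mask voxel. Regional homogeneity (ReHo) is
Kendall's coefficient of concordance W between a voxel and its 26 spatial
neighbors, computed from per-series temporal ranks:
`W = 12 S / (m^2 (n^3 - n))` with `S` the squared deviation of the
per-timepoint rank sums. Ties are broken by average ranks without the tie
correction by default — the series are continuous, so ties have measure
zero — and the corrected denominator is available behind a flag.
Edge-of-mask voxels use only their in-mask neighbors (`m < 27`) rather
than being dropped, which keeps maps defined on small grids; a voxel with
no in-mask neighbor is undefined (`NA`).

# Graph metrics

Connectivity matrices are proportionally thresholded: the same fraction
`p` of each subject's strongest *positive* edges is retained
(`round(p R(R-1)/2)` edges; negative edges are always discarded; ties
break deterministically by weight, then row, then column). Metrics are
computed at 10–30% sparsity in steps of 5 and averaged across levels, for
weighted or binarized graphs.

Choices the literature leaves open, fixed here:

* weighted shortest-path length uses `d = 1/w`, the standard choice for
  connectivity weights;
* weighted clustering uses the Onnela geometric-mean formulation, with
  weights normalized by the maximum;
* local efficiency of a node is the global efficiency of its neighbor
  subgraph; regional efficiency is the mean inverse distance to all other
  nodes; betweenness is normalized by `(R-1)(R-2)/2` so it is a fraction
  of shortest paths;
* `gamma` and `lambda` normalize clustering and path length by the mean of
  an ensemble (default 100) of degree-preserving rewired graphs (10 swaps
  per edge, seeded); "equivalent numbers of nodes and edges" also admits
  an Erdős–Rényi null, available via `null = "er"`. Small-worldness is
  `sigma = gamma/lambda` identically;
* modularity is the best-of-5 seeded Louvain Q. Because the partition is
  algorithm- and seed-dependent, only the value Q — not the labels — is
  treated as a subject feature.

All deterministic metrics are validated against exhaustive brute-force
oracles (Floyd–Warshall, triangle counting, simple-path enumeration) on
thousands of random graphs of up to 8 nodes.

# Feature ranking: mSVM-RFE

Features are ranked by recursive elimination under a linear soft-margin
SVM: fit, standardizing features to mean 0/sd 1 on exactly the rows in the
fit (never the hold-out rows), eliminate the least useful features,
repeat. The single-fit criterion is the squared weight `w^2`. For
stability, the multiple-subsample variant fits the SVM on (default) 10
stratified 90% subsamples per pass and ranks by `mean(w^2)/sd(w^2)`,
rewarding usefulness that is large *and* stable. With one subsample at
fraction 1 the ranking reduces exactly to the single-fit algorithm.

For tractability on large feature sets, half of the surviving features are
dropped per pass while more than 5,000 survive, then elimination proceeds
one at a time (the `12000 -> 6000 -> 3000 -> one-by-one` schedule). `C` is
fixed at 1 for ranking fits and exposed in the configuration. Ties in the
criterion break by original column order.

In simulation, the subsample-averaged criterion makes the *top* of the
ranking — the part subset selection consumes — more reproducible under
jackknife perturbation of the data, while the ordering of the
uninformative tail can become noisier; the test suite asserts the former.

# Subset selection and tuning

The number of top features `k*` is chosen by **external** 10-fold
cross-validation: within each stratified fold, features are ranked on the
training nine-tenths only, then for each candidate `k` an RBF-SVM is tuned
by internal stratified 10-fold grid search (`C` in `2^-5..2^15`, kernel
width in `2^-15..2^3`, log-2 spaced; ties prefer smaller `C`, then
smaller width) and scored on the held-out tenth. `k*` maximizes the mean
hold-out accuracy, ties to the smallest `k`. Hyperparameters are re-tuned
per (fold, k) — the stricter reading of nested cross-validation — which
the small grid keeps affordable.

Ranking inside the fold is what makes the resulting accuracy estimate
unbiased: with permuted labels the selected model's expected accuracy sits
within binomial noise of the majority-class rate, and the suite checks
exactly that. The default `k` grid is an approximately geometric ladder
(1, 2, 5, 10, 25, 50, ...) capped at the feature count; accuracy is the
selection objective (the competition metric), with balanced accuracy
available for heavily skewed sites.

# Site-specific classifiers and alignment

One classifier is trained per site and per modality on *all* of that
site's training rows, using the top `k*` features, standardized by the
site's own statistics. A site lacking a feature (as with missing IQ)
simply trains without it; imputation across sites is never used, though a
median-impute flag exists for prediction-time gaps.

Sites without complete labeled training data use an across-site model
after feature-wise mean alignment: each site's TD mean is mapped onto the
pooled TD mean (exactly — the post-condition holds to machine precision,
and within-site class contrasts are untouched because the correction is a
pure per-site shift). A site with no labels at all is aligned more crudely
on its grand mean. Only means are aligned; variance rescaling exists
behind a flag but is off by default, as mean alignment is the documented
procedure and variance matching is an extrapolation.

# Voting, subtypes, scoring

Each modality-level model casts one TD/ADHD vote per test subject; the
modal vote wins, with ties going to TD (the majority class, and the class
whose correct calls carry full weight in scoring; the rule is
configurable). Subjects called ADHD receive the modal ADHD subtype among
their site's ADHD training subjects — the site-specific pretest
probability — with ties to ADHD-C, the more prevalent subtype overall.

Scoring reports three-class accuracy, two-class sensitivity and
specificity, subtype accuracy among true-ADHD subjects called ADHD, and
points under a 1 / 1 / 0.5 / 0 scheme (correct TD / correct ADHD with
correct subtype / correct ADHD, wrong subtype / otherwise). The scheme is
inferred from the published half-point totals and maximum and is
configurable. Prevalence percentages round half away from zero, the
convention that reproduces the published demographic summaries.

# The synthetic cohort generator

The generator's defaults reproduce the training-set conditions: the
seven-site class-count table (491 TD / 163 ADHD-C / 11 ADHD-H / 111
ADHD-I), a −9 point mean IQ shift in ADHD with population sd 15, IQ
missing site-wise at NI, site-specific age ranges (no OHSU subject above
12, none below 10 at Pitt), female fractions per class matching the
male-skewed prevalence, and T = 176 samples at TR = 2 s band-limited to
0.009–0.08 Hz. T and TR are not published per site; the defaults are
configurable, not asserted. Site IQ means (105–115) are plausible
research-cohort values chosen once.

ROI series are drawn by frequency-domain masking of white Gaussian noise
*before* covariance coloring — simple and exactly controllable, unlike an
IIR filter — then colored by the Cholesky factor of a class-dependent
covariance: identity plus planted edges whose Fisher-z value differs by
`d` between classes. Voxel data are locally smoothed Gaussian noise plus,
inside a planted block, a shared signal whose variance fraction is larger
for ADHD subjects, which raises Kendall's W there. Morphometry is a
747-column battery (9 measures × 34 cortical regions × 2 hemispheres + 3
measures × 45 segmentations) with standardized class shifts on configured
columns. ADHD-H subjects are generated but excluded downstream by default,
mirroring their exclusion from prediction.

What the generator does *not* emulate: hemodynamics, motion artifacts,
scanner-specific noise spectra, registration error, or realistic
correlation structure between modalities. Passing tests therefore
demonstrate that the machinery is correct and unbiased, not that real
imaging data carry this much signal.

# Problem sizes and numerical choices

The test suite and the acceptance script exercise the pipeline at reduced
scale, chosen as the smallest sizes at which each property is
demonstrable: 2–3 sites of 30–50 subjects, 6–8 ROIs at T = 96, 100-feature
ranking problems, 5×5×5 voxel grids, external cross-validation with 3–5
folds, and an elimination schedule switching to one-by-one below 16–64
features. The end-to-end demonstration uses coarser hyperparameter grids
(`2^-9..2^3`) than the full study grid, and 20-graph null ensembles rather
than 100. Each scaled setting is an explicit argument of the corresponding
configuration object; the study-scale values remain the defaults of
`rfe_config()`, `select_config()` and `metrics_across_sparsities()`.

Degenerate inputs are handled deterministically throughout: correlation
caps before `atanh`; zero-variance features standardize to constant zero
and get zero SVM weight; subsamples that lose a class are redrawn with an
incremented seed (logged); a sparsity level with no finite path length is
excluded from the cross-level average with a warning; empty vote sets are
an error. Every randomized stage draws a named seed from the run's master
seed via a documented integer hash, so any stage can be re-run in
isolation and identical configurations give byte-identical artifacts.

# Known limitations

* The alignment corrects means only; site differences in scale or
  covariance pass through.
* Louvain modularity is partition-dependent even seeded; Q values are
  comparable only within a fixed package version.
* The competition point scheme and the subsample fraction of the ranking
  are reconstructed from published totals and the cited resampling scheme
  respectively; both are configurable rather than asserted.
* The synthetic null ("no planted effects") makes class and site exactly
  exchangeable given the generator; real no-signal data would still carry
  site-demographic confounds.
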