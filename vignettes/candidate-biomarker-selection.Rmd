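---
title: "Candidate biomarker selection from spectral-count proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate biomarker selection from spectral-count proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsel)
```

# The problem

Label-free shotgun proteomics quantifies each protein by its spectral count:
the number of MS/MS spectra assigned to it in one LC-MS/MS run. A typical
discovery experiment yields a matrix of a few thousand proteins by a few
dozen runs, with runs grouped into biological classes (here the motivating
design is three classes of cell-line secretomes — carcinoma, melanoma and
non-cancerous — with six runs each). The analytical task is to reduce those
thousands of proteins to a short, ranked panel of candidate biomarkers that
discriminates the classes, with an honest estimate of how well a classifier
built on that panel would perform on unseen samples.

protsel implements this as a pipeline of: a low-count filter; three
complementary selectors (a univariate beta-binomial count test, the
semi-multivariate nearest shrunken centroids classifier, and multivariate
linear SVM recursive feature elimination); double cross-validation for the
two classifiers; concordance analysis of the resulting ranked lists; and
clustering diagnostics that quantify, before and after selection, how
cleanly the samples group by class.

# Models and procedures

## Count filtering and feature scales

Proteins whose total spectral count across all runs is at most 2 are
discarded: one or two spectra in an entire experiment cannot carry class
information, and such rows only add noise to distance computations. The sum
across runs is the default aggregate; the per-run maximum is available via
`aggregator = "max"` because the total-versus-maximum reading of such a
filter is genuinely ambiguous — with a threshold this low the two differ for
few proteins.

Downstream methods work on one of three feature scales: per-run relative
abundances (count divided by the run's total spectra; the default, since it
removes run-depth differences), raw counts, or per-training-fold z-scores.
The clustering diagnostics z-score each protein across runs, mapping
constant rows to zero so they are neutral in Pearson and Euclidean
distances.

## Beta-binomial differential abundance test

For protein $i$, the count $y_{ij}$ in run $j$ is modeled as the number of
successes in $T_j$ trials, where $T_j$ is the run's total spectral count.
The success probability is beta-distributed with mean $\pi$ and
overdispersion $\theta$ (shape parameters $\alpha = \pi/\theta$,
$\beta = (1-\pi)/\theta$), so between-run variability beyond binomial
sampling is absorbed by $\theta$; at $\theta \to 0$ the model collapses to
the binomial. The null model shares one $\pi$ across all runs; the
alternative gives each class its own $\pi_g$ with a shared $\theta$. Both
are fit by maximum likelihood (BFGS on logit-$\pi$ and log-$\theta$, several
starts including the pooled and per-class proportions) and compared with
$\Lambda = 2(\ell_{\mathrm{alt}} - \ell_{\mathrm{null}})$, referred to
$\chi^2_{G-1}$. $\Lambda$ is floored at zero and the alternative
log-likelihood is never reported below the null's (the models are nested;
any discrepancy is optimizer jitter). Proteins are ranked by p-value and
selected at raw $p < 0.05$ by default — no multiplicity correction, matching
the selection convention this pipeline is built around; Benjamini-Hochberg
is available as an option. A one-way ANOVA on raw counts per protein is
provided as the classical univariate baseline.

## Nearest shrunken centroids

For feature $i$ and class $k$ the standardized centroid deviation is
$d_{ik} = (\bar{x}_{ik} - \bar{x}_i) / (m_k (s_i + s_0))$ with $s_i$ the
pooled within-class standard deviation, $s_0$ the median of all $s_i$, and
$m_k = \sqrt{1/n_k - 1/n}$. Soft-thresholding
$d'_{ik} = \mathrm{sign}(d_{ik}) \max(|d_{ik}| - \Delta, 0)$ shrinks the
class centroids toward the overall centroid; features whose $d'_{ik}$ vanish
in every class drop out of the classifier, so $\Delta$ doubles as the
feature-selection dial. Prediction minimizes
$\delta_k(x) = \sum_i (x_i - \bar{x}'_{ik})^2 / (s_i + s_0)^2 - 2\log\pi_k$
and class probabilities are proportional to $e^{-\delta_k/2}$. The
$\sqrt{1/n_k - 1/n}$ convention for $m_k$ is the default because it is the
standard error of $\bar{x}_{ik} - \bar{x}_i$ when the overall centroid
includes class $k$; the $\sqrt{1/n_k + 1/n}$ variant seen in some
descriptions is available as `mk_convention = "plus"`. Priors default to
empirical class frequencies. Feature ranking uses the unshrunken
$\max_k |d_{ik}|$, so the ranking is $\Delta$-independent and the survivors
at any $\Delta$ are exactly the top-$N$ of that ranking.

## SVM recursive feature elimination

One-vs-one linear soft-margin SVMs are trained on standardized features
(centered and scaled with training-fold statistics — required for squared
weights to be comparable across features; multiclass decomposition is
one-vs-one with vote ties broken by summed decision values). Each surviving
feature is scored by $c_i = \sum_b w_{bi}^2$ over the binary problems, and
the lowest-scoring features are removed: one per round once at most 200
survive, 10% of survivors per round above that (this bounds the number of
rounds on a ~1,700-protein matrix while keeping single-feature resolution
where it matters; the step is configurable and recorded). Criterion ties
eliminate the lexicographically larger protein id, making the ranking
deterministic. The final ranking is the reverse elimination order. Because
the survivors at size $N$ are exactly the final top-$N$, the models trained
along the elimination path double as the top-$N$ classifiers evaluated in
the inner cross-validation loop.

## Double cross-validation

Tuning a classifier and estimating its error on the same folds is
optimistically biased, so both classifiers run inside a nested scheme: the
outer loop (stratified 6-fold by default, holding out one run per class per
fold in the 3x6 design; leave-one-out available) estimates prediction error
on samples never seen by any tuning decision, while an inner loop
(stratified 5-fold on the outer-training set) picks the NSC shrinkage
$\Delta$ (30-point grid from 0 to $\max|d_{ik}|$) or the SVM cost $C$ (grid
$\{0.01, 0.1, 1, 10, 100\}$) and the subset size $N$. The subset-size rules
differ by design: SVM-RFE takes the smallest $N$ attaining the minimal mean
inner error; NSC breaks error ties by the larger summed probability assigned
to the true class, then the smaller $N$. After the outer loop the same inner
tuning is applied once to the full data set and the model is refit to emit
the reported ranked list; outer-fold error, the confusion matrix and
one-vs-rest sensitivity/specificity come exclusively from held-out
predictions. All fold randomness flows from one recorded seed, so reports
are byte-reproducible; perturbing an outer-test fold's counts provably
leaves that fold's tuning untouched (this is asserted in the test suite).

The fold counts themselves are a design choice — the motivating study does
not record its folds — so they are explicit configuration, and DCV-derived
numbers are expected to match published counterparts only approximately.

## Class association, concordance, clustering diagnostics

Each selected protein is associated with the class whose mean relative
abundance deviates most from the overall mean in standardized units
($(\bar{x}_{ik} - \bar{x}_i)/(s_i + s_0)$, an NSC-style decision-boundary
rule applied uniformly to all three methods' lists), with an up/down
direction and an ambiguity flag when class means coincide. Ranked lists are
compared by the Jaccard coefficient over top-$k$ prefixes (mean pairwise as
the headline curve, the 3-way coefficient alongside) and the optimal subsets
by a 7-region Venn partition. Sample structure is summarized by hierarchical
clustering on the Pearson distance ($1 - r$) of z-scored profiles, a
neighbor-joining tree built from the Euclidean distance matrix, and
silhouette coefficients computed both from the distance matrix and from the
tree's path-length distances. Average linkage is the hierarchical default
(logged in reports; the original platform's default is not recoverable).
Negative NJ branch estimates — possible on non-additive data — are clamped
to zero with the deficit moved to the sibling branch, preserving local leaf
distances; silhouettes of singleton classes are 0 by Rousseeuw's convention.

# The synthetic-data generator

`synthetic_spec()` / `generate_counts()` emulate the motivating design:
three classes by six runs, per-run totals uniform on 7,500-9,500 spectra,
~1,700 proteins at post-filter scale, log-normal baseline relative
abundances (sdlog 2, matching the heavy-tailed abundance distributions of
shotgun data). Planted proteins have their relative abundance multiplied by
a fold effect in one class, after which profiles renormalize; counts are
drawn multinomially when $\theta_{\mathrm{sim}} = 0$ (column sums then equal
the requested totals exactly) and beta-binomially otherwise.

The default overdispersion required an explicit calibration decision. In the
$\alpha = \pi/\theta$ parameterization, $\theta$ is approximately the
intraclass correlation between spectra, so at 8,000-spectra depth even
$\theta = 0.05$ inflates variances several-hundred-fold and drives pairwise
replicate correlations to near zero — nothing like real replicate LC-MS/MS
runs, whose pairwise $R^2$ is reported in the 0.64-0.96 range for this kind
of data. The default is therefore $\theta_{\mathrm{sim}} = 0.001$, which
places simulated within-class replicate $R^2$ at about 0.75-0.85, inside
that range; the type-I-error simulation in the acceptance checks still uses
$\theta_{\mathrm{sim}} = 0.05$ deliberately, as a harsher stress test of the
test's calibration under strong overdispersion.

`plant_effects()` chooses which proteins carry effects: by default inside
the abundance-rank window from the top 10% down to the median, split evenly
across two classes. The window avoids the most abundant proteins (a fold-10
effect there shifts the whole per-run composition, so renormalization
compresses the very effect being planted) and sub-median proteins (removed
by the low-count filter regardless of effect); two affected classes keep all
three classes mutually separable, which a single affected class would not.

What passing on such data does and does not show: the generator reproduces
count discreteness, depth variation, heavy-tailed abundances, compositional
coupling and overdispersion, but not peptide-level identification artifacts,
shared-peptide ambiguity, batch effects, or missingness beyond sampling
zeros. Recovery rates on planted effects are therefore upper bounds on what
identical settings would achieve on real data.

# Numerical choices and degenerate inputs

* $\theta$ is optimized on a log scale, $\pi$ on a logit scale; proportions
  are clamped away from 0/1 only for starting values, not in the
  likelihood. Zero-count classes are handled by the likelihood itself
  (no pseudocounts by default).
* Features with zero pooled spread and $s_0 = 0$ get $d_{ik} = 0$; constant
  rows z-score to zero; a constant vector's Pearson distance is defined
  as 1 to everything.
* Equal-count ANOVA rows (no variance anywhere) take $p = 1$; infinite F
  (zero within-class, nonzero between-class variance) takes $p = 0$.
* All ranking ties break deterministically: by descending test statistic
  then protein id (beta-binomial), by protein id (NSC score ties), by
  eliminating the lexicographically larger id (RFE criterion ties).
* The low-count filter is idempotent, and run totals are recomputed after
  any protein subsetting.

# Problem sizes used in the checks

The test suite and the acceptance script run the full pipeline at the
design's native scale — 1,700 proteins by 18 runs with 50 planted fold-10
effects — plus a 1,000-protein null for test calibration; unit tests use
smaller matrices (tens to hundreds of proteins) chosen so each property is
exercised in seconds. The double cross-validation defaults (6 outer, 5
inner folds, full $C$ grid) are used unchanged at full scale.

# Known limitations

* The beta-binomial p-value relies on the $\chi^2$ approximation to the
  LRT; for proteins observed in only a handful of spectra it is
  conservative.
* SVM-RFE rankings below the elimination step's resolution (above 200
  survivors, 10% of features leave per round) are block-granular.
* The class-association rule is a single uniform convention; the original
  study's exact supplementary rule is not recorded, so per-class panel
  counts are comparable only in spirit.
* NJ trees are point estimates; no support values are computed.
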