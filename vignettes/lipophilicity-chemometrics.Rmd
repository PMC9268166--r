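---
title: "Comparing lipophilicity scales: SRD, chemometrics and GA-PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lipophilicity scales: SRD, chemometrics and GA-PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipochemo)
```

## The problem

Lipophilicity — the affinity of a molecule for nonpolar environments,
classically logP or, for ionizable molecules at physiological pH, logD —
can be estimated by many computational algorithms and measured by many
chromatographic systems, and the resulting scales disagree. For the
27-compound sulfonamide series packaged here, the in-silico predictions
for a single molecule can span more than seven logP units. This package
implements a complete chemometric workflow for deciding which scale best
represents a compound series, how the scales group, and which molecular
descriptors drive chromatographic retention and biological activity.

The packaged data are two plain-text tables: 27 compounds x 7
computational logP scales, and 27 compounds x 9 chromatographic and
auxiliary columns (CHI indices on IAM and C18 phases, their transformed
surrogates, extrapolated log k~w~ values on C8/CN/phenyl phases, pKa and
pIC~50~ against the HCT-116 colon-cancer line).

## Index transforms

Gradient-HPLC retention is expressed as the chromatographic
hydrophobicity index (CHI, roughly 0–100). Two fixed linear calibrations
map it onto logk/logD-like scales:

$$\log k_{IAM} = 0.045\,\mathrm{CHI}_{IAM} + 0.42, \qquad
  \mathrm{CHI}\log D = 0.0525\,\mathrm{CHI}_{C18} - 1.467.$$

The constants are exposed in `transform_constants` and are not meant to
be edited; `chi_to_logk_iam()` and `chi_to_chi_logd()` apply them.
Consensus logP is the arithmetic mean of the five SwissADME predictions
(`consensus_logp()`).

Because the packaged tables print values rounded to two decimals, the
package compares recomputed transforms to printed columns after rounding
half-away-from-zero (`round_half_up()`, with a 1e-8 guard absorbing
binary floating-point error just below the .5 boundary) and at a
tolerance of one unit in the last printed digit. The consensus column
tolerates ±0.01 because its inputs are themselves pre-rounded (compound
3 differs by 0.006 for exactly this reason).

## Sum of ranking differences

`srd()` takes a compounds x measures table. Each column ranks the
compounds (average ranks on ties); the reference ranking is the ranking
of the row averages — a "consensus" reference. For measure $j$,

$$\mathrm{SRD}_j = \sum_{i=1}^{n} \lvert r_{ij} - r_i^{ref}\rvert,$$

normalized to percent of the maximum $(n^2-1)/2$ (odd $n$) or $n^2/2$
(even $n$). Small SRD means the measure ranks the compounds like the
consensus.

### Column scaling for the reference

Per-column ranks are invariant to monotone transforms, but the row
average is not: the measures must first be brought to a common scale.
The package supports `"range"` (min–max) scaling, `"zscore"`
autoscaling, and `"none"`, with **range scaling as the default**. This
was a genuinely open design choice, settled empirically on the packaged
table: with range scaling the 12-measure analysis reproduces every
qualitative feature reported for this series — consensus logP closest to
the reference; the CN and phenyl retention factors and CHI logD furthest;
WLogP, Silicos-IT logP and XLogP3 tightly grouped; logk~IAM~ and KOWWIN
logP adjacent — whereas z-scoring swaps two measures in the far group.
Range scaling is also the common preprocessing choice in the SRD
literature when measures live on incommensurate scales.

### CRRN: the random-ranking null

Whether an SRD value is better than chance is judged against the null
distribution of SRD between a random permutation and a fixed reference
(comparison of ranks by random numbers). `crrn()` computes it two ways:

* **Exact** (n ≤ 10): the distribution follows from the polynomial
  permanent of the matrix $x^{|i-j|}$, evaluated by Ryser's formula —
  algebraically identical to enumerating all $n!$ permutations, and
  cross-checked against literal enumeration in the tests. For $n=3$ the
  distribution is $\{0\!:\!1/6,\; 2\!:\!1/3,\; 4\!:\!1/2\}$ with mean
  $8/3$; in general the mean is $(n^2-1)/3$.
* **Monte-Carlo** (any n): seeded uniform random permutations, default
  $10^6$ draws. For $n = 27$ the 5/25/50/75/95% quantiles land at
  192/222/244/264/292 raw SRD units (the support is the even lattice, so
  empirical quantiles can sit one lattice step from a smooth-fit value).

Quantiles are reported empirically rather than through a Gaussian fit:
the quantiles are what is used downstream, and the empirical ones make
no distributional assumption.

### Cross-validation and grouping

`srd_crossvalidate()` partitions the compounds at random into 7 nearly
equal folds (27 → 4,4,4,4,4,4,3), leaves each fold out in turn, and
repeats the whole computation (rescaling, reference, SRD%) on the
remainder, giving 7 SRD% values per measure for box–whisker display.
Measures are then compared pairwise with an exact two-sided Wilcoxon
matched-pair test (`wilcoxon_matched_pairs()`): zero differences are
dropped, ties get average ranks, and the exact null distribution of the
signed-rank sum is built by generating-function convolution over the
$2^n$ sign assignments (ranks doubled so tied half-ranks become
integers) for up to 25 informative pairs, with the tie-corrected normal
approximation beyond. The convolution is identical to literal
enumeration and is verified against it in the tests.

## Correlation, PCA and clustering

`correlation_matrix()` is plain Pearson correlation.  `lipo_pca()`
standardizes the columns (sample SD, $n-1$) and decomposes by SVD —
equivalently, PCA of the correlation matrix, which removes the arbitrary
scale differences between measures. Signs are fixed deterministically
(the largest-magnitude loading of each component is made positive) so
results are reproducible across platforms. `hierarchical_cluster()`
applies Ward's minimum-variance linkage on Euclidean distances between
standardized measure vectors (or compound vectors), the standard
choice for clustered heatmaps of standardized chemometric data; the
tests verify the linkage against an independent Lance–Williams
recursion. On the packaged 13-column table (12 lipophilicity measures +
pIC~50~), cutting at $k=2$ separates the computational from the
chromatographic measures. pKa is excluded by default (it is not a
lipophilicity measure); pIC~50~ is included only on request.

## PLS and validation statistics

`pls_fit()` implements single-response NIPALS PLS on autoscaled
descriptors and a centered response; for one response the weight step
closes in a single pass ($w \propto X^T y$), so extraction is exact and
deterministic. Autoscaling inside the fit is the QSRR norm for
heterogeneous descriptor matrices; the choice is invisible to
predictions at full rank, where PLS provably equals ordinary least
squares (asserted to 1e-8 in the tests). `q2_loo()` computes
leave-one-out predictions, $Q^2_{loo} = 1 - PRESS/TSS$ (TSS about the
full-training mean) and $RMSE_{cv} = \sqrt{PRESS/n}$.

`validation_stats()` evaluates the external-validation battery on a
training/test pair: training $R^2$; $Q^2_{F1}$ (external residual sum of
squares against deviations from the *training* mean), $Q^2_{F2}$
(against the external mean), $Q^2_{F3}$ (per-observation variances,
training-set normalized), RMSEP, and Lin's concordance correlation
coefficient. Degenerate denominators yield `NA` plus an entry in the
`undefined` field — never infinities. $Q^2_{F1} \ge Q^2_{F2}$ whenever
the two means differ, an algebraic identity the tests assert on random
data.

## GA-PLS descriptor selection

`ga_pls()` evolves chromosomes of 5 distinct descriptor indices with a
3-LV PLS training-$R^2$ fitness, population 500 and per-gene mutation
0.1. The training/test split (18/9 by default, `split_minmax()`) always
keeps the compounds with the extreme endpoint values in training, so the
model never extrapolates beyond the training range of y.

The remaining operators were open design choices, settled by a
documented failure analysis on synthetic data with a planted informative
subset. With textbook positional uniform crossover and plain elitism,
the search reliably *converged prematurely*: with only 18 training
compounds, a 3-LV PLS can overfit five pure-noise descriptors to
$R^2 \approx 0.95$, and such lucky subsets take over the population
before the true subset (fitness $\approx 0.997$, a tiny basin among
$\binom{100}{5} \approx 7.5\times10^7$ subsets) is assembled. Three
standard remedies fix this without touching the fitness criterion:

* **set-semantics uniform crossover** — genes common to both parents are
  kept, the remaining slots are drawn from the parents' symmetric
  difference (positional crossover destroys shared building blocks in a
  subset encoding);
* **population uniqueness** — duplicate chromosomes are mutated away,
  preventing takeover by copies of one local optimum, plus 5% random
  immigrants per generation;
* **informed initialization** — a greedy beam search under the same
  fitness (partial subsets scored with as many LVs as they admit, beam
  width twice the descriptor count, bounded 50–250) seeds the initial
  population; elitism keeps its best candidate alive while the GA
  explores around it.

With these operators the search recovers a planted 5-descriptor subset
(27 compounds, 100 candidates, 5% noise) in 20/20 test seeds, and the
fitness trajectory is monotone by construction. The selected subset is
refit and fully validated (LOO $Q^2$, external statistics), and
`y_randomization()` (200 permutations of y on the fixed selected
descriptors) plus `leverage_ad()` (leverages on the autoscaled
descriptors with intercept, $h^* = 3(p+1)/n_{train}$, ±3σ standardized
residual band — the conventional Williams-plot thresholds) complete the
robustness assessment.

A config switch (`ga_config(fitness = "q2_loo")`) lets users optimize
LOO $Q^2$ instead; the default follows the training-$R^2$ convention.
The interpretation "5 descriptors per model" (rather than 5 per latent
variable) is used throughout.

## Synthetic data: what it emulates, and what it does not

`make_descriptor_dataset()` generates standard-normal descriptors with
optional exchangeable block correlation, a random 5-gene support with
coefficients drawn from $\pm U(0.5, 2)$ (bounded away from zero so the
support is identifiable), and Gaussian noise scaled to a fraction
(default 5%) of the signal SD. `make_lipo_table()` generates measure
families as positive-slope affine transforms of one latent lipophilicity
scale plus Gaussian noise. Both are pure functions of their seed.

These generators reproduce the *statistical structure* the methods
assume — a low-dimensional informative subset in a wide descriptor
matrix; measures that are monotone distortions of one latent property —
but not the *chemistry*: real descriptor blocks are heavy-tailed,
discrete and collinear in structured ways, retention noise is not
homoscedastic, and real lipophilicity scales differ by nonlinear (not
affine) distortions near ionization transitions. Passing the synthetic
recovery tests therefore demonstrates correctness of the algorithms
under their stated model, not performance guarantees on arbitrary real
series.

## Numerical choices and problem sizes

* Standardization uses the sample SD ($n-1$); zero-variance columns are
  an error naming the column.
* Exact CRRN is limited to n ≤ 10 (the permanent's cost grows as
  $2^n$); larger n uses Monte-Carlo, $10^6$ draws by default.
* Exact Wilcoxon p-values are computed up to 25 informative pairs.
* GA ties in the final ordering are broken by sorted descriptor index;
  SRD orderings break ties by measure name.
* The test-suite problem sizes — 100-seed SRD recovery replicates,
  20-seed GA recovery at 27x100, $5\times10^4$–$10^6$ CRRN draws —
  were chosen so the whole suite completes in a few minutes while
  keeping the binomial pass criteria (e.g. ≥18/20, ≥95/100) statistically
  meaningful.
* Near-constant descriptor removal defaults to variance ≤ 1e-8 on the
  unscaled matrix, mimicking routine descriptor cleaning.

## Known limitations

* The exact CRRN distribution assumes a tie-free reference ranking; a
  ties-aware null is not implemented (the packaged table's reference has
  no rank-order-relevant ties).
* PLS is single-response (PLS1); multi-response and nonlinear variants
  are out of scope.
* The commercial descriptor matrix behind the original QSRR models is
  not redistributable, so the GA-PLS workflow is demonstrated on
  synthetic or user-supplied descriptors; the published per-endpoint
  statistics are not reproduced by this package.
* The Williams-plot threshold $h^* = 3(p+1)/n$ and the ±3σ band are
  conventions, not tests with controlled error rates.
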