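---
title: "Estimating breast epithelial subtype proportions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating breast epithelial subtype proportions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistratify)
```

This vignette is the package's own account of the statistical machinery it
implements: the deconvolution model and its estimator, how signature matrices
are built, how single cells are labelled, and the numerical and design
choices made where the methodology admits more than one reasonable reading.

## The deconvolution model

Bulk-tissue genomic measurements are convolved signals: a methylation rate or
expression level observed in a tissue sample is a mixture of the signals of
the cell types present, weighted by their proportions. The model is linear,

$$X = A W + \varepsilon,$$

with $X \in \mathbb{R}^{p \times n}$ the bulk observations, $A$ the
cell-type signature matrix over $p'$ discriminative features, and
$W \in [0,1]^{k \times n}$ the mixing proportions, each column summing to 1.
For DNA methylation, entries of $X$ and $A$ are beta values — the fraction
of DNA strands methylated at a cytosine locus — which live in $[0,1]$ and,
because a convex combination of beta values is a beta value, make the
mixture interpretation exact. The package validates these range constraints
on construction of every container.

### The RLM-pseudo-inverse estimator

`deconvolve()` estimates each column of $W$ independently as
$\hat W_{:,j} = A^{\dagger} X_{:,j}$, where the pseudo-inverse is realised
by a robust linear fit (`MASS::rlm`, Huber $\psi$ with tuning constant
1.345, MAD scale estimate, no intercept — the model has none, and
proportions absorb any mean). Robustness matters because bulk data carry
features that are aberrant in individual samples (failed probes, somatic
events, mapping artefacts); the Huber loss downweights them smoothly instead
of letting them leverage the least-squares solution.

Three numerical choices deserve note:

* **Iteration budget.** The IRLS tolerance is $10^{-8}$ on the coefficient
  update with a cap of 400 iterations. Near the contamination level at which
  the Huber estimator transitions between fitting and rejecting a feature
  (~40% corruption in our simulations), the interleaved MAD rescaling makes
  convergence slow; a tight cap there misreports slow convergence as
  estimation failure, so the budget is deliberately generous. The cost is
  negligible at the package's problem sizes (tens of features, a handful of
  cell types).
* **Exact fits.** When the least-squares residuals are numerically zero the
  MAD scale is zero and IRLS weights are undefined; the OLS solution is then
  already the robust solution and is returned directly.
* **Inestimability.** A sample is flagged inestimable when the fit fails to
  converge or when thresholding (below) zeroes every coefficient. Flagged
  samples appear as `NA` columns and are excluded from downstream summaries;
  their rate is reported.

Raw robust coefficients can be slightly negative. The **adaptive noise
threshold** treats the most negative coefficient as a yardstick for the
noise floor: with $m = |\min_l \hat w_l|$ when the minimum is negative,
every coefficient with $|\hat w_l| \le m$ is set to zero — all negatives,
and any positive too small to be distinguished from that noise level. A
stricter alternative reading (zero only the negative entries) is available
via `most_negative_only = TRUE`. Surviving coefficients are normalised to
sum to one; normalisation is idempotent and never produces negatives.

### Hierarchical two-stage estimation

Breast tissue contains far more than epithelium. `hierarchical_deconvolve()`
first estimates the general cell types (epithelial, adipose, fibroblast,
immune) from a general signature matrix — supplied by the user, typically
from an established whole-tissue reference — and then the epithelial subtype
split from the subtype signature. The two stages use their own feature sets,
each intersected with the bulk matrix independently, and stage-2 features
are used as-is (no exclusion of stage-1 loci; nothing in the design requires
disjointness, though in practice the locus-selection criteria produce
disjoint sets). Tissue-relative subtype proportions are defined
multiplicatively: stage-2 fractions scaled by the stage-1 epithelial
proportion, so their column sums equal the epithelial proportion exactly.
This composition is a design choice — the two stages could in principle be
estimated jointly — adopted because it keeps each stage identifiable with
its own reference and makes the consistency constraint exact by
construction.

## Building the signature matrix

### Pre-selection and the modified Mahalanobis ranking

Given labelled single cells $Y$, candidate features for cell type $\phi$
are screened by the standardised difference
$(\bar Y_{in} - \bar Y_{out}) / \sqrt{\mathbb{V} Y_{out}}$ exceeding a
threshold $\lambda$. No universally sensible $\lambda$ exists across data
scales, so by default the package keeps the top 1000 features by this
statistic instead; this also bounds the size of the covariance matrix
estimated next. A feature whose out-group variance is zero but whose means
differ is a perfect discriminator and passes any threshold (the statistic is
$\pm\infty$ by the sign of the difference).

The refinement step ranks the pre-selected features by
$$d = \hat\Sigma^{-1}_{out}\,\big[(\bar Y_{in} - \bar Y_{out}) \circ |\bar Y_{in} - \bar Y_{out}|\big],$$
the signed-squared difference whitened by the out-group covariance. The
whitening is the point: two perfectly correlated features carry one
feature's worth of discriminative signal, and $d$ splits or discounts it
accordingly, where a per-feature statistic would happily select an entire
correlated block. With a diagonal covariance, $d$ reduces exactly to the
per-feature signed squared standardised differences.

Numerics: the covariance of the out-group cells may be singular (fewer cells
than features), so the solve is against $\hat\Sigma + \epsilon I$ with
$\epsilon = 10^{-6} \times \overline{\mathrm{diag}(\hat\Sigma)}$
(configurable), always as a linear solve, never an explicit inverse; the
condition number is reported and a singular regularised system is a hard
error. Ranking is by decreasing signed $d$ (an `absolute` flag ranks by
$|d|$ instead — "largest values" admits either reading and the signed
convention is the default because a negative $d$ indicates depletion, which
is less useful in a non-negative mixture). Ties break lexicographically by
feature ID so results are deterministic.

### The differential-expression ranking

The alternative ranking tests each gene for upregulation in the target type
against all other cells pooled. It is a deliberately self-contained
negative-binomial test: group rates per unit library size, a
method-of-moments dispersion per gene moderated by a lowess trend on
abundance, and a one-sided Wald statistic on the log rate ratio, with a
half-count continuity correction so that all-zero groups yield finite,
extreme statistics. It is a functional stand-in for the gene ranking of a
full DE framework, not a numerical clone of any; under a simulated null its
p-values are uniform (checked by a Kolmogorov–Smirnov test in the suite).

Either way, `build_reference()` takes the union of each type's top 250
features and averages cells within types to form $A$'s columns; the result
is invariant to cell order.

### Selecting methylation loci from purified profiles

When only one purified beta profile per epithelial subtype is available
(bisulphite sequencing of sorted cells), covariance-based ranking is
impossible and `select_dname_loci()` applies three screening criteria per
subtype: (1) variance across non-epithelial lineages $< 0.001$ — the locus
must be quiet in everything that is not epithelium; (2) $|\beta_{subtype} -
\overline{\beta}_{nonepi}| \ge 0.5$ — a large, unambiguous offset;
(3) among candidates, the greatest maximum pairwise difference between the
epithelial subtypes. The count retained per subtype is a quota (default
20 before the union across subtypes, giving signature sizes of a few dozen
loci) because no principled closed-form count exists; it is configurable.
The read-depth floor of 20 used when forming beta values from bisulphite
counts bounds the granularity of an individual methylation rate at 0.05.

## GMM-LE clustering

To label single cells in the first place, the package clusters them by a
Gaussian mixture model fitted in the Laplacian eigenspace (GMM-LE). The
similarity graph is a cosine kNN graph on log-transformed counts
(`n_neighbors = 50` by default), symmetrised by the elementwise maximum.
The embedding takes the top-$K$ eigenvectors of the regularised normalised
adjacency $D_\tau^{-1/2} A D_\tau^{-1/2}$, $D_\tau = D + \tau I$, with
$\tau$ defaulting to the mean degree — the standard regulariser, which keeps
low-degree cells from dominating the spectrum — and then normalises the
eigenvector rows to unit length (the degree correction: cluster identity
lives in the direction, degree in the magnitude). Eigenvector signs are
fixed by making each vector's largest-magnitude entry positive, so the
embedding is deterministic; with dense symmetric `eigen()` the decomposition
is exact at the package's intended scales (hundreds to a few thousand
cells).

The mixture is fitted with full covariances per component via `mclust`,
cells assigned by maximum posterior probability. Two degenerate regimes are
handled explicitly: a graph with at most `n_clusters` connected components
embeds as exact point masses, where EM is undefined and the assignment is
simply the partition of distinct rows (recovered exactly); and if the
full-covariance fit collapses, simpler covariance structures and finally a
minute seeded jitter are tried before erroring. Graph construction,
neighbourhood size and $\tau$ are all configurable, because none of them is
canonical; clusters are provisionally named by their argmax mean
log-expression over user-supplied marker sets.

## Quantile-matching augmentation

RNA signature matrices built from single cells must sometimes be deconvolved
alongside bulk-derived reference profiles (e.g. purified stromal or adipose
RNA-seq), whose scale and zero structure are very different.
`augment_reference_set()` re-expresses a bulk profile on the empirical
distribution of a randomly sampled single-cell library:
$\tilde x_i = \hat F_b^{-1}[\hat F_{ref}(x^{ref}_i)]$ with right-continuous
ECDFs and the type-1 (smallest-value) inverse. The conventions matter at
ties and are therefore fixed and tested: ranks of the reference are
preserved exactly, ties in the reference map to equal outputs, a constant
reference maps to the library's maximum, and every output value is drawn
from the sampled library's value multiset — so the augmented profile
inherits the library's zero inflation, which is the point. Cells are sampled
uniformly with replacement across the $B$ draws (without-replacement
sampling would cap $B$ at the number of cells for no benefit), all seeded.

## The robustness simulation

`robustness_experiment()` measures parameter recovery under controlled
corruption: mixing weights drawn i.i.d. $\mathcal U(0,1)$ and column-normalised,
noiseless mixtures $X = AW$, then exactly
$\mathrm{round}(f \cdot p \cdot n)$ entries replaced by fresh
$\mathcal U(0,1)$ draws, for each corruption fraction $f$ on a grid; the
deconvolved $\hat W$ is scored by MSE against the truth over estimable
columns, with the inestimable percentage tracked separately. Column
normalisation of the simulated weights is the default because proportions
must sum to one; a `raw_uniform` flag reproduces the unnormalised design.
Aggregation across repetitions reports the mean and a percentile-bootstrap
95% CI (the CI method is a package choice; at these repetition counts the
bootstrap is cheap and assumption-free). Corruption noise is
$\mathcal U(0,1)$ regardless of modality — for beta values this is noise on
the natural scale; for RNA it is a deliberate stress test rather than a
realistic error model.

Desk-scale defaults in the test suite and acceptance script are $n = 100$
samples with 20–50 repetitions and the noise grid
$\{0, 0.2, 0.4, 0.6, 0.8\}$; a full run at 1000 repetitions is a
command-line flag away and scales linearly.

## What the synthetic generators do and do not emulate

`make_synthetic_reference()` produces block-structured beta signatures: each
type has its own set of hypermethylated loci (baseline 0.15, separation 0.5,
uniform jitter 0.02) — the shape that the three locus-selection criteria
would produce from real purified profiles, at the canonical 58×3 size. The
defaults were chosen once to mirror those selection criteria (a Δβ of at
least 0.5 over a quiet low-beta background) and are not tuned per analysis.
`make_synthetic_sc()` produces negative-binomial counts (dispersion 0.3,
log-normal library sizes, a quarter of genes as markers with fold-change 8
split across types) with known labels.

These generators give exact ground truth and planted structure, which is
what the tests need; they do **not** emulate batch effects, doublets,
ambient contamination, cell-type abundance imbalance, correlated feature
blocks beyond the planted markers, or realistic dropout beyond what the NB
model implies. Passing tests therefore demonstrate correctness of the
estimators under their stated models and robustness to the stated
corruption process — not performance on any particular real cohort, for
which external validation (e.g. cross-platform agreement on matched
samples) remains necessary.

## Known limitations

* The general-cell-type signature for stage 1 of the hierarchy is accepted
  as user input; its derivation is out of scope.
* The DE ranking is asymptotic (Wald); at very low counts or tiny cell
  numbers its calibration degrades, as for any moment-based NB test.
* The dense eigendecomposition in GMM-LE is quadratic in cell number;
  beyond ~10⁴ cells an iterative eigensolver would be the natural
  replacement.
* Proportions are point estimates; no uncertainty is attached to individual
  samples.

## A compact end-to-end run

```{r example, eval = FALSE}
A   <- make_synthetic_reference(p = 58, k = 3, seed = 1)
sim <- simulate_mixtures(A, n = 100, seed = 2)
fit <- deconvolve(A, corrupt_with_noise(sim$X, 0.4, seed = 3))
summary(fit)
mean((coef(fit)[, !fit$inestimable] -
        sim$W_true$values[, !fit$inestimable])^2)
```
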