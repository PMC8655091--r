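# epistratify

Reference-based deconvolution of breast epithelial cell subtypes from bulk
genomic data.

## The problem

Hormone receptor negative breast cancers are thought to arise from luminal
progenitor cells, one of the three main subtypes of the breast epithelium
(luminal progenitor, luminal mature, basal). Single-cell assays can phenotype
these cells directly but are impractical for cohort-scale studies, so their
*quantities* must be tracked in bulk-tissue data instead. `epistratify`
estimates per-sample cell-type proportions from bulk DNA methylation (beta
values) or RNA-seq profiles, given a signature matrix of cell-type reference
profiles, and provides the machinery to build those signatures from labelled
single-cell data or purified methylation profiles.

## The model

The deconvolution model is

    X = A W + e

where `X` (p features × n samples) holds the bulk observations, `A` (p × k)
the expected profile of each of k cell types over discriminative features,
and `W` (k × n) the mixing proportions, column-stochastic. `W` is estimated
one sample at a time by the **RLM-pseudo-inverse (RLM-PI)**:

1. robust (Huber IRLS, tuning constant 1.345, MAD scale) linear regression of
   the sample on `A`, no intercept — robustness lets heavily corrupted
   features be downweighted rather than poisoning the fit;
2. an **adaptive noise threshold**: if the most negative raw coefficient has
   magnitude `m`, every coefficient with magnitude ≤ `m` is set to 0 (small
   negative coefficients are noise, and positives indistinguishable from that
   noise floor are zeroed with them);
3. normalisation to sum to 1. Samples whose fit does not converge, or whose
   coefficients are entirely zeroed, are flagged *inestimable*.

A two-stage **hierarchical** variant first estimates general cell types
(epithelial, adipose, fibroblast, immune), then the epithelial subtype split,
and reports subtype proportions relative to the whole tissue by multiplying
the two.

Signature construction ranks features per cell type either by a **modified
Mahalanobis statistic** `d = Σ⁻¹(δ ∘ |δ|)` (the signed-squared mean
difference whitened by the out-group covariance, which discounts redundant
correlated features) or by a **negative-binomial differential-expression
test**, taking the union of per-type top-250 lists; purified DNA methylation
profiles are screened by three criteria (non-epithelial variance < 0.001,
|Δβ| ≥ 0.5 vs the non-epithelial mean, greatest between-subtype spread).
Single cells are labelled by **GMM-LE clustering**: a Gaussian mixture model
fitted in the eigenspace of a regularised, degree-corrected graph Laplacian.

## Worked example

```r
library(epistratify)

A <- make_synthetic_reference(p = 58, k = 3, seed = 1)      # beta signature
colnames(A$values) <- c("lum_prog", "lum_mature", "basal")
A <- reference_matrix(A$values, "dname_beta")

sim     <- simulate_mixtures(A, n = 50, seed = 2)           # known truth
X_noisy <- corrupt_with_noise(sim$X, fraction = 0.4, seed = 3)

fit <- deconvolve(A, X_noisy)
summary(fit)
#> RLM-PI deconvolution summary
#>   samples: 50   cell types: 3   signature features: 58
#>   inestimable: 2.0%   reference condition number: 1.91
#>   mean proportions over estimable samples:
#>   lum_prog lum_mature      basal
#>     0.3042     0.3697     0.3261

round(coef(fit)[, 1:4], 3)
#>             sim1  sim2  sim3  sim4
#> lum_prog   0.300 0.082 0.090 0.508
#> lum_mature 0.438 0.459 0.583 0.305
#> basal      0.262 0.459 0.327 0.187
```

Even with 40% of the bulk matrix replaced by uniform noise, the recovered
proportions have mean squared error ≈ 0.004 against the planted truth
(~0.05 per-entry error on quantities in [0,1]) — the robust fit is doing the
work an ordinary least-squares pseudo-inverse could not.

The same estimator is exposed as a command line tool:

```sh
exec/epistratify fixtures --kind ref --seed 5 --out A.tsv
exec/epistratify fixtures --kind mixture --n 100 --seed 5 --out X.tsv
exec/epistratify deconvolve --ref A.tsv --bulk X.tsv --modality dname_beta --out W.tsv
```

Every output is accompanied by a `.provenance.json` sidecar recording the
parameters and seed.

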