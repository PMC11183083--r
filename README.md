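# batcheval

Batch-effect evaluation for radiomics-style feature matrices: a
dataset-level multivariate screen (PERMANOVA over six distance metrics), a
feature-level effect size (the Robust Effect Size Index with bootstrap
confidence intervals), the univariate tests traditionally used for the job
(Wilcoxon rank-sum, Kolmogorov–Smirnov, k-sample Anderson–Darling),
empirical-Bayes location/scale harmonization (ComBat) with covariate
protection, a batch-effect simulator, and a power/Type-I-error study
harness.

## Who this is for

Quantitative imaging features extracted from multi-center studies carry
technical variation from scanner, site, and acquisition year — batch
effects. Analysts need to decide whether a feature table needs
harmonization, and afterwards whether harmonization worked. P-values alone
answer neither question well: at radiomics sample sizes (tens of thousands
of scans) univariate tests reject everywhere, before *and* after
harmonization. `batcheval` implements the two-stage alternative: screen
the dataset as a whole with a distribution-free multivariate test, then
quantify per-feature effect magnitude with an interpretable, unitless
effect size whose precision *improves* with sample size.

## The methods in brief

**PERMANOVA.** From a pairwise distance matrix D over samples, with
A = (−½ d²ᵢⱼ), G = CAC the Gower-centered form (C = I − 𝟙𝟙′/n), and H the
projection onto the one-hot batch design,

    F = [tr(HGH)/(g−1)] / [tr((I−H)G(I−H))/(n−g)] = [SS_B/(g−1)] / [SS_W/(n−g)]

is referred to a permutation null from random relabelings; p-values use
the add-one convention. Metrics: Euclidean, chord, Clark, Gower,
quantitative Jaccard (2B/(1+B) of Bray–Curtis B), Mahalanobis. Clark and
Jaccard require positive data, so an elementwise exponential transform is
applied for them by default. Permutations are evaluated through the
group-sum identity in BLAS-batched blocks, so 2000 permutations at
n = 2500 take well under a second once distances exist.

**RESI.** Per feature, OLS of the feature on the batch factor with a
heteroskedasticity-consistent sandwich covariance; the index is the signed
square root of the robust Wald chi-square's excess over its degrees of
freedom, scaled by n:  S = sign(χ² − q)·√(|χ² − q|/n), q = g − 1. For a
balanced two-group mean difference of Cohen's d, S → d/2. Percentile
bootstrap confidence intervals (case resampling, default 500 replicates)
accompany every estimate.

**ComBat.** Standard parametric empirical-Bayes location/scale
harmonization with covariate protection, provided as a fit/apply pair and
cross-checked against `sva::ComBat`.

**Simulator.** Y = γᵢ + δᵢ·ε with ε ~ N(0,1), per-group location
γᵢ ~ U(−2, 2) and scale δᵢ ~ U(0.8, 1.2), two random batch groups — the
generative model under which the power study calibrates all of the above.

## Worked example

```r
library(batcheval)

be <- simulateBatchData(200, seed = 7)   # 200 samples x 20 features, 2 batches
be
#> BatchExperiment: 200 samples x 20 features
#> batch levels (2): batch1, batch2
#> reference level: batch1
#> simulated; batch effects present: TRUE

## 1. dataset-level screen
screenDataset(be, metrics = c("euclidean", "clark"),
              nPermutations = 499, seed = 1)$table
#>     metric   pseudoF pValue reject status
#>  euclidean 128.32819  0.002   TRUE     ok
#>      clark  70.97507  0.002   TRUE     ok

## 2. feature-level quantification
head(resiTable(be, nBoot = 200, seed = 2), 3)
#>    feature  level      resi     ciLow    ciHigh   overall ... status
#>  feature01 batch2 0.7489771 0.6294239 0.8870374 0.7489771 ...     ok
#>  feature02 batch2 0.8353233 0.6715638 1.0132109 0.8353233 ...     ok
#>  feature03 batch2 0.9354502 0.7662712 1.1251713 0.9354502 ...     ok

## 3. harmonize and re-evaluate
cp <- compareHarmonization(be, metrics = "clark", nPermutations = 499,
                           nBoot = 0, seed = 3)
cp$adRejection
#>  pre post
#>    1    0
round(colMeans(cp$deltaResi[, c("pre", "post")]), 3)
#>   pre  post
#> 0.793 0.006
```

Both screening metrics reject decisively (permutation p = 0.002, the
add-one floor at 499 permutations). Every feature rejects the
Anderson–Darling test before harmonization and none after; the mean
absolute effect size of batch drops from 0.79 (a large effect — the
equivalent of Cohen's d ≈ 1.6) to 0.006 (negligible). The signed
per-feature values in `resi` tell you *which* batch sits above or below
the reference and by how much.

A thin command-line front end covering the same workflow is installed at
`inst/scripts/batcheval` (subcommands `simulate`, `permanova`, `resi`,
`utest`, `combat`, `screen`, `quantify`, `compare`, `power-study`).

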