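---
title: "Methods: penalized phenotype prediction from SNP dosages"
author: "snpLasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized phenotype prediction from SNP dosages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In genome-enabled prediction a quantitative trait measured on *n*
individuals is predicted from *p* SNP dosages with *p* far larger than
*n*.  Ordinary least squares is then undefined, and penalized regression
shrinks the coefficient vector toward zero to obtain a usable estimator.
snpLasso implements the full analysis chain for the LASSO case — from
genotype simulation and quality control through LD clumping to a
coordinate-descent solver and nested cross-validation — so that the
behaviour of the estimator under controlled heritability and sample size
can be studied end to end on synthetic data.

# Model

The working model is the standard linear one,

$$ y = \beta_0 + X\beta + \epsilon, \qquad \epsilon \sim N(0, \sigma^2 I), $$

with the LASSO estimator

$$ \hat\beta_0, \hat\beta = \arg\min \Big[ \tfrac{1}{2n}
   \sum_i \big(y_i - \beta_0 - \textstyle\sum_j \beta_j x_{ij}\big)^2
   + \lambda \sum_j |\beta_j| \Big]. $$

The $\ell_1$ penalty sets coefficients exactly to zero, performing
variable selection; $\lambda$ controls the amount of shrinkage.  We scale
the residual sum of squares by $1/(2n)$: unlike the unscaled form, this
makes $\lambda$ values comparable across training sets of different sizes
(essential inside cross-validation, where each outer fold has its own
training *n*) and matches the convention of the widely used pathwise
coordinate-descent solvers, so reported $\lambda$ ranges can be read
against the literature.  The unscaled objective is available through
`objectiveScaling = "rss"`; the two differ only by the reparameterization
$\lambda \mapsto \lambda / (2n)$.  The intercept is never penalized.

# The solver

`fitLassoPath()` runs cyclic coordinate descent on column-standardized
predictors (population $1/n$ variance; coefficients are mapped back to
the dosage scale afterwards).  The coordinate update is the
soft-thresholding operator $S(z, \lambda) = \mathrm{sign}(z)\,
\max(|z|-\lambda, 0)$.  The $\lambda$ grid is log-spaced from
$\lambda_{\max} = \max_j |x_j^\top y_c| / n$ (the smallest penalty whose
solution is all-zero) down to `lambdaMinRatio` times it (default $10^{-4}$
when $n > p$, else $10^{-2}$), and each grid point is warm-started from
the previous solution.  Per grid point the solver performs a full sweep,
iterates on the active set until stable, then makes a confirming full
sweep; convergence is a maximum standardized-coefficient change below
`tol` (default $10^{-7}$), which certifies the Karush-Kuhn-Tucker
conditions coordinate-wise.  `kktViolations()` re-checks those conditions
independently after the fact.

Coordinate updates are cyclic in fixed column order, never randomized, so
every fit is deterministic.  Optional sequential strong-rule screening
(`screen = TRUE`) restricts the sweeps to a candidate set predicted from
the previous grid point's gradient and then verifies the *full* KKT
system with one matrix-vector product, adding any violator and resuming;
the screened solution therefore satisfies exactly the same optimality
conditions as the unscreened one (a property the test suite asserts), and
screening is off by default purely as a correctness-first stance.
Missing dosages are mean-imputed per SNP before fitting, the standard
choice in genotype prediction; it preserves column means and hence the
intercept.

Degenerate inputs are handled explicitly: constant columns are frozen at
zero rather than standardized; a response uncorrelated with every
predictor has $\lambda_{\max} = 0$ and requires an explicit grid; ties in
the inner-CV MSE curve resolve toward the larger $\lambda$ (parsimony).
$\lambda_{\max}$ is inflated by one part in $10^{12}$ to absorb
summation-order differences between BLAS kernels, keeping "all
coefficients zero at $\lambda_{\max}$" exact.

# Nested cross-validation

Selecting $\lambda$ and estimating predictive performance with the same
cross-validation would be optimistic.  `nestedCV()` therefore uses an
outer $k$-fold loop (default 10) for assessment only: within each outer
training set, an inner $k$-fold loop (default 10) fits the path on each
inner-training subset and selects the $\lambda$ minimizing the mean
validation MSE; the model is refit on the whole outer training set at
that $\lambda$ and predicts the held-out fold.  Every sample is thus
predicted exactly once by a model that never saw it; under zero
heritability the pooled observed-predicted correlation is centered on
zero, the signature that no selection optimism leaks through (asserted in
the tests).  The $\lambda$ grid is recomputed from each outer training
set (so $\lambda_{\max}$ reflects that fold) but shared across that
fold's inner splits, otherwise the "mean MSE per $\lambda$" curve would
be ill-defined.  Folds are plain uniform random partitions — the designs
studied here handle relatedness through principal components, not
through family-aware folds.

Pooled predictions are summarized by three metrics: the Pearson
correlation between observed and predicted values (for a genetic
predictor its population ceiling is $\sqrt{h^2}$), the mean squared
error, and the slope of the best-fit line of predicted on observed, for
which 1 indicates perfect calibration and heavy shrinkage gives values
far below 1.  Constant predictions are flagged and reported with r and
slope 0.

# Synthetic data: what it emulates and what it does not

`simulateGenotypes()` draws each LD-block anchor SNP as Binomial(2, maf)
with maf uniform on [`mafLow`, `mafHigh`] (defaults 0.05-0.5), and each
allele of a non-anchor SNP copies the anchor allele with probability
`ldCopyProb`, giving expected allelic correlation `ldCopyProb` and dosage
$r^2$ of `ldCopyProb`$^2$ — direct, testable control of LD for the
clumping stage, in place of coalescent realism.  `simulatePhenotype()`
adds Gaussian noise whose variance
$\sigma^2 = \beta^2\,2f(1-f)\,(1-h^2)/h^2$ (with $f$ the causal column's
empirical allele frequency) makes the genetic share of the variance equal
$h^2$; the induced observed-vs-genetic correlation converges to
$\sqrt{h^2}$.  The headline design uses a single causal SNP with
$\beta = -0.44$ on the raw 0/1/2 dosage scale, $h^2 = 0.05$ and causal
maf 0.3.  The effect is parameterized on the raw dosage scale because a
standardized-genotype parameterization would tie $\beta^2$ to
$h^2 \cdot \mathrm{Var}(y)$ and could not hold both of those values at
once; the causal allele frequency is not dictated by the design, so 0.3
was chosen once as a mid-range value and is exposed as a parameter.

`simulateVisits()` produces the raw 4-visit triglyceride-style table used
to exercise phenotype construction: log-normal baseline values with age,
center (2 levels by default; the number of centers in the motivating
cohort is unreported) and smoking effects, a negative treatment shift
between visits 2 and 3, a causal effect injected into the follow-up log
values, and independent per-visit missingness.

What the generator does **not** emulate: real LD decay and haplotype
structure, allele-frequency spectra shaped by demography, family
structure, dominance or epistasis, and genotyping artifacts beyond
missing-completely-at-random dosages.  Tests passing on these synthetic
cohorts therefore certify the *algorithms* — solver optimality, no CV
leakage, correct filtering arithmetic — not the field performance of
LASSO prediction on any real cohort.

# Phenotype construction

`buildBaselineFollowup()` works on the natural-log scale (the log base
only rescales effect sizes); baseline is the mean of log visits 1-2 and
follow-up of log visits 3-4, each falling back to the single available
visit and dropping (with a recorded reason) samples missing a whole
pair.  `adjustPhenotype()` regresses follow-up on intercept, baseline,
age, center dummies, smoking and the top genotype principal components
(default 20), using complete cases, and returns residuals standardized
with the $n-1$ denominator (immaterial at these sample sizes; fixed for
exactness of tests).  `computePCs()` mean-imputes, standardizes, drops
monomorphic columns and takes unit-variance left singular scores, with
the sign convention that each component's largest-magnitude loading is
positive.  PCs are computed after QC on the full retained SNP set, before
clumping.  `qqDiagnostic()` adds the genomic-inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2_1)/0.4549$ as a supporting
diagnostic for confounding control.

# QC and clumping conventions

`applyQC()` removes SNPs with maf strictly below 0.01, then (among
survivors) exact Hardy-Weinberg $p \le 10^{-5}$ (inclusive boundary),
then call rate below a threshold that defaults to off; each SNP is
attributed to its first failing rule so the per-rule counts are
well-defined and partition the input.  The HWE test is the exact
conditional test (the field standard near the maf threshold, and the
default of the standard genotype-QC tool), computed in log space; a
chi-square alternative is provided for comparison.  It is computed on all
samples, with no founders-only logic, consistent with handling
relatedness through PCs.

`clumpSnps()` is the greedy procedure: rank by p-value (ties by position,
then id), seed a clump with the best unassigned SNP, absorb unassigned
same-chromosome SNPs within the window whose dosage $r^2$ reaches the
threshold.  Defaults $r^2 = 0.5$, window 250 kb follow the wrapped
tool's conventions; the index/member p-value bounds default to 1 because
clumping is used here to thin the *whole* SNP set, not to refine hits.
$r^2$ is genotypic (dosage correlation on pairwise-complete samples), so
no phasing is needed; cross-chromosome pairs never clump.

# Problem sizes and numerical tolerances in the test suite

The distributed tests run the study designs at sizes chosen to finish on
a single desktop core while leaving the statistical conclusions intact:
the small-sample shrinkage run uses the full n = 700 x p = 56,000 design
with 5 inner folds and a 50-point lambda grid, averaged over three
replicate cohorts because the fold-mean coefficient carries a
dataset-level standard error of about 0.08 at this sample size; the
large-sample run uses n = 7,753 with p = 20,000 and 3 inner folds; the
penalty-monotonicity comparison uses p = 2,000 with 10-fold CV selection
over five seeds.  These runs use solver tolerance 1e-4 (about the
working precision of standard pathwise solvers; the package default is
stricter), a lambda-grid floor of 0.1-0.15 times lambda_max (selections
are verified to sit strictly inside the grid), and strong-rule screening
(KKT-backstopped, hence exact).  Solver correctness is held to tight tolerances: objective
agreement with an exhaustive sign-pattern oracle to $10^{-8}$ on
instances with p <= 8, the orthonormal-design closed form to $10^{-10}$,
zero KKT violations at $10^{-6}$, and exact-test agreement with a direct
enumeration oracle to $10^{-12}$ for totals up to 50.

# Known limitations

Only the LASSO penalty is implemented; ridge, adaptive and heavy-tailed
variants are out of scope.  The pipeline handles quantitative traits
with Gaussian errors; no binary or survival outcomes.  Clumping retains
a single representative per clump rather than aggregating within-clump
information.  The simulators are stationary and unlinked to any real
genome build; positions are synthetic 10 kb grids.  Sample-level QC
(heterozygosity, sex checks, relatedness pruning) is not performed.
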