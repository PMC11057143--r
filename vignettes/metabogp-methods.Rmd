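---
title: "Genomic prediction of metabolic traits: models, kernels and benchmarking design"
author: "MetaboGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of metabolic traits: models, kernels and benchmarking design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

MetaboGP benchmarks whole-genome prediction of quantitative
blood-metabolite-like traits in dairy-cattle cohorts. The pipeline covers
genotype quality control, relationship kernels (additive, dominance,
additive-by-additive epistatic), a Gibbs-sampling Bayesian animal model for
variance components with a random herd/date batch effect, phenotype
adjustment, five predictors (GBLUP, BayesB, elastic net, gradient boosting,
a stacking ensemble), two cross-validation designs (genomic-distance
tenfold and leave-batch-out), and gradient-boosting relative-influence SNP
preselection. Because cohorts of this kind are typically not publicly
deposited, a synthetic cohort generator with controllable variance
fractions makes every stage testable end-to-end.

# The animal model and variance components

The baseline model for a trait vector $y$ over $n$ cows is

$$ y = Xb + Wh + Za + e $$

with fixed effects $b$ (days-in-milk class, six levels; parity class, four
levels; the first two genotype principal components as covariates), i.i.d.
random batch effects $h \sim N(0, I\sigma^2_{batch})$, additive genomic
values $a \sim N(0, G\sigma^2_a)$ and residuals $e \sim N(0, I\sigma^2_e)$.
The extended model adds dominance $d \sim N(0, D\sigma^2_d)$ and
additive-by-additive epistatic values
$ep_{aa} \sim N(0, G\!\circ\!G\,\sigma^2_{ep})$.

Kernels:

* $G = MM'/(2\sum_j p_j(1-p_j))$ (VanRaden), $M$ the dosage matrix centered
  by twice the counted-allele frequency per marker;
* $D = WW'/\sum_j(2p_jq_j)^2$ (Vitezica), with dominance covariates
  $-2p^2$, $2pq$, $-2q^2$ for genotypes 0/1/2 — HWE-centered and invariant
  to which allele is counted;
* $G\!\circ\!G$, the Hadamard (element-wise) square of $G$, not rescaled by
  default (a `normalize` flag divides by the mean diagonal).

Heritability is $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{batch} +
\sigma^2_e)$ in the baseline model, and the batch fraction replaces
$\sigma^2_a$ in the numerator. For the extended model the dominance and
epistatic fractions $d^2$ and $ep^2_{aa}$ are reported with the batch
variance included in the denominator by default
(`summarizeRatios(..., include_batch = TRUE)`); the alternative convention
omitting $\sigma^2_{batch}$ is available with the flag, since both
conventions circulate in the literature. Ratios are always computed per
retained posterior sample and then averaged — a posterior mean of the
ratio, not a ratio of posterior means.

## Gibbs sampler

Fixed effects take a flat prior; every variance takes a scaled
inverse-chi-square prior with `prior_df = 5` and scale set so the prior
splits the observed phenotypic variance equally across the fitted variance
components. Correlated random vectors are sampled in the eigenbasis of
their kernel: one spectral decomposition per kernel turns each conditional
draw into $n$ independent normals, which keeps per-iteration cost linear in
$n$ after two rotations. The sampler is implemented in C++
(RcppArmadillo) and driven by R's RNG, so `set.seed()` makes chains
reproducible. Null eigenvalue directions carry no mass (effects there are
exactly zero), which also handles the rank deficiency that
sample-frequency centering induces in $G$.

The reference chain configuration is 500,000 cycles, 50,000 burn-in,
thinning 10 — 45,000 retained samples; short chains for tests and examples
keep the same structure. Convergence is monitored with the Geweke
diagnostic: the means of the first 10% and last 50% of a chain are
compared with a z-statistic whose segment variances come from the AR-fit
spectral density at frequency zero.

Adjusted phenotypes $y^* = y - X\hat b - W\hat h$ (posterior means) are the
response for all predictors.

# Predictors

**GBLUP** fits $y^* = 1\mu + g + e$, $g \sim N(0, G\sigma^2_g)$, with
variances estimated on the training fold by eigen-based REML (the
likelihood is profiled over the variance ratio on the eigenvalue scale).
Validation individuals are predicted by the conditional expectation
$G_{vt}G_{tt}^{-1}\hat g$, evaluated in the equivalent, numerically stable
form $\sigma^2_g G_{vt} V^{-1}(y^*-\hat\mu)$. With a matched penalty
$\lambda = \sigma^2_e/\sigma^2_u$ this is identical to marker ridge
regression, which the tests verify to $r \ge 1 - 10^{-8}$.

**BayesB** places a mixture prior on each marker effect: a point mass at
zero with probability $\pi$ and a scaled-$t$ slab with 5 degrees of freedom
otherwise, implemented hierarchically (per-marker scaled-inverse-chi-square
variances) with a collapsed inclusion update. Defaults: $\pi = 0.95$, and
slab scale solved so the prior attributes half of $\mathrm{var}(y^*)$ to
the markers; both are configurable, since the values used with typical
tooling are rarely reported. The reference chain is 200,000/50,000/10
(15,000 retained samples). A single-marker fixture with the residual
variance fixed is checked against 1-D quadrature of the mixture posterior.

**Elastic net** minimizes
$\tfrac{1}{2N}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
\lambda\big((1-\alpha)\lVert\beta\rVert^2_2 + \alpha\lVert\beta\rVert_1\big)$
— note the un-halved ridge term. Solutions come from glmnet after an exact
penalty reparameterisation (glmnet halves its ridge term and internally
standardizes the response, which scales the effective ridge weight by the
response SD; both are undone analytically). The tests check the
subgradient optimality conditions of the loss above directly. The
$\alpha$ grid is $0, 0.1, \ldots, 1$; the $\lambda$ grid is 50 log-spaced
values from $\lambda_{max}$ (the smallest penalty zeroing all coefficients
at $\alpha = 1$) down to $10^{-4}\lambda_{max}$, with a raw $0$–$1$ step
$0.1$ grid available by flag since the printed description of the search
is ambiguous for $\lambda$. The winner of the inner 5-fold search
maximizes out-of-fold accuracy, breaking ties by lower MSE, then smaller
$\lambda$, then smaller $\alpha$.

**GBM** is squared-error gradient boosting of regression trees (xgboost
backend, histogram trees, no L2 regularization, one thread). The search
grids are: trees in {100, 200, 300, 500, 750, 1000, 1250, 1500, 2000,
2500, 3000}, learning rate 0.01–1 in steps of 0.05, maximum depth 0–50 in
steps of 5, and minimum observations per leaf 5–50 in steps of 15. Depth
0 is interpreted as "no depth limit" (a depth-0 tree is degenerate);
xgboost's loss-guided growth implements it. Hyperparameters are chosen by
random search (36 draws by default) scored by inner 5-fold MSE. Relative
influence is the per-marker share of total split gain on a percentage
scale (summing to 100 whenever at least one split occurred).

**Stacking** trains the two base learners (elastic net and GBM) with
K-fold cross-validation inside the training set so every training
individual has an out-of-fold base prediction, then fits the meta-learner
— a linear model with intercept and non-negative weights, solved exactly
by active-set enumeration over the two weights. If the non-negativity
constraint empties the ensemble (both weights clamped at zero), the stack
falls back to the base learner with the lower out-of-fold MSE rather than
emitting a constant prediction. The meta-learner family used by common
stacking tooling is not generally reported; non-negative least squares is
the transparent default here.

All predictors compute marker centering statistics (and VanRaden
denominators) on the training fold only and reuse them for validation, so
no validation-side information reaches any fit; a leakage suite perturbs
validation phenotypes and asserts bit-identical training-side behavior for
all five models and both CV designs.

# Cross-validation designs

*Genomic-distance tenfold.* Distances are the kernel-induced Euclidean
form $d_{ij} = \sqrt{G_{ii} + G_{jj} - 2G_{ij}}$ (the construction behind
"genomic distance" is rarely specified; this form is determined by $G$
itself). Folds come from Ward clustering of the distance matrix, balanced
to sizes $\lfloor n/k \rfloor$/$\lceil n/k \rceil$ by greedily moving,
from each oversized fold, the individual closest on average to the
receiving fold. The construction is deterministic given the distance
matrix; 1,353 individuals in ten folds yield the 135/136 size multiset.

*Leave-batch-out.* Per repeat, $\lfloor 0.8B \rfloor$ batches train and
the remainder validate (21 batches split 16/5); all records of a batch
travel together. Five repeats cannot make each of 21 batches a validation
member exactly once, so repeats draw disjoint validation sets while
unused batches remain and then top up from used ones, with a message.

# The synthetic cohort generator

`simConfig()` fixes the study conditions; `simulateCohort()` produces
genotypes, a true architecture and phenotype records.

* **Genotypes.** Ancestral counted-allele frequencies are uniform on the
  configured MAF range; subpopulation frequencies follow a Balding–Nichols
  Beta draw at the configured $F_{st}$ (default 0.05, two subpopulations —
  the modest substructure typical of a single-breed cohort), truncated to
  the MAF range so the realized-MAF contract holds by construction.
  Haplotypes threshold block-equicorrelated latent Gaussians at the
  Hardy–Weinberg quantile, giving controllable within-block LD
  (default blocks of 20 markers at latent correlation 0.5) and HWE within
  subpopulations. An optional herd-lineage level (`fst_batch`) drifts
  per-batch frequencies around their subpopulation, making batch-mates
  genetic relatives.
* **Architecture.** Additive QTL act on centered dosages; dominance QTL on
  centered heterozygosity indicators; epistatic QTL pairs on products of
  centered dosages of *adjacent* markers (same LD block where possible).
  Cis-pairs are deliberate: interactions between linked loci carry a
  marginal (quadratic) signal through the LD correlation, as interacting
  loci do in real data, whereas products of independent distant loci have
  no marginal effect and are invisible to every predictor. Raw effects are
  standard normal and each component is rescaled so its realized variance
  on the simulated cohort equals its target fraction — the effect-size
  distribution is therefore immaterial to the variance targets.
* **Phenotypes.** One record per individual with days-in-milk class (6
  levels), parity class (4 levels), batch (21 by default, Dirichlet(5)
  sizes so batch sizes vary as in field data) and an independent Gaussian
  residual carrying the leftover variance fraction. The defaults emulate
  the cohort scale the pipeline targets (1,353 cows, 61,226 SNPs on 29
  autosomes); tests use scaled-down cohorts.

What the generator does *not* emulate: pedigree/family structure beyond
the lineage-drift device, repeated records, genotype-by-environment
interaction, non-Gaussian trait distributions, and realistic genome-wide
LD decay. Passing tests therefore demonstrate correctness of the
machinery and qualitative behavior under controlled architectures, not
performance claims about any real cohort.

# Scenario design for the qualitative benchmarks

The acceptance suite asserts orderings, not point values; the scenarios
were fixed as study conditions before the assertions were frozen.

* *Epistatic advantage*: h² = 0.08, d² = 0.04, ep² = 0.45 with 8 strong
  cis-epistatic pairs at LD 0.7, n = 400, m = 400, 20 replicates. Tree
  ensembles (GBM, Stack) beat GBLUP by roughly +0.1 accuracy here; the
  stack is compared at 5 out-of-fold folds because meta-weights estimated
  from fewer than ~300 training records are too noisy for a stable
  comparison.
* *Additive equivalence*: h² = 0.35 spread over 200 of 400 markers;
  GBLUP, BayesB ($\pi = 0.5$, matching the dense architecture) and the
  elastic net agree within 0.05.
* *Confounded batch structure*: 21 batches nested in two subpopulations
  with herd-lineage drift (`fst_batch = 0.06`) and batch fraction 0.35,
  response adjusted for fixed effects only. Batch-mates are then
  relatives whose shared batch signal is predictable from training data
  in the tenfold design but excluded wholesale in batch-out, so
  leave-batch-out accuracy drops below genomic tenfold — the dependence
  the batch-out design exists to remove. Full model-based batch
  adjustment under this strong confounding strips the shared signal
  itself (and with it the contrast being measured), which is why this
  scenario adjusts for fixed effects only.
* *Accuracy–heritability ladder*: ten additive traits with h² from 0.05
  to 0.5; GBLUP tenfold accuracy regressed on h² gives $R^2 \ge 0.5$.

# Numerical choices and degenerate inputs

* Kernels are accepted as positive semi-definite when the smallest
  eigenvalue exceeds $-10^{-8}\,\mathrm{tr}/n$; negative eigenvalues
  within tolerance are clipped to zero.
* A singular GBLUP training system receives a logged jitter of
  $10^{-8}\,\mathrm{tr}/n$.
* Monomorphic-only panels (zero VanRaden or Vitezica denominators),
  all-missing markers, constant chains in the Geweke test, and $k$ larger
  than the available markers or individuals are rejected with explicit
  errors; $\pi = 1$ in BayesB degrades to an intercept-only model with a
  warning.
* QC filter order: non-autosomal markers, sample call rate, marker call
  rate, MAF (strictly below 0.05 removed; exactly 0.05 retained), HWE
  (1-df chi-square, $p \le 10^{-5}$ removed). The chi-square rather than
  an exact test is the standard choice at cohort sizes above a thousand.
  Mean imputation (missing $\to 2p_j$) runs after filtering.
* Problem sizes in tests and in `scripts/acceptance.R` are package
  choices balancing statistical resolution against runtime: parameter
  recovery uses n = 400, m = 1,500 with 15,000-cycle chains (8 replicates
  in the tests, 5 in the script); ordering benchmarks use n = 300–400,
  m = 400.

# Known limitations

* REML appears only as a cross-check oracle in the tests; the Gibbs
  sampler is the estimator.
* The dominance and epistatic ratio conventions differ between
  literature sources; both are implemented but only one can be the
  default.
* BayesB's $\pi$ and slab scale, the elastic net's $\lambda$ grid, the
  GBM search budget and the stacking meta-learner family are documented
  package defaults, not values taken from any specific study.
* Single records per individual; multi-trait models, pedigree kernels and
  higher-order epistatic kernels are out of scope.
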