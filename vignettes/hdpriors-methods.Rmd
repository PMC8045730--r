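---
title: "Tree-based penalized-complexity priors for genomic variance decomposition"
author: "hdpriors authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based penalized-complexity priors for genomic variance decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpriors)
```

## The model

`hdpriors` fits the genomic mixed model

$$y_{ir} = \mu + g_i + e_{ir}, \qquad e_{ir} \sim N(0, \sigma_e^2),$$

where the genetic value of individual $i$ decomposes as $g_i = a_i$
(model A), $g_i = a_i + d_i$ (model AD) or $g_i = a_i + d_i + x_i$
(model ADX), with

$$a \sim N(0, \sigma_a^2 A), \quad d \sim N(0, \sigma_d^2 D), \quad
  x \sim N(0, \sigma_x^2 X).$$

$A = Z_a Z_a^\top / S_a$ is the additive genomic relationship matrix from
the column-centered 0/1/2 marker codes, $D = Z_d Z_d^\top / S_d$ the
dominance analogue from the centered heterozygosity coding, and
$X = (A \odot A) / S_x$ the additive-by-additive epistasis structure
(Hadamard square of the scaled $A$, re-scaled). Each scaling constant is
the geometric mean of the unscaled diagonal, so every structure describes
unit variance for a "typical" individual; this common scale is what makes
variance proportions across components comparable. Geometric-mean scaling
is unit-invariant; the common alternative (mean of the diagonal) differs
by well under a percent on simulated data and either choice could be
defended — we fix the geometric mean once and use it everywhere,
including for the EK-weighted mixture matrices inside the tree.

Markers with minor allele frequency below 5% are removed before either
coding is built (at-threshold markers are retained). Filtering happens
once, on the raw genotype matrix, so the additive and dominance codings
always describe the same marker panel.

## The variance-decomposition tree

The phenotypic variance $\sigma_P^2 = \sigma_g^2 + \sigma_e^2$ is
decomposed along a tree of binary splits: phenotypic into genetic versus
environmental (proportion $p_{g/(g+e)}$, the broad-sense heritability),
genetic into additive versus nonadditive ($p_{a/g}$), and nonadditive
into dominance versus epistasis ($p_{d/(d+x)}$). Expert knowledge enters
as the elicited medians $R$ of these proportions — ratios are far easier
to elicit than absolute variances. `leafVariances()` maps
$(\sigma_P^2, p_{g/(g+e)}, p_{a/g}, p_{d/(d+x)})$ back to the component
variances; the map is a stick-breaking bijection whose Jacobian
$\sigma_P^2 \cdot (\sigma_P^2 p_g) \cdot (\sigma_P^2 p_g (1 - p_a))$
(one factor of entering variance mass per split present) is applied
whenever densities are moved between the two parameterizations.

```{r tree-demo}
trial <- simulateTrial(simConfig(nIndividuals = 40, seed = 1))
tree <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
cat(renderTree(tree))
```

## PC priors on standard deviations and proportions

The PC prior for a standard deviation is exponential with rate
$-\ln(\alpha)/V$, fixed by the statement $P(\sigma > V) = \alpha$. The
component-wise prior set uses $\alpha = 0.25$ and upper values obtained
by walking the tree downward: $V(\sigma_e) = (1 - h_g^2)\,V_P$,
$V(\sigma_a) = h_a^2 V_P$, $V(\sigma_d) = h_d^2 V_P$,
$V(\sigma_x) = (h_g^2 - h_a^2 - h_d^2) V_P$, so an estimate $V_P$ of the
phenotypic variance from a comparable dataset is required — the practical
weakness of the component-wise route that motivates the model-wise one.

For a proportion $p$ mixing two covariance structures
$\Sigma(p) = p\,C_1 + (1-p)\,C_0$, the PC prior is built from the
distance $d(p) = \sqrt{2\,\mathrm{KL}\!\left(N(0, \Sigma(p)) \,\|\,
N(0, C_0)\right)}$, computed from the generalized eigenvalues of
$C_1$ relative to $C_0$. Two styles are provided:

* `pc0Proportion()` — base model $p = 0$, density
  $\propto \exp(-\theta d(p))\,d'(p)$, with $\theta$ calibrated by
  root-finding so the median equals the elicited $R$. When $R$ exceeds
  the flat-penalty median the same exponential family is continued
  through negative rates; for the study's values ($R = 0.25$ at the
  root) the rate is positive, i.e. genuine shrinkage toward the
  environment-only model.
* `pcmProportion()` — base model $p = R$, distance measured from $R$ on
  both sides, one shared rate, each side renormalized to mass one half
  (hence the median is exactly $R$), and the rate calibrated so that 75%
  of the mass falls in $[\mathrm{logit}(R) - 1, \mathrm{logit}(R) + 1]$
  on logit scale.

The no-EK default replaces the split priors with those implied by a
symmetric flat Dirichlet over the leaf shares of phenotypic variance; by
Dirichlet aggregation the root split is Beta$(k-1, 1)$ for $k$ leaves,
the genetic split Beta$(1, \text{number of nonadditive leaves})$ and the
nonadditive split uniform.

### Numerical construction

Proportion priors are tabulated on 1,000 equally spaced points on
$(0,1)$ (endpoints excluded by half a step) and stored as log densities.
Because the density is exponential in the piecewise-linear distance,
per-cell integrals have closed form; calibration, medians and interval
masses all use that exact quadrature, with the true support endpoints
$p = 0, 1$ (where $d$ may be infinite for rank-deficient structures)
appended so that no probability mass is silently truncated. For the PCM
prior, $R$ itself is inserted as a quadrature node so that the kink of
the distance at the base model falls on a cell boundary. With these
choices the calibrated rate moves by about $10^{-7}$ (relative) when the
grid is doubled. The generalized eigenvalue problem adds a jitter of
$10^{-8}$ times the typical diagonal to the base matrix, since genomic
cross-products are routinely rank deficient. Beyond the outermost grid
points the log density is extended linearly (the prior's support is all
of $(0,1)$); a hard wall there would misreport boundary-hugging
posteriors as sampler failures.

The model-wise prior is assembled bottom-up, conditioning each split on
the elicited values below it: the nonadditive split compares $D$ against
$X$; the genetic split compares $A$ against the mixture
$R_{d/(d+x)} D + (1 - R_{d/(d+x)}) X$; the root compares the genetic
mixture $R_{a/g} A + (1 - R_{a/g})(\cdots)$ against the identity. Every
mixture is re-scaled to typical variance 1 before use, consistent with
the leaf matrices (scaling the mixture, not its ingredients, is the
choice here; the alternative — using the unscaled mixture at the root —
changes the root prior only through the typical-diagonal factor, which
is already 1 up to small sampling noise). The total variance
$\sigma_P^2$ carries the improper Jeffreys prior, flat in
$\log \sigma_P^2$.

```{r prior-demo}
hp <- buildHDPrior(tree, "expert")
hp
c(rootMedian = priorMedian(hp@splitPriors$p_g),
  pcmMass = priorMass(hp@splitPriors$p_a,
                      plogis(qlogis(0.85) - 1), plogis(qlogis(0.85) + 1)))
```

## Inference

The likelihood is the marginal Gaussian with the genetic values
integrated out. Replicated observations are collapsed exactly into
per-individual means (covariance $G + \sigma_e^2 \mathrm{diag}(1/r_i)$)
plus a within-individual sum of squares on $N - n$ degrees of freedom,
so every likelihood and gradient evaluation costs one $n \times n$
Cholesky factorization rather than $N \times N$. The collapse is
validated against a dense $N$-dimensional multivariate-normal oracle in
the test suite.

The Bayesian path samples $(\mu, \log \sigma_P^2,
\mathrm{logit}\,p_s)$ — the Jeffreys prior is flat in $\log \sigma_P^2$
and explicit logit Jacobians are applied — with a Hamiltonian Monte
Carlo sampler written for this package: leapfrog dynamics with
trajectory lengths drawn uniformly up to `maxLeapfrog`, dual-averaging
step-size adaptation toward an average along-trajectory acceptance of
0.8, a diagonal mass matrix estimated from the middle of warmup, and a
divergence diagnostic that flags any transition whose Hamiltonian error
exceeds 1000 at any leapfrog step. A fit is *stable* when fewer than 1%
of post-warmup draws are divergent. Divergence counts from this sampler
are comparable across prior settings fitted by this package, but not
numerically to counts from other samplers: the collapsed
five-parameter posterior is far better conditioned than the
latent-effect geometries that general-purpose samplers explore, so
divergence rates here are much lower across the board. The intercept
carries a $N(0, 1000)$ prior; default initial values are zero for the
intercept and all log/logit coordinates.

The ML baseline maximizes the same collapsed likelihood over $\mu$ and
the log variances with bounded L-BFGS (default lower bounds $-20$ for
the environmental and $-50$ for the genetic log variances), reports
convergence and flags estimates sitting on a bound; either condition
marks the fit unstable.

Individual genetic values are recovered after sampling by drawing once
per posterior draw from the joint conditional Gaussian of the component
values given the phenotypes (block cross-covariances
$\sigma_c^2 K_c$); posterior-predictive phenotypes add fresh
environmental noise per draw.

## The trial simulator

`simConfig()` defaults encode the simulated advanced-yield-trial stage:
100 individuals with 5 replicates, founder additive/dominance/epistasis
variances 1.0/0.5/0.1 and environmental variance 6.0. Genotypes are
drawn at independent biallelic loci in Hardy–Weinberg proportions with
allele frequencies Uniform(0.05, 0.95); markers and causal loci are
disjoint sets, so markers tag, but never coincide with, causal loci.
Marker and causal counts default to 2 chromosomes × 200 loci — enough
for well-conditioned relationship matrices at $n = 100$ while keeping a
full simulate–fit–evaluate cycle in seconds; the study-scale counts
(21 × 1000) are a `simConfig()` call away. Causal effects are standard
normal on the centered additive, heterozygosity and (for epistasis)
pairwise-product codings, with `nPairs = nCausal/2` disjoint locus
pairs, and each component's value vector is rescaled so its realized
cohort variance (denominator $n$) equals the target *exactly* — the
convention used when founder variances are specified in breeding
simulators, and what makes the simulator's variance targets
deterministic test anchors. What the generator does **not** emulate:
linkage and linkage disequilibrium, selection history across breeding
cycles, inbreeding, and genotype-by-environment structure. Passing
tests therefore demonstrate correctness of the machinery and
qualitative behavior of the priors under clean polygenic architecture,
not performance on real breeding data, where LD-induced confounding
between components is typically stronger.

```{r sim-demo}
trial$truth
```

## Evaluation

`crps()` uses the empirical-sample form
$\mathrm{mean}|X - y| - \tfrac12 \mathrm{mean}|X - X'|$ with the second
mean over all ordered pairs of draws (computed by sorting); a single
draw reduces it to the absolute error, which is how phenotype-based
point selection is scored. `topkSelection()` counts how many of the
true top-$k$ individuals are recovered when ranking on posterior means,
with ties broken by individual id. `crossValidate()` partitions
*individuals* (not observations) into folds so that replicates never
straddle the train/test split, refits per fold — rebuilding the
tree-based prior from the training-fold matrices, because these priors
are dataset specific — and reports per-fold and pooled held-out
correlation and CRPS. Fold submatrices keep their parent scaling so
that fitted variances and cross-covariance rows remain on one scale
across the partition.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use the default trial
(100 × 5, 400 markers) for prior calibration and simulator checks,
$n \le 40$ trials for oracle comparisons, single-chain sampler budgets
of 150–400 warmup and 150–400 draws for fit-based checks, 50 seeded
replicates for credible-interval coverage and 30 for the
prior-stability comparison. These sizes were chosen so a full check
cycle runs on one desk CPU in minutes; all entry points accept the
study-scale settings. Every stochastic step is seeded through a single
integer argument.

## Known limitations

* Dense linear algebra throughout: comfortable to a few thousand
  individuals, not beyond.
* Only the intercept as fixed effect; no genotype-by-environment or
  multi-trait extensions.
* The divergence-based stability diagnostic is less provocable on the
  collapsed posterior than on latent-effect parameterizations, so
  stability contrasts between prior settings are compressed relative to
  latent-space samplers (estimates of the confounded components still
  show the expected behavior: under the no-EK default tree prior the
  epistasis variance absorbs environmental variation).
* PC priors on correlations and arbitrary user-defined tree topologies
  are out of scope; the three-model family A/AD/ADX is what is tested.
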