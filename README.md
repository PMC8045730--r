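# hdpriors

Robust Bayesian genomic modeling of additive and nonadditive variation,
with priors that encode expert knowledge about *ratios* of variance
components.

## The problem

Breeders and quantitative geneticists decompose phenotypic variation into
environmental noise and genetic variation, and the genetic part further
into additive, dominance and (additive-by-additive) epistatic values.
Dominance and epistasis are notoriously hard to separate from each other
and from the environment — the epistasis covariance structure is close to
the identity, so unpenalized fits happily absorb environmental noise into
spurious nonadditive "signal", and maximum-likelihood optimizers stall at
boundary estimates. What experts *do* reliably know are relative
magnitudes: broad-sense heritability, the share of additive within
genetic variance, the split of nonadditive variance. `hdpriors` turns
exactly that knowledge into a joint prior.

## The model and priors

The genomic mixed model is

    y_ir = mu + g_i + e_ir,   g_i = a_i (+ d_i (+ x_i)),
    a ~ N(0, s2_a A),  d ~ N(0, s2_d D),  x ~ N(0, s2_x X),
    e ~ N(0, s2_e I)

with relationship matrices `A = Za Za'/Sa`, `D = Zd Zd'/Sd`,
`X = (A ∘ A)/Sx` built from 0/1/2 marker codes (MAF-filtered at 5%,
column-centered; `∘` the Hadamard product; scaling constants = geometric
mean of the diagonal). The phenotypic variance is decomposed along a tree
of splits with proportions `p_g/(g+e)` (broad-sense heritability),
`p_a/g` and `p_d/(d+x)`; elicited medians R for these proportions drive
penalized-complexity (PC) priors:

* `PC0(R)` on a proportion shrinks toward the simpler base model (p = 0)
  with an exponential penalty on the Kullback–Leibler-based distance,
  rate calibrated so the prior median is R;
* `PCM(R)` shrinks toward p = R itself, with 75% prior mass inside
  `[logit(R) − 1, logit(R) + 1]`;
* the total variance gets the scale-invariant Jeffreys prior, so no
  absolute variance statement is ever needed.

These proportion priors depend on the actual relationship matrices — they
are dataset specific and constructed numerically. Component-wise
`PC0(V, alpha)` priors on each standard deviation, and no-expert-knowledge
defaults (flat Dirichlet over variance shares; `PC0(0.968, 0.01)`), are
included for comparison. Fitting is by Hamiltonian Monte Carlo on the
collapsed likelihood (genetic values marginalized, replicates reduced
exactly) with divergence-based stability diagnostics, or by bounded
L-BFGS maximum likelihood as a baseline. A breeding-trial simulator with
exact variance-target scaling and evaluation tools (CRPS, top-k selection
accuracy, variance recovery, repeated k-fold cross-validation) complete
the toolkit.

## Worked example

```r
library(hdpriors)

# one simulated advanced-yield trial: 100 individuals x 5 replicates,
# founder variances 1.0 (additive), 0.5 (dominance), 0.1 (epistasis), 6.0 (noise)
trial <- simulateTrial(simConfig(seed = 42))
trial$truth
#> TruthSet: 100 individuals
#>   realized variances: additive = 1, dominance = 0.5, epistasis = 0.1, genetic = 1.239

tree <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
cat(renderTree(tree))
#> phenotype  (sigmaP2 ~ Jeffreys)
#> +-- genetic  [p_g ~ PC0(R = 0.25)]
#> |   +-- additive (A)  [p_a ~ PCM(R = 0.85)]
#> |   \-- nonadditive
#> |       +-- dominance (D)  [p_d ~ PCM(R = 0.67)]
#> |       \-- epistasis (X)
#> \-- environment (I)

prior <- buildHDPrior(tree, "expert")    # the ADX-tree* setting
fit <- fitBayes(trial$data, prior, chains = 1, warmup = 300, draws = 500,
                seed = 1, maxLeapfrog = 32)
fit
#> FitResult (bayes, model ADX): 500 draw(s)
#>   divergent transitions: 0 / 500 (stable: TRUE)
#>   posterior means: mu = -0.111, sigmaP2 = 7.95, p_g = 0.169, p_a = 0.842,
#>   p_d = 0.625, sigma2_e = 6.6, sigma2_a = 1.14, sigma2_d = 0.132, sigma2_x = 0.0836

evaluateFit(fit, trial$truth)
#> EvaluationReport
#>   correlation: a 0.487, d 0.315, x 0.095, g 0.729
#>   CRPS: a 0.510, d 0.406, x 0.185, g 0.430
#>   top-k recovered: genetic 6, additive 3
#>   variance ratios: a 1.137, d 0.263, x 0.836
#>   stable: TRUE
```

Reading the output: the fit is stable (no divergent transitions); the
posterior means put the environmental variance at 6.6 (truth 6.0) and the
additive variance at 1.14 (truth 1.0), with the expert prior keeping the
weakly identified epistasis variance at 0.08 rather than letting it soak
up environmental noise; 6 of the true 10 genetically best individuals are
recovered for variety selection. Swapping `"expert"` for `"default"`
(flat Dirichlet, no expert knowledge) on the same data inflates the
epistasis variance roughly fivefold at the expense of the environmental
term — the overfitting the priors exist to prevent.

A command-line interface over the same functions ships in
`inst/cli/hdpriors-cli.R` (subcommands `simulate`, `fit`, `evaluate`,
`cv`, `prior-plot`, `tree`).

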