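test_that("collapsed likelihood equals the dense multivariate-normal oracle", {
    # replicated ADX data
    for (s in 1:3) {
        trial <- smallTrial(seed = s, n = 5 + 3 * s)  # n <= 14, N <= 70
        par <- c(mu = 0.3, sigma2_e = 5, sigma2_a = 1.2, sigma2_d = 0.4,
                 sigma2_x = 0.2)
        expect_equal(logLikelihood(par, trial$data),
                     denseMVNLogLik(par, trial$data), tolerance = 1e-8)
    }
    # unbalanced design
    trial <- smallTrial(seed = 9, n = 10)
    keep <- -c(3, 14, 25)
    ph <- trial$phenotypes[keep, ]
    dat <- genomicData(ph, trial$matrices)
    par <- c(mu = -1, sigma2_e = 7, sigma2_a = 0.8, sigma2_d = 0.1,
             sigma2_x = 0.05)
    expect_equal(logLikelihood(par, dat), denseMVNLogLik(par, dat),
                 tolerance = 1e-8)
    # bivariate hand computation: y = (1, -1), A = I, s2a = s2e = 0.5
    A <- identityRelationship(c("i1", "i2"))
    A@kind <- "A"
    d2 <- genomicData(data.frame(individual_id = c("i1", "i2"),
                                 value = c(1, -1)), list(a = A))
    expect_equal(logLikelihood(c(mu = 0, sigma2_e = 0.5, sigma2_a = 0.5),
                               d2),
                 sum(dnorm(c(1, -1), 0, 1, log = TRUE)), tolerance = 1e-12)
    expect_error(logLikelihood(c(mu = 0, sigma2_e = 0, sigma2_a = 0), d2),
                 "singular total covariance")
})

test_that("log posterior decomposes into likelihood plus prior terms", {
    trial <- smallTrial(seed = 2, n = 15)
    tree <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
    hp <- buildHDPrior(tree, "expert")
    par <- c(mu = 0.4, sigma2_e = 6, sigma2_a = 1, sigma2_d = 0.3,
             sigma2_x = 0.1)
    tc <- hdpriors:::treeCoordinates(par[-1])
    lp <- logPosterior(par, trial$data, hp)
    expected <- logLikelihood(par, trial$data) +
        dnorm(0.4, 0, sqrt(1000), log = TRUE) +
        hdLogPrior(hp, tc$sigmaP2, tc$proportions) -
        log(hdpriors:::treeJacobian(tc$sigmaP2, tc$proportions))
    expect_equal(lp, expected, tolerance = 1e-10)
    # intercept prior is the stated N(0, 1000)
    lp0 <- logPosterior(c(mu = 0, par[-1]), trial$data, hp)
    expect_equal(lp0 - logLikelihood(c(mu = 0, par[-1]), trial$data) -
                     (lp - logLikelihood(par, trial$data) -
                      dnorm(0.4, 0, sqrt(1000), log = TRUE)),
                 dnorm(0, 0, sqrt(1000), log = TRUE), tolerance = 1e-10)
    # outside support: -Inf, not an exception
    expect_identical(logPosterior(c(mu = 0, sigma2_e = -1, par[-(1:2)]),
                                  trial$data, hp), -Inf)

    # component-wise prior decomposition
    cp <- componentwisePriors(ekSpec(0.25, 0.85, 0.67), VP = 1.86,
                              model = "ADX")
    lpc <- logPosterior(par, trial$data, cp)
    manual <- logLikelihood(par, trial$data) +
        dnorm(0.4, 0, sqrt(1000), log = TRUE) +
        sum(vapply(names(cp@priors), function(nm) {
            s <- sqrt(par[[sub("sigma_", "sigma2_", nm)]])
            log(dPCSD(s, cp@priors[[nm]])) - log(2 * s)
        }, numeric(1)))
    expect_equal(lpc, manual, tolerance = 1e-10)
})

test_that("tree and component parameterizations agree through the Jacobian", {
    trial <- smallTrial(seed = 4, n = 12)
    tree <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
    hp <- buildHDPrior(tree, "expert")
    for (s in 1:5) {
        set.seed(s)
        theta <- c(mu = rnorm(1), sigmaP2 = runif(1, 1, 10),
                   p_g = runif(1, 0.05, 0.95), p_a = runif(1, 0.05, 0.95),
                   p_d = runif(1, 0.05, 0.95))
        vars <- leafVariances(theta[["sigmaP2"]],
                              theta[c("p_g", "p_a", "p_d")])
        lpTree <- logPosterior(theta, trial$data, hp,
                               parameterization = "tree")
        lpComp <- logPosterior(c(mu = theta[["mu"]], vars), trial$data, hp)
        # numerical Jacobian of (sigmaP2, p) -> variances as the oracle
        h <- 1e-6
        J <- matrix(0, 4, 4)
        base <- c(theta[["sigmaP2"]], theta[["p_g"]], theta[["p_a"]],
                  theta[["p_d"]])
        for (j in 1:4) {
            up <- base; up[j] <- up[j] + h
            dn <- base; dn[j] <- dn[j] - h
            vu <- leafVariances(up[1], c(p_g = up[2], p_a = up[3],
                                         p_d = up[4]))
            vd <- leafVariances(dn[1], c(p_g = dn[2], p_a = dn[3],
                                         p_d = dn[4]))
            J[, j] <- (vu - vd) / (2 * h)
        }
        expect_equal(lpTree - lpComp, log(abs(det(J))), tolerance = 1e-5)
        # the closed form used internally matches the numerical determinant
        expect_equal(hdpriors:::treeJacobian(theta[["sigmaP2"]],
                                             theta[c("p_g", "p_a", "p_d")]),
                     abs(det(J)), tolerance = 1e-4)
    }
})

test_that("ML fitting matches textbook closed forms and flags boundaries", {
    # intercept-plus-noise: genetic variance shrinks to its bound and
    # mu -> ybar, sigma2_e -> mean squared deviation
    set.seed(10)
    ids <- sprintf("i%02d", 1:40)
    I <- identityRelationship(ids)
    I@kind <- "A"
    y <- rnorm(40, 3, 2)
    dat <- genomicData(data.frame(individual_id = ids, value = y),
                       list(a = I))
    # with A = I and one observation each, sigma2_a and sigma2_e are not
    # separable; drive the genetic part to zero with the bound to recover
    # the textbook Gaussian ML
    fit <- fitML(dat, init = c(log_sigma2_a = -50))
    est <- fit@draws[1, ]
    expect_equal(unname(est["mu"]), mean(y), tolerance = 1e-4)
    expect_equal(unname(est["sigma2_e"] + est["sigma2_a"]),
                 mean((y - mean(y))^2), tolerance = 1e-3)

    # replicated data make the split identifiable without bounds
    trial <- smallTrial(seed = 5, n = 40, model = "A")
    fitA <- fitML(genomicData(trial$phenotypes, trial$matrices["a"]),
                  bounds = FALSE)
    expect_true(fitA@diagnostics$converged)
    expect_false(fitA@diagnostics$atBound)
    expect_lt(abs(fitA@draws[1, "sigma2_e"] - 6), 2.5)

    # pure-noise AD data: dominance variance estimate collapses toward
    # its lower bound
    set.seed(11)
    trialN <- simulateTrial(simConfig(nIndividuals = 40, markersPerChr = 60,
                                      causalPerChr = 60, varA = 1e-4,
                                      varD = 1e-4, varX = 0, varE = 6,
                                      seed = 14), model = "AD")
    fitN <- fitML(genomicData(trialN$phenotypes, trialN$matrices[c("a", "d")]))
    expect_lt(fitN@draws[1, "sigma2_d"], 1e-2)
    # a bound that truncates the optimum is flagged and marks the fit
    # unstable
    fitB <- fitML(genomicData(trialN$phenotypes, trialN$matrices[c("a", "d")]),
                  lowerGen = log(0.5))
    expect_true(fitB@diagnostics$atBound)
    expect_false(stability(fitB))

    # custom init is accepted and recorded
    fitI <- fitML(genomicData(trial$phenotypes, trial$matrices["a"]),
                  init = c(mu = 0.5, log_sigma2_e = log(6)))
    expect_equal(unname(fitI@settings$init["log_sigma2_e"]), log(6))
})

test_that("conjugate posterior check: Jeffreys-noise model matches scaled-inverse-chi-square", {
    # y_i ~ N(0, s2), prior 1/s2: posterior s2 | y is Inv-Gamma(n/2, S/2)
    set.seed(8)
    n <- 40
    y <- rnorm(n, 0, 2)
    S <- sum(y^2)
    fn <- function(q) {   # q = log s2
        s2 <- exp(q)
        list(value = -0.5 * n * q - 0.5 * S / s2,
             grad = -0.5 * n + 0.5 * S / s2)
    }
    set.seed(9)
    r <- hmcSample(fn, init = 0, warmup = 400, draws = 3000,
                   maxLeapfrog = 8)
    s2draws <- exp(r$samples[, 1])
    postMean <- S / (n - 2)                       # Inv-Gamma mean
    postSD <- sqrt((S / 2)^2 / ((n / 2 - 1)^2 * (n / 2 - 2)))
    ess <- essOf(s2draws)
    expect_lt(abs(mean(s2draws) - postMean), 3 * postSD / sqrt(ess))
    # quantiles agree loosely with the closed form
    qTheory <- (S / 2) / qgamma(c(0.75, 0.25), n / 2)
    expect_equal(unname(quantile(s2draws, c(0.25, 0.75))), qTheory,
                 tolerance = 0.08)
})

test_that("Bayesian fit is seed-reproducible and agrees with a grid posterior", {
    trial <- simulateTrial(simConfig(nIndividuals = 30, markersPerChr = 60,
                                     causalPerChr = 60, varA = 4, varD = 0,
                                     varX = 0, varE = 1, seed = 20),
                           model = "A")
    dat <- genomicData(trial$phenotypes, trial$matrices["a"])
    tree <- buildTree("A", ekSpec(0.25, model = "A"), trial$matrices["a"])
    hp <- buildHDPrior(tree, "expert")
    f1 <- fitBayes(dat, hp, chains = 1, warmup = 200, draws = 400,
                   seed = 3, maxLeapfrog = 16)
    f2 <- fitBayes(dat, hp, chains = 1, warmup = 200, draws = 400,
                   seed = 3, maxLeapfrog = 16)
    expect_identical(f1@draws, f2@draws)
    expect_true(stability(f1))

    # brute-force 2-d grid posterior over (log sigmaP2, p_g) with the
    # intercept held at its tightly identified posterior mean
    muHat <- mean(f1@draws[, "mu"])
    lVg <- seq(log(1), log(12), length.out = 60)
    pg <- seq(0.02, 0.995, length.out = 120)
    logpost <- matrix(NA_real_, length(lVg), length(pg))
    for (i in seq_along(lVg)) for (j in seq_along(pg)) {
        vars <- leafVariances(exp(lVg[i]), c(p_g = pg[j]))
        logpost[i, j] <- logLikelihood(c(mu = muHat, vars), dat) +
            priorLogDensity(hp@splitPriors$p_g, pg[j])
    }
    w <- exp(logpost - max(logpost))
    margP <- colSums(w) / sum(w)
    cdf <- cumsum(margP)
    lo <- pg[which(cdf >= 0.025)[1]]
    hi <- pg[which(cdf >= 0.975)[1]]
    pgHat <- mean(f1@draws[, "p_g"])
    expect_gt(pgHat, lo)
    expect_lt(pgHat, hi)
    # strong signal: the posterior identifies a large genetic proportion
    expect_gt(pgHat, 0.5)
})

test_that("stability thresholds follow the 1% divergence and ML convergence rules", {
    mkfit <- function(div, n) new("FitResult", method = "bayes",
        model = "A", draws = matrix(0, 1, 1),
        diagnostics = list(divergent = div, nDraws = n),
        settings = list(), data = smallTrial(seed = 1, n = 5,
                                             model = "A")$data)
    expect_true(stability(mkfit(0L, 4000L)))
    expect_true(stability(mkfit(39L, 4000L)))    # 0.975% < 1%
    expect_false(stability(mkfit(41L, 4000L)))   # 1.025% >= 1%
    expect_false(stability(mkfit(40L, 4000L)))   # exactly 1% is not < 1%
})

test_that("pure-noise data shrink the genetic proportion below its prior median", {
    set.seed(30)
    trial <- simulateTrial(simConfig(nIndividuals = 40, markersPerChr = 60,
                                     causalPerChr = 60, varA = 1e-6,
                                     varD = 1e-6, varX = 1e-6, varE = 6,
                                     seed = 31))
    tree <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
    hp <- buildHDPrior(tree, "expert")
    fit <- fitBayes(trial$data, hp, chains = 1, warmup = 250, draws = 300,
                    seed = 7, maxLeapfrog = 24)
    expect_lt(median(fit@draws[, "p_g"]),
              priorMedian(hp@splitPriors$p_g))
})
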