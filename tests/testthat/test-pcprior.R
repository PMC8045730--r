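test_that("PC prior on a standard deviation is the calibrated exponential", {
    pr <- pcSD(0.968, 0.01)
    expect_equal(1 - pPCSD(0.968, pr), 0.01, tolerance = 1e-12)
    expect_equal(pr@rate, -log(0.01) / 0.968, tolerance = 1e-12)
    # alpha = exp(-1) gives rate 1/V
    expect_equal(pcSD(2.5, exp(-1))@rate, 1 / 2.5, tolerance = 1e-12)
    # exponential median formula
    expect_equal(qPCSD(0.5, pcSD(0.465, 0.25)), log(2) * 0.465 / log(4),
                 tolerance = 1e-12)
    expect_error(pcSD(-1, 0.25), "positive")
    expect_error(pcSD(1, 1.2), "alpha")
    # sample mean matches 1/rate within 3 standard errors
    set.seed(1)
    x <- rPCSD(1e5, pr)
    expect_lt(abs(mean(x) - 1 / pr@rate), 3 * sd(x) / sqrt(1e5))
})

test_that("component-wise upper values follow the tree arithmetic", {
    csA <- componentwisePriors(ekSpec(0.25, model = "A"), VP = 1.86,
                               model = "A")
    expect_equal(csA@priors$sigma_a@upperValue, 0.465)
    expect_equal(csA@priors$sigma_e@upperValue, 1.395)
    expect_equal(csA@priors$sigma_a@tailProb, 0.25)

    cs3 <- componentwisePriors(ekSpec(0.25, 0.85, 0.67), VP = 1.86,
                               model = "ADX")
    expect_equal(cs3@priors$sigma_d@upperValue, 0.25 * 0.15 * 0.67 * 1.86)
    # upper values over all components sum to VP
    expect_equal(sum(vapply(cs3@priors, function(p) p@upperValue,
                            numeric(1))),
                 1.86, tolerance = 1e-9)
    # degenerate hg2 = 1 disallowed (zero environmental upper value)
    expect_error(ekSpec(1, model = "A"), "0, 1")
    # a zero implied upper value is named in the error: RAg = 1 under ADX
    # leaves nothing for dominance and epistasis
    expect_error(componentwisePriors(ekSpec(0.25, 1, 0.67), VP = 1.86,
                                     model = "ADX"), "sigma_d")
})

test_that("distance curve matches the brute-force Gaussian KL oracle", {
    # 1x1 closed form: C1 = 2, C0 = 1 -> d(p) = sqrt(p - log(1+p))
    dc <- distanceCurve(matrix(2), matrix(1), grid = c(0.2, 0.5, 0.8))
    expect_equal(dc$d, sqrt(dc$p - log(1 + dc$p)), tolerance = 1e-7)
    # d(1) limit ~ sqrt(1 - log 2)
    dc1 <- distanceCurve(matrix(2), matrix(1), grid = 1 - 1e-9)
    expect_equal(dc1$d, sqrt(1 - log(2)), tolerance = 1e-6)

    # identical structures -> d = 0
    C <- randomSPD(4, 1)
    dc0 <- distanceCurve(C, C, grid = c(0.3, 0.7))
    expect_lt(max(dc0$d), 1e-6)

    # random SPD pairs vs trace/log-det oracle
    for (s in 1:4) {
        C1 <- randomSPD(5, 10 + s)
        C0 <- randomSPD(5, 20 + s)
        grid <- c(0.1, 0.35, 0.6, 0.9)
        dc <- distanceCurve(C1, C0, grid)
        oracle <- vapply(grid, function(p) bruteKL(C1, C0, p), numeric(1))
        expect_equal(dc$d, oracle, tolerance = 1e-8)
        expect_true(all(diff(c(0, dc$d)) > -1e-12))  # non-decreasing from 0
    }
    expect_error(distanceCurve(randomSPD(3, 1), randomSPD(4, 2)),
                 "dimension mismatch")
})

test_that("PC0 proportion prior calibrates its median and normalizes", {
    C1 <- randomSPD(6, 5)
    C0 <- diag(6)
    pr <- pc0Proportion(C1, C0, R = 0.25)
    # P(p <= R) recomputed from the construction = 0.5
    expect_equal(priorMass(pr, 0, 0.25), 0.5, tolerance = 1e-3)
    expect_equal(priorMedian(pr), 0.25, tolerance = 1e-3)
    # stored density integrates to 1 (trapezoid)
    g <- pr@grid
    dens <- exp(pr@logDensity)
    expect_equal(sum((dens[-1] + dens[-length(dens)]) / 2 * diff(g)), 1,
                 tolerance = 1e-6)
    # 1x1 case against a brute-force change-of-variables oracle:
    # p has density theta exp(-theta d(p)) |d'(p)| / Z on (0,1)
    pr1 <- pc0Proportion(matrix(2), matrix(1), R = 0.5)
    th <- pr1@theta
    dfun <- function(p) sqrt(p - log(1 + p))
    Z <- integrate(function(p) {
        eps <- 1e-7
        dd <- (dfun(p + eps) - dfun(pmax(p - eps, 0))) / (2 * eps)
        exp(-th * dfun(p)) * dd
    }, 1e-8, 1)$value
    mid <- c(0.2, 0.5, 0.8)
    eps <- 1e-7
    oracle <- exp(-th * dfun(mid)) *
        (dfun(mid + eps) - dfun(mid - eps)) / (2 * eps) / Z
    expect_equal(exp(priorLogDensity(pr1, mid)), oracle, tolerance = 3e-3)
    # degenerate split errors
    expect_error(pc0Proportion(C0, C0, 0.25), "degenerate split")
})

test_that("PCM proportion prior places the stated mass in the logit interval", {
    trial <- smallTrial(seed = 3, n = 30)
    D <- trial$matrices$d
    X <- trial$matrices$x
    pr <- pcmProportion(D, X, R = 0.85, mass = 0.75)
    lo <- plogis(qlogis(0.85) - 1)
    hi <- plogis(qlogis(0.85) + 1)
    expect_equal(priorMass(pr, lo, hi), 0.75, tolerance = 1e-3)
    # median sits at R within grid resolution
    expect_equal(priorMedian(pr), 0.85, tolerance = 1e-3)
    # calibration is monotone: near-unit mass concentrates the prior
    pr99 <- pcmProportion(D, X, R = 0.85, mass = 0.999)
    expect_gte(priorMass(pr99, lo, hi), 0.999 - 1e-3)
    expect_gt(pr99@theta, pr@theta)
})

test_that("doubling the grid changes the calibrated concentration by < 0.1%", {
    trial <- smallTrial(seed = 5, n = 30)
    g1 <- (seq_len(1000) - 0.5) / 1000
    g2 <- (seq_len(2000) - 0.5) / 2000
    prm1 <- pcmProportion(trial$matrices$d, trial$matrices$x, 0.67,
                          grid = g1)
    prm2 <- pcmProportion(trial$matrices$d, trial$matrices$x, 0.67,
                          grid = g2)
    expect_lt(abs(prm2@theta - prm1@theta) / prm1@theta, 0.001)
    I <- identityRelationship(rownames(relMatrix(trial$matrices$a)))
    pr01 <- pc0Proportion(trial$matrices$a, I, 0.25, grid = g1)
    pr02 <- pc0Proportion(trial$matrices$a, I, 0.25, grid = g2)
    expect_lt(abs(pr02@theta - pr01@theta) / pr01@theta, 0.001)
})

test_that("Dirichlet marginals are the Beta(1, k-1) aggregation", {
    m2 <- dirichletMarginals(2)
    expect_length(m2, 2)
    # k = 2: uniform density
    # grid truncation renormalizes by ~1e-3; compare at that scale
    expect_equal(exp(priorLogDensity(m2[[1]], c(0.1, 0.5, 0.9))),
                 rep(1, 3), tolerance = 2e-3)
    # k = 3: density 2 (1 - p)
    m3 <- dirichletMarginals(3)
    p <- c(0.2, 0.6)
    expect_equal(exp(priorLogDensity(m3[[1]], p)), 2 * (1 - p),
                 tolerance = 2e-3)
    # all marginals integrate to 1
    for (pr in c(m2, m3)) {
        g <- pr@grid
        dens <- exp(pr@logDensity)
        expect_equal(sum((dens[-1] + dens[-length(dens)]) / 2 * diff(g)),
                     1, tolerance = 1e-6)
    }
    expect_error(dirichletMarginals(1), "at least 2")
})

test_that("priors serialize to a tabular format", {
    pr <- pc0Proportion(randomSPD(4, 2), diag(4), 0.3)
    f <- withr::local_tempfile(fileext = ".tsv")
    writePrior(pr, f)
    tab <- read.delim(f)
    expect_equal(tab$p, pr@grid)
    expect_equal(tab$density, exp(pr@logDensity))
})
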