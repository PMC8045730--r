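test_that("genotype simulation is seeded, disjoint and Hardy-Weinberg-consistent", {
    cfg <- simConfig(nIndividuals = 60, markersPerChr = 40, causalPerChr = 40,
                     seed = 5)
    g1 <- simulateGenotypes(cfg)
    g2 <- simulateGenotypes(cfg)
    expect_identical(genotypes(g1$markers), genotypes(g2$markers))
    expect_identical(genotypes(g1$causal), genotypes(g2$causal))
    expect_length(intersect(markerIds(g1$markers), markerIds(g1$causal)), 0)
    # degenerate frequency 0.5: per-locus genotype mean ~ 1 within 3 SE
    cfg5 <- simConfig(nIndividuals = 400, markersPerChr = 50,
                      causalPerChr = 5, freqRange = c(0.5, 0.5), seed = 6)
    gm <- colMeans(genotypes(simulateGenotypes(cfg5)$markers))
    se <- sqrt(2 * 0.5 * 0.5 / 400)
    expect_lt(max(abs(gm - 1)), 4 * se)   # 100 loci, allow extreme order stat
    expect_lt(abs(mean(gm) - 1), 3 * se / sqrt(50))
    # fixed allele frequencies are rejected
    expect_error(simConfig(freqRange = c(0.05, 1)), "monomorphic")
})

test_that("true values hit the target variances exactly and additively", {
    cfg <- simConfig(nIndividuals = 80, markersPerChr = 60, causalPerChr = 60,
                     seed = 11)
    tr <- simulateTruth(simulateGenotypes(cfg)$causal, cfg)
    pv <- function(v) mean((v - mean(v))^2)
    expect_equal(pv(tr@a), 1.0, tolerance = 1e-12)
    expect_equal(pv(tr@d), 0.5, tolerance = 1e-12)
    expect_equal(pv(tr@x), 0.1, tolerance = 1e-12)
    expect_equal(tr@g, tr@a + tr@d + tr@x)
    expect_equal(unname(tr@realizedVariances[c("additive", "dominance",
                                               "epistasis")]),
                 c(1.0, 0.5, 0.1), tolerance = 1e-12)

    # zero targets give exactly zero components
    cfg0 <- simConfig(nIndividuals = 40, markersPerChr = 30,
                      causalPerChr = 30, varD = 0, varX = 0, seed = 12)
    tr0 <- simulateTruth(simulateGenotypes(cfg0)$causal, cfg0)
    expect_identical(unname(tr0@d), rep(0, 40))
    expect_identical(unname(tr0@x), rep(0, 40))
    expect_equal(tr0@g, tr0@a)

    # fully inbred causal genotypes cannot carry dominance variance
    inbred <- snpMatrix(matrix(sample(c(0, 2), 40 * 20, replace = TRUE),
                               40, 20))
    expect_error(simulateTruth(inbred, cfg0 <- simConfig(
        nIndividuals = 40, markersPerChr = 20, causalPerChr = 10,
        seed = 1)), "heterozygotes")
})

test_that("phenotypes follow y = mu + g + e with the stated noise", {
    cfg <- simConfig(seed = 21)   # trial defaults: 100 x 5, varE = 6
    geno <- simulateGenotypes(cfg)
    tr <- simulateTruth(geno$causal, cfg)
    ph <- simulatePhenotypes(tr, cfg)
    expect_equal(nrow(ph), 500)
    expect_equal(sort(unique(table(ph$individual_id))), 5L)
    # pooled residual variance within 3 SE of 6.0
    res <- ph$value - cfg@mu - tr@g[ph$individual_id]
    se <- 6 * sqrt(2 / (500 - 1))
    expect_lt(abs(mean(res^2) - 6), 3 * se)
    # replicate means: var of individual means ~ var(g) + 6/5
    im <- tapply(ph$value, ph$individual_id, mean)
    expect_lt(abs(var(im) - (var(tr@g) + 6 / 5)), 1.2)
    # noiseless case reproduces mu + g exactly
    cfgN <- simConfig(nIndividuals = 30, markersPerChr = 30,
                      causalPerChr = 30, varE = 1e-300, mu = 2, seed = 3)
    trN <- simulateTruth(simulateGenotypes(cfgN)$causal, cfgN)
    phN <- simulatePhenotypes(trN, cfgN)
    expect_equal(phN$value, 2 + unname(trN@g[phN$individual_id]),
                 tolerance = 1e-8)
})

test_that("broad-sense heritability of one observation is ~0.21 by construction", {
    cfg <- simConfig(seed = 33)
    tr <- simulateTruth(simulateGenotypes(cfg)$causal, cfg)
    pv <- function(v) mean((v - mean(v))^2)
    comp <- c(pv(tr@a), pv(tr@d), pv(tr@x))
    # realized component variances are exact, so the component-sum
    # heritability is (1.0 + 0.5 + 0.1) / (1.6 + 6.0) exactly
    expect_equal(sum(comp) / (sum(comp) + 6.0), 1.6 / 7.6,
                 tolerance = 1e-12)
    # the components are nearly orthogonal, so the realized variance of g
    # is close to the component sum
    expect_lt(abs(pv(tr@g) - 1.6) / 1.6, 0.35)
})

test_that("simulateTrial wires tables, matrices and truth together", {
    trial <- smallTrial(seed = 9, n = 30)
    expect_s4_class(trial$data, "GenomicData")
    expect_setequal(names(trial$data@matrices), c("a", "d", "x"))
    expect_equal(nlevels(trial$data@individual), 30)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeTruth(trial$truth, f)
    tab <- read.delim(f)
    expect_equal(tab$g, unname(trial$truth@g))
})
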