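test_that("implied leaf shares follow the telescoping product", {
    sh <- impliedLeafShares(ekSpec(0.25, 0.85, 0.67))
    expect_equal(unname(sh["dominance"]), 0.15 * 0.67)   # ~ 0.10
    expect_equal(unname(sh["epistasis"]), 0.15 * 0.33)   # ~ 0.05
    opp <- impliedLeafShares(ekSpec(0.25, 0.05, 0.11))
    expect_equal(unname(opp["epistasis"]), 0.95 * 0.89)  # ~ 0.85
    # shares always sum to 1 exactly, and the map inverts
    for (s in 1:20) {
        set.seed(s)
        r <- runif(2, 0.01, 0.99)
        ek <- ekSpec(0.3, r[1], r[2])
        sh <- impliedLeafShares(ek)
        expect_equal(sum(sh), 1)
        expect_equal(unname(sh["additive"]), r[1], tolerance = 1e-12)
        expect_equal(unname(sh["dominance"] / (1 - sh["additive"])), r[2],
                     tolerance = 1e-12)
    }
})

test_that("trees carry the right splits, leaves and EK labels", {
    trial <- smallTrial(seed = 2, n = 20)
    m <- trial$matrices
    trA <- buildTree("A", ekSpec(0.25, model = "A"), m["a"])
    expect_length(trA@splits, 1)
    expect_setequal(names(trA@matrices), c("a", "e"))
    tr3 <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), m)
    expect_length(tr3@splits, 3)
    expect_setequal(names(tr3@matrices), c("a", "d", "x", "e"))
    expect_error(buildTree("AD", ekSpec(0.25, 0.85), m["a"]),
                 "missing relationship matrix")
    # rendering is deterministic and reflects the topology
    r1 <- renderTree(tr3)
    r2 <- renderTree(buildTree("ADX", ekSpec(0.25, 0.85, 0.67), m))
    expect_identical(r1, r2)
    expect_match(r1, "epistasis")
    expect_match(renderTree(trA), "p_g ~ PC0", fixed = TRUE)
    expect_no_match(renderTree(trA), "dominance")
})

test_that("leaf variances conserve the total exactly", {
    lv <- leafVariances(1, c(p_g = 0.25, p_a = 0.85, p_d = 0.67))
    expect_equal(unname(lv), c(0.75, 0.25 * 0.85, 0.25 * 0.15 * 0.67,
                               0.25 * 0.15 * 0.33))
    expect_equal(sum(lv), 1)
    # degenerate split: no genetic variance
    lv0 <- leafVariances(3, c(p_g = 0))
    expect_equal(unname(lv0), c(3, 0))
    # exact conservation over random inputs, all model depths
    for (s in 1:25) {
        set.seed(s)
        tot <- runif(1, 0.1, 50)
        p <- runif(3)
        expect_equal(sum(leafVariances(tot, c(p_g = p[1]))), tot)
        expect_equal(sum(leafVariances(tot, c(p_g = p[1], p_a = p[2]))),
                     tot)
        expect_equal(sum(leafVariances(tot, c(p_g = p[1], p_a = p[2],
                                              p_d = p[3]))), tot)
    }
})

test_that("expert HD prior on a one-split tree equals the direct PC0 prior", {
    trial <- smallTrial(seed = 4, n = 25, model = "A")
    A <- trial$matrices$a
    tr <- buildTree("A", ekSpec(0.25, model = "A"), list(a = A))
    hp <- buildHDPrior(tr, "expert")
    direct <- pc0Proportion(A, identityRelationship(rownames(relMatrix(A))),
                            0.25)
    expect_lt(max(abs(hp@splitPriors$p_g@logDensity - direct@logDensity)),
              1e-10)
    expect_equal(hp@styleLabel, "A-tree*")
})

test_that("HD prior styles produce the documented split priors", {
    trial <- smallTrial(seed = 6, n = 25)
    tr <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
    hpE <- buildHDPrior(tr, "expert")
    expect_equal(names(hpE@splitPriors), c("p_g", "p_a", "p_d"))
    expect_equal(vapply(hpE@splitPriors, function(p) p@style, character(1)),
                 c(p_g = "PC0", p_a = "PCM", p_d = "PCM"))
    expect_equal(priorMedian(hpE@splitPriors$p_g), 0.25, tolerance = 2e-3)
    expect_equal(priorMedian(hpE@splitPriors$p_a), 0.85, tolerance = 2e-3)
    expect_equal(priorMedian(hpE@splitPriors$p_d), 0.67, tolerance = 2e-3)
    expect_equal(hpE@styleLabel, "ADX-tree*")

    hpD <- buildHDPrior(tr, "default")
    expect_equal(hpD@styleLabel, "ADX-tree")
    # aggregated flat Dirichlet over 4 shares: root Beta(3,1),
    # genetic split Beta(1,2), nonadditive split uniform
    p <- c(0.25, 0.6)
    expect_equal(exp(priorLogDensity(hpD@splitPriors$p_g, p)), 3 * p^2,
                 tolerance = 3e-3)
    expect_equal(exp(priorLogDensity(hpD@splitPriors$p_a, p)),
                 2 * (1 - p), tolerance = 3e-3)
    expect_equal(exp(priorLogDensity(hpD@splitPriors$p_d, p)), c(1, 1),
                 tolerance = 3e-3)

    hpO <- buildHDPrior(tr, "opposite")
    expect_equal(hpO@styleLabel, "ADX-tree-opp*")
    expect_equal(priorMedian(hpO@splitPriors$p_a), 0.05, tolerance = 2e-3)
    # model A default is the uniform prior on p_g
    trA <- buildTree("A", ekSpec(0.25, model = "A"), trial$matrices["a"])
    hpA <- buildHDPrior(trA, "default")
    expect_equal(exp(priorLogDensity(hpA@splitPriors$p_g, c(0.2, 0.8))),
                 c(1, 1), tolerance = 2e-3)
})

test_that("joint HD log prior factorizes and is finite on the interior", {
    trial <- smallTrial(seed = 8, n = 25)
    tr <- buildTree("ADX", ekSpec(0.25, 0.85, 0.67), trial$matrices)
    hp <- buildHDPrior(tr, "expert")
    props <- c(p_g = 0.3, p_a = 0.8, p_d = 0.5)
    lp <- hdLogPrior(hp, 2.5, props)
    manual <- -log(2.5) +
        sum(vapply(names(props), function(nm)
            priorLogDensity(hp@splitPriors[[nm]], props[[nm]]),
            numeric(1)))
    expect_equal(lp, manual, tolerance = 1e-12)
    # Jeffreys is flat on the log scale: doubling sigmaP2 changes nothing
    expect_equal(hdLogPrior(hp, 5, props, samplingScale = TRUE),
                 hdLogPrior(hp, 10, props, samplingScale = TRUE))
    # finite and continuous on a dense interior grid
    for (v in seq(0.05, 0.95, by = 0.09)) {
        val <- hdLogPrior(hp, 1, c(p_g = v, p_a = v, p_d = v))
        expect_true(is.finite(val))
    }
    expect_identical(hdLogPrior(hp, 1, c(p_g = 0, p_a = 0.5, p_d = 0.5)),
                     -Inf)
    expect_identical(hdLogPrior(hp, -1, props), -Inf)
})
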