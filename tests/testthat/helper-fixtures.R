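# Shared fixtures and independent oracles, built in code.

# small genotype matrix with controlled columns
tinySNP <- function() {
    snpMatrix(cbind(mono = c(0, 0, 0, 0),
                    rare = c(0, 0, 0, 1),
                    bal  = c(0, 1, 1, 2)))
}

# random genotype matrix (always polymorphic enough for coding)
randomSNP <- function(n, m, seed) {
    set.seed(seed)
    repeat {
        g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
        if (all(apply(g, 2, function(x) length(unique(x)) > 1))) break
    }
    snpMatrix(g)
}

# random symmetric positive-definite matrix
randomSPD <- function(n, seed) {
    set.seed(seed)
    A <- matrix(rnorm(n * n), n)
    crossprod(A) / n + diag(n) * 0.5
}

# brute-force Gaussian KL distance d(p) = sqrt(2 KL(N(0, pC1+(1-p)C0) ||
# N(0, C0))) via the trace / log-det formula (independent of the
# eigenvalue route used by the package)
bruteKL <- function(C1, C0, p) {
    C0j <- C0 + diag(1e-8 * exp(mean(log(diag(C0)))), nrow(C0))
    S <- p * C1 + (1 - p) * C0j
    M <- solve(C0j, S)
    kl <- 0.5 * (sum(diag(M)) - nrow(C0) -
                 determinant(M, logarithm = TRUE)$modulus)
    sqrt(max(2 * as.numeric(kl), 0))
}

# dense multivariate-normal log-likelihood at observation level (oracle
# for the collapsed representation)
denseMVNLogLik <- function(params, data) {
    idx <- as.integer(data@individual)
    N <- length(data@y)
    V <- diag(params[["sigma2_e"]], N)
    for (c. in names(data@matrices)) {
        K <- relMatrix(data@matrices[[c.]])
        V <- V + params[[paste0("sigma2_", c.)]] * K[idx, idx]
    }
    res <- data@y - params[["mu"]]
    ch <- chol(V)
    -0.5 * N * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * sum(backsolve(ch, res, transpose = TRUE)^2)
}

# effective sample size from the empirical autocorrelation (initial
# positive sequence), for Monte-Carlo error bars on posterior means
essOf <- function(x) {
    n <- length(x)
    rho <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
    s <- 0
    for (r in rho) {
        if (r < 0.05) break
        s <- s + r
    }
    max(n / (1 + 2 * s), 10)
}

# a small simulated trial shared by several tests
smallTrial <- function(seed = 7, n = 40, model = "ADX") {
    simulateTrial(simConfig(nIndividuals = n, markersPerChr = 80,
                            causalPerChr = 80, seed = seed), model = model)
}
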