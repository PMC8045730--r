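#' Simulation configuration for one breeding-trial stage
#'
#' Settings for the synthetic advanced-yield-trial generator: founder
#' genotypes at independent biallelic loci in Hardy-Weinberg proportions,
#' causal additive/dominance/epistasis effects rescaled so the realized
#' cohort variances hit their targets exactly, and replicated phenotypes
#' with Gaussian environmental noise. The defaults mirror the simulated
#' wheat trial stage: 100 individuals with 5 replicates and founder
#' variances 1.0 (additive), 0.5 (dominance), 0.1 (epistasis) and 6.0
#' (environmental); marker and causal-locus counts default to a desk-scale
#' 2 chromosomes x 200 loci each.
#'
#' @param nIndividuals number of individuals in the trial cohort.
#' @param nChromosomes,markersPerChr,causalPerChr genome layout; markers
#'   and causal loci are drawn disjointly (causal loci are not observed as
#'   markers).
#' @param freqRange allele-frequency range for the per-locus Uniform draw;
#'   both ends must be strictly inside (0, 1) so no locus is monomorphic by
#'   construction.
#' @param varA,varD,varX target additive, dominance and epistasis
#'   variances (>= 0; zero switches the component off).
#' @param varE environmental variance (> 0).
#' @param replicates phenotype replicates per individual.
#' @param mu trial intercept.
#' @param nPairs number of disjoint causal-locus pairs carrying
#'   additive-by-additive effects (default: half the causal loci).
#' @param seed RNG seed.
#' @return A \code{SimConfig} object.
#' @export
simConfig <- function(nIndividuals = 100L, nChromosomes = 2L,
                      markersPerChr = 200L, causalPerChr = 200L,
                      freqRange = c(0.05, 0.95), varA = 1.0, varD = 0.5,
                      varX = 0.1, varE = 6.0, replicates = 5L, mu = 0,
                      nPairs = NULL, seed = 1L) {
    nCausal <- as.integer(nChromosomes * causalPerChr)
    if (is.null(nPairs)) nPairs <- nCausal %/% 2L
    new("SimConfig",
        nIndividuals = as.integer(nIndividuals),
        nChromosomes = as.integer(nChromosomes),
        markersPerChr = as.integer(markersPerChr),
        causalPerChr = as.integer(causalPerChr),
        freqRange = freqRange, varA = varA, varD = varD, varX = varX,
        varE = varE, replicates = as.integer(replicates), mu = mu,
        nPairs = as.integer(nPairs), seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
setClass("SimConfig",
    representation(nIndividuals = "integer", nChromosomes = "integer",
                   markersPerChr = "integer", causalPerChr = "integer",
                   freqRange = "numeric", varA = "numeric", varD = "numeric",
                   varX = "numeric", varE = "numeric",
                   replicates = "integer", mu = "numeric",
                   nPairs = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nIndividuals < 2L) return("need at least 2 individuals")
    fr <- object@freqRange
    if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
        return(paste("freqRange must lie strictly inside (0, 1):",
                     "fixed allele frequencies 0 and 1 give monomorphic",
                     "loci, undefined for variance scaling"))
    if (any(c(object@varA, object@varD, object@varX) < 0))
        return("genetic target variances must be >= 0")
    if (object@varE <= 0) return("environmental variance must be > 0")
    if (object@replicates < 1L) return("replicates must be >= 1")
    if (object@nPairs > (object@causalPerChr * object@nChromosomes) %/% 2L)
        return("nPairs cannot exceed half the causal loci (disjoint pairs)")
    TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d individuals x %d replicates, ",
                       "%d markers, %d causal loci\n"),
                object@nIndividuals, object@replicates,
                object@nChromosomes * object@markersPerChr,
                object@nChromosomes * object@causalPerChr))
    cat(sprintf("  target variances: A %.3g, D %.3g, X %.3g, E %.3g\n",
                object@varA, object@varD, object@varX, object@varE))
})

#' True genetic values of a simulated cohort
#'
#' @slot a,d,x,g per-individual true additive, dominance, epistasis and
#'   total genetic values (g = a + d + x exactly).
#' @slot realizedVariances named vector of realized cohort variances
#'   (denominator n), equal to the targets exactly after rescaling.
#' @slot effects list of the causal effect vectors and epistatic locus
#'   pairs.
#' @seealso \code{\link{simulateTruth}}
#' @export
setClass("TruthSet",
    representation(a = "numeric", d = "numeric", x = "numeric",
                   g = "numeric", realizedVariances = "numeric",
                   effects = "list"))

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet: %d individuals\n", length(object@g)))
    cat("  realized variances:",
        paste(sprintf("%s = %.4g", names(object@realizedVariances),
                      object@realizedVariances), collapse = ", "), "\n")
})

# draw an n x m genotype matrix in HWE with per-locus frequencies f
drawGenotypes <- function(n, f, ids, prefix) {
    g <- vapply(f, function(p) rbinom(n, 2L, p), numeric(n))
    rownames(g) <- ids
    colnames(g) <- prefix
    g
}

#' Simulate founder genotypes
#'
#' Draws marker and causal-locus genotypes independently per locus in
#' Hardy-Weinberg proportions, with allele frequencies from
#' Uniform(\code{freqRange}). Markers and causal loci are disjoint sets:
#' the markers observe, but do not coincide with, the causal loci.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{markers} and \code{causal}, both
#'   \code{\link{SNPMatrix}} objects over the same individuals.
#' @export
simulateGenotypes <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(cfg@seed)
    n <- cfg@nIndividuals
    ids <- sprintf("ind%03d", seq_len(n))
    chr <- rep(seq_len(cfg@nChromosomes), each = cfg@markersPerChr)
    mIds <- sprintf("chr%d_m%d", chr,
                    sequence(rep(cfg@markersPerChr, cfg@nChromosomes)))
    chrq <- rep(seq_len(cfg@nChromosomes), each = cfg@causalPerChr)
    qIds <- sprintf("chr%d_q%d", chrq,
                    sequence(rep(cfg@causalPerChr, cfg@nChromosomes)))
    fM <- runif(length(mIds), cfg@freqRange[1], cfg@freqRange[2])
    fQ <- runif(length(qIds), cfg@freqRange[1], cfg@freqRange[2])
    list(markers = snpMatrix(drawGenotypes(n, fM, ids, mIds)),
         causal = snpMatrix(drawGenotypes(n, fQ, ids, qIds)))
}

# rescale a value vector so its cohort variance equals the target exactly
rescaleToVariance <- function(v, target, component) {
    if (target == 0) return(rep(0, length(v)))
    s <- popVar(v)
    if (s < .Machine$double.eps)
        stop(sprintf(paste("cannot realize %s variance %g: the causal",
                           "genotypes carry no variation for this component"),
                     component, target))
    v * sqrt(target / s)
}

#' Simulate true genetic values from causal genotypes
#'
#' Additive values are linear combinations of centered additive codings at
#' the causal loci; dominance values of centered heterozygosity codings;
#' epistasis values of centered products of additive codings at random
#' disjoint locus pairs. Effect coefficients are standard normal, and each
#' component's value vector is rescaled so its realized cohort variance
#' equals the target exactly (components with target 0 are exactly zero).
#'
#' @param causal \code{\link{SNPMatrix}} of causal-locus genotypes.
#' @param cfg a \code{\link{simConfig}}.
#' @return A \code{\link{TruthSet}}.
#' @export
simulateTruth <- function(causal, cfg) {
    stopifnot(is(causal, "SNPMatrix"), is(cfg, "SimConfig"))
    set.seed(cfg@seed + 1L)
    n <- nrow(genotypes(causal))
    m <- ncol(genotypes(causal))
    Za <- codeAdditive(causal)@values
    alpha <- rnorm(m)
    a <- rescaleToVariance(drop(Za %*% alpha), cfg@varA, "additive")
    d <- rep(0, n)
    delta <- numeric(0)
    if (cfg@varD > 0) {
        H <- (genotypes(causal) == 1) * 1
        if (all(H == 0))
            stop("cannot realize dominance variance: fully inbred causal ",
                 "genotypes have no heterozygotes")
        Zd <- scale(H, center = TRUE, scale = FALSE)
        delta <- rnorm(m)
        d <- rescaleToVariance(drop(Zd %*% delta), cfg@varD, "dominance")
    }
    x <- rep(0, n)
    pairs <- matrix(integer(0), 0, 2)
    eps <- numeric(0)
    if (cfg@varX > 0) {
        loci <- sample.int(m, 2L * cfg@nPairs)
        pairs <- matrix(loci, ncol = 2)
        W <- Za[, pairs[, 1], drop = FALSE] * Za[, pairs[, 2], drop = FALSE]
        W <- scale(W, center = TRUE, scale = FALSE)
        eps <- rnorm(nrow(pairs))
        x <- rescaleToVariance(drop(W %*% eps), cfg@varX, "epistasis")
    }
    g <- a + d + x
    names(a) <- names(d) <- names(x) <- names(g) <- rownames(genotypes(causal))
    new("TruthSet", a = a, d = d, x = x, g = g,
        realizedVariances = c(additive = popVar(a), dominance = popVar(d),
                              epistasis = popVar(x), genetic = popVar(g)),
        effects = list(alpha = alpha, delta = delta, epsilon = eps,
                       pairs = pairs))
}

#' Simulate replicated phenotypes
#'
#' \code{y[i, r] = mu + g_i + e[i, r]} with iid Gaussian environmental
#' noise of variance \code{varE}.
#'
#' @param truth a \code{\link{TruthSet}}.
#' @param cfg a \code{\link{simConfig}}.
#' @return data.frame with columns \code{individual_id}, \code{value},
#'   \code{replicate} (the phenotype-table format consumed by
#'   \code{\link{genomicData}}).
#' @export
simulatePhenotypes <- function(truth, cfg) {
    stopifnot(is(truth, "TruthSet"), is(cfg, "SimConfig"))
    set.seed(cfg@seed + 2L)
    ids <- names(truth@g)
    n <- length(ids)
    r <- cfg@replicates
    e <- rnorm(n * r, 0, sqrt(cfg@varE))
    data.frame(individual_id = rep(ids, times = r),
               value = cfg@mu + rep(truth@g, times = r) + e,
               replicate = rep(seq_len(r), each = n),
               stringsAsFactors = FALSE)
}

#' Simulate a complete trial dataset
#'
#' One-call pipeline: genotypes, MAF filtering of the markers,
#' relationship matrices A/D/X, true genetic values and replicated
#' phenotypes.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param model which relationship matrices to carry (\code{"ADX"} builds
#'   all three).
#' @param mafThreshold marker MAF filter (default 0.05).
#' @return list with \code{data} (a \code{\link{GenomicData}}),
#'   \code{truth}, \code{markers}, \code{causal}, \code{phenotypes} and
#'   \code{matrices}.
#' @export
simulateTrial <- function(cfg, model = c("ADX", "AD", "A"),
                          mafThreshold = 0.05) {
    model <- match.arg(model)
    geno <- simulateGenotypes(cfg)
    markers <- filterMAF(geno$markers, mafThreshold)
    A <- buildRelationship(codeAdditive(markers), "A")
    matrices <- list(a = A)
    if (model %in% c("AD", "ADX"))
        matrices$d <- buildRelationship(codeDominance(markers), "D")
    if (model == "ADX")
        matrices$x <- buildRelationship(A, "X")
    truth <- simulateTruth(geno$causal, cfg)
    pheno <- simulatePhenotypes(truth, cfg)
    list(data = genomicData(pheno, matrices), truth = truth,
         markers = markers, causal = geno$causal, phenotypes = pheno,
         matrices = matrices)
}

#' Write simulated truth as a delimited table
#'
#' @param truth a \code{\link{TruthSet}}.
#' @param file output path.
#' @export
writeTruth <- function(truth, file) {
    utils::write.table(
        data.frame(individual_id = names(truth@g), a = truth@a, d = truth@d,
                   x = truth@x, g = truth@g),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
}
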