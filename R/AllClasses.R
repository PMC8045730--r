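#' @import methods
#' @importFrom stats approx dnorm integrate median optim qnorm quantile rbinom
#'   rexp rnorm runif sd setNames uniroot var cor rchisq
NULL

#' SNP genotype matrix
#'
#' Biallelic SNP genotypes for \code{n} individuals at \code{m} markers,
#' coded additively as 0/1/2 counts of one allele. Row names are individual
#' ids, column names are marker ids. Missing genotypes are not allowed;
#' reject or impute at ingestion (see \code{\link{readGenotypes}}).
#'
#' @slot genotypes integer-valued n x m matrix with entries in \{0, 1, 2\}.
#'
#' @seealso \code{\link{filterMAF}}, \code{\link{codeAdditive}},
#'   \code{\link{codeDominance}}
#' @export
setClass("SNPMatrix", representation(genotypes = "matrix"))

setValidity("SNPMatrix", function(object) {
    g <- object@genotypes
    if (!is.numeric(g)) return("genotypes must be numeric")
    if (anyNA(g)) return("missing genotypes are not allowed")
    if (!all(g %in% c(0, 1, 2))) return("genotype codes must be 0, 1 or 2")
    if (nrow(g) < 2L) return("at least 2 individuals are required")
    if (ncol(g) < 1L) return("at least 1 marker is required")
    if (is.null(rownames(g))) return("individual ids (rownames) are required")
    if (is.null(colnames(g))) return("marker ids (colnames) are required")
    if (anyDuplicated(rownames(g))) return("duplicated individual ids")
    TRUE
})

#' Centered marker coding
#'
#' A column-centered real coding of a genotype matrix: either the additive
#' coding (0/1/2 minus column means) or the dominance coding (heterozygote
#' indicator minus column means). Every column sums to zero.
#'
#' @slot values n x m real matrix with zero column sums.
#' @slot coding \code{"additive_centered"} or \code{"dominance_centered"}.
#' @export
setClass("CodedMatrix", representation(values = "matrix", coding = "character"))

setValidity("CodedMatrix", function(object) {
    if (!object@coding %in% c("additive_centered", "dominance_centered"))
        return("unknown coding")
    cs <- colSums(object@values)
    if (max(abs(cs)) >= 1e-9 * nrow(object@values))
        return("columns are not centered")
    TRUE
})

#' Scaled genomic relationship matrix
#'
#' An n x n covariance structure among individuals for one genetic component
#' (additive A, dominance D, additive-by-additive epistasis X) or the
#' identity for the environment. Cross-products are divided by a scaling
#' constant so that the typical (geometric-mean) diagonal value is 1, which
#' puts all components on a common variance scale.
#'
#' @slot matrix symmetric positive semi-definite n x n matrix.
#' @slot scalingConstant the positive constant the raw cross-product was
#'   divided by.
#' @slot kind one of \code{"A"}, \code{"D"}, \code{"X"}, \code{"identity"}.
#' @seealso \code{\link{buildRelationship}}, \code{\link{scaleConstant}}
#' @export
setClass("RelationshipMatrix",
    representation(matrix = "matrix", scalingConstant = "numeric",
                   kind = "character"))

setValidity("RelationshipMatrix", function(object) {
    M <- object@matrix
    if (nrow(M) != ncol(M)) return("matrix must be square")
    if (max(abs(M - t(M))) >= 1e-8) return("matrix must be symmetric")
    if (length(object@scalingConstant) != 1L || object@scalingConstant <= 0)
        return("scalingConstant must be a positive scalar")
    if (!object@kind %in% c("A", "D", "X", "identity"))
        return("kind must be A, D, X or identity")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= -1e-8 * sum(diag(M)) / nrow(M))
        return("matrix is not positive semi-definite within tolerance")
    TRUE
})

#' Penalized-complexity prior on a standard deviation
#'
#' The PC prior for the standard deviation of a zero-mean random effect
#' shrinks toward sigma = 0 and is an exponential distribution with rate
#' \code{-log(tailProb) / upperValue}, calibrated so that
#' \code{P(sigma > upperValue) = tailProb}.
#'
#' @slot upperValue upper value V (response standard-deviation units).
#' @slot tailProb tail probability alpha in (0, 1).
#' @slot rate exponential rate lambda = -log(alpha) / V.
#' @seealso \code{\link{pcSD}}
#' @export
setClass("PCPriorSD",
    representation(upperValue = "numeric", tailProb = "numeric",
                   rate = "numeric"))

setValidity("PCPriorSD", function(object) {
    if (object@upperValue <= 0) return("upperValue must be positive")
    if (object@tailProb <= 0 || object@tailProb >= 1)
        return("tailProb must be in (0, 1)")
    if (abs(object@rate - (-log(object@tailProb) / object@upperValue)) > 1e-12)
        return("rate inconsistent with upperValue and tailProb")
    TRUE
})

#' Numerically tabulated prior on a variance proportion
#'
#' A prior density for a proportion p in (0, 1) of one variance within the
#' sum of two structured components, stored as log-density values on a fixed
#' grid. Styles: \code{"PC0"} (shrinks to p = 0, median calibrated),
#' \code{"PCM"} (shrinks to the median, logit-interval mass calibrated) and
#' \code{"dirichlet_marginal"} (Beta marginal of a flat Dirichlet).
#'
#' @slot grid strictly increasing grid in (0, 1).
#' @slot logDensity log prior density at the grid points (normalized).
#' @slot style \code{"PC0"}, \code{"PCM"} or \code{"dirichlet_marginal"}.
#' @slot medianTarget the median R the prior was calibrated to (NA for
#'   Dirichlet marginals).
#' @slot concentrationMass for PCM, the probability mass allocated to the
#'   logit interval \code{[logit(R) - 1, logit(R) + 1]}.
#' @slot distanceCurve data.frame with columns \code{p}, \code{d}: the
#'   Kullback-Leibler-based distance used in the construction (empty for
#'   Dirichlet marginals).
#' @slot theta calibrated concentration (rate) parameter (NA for Dirichlet).
#' @seealso \code{\link{pc0Proportion}}, \code{\link{pcmProportion}},
#'   \code{\link{dirichletMarginals}}
#' @export
setClass("ProportionPrior",
    representation(grid = "numeric", logDensity = "numeric",
                   style = "character", medianTarget = "numeric",
                   concentrationMass = "numeric",
                   distanceCurve = "data.frame", theta = "numeric"))

setValidity("ProportionPrior", function(object) {
    g <- object@grid
    if (length(g) < 10L) return("grid too short")
    if (any(diff(g) <= 0)) return("grid must be strictly increasing")
    if (g[1] <= 0 || g[length(g)] >= 1) return("grid must lie inside (0, 1)")
    if (length(object@logDensity) != length(g))
        return("logDensity length must match grid")
    if (!object@style %in% c("PC0", "PCM", "dirichlet_marginal"))
        return("unknown style")
    z <- trapint(g, exp(object@logDensity))
    if (abs(z - 1) > 1e-6) return("density does not integrate to 1")
    TRUE
})

#' Component-wise PC prior set
#'
#' Independent PC priors on the standard deviations of each model component
#' (environmental, additive and optionally dominance and epistasis), with
#' upper values derived from expert knowledge on variance ratios and the
#' phenotypic variance VP.
#'
#' @slot priors named list of \code{\link{PCPriorSD}} objects
#'   (\code{sigma_e}, \code{sigma_a}, and for AD/ADX \code{sigma_d},
#'   for ADX \code{sigma_x}).
#' @slot provenance list recording the EK values, VP and alpha used.
#' @seealso \code{\link{componentwisePriors}}
#' @export
setClass("ComponentPriorSet",
    representation(priors = "list", provenance = "list"))

#' Expert knowledge on variance ratios
#'
#' The three elicited proportions driving the variance-decomposition tree:
#' genetic-to-phenotypic (broad-sense heritability, EK-pheno),
#' additive-to-genetic (EK-genetic) and dominance-to-nonadditive
#' (EK-nonadd). For model A the lower two are fixed at 1; for model AD the
#' lowest is fixed at 1.
#'
#' @slot RGge proportion of genetic to phenotypic variance, hg2.
#' @slot RAg proportion of additive to genetic variance.
#' @slot RDdx proportion of dominance to nonadditive variance.
#' @seealso \code{\link{ekSpec}}, \code{\link{impliedLeafShares}}
#' @export
setClass("EKSpec",
    representation(RGge = "numeric", RAg = "numeric", RDdx = "numeric"))

setValidity("EKSpec", function(object) {
    ok <- function(x) length(x) == 1L && x > 0 && x <= 1
    if (!ok(object@RGge) || object@RGge >= 1)
        return("RGge must be in (0, 1)")
    if (!ok(object@RAg)) return("RAg must be in (0, 1]")
    if (!ok(object@RDdx)) return("RDdx must be in (0, 1]")
    TRUE
})

#' Variance-decomposition tree
#'
#' The tree of variance splits defining models A, AD and ADX: phenotypic ->
#' \{genetic, environmental\}, genetic -> \{additive, nonadditive\},
#' nonadditive -> \{dominance, epistasis\}. Each split carries its EK value
#' and prior style; each leaf is bound to a relationship matrix (identity
#' for the environmental leaf).
#'
#' @slot model \code{"A"}, \code{"AD"} or \code{"ADX"}.
#' @slot splits list of split descriptors ordered from root down, each with
#'   elements \code{name}, \code{ek}, \code{style}.
#' @slot matrices named list of \code{\link{RelationshipMatrix}} leaf
#'   bindings (\code{a}, \code{e}, and per model \code{d}, \code{x}).
#' @slot ek the \code{\link{EKSpec}} used.
#' @seealso \code{\link{buildTree}}, \code{\link{buildHDPrior}},
#'   \code{\link{renderTree}}
#' @export
setClass("VarianceTree",
    representation(model = "character", splits = "list", matrices = "list",
                   ek = "EKSpec"))

#' Joint hierarchical-decomposition prior
#'
#' The model-wise prior over the total phenotypic variance and the tree's
#' split proportions: an improper Jeffreys prior (flat in log sigmaP2) on
#' the total variance and one \code{\link{ProportionPrior}} per split,
#' constructed bottom-up conditional on the expert knowledge below each
#' split. The joint log prior is the sum of the split log densities minus
#' log sigmaP2.
#'
#' @slot tree the \code{\link{VarianceTree}} the prior was built for.
#' @slot splitPriors named list of \code{\link{ProportionPrior}} objects,
#'   one per split (\code{p_g}, and per model \code{p_a}, \code{p_d}).
#' @slot styleLabel prior-family label, e.g. \code{"ADX-tree*"},
#'   \code{"A-tree"}.
#' @seealso \code{\link{buildHDPrior}}, \code{\link{logPosterior}}
#' @export
setClass("HDJointPrior",
    representation(tree = "VarianceTree", splitPriors = "list",
                   styleLabel = "character"))

#' Phenotypes and genomic structures for one analysis
#'
#' Observed phenotypic values with an observation-to-individual design map
#' and the scaled relationship matrices of the genetic components included
#' in the model. Replicated observations are supported; the likelihood
#' collapses them exactly through per-individual means.
#'
#' @slot y length-N phenotype vector.
#' @slot individual factor of length N mapping observations to individuals;
#'   levels match the relationship-matrix ids.
#' @slot matrices named list of \code{\link{RelationshipMatrix}} objects for
#'   the genetic components (\code{a}, optionally \code{d}, \code{x}).
#' @seealso \code{\link{genomicData}}, \code{\link{fitBayes}},
#'   \code{\link{fitML}}
#' @export
setClass("GenomicData",
    representation(y = "numeric", individual = "factor", matrices = "list"))

setValidity("GenomicData", function(object) {
    if (length(object@y) != length(object@individual))
        return("y and individual must have equal length")
    if (anyNA(object@y)) return("missing phenotypes are not allowed")
    if (length(object@matrices) < 1L)
        return("at least one genetic relationship matrix is required")
    n <- nlevels(object@individual)
    for (nm in names(object@matrices)) {
        K <- object@matrices[[nm]]
        if (!is(K, "RelationshipMatrix"))
            return("matrices must be RelationshipMatrix objects")
        if (nrow(K@matrix) != n)
            return(sprintf("matrix '%s' dimension does not match individuals", nm))
        if (!identical(rownames(K@matrix), levels(object@individual)))
            return(sprintf("matrix '%s' ids do not match individual levels", nm))
    }
    if (length(object@y) < n) return("fewer observations than individuals")
    TRUE
})

#' Model fit result
#'
#' Posterior draws (Bayesian path) or a point estimate (ML path) of the
#' variance parameters, together with stability diagnostics, sampler or
#' optimizer settings and the data the model was fitted to.
#'
#' @slot method \code{"bayes"} or \code{"ml"}.
#' @slot model \code{"A"}, \code{"AD"} or \code{"ADX"}.
#' @slot draws matrix of posterior draws (rows) of the sampled
#'   parameterization plus derived component variances; for ML a single row
#'   with the point estimate.
#' @slot diagnostics list: Bayesian \code{divergent} count and \code{nDraws}
#'   (post-warmup); ML \code{converged} and \code{atBound} flags.
#' @slot settings list of seed, chain/warmup/draw counts or optimizer
#'   bounds and initial values.
#' @slot data the \code{\link{GenomicData}} used for fitting.
#' @seealso \code{\link{fitBayes}}, \code{\link{fitML}},
#'   \code{\link{stability}}, \code{\link{predictValues}}
#' @export
setClass("FitResult",
    representation(method = "character", model = "character",
                   draws = "matrix", diagnostics = "list",
                   settings = "list", data = "GenomicData"))
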