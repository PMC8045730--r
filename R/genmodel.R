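#' Assemble phenotypes and relationship matrices for model fitting
#'
#' @param phenotypes data.frame with columns \code{individual_id},
#'   \code{value} and (optionally) \code{replicate}.
#' @param matrices named list of genetic \code{\link{RelationshipMatrix}}
#'   objects (\code{a}, optionally \code{d}, \code{x}) whose row names
#'   cover every phenotyped individual.
#' @return A \code{\link{GenomicData}}.
#' @export
genomicData <- function(phenotypes, matrices) {
    stopifnot(all(c("individual_id", "value") %in% names(phenotypes)))
    ids <- rownames(relMatrix(matrices[[1]]))
    unknown <- setdiff(unique(phenotypes$individual_id), ids)
    if (length(unknown))
        stop("phenotyped individuals missing from the relationship ",
             "matrices: ", paste(utils::head(unknown, 5), collapse = ", "))
    ind <- factor(phenotypes$individual_id, levels = ids)
    new("GenomicData", y = as.numeric(phenotypes$value), individual = ind,
        matrices = matrices)
}

setMethod("show", "GenomicData", function(object) {
    cat(sprintf("GenomicData: %d observations on %d individuals; components: %s\n",
                length(object@y), nlevels(object@individual),
                paste(names(object@matrices), collapse = ", ")))
})

#' @describeIn genomicData model implied by the genetic components present
#' @param data a \code{GenomicData}.
#' @export
dataModel <- function(data) {
    comp <- names(data@matrices)
    if (all(c("d", "x") %in% comp)) "ADX" else if ("d" %in% comp) "AD" else "A"
}

# Exact collapse of replicated observations: per-individual means ybar with
# residual covariance sigma2_e/r_i around mu + g_i, plus the within-
# individual sum of squares SSW on N - n degrees of freedom.
collapseData <- function(data) {
    idx <- as.integer(data@individual)
    n <- nlevels(data@individual)
    r <- tabulate(idx, nbins = n)
    if (any(r == 0L))
        stop("individual without observations in the design")
    ybar <- as.numeric(rowsum(data@y, idx) / r)
    SSW <- sum((data@y - ybar[idx])^2)
    list(ybar = ybar, r = r, SSW = SSW, n = n, N = length(data@y))
}

# component variances present in a parameter vector, in data order
geneticVariancesOf <- function(params, data) {
    nms <- paste0("sigma2_", names(data@matrices))
    v <- params[nms]
    if (anyNA(v)) stop("parameter vector lacks a component variance")
    names(v) <- names(data@matrices)
    v
}

#' Marginal Gaussian log-likelihood of the genomic mixed model
#'
#' The genetic values are marginalized out: y ~ N(mu 1, sum_c sigma2_c K_c
#' expanded to observation level + sigma2_e I_N). Replicates are collapsed
#' exactly through per-individual means, so only n x n decompositions are
#' needed.
#'
#' @param params named numeric vector with \code{mu}, \code{sigma2_e} and
#'   one \code{sigma2_<c>} per genetic component of \code{data} (e.g.
#'   \code{sigma2_a}).
#' @param data a \code{\link{GenomicData}}.
#' @return scalar log-likelihood (\code{-Inf} outside the parameter
#'   space).
#' @export
logLikelihood <- function(params, data) {
    cs <- collapseData(data)
    vg <- geneticVariancesOf(params, data)
    s2e <- params[["sigma2_e"]]
    if (any(vg < 0) || s2e < 0) return(-Inf)
    if (s2e == 0 && all(vg == 0))
        stop("singular total covariance: all variances are zero")
    if (s2e <= 0) return(-Inf)
    G <- matrix(0, cs$n, cs$n)
    for (i in seq_along(vg))
        G <- G + vg[i] * relMatrix(data@matrices[[i]])
    Sm <- G + diag(s2e / cs$r, cs$n)
    U <- tryCatch(chol(Sm), error = function(e) NULL)
    if (is.null(U)) return(-Inf)
    res <- cs$ybar - params[["mu"]]
    w <- backsolve(U, res, transpose = TRUE)
    # - sum(log r)/2: determinant factor from evaluating the individual-
    # mean block on the sqrt(r)-scaled orthonormal coordinates
    ll <- -0.5 * (cs$N - cs$n) * log(2 * pi * s2e) - cs$SSW / (2 * s2e) -
        0.5 * sum(log(cs$r)) -
        sum(log(diag(U))) - 0.5 * cs$n * log(2 * pi) - 0.5 * sum(w^2)
    as.numeric(ll)
}

# gradient of logLikelihood wrt (mu, sigma2_e, sigma2_c ...); shares the
# collapsed representation. Returns a named vector.
gradLogLikelihood <- function(params, data, cs = collapseData(data)) {
    vg <- geneticVariancesOf(params, data)
    s2e <- params[["sigma2_e"]]
    G <- matrix(0, cs$n, cs$n)
    for (i in seq_along(vg))
        G <- G + vg[i] * relMatrix(data@matrices[[i]])
    Sm <- G + diag(s2e / cs$r, cs$n)
    U <- chol(Sm)
    Sinv <- chol2inv(U)
    res <- cs$ybar - params[["mu"]]
    u <- Sinv %*% res
    out <- c(mu = sum(u))
    out["sigma2_e"] <- -(cs$N - cs$n) / (2 * s2e) + cs$SSW / (2 * s2e^2) -
        0.5 * sum(diag(Sinv) / cs$r) + 0.5 * sum(u^2 / cs$r)
    for (i in seq_along(vg)) {
        K <- relMatrix(data@matrices[[i]])
        out[paste0("sigma2_", names(vg)[i])] <-
            -0.5 * sum(Sinv * K) + 0.5 * sum(u * (K %*% u))
    }
    out
}

# fused log-likelihood and gradient sharing one Cholesky factorization
# (the sampler evaluates both at every leapfrog step); NULL outside the
# parameter space or on factorization failure
llGradLogLikelihood <- function(params, data, cs) {
    vg <- geneticVariancesOf(params, data)
    s2e <- params[["sigma2_e"]]
    if (any(vg < 0) || s2e <= 0) return(NULL)
    G <- matrix(0, cs$n, cs$n)
    for (i in seq_along(vg))
        G <- G + vg[i] * relMatrix(data@matrices[[i]])
    Sm <- G + diag(s2e / cs$r, cs$n)
    U <- tryCatch(chol(Sm), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    Sinv <- chol2inv(U)
    res <- cs$ybar - params[["mu"]]
    u <- Sinv %*% res
    ll <- -0.5 * (cs$N - cs$n) * log(2 * pi * s2e) - cs$SSW / (2 * s2e) -
        0.5 * sum(log(cs$r)) - sum(log(diag(U))) -
        0.5 * cs$n * log(2 * pi) - 0.5 * sum(res * u)
    grad <- c(mu = sum(u))
    grad["sigma2_e"] <- -(cs$N - cs$n) / (2 * s2e) + cs$SSW / (2 * s2e^2) -
        0.5 * sum(diag(Sinv) / cs$r) + 0.5 * sum(u^2 / cs$r)
    for (i in seq_along(vg)) {
        K <- relMatrix(data@matrices[[i]])
        grad[paste0("sigma2_", names(vg)[i])] <-
            -0.5 * sum(Sinv * K) + 0.5 * sum(u * (K %*% u))
    }
    list(value = as.numeric(ll), grad = grad)
}

# |Jacobian| of (sigmaP2, proportions) -> component variances: the product
# of the variance mass entering each split (stick-breaking determinant).
treeJacobian <- function(sigmaP2, proportions) {
    J <- sigmaP2
    if ("p_a" %in% names(proportions))
        J <- J * sigmaP2 * proportions[["p_g"]]
    if ("p_d" %in% names(proportions))
        J <- J * sigmaP2 * proportions[["p_g"]] * (1 - proportions[["p_a"]])
    J
}

# component variances -> (sigmaP2, proportions); inverse of leafVariances
treeCoordinates <- function(vars) {
    tot <- sum(vars)
    g <- tot - vars[["sigma2_e"]]
    p <- c(p_g = g / tot)
    if ("sigma2_d" %in% names(vars)) {
        p["p_a"] <- vars[["sigma2_a"]] / g
        if ("sigma2_x" %in% names(vars)) {
            nonadd <- vars[["sigma2_d"]] + vars[["sigma2_x"]]
            p["p_d"] <- if (nonadd > 0) vars[["sigma2_d"]] / nonadd else 0.5
        }
    }
    list(sigmaP2 = tot, proportions = p)
}

#' Log posterior density of the genomic mixed model
#'
#' Log-likelihood plus log-prior. The intercept always carries its
#' near-translation-invariant N(0, 1000) prior. With an
#' \code{\link{HDJointPrior}} the variance prior is Jeffreys on the total
#' plus the split densities (evaluated at the tree coordinates implied by
#' the component variances); with a \code{\link{ComponentPriorSet}} it is
#' the sum of the exponential PC-prior log densities on the component
#' standard deviations.
#'
#' @inheritParams logLikelihood
#' @param prior an \code{\link{HDJointPrior}} or
#'   \code{\link{ComponentPriorSet}}.
#' @param parameterization how \code{params} is expressed and on which
#'   scale the density lives: \code{"component"} (default) takes component
#'   variances; \code{"tree"} takes \code{mu}, \code{sigmaP2} and the
#'   split proportions \code{p_g}/\code{p_a}/\code{p_d} (HD priors only),
#'   with the stick-breaking Jacobian relating the two densities.
#' @return scalar log posterior (up to the model-evidence constant);
#'   \code{-Inf} outside the prior support, never an exception.
#' @export
logPosterior <- function(params, data, prior,
                         parameterization = c("component", "tree")) {
    parameterization <- match.arg(parameterization)
    if (parameterization == "tree") {
        stopifnot(is(prior, "HDJointPrior"))
        pn <- intersect(c("p_g", "p_a", "p_d"), names(params))
        props <- params[pn]
        if (params[["sigmaP2"]] <= 0 || any(props <= 0) || any(props >= 1))
            return(-Inf)
        vars <- leafVariances(params[["sigmaP2"]], props)
        cparams <- c(mu = params[["mu"]], vars)
        ll <- logLikelihood(cparams, data)
        lp <- hdLogPrior(prior, params[["sigmaP2"]], props)
        return(ll + lp + dnorm(params[["mu"]], 0, sqrt(1000), log = TRUE))
    }
    ll <- logLikelihood(params, data)
    if (!is.finite(ll)) return(-Inf)
    lp <- dnorm(params[["mu"]], 0, sqrt(1000), log = TRUE)
    if (is(prior, "HDJointPrior")) {
        vars <- params[setdiff(names(params), "mu")]
        tc <- treeCoordinates(vars)
        lp <- lp + hdLogPrior(prior, tc$sigmaP2, tc$proportions) -
            log(treeJacobian(tc$sigmaP2, tc$proportions))
    } else if (is(prior, "ComponentPriorSet")) {
        # exponential PC prior on each sd, with the sd -> variance Jacobian
        for (nm in names(prior@priors)) {
            v <- params[[nm2var(nm)]]
            if (is.null(v) || v <= 0) return(-Inf)
            s <- sqrt(v)
            lp <- lp + log(dPCSD(s, prior@priors[[nm]])) - log(2 * s)
        }
    } else stop("unsupported prior class: ", class(prior))
    ll + lp
}

# "sigma_a" -> "sigma2_a"
nm2var <- function(nm) sub("^sigma_", "sigma2_", nm)
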