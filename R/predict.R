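# Conditional (mixed-model) recovery of individual genetic values and
# posterior-predictive phenotypes from a fitted model.

# per-draw helper: Sm^{-1} of the fitted (training) individuals
fitKernel <- function(fit) {
    cs <- collapseData(fit@data)
    list(cs = cs, mats = lapply(fit@data@matrices, relMatrix))
}

#' Posterior draws of individual genetic values
#'
#' For each posterior draw of the variance parameters, the joint
#' conditional Gaussian of the component values (a, and per model d, x)
#' given the phenotypes is formed from the mixed-model identities and
#' sampled once; g = a + d + x per draw. With
#' \code{conditionalDraws = FALSE} the conditional means (BLUP-type
#' estimates given the draw's variances) are returned instead of samples —
#' the default for single-draw ML fits.
#'
#' @param fit a \code{\link{FitResult}}.
#' @param conditionalDraws sample the conditional distribution (default
#'   for Bayesian fits).
#' @param seed RNG seed for the conditional sampling.
#' @return list with \code{draws} (named list of draws x n matrices for
#'   each component and \code{g}) and \code{means} (named list of
#'   posterior-mean vectors).
#' @export
predictValues <- function(fit, conditionalDraws = fit@method == "bayes",
                          seed = 1L) {
    stopifnot(is(fit, "FitResult"))
    set.seed(seed)
    fk <- fitKernel(fit)
    cs <- fk$cs
    comps <- names(fit@data@matrices)
    n <- cs$n
    nd <- nrow(fit@draws)
    out <- lapply(c(comps, "g"), function(c.)
        matrix(0, nd, n, dimnames = list(NULL, levels(fit@data@individual))))
    names(out) <- c(comps, "g")
    for (it in seq_len(nd)) {
        dr <- fit@draws[it, ]
        vg <- dr[paste0("sigma2_", comps)]
        s2e <- dr[["sigma2_e"]]
        active <- comps[vg > 0]
        Sm <- diag(s2e / cs$r, n)
        for (c. in comps)
            Sm <- Sm + dr[[paste0("sigma2_", c.)]] * fk$mats[[c.]]
        U <- chol(Sm)
        u <- chol2inv(U) %*% (cs$ybar - dr[["mu"]])
        if (length(active)) {
            B <- do.call(rbind, lapply(active, function(c.)
                dr[[paste0("sigma2_", c.)]] * fk$mats[[c.]]))
            cm <- drop(B %*% u)
            if (conditionalDraws) {
                # joint conditional covariance of the active components
                V <- matrix(0, n * length(active), n * length(active))
                for (k in seq_along(active)) {
                    i <- (k - 1) * n + seq_len(n)
                    V[i, i] <- dr[[paste0("sigma2_", active[k])]] *
                        fk$mats[[active[k]]]
                }
                SinvBt <- chol2inv(U) %*% t(B)
                V <- symmetrize(V - B %*% SinvBt)
                ev <- eigen(V, symmetric = TRUE)
                lam <- pmax(ev$values, 0)
                z <- ev$vectors %*% (sqrt(lam) * rnorm(length(lam)))
                cm <- cm + drop(z)
            }
            for (k in seq_along(active))
                out[[active[k]]][it, ] <- cm[(k - 1) * n + seq_len(n)]
        }
        out$g[it, ] <- Reduce(`+`, lapply(comps, function(c.) out[[c.]][it, ]))
    }
    list(draws = out, means = lapply(out, colMeans))
}

#' Posterior-predictive phenotypes for (held-out) individuals
#'
#' For each posterior draw: the conditional genetic value of the requested
#' individuals given the fitted phenotypes (through the cross-covariance
#' rows of the relationship matrices), plus the intercept, plus fresh
#' environmental noise with that draw's variance. Point predictions are
#' the posterior means of intercept + genetic value and are unaffected by
#' the zero-mean noise.
#'
#' @param fit a \code{\link{FitResult}}.
#' @param ids individuals to predict; must be present in \code{matrices}.
#' @param matrices named list of \code{\link{RelationshipMatrix}} objects
#'   covering both the fitted and the requested individuals, on the same
#'   scaling as the matrices used for fitting (default: the fit's own
#'   matrices, i.e. in-sample prediction).
#' @param addNoise include the environmental noise term in the draws.
#' @param seed RNG seed.
#' @return list with \code{ids}, \code{yDraws} (draws x length(ids)
#'   posterior-predictive phenotypes), \code{gDraws} (conditional genetic
#'   values) and \code{pointPred} (posterior-mean predictions).
#' @export
predictPhenotypes <- function(fit, ids, matrices = fit@data@matrices,
                              addNoise = TRUE, seed = 1L) {
    stopifnot(is(fit, "FitResult"))
    set.seed(seed)
    comps <- names(fit@data@matrices)
    if (!setequal(comps, names(matrices)))
        stop("prediction matrices must carry the fitted components")
    allIds <- rownames(relMatrix(matrices[[1]]))
    unknown <- setdiff(ids, allIds)
    if (length(unknown))
        stop("unknown individual(s): ",
             paste(utils::head(unknown, 5), collapse = ", "))
    trainIds <- levels(fit@data@individual)
    if (!all(trainIds %in% allIds))
        stop("prediction matrices must include the fitted individuals")
    cs <- collapseData(fit@data)
    n <- cs$n
    m <- length(ids)
    nd <- nrow(fit@draws)
    yDraws <- gDraws <- matrix(0, nd, m, dimnames = list(NULL, ids))
    pointAcc <- numeric(m)
    for (it in seq_len(nd)) {
        dr <- fit@draws[it, ]
        s2e <- dr[["sigma2_e"]]
        Sm <- diag(s2e / cs$r, n)
        C <- matrix(0, m, n)
        Vnew <- matrix(0, m, m)
        for (c. in comps) {
            K <- relMatrix(matrices[[c.]])
            v <- dr[[paste0("sigma2_", c.)]]
            Sm <- Sm + v * K[trainIds, trainIds]
            C <- C + v * K[ids, trainIds, drop = FALSE]
            Vnew <- Vnew + v * K[ids, ids, drop = FALSE]
        }
        U <- chol(Sm)
        Sinv <- chol2inv(U)
        condMean <- dr[["mu"]] + drop(C %*% (Sinv %*% (cs$ybar - dr[["mu"]])))
        condCov <- symmetrize(Vnew - C %*% Sinv %*% t(C))
        ev <- eigen(condCov, symmetric = TRUE)
        z <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(m))
        g <- condMean + drop(z)
        gDraws[it, ] <- g
        yDraws[it, ] <- g + if (addNoise) rnorm(m, 0, sqrt(s2e)) else 0
        pointAcc <- pointAcc + condMean
    }
    list(ids = ids, yDraws = yDraws, gDraws = gDraws,
         pointPred = setNames(pointAcc / nd, ids))
}

#' Subset a relationship matrix to a set of individuals
#'
#' Keeps the parent scaling (the subset of a typical-variance-1 matrix has
#' typical diagonal close to 1, and keeping the scale makes fitted
#' variances and cross-covariance rows directly comparable across
#' train/test partitions).
#'
#' @param K a \code{\link{RelationshipMatrix}}.
#' @param ids individuals to keep.
#' @return A \code{\link{RelationshipMatrix}}.
#' @export
subsetRelationship <- function(K, ids) {
    M <- relMatrix(K)[ids, ids, drop = FALSE]
    new("RelationshipMatrix", matrix = M,
        scalingConstant = scalingConstant(K), kind = K@kind)
}
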