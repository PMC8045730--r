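#' PC prior on a standard deviation
#'
#' Constructs the penalized-complexity prior for the standard deviation of
#' a zero-mean random effect: an exponential distribution on sigma with
#' rate \code{-log(alpha) / V}, so that \code{P(sigma > V) = alpha}. The
#' prior shrinks toward sigma = 0, i.e. toward a model without the effect.
#'
#' @param V upper value (positive, response standard-deviation units).
#' @param alpha upper-tail probability in (0, 1); 0.25 gives a weakly
#'   informative prior toward V, 0.01 the no-EK default of the PC-prior
#'   literature (with V = 0.968).
#' @return A \code{\link{PCPriorSD}}.
#' @examples
#' pr <- pcSD(0.968, 0.01)
#' 1 - pPCSD(0.968, pr)  # 0.01
#' @export
pcSD <- function(V, alpha) {
    if (!is.numeric(V) || length(V) != 1L || V <= 0)
        stop("upper value V must be a positive scalar")
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("tail probability alpha must be in (0, 1)")
    new("PCPriorSD", upperValue = V, tailProb = alpha, rate = -log(alpha) / V)
}

#' @describeIn pcSD prior density at sigma = x
#' @param x,q,p,n usual distribution-function arguments.
#' @param prior a \code{\link{PCPriorSD}}.
#' @export
dPCSD <- function(x, prior) stats::dexp(x, rate = prior@rate)

#' @describeIn pcSD cumulative distribution function
#' @export
pPCSD <- function(q, prior) stats::pexp(q, rate = prior@rate)

#' @describeIn pcSD quantile function
#' @export
qPCSD <- function(p, prior) stats::qexp(p, rate = prior@rate)

#' @describeIn pcSD random sampling
#' @export
rPCSD <- function(n, prior) stats::rexp(n, rate = prior@rate)

setMethod("show", "PCPriorSD", function(object) {
    cat(sprintf("PCPriorSD: P(sigma > %.4g) = %.3g  (exponential rate %.4g)\n",
                object@upperValue, object@tailProb, object@rate))
})

#' Component-wise PC prior set from expert knowledge
#'
#' Builds independent PC priors on the standard deviations of every model
#' component. Upper values follow the variance-decomposition tree downward:
#' \code{V(sigma_e) = (1 - hg2) VP}, \code{V(sigma_a) = ha2 VP},
#' \code{V(sigma_d) = hd2 VP}, \code{V(sigma_x) = (hg2 - ha2 - hd2) VP},
#' where \code{hg2 = RGge}, \code{ha2 = hg2 RAg} and
#' \code{hd2 = hg2 (1 - RAg) RDdx}. Only the components present in the
#' chosen model are returned.
#'
#' @param ek an \code{\link{EKSpec}}.
#' @param VP phenotypic variance elicited from a comparable dataset.
#' @param alpha tail probability for every component (default 0.25).
#' @param model \code{"A"}, \code{"AD"} or \code{"ADX"}.
#' @return A \code{\link{ComponentPriorSet}}.
#' @examples
#' componentwisePriors(ekSpec(0.25, model = "A"), VP = 1.86, model = "A")
#' @export
componentwisePriors <- function(ek, VP, alpha = 0.25,
                                model = c("A", "AD", "ADX")) {
    model <- match.arg(model)
    stopifnot(is(ek, "EKSpec"), VP > 0)
    hg2 <- ek@RGge
    ha2 <- hg2 * ek@RAg
    hd2 <- hg2 * (1 - ek@RAg) * ek@RDdx
    upper <- c(sigma_e = (1 - hg2) * VP, sigma_a = ha2 * VP)
    if (model %in% c("AD", "ADX")) upper["sigma_d"] <- hd2 * VP
    if (model == "ADX") upper["sigma_x"] <- (hg2 - ha2 - hd2) * VP
    bad <- names(upper)[upper <= 0]
    if (length(bad))
        stop("EK combination implies a non-positive upper value for: ",
             paste(bad, collapse = ", "),
             " (RGge = ", hg2, ", RAg = ", ek@RAg, ", RDdx = ", ek@RDdx, ")")
    new("ComponentPriorSet",
        priors = lapply(upper, pcSD, alpha = alpha),
        provenance = list(RGge = hg2, RAg = ek@RAg, RDdx = ek@RDdx, VP = VP,
                          alpha = alpha, model = model, style = "expert"))
}

#' Default component-wise PC prior set (no expert knowledge)
#'
#' The same PC prior \code{PC0(V, alpha)} on every standard deviation, with
#' the conventional no-EK default V = 0.968, alpha = 0.01.
#'
#' @inheritParams componentwisePriors
#' @param V common upper value.
#' @export
defaultComponentwisePriors <- function(model = c("A", "AD", "ADX"),
                                       V = 0.968, alpha = 0.01) {
    model <- match.arg(model)
    comps <- switch(model,
        A = c("sigma_e", "sigma_a"),
        AD = c("sigma_e", "sigma_a", "sigma_d"),
        ADX = c("sigma_e", "sigma_a", "sigma_d", "sigma_x"))
    new("ComponentPriorSet",
        priors = setNames(lapply(comps, function(nm) pcSD(V, alpha)), comps),
        provenance = list(V = V, alpha = alpha, model = model,
                          style = "default"))
}

setMethod("show", "ComponentPriorSet", function(object) {
    cat(sprintf("ComponentPriorSet (%s, model %s):\n",
                object@provenance$style, object@provenance$model))
    for (nm in names(object@priors)) {
        pr <- object@priors[[nm]]
        cat(sprintf("  %s ~ PC0(%.4g, %.3g)\n", nm, pr@upperValue,
                    pr@tailProb))
    }
})

# Generalized eigenvalues of C1 relative to C0 (both symmetric, C0 made
# strictly PD with jitter 1e-8 * typical diagonal to absorb the rank
# deficiency of genomic cross-products).
generalizedEigen <- function(C1, C0) {
    if (!all(dim(C1) == dim(C0)))
        stop("dimension mismatch between the two covariance structures")
    C0j <- C0 + diag(1e-8 * scaleConstant(C0), nrow(C0))
    U <- chol(C0j)
    Uinv <- backsolve(U, diag(nrow(U)))
    B <- symmetrize(t(Uinv) %*% C1 %*% Uinv)
    # clamp tiny negative roundoff: the pencil of two PSD matrices has
    # nonnegative generalized eigenvalues
    pmax(eigen(B, symmetric = TRUE, only.values = TRUE)$values, 0)
}

# distance table for the base at p = 0; valid on [0, 1] (d may be +Inf at
# p = 1 when C1 is rank deficient, which simply truncates the density)
pc0DistTable <- function(lam, p) {
    dl <- lam - 1
    d2 <- vapply(p, function(pp) sum(pp * dl - log1p(pp * dl)), numeric(1))
    d <- sqrt(pmax(d2, 0))
    dprime <- vapply(seq_along(p), function(i) {
        s <- sum(dl^2 * p[i] / (1 + p[i] * dl))
        if (is.finite(d[i]) && d[i] > 0) s / (2 * d[i])
        else if (d[i] == 0) sqrt(sum(dl^2) / 2) else Inf
    }, numeric(1))
    data.frame(p = p, d = d, dprime = dprime)
}

# distance table for the base at p = R (same eigenbasis, ratio form)
pcmDistTable <- function(lam, p, R) {
    dl <- lam - 1
    muR <- 1 + R * dl
    d2 <- vapply(p, function(pp) {
        r <- (1 + pp * dl) / muR
        sum(r - 1 - log(r))
    }, numeric(1))
    d <- sqrt(pmax(d2, 0))
    dprime <- vapply(seq_along(p), function(i) {
        s <- sum(dl / muR - dl / (1 + p[i] * dl))
        if (is.finite(d[i]) && d[i] > 0) s / (2 * d[i])
        else if (d[i] == 0) sign(p[i] - R) * sqrt(sum((dl / muR)^2) / 2)
        else Inf
    }, numeric(1))
    data.frame(p = p, d = d, dprime = dprime)
}

#' Kullback-Leibler distance curve between two covariance structures
#'
#' For the one-parameter family \code{Sigma(p) = p C1 + (1 - p) C0}, the
#' PC-prior distance from the base model \code{C0} is
#' \code{d(p) = sqrt(2 KL(N(0, Sigma(p)) || N(0, C0)))
#'      = sqrt(sum_i [p (lambda_i - 1) - log(1 + p (lambda_i - 1))])},
#' with \code{lambda_i} the generalized eigenvalues of \code{C1} relative
#' to \code{C0}. \code{d} is zero at p = 0 and non-decreasing in p.
#'
#' @param C1,C0 \code{\link{RelationshipMatrix}} objects (or plain
#'   symmetric matrices) of equal dimension, both scaled.
#' @param grid evaluation points strictly inside (0, 1).
#' @return data.frame with columns \code{p}, \code{d} and \code{dprime}
#'   (the analytic derivative of d).
#' @export
distanceCurve <- function(C1, C0, grid = defaultGrid()) {
    if (is(C1, "RelationshipMatrix")) C1 <- relMatrix(C1)
    if (is(C0, "RelationshipMatrix")) C0 <- relMatrix(C0)
    stopifnot(all(grid > 0), all(grid < 1))
    lam <- generalizedEigen(C1, C0)
    out <- pc0DistTable(lam, grid)
    if (any(!is.finite(out$d)))
        stop("1 + p (lambda - 1) <= 0: covariance family is degenerate")
    out
}

# The PC-prior density is exponential in the tabulated distance d(p), so
# with d piecewise linear the per-cell integrals of exp(-theta (d - dmin))
# |d'| have closed form |E_i - E_{i+1}| / theta. Using these exact cell
# masses for calibration and for recomputing summaries makes the
# calibrated concentration essentially independent of grid resolution.
# reference distance keeping exp(-theta (d - dref)) bounded by 1
drefOf <- function(d, theta) {
    df <- d[is.finite(d)]
    if (theta >= 0) min(df) else max(df)
}

expCellMasses <- function(d, theta) {
    E <- exp(-theta * (d - drefOf(d, theta)))
    abs(E[-length(E)] - E[-1]) / abs(theta)
}

# per-cell scale factors renormalizing each side of a PCM base at R to
# mass 1/2 (R is a node of the table); 1 for one-sided (PC0) tables
pcmCellScale <- function(p, d, theta, R) {
    cm <- expCellMasses(d, theta)
    left <- p[-1] <= R + 1e-12
    sL <- sum(cm[left])
    sR <- sum(cm[!left])
    if (sL <= 0 || sR <= 0)
        stop("degenerate split: one side of the base model carries no mass")
    ifelse(left, 0.5 / sL, 0.5 / sR)
}

expMass <- function(p, d, theta, lo, hi, scale = 1) {
    dref <- drefOf(d, theta)
    cm <- expCellMasses(d, theta) * scale
    scale <- rep_len(scale, length(cm))
    K <- length(p)
    cum <- c(0, cumsum(cm))
    at <- function(x) {
        x <- min(max(x, p[1]), p[K])
        i <- findInterval(x, p, all.inside = TRUE)
        frac <- (x - p[i]) / (p[i + 1] - p[i])
        dx <- d[i] + frac * (d[i + 1] - d[i])   # d linear within the cell
        if (!is.finite(dx)) return(cum[i] + frac * cm[i])
        cum[i] + scale[i] * abs(exp(-theta * (d[i] - dref)) -
                                exp(-theta * (dx - dref))) / abs(theta)
    }
    (at(hi) - at(lo)) / cum[length(cum)]
}

expQuantile <- function(p, d, theta, q, scale = 1) {
    dref <- drefOf(d, theta)
    cm <- expCellMasses(d, theta) * scale
    scale <- rep_len(scale, length(cm))
    cum <- c(0, cumsum(cm))
    target <- q * cum[length(cum)]
    i <- min(max(findInterval(target, cum, all.inside = TRUE), 1L),
             length(cm))
    if (cm[i] <= 0 || !is.finite(d[i + 1]) || d[i + 1] == d[i])
        return(p[i] + 0.5 * (p[i + 1] - p[i]))
    Ei <- exp(-theta * (d[i] - dref))
    Ex <- Ei - sign(d[i + 1] - d[i]) * sign(theta) * abs(theta) *
        (target - cum[i]) / scale[i]
    dx <- dref - log(Ex) / theta
    frac <- (dx - d[i]) / (d[i + 1] - d[i])
    p[i] + min(max(frac, 0), 1) * (p[i + 1] - p[i])
}

# numerical median of a grid density
gridMedian <- function(grid, dens) {
    cdf <- cumtrapint(grid, dens)
    cdf <- cdf / cdf[length(cdf)]
    stats::approx(cdf, grid, xout = 0.5, ties = "ordered")$y
}

# mass of a grid density inside [lo, hi] (trapezoid, interval ends
# interpolated)
gridMass <- function(grid, dens, lo, hi) {
    cdf <- cumtrapint(grid, dens)
    tot <- cdf[length(cdf)]
    at <- function(x) {
        if (x <= grid[1]) return(0)
        if (x >= grid[length(grid)]) return(tot)
        stats::approx(grid, cdf, xout = x)$y
    }
    (at(hi) - at(lo)) / tot
}

# bisection in log|theta|; f must be monotone increasing in theta. The
# usual solution has theta > 0 (shrinkage toward the base); when the
# target lies beyond the flat-penalty limit the sign is flipped and the
# same exponential family is continued through negative rates.
calibrateTheta <- function(f, lower = 1e-6, upper = 1e6, tol = 1e-10) {
    flo <- f(lower)
    fhi <- f(upper)
    if (is.na(flo) || is.na(fhi))
        stop("root-finding failure: calibration functional is undefined ",
             "on the theta bracket")
    if (flo * fhi <= 0) {
        r <- uniroot(function(lt) f(exp(lt)), lower = log(lower),
                     upper = log(upper), tol = tol)
        return(exp(r$root))
    }
    fneg <- f(-upper)
    if (is.na(fneg) || flo * fneg > 0)
        stop(sprintf(paste("root-finding failure: calibration functional has",
                           "values %.4g and %.4g at theta bracket [%g, %g]"),
                     fneg, fhi, -upper, upper))
    r <- uniroot(function(lt) f(-exp(lt)), lower = log(lower),
                 upper = log(upper), tol = tol)
    -exp(r$root)
}

#' PC prior on a variance proportion shrinking toward zero
#'
#' Constructs \code{p ~ PC0(R)}: the PC prior on the proportion p of the
#' structured component \code{C1} within \code{p C1 + (1 - p) C0}, with
#' base model p = 0 (only \code{C0}) and exponential penalty on the
#' KL-based distance \code{d(p)}. The rate theta is calibrated by
#' root-finding so that the prior median equals R, i.e.
#' \code{P(p > R) = 0.5}.
#'
#' @inheritParams distanceCurve
#' @param R prior median in (0, 1).
#' @return A \code{\link{ProportionPrior}} of style \code{"PC0"}.
#' @export
pc0Proportion <- function(C1, C0, R, grid = defaultGrid()) {
    stopifnot(R > 0, R < 1)
    if (is(C1, "RelationshipMatrix")) C1 <- relMatrix(C1)
    if (is(C0, "RelationshipMatrix")) C0 <- relMatrix(C0)
    lam <- generalizedEigen(C1, C0)
    dc <- pc0DistTable(lam, c(0, grid, 1))   # true support endpoints
    if (max(dc$d[is.finite(dc$d)]) < 1e-6)
        stop("degenerate split: the two covariance structures are identical")
    f <- function(theta) expMass(dc$p, dc$d, theta, 0, R) - 0.5
    theta <- calibrateTheta(f)
    inner <- dc[-c(1, nrow(dc)), ]
    dens <- exp(-theta * (inner$d - drefOf(inner$d, theta))) * inner$dprime
    dens <- dens / trapint(grid, dens)
    new("ProportionPrior", grid = grid, logDensity = log(dens),
        style = "PC0", medianTarget = R, concentrationMass = NA_real_,
        distanceCurve = dc[c("p", "d")], theta = theta)
}

#' PC prior on a variance proportion shrinking toward its median
#'
#' Constructs \code{p ~ PCM(R)}: the base model is p = R, the distance is
#' measured from R within the family \code{p C1 + (1 - p) C0}, and a single
#' exponential rate penalizes the distance on both sides, each side
#' renormalized to mass one half so the prior median equals R exactly. The
#' rate is calibrated so that the prior mass inside
#' \code{[logit(R) - 1, logit(R) + 1]} on logit scale equals \code{mass}.
#'
#' @inheritParams pc0Proportion
#' @param mass probability allocated to the logit interval (default 0.75).
#' @return A \code{\link{ProportionPrior}} of style \code{"PCM"}.
#' @export
pcmProportion <- function(C1, C0, R, mass = 0.75, grid = defaultGrid()) {
    stopifnot(R > 0, R < 1, mass > 0, mass < 1)
    if (is(C1, "RelationshipMatrix")) C1 <- relMatrix(C1)
    if (is(C0, "RelationshipMatrix")) C0 <- relMatrix(C0)
    lam <- generalizedEigen(C1, C0)
    # R is a node of the table so the V-shaped kink of d at the base model
    # falls on a cell boundary (keeps the cell masses exact)
    dc <- pcmDistTable(lam, sort(unique(c(0, grid, R, 1))), R)
    if (max(dc$d[is.finite(dc$d)]) < 1e-6)
        stop("degenerate split: the two covariance structures are identical")
    lo <- invlogit(logit(R) - 1)
    hi <- invlogit(logit(R) + 1)
    f <- function(theta)
        expMass(dc$p, dc$d, theta, lo, hi,
                scale = pcmCellScale(dc$p, dc$d, theta, R)) - mass
    theta <- calibrateTheta(f)
    inner <- pcmDistTable(lam, grid, R)
    sideScale <- pcmCellScale(dc$p, dc$d, theta, R)
    w <- ifelse(grid <= R, sideScale[1], sideScale[length(sideScale)])
    dens <- w * exp(-theta * (inner$d - drefOf(inner$d, theta))) *
        abs(inner$dprime)
    dens <- dens / trapint(grid, dens)
    new("ProportionPrior", grid = grid, logDensity = log(dens),
        style = "PCM", medianTarget = R, concentrationMass = mass,
        distanceCurve = dc[c("p", "d")], theta = theta)
}

# Beta(a, b) tabulated as a ProportionPrior (flat-Dirichlet marginals and
# the aggregated split priors of the default tree).
betaProportionPrior <- function(a, b, grid = defaultGrid()) {
    dens <- stats::dbeta(grid, a, b)
    dens <- dens / trapint(grid, dens)
    new("ProportionPrior", grid = grid, logDensity = log(dens),
        style = "dirichlet_marginal", medianTarget = NA_real_,
        concentrationMass = NA_real_,
        distanceCurve = data.frame(p = numeric(0), d = numeric(0)),
        theta = NA_real_)
}

#' Marginals of the flat Dirichlet prior over variance shares
#'
#' The no-EK default of the tree-based prior puts a symmetric flat
#' Dirichlet (concentration 1 per component) on the k leaf shares of
#' phenotypic variance. Each share then has marginal Beta(1, k - 1); for
#' k = 2 this is the uniform prior on (0, 1).
#'
#' @param k number of model components (leaves), k >= 2.
#' @param grid tabulation grid.
#' @return list of k \code{\link{ProportionPrior}} objects (the identical
#'   Beta(1, k - 1) marginals).
#' @seealso \code{\link{buildHDPrior}} with \code{style = "default"}, which
#'   uses the aggregated split priors implied by the same Dirichlet.
#' @export
dirichletMarginals <- function(k, grid = defaultGrid()) {
    if (k < 2) stop("k must be at least 2")
    replicate(k, betaProportionPrior(1, k - 1, grid), simplify = FALSE)
}

#' Evaluate, summarize and export proportion priors
#'
#' \code{priorLogDensity} interpolates the stored log density linearly
#' between grid points; beyond the outermost grid points (the prior's
#' support is all of (0, 1)) the edge slope is extended, and outside
#' \code{[0, 1]} the value is \code{-Inf}. \code{priorMedian} and
#' \code{priorMass} recompute summaries by numerical integration of the
#' tabulated prior; \code{writePrior} serializes the tabulated density.
#'
#' @param prior a \code{\link{ProportionPrior}}.
#' @param p evaluation points.
#' @return \code{priorLogDensity}: log density values; \code{priorMedian}:
#'   the numerical median; \code{priorMass}: the mass in \code{[lo, hi]}.
#' @export
priorLogDensity <- function(prior, p) {
    g <- prior@grid
    ld <- prior@logDensity
    K <- length(g)
    out <- rep(-Inf, length(p))
    inside <- p > 0 & p < 1
    if (any(inside)) {
        i <- findInterval(p[inside], g, all.inside = TRUE)
        slope <- (ld[i + 1] - ld[i]) / (g[i + 1] - g[i])
        out[inside] <- ld[i] + slope * (p[inside] - g[i])
    }
    out
}

#' @rdname priorLogDensity
#' @export
priorMedian <- function(prior) {
    if (prior@style %in% c("PC0", "PCM") && nrow(prior@distanceCurve)) {
        dc <- prior@distanceCurve
        s <- if (prior@style == "PCM")
            pcmCellScale(dc$p, dc$d, prior@theta, prior@medianTarget) else 1
        expQuantile(dc$p, dc$d, prior@theta, 0.5, scale = s)
    } else gridMedian(prior@grid, exp(prior@logDensity))
}

#' @rdname priorLogDensity
#' @param lo,hi interval bounds.
#' @export
priorMass <- function(prior, lo, hi) {
    if (prior@style %in% c("PC0", "PCM") && nrow(prior@distanceCurve)) {
        dc <- prior@distanceCurve
        s <- if (prior@style == "PCM")
            pcmCellScale(dc$p, dc$d, prior@theta, prior@medianTarget) else 1
        expMass(dc$p, dc$d, prior@theta, lo, hi, scale = s)
    } else gridMass(prior@grid, exp(prior@logDensity), lo, hi)
}

#' @rdname priorLogDensity
#' @param file output path (tab-delimited columns \code{p},
#'   \code{density}).
#' @export
writePrior <- function(prior, file) {
    utils::write.table(
        data.frame(p = prior@grid, density = exp(prior@logDensity)),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
}

setMethod("show", "ProportionPrior", function(object) {
    cat(sprintf("ProportionPrior (%s): %d grid points", object@style,
                length(object@grid)))
    if (!is.na(object@medianTarget))
        cat(sprintf(", median target %.3g", object@medianTarget))
    if (!is.na(object@concentrationMass))
        cat(sprintf(", logit-interval mass %.3g", object@concentrationMass))
    cat("\n")
})

#' @describeIn priorLogDensity density plot of a proportion prior
#' @param y ignored.
#' @param ... passed to \code{plot.default}.
#' @export
setMethod("plot", signature(x = "ProportionPrior", y = "missing"),
    function(x, y, ...) {
        graphics::plot(x@grid, exp(x@logDensity), type = "l",
                       xlab = "variance proportion p", ylab = "prior density",
                       main = sprintf("%s prior", x@style), ...)
        if (!is.na(x@medianTarget))
            graphics::abline(v = x@medianTarget, lty = 2, col = "grey40")
        invisible(NULL)
    })
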