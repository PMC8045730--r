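# Hamiltonian Monte Carlo with dual-averaging step-size adaptation,
# diagonal mass-matrix estimation and an energy-error divergence
# diagnostic. The sampler works on an unconstrained parameterization
# supplied by the caller (log / logit coordinates), so the posterior
# support is all of R^d and divergences signal genuine geometry problems.

# Stan-like heuristic for a reasonable initial step size
findInitStep <- function(fn, q, mass, eps = 0.1) {
    d <- length(q)
    f0 <- fn(q)
    onestep <- function(eps) {
        p0 <- rnorm(d, 0, sqrt(mass))
        H0 <- -f0$value + sum(p0^2 / (2 * mass))
        p <- p0 + 0.5 * eps * f0$grad
        qn <- q + eps * p / mass
        f1 <- fn(qn)
        if (any(!is.finite(f1$grad)) || !is.finite(f1$value)) return(-Inf)
        p <- p + 0.5 * eps * f1$grad
        -(-f1$value + sum(p^2 / (2 * mass)) - H0)
    }
    a <- onestep(eps)
    dir <- if (is.finite(a) && a > log(0.5)) 1 else -1
    for (i in 1:50) {
        eps2 <- eps * 2^dir
        a <- onestep(eps2)
        ok <- is.finite(a) && a > log(0.5)
        if ((dir == 1 && !ok) || (dir == -1 && ok)) break
        eps <- eps2
    }
    eps
}

#' Hamiltonian Monte Carlo sampler
#'
#' Samples an unnormalized log density on an unconstrained space with
#' leapfrog dynamics, jittered trajectory lengths, dual-averaging step-size
#' adaptation toward a target acceptance rate, diagonal mass-matrix
#' estimation from the middle of warmup, and a divergence diagnostic: a
#' transition whose Hamiltonian error exceeds \code{divergenceThreshold}
#' at any point along the trajectory (or becomes non-finite) is flagged
#' divergent and rejected.
#'
#' @param fn function(q) returning \code{list(value = , grad = )}, the log
#'   density (may be \code{-Inf}) and its gradient.
#' @param init initial position.
#' @param warmup,draws iteration counts (divergences are counted over the
#'   post-warmup draws).
#' @param maxLeapfrog trajectory lengths are drawn uniformly from
#'   1..\code{maxLeapfrog} each iteration.
#' @param adaptTarget dual-averaging acceptance-rate target.
#' @param divergenceThreshold energy-error threshold.
#' @return list with \code{samples} (draws x d matrix), \code{divergent}
#'   count, \code{acceptRate}, \code{stepSize} and \code{massDiag}.
#' @export
hmcSample <- function(fn, init, warmup = 1000L, draws = 1000L,
                      maxLeapfrog = 32L, adaptTarget = 0.8,
                      divergenceThreshold = 1000) {
    d <- length(init)
    q <- init
    f <- fn(q)
    if (!is.finite(f$value))
        stop("initial point has non-finite log posterior")

    mass <- rep(1, d)

    transition <- function(q, fq, eps, mass) {
        L <- sample.int(maxLeapfrog, 1L)
        p0 <- rnorm(d, 0, sqrt(mass))
        H0 <- -fq$value + sum(p0^2 / (2 * mass))
        p <- p0
        qn <- q
        fqn <- fq
        diverged <- FALSE
        astat <- 0   # along-trajectory acceptance statistic (for adaptation)
        p <- p + 0.5 * eps * fqn$grad
        for (l in seq_len(L)) {
            qn <- qn + eps * p / mass
            fqn <- fn(qn)
            if (!is.finite(fqn$value) || any(!is.finite(fqn$grad))) {
                diverged <- TRUE
                break
            }
            p <- p + (if (l < L) eps else 0.5 * eps) * fqn$grad
            # energy error checked at every leapfrog step, as in the
            # Hamiltonian divergence diagnostic
            Hl <- -fqn$value + sum(p^2 / (2 * mass))
            if (Hl - H0 > divergenceThreshold) {
                diverged <- TRUE
                break
            }
            astat <- astat + min(1, exp(-(Hl - H0)))
        }
        dH <- if (diverged) Inf else
            (-fqn$value + sum(p^2 / (2 * mass))) - H0
        alpha <- if (!is.finite(dH)) 0 else min(1, exp(-dH))
        astat <- astat / L
        if (!diverged && runif(1) < alpha)
            list(q = qn, fq = fqn, alpha = alpha, astat = astat,
                 diverged = diverged)
        else list(q = q, fq = fq, alpha = alpha, astat = astat,
                  diverged = diverged)
    }

    adaptPhase <- function(q, fq, niter, mass, eps0 = NULL,
                           keepFrom = NULL) {
        if (is.null(eps0)) eps0 <- findInitStep(fn, q, mass)
        muDA <- log(10 * eps0)
        Hbar <- 0; logEpsBar <- 0; eps <- eps0
        gamma <- 0.05; t0 <- 10; kappa <- 0.75
        kept <- if (!is.null(keepFrom))
            matrix(NA_real_, niter - keepFrom + 1L, d) else NULL
        for (t in seq_len(niter)) {
            tr <- transition(q, fq, eps, mass)
            q <- tr$q; fq <- tr$fq
            Hbar <- (1 - 1 / (t + t0)) * Hbar +
                (adaptTarget - tr$astat) / (t + t0)
            logEps <- muDA - sqrt(t) / gamma * Hbar
            logEpsBar <- t^(-kappa) * logEps + (1 - t^(-kappa)) * logEpsBar
            eps <- exp(logEps)
            if (!is.null(kept) && t >= keepFrom)
                kept[t - keepFrom + 1L, ] <- q
        }
        list(q = q, fq = fq, eps = exp(logEpsBar), kept = kept)
    }

    # warmup: step-size adaptation, mass estimation, re-adaptation
    w1 <- max(20L, floor(warmup * 0.6))
    w2 <- max(10L, warmup - w1)
    ph1 <- adaptPhase(q, f, w1, mass, keepFrom = max(2L, floor(w1 / 2)))
    v <- apply(ph1$kept, 2, var)
    v <- 0.8 * v + 0.2        # regularize toward unit scale
    massNew <- 1 / pmax(v, 1e-6)
    # re-anchor the step size for the new metric
    eps1 <- ph1$eps * exp(mean(0.5 * (log(mass) - log(massNew))))
    mass <- massNew
    ph2 <- adaptPhase(ph1$q, ph1$fq, w2, mass, eps0 = eps1)
    q <- ph2$q; f <- ph2$fq; eps <- ph2$eps

    samples <- matrix(NA_real_, draws, d)
    ndiv <- 0L
    acc <- 0
    for (t in seq_len(draws)) {
        tr <- transition(q, f, eps, mass)
        q <- tr$q; f <- tr$fq
        if (tr$diverged) ndiv <- ndiv + 1L
        acc <- acc + tr$alpha
        samples[t, ] <- q
    }
    colnames(samples) <- names(init)
    list(samples = samples, divergent = ndiv, acceptRate = acc / draws,
         stepSize = eps, massDiag = mass)
}

# component variances and their partial derivatives under the tree
# parameterization (V = sigmaP2, p = split proportions). Returns vars
# (named, in e/a/d/x order for the model) and the matrix of d vars / d p.
varsAndPartials <- function(V, p, model) {
    pg <- p[["p_g"]]
    if (model == "A") {
        vars <- c(sigma2_e = V * (1 - pg), sigma2_a = V * pg)
        P <- matrix(c(-V, V), ncol = 1,
                    dimnames = list(names(vars), "p_g"))
        return(list(vars = vars, P = P))
    }
    pa <- p[["p_a"]]
    if (model == "AD") {
        vars <- c(sigma2_e = V * (1 - pg), sigma2_a = V * pg * pa,
                  sigma2_d = V * pg * (1 - pa))
        P <- cbind(p_g = c(-V, V * pa, V * (1 - pa)),
                   p_a = c(0, V * pg, -V * pg))
        rownames(P) <- names(vars)
        return(list(vars = vars, P = P))
    }
    pd <- p[["p_d"]]
    vars <- c(sigma2_e = V * (1 - pg), sigma2_a = V * pg * pa,
              sigma2_d = V * pg * (1 - pa) * pd,
              sigma2_x = V * pg * (1 - pa) * (1 - pd))
    P <- cbind(p_g = c(-V, V * pa, V * (1 - pa) * pd,
                       V * (1 - pa) * (1 - pd)),
               p_a = c(0, V * pg, -V * pg * pd, -V * pg * (1 - pd)),
               p_d = c(0, 0, V * pg * (1 - pa), -V * pg * (1 - pa)))
    rownames(P) <- names(vars)
    list(vars = vars, P = P)
}

# slope of the linearly interpolated log density of a ProportionPrior
interpLogDensSlope <- function(prior, p) {
    g <- prior@grid
    i <- findInterval(p, g, all.inside = TRUE)
    (prior@logDensity[i + 1] - prior@logDensity[i]) / (g[i + 1] - g[i])
}

#' Bayesian fit of the genomic mixed model
#'
#' Samples the posterior with \code{\link{hmcSample}}. Under an
#' \code{\link{HDJointPrior}} the sampled parameterization is
#' \code{(mu, log sigmaP2, logit proportions)} — the Jeffreys prior is flat
#' in log sigmaP2 and the split densities carry explicit logit Jacobians.
#' Under a \code{\link{ComponentPriorSet}} it is
#' \code{(mu, log sigma_c)} per component. Genetic values are marginalized
#' out of the sampled posterior (collapsed likelihood) and recovered with
#' \code{\link{predictValues}}.
#'
#' @param data a \code{\link{GenomicData}}.
#' @param prior an \code{\link{HDJointPrior}} or
#'   \code{\link{ComponentPriorSet}} matching the data's components.
#' @param chains,warmup,draws sampler budget (totals are per chain).
#' @param seed RNG seed; chains use \code{seed}, \code{seed + 1}, ...
#' @param maxLeapfrog,adaptTarget,divergenceThreshold see
#'   \code{\link{hmcSample}}.
#' @param init optional named initial values on the sampling scale
#'   (defaults to zero, i.e. unit variances and balanced splits).
#' @return A \code{\link{FitResult}} with draws of the sampled coordinates
#'   and the derived component variances, total variance and proportions.
#' @export
fitBayes <- function(data, prior, chains = 4L, warmup = 1000L,
                     draws = 1000L, seed = 1L, maxLeapfrog = 32L,
                     adaptTarget = 0.8, divergenceThreshold = 1000,
                     init = NULL) {
    stopifnot(is(data, "GenomicData"))
    cs <- collapseData(data)
    model <- dataModel(data)
    comps <- names(data@matrices)

    if (is(prior, "HDJointPrior")) {
        if (prior@tree@model != model)
            stop("prior was built for model ", prior@tree@model,
                 " but the data carry model ", model)
        splitNames <- names(prior@splitPriors)
        qnames <- c("mu", "lV", paste0("z_", sub("p_", "", splitNames)))
        unpack <- function(q) {
            V <- unname(exp(q[2]))
            p <- invlogit(unname(q[-(1:2)]))
            names(p) <- splitNames
            list(mu = unname(q[1]), V = V, p = p)
        }
        bad <- list(value = -Inf, grad = rep(NaN, 2L + length(splitNames)))
        fn <- function(q) {
            u <- unpack(q)
            if (!is.finite(u$V) || any(u$p <= 0) || any(u$p >= 1))
                return(bad)
            vp <- varsAndPartials(u$V, u$p, model)
            lg <- llGradLogLikelihood(c(mu = u$mu, vp$vars), data, cs)
            if (is.null(lg) || !is.finite(lg$value) ||
                any(!is.finite(lg$grad))) return(bad)
            val <- lg$value + dnorm(u$mu, 0, sqrt(1000), log = TRUE)
            dvars <- lg$grad[-1][names(vp$vars)]
            grad <- numeric(length(q))
            grad[1] <- lg$grad[["mu"]] - u$mu / 1000
            grad[2] <- sum(dvars * vp$vars)  # d sigma2_c / d log V = sigma2_c
            for (k in seq_along(splitNames)) {
                nm <- splitNames[k]
                ps <- u$p[[nm]]
                val <- val + priorLogDensity(prior@splitPriors[[nm]], ps) +
                    log(ps * (1 - ps))
                dll_dp <- sum(dvars * vp$P[, nm])
                dpr_dp <- interpLogDensSlope(prior@splitPriors[[nm]], ps)
                grad[2 + k] <- (dll_dp + dpr_dp) * ps * (1 - ps) +
                    (1 - 2 * ps)
            }
            if (!is.finite(val)) return(bad)
            list(value = val, grad = grad)
        }
        init0 <- setNames(rep(0, length(qnames)), qnames)
        derive <- function(q) {
            u <- unpack(q)
            vars <- varsAndPartials(u$V, u$p, model)$vars
            c(mu = unname(u$mu), sigmaP2 = unname(u$V), u$p, vars)
        }
        priorLabel <- prior@styleLabel
    } else if (is(prior, "ComponentPriorSet")) {
        sdNames <- names(prior@priors)   # sigma_e, sigma_a, ...
        need <- paste0("sigma_", c("e", comps))
        if (!setequal(sdNames, need))
            stop("component prior set does not match the data's components")
        sdNames <- need
        qnames <- c("mu", paste0("t_", sub("sigma_", "", sdNames)))
        rates <- vapply(prior@priors[sdNames], function(p) p@rate,
                        numeric(1))
        unpack <- function(q) {
            vars <- exp(2 * q[-1])
            names(vars) <- nm2var(sdNames)
            list(mu = unname(q[1]), vars = vars, sds = exp(q[-1]))
        }
        bad <- list(value = -Inf, grad = rep(NaN, 1L + length(sdNames)))
        fn <- function(q) {
            u <- unpack(q)
            if (any(!is.finite(u$vars))) return(bad)
            lg <- llGradLogLikelihood(c(mu = u$mu, u$vars), data, cs)
            if (is.null(lg) || !is.finite(lg$value) ||
                any(!is.finite(lg$grad))) return(bad)
            val <- lg$value + dnorm(u$mu, 0, sqrt(1000), log = TRUE) +
                sum(log(rates) - rates * u$sds + log(u$sds))
            grad <- c(lg$grad[["mu"]] - u$mu / 1000,
                      lg$grad[names(u$vars)] * 2 * u$vars -
                          rates * u$sds + 1)
            if (!is.finite(val)) return(bad)
            list(value = val, grad = unname(grad))
        }
        init0 <- setNames(rep(0, length(qnames)), qnames)
        derive <- function(q) {
            u <- unpack(q)
            tc <- treeCoordinates(u$vars)
            c(mu = unname(u$mu), sigmaP2 = unname(tc$sigmaP2),
              tc$proportions, u$vars)
        }
        priorLabel <- paste0(model, "-comp",
                             if (prior@provenance$style == "expert") "*")
    } else stop("unsupported prior class: ", class(prior))

    if (!is.null(init)) init0[names(init)] <- init
    allDraws <- NULL
    ndiv <- 0L
    acc <- numeric(chains)
    for (ch in seq_len(chains)) {
        set.seed(seed + ch - 1L)
        res <- hmcSample(fn, init0, warmup = warmup, draws = draws,
                         maxLeapfrog = maxLeapfrog,
                         adaptTarget = adaptTarget,
                         divergenceThreshold = divergenceThreshold)
        ndiv <- ndiv + res$divergent
        acc[ch] <- res$acceptRate
        allDraws <- rbind(allDraws, res$samples)
    }
    der <- t(apply(allDraws, 1, derive))
    out <- cbind(allDraws, der[, setdiff(colnames(der), colnames(allDraws)),
                               drop = FALSE])
    new("FitResult", method = "bayes", model = model, draws = out,
        diagnostics = list(divergent = ndiv, nDraws = nrow(out),
                           acceptRate = mean(acc)),
        settings = list(seed = seed, chains = chains, warmup = warmup,
                        draws = draws, maxLeapfrog = maxLeapfrog,
                        adaptTarget = adaptTarget,
                        divergenceThreshold = divergenceThreshold,
                        prior = priorLabel),
        data = data)
}

#' Maximum-likelihood fit of the genomic mixed model
#'
#' Maximizes the marginal log-likelihood over the intercept and the
#' log-variances with the bounded quasi-Newton optimizer
#' (\code{optim(method = "L-BFGS-B")}), using analytic gradients. Default
#' box bounds on the natural-log-variance scale are -20 for the
#' environmental variance and -50 for the genetic variances; the default
#' initial value is 0 for the intercept and all log-variances. The fit is
#' flagged unstable when the optimizer does not converge or any estimate
#' sits on a bound.
#'
#' @param data a \code{\link{GenomicData}}.
#' @param init optional named initial values: \code{mu} and
#'   \code{log_sigma2_e}, \code{log_sigma2_a}, ... (e.g. posterior medians
#'   from a Bayesian fit).
#' @param lowerEnv,lowerGen,upper log-variance bounds; set
#'   \code{bounds = FALSE} to optimize unconstrained.
#' @param bounds apply the box bounds.
#' @return A \code{\link{FitResult}} (single-row draws matrix).
#' @export
fitML <- function(data, init = NULL, lowerEnv = -20, lowerGen = -50,
                  upper = 30, bounds = TRUE) {
    stopifnot(is(data, "GenomicData"))
    comps <- names(data@matrices)
    model <- dataModel(data)
    vnames <- paste0("sigma2_", c("e", comps))
    qnames <- c("mu", paste0("log_", vnames))
    par0 <- setNames(rep(0, length(qnames)), qnames)
    if (!is.null(init)) par0[names(init)] <- init
    tovars <- function(q) setNames(exp(q[-1]), vnames)
    nll <- function(q) {
        ll <- logLikelihood(c(mu = unname(q[1]), tovars(q)), data)
        if (!is.finite(ll)) return(1e10)
        -ll
    }
    ngr <- function(q) {
        vars <- tovars(q)
        gl <- tryCatch(gradLogLikelihood(c(mu = unname(q[1]), vars), data),
                       error = function(e) NULL)
        if (is.null(gl) || any(!is.finite(gl))) return(rep(0, length(q)))
        -c(gl[["mu"]], gl[vnames] * vars)
    }
    lo <- if (bounds) c(-Inf, lowerEnv, rep(lowerGen, length(comps))) else
        rep(-Inf, length(qnames))
    hi <- if (bounds) c(Inf, rep(upper, length(vnames))) else
        rep(Inf, length(qnames))
    opt <- optim(par0, nll, ngr, method = "L-BFGS-B", lower = lo,
                 upper = hi, control = list(maxit = 500L))
    vars <- tovars(opt$par)
    atBound <- bounds && any(abs(opt$par[-1] - lo[-1]) < 1e-6 |
                             abs(opt$par[-1] - hi[-1]) < 1e-6)
    tc <- treeCoordinates(vars)
    draw <- c(mu = unname(opt$par[1]), sigmaP2 = unname(tc$sigmaP2),
              tc$proportions, vars)
    new("FitResult", method = "ml", model = model,
        draws = matrix(draw, nrow = 1, dimnames = list(NULL, names(draw))),
        diagnostics = list(converged = opt$convergence == 0,
                           atBound = atBound, message = opt$message,
                           logLik = -opt$value),
        settings = list(init = par0, bounds = bounds, lowerEnv = lowerEnv,
                        lowerGen = lowerGen, upper = upper),
        data = data)
}

#' Stability of a model fit
#'
#' Bayesian fits are stable when fewer than 1 percent of the post-warmup
#' draws had divergent transitions; ML fits when the optimizer converged
#' and no variance estimate sits on a bound.
#'
#' @param fit a \code{\link{FitResult}}.
#' @return logical.
#' @export
stability <- function(fit) {
    stopifnot(is(fit, "FitResult"))
    if (fit@method == "bayes")
        fit@diagnostics$divergent / fit@diagnostics$nDraws < 0.01
    else
        isTRUE(fit@diagnostics$converged) && !isTRUE(fit@diagnostics$atBound)
}

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult (%s, model %s): %d draw(s)\n", object@method,
                object@model, nrow(object@draws)))
    if (object@method == "bayes")
        cat(sprintf("  divergent transitions: %d / %d (stable: %s)\n",
                    object@diagnostics$divergent, object@diagnostics$nDraws,
                    stability(object)))
    else
        cat(sprintf("  converged: %s, at bound: %s\n",
                    object@diagnostics$converged, object@diagnostics$atBound))
    m <- colMeans(object@draws)
    keep <- grep("^(mu|sigma2_|sigmaP2|p_)", names(m), value = TRUE)
    cat("  posterior means:",
        paste(sprintf("%s = %.3g", keep, m[keep]), collapse = ", "), "\n")
})
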