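#' Continuous ranked probability score of an empirical predictive sample
#'
#' Empirical-sample CRPS: \code{mean|X - y| - mean|X - X'| / 2}, with the
#' second mean over all ordered pairs of draws (computed in O(n log n) via
#' sorting). A single draw reduces it to the absolute error, so point
#' forecasts are scored by their mean absolute error.
#'
#' @param draws predictive samples (at least one).
#' @param truth observed/true value.
#' @return scalar score, >= 0 (lower is better).
#' @examples
#' crps(c(0, 2), 1)  # 0.5
#' @export
crps <- function(draws, truth) {
    n <- length(draws)
    if (n < 1L) stop("at least one predictive draw is required")
    s <- sort(draws)
    spread <- 2 * sum((2 * seq_len(n) - n - 1) * s) / n^2
    mean(abs(draws - truth)) - spread / 2
}

#' Top-k selection accuracy
#'
#' How many of the k individuals with the highest estimated values are
#' among the k individuals with the highest true values. Ties are broken
#' deterministically by individual id.
#'
#' @param estimates,truth named numeric vectors over the same individuals.
#' @param k selection size (default 10).
#' @return integer in [0, k].
#' @export
topkSelection <- function(estimates, truth, k = 10L) {
    if (is.null(names(estimates)) || is.null(names(truth)))
        stop("estimates and truth must be named by individual id")
    if (anyDuplicated(names(estimates)) || anyDuplicated(names(truth)))
        stop("duplicated individual ids")
    if (!setequal(names(estimates), names(truth)))
        stop("estimates and truth must cover the same individuals")
    if (k > length(truth)) stop("k exceeds the number of individuals")
    topBy <- function(v) names(v)[order(-v, names(v))][seq_len(k)]
    length(intersect(topBy(estimates), topBy(truth)))
}

#' Variance-recovery ratios
#'
#' Estimated over true variance per component (1 is perfect). Components
#' with zero true variance are skipped with a warning.
#'
#' @param estimates,truth named numeric vectors of variance estimates and
#'   true variances (shared names).
#' @return named vector of ratios for the assessable components.
#' @export
varianceRecovery <- function(estimates, truth) {
    shared <- intersect(names(estimates), names(truth))
    zero <- shared[truth[shared] == 0]
    if (length(zero))
        warning("skipping component(s) with zero true variance: ",
                paste(zero, collapse = ", "))
    keep <- setdiff(shared, zero)
    estimates[keep] / truth[keep]
}

#' Evaluation of a fit against simulated truth
#'
#' @slot correlations per-component Pearson correlation of posterior-mean
#'   values with the true values.
#' @slot crpsValues per-component mean CRPS over individuals.
#' @slot topk counts of true top-k individuals recovered when ranking on
#'   the estimated genetic value (variety selection) and additive value
#'   (parent selection).
#' @slot varianceRatios estimated / true variance per component.
#' @slot stable stability flag of the fit.
#' @seealso \code{\link{evaluateFit}}
#' @export
setClass("EvaluationReport",
    representation(correlations = "numeric", crpsValues = "numeric",
                   topk = "integer", varianceRatios = "numeric",
                   stable = "logical"))

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    cat("  correlation:",
        paste(sprintf("%s %.3f", names(object@correlations),
                      object@correlations), collapse = ", "), "\n")
    cat("  CRPS:",
        paste(sprintf("%s %.3f", names(object@crpsValues),
                      object@crpsValues), collapse = ", "), "\n")
    cat(sprintf("  top-k recovered: genetic %d, additive %d\n",
                object@topk[["genetic"]], object@topk[["additive"]]))
    cat("  variance ratios:",
        paste(sprintf("%s %.3f", names(object@varianceRatios),
                      object@varianceRatios), collapse = ", "), "\n")
    cat(sprintf("  stable: %s\n", object@stable))
})

#' Evaluate a fitted model against simulated truth
#'
#' Computes per-component correlations and CRPS of the recovered
#' individual values against the true values, top-k selection accuracy on
#' the genetic and additive values (posterior means used for ranking),
#' variance-recovery ratios and the stability flag.
#'
#' @param fit a \code{\link{FitResult}}.
#' @param truth a \code{\link{TruthSet}} over the same individuals.
#' @param k selection size (default 10).
#' @param values optional precomputed \code{\link{predictValues}} result.
#' @param seed seed for the conditional value draws.
#' @return An \code{\link{EvaluationReport}}.
#' @export
evaluateFit <- function(fit, truth, k = 10L, values = NULL, seed = 1L) {
    stopifnot(is(fit, "FitResult"), is(truth, "TruthSet"))
    if (is.null(values)) values <- predictValues(fit, seed = seed)
    comps <- names(values$draws)
    trueOf <- c(a = "a", d = "d", x = "x", g = "g")
    cors <- crp <- setNames(numeric(0), character(0))
    for (c. in comps) {
        tv <- slot(truth, trueOf[[c.]])
        est <- values$means[[c.]][names(tv)]
        cors[c.] <- if (sd(est) > 0 && sd(tv) > 0) cor(est, tv) else NA_real_
        crp[c.] <- mean(vapply(seq_along(tv), function(i)
            crps(values$draws[[c.]][, names(tv)[i]], tv[i]), numeric(1)))
    }
    ids <- names(truth@g)
    topk <- c(genetic = topkSelection(values$means$g[ids], truth@g, k),
              additive = topkSelection(values$means$a[ids], truth@a, k))
    estVar <- colMeans(fit@draws)[paste0("sigma2_", comps)]
    names(estVar) <- comps
    trueVar <- c(a = truth@realizedVariances[["additive"]],
                 d = truth@realizedVariances[["dominance"]],
                 x = truth@realizedVariances[["epistasis"]])
    ratios <- suppressWarnings(
        varianceRecovery(estVar, trueVar[comps[comps != "g"]]))
    new("EvaluationReport", correlations = cors, crpsValues = crp,
        topk = setNames(as.integer(topk), names(topk)),
        varianceRatios = ratios, stable = stability(fit))
}

#' Repeated k-fold cross-validation result
#'
#' @slot results data.frame with one row per repeat x fold: held-out
#'   correlation and mean CRPS.
#' @slot pooled data.frame with one row per repeat: metrics over the
#'   pooled held-out predictions of that repeat.
#' @slot folds list (one entry per repeat) of fold assignments.
#' @slot seed the partitioning seed.
#' @export
setClass("CVResult",
    representation(results = "data.frame", pooled = "data.frame",
                   folds = "list", seed = "integer"))

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %d repeat(s) x %d fold(s)\n",
                length(object@folds), max(object@results$fold)))
    cat(sprintf("  mean held-out correlation: %.3f, mean CRPS: %.3f\n",
                mean(object@results$cor, na.rm = TRUE),
                mean(object@results$crps)))
})

#' Repeated k-fold cross-validation of phenotype prediction
#'
#' Individuals (not observations) are partitioned into folds per repeat,
#' so replicates of one individual never straddle the train/test split.
#' For each fold the model is refit on the training individuals — with the
#' tree-based prior rebuilt from the training-fold relationship matrices,
#' since these priors are dataset specific — the held-out phenotypes are
#' predicted from their posterior-predictive distribution, and the
#' correlation between point predictions and observations plus the mean
#' CRPS of the predictive draws are recorded per fold and pooled per
#' repeat.
#'
#' @param data a \code{\link{GenomicData}}.
#' @param ek an \code{\link{EKSpec}} (used by the tree prior styles).
#' @param method \code{"bayes"} or \code{"ml"}.
#' @param style prior style for the Bayesian path: \code{"expert"},
#'   \code{"default"} or \code{"opposite"}.
#' @param folds,repeats cross-validation layout.
#' @param seed partitioning and fitting seed.
#' @param chains,warmup,draws sampler budget per fold fit.
#' @param ... further arguments to \code{\link{fitBayes}}.
#' @return A \code{\link{CVResult}}.
#' @export
crossValidate <- function(data, ek, method = c("bayes", "ml"),
                          style = "expert", folds = 5L, repeats = 5L,
                          seed = 1L, chains = 1L, warmup = 300L,
                          draws = 300L, ...) {
    method <- match.arg(method)
    stopifnot(is(data, "GenomicData"))
    ids <- levels(data@individual)
    n <- length(ids)
    if (n < 2L * folds) stop("need at least 2 individuals per fold")
    model <- dataModel(data)
    rows <- list()
    foldList <- list()
    for (rep. in seq_len(repeats)) {
        set.seed(seed + 1000L * rep.)
        assign. <- sample(rep(seq_len(folds), length.out = n))
        names(assign.) <- ids
        foldList[[rep.]] <- assign.
        poolPred <- poolObs <- numeric(0)
        poolCrps <- numeric(0)
        for (f in seq_len(folds)) {
            testIds <- ids[assign. == f]
            trainIds <- ids[assign. != f]
            keep <- data@individual %in% trainIds
            if (!any(!keep)) stop("fold with zero held-out observations")
            trainMats <- lapply(data@matrices, subsetRelationship,
                                ids = trainIds)
            trainData <- genomicData(
                data.frame(individual_id = as.character(
                               data@individual[keep]),
                           value = data@y[keep]),
                trainMats)
            if (method == "bayes") {
                tree <- buildTree(model, ek, trainMats)
                prior <- buildHDPrior(tree, style)
                fit <- fitBayes(trainData, prior, chains = chains,
                                warmup = warmup, draws = draws,
                                seed = seed + 17L * rep. + f, ...)
            } else {
                fit <- fitML(trainData)
            }
            pred <- predictPhenotypes(fit, testIds,
                                      matrices = data@matrices,
                                      seed = seed + 31L * rep. + f)
            testObs <- !keep
            obsY <- data@y[testObs]
            obsId <- as.character(data@individual[testObs])
            pp <- pred$pointPred[obsId]
            cc <- vapply(seq_along(obsY), function(i)
                crps(pred$yDraws[, obsId[i]], obsY[i]), numeric(1))
            rows[[length(rows) + 1L]] <- data.frame(
                repeat. = rep., fold = f,
                cor = if (sd(pp) > 0 && sd(obsY) > 0) cor(pp, obsY)
                      else NA_real_,
                crps = mean(cc))
            poolPred <- c(poolPred, pp)
            poolObs <- c(poolObs, obsY)
            poolCrps <- c(poolCrps, cc)
        }
        pooledRow <- data.frame(repeat. = rep.,
                                cor = cor(poolPred, poolObs),
                                crps = mean(poolCrps))
        attr(foldList[[rep.]], "pooled") <- pooledRow
    }
    results <- do.call(rbind, rows)
    pooled <- do.call(rbind, lapply(foldList, attr, which = "pooled"))
    new("CVResult", results = results, pooled = pooled, folds = foldList,
        seed = as.integer(seed))
}
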