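#' Expert-knowledge specification
#'
#' Bundles the three elicited variance ratios. For model \code{"A"} the
#' additive-to-genetic and dominance-to-nonadditive ratios are fixed at 1
#' exactly; for \code{"AD"} the dominance-to-nonadditive ratio is fixed at
#' 1.
#'
#' @param RGge genetic-to-phenotypic proportion (broad-sense heritability).
#' @param RAg additive-to-genetic proportion.
#' @param RDdx dominance-to-nonadditive proportion.
#' @param model when given, unused ratios are forced to 1.
#' @return An \code{\link{EKSpec}}.
#' @examples
#' ekSpec(0.25, 0.85, 0.67)          # full ADX triple
#' ekSpec(0.25, model = "A")         # RAg = RDdx = 1
#' @export
ekSpec <- function(RGge, RAg = 1, RDdx = 1, model = NULL) {
    if (!is.null(model)) {
        model <- match.arg(model, c("A", "AD", "ADX"))
        if (model == "A") RAg <- 1
        if (model %in% c("A", "AD")) RDdx <- 1
    }
    new("EKSpec", RGge = RGge, RAg = RAg, RDdx = RDdx)
}

setMethod("show", "EKSpec", function(object) {
    cat(sprintf("EKSpec: R_g/(g+e) = %.3g, R_a/g = %.3g, R_d/(d+x) = %.3g\n",
                object@RGge, object@RAg, object@RDdx))
})

#' Leaf shares of genetic variance implied by the EK ratios
#'
#' Following the tree downward, the additive share of genetic variance is
#' \code{RAg}, the dominance share \code{(1 - RAg) RDdx} and the epistasis
#' share \code{(1 - RAg)(1 - RDdx)}; the three sum to 1 exactly.
#'
#' @param ek an \code{\link{EKSpec}}.
#' @return named numeric vector \code{additive}, \code{dominance},
#'   \code{epistasis}.
#' @examples
#' impliedLeafShares(ekSpec(0.25, 0.85, 0.67))  # dominance ~ 0.10
#' @export
impliedLeafShares <- function(ek) {
    stopifnot(is(ek, "EKSpec"))
    c(additive = ek@RAg,
      dominance = (1 - ek@RAg) * ek@RDdx,
      epistasis = (1 - ek@RAg) * (1 - ek@RDdx))
}

#' Build the variance-decomposition tree
#'
#' Assembles the tree for one of the three model formulations: model A has
#' the single root split (leaves additive, environment), AD adds the
#' genetic split (additive vs dominance) and ADX the nonadditive split
#' (dominance vs epistasis). Every leaf must be bound to a relationship
#' matrix; the environmental leaf defaults to the identity.
#'
#' @param model \code{"A"}, \code{"AD"} or \code{"ADX"}.
#' @param ek an \code{\link{EKSpec}} (ratios of splits absent from the
#'   model are forced to 1).
#' @param matrices named list of \code{\link{RelationshipMatrix}} objects:
#'   \code{a} always, \code{d} for AD/ADX, \code{x} for ADX; \code{e} is
#'   created as the identity when missing.
#' @return A \code{\link{VarianceTree}}.
#' @export
buildTree <- function(model = c("A", "AD", "ADX"), ek, matrices) {
    model <- match.arg(model)
    stopifnot(is(ek, "EKSpec"))
    ek <- ekSpec(ek@RGge, ek@RAg, ek@RDdx, model = model)
    need <- switch(model, A = "a", AD = c("a", "d"), ADX = c("a", "d", "x"))
    missing <- setdiff(need, names(matrices))
    if (length(missing))
        stop("missing relationship matrix for required leaf: ",
             paste(missing, collapse = ", "))
    if (!"e" %in% names(matrices))
        matrices$e <- identityRelationship(rownames(relMatrix(matrices$a)))
    matrices <- matrices[c(need, "e")]
    splits <- list(list(name = "p_g", ek = ek@RGge, style = "PC0"))
    if (model %in% c("AD", "ADX"))
        splits <- c(splits, list(list(name = "p_a", ek = ek@RAg,
                                      style = "PCM")))
    if (model == "ADX")
        splits <- c(splits, list(list(name = "p_d", ek = ek@RDdx,
                                      style = "PCM")))
    new("VarianceTree", model = model, splits = splits, matrices = matrices,
        ek = ek)
}

# EK-weighted mixture of scaled relationship matrices, rescaled to typical
# diagonal 1 (every node of the tree is a unit-typical-variance structure)
mixtureMatrix <- function(weights, mats) {
    M <- Reduce(`+`, Map(function(w, K) w * relMatrix(K), weights, mats))
    M / scaleConstant(M)
}

#' Build the joint tree-based (model-wise) prior
#'
#' Bottom-up construction of the hierarchical-decomposition prior. With
#' \code{style = "expert"}: the lowest split gets \code{PCM(RDdx)}
#' comparing the dominance structure against the epistasis structure; the
#' middle split gets \code{PCM(RAg)} comparing the additive structure
#' against the EK-weighted nonadditive mixture
#' \code{RDdx D + (1 - RDdx) X}; the root split gets \code{PC0(RGge)}
#' comparing the EK-weighted genetic mixture against the identity — each
#' split above the lowest conditions on the EK values below it, and every
#' mixture is rescaled to typical variance 1. The total phenotypic variance
#' gets the improper Jeffreys prior (flat in log sigmaP2).
#'
#' \code{style = "default"} replaces the split priors with those implied by
#' a symmetric flat Dirichlet over the leaf shares of phenotypic variance
#' (by Dirichlet aggregation: root Beta(k - 1, 1) for k leaves, genetic
#' split Beta(1, number of nonadditive leaves), nonadditive split uniform).
#' \code{style = "opposite"} applies the expert construction with the
#' almost-opposite belief triple (same RGge, RAg = 0.05, RDdx = 0.11).
#'
#' @param tree a \code{\link{VarianceTree}}.
#' @param style \code{"expert"}, \code{"default"} or \code{"opposite"}.
#' @param grid tabulation grid for the split priors.
#' @return An \code{\link{HDJointPrior}}.
#' @examples
#' \donttest{
#' Z <- simulateGenotypes(simConfig(nIndividuals = 40, seed = 1))$markers
#' A <- buildRelationship(codeAdditive(Z), "A")
#' tr <- buildTree("A", ekSpec(0.25, model = "A"), list(a = A))
#' pr <- buildHDPrior(tr, "expert")
#' }
#' @export
buildHDPrior <- function(tree, style = c("expert", "default", "opposite"),
                         grid = defaultGrid()) {
    style <- match.arg(style)
    stopifnot(is(tree, "VarianceTree"))
    model <- tree@model
    if (style == "opposite") {
        if (model != "ADX")
            stop("the opposite-EK setting is defined for model ADX")
        tree <- buildTree(model, ekSpec(tree@ek@RGge, 0.05, 0.11),
                          tree@matrices)
    }
    m <- tree@matrices
    ek <- tree@ek
    priors <- list()
    if (style == "default") {
        k <- length(m)  # leaves including environment
        priors$p_g <- betaProportionPrior(k - 1, 1, grid)
        if (model %in% c("AD", "ADX"))
            priors$p_a <- betaProportionPrior(1, k - 2, grid)
        if (model == "ADX")
            priors$p_d <- betaProportionPrior(1, 1, grid)
        label <- paste0(model, "-tree")
    } else {
        if (model == "ADX")
            priors$p_d <- pcmProportion(m$d, m$x, ek@RDdx, grid = grid)
        nonadd <- switch(model,
            AD = relMatrix(m$d),
            ADX = mixtureMatrix(c(ek@RDdx, 1 - ek@RDdx), m[c("d", "x")]),
            NULL)
        if (!is.null(nonadd))
            priors$p_a <- pcmProportion(relMatrix(m$a), nonadd, ek@RAg,
                                        grid = grid)
        genetic <- if (is.null(nonadd)) relMatrix(m$a) else
            mixtureMatrix(c(ek@RAg, 1 - ek@RAg),
                          list(new("RelationshipMatrix",
                                   matrix = relMatrix(m$a),
                                   scalingConstant = 1, kind = "A"),
                               new("RelationshipMatrix", matrix = nonadd,
                                   scalingConstant = 1, kind = "identity")))
        priors$p_g <- pc0Proportion(genetic, relMatrix(m$e), ek@RGge,
                                    grid = grid)
        label <- paste0(model, "-tree", if (style == "opposite") "-opp", "*")
    }
    order <- intersect(c("p_g", "p_a", "p_d"), names(priors))
    new("HDJointPrior", tree = tree, splitPriors = priors[order],
        styleLabel = label)
}

#' Leaf variances from total variance and split proportions
#'
#' Distributes the phenotypic variance down the tree:
#' \code{sigma2_e = total (1 - p_g)}, \code{sigma2_a = total p_g p_a},
#' \code{sigma2_d = total p_g (1 - p_a) p_d},
#' \code{sigma2_x = total p_g (1 - p_a)(1 - p_d)}. The leaf variances sum
#' to the total exactly (telescoping identity).
#'
#' @param total phenotypic variance sigmaP2 (> 0).
#' @param proportions named vector with \code{p_g} and optionally
#'   \code{p_a}, \code{p_d} (each in [0, 1]); omitted entries mean the
#'   corresponding split is absent (ratio 1).
#' @return named numeric vector \code{sigma2_e}, \code{sigma2_a} and, when
#'   the matching proportions are supplied, \code{sigma2_d},
#'   \code{sigma2_x}.
#' @examples
#' leafVariances(1, c(p_g = 0.25, p_a = 0.85, p_d = 0.67))
#' @export
leafVariances <- function(total, proportions) {
    stopifnot(total > 0)
    p <- proportions
    stopifnot("p_g" %in% names(p), all(p >= 0), all(p <= 1))
    pg <- p[["p_g"]]
    out <- c(sigma2_e = total * (1 - pg))
    if (!"p_a" %in% names(p)) {
        out["sigma2_a"] <- total * pg
        return(out)
    }
    pa <- p[["p_a"]]
    out["sigma2_a"] <- total * pg * pa
    if (!"p_d" %in% names(p)) {
        out["sigma2_d"] <- total * pg * (1 - pa)
        return(out)
    }
    pd <- p[["p_d"]]
    out["sigma2_d"] <- total * pg * (1 - pa) * pd
    out["sigma2_x"] <- total * pg * (1 - pa) * (1 - pd)
    out
}

#' Joint log prior of an HD prior
#'
#' Evaluates the joint log prior density. On the natural scale
#' (\code{samplingScale = FALSE}) this is
#' \code{-log(sigmaP2) + sum_s log pi_s(p_s)} (Jeffreys on the total plus
#' the split densities). On the sampling scale the parameters are
#' \code{log sigmaP2} and \code{logit p_s}: Jeffreys becomes flat and each
#' split density gains the Jacobian \code{p_s (1 - p_s)}. Outside the
#' support the value is \code{-Inf}.
#'
#' @param prior an \code{\link{HDJointPrior}}.
#' @param sigmaP2 total phenotypic variance.
#' @param proportions named vector of split proportions (names matching the
#'   prior's splits).
#' @param samplingScale evaluate in the (log, logit) parameterization.
#' @return scalar log density (possibly \code{-Inf}).
#' @export
hdLogPrior <- function(prior, sigmaP2, proportions, samplingScale = FALSE) {
    stopifnot(is(prior, "HDJointPrior"))
    if (sigmaP2 <= 0) return(-Inf)
    lp <- if (samplingScale) 0 else -log(sigmaP2)
    for (nm in names(prior@splitPriors)) {
        if (!nm %in% names(proportions))
            stop("missing proportion: ", nm)
        p <- proportions[[nm]]
        if (p <= 0 || p >= 1) return(-Inf)
        lp <- lp + priorLogDensity(prior@splitPriors[[nm]], p)
        if (samplingScale) lp <- lp + log(p * (1 - p))
    }
    lp
}

#' Deterministic text rendering of a variance tree
#'
#' Draws the tree with its splits, EK edge labels and prior styles as a
#' fixed-width diagram. Identical trees render byte-identically.
#'
#' @param tree a \code{\link{VarianceTree}}.
#' @return single character string (also printed by the
#'   \code{show} method of \code{\link{VarianceTree}}).
#' @export
renderTree <- function(tree) {
    stopifnot(is(tree, "VarianceTree"))
    ek <- tree@ek
    st <- function(nm) {
        s <- Filter(function(x) x$name == nm, tree@splits)
        if (!length(s)) return(NULL)
        s[[1]]
    }
    lab <- function(s) sprintf("[%s ~ %s(R = %.3g)]", s$name, s$style, s$ek)
    lines <- c("phenotype  (sigmaP2 ~ Jeffreys)",
               sprintf("+-- genetic  %s", lab(st("p_g"))))
    if (tree@model == "A") {
        lines <- c(lines, "|   \\-- additive (A)")
    } else if (tree@model == "AD") {
        lines <- c(lines,
                   sprintf("|   +-- additive (A)  %s", lab(st("p_a"))),
                   "|   \\-- dominance (D)")
    } else {
        lines <- c(lines,
                   sprintf("|   +-- additive (A)  %s", lab(st("p_a"))),
                   "|   \\-- nonadditive",
                   sprintf("|       +-- dominance (D)  %s", lab(st("p_d"))),
                   "|       \\-- epistasis (X)")
    }
    lines <- c(lines, "\\-- environment (I)")
    paste(lines, collapse = "\n")
}

setMethod("show", "VarianceTree", function(object) {
    cat(sprintf("VarianceTree (model %s, %d individuals)\n", object@model,
                nrow(relMatrix(object@matrices$a))))
    cat(renderTree(object), "\n")
})

setMethod("show", "HDJointPrior", function(object) {
    cat(sprintf("HDJointPrior: %s\n", object@styleLabel))
    for (nm in names(object@splitPriors)) {
        pr <- object@splitPriors[[nm]]
        if (pr@style == "dirichlet_marginal")
            cat(sprintf("  %s ~ Dirichlet-implied (aggregated Beta)\n", nm))
        else
            cat(sprintf("  %s ~ %s(%.3g)\n", nm, pr@style, pr@medianTarget))
    }
    cat("  sigmaP2 ~ Jeffreys (improper, flat in log sigmaP2)\n")
})

#' Read a tree/prior configuration file
#'
#' The configuration is a DCF (Debian-control / \code{read.dcf}) file with
#' fields \code{model} (A/AD/ADX), \code{RGge}, \code{RAg}, \code{RDdx}
#' and \code{style} — either \code{expert}/\code{default}/\code{opposite}
#' or a prior-family label (\code{A-tree}, \code{A-tree*}, \code{AD-tree*},
#' \code{ADX-tree*}, \code{ADX-tree-opp*}, \code{AD-tree},
#' \code{ADX-tree}).
#'
#' @param file path.
#' @return list with elements \code{model}, \code{ek}
#'   (\code{\link{EKSpec}}) and \code{style}.
#' @export
readTreeConfig <- function(file) {
    dcf <- read.dcf(file)
    get <- function(nm, default = NA) {
        if (nm %in% colnames(dcf)) dcf[1, nm] else default
    }
    label <- get("style", "expert")
    style <- label
    model <- get("model", NA)
    if (grepl("-tree", label)) {
        model <- sub("-tree.*", "", label)
        style <- if (grepl("opp", label)) "opposite"
                 else if (grepl("\\*$", label)) "expert" else "default"
    }
    if (is.na(model)) stop("config must give 'model' or a tree-style label")
    model <- match.arg(model, c("A", "AD", "ADX"))
    num <- function(nm, default) {
        v <- get(nm, NA)
        if (is.na(v)) default else as.numeric(v)
    }
    ek <- ekSpec(num("RGge", 0.25), num("RAg", 0.85), num("RDdx", 0.67),
                 model = model)
    list(model = model, ek = ek, style = style)
}
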