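#' Construct an SNPMatrix
#'
#' @param genotypes numeric n x m matrix with entries in \{0, 1, 2\}.
#' @param individualIds optional length-n ids (default: existing rownames or
#'   \code{ind1..indn}).
#' @param markerIds optional length-m ids (default: existing colnames or
#'   \code{m1..mm}).
#' @return A \code{\link{SNPMatrix}}.
#' @examples
#' Z <- snpMatrix(matrix(c(0, 1, 2, 1, 0, 0, 2, 2), nrow = 4))
#' dim(genotypes(Z))
#' @export
snpMatrix <- function(genotypes, individualIds = NULL, markerIds = NULL) {
    genotypes <- as.matrix(genotypes)
    if (!is.null(individualIds)) rownames(genotypes) <- individualIds
    if (!is.null(markerIds)) colnames(genotypes) <- markerIds
    if (is.null(rownames(genotypes)))
        rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- paste0("m", seq_len(ncol(genotypes)))
    new("SNPMatrix", genotypes = genotypes)
}

#' @describeIn snpMatrix genotype matrix accessor
#' @param x an \code{SNPMatrix}.
#' @export
genotypes <- function(x) {
    stopifnot(is(x, "SNPMatrix"))
    x@genotypes
}

#' @describeIn snpMatrix individual id accessor
#' @export
individualIds <- function(x) rownames(genotypes(x))

#' @describeIn snpMatrix marker id accessor
#' @export
markerIds <- function(x) colnames(genotypes(x))

setMethod("show", "SNPMatrix", function(object) {
    g <- object@genotypes
    cat(sprintf("SNPMatrix: %d individuals x %d markers\n", nrow(g), ncol(g)))
    cat(sprintf("  minor allele frequency range: [%.3f, %.3f]\n",
                min(mafValues(object)), max(mafValues(object))))
})

#' Minor allele frequencies
#'
#' Per-marker minor allele frequency of an \code{\link{SNPMatrix}}: the
#' allele frequency \code{mean(column) / 2}, folded to \code{[0, 0.5]}.
#'
#' @param Z an \code{\link{SNPMatrix}}.
#' @return numeric vector of length m.
#' @export
mafValues <- function(Z) {
    f <- colMeans(genotypes(Z)) / 2
    pmin(f, 1 - f)
}

#' Remove markers with low minor allele frequency
#'
#' Markers with minor allele frequency strictly below the threshold are
#' removed; markers at or above it are retained. Column order and the
#' individual set are unchanged. Filtering is applied once, before both the
#' additive and the dominance coding.
#'
#' @param Z an \code{\link{SNPMatrix}}.
#' @param threshold MAF threshold in \code{[0, 0.5]} (default 0.05).
#' @return The filtered \code{\link{SNPMatrix}}.
#' @examples
#' Z <- snpMatrix(cbind(mono = c(0, 0, 0, 0), poly = c(0, 1, 1, 2)))
#' markerIds(filterMAF(Z, 0.05))
#' @export
filterMAF <- function(Z, threshold = 0.05) {
    stopifnot(threshold >= 0, threshold <= 0.5)
    keep <- mafValues(Z) >= threshold
    if (!any(keep))
        stop("empty marker set: all markers fall below the MAF threshold")
    snpMatrix(genotypes(Z)[, keep, drop = FALSE])
}

#' Centered additive marker coding
#'
#' Column-centers the 0/1/2 genotype codes, yielding the matrix Za used to
#' build the additive relationship matrix.
#'
#' @param Z an \code{\link{SNPMatrix}} (already MAF-filtered).
#' @return A \code{\link{CodedMatrix}} with coding
#'   \code{"additive_centered"}.
#' @export
codeAdditive <- function(Z) {
    v <- scale(genotypes(Z), center = TRUE, scale = FALSE)
    attr(v, "scaled:center") <- NULL
    new("CodedMatrix", values = v, coding = "additive_centered")
}

#' Centered dominance marker coding
#'
#' Recodes genotypes to a heterozygosity indicator (heterozygote 1,
#' homozygotes 0) and column-centers, yielding the matrix Zd used to build
#' the dominance relationship matrix.
#'
#' @inheritParams codeAdditive
#' @return A \code{\link{CodedMatrix}} with coding
#'   \code{"dominance_centered"}.
#' @export
codeDominance <- function(Z) {
    h <- (genotypes(Z) == 1) * 1
    v <- scale(h, center = TRUE, scale = FALSE)
    attr(v, "scaled:center") <- NULL
    new("CodedMatrix", values = v, coding = "dominance_centered")
}

setMethod("show", "CodedMatrix", function(object) {
    cat(sprintf("CodedMatrix (%s): %d x %d\n", object@coding,
                nrow(object@values), ncol(object@values)))
})

#' Typical-variance scaling constant
#'
#' The constant S such that C / S has typical diagonal value 1, realized as
#' the geometric mean of the diagonal of C. Geometric-mean scaling is
#' invariant to measurement units and puts all relationship matrices on a
#' common "variance of a typical individual" scale.
#'
#' @param C symmetric matrix with strictly positive diagonal.
#' @return positive scalar S.
#' @examples
#' scaleConstant(diag(c(1, 4)))  # 2
#' @export
scaleConstant <- function(C) {
    d <- diag(as.matrix(C))
    if (any(d <= 0))
        stop("non-positive diagonal entry; cannot scale to typical variance 1")
    exp(mean(log(d)))
}

#' Build a scaled genomic relationship matrix
#'
#' Additive: \code{A = Za Za' / Sa}; dominance: \code{D = Zd Zd' / Sd};
#' additive-by-additive epistasis: \code{X = A (*) A / Sx}, the Hadamard
#' square of the already-scaled A, re-scaled. Scaling constants are the
#' geometric mean of the unscaled diagonal (\code{\link{scaleConstant}}).
#'
#' @param M for kinds \code{"A"}/\code{"D"} the matching
#'   \code{\link{CodedMatrix}}; for kind \code{"X"} the built additive
#'   \code{\link{RelationshipMatrix}}.
#' @param kind \code{"A"}, \code{"D"} or \code{"X"}.
#' @return A \code{\link{RelationshipMatrix}}.
#' @examples
#' Z <- snpMatrix(cbind(a = c(0, 1, 2, 1), b = c(2, 1, 0, 1)))
#' A <- buildRelationship(codeAdditive(Z), "A")
#' X <- buildRelationship(A, "X")
#' @export
buildRelationship <- function(M, kind = c("A", "D", "X")) {
    kind <- match.arg(kind)
    if (kind == "X") {
        if (!is(M, "RelationshipMatrix") || M@kind != "A")
            stop("kind 'X' requires the built additive RelationshipMatrix")
        C <- M@matrix * M@matrix
    } else {
        if (!is(M, "CodedMatrix"))
            stop("kinds 'A' and 'D' require a CodedMatrix")
        expected <- c(A = "additive_centered", D = "dominance_centered")[[kind]]
        if (M@coding != expected)
            stop(sprintf("kind '%s' requires coding '%s'", kind, expected))
        C <- tcrossprod(M@values)
    }
    C <- symmetrize(C)
    if (all(abs(diag(C)) < 1e-12))
        stop(sprintf(paste("zero cross-product for component '%s' (no variation",
                           "in this coding); drop the component from the model"),
                     kind))
    S <- scaleConstant(C)
    new("RelationshipMatrix", matrix = C / S, scalingConstant = S, kind = kind)
}

#' Identity relationship matrix
#'
#' The n x n identity used as the covariance structure of the environmental
#' leaf (and as the base model of the root split).
#'
#' @param ids individual ids (character vector).
#' @return A \code{\link{RelationshipMatrix}} of kind \code{"identity"}.
#' @export
identityRelationship <- function(ids) {
    n <- length(ids)
    I <- diag(n)
    dimnames(I) <- list(ids, ids)
    new("RelationshipMatrix", matrix = I, scalingConstant = 1,
        kind = "identity")
}

#' @describeIn buildRelationship matrix accessor
#' @param x a \code{RelationshipMatrix}.
#' @export
relMatrix <- function(x) {
    stopifnot(is(x, "RelationshipMatrix"))
    x@matrix
}

#' @describeIn buildRelationship scaling-constant accessor
#' @export
scalingConstant <- function(x) {
    stopifnot(is(x, "RelationshipMatrix"))
    x@scalingConstant
}

setMethod("show", "RelationshipMatrix", function(object) {
    cat(sprintf("RelationshipMatrix (kind %s): %d x %d, scaling constant %.4g\n",
                object@kind, nrow(object@matrix), ncol(object@matrix),
                object@scalingConstant))
})
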