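# Delimited-text and VCF ingestion/export.

#' Read a genotype table
#'
#' Reads a tab- or comma-delimited genotype table with individuals in rows,
#' a header row of marker ids, and the individual id in the first column.
#' Codes must be 0/1/2 counts of one allele. Missing genotypes are rejected
#' unless \code{impute = TRUE}, in which case they are replaced by the
#' rounded column mean (off by default; silent mean-imputation distorts
#' relationship matrices).
#'
#' @param file path to the table.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header line.
#' @param impute replace missing genotypes by the rounded column mean.
#' @return A \code{\link{SNPMatrix}}.
#' @export
readGenotypes <- function(file, sep = NULL, impute = FALSE) {
    if (is.null(sep)) {
        header <- readLines(file, n = 1L)
        sep <- if (grepl("\t", header)) "\t" else ","
    }
    tab <- utils::read.table(file, header = TRUE, sep = sep,
                             row.names = 1L, check.names = FALSE)
    g <- as.matrix(tab)
    if (anyNA(g)) {
        if (!impute)
            stop("missing genotypes found; re-run with impute = TRUE ",
                 "or clean the input")
        for (j in seq_len(ncol(g))) {
            miss <- is.na(g[, j])
            if (all(miss)) stop("marker with all genotypes missing")
            g[miss, j] <- round(mean(g[!miss, j]))
        }
    }
    snpMatrix(g)
}

#' Write a genotype table
#'
#' @param Z an \code{\link{SNPMatrix}}.
#' @param file output path.
#' @param sep field separator (default tab).
#' @export
writeGenotypes <- function(Z, file, sep = "\t") {
    g <- genotypes(Z)
    df <- data.frame(id = rownames(g), g, check.names = FALSE)
    utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read hard-call genotypes from a VCF
#'
#' Extracts diploid GT hard calls (phased or unphased) and codes each
#' genotype as the count of the ALT allele. Requires the vcfR package.
#' Missing or non-diploid calls are rejected.
#'
#' @param file path to an (uncompressed or gzipped) VCF.
#' @return A \code{\link{SNPMatrix}} (individuals x markers).
#' @export
readGenotypesVCF <- function(file) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("VCF ingestion requires the 'vcfR' package")
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
        alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
        vapply(alleles, function(a) {
            if (length(a) != 2L || anyNA(a) || any(a == "."))
                return(NA_real_)
            sum(a == "1")
        }, numeric(1))
    }
    g <- t(apply(gt, 2L, count_alt))   # individuals x markers
    if (anyNA(g)) stop("missing or non-diploid GT calls in VCF")
    rownames(g) <- colnames(gt)
    colnames(g) <- rownames(gt)
    snpMatrix(g)
}

#' Write / read a relationship matrix as a delimited square table
#'
#' The table has an id header row and an id first column; the scaling
#' constant is recorded in a comment line.
#'
#' @param K a \code{\link{RelationshipMatrix}}.
#' @param file path.
#' @param sep field separator (default tab).
#' @export
writeRelationship <- function(K, file, sep = "\t") {
    M <- relMatrix(K)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# kind=%s scaling_constant=%.17g", K@kind,
                       scalingConstant(K)), con)
    df <- data.frame(id = rownames(M), M, check.names = FALSE)
    utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' @rdname writeRelationship
#' @export
readRelationship <- function(file, sep = "\t") {
    header <- readLines(file, n = 1L)
    kind <- sub(".*kind=(\\S+).*", "\\1", header)
    S <- as.numeric(sub(".*scaling_constant=(\\S+).*", "\\1", header))
    tab <- utils::read.table(file, header = TRUE, sep = sep, skip = 1L,
                             row.names = 1L, check.names = FALSE)
    M <- as.matrix(tab)
    colnames(M) <- rownames(M)
    new("RelationshipMatrix", matrix = symmetrize(M), scalingConstant = S,
        kind = kind)
}

#' Read a phenotype table
#'
#' Reads a delimited table with columns \code{individual_id}, \code{value}
#' and \code{replicate} (header required; extra columns ignored).
#'
#' @param file path.
#' @param sep separator; auto-detected when \code{NULL}.
#' @return data.frame with columns \code{individual_id}, \code{value},
#'   \code{replicate}.
#' @export
readPhenotypes <- function(file, sep = NULL) {
    if (is.null(sep)) {
        header <- readLines(file, n = 1L)
        sep <- if (grepl("\t", header)) "\t" else ","
    }
    tab <- utils::read.table(file, header = TRUE, sep = sep,
                             check.names = FALSE)
    need <- c("individual_id", "value", "replicate")
    if (!all(need %in% names(tab)))
        stop("phenotype table must have columns: ",
             paste(need, collapse = ", "))
    tab[need]
}
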