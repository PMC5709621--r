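# Detection-rate QC and counts-per-million normalization.
#
# Detection rates are computed on raw counts, before any normalization.
# Filtering removes low-detection cells first, then recomputes gene
# detection rates on the surviving cells and removes low-detection
# genes (one pass; iteration to a fixpoint is available behind a flag).
# A rate exactly equal to the threshold is retained.

.countsOf <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
}

#' Per-cell and per-gene detection rates
#'
#' The cell rate is the share of genes with a positive count in that
#' cell; the gene rate is the share of cells in which the gene has a
#' positive count.
#'
#' @param x a \linkS4class{KnockdownExperiment} or a counts matrix
#'   (genes x cells).
#' @return list with named numeric vectors \code{cell_rate} and
#'   \code{gene_rate}.
#' @export
computeDetectionRates <- function(x) {
    m <- .countsOf(x)
    if (nrow(m) == 0 || ncol(m) == 0) stop("empty matrix")
    pos <- m > 0
    list(cell_rate = colMeans(pos), gene_rate = rowMeans(pos))
}

#' Filter genes and cells by detection rate
#'
#' Drops cells whose detection rate is below \code{threshold}, then
#' drops genes whose detection rate, recomputed on the surviving cells,
#' is below \code{threshold}. Rates equal to the threshold survive.
#' Survivors keep their original order and counts are unchanged.
#'
#' @param x a \linkS4class{KnockdownExperiment} or counts matrix.
#' @param threshold detection-rate threshold in (0, 1); default 0.05.
#' @param iterate if \code{TRUE}, repeat the cells-then-genes pass until
#'   no further removals (default \code{FALSE}: the single documented
#'   pass).
#' @return the filtered object, same class as the input.
#' @export
filterByDetection <- function(x, threshold = 0.05, iterate = FALSE) {
    stopifnot(threshold > 0, threshold < 1)
    repeat {
        m <- .countsOf(x)
        keep_cells <- colMeans(m > 0) >= threshold
        if (!any(keep_cells)) stop("all cells removed by detection filter")
        x2 <- x[, keep_cells]
        m2 <- .countsOf(x2)
        keep_genes <- rowMeans(m2 > 0) >= threshold
        if (!any(keep_genes)) stop("all genes removed by detection filter")
        x2 <- x2[keep_genes, ]
        done <- all(keep_cells) && all(keep_genes)
        x <- x2
        if (done || !iterate) break
    }
    x
}

#' Flag cells dominated by a single gene
#'
#' Operationalization of PCR-bias outlier removal: a cell is flagged
#' when any single gene accounts for more than
#' \code{max_gene_fraction} of the cell's total reads.
#'
#' @param x a \linkS4class{KnockdownExperiment} or counts matrix with at
#'   least 5 cells.
#' @param max_gene_fraction flag threshold on the largest per-gene share
#'   of a cell's reads (default 0.10).
#' @return character vector of flagged cell ids, sorted
#'   lexicographically (possibly empty).
#' @export
flagOutlierCells <- function(x, max_gene_fraction = 0.10) {
    m <- .countsOf(x)
    if (ncol(m) < 5) stop("outlier flagging needs at least 5 cells")
    stopifnot(max_gene_fraction > 0, max_gene_fraction < 1)
    totals <- colSums(m)
    frac <- apply(m, 2, max) / ifelse(totals > 0, totals, NA)
    ids <- colnames(m)[!is.na(frac) & frac > max_gene_fraction]
    sort(ids)
}

#' Counts-per-million normalization
#'
#' Scales every cell (column) so its total equals \code{cpm_scale}.
#'
#' @param x a \linkS4class{KnockdownExperiment} or counts matrix with no
#'   all-zero cells (guaranteed after \code{\link{filterByDetection}}).
#' @param cpm_scale target per-cell total (default one million).
#' @return for a matrix input, the normalized matrix with a
#'   \code{provenance} attribute (scale and original cell totals); for a
#'   \linkS4class{KnockdownExperiment}, the object with a \code{"cpm"}
#'   assay added and provenance in \code{metadata()}.
#' @export
normalizeCPM <- function(x, cpm_scale = 1e6) {
    stopifnot(cpm_scale > 0)
    m <- .countsOf(x)
    totals <- colSums(m)
    if (any(totals == 0))
        stop("all-zero cell(s) present; run filterByDetection first")
    cpm <- sweep(m, 2, totals, "/") * cpm_scale
    prov <- list(cpm_scale = cpm_scale, original_totals = totals)
    if (is(x, "SummarizedExperiment")) {
        assay(x, "cpm") <- cpm
        metadata(x)$cpm_provenance <- prov
        x
    } else {
        attr(cpm, "provenance") <- prov
        cpm
    }
}
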