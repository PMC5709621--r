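# Readers and writers: MatrixMarket counts + gene/cell TSVs, result
# tables, and the flat key=value pipeline configuration.

#' @importFrom Matrix readMM writeMM
#' @importFrom utils read.delim write.table
NULL

RESULT_COLUMNS <- c("gene_id", "p1", "p2", "pvalue", "qvalue", "log2_fc",
                    "log2_fc_detectable", "log2_fc_undetectable",
                    "direction", "significant", "converged", "boundary")

#' Read a count matrix with gene and cell annotations
#'
#' The matrix file is MatrixMarket coordinate integer format (1-based);
#' the gene and cell files are headered TSVs whose first columns are
#' \code{gene_id} and \code{cell_id}, in matrix row/column order. When
#' the cell file carries \code{treatment} and \code{batch} columns a
#' \linkS4class{KnockdownExperiment} is returned; otherwise the bare
#' integer matrix with dimnames. Only integer counts are accepted
#' (a deposited matrix must be raw counts, not normalized values).
#'
#' @param matrix_path,gene_path,cell_path file paths.
#' @return a \linkS4class{KnockdownExperiment} or an integer matrix.
#' @export
readCountMatrix <- function(matrix_path, gene_path, cell_path) {
    m <- as.matrix(readMM(matrix_path))
    genes <- read.delim(gene_path, stringsAsFactors = FALSE)
    cells <- read.delim(cell_path, stringsAsFactors = FALSE)
    if (!("gene_id" %in% colnames(genes)))
        stop("gene annotation file lacks a 'gene_id' column: ", gene_path)
    if (!("cell_id" %in% colnames(cells)))
        stop("cell annotation file lacks a 'cell_id' column: ", cell_path)
    if (nrow(genes) != nrow(m))
        stop("dimension mismatch: matrix has ", nrow(m), " rows but ",
             gene_path, " lists ", nrow(genes), " genes")
    if (nrow(cells) != ncol(m))
        stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
             cell_path, " lists ", nrow(cells), " cells")
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene id in ", gene_path)
    if (anyDuplicated(cells$cell_id)) stop("duplicate cell id in ", cell_path)
    if (anyNA(m) || any(m < 0)) stop("negative or missing counts in ",
                                     matrix_path)
    if (any(m != floor(m))) stop("non-integer counts in ", matrix_path)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(genes$gene_id, cells$cell_id)
    if (all(c("treatment", "batch") %in% colnames(cells))) {
        dg <- if ("dosage_group" %in% colnames(cells)) cells$dosage_group
              else NA_character_
        KnockdownExperiment(m, treatment = cells$treatment,
                            batch = cells$batch, dosage_group = dg)
    } else m
}

#' Write a count matrix with gene and cell annotations
#'
#' Inverse of \code{\link{readCountMatrix}}: MatrixMarket coordinate
#' integer matrix plus headered gene/cell TSVs in matrix order.
#'
#' @param x a \linkS4class{KnockdownExperiment} or integer matrix with
#'   dimnames.
#' @param matrix_path,gene_path,cell_path output paths.
#' @return invisibly, the three paths.
#' @export
writeCountMatrix <- function(x, matrix_path, gene_path, cell_path) {
    if (is(x, "SummarizedExperiment")) {
        m <- assay(x, "counts")
        cells <- data.frame(cell_id = colnames(m),
                            as.data.frame(colData(x)))
    } else {
        m <- as.matrix(x)
        cells <- data.frame(cell_id = colnames(m))
    }
    writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
            matrix_path)
    write.table(data.frame(gene_id = rownames(m)), gene_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cells, cell_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(matrix_path, gene_path, cell_path))
}

#' Write a differential-expression results table
#'
#' Headered TSV with one row per gene and a fixed, documented column
#' order: \code{gene_id, p1, p2, pvalue, qvalue, log2_fc,
#' log2_fc_detectable, log2_fc_undetectable, direction, significant,
#' converged, boundary}. A comment line records the design and FDR
#' level. Numeric fields carry 15 significant digits.
#'
#' @param deres a \linkS4class{DEResults}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeResultsTable <- function(deres, path) {
    stopifnot(is(deres, "DEResults"))
    df <- as.data.frame(deres)
    for (col in setdiff(RESULT_COLUMNS, colnames(df)))
        df[[col]] <- rep(NA, nrow(df))
    df <- df[, RESULT_COLUMNS, drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
        ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE,
                                      scientific = NA))
    })
    con <- tryCatch(file(path, "w"), error = function(e)
        stop("cannot write results table to ", path, ": ",
             conditionMessage(e)))
    on.exit(close(con))
    writeLines(sprintf("# design=%s fdr_level=%s", deres@design,
                       format(deres@fdrLevel, digits = 15)), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read back a written results table
#'
#' @param path a TSV written by \code{\link{writeResultsTable}}.
#' @return a \linkS4class{DEResults}.
#' @export
readResultsTable <- function(path) {
    hdr <- readLines(path, n = 1)
    design <- sub("^# design=(\\S+).*$", "\\1", hdr)
    fdr <- as.numeric(sub("^.*fdr_level=(\\S+)$", "\\1", hdr))
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (nrow(df) == 0)
        df <- as.data.frame(lapply(df, identity))
    new("DEResults", DataFrame(df), design = design, fdrLevel = fdr)
}

#' Pipeline configuration
#'
#' Flat configuration with documented defaults equal to the study's
#' settings: 5 percent detection threshold, CPM scale of one million,
#' 5 percent FDR, outlier flagging at a 10 percent max-gene fraction.
#'
#' @param detection_threshold detection-rate threshold, in (0,1).
#' @param cpm_scale per-cell normalization total.
#' @param fdr_level FDR level, in (0,1).
#' @param target_gene target gene id.
#' @param outlier_max_gene_fraction outlier-cell flag threshold, (0,1).
#' @param seed integer seed, logged and set by the pipeline.
#' @param cell_cycle_gene_file optional path to a one-symbol-per-line
#'   panel file (\code{NA}: use the panel recorded in the object's
#'   metadata, e.g. by the simulator).
#' @param n_factors number of latent factors to remove (default 1).
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(detection_threshold = 0.05, cpm_scale = 1e6,
                           fdr_level = 0.05, target_gene = "TARGET",
                           outlier_max_gene_fraction = 0.10, seed = 1,
                           cell_cycle_gene_file = NA_character_,
                           n_factors = 1) {
    cfg <- list(detection_threshold = detection_threshold,
                cpm_scale = cpm_scale, fdr_level = fdr_level,
                target_gene = target_gene,
                outlier_max_gene_fraction = outlier_max_gene_fraction,
                seed = as.integer(seed),
                cell_cycle_gene_file = cell_cycle_gene_file,
                n_factors = as.integer(n_factors))
    with(cfg, stopifnot(detection_threshold > 0, detection_threshold < 1,
                        fdr_level > 0, fdr_level < 1,
                        outlier_max_gene_fraction > 0,
                        outlier_max_gene_fraction < 1,
                        cpm_scale > 0, n_factors >= 1))
    structure(cfg, class = "PipelineConfig")
}

#' Read a flat key=value configuration file
#'
#' One \code{key=value} pair per line; blank lines and \code{#}
#' comments ignored; unknown keys are an error. Values are coerced to
#' the type of the corresponding \code{\link{pipelineConfig}} default.
#'
#' @param path configuration file path.
#' @return a \code{"PipelineConfig"} list.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- vapply(kv, length, integer(1)) != 2
    if (any(bad)) stop("malformed config line(s): ",
                       paste(lines[bad], collapse = "; "))
    keys <- trimws(vapply(kv, `[`, character(1), 1))
    vals <- trimws(vapply(kv, `[`, character(1), 2))
    defaults <- pipelineConfig()
    unknown <- setdiff(keys, names(defaults))
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "))
    args <- list()
    for (i in seq_along(keys)) {
        d <- defaults[[keys[i]]]
        args[[keys[i]]] <- if (is.numeric(d)) as.numeric(vals[i]) else vals[i]
    }
    do.call(pipelineConfig, args)
}
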