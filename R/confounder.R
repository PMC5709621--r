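# Latent-factor correction for cell-cycle/batch confounding.
#
# A single-factor linear surrogate for latent-variable batch/cell-cycle
# correction: log2(CPM+1) expression of a cell-cycle gene panel is
# residualized against protected treatment covariates, the leading
# right singular vector of the residual matrix is the per-cell factor,
# and the factor is regressed out of every gene while the protected
# covariates are retained in each regression (and, because the factor
# is orthogonal to them by construction, mathematically untouched).

.log2cpm <- function(m) log2(m + 1)

#' Load a cell-cycle gene panel and intersect it with a matrix
#'
#' Reads a one-symbol-per-line panel file and intersects it
#' (case-sensitively, exact match) with the gene ids under analysis.
#'
#' @param path panel file, one gene symbol per line.
#' @param matrix_gene_ids gene ids of the analyzed matrix.
#' @return list with \code{gene_ids} (the full panel), \code{matched}
#'   (the intersection, in panel order) and \code{n_matched}.
#' @examples
#' # a synthetic 189-entry stand-in for a GO-derived cell-cycle panel,
#' # demonstrating the one-symbol-per-line format
#' panel_file <- system.file("extdata", "synthetic_cell_cycle_panel.txt",
#'                           package = "knockdownDE")
#' cc <- loadCellCycleGenes(panel_file, readLines(panel_file)[1:102])
#' cc$n_matched
#' @export
loadCellCycleGenes <- function(path, matrix_gene_ids) {
    ids <- readLines(path)
    ids <- unique(ids[nzchar(trimws(ids))])
    if (!length(ids)) stop("empty cell-cycle gene file: ", path)
    matched <- ids[ids %in% matrix_gene_ids]
    if (!length(matched))
        stop("no cell-cycle genes matched the analyzed matrix ",
             "(matching is case-sensitive)")
    list(gene_ids = ids, matched = matched, n_matched = length(matched))
}

#' Fit the latent confounder factor
#'
#' Per panel gene, log2(CPM+1) expression is regressed on the protected
#' covariates (treatment design, including intercept); the factor is
#' the leading singular direction of the residual matrix, with scores
#' standardized to zero mean and unit variance. The sign is fixed so
#' the largest-magnitude gene loading is positive.
#'
#' @param log_expression matrix of log2(CPM+1) values, matched
#'   cell-cycle genes x cells (at least 5 genes, 4 cells).
#' @param treatment_design protected covariate matrix (cells x
#'   covariates) from \code{\link{makeDesignMatrix}}.
#' @return a \linkS4class{LatentFactorModel}.
#' @export
fitLatentFactor <- function(log_expression, treatment_design) {
    L <- as.matrix(log_expression)
    D <- as.matrix(treatment_design)
    if (nrow(L) < 5) stop("need at least 5 matched cell-cycle genes")
    if (ncol(L) < 4) stop("need at least 4 cells")
    stopifnot(ncol(L) == nrow(D))
    fit <- stats::lm.fit(D, t(L))
    B <- t(stats::coef(fit))            # genes x covariates
    R <- t(stats::residuals(fit))       # genes x cells
    sv <- svd(R)
    if (sv$d[1] < 1e-10 * max(1, sqrt(sum(R^2))) || sv$d[1] < 1e-12)
        stop("residual matrix has rank 0; expression is constant ",
             "across cells after removing protected covariates")
    scores <- sv$v[, 1]
    scores <- (scores - mean(scores)) / sd(scores)
    loadings <- drop(R %*% scores) / (ncol(L) - 1)
    if (loadings[which.max(abs(loadings))] < 0) {
        scores <- -scores
        loadings <- -loadings
    }
    names(scores) <- colnames(L)
    names(loadings) <- rownames(L)
    colnames(B) <- colnames(D)
    new("LatentFactorModel", factorScores = scores, geneLoadings = loadings,
        treatmentCoefficients = B, protectedDesign = D,
        varianceExplained = sv$d[1]^2 / sum(sv$d^2))
}

#' Regress the latent factor out of an expression matrix
#'
#' For every gene (not only panel genes), the loading of log2(CPM+1)
#' expression on the factor scores is fitted jointly with the protected
#' covariates, the \code{loading * scores} term alone is subtracted,
#' and values are back-transformed by \code{2^x - 1} and clipped at
#' zero. Because the scores are orthogonal to the protected covariates,
#' treatment-attributable signal is untouched.
#'
#' @param x a \linkS4class{KnockdownExperiment} with a \code{"cpm"}
#'   assay, or a CPM matrix (genes x cells).
#' @param model a \linkS4class{LatentFactorModel} fitted on the same
#'   cells.
#' @return same class as the input: corrected CPM values (for a
#'   \code{KnockdownExperiment}, added as the \code{"corrected"} assay).
#' @export
regressOutFactor <- function(x, model) {
    stopifnot(is(model, "LatentFactorModel"))
    cpm <- if (is(x, "SummarizedExperiment")) assay(x, "cpm") else as.matrix(x)
    cells <- colnames(cpm)
    if (is.null(cells) || !identical(cells, names(model@factorScores)))
        stop("cells of the matrix and the fitted model do not match")
    L <- .log2cpm(cpm)
    D <- cbind(model@protectedDesign, factor = model@factorScores)
    fit <- stats::lm.fit(D, t(L))
    beta_f <- stats::coef(fit)["factor", ]
    Lc <- L - outer(beta_f, model@factorScores)
    out <- pmax(2^Lc - 1, 0)
    dimnames(out) <- dimnames(cpm)
    if (is(x, "SummarizedExperiment")) {
        assay(x, "corrected") <- out
        x
    } else out
}

#' Principal-component summary of cells
#'
#' Standard PCA of cells on gene-centered log2(CPM+1) expression, with
#' component variances reported as percentages of the total.
#'
#' @param x a \linkS4class{KnockdownExperiment} or a CPM matrix (genes x
#'   cells); log transformation and gene centering are applied here.
#' @param n_components number of components to return.
#' @param assay_name for a \code{KnockdownExperiment}, which assay to
#'   summarize (default \code{"corrected"} when present, else
#'   \code{"cpm"}).
#' @return list with \code{component_variance_fractions} (percentages,
#'   non-increasing) and \code{cell_scores} (cells x components).
#' @export
pcaSummary <- function(x, n_components = 2, assay_name = NULL) {
    if (is(x, "SummarizedExperiment")) {
        if (is.null(assay_name))
            assay_name <- if ("corrected" %in% assayNames(x)) "corrected"
                          else "cpm"
        m <- assay(x, assay_name)
    } else m <- as.matrix(x)
    if (ncol(m) < 2) stop("need at least 2 cells")
    if (n_components > min(dim(m)))
        stop("n_components exceeds the matrix dimensions")
    L <- .log2cpm(m)
    Lc <- L - rowMeans(L)
    pc <- stats::prcomp(t(Lc), center = FALSE)
    fr <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    scores <- pc$x[, seq_len(n_components), drop = FALSE]
    rownames(scores) <- colnames(m)
    list(component_variance_fractions = fr[seq_len(n_components)],
         cell_scores = scores)
}
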