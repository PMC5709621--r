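#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assays assayNames colData
#'   colData<- rowData rowData<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

VALID_TREATMENTS <- c("SCR", "siTARGET")
VALID_DOSAGE <- c("SCR", "detectable", "undetectable")

#' Single-cell knockdown experiment container
#'
#' Extends \linkS4class{SingleCellExperiment}. The \code{"counts"} assay
#' holds raw non-negative integer counts (genes are rows, cells are
#' columns); QC, normalization and confounder correction add
#' \code{"cpm"} and \code{"corrected"} assays. Per-cell annotations live
#' in \code{colData}: \code{treatment} (\code{"SCR"} or
#' \code{"siTARGET"}), \code{batch}, and \code{dosage_group}
#' (\code{"SCR"}, \code{"detectable"}, \code{"undetectable"}, or
#' \code{NA} before assignment).
#'
#' @export
setClass("KnockdownExperiment", contains = "SingleCellExperiment")

.validKDE <- function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cts <- assay(object, "counts")
        if (anyNA(cts) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
        else if (any(cts != floor(cts)))
            msg <- c(msg, "counts must be integral")
    }
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and cell identifiers are required as dimnames")
    else {
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicate gene id")
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicate cell id")
    }
    cd <- colData(object)
    for (col in c("treatment", "batch", "dosage_group"))
        if (!(col %in% colnames(cd)))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (all(c("treatment", "dosage_group") %in% colnames(cd))) {
        tr <- as.character(cd$treatment)
        if (!all(tr %in% VALID_TREATMENTS))
            msg <- c(msg, "treatment must be 'SCR' or 'siTARGET'")
        dg <- as.character(cd$dosage_group)
        set <- !is.na(dg)
        if (!all(dg[set] %in% VALID_DOSAGE))
            msg <- c(msg, "dosage_group must be SCR/detectable/undetectable")
        bad <- set & ((dg == "SCR") != (tr == "SCR"))
        if (any(bad, na.rm = TRUE))
            msg <- c(msg, "dosage_group is 'SCR' if and only if treatment is 'SCR'")
    }
    if (length(msg)) msg else TRUE
}
setValidity("KnockdownExperiment", .validKDE)

#' Construct a KnockdownExperiment
#'
#' @param counts integer matrix, genes x cells, with unique dimnames.
#' @param treatment character vector, one of \code{"SCR"},
#'   \code{"siTARGET"} per cell.
#' @param batch character vector of batch labels per cell.
#' @param dosage_group optional character vector (\code{NA} = unset).
#' @param ... further arguments passed to
#'   \code{\link[SingleCellExperiment]{SingleCellExperiment}}.
#' @return A validated \linkS4class{KnockdownExperiment}.
#' @examples
#' m <- matrix(rpois(12, 4), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' kde <- KnockdownExperiment(m, treatment = c("SCR", "SCR", "siTARGET",
#'                            "siTARGET"), batch = c("b1", "b1", "b2", "b2"))
#' @export
KnockdownExperiment <- function(counts, treatment, batch,
                                dosage_group = NA_character_, ...) {
    counts <- as.matrix(counts)
    cd <- DataFrame(treatment = as.character(treatment),
                    batch = as.character(batch),
                    dosage_group = rep_len(as.character(dosage_group),
                                           ncol(counts)),
                    row.names = colnames(counts))
    sce <- SingleCellExperiment(assays = list(counts = counts),
                                colData = cd, ...)
    new("KnockdownExperiment", sce)
}

setMethod("show", "KnockdownExperiment", function(object) {
    callNextMethod()
    tr <- table(colData(object)$treatment)
    cat("treatment:", paste(names(tr), tr, sep = "=", collapse = " "), "\n")
    dg <- colData(object)$dosage_group
    if (!all(is.na(dg))) {
        tb <- table(dg, useNA = "no")
        cat("dosage_group:", paste(names(tb), tb, sep = "=", collapse = " "),
            "\n")
    }
})

#' Beta-Poisson distribution parameters
#'
#' Parameters of the beta-Poisson law: a Poisson count whose rate is
#' \code{rateScale * u} with \code{u ~ Beta(alpha, beta)}. Its mean is
#' \code{rateScale * alpha / (alpha + beta)}; \code{rateScale = 0} is the
#' point mass at zero.
#'
#' @slot alpha,beta positive Beta shape parameters.
#' @slot rateScale non-negative Poisson rate scale.
#' @export
setClass("BetaPoissonParams",
         representation(alpha = "numeric", beta = "numeric",
                        rateScale = "numeric"))

setValidity("BetaPoissonParams", function(object) {
    msg <- character()
    if (length(object@alpha) != 1 || !is.finite(object@alpha) ||
        object@alpha <= 0)
        msg <- c(msg, "alpha must be a single positive finite number")
    if (length(object@beta) != 1 || !is.finite(object@beta) ||
        object@beta <= 0)
        msg <- c(msg, "beta must be a single positive finite number")
    if (length(object@rateScale) != 1 || !is.finite(object@rateScale) ||
        object@rateScale < 0)
        msg <- c(msg, "rateScale must be a single non-negative finite number")
    if (length(msg)) msg else TRUE
})

#' @rdname BetaPoissonParams-class
#' @param alpha,beta positive Beta shape parameters.
#' @param rateScale non-negative Poisson rate scale.
#' @examples
#' bp <- BetaPoissonParams(alpha = 2, beta = 3, rateScale = 30)
#' bpMean(bp)  # 30 * 2/5 = 12
#' @export
BetaPoissonParams <- function(alpha, beta, rateScale) {
    new("BetaPoissonParams", alpha = as.numeric(alpha),
        beta = as.numeric(beta), rateScale = as.numeric(rateScale))
}

setMethod("show", "BetaPoissonParams", function(object) {
    cat(sprintf("BetaPoissonParams: alpha=%.4g beta=%.4g rateScale=%.4g (mean %.4g)\n",
                object@alpha, object@beta, object@rateScale, bpMean(object)))
})

#' @rdname BetaPoissonParams-class
#' @param params a \code{BetaPoissonParams} object.
#' @return \code{bpMean} returns the distribution mean.
#' @export
bpMean <- function(params) {
    stopifnot(is(params, "BetaPoissonParams"))
    params@rateScale * params@alpha / (params@alpha + params@beta)
}

#' Per-gene beta-Poisson GLM fit
#'
#' Result of \code{\link{fitBpGlm}} for one gene: coefficients on the
#' log-mean scale for an indicator design, fitted per-group means,
#' shared Beta shape parameters, and convergence diagnostics.
#'
#' @slot geneId gene identifier.
#' @slot coefficients named numeric, log-mean-scale coefficients.
#' @slot groupMeans named numeric, fitted mean per design cell-group.
#' @slot shapes numeric, \code{c(alpha, beta)} shared across cells.
#' @slot logLik maximized log-likelihood.
#' @slot converged logical convergence flag.
#' @slot nIter iteration count from the optimizer.
#' @slot boundary logical; \code{TRUE} when an all-zero design group was
#'   pinned at the documented mean floor.
#' @slot design character, design-matrix column names.
#' @export
setClass("GeneFitResult",
         representation(geneId = "character", coefficients = "numeric",
                        groupMeans = "numeric", shapes = "numeric",
                        logLik = "numeric", converged = "logical",
                        nIter = "integer", boundary = "logical",
                        design = "character"))

setMethod("show", "GeneFitResult", function(object) {
    cat("GeneFitResult for", object@geneId, "\n")
    cat("  coefficients:", paste(names(object@coefficients),
        sprintf("%.4g", object@coefficients), sep = "=", collapse = " "), "\n")
    cat(sprintf("  shapes: alpha=%.4g beta=%.4g  logLik=%.4f\n",
                object@shapes[1], object@shapes[2], object@logLik))
    cat(sprintf("  converged: %s (%d iterations)%s\n", object@converged,
                object@nIter, if (object@boundary) " [boundary_fit]" else ""))
})

#' Latent-factor model for cell-cycle/batch confounding
#'
#' A single-factor linear surrogate for latent-variable confounder
#' correction: per-cell factor scores (zero mean, unit variance)
#' estimated as the leading singular direction of treatment-protected
#' residuals of log2(CPM+1) expression on the cell-cycle gene panel.
#'
#' @slot factorScores named numeric, one standardized score per cell.
#' @slot geneLoadings named numeric, loading per cell-cycle gene.
#' @slot treatmentCoefficients matrix, protected-covariate coefficients
#'   (cell-cycle genes x covariates); never regressed out.
#' @slot protectedDesign the protected covariate matrix (cells x
#'   covariates, including intercept).
#' @slot varianceExplained fraction of residual variance on the panel
#'   explained by the factor.
#' @export
setClass("LatentFactorModel",
         representation(factorScores = "numeric", geneLoadings = "numeric",
                        treatmentCoefficients = "matrix",
                        protectedDesign = "matrix",
                        varianceExplained = "numeric"))

setValidity("LatentFactorModel", function(object) {
    s <- object@factorScores
    if (length(s) >= 2 &&
        (abs(mean(s)) > 1e-6 || abs(stats::sd(s) - 1) > 1e-6))
        return("factorScores must be standardized (zero mean, unit variance)")
    TRUE
})

setMethod("show", "LatentFactorModel", function(object) {
    cat(sprintf("LatentFactorModel: %d cells, %d panel genes, %.1f%% of residual panel variance\n",
                length(object@factorScores), length(object@geneLoadings),
                100 * object@varianceExplained))
})

#' Differential-expression results
#'
#' A \linkS4class{DFrame} of per-gene results for one design, with the
#' design name, FDR level and target gene carried alongside. Columns:
#' \code{gene_id}, per-coefficient p-values \code{p1}/\code{p2} (only
#' the three-group design has \code{p2}), \code{pvalue} (raw or
#' Fisher-combined), \code{qvalue}, \code{log2_fc} (primary contrast),
#' \code{log2_fc_detectable}/\code{log2_fc_undetectable} for the
#' three-group design, \code{direction}, \code{significant},
#' \code{converged}, \code{boundary}.
#'
#' @slot design one of \code{"two_group"}, \code{"three_group"},
#'   \code{"detectable_vs_undetectable"}.
#' @slot fdrLevel FDR level used for the \code{significant} flag.
#' @export
setClass("DEResults", contains = "DFrame",
         representation(design = "character", fdrLevel = "numeric"))

setValidity("DEResults", function(object) {
    msg <- character()
    if (!(object@design %in% c("two_group", "three_group",
                               "detectable_vs_undetectable")))
        msg <- c(msg, "unknown design")
    need <- c("gene_id", "pvalue", "qvalue", "log2_fc", "direction",
              "significant")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
    if ("significant" %in% colnames(object) && "qvalue" %in% colnames(object)) {
        ok <- is.na(object$qvalue) |
            (object$significant == (object$qvalue <= object@fdrLevel))
        if (!all(ok))
            msg <- c(msg, "significant flag must equal qvalue <= fdrLevel")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "DEResults", function(object) {
    cat(sprintf("DEResults [%s]: %d genes, %d significant at FDR %.3g\n",
                object@design, nrow(object),
                sum(object$significant, na.rm = TRUE), object@fdrLevel))
    callNextMethod()
})

#' @rdname DEResults-class
#' @param object a \code{DEResults} object.
#' @return \code{designName} returns the design label; \code{fdrLevel}
#'   the FDR level; \code{significantGenes} the significant gene ids.
#' @export
designName <- function(object) object@design

#' @rdname DEResults-class
#' @export
fdrLevel <- function(object) object@fdrLevel

#' @rdname DEResults-class
#' @export
significantGenes <- function(object) {
    object$gene_id[!is.na(object$significant) & object$significant]
}
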