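# Differential-expression designs, Fisher's-method combination, FDR,
# dosage grouping, overlap and direction-bias analyses.

#' Assign knockdown cells to dosage groups
#'
#' Uses raw (pre-correction) counts of the target gene: control cells
#' are \code{"SCR"}; knockdown cells with zero target counts are
#' \code{"undetectable"}, with positive counts \code{"detectable"}.
#'
#' @param x a \linkS4class{KnockdownExperiment}.
#' @param target_gene target gene id; defaults to
#'   \code{metadata(x)$target_gene}.
#' @return the object with \code{colData()$dosage_group} set.
#' @export
assignDosageGroups <- function(x, target_gene = metadata(x)$target_gene) {
    stopifnot(is(x, "KnockdownExperiment"))
    if (is.null(target_gene) || !(target_gene %in% rownames(x)))
        stop("target gene '", target_gene, "' is absent from the matrix")
    tgt <- assay(x, "counts")[target_gene, ]
    tr <- colData(x)$treatment
    dg <- ifelse(tr == "SCR", "SCR",
                 ifelse(tgt == 0, "undetectable", "detectable"))
    colData(x)$dosage_group <- dg
    validObject(x)
    x
}

#' Combine two p-values by Fisher's method
#'
#' \eqn{F^* = -2\log p_1 - 2\log p_2} referred to a chi-squared law
#' with four degrees of freedom; the combined p-value is its survival
#' function at \eqn{F^*}. Zeros are floored at 1e-300 with a warning.
#'
#' @param p1,p2 numeric vectors of p-values in [0, 1] (recycled).
#' @return a \linkS4class{DFrame} with columns \code{p1}, \code{p2},
#'   \code{statistic}, \code{df} and \code{p_combined}.
#' @examples
#' fisherCombine(0.05, 0.05)$p_combined  # ~0.01748
#' @export
fisherCombine <- function(p1, p2) {
    n <- max(length(p1), length(p2))
    p1 <- rep_len(as.numeric(p1), n)
    p2 <- rep_len(as.numeric(p2), n)
    bad <- function(p) any(!is.na(p) & (p < 0 | p > 1))
    if (bad(p1) || bad(p2)) stop("p-values must lie in [0, 1]")
    if (any(p1 == 0 | p2 == 0, na.rm = TRUE)) {
        warning("zero p-value(s) floored at 1e-300")
        p1 <- pmax(p1, 1e-300)
        p2 <- pmax(p2, 1e-300)
    }
    stat <- -2 * log(p1) - 2 * log(p2)
    DataFrame(p1 = p1, p2 = p2, statistic = stat, df = 4L,
              p_combined = pchisq(stat, df = 4, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. Missing p-values are excluded from the
#' adjustment (they keep \code{NA} q-values) and their count is
#' attached as attribute \code{n_missing}.
#'
#' @param p numeric vector of p-values in [0, 1], \code{NA} allowed.
#' @return numeric vector of q-values, same length and order.
#' @export
fdrAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    attr(q, "n_missing") <- sum(!ok)
    q
}

# ---- shared worker for the three designs ---------------------------------

# Pick the matrix to fit: rounded corrected values when present, else
# rounded CPM, else raw counts. round() is round-half-to-even.
.fitValues <- function(x) {
    if (!is(x, "SummarizedExperiment"))
        return(list(values = round(as.matrix(x)), assay = "matrix"))
    nm <- if ("corrected" %in% assayNames(x)) "corrected"
          else if ("cpm" %in% assayNames(x)) "cpm" else "counts"
    list(values = round(assay(x, nm)), assay = nm)
}

.direction <- function(lfc) ifelse(!is.na(lfc) & lfc > 0, "up", "down")

.newDEResults <- function(df, design, fdr_level) {
    df$qvalue <- as.numeric(fdrAdjust(df$pvalue))
    df$significant <- !is.na(df$qvalue) & df$qvalue <= fdr_level
    res <- new("DEResults", DataFrame(df), design = design,
               fdrLevel = fdr_level)
    validObject(res)
    res
}

#' Two-group differential expression (control vs knockdown)
#'
#' Per gene: beta-Poisson GLM with intercept and knockdown indicator;
#' the indicator coefficient is tested by likelihood ratio, q-values
#' are Benjamini-Hochberg, and direction follows the sign of the
#' knockdown coefficient (ties count as down). Values fitted are the
#' rounded corrected matrix when present (else rounded CPM, else raw
#' counts). Per-gene fit failures are reported as \code{NA} p-values,
#' never dropped.
#'
#' @param x a \linkS4class{KnockdownExperiment}.
#' @param fdr_level FDR level for the significance flag (default 0.05).
#' @param verbose print a progress line every 500 genes.
#' @return a \linkS4class{DEResults}.
#' @export
runTwoGroupDesign <- function(x, fdr_level = 0.05, verbose = FALSE) {
    stopifnot(is(x, "KnockdownExperiment"))
    tr <- colData(x)$treatment
    if (sum(tr == "SCR") < 2 || sum(tr == "siTARGET") < 2)
        stop("underpowered design: both groups need at least 2 cells")
    fv <- .fitValues(x)
    X <- makeDesignMatrix(tr)
    .runIndicatorDesign(fv$values, X, tested = "I_siTARGET",
                        design = "two_group", fdr_level = fdr_level,
                        verbose = verbose)
}

#' Three-group (dosage) differential expression
#'
#' Per gene: beta-Poisson GLM with intercept, detectable-knockdown and
#' undetectable-knockdown indicators. Each indicator is tested by
#' likelihood ratio; the two p-values are combined by Fisher's method
#' (chi-squared, 4 df) and q-values are computed on the combined
#' p-value. Direction follows the undetectable-group contrast. When the
#' detectable group is empty the design degenerates and the two-group
#' analysis is run instead, with a warning.
#'
#' @inheritParams runTwoGroupDesign
#' @return a \linkS4class{DEResults}.
#' @export
runThreeGroupDesign <- function(x, fdr_level = 0.05, verbose = FALSE) {
    stopifnot(is(x, "KnockdownExperiment"))
    dg <- colData(x)$dosage_group
    if (any(is.na(dg)))
        stop("dosage groups are unset; run assignDosageGroups() first")
    if (sum(dg == "detectable") == 0) {
        warning("no detectable-knockdown cells: three-group design ",
                "degenerates; running the two-group design (the ",
                "detectable-group coefficient is absent)")
        return(runTwoGroupDesign(x, fdr_level, verbose))
    }
    if (sum(dg == "SCR") < 2 || sum(dg == "detectable") < 2 ||
        sum(dg == "undetectable") < 2)
        stop("underpowered design: all three dosage groups need >= 2 cells")
    fv <- .fitValues(x)
    X <- makeDesignMatrix(colData(x)$treatment, dg)
    .runIndicatorDesign(fv$values, X,
                        tested = c("I_siTARGET_detectable",
                                   "I_siTARGET_undetectable"),
                        design = "three_group", fdr_level = fdr_level,
                        verbose = verbose)
}

#' Detectable vs undetectable knockdown cells
#'
#' Two-group beta-Poisson fit restricted to knockdown cells, with the
#' indicator marking undetectable (zero target count) cells.
#'
#' @inheritParams runTwoGroupDesign
#' @return a \linkS4class{DEResults}.
#' @export
runDetectableVsUndetectable <- function(x, fdr_level = 0.05,
                                        verbose = FALSE) {
    stopifnot(is(x, "KnockdownExperiment"))
    dg <- colData(x)$dosage_group
    if (any(is.na(dg)))
        stop("dosage groups are unset; run assignDosageGroups() first")
    kd <- x[, dg != "SCR"]
    dgk <- colData(kd)$dosage_group
    if (sum(dgk == "detectable") < 2 || sum(dgk == "undetectable") < 2)
        stop("statistically underpowered: both knockdown subgroups ",
             "need at least 2 cells")
    fv <- .fitValues(kd)
    X <- cbind(intercept = 1,
               I_siTARGET_undetectable = as.numeric(dgk == "undetectable"))
    .runIndicatorDesign(fv$values, X, tested = "I_siTARGET_undetectable",
                        design = "detectable_vs_undetectable",
                        fdr_level = fdr_level, verbose = verbose)
}

.runIndicatorDesign <- function(values, X, tested, design, fdr_level,
                                verbose = FALSE) {
    genes <- rownames(values)
    n <- length(genes)
    p_mat <- matrix(NA_real_, n, length(tested))
    lfc_mat <- matrix(NA_real_, n, length(tested))
    converged <- logical(n)
    boundary <- logical(n)
    for (i in seq_len(n)) {
        y <- values[i, ]
        fit <- fitBpGlm(y, X, gene_id = genes[i])
        converged[i] <- fit@converged
        boundary[i] <- fit@boundary
        lfc_mat[i, ] <- fit@coefficients[tested] / log(2)
        for (j in seq_along(tested)) {
            pj <- testCoefficient(fit, tested[j], y, X)
            p_mat[i, j] <- as.numeric(pj)
        }
        if (verbose && i %% 500 == 0)
            message("  fitted ", i, "/", n, " genes")
    }
    if (design == "three_group") {
        comb <- fisherCombine(p_mat[, 1], p_mat[, 2])
        df <- DataFrame(gene_id = genes, p1 = p_mat[, 1], p2 = p_mat[, 2],
                        pvalue = comb$p_combined,
                        log2_fc = lfc_mat[, 2],
                        log2_fc_detectable = lfc_mat[, 1],
                        log2_fc_undetectable = lfc_mat[, 2],
                        direction = .direction(lfc_mat[, 2]),
                        converged = converged, boundary = boundary)
    } else {
        df <- DataFrame(gene_id = genes, p1 = p_mat[, 1], p2 = NA_real_,
                        pvalue = p_mat[, 1], log2_fc = lfc_mat[, 1],
                        direction = .direction(lfc_mat[, 1]),
                        converged = converged, boundary = boundary)
    }
    .newDEResults(df, design, fdr_level)
}

#' Overlap (Venn) summary of the three analyses
#'
#' Exact set intersections of significant genes by id; the reported
#' counts satisfy inclusion-exclusion identities by construction.
#'
#' @param two_group,three_group,det_vs_undet \linkS4class{DEResults}
#'   from the three designs, over the same gene universe.
#' @return list with the per-design significant sets, all pairwise and
#'   triple intersection counts, the seven disjoint Venn region counts,
#'   and the ids of genes significant in all three analyses.
#' @export
overlapSets <- function(two_group, three_group, det_vs_undet) {
    res <- list(two_group = two_group, three_group = three_group,
                detectable_vs_undetectable = det_vs_undet)
    uni <- lapply(res, function(r) sort(r$gene_id))
    if (!all(vapply(uni[-1], identical, logical(1), y = uni[[1]])))
        stop("the three analyses must share one gene universe")
    sets <- lapply(res, significantGenes)
    A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
    regions <- c(
        only_two_group = length(setdiff(setdiff(A, B), C)),
        only_three_group = length(setdiff(setdiff(B, A), C)),
        only_det_vs_undet = length(setdiff(setdiff(C, A), B)),
        two_and_three_only = length(setdiff(intersect(A, B), C)),
        two_and_det_only = length(setdiff(intersect(A, C), B)),
        three_and_det_only = length(setdiff(intersect(B, C), A)),
        all_three = length(intersect(intersect(A, B), C)))
    list(sets = sets,
         sizes = vapply(sets, length, integer(1)),
         pairwise = c(two_and_three = length(intersect(A, B)),
                      two_and_det = length(intersect(A, C)),
                      three_and_det = length(intersect(B, C))),
         triple = length(intersect(intersect(A, B), C)),
         regions = regions,
         genes_in_all = sort(intersect(intersect(A, B), C)))
}

#' Direction-bias contingency test
#'
#' Builds the 2x2 table (DEG / non-DEG) x (down / up) from a result set
#' and returns the two-sided Fisher exact p-value (summing
#' hypergeometric outcomes no more probable than the observed table).
#' Exact fold-change ties count as down.
#'
#' @param deres a \linkS4class{DEResults} covering all analyzed genes.
#' @return list with \code{table} (2x2 integer matrix) and
#'   \code{p_value}; a zero margin gives \code{p_value = 1} with a
#'   warning.
#' @export
directionBiasTest <- function(deres) {
    stopifnot(is(deres, "DEResults"))
    deg <- factor(ifelse(deres$significant, "DEG", "non-DEG"),
                  levels = c("DEG", "non-DEG"))
    dir <- factor(deres$direction, levels = c("down", "up"))
    tab <- table(deg, dir)
    tab <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("a zero margin: direction-bias test is degenerate, p = 1")
        return(list(table = tab, p_value = 1))
    }
    list(table = tab,
         p_value = stats::fisher.test(tab, alternative = "two.sided")$p.value)
}
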