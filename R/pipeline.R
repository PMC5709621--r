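# End-to-end pipeline driver: filter -> normalize -> outlier removal ->
# confounder correction -> dosage grouping -> designs -> FDR -> overlap.

.logStage <- function(verbose, stage, x, extra = "") {
    if (verbose)
        message(sprintf("[%s] genes=%d cells=%d %s", stage, nrow(x),
                        ncol(x), extra))
}

#' Run the full differential-expression pipeline
#'
#' Executes detection-rate filtering, CPM normalization, outlier-cell
#' removal, latent-factor confounder correction, dosage grouping on raw
#' counts, the three differential-expression designs, FDR, the overlap
#' summary, and the direction-bias test. Emits one structured log line
#' per stage and a machine-readable run report (per-stage dimensions,
#' seed, configuration echo).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param x a \linkS4class{KnockdownExperiment} whose annotations cover
#'   every cell.
#' @param correct run the confounder correction (default \code{TRUE};
#'   requires a cell-cycle panel from
#'   \code{config$cell_cycle_gene_file} or the object metadata).
#' @param verbose print one structured line per stage.
#' @return list with \code{kde} (the processed object),
#'   \code{results} (named list of \linkS4class{DEResults}),
#'   \code{overlap}, \code{direction_bias}, \code{factor_model} and
#'   \code{report}.
#' @export
runPipeline <- function(config, x, correct = TRUE, verbose = TRUE) {
    stopifnot(inherits(config, "PipelineConfig"),
              is(x, "KnockdownExperiment"))
    set.seed(config$seed)
    if (verbose) message("[config] seed=", config$seed)
    stages <- list()
    errors <- character()
    note <- function(stage, obj)
        stages[[length(stages) + 1]] <<- data.frame(
            stage = stage, n_genes = nrow(obj), n_cells = ncol(obj))
    note("input", x)

    x <- filterByDetection(x, config$detection_threshold)
    .logStage(verbose, "filter", x,
              sprintf("threshold=%g", config$detection_threshold))
    note("detection_filter", x)

    tr <- colData(x)$treatment
    if (sum(tr == "SCR") < 2 || sum(tr == "siTARGET") < 2)
        stop("underpowered design: fewer than 2 cells in a required ",
             "group after filtering")

    x <- normalizeCPM(x, config$cpm_scale)
    .logStage(verbose, "normalize", x, sprintf("scale=%g", config$cpm_scale))
    note("cpm_normalize", x)

    out_ids <- flagOutlierCells(x, config$outlier_max_gene_fraction)
    if (length(out_ids)) x <- x[, !(colnames(x) %in% out_ids)]
    .logStage(verbose, "outliers", x,
              sprintf("removed=%d", length(out_ids)))
    note("outlier_removal", x)

    model <- NULL
    if (correct) {
        panel <- if (!is.na(config$cell_cycle_gene_file)) {
            loadCellCycleGenes(config$cell_cycle_gene_file,
                               rownames(x))$matched
        } else {
            intersect(metadata(x)$cell_cycle_genes, rownames(x))
        }
        if (length(panel) >= 5) {
            L <- .log2cpm(assay(x, "cpm")[panel, , drop = FALSE])
            model <- fitLatentFactor(L, makeDesignMatrix(
                colData(x)$treatment))
            x <- regressOutFactor(x, model)
            .logStage(verbose, "correct", x,
                      sprintf("panel=%d varexp=%.3f", length(panel),
                              model@varianceExplained))
        } else {
            errors <- c(errors, "confounder correction skipped: no usable cell-cycle panel")
            if (verbose) message("[correct] skipped: no usable panel")
        }
    }
    note("confounder_correction", x)

    x <- assignDosageGroups(x, config$target_gene)
    dg <- colData(x)$dosage_group
    group_sizes <- c(SCR = sum(dg == "SCR"),
                     detectable = sum(dg == "detectable"),
                     undetectable = sum(dg == "undetectable"))
    if (verbose)
        message(sprintf("[dosage] SCR=%d detectable=%d undetectable=%d",
                        group_sizes[1], group_sizes[2], group_sizes[3]))

    results <- list()
    results$two_group <- runTwoGroupDesign(x, config$fdr_level,
                                           verbose = verbose)
    if (verbose) message("[de:two_group] significant=",
                         sum(results$two_group$significant))
    results$three_group <- tryCatch(
        runThreeGroupDesign(x, config$fdr_level, verbose = verbose),
        error = function(e) {
            errors <<- c(errors, paste("three_group:", conditionMessage(e)))
            NULL
        })
    results$detectable_vs_undetectable <- tryCatch(
        runDetectableVsUndetectable(x, config$fdr_level, verbose = verbose),
        error = function(e) {
            errors <<- c(errors, paste("detectable_vs_undetectable:",
                                       conditionMessage(e)))
            NULL
        })
    results <- Filter(Negate(is.null), results)

    overlap <- NULL
    if (all(c("two_group", "three_group", "detectable_vs_undetectable")
            %in% names(results)) &&
        results$three_group@design == "three_group")
        overlap <- overlapSets(results$two_group, results$three_group,
                               results$detectable_vs_undetectable)
    dirtest <- directionBiasTest(results$two_group)

    report <- list(
        seed = config$seed,
        config = unclass(config),
        stages = do.call(rbind, stages),
        outlier_cells = out_ids,
        group_sizes = group_sizes,
        n_significant = vapply(results, function(r)
            sum(r$significant, na.rm = TRUE), integer(1)),
        overlap_counts = if (!is.null(overlap))
            c(overlap$pairwise, triple = overlap$triple) else NULL,
        direction_bias_p = dirtest$p_value,
        errors = errors,
        n_stage_errors = length(errors))

    list(kde = x, results = results, overlap = overlap,
         direction_bias = dirtest, factor_model = model, report = report)
}

#' Write the run report as JSON
#'
#' @param report the \code{report} element of \code{\link{runPipeline}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRunReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, force = TRUE)
    invisible(path)
}
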