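# Synthetic knockdown-dosage single-cell datasets with known truth.
#
# Counts are drawn from the per-gene beta-Poisson model with per-cell
# library-size scaling. A designated target gene hits prescribed CPM
# means in control and detectable-knockdown cells and is structurally
# zero in undetectable-knockdown cells. A latent batch-linked factor
# loads multiplicatively on a designated cell-cycle gene panel.
# Differential expression is planted multiplicatively on knockdown
# group means, majority-down, with a dosage-monotone sub-class whose
# effect deepens as target expression falls.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 46 control (SCR) cells in two
#' batches, 20 detectable- and 25 undetectable-knockdown cells in one
#' batch, target-gene CPM means of 101.6 (SCR) and 37.7 (detectable),
#' structural zeros in undetectable cells, 72 percent of planted DE
#' genes down-regulated, and library sizes log-uniform on 0.5-1.5
#' million reads.
#'
#' @param n_scr,n_detectable,n_undetectable cells per dosage group.
#' @param n_genes total genes, including the target.
#' @param frac_de fraction of non-target genes with planted DE.
#' @param frac_down_among_de fraction of DE genes that are
#'   down-regulated.
#' @param lfc_magnitude length-2 range of |log2 fold change| for planted
#'   DE genes (drawn uniformly).
#' @param frac_monotone_among_de fraction of DE genes whose effect is
#'   dosage-monotone (half-strength in detectable cells).
#' @param target_gene id of the knocked-down target gene.
#' @param target_scr_cpm,target_detectable_cpm target-gene mean CPM in
#'   SCR and detectable-knockdown cells.
#' @param library_size_range length-2 range of per-cell library sizes
#'   (reads), sampled log-uniformly.
#' @param confounder_strength standard deviations of the multiplicative
#'   (log2-scale) latent-factor effect on panel genes.
#' @param frac_cell_cycle fraction of genes in the cell-cycle panel.
#' @param n_batches number of batches (the study structure: two SCR
#'   batches plus one knockdown batch).
#' @param seed integer seed; the same configuration and seed reproduce
#'   the dataset exactly.
#' @return a validated configuration list of class
#'   \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_scr = 46, n_detectable = 20,
                             n_undetectable = 25, n_genes = 2000,
                             frac_de = 0.1, frac_down_among_de = 0.72,
                             lfc_magnitude = c(1, 3),
                             frac_monotone_among_de = 0.1,
                             target_gene = "TARGET",
                             target_scr_cpm = 101.6,
                             target_detectable_cpm = 37.7,
                             library_size_range = c(5e5, 1.5e6),
                             confounder_strength = 1,
                             frac_cell_cycle = 0.1,
                             n_batches = 3, seed = 1) {
    cfg <- list(n_scr = n_scr, n_detectable = n_detectable,
                n_undetectable = n_undetectable, n_genes = n_genes,
                frac_de = frac_de, frac_down_among_de = frac_down_among_de,
                lfc_magnitude = lfc_magnitude,
                frac_monotone_among_de = frac_monotone_among_de,
                target_gene = target_gene, target_scr_cpm = target_scr_cpm,
                target_detectable_cpm = target_detectable_cpm,
                library_size_range = library_size_range,
                confounder_strength = confounder_strength,
                frac_cell_cycle = frac_cell_cycle,
                n_batches = n_batches, seed = seed)
    with(cfg, {
        stopifnot(n_scr >= 0, n_detectable >= 0, n_undetectable >= 0,
                  n_genes >= 2,
                  frac_de >= 0, frac_de <= 1,
                  frac_down_among_de >= 0, frac_down_among_de <= 1,
                  frac_monotone_among_de >= 0, frac_monotone_among_de <= 1,
                  length(lfc_magnitude) == 2, all(lfc_magnitude > 0),
                  all(library_size_range > 0),
                  length(library_size_range) == 2,
                  target_scr_cpm > 0, target_detectable_cpm > 0,
                  confounder_strength >= 0,
                  frac_cell_cycle >= 0, frac_cell_cycle <= 1)
    })
    structure(cfg, class = "SimulationConfig")
}

#' @rdname simulationConfig
#' @details \code{paperEmulationPreset} returns the configuration at the
#'   study's scale: 15,351 genes, dosage groups of 46/20/25 cells,
#'   three batches, majority-down DE planting.
#' @export
paperEmulationPreset <- function() {
    simulationConfig(n_genes = 15351)
}

#' Generate a synthetic knockdown-dosage dataset
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{kde} (a \linkS4class{KnockdownExperiment};
#'   dosage groups unset, the generator's group memberships recoverable
#'   from the truth metadata), \code{truth} (per-gene
#'   \linkS4class{DFrame}: \code{is_de}, true log2 fold changes per
#'   dosage group, cell-cycle panel flag, baseline beta-Poisson
#'   parameters) and \code{cell_truth} (per-cell simulated group and
#'   factor value). The target gene id and panel gene ids are stored in
#'   \code{metadata(kde)}.
#' @examples
#' sim <- generateDataset(simulationConfig(n_genes = 100, seed = 7))
#' sim$kde
#' @export
generateDataset <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (config$n_batches != 3)
        warning("the generator emulates the study's 3-batch structure; ",
                "n_batches is recorded but 3 batches are produced")
    set.seed(config$seed)
    n_cells <- config$n_scr + config$n_detectable + config$n_undetectable
    stopifnot(n_cells >= 1)
    grp <- rep(c("SCR", "detectable", "undetectable"),
               c(config$n_scr, config$n_detectable, config$n_undetectable))
    cell_ids <- sprintf("cell%03d", seq_len(n_cells))
    # two SCR batches, one knockdown batch, as in the study
    batch <- ifelse(grp == "SCR",
                    rep(c("SCR1", "SCR2"), length.out = config$n_scr)[
                        cumsum(grp == "SCR")],
                    "KD1")
    treatment <- ifelse(grp == "SCR", "SCR", "siTARGET")

    ng <- config$n_genes
    gene_ids <- c(config$target_gene,
                  sprintf("G%05d", seq_len(ng - 1)))
    # baseline gene parameters (target is row 1, parameterized below).
    # Mean CPM is heavy-tailed with a low median (most genes near the
    # dropout regime) and averages one million over 15,351 genes, the
    # study's post-filter transcriptome, independent of n_genes so that
    # per-gene expression magnitudes stay at the study's scale in
    # scaled-down simulations.
    alpha <- c(2, stats::runif(ng - 1, 0.2, 1.5))
    beta <- c(1, stats::runif(ng - 1, 1, 5))
    cpm_per_gene <- (1e6 - config$target_scr_cpm) / 15350
    base_cpm <- stats::rlnorm(ng - 1, meanlog = log(2), sdlog = 3.0)
    # cap the top gene at ~1.5% of the transcriptome's mass (15,000 CPM
    # at the full 15,351-gene scale) so scaled-down simulations keep
    # the study's composition structure
    base_cpm <- base_cpm * cpm_per_gene / mean(base_cpm)
    base_cpm <- pmin(base_cpm, 0.015 * cpm_per_gene * (ng - 1))
    base_cpm <- base_cpm * cpm_per_gene / mean(base_cpm)
    mean_cpm <- c(config$target_scr_cpm, base_cpm)

    # planted DE among non-target genes
    is_de <- c(FALSE, stats::runif(ng - 1) < config$frac_de)
    if (config$frac_de == 0 && config$frac_down_among_de > 0)
        warning("frac_de = 0: the DE set is empty, ",
                "frac_down_among_de has no effect")
    sign_de <- ifelse(stats::runif(ng) < config$frac_down_among_de, -1, 1)
    mag <- stats::runif(ng, config$lfc_magnitude[1], config$lfc_magnitude[2])
    monotone <- is_de & (stats::runif(ng) < config$frac_monotone_among_de)
    lfc_undet <- ifelse(is_de, sign_de * mag, 0)
    lfc_det <- ifelse(is_de, ifelse(monotone, 0.5, 1) * lfc_undet, 0)

    # cell-cycle panel: non-target, non-DE genes from the upper half of
    # the expression distribution (annotated cell-cycle genes that
    # survive detection filtering are well expressed)
    panel_pool <- setdiff(which(!is_de & mean_cpm > stats::median(mean_cpm)),
                          1L)
    n_panel <- round(config$frac_cell_cycle * ng)
    panel <- sort(sample(panel_pool, min(n_panel, length(panel_pool))))
    is_cc <- rep(FALSE, ng)
    is_cc[panel] <- TRUE
    loadings <- stats::runif(ng, 0.5, 1.5) * is_cc

    # batch-linked latent factor, standardized across cells
    offs <- c(SCR1 = 1, SCR2 = -1, KD1 = 0)
    f <- offs[batch] + stats::rnorm(n_cells, 0, 0.5)
    f <- (f - mean(f)) / stats::sd(f)

    libsize <- exp(stats::runif(n_cells, log(config$library_size_range[1]),
                                log(config$library_size_range[2])))
    s <- libsize / 1e6

    # per-gene, per-cell mean CPM
    lfc_cell <- matrix(0, ng, n_cells)
    lfc_cell[, grp == "detectable"] <- lfc_det
    lfc_cell[, grp == "undetectable"] <- lfc_undet
    mu <- mean_cpm * 2^(lfc_cell +
                        config$confounder_strength *
                            outer(loadings, f))
    mu[1, grp == "detectable"] <- config$target_detectable_cpm
    mu[1, grp == "undetectable"] <- 0
    mu <- sweep(mu, 2, s, "*")

    lambda <- mu * (alpha + beta) / alpha
    u <- matrix(stats::rbeta(ng * n_cells, alpha, beta), ng, n_cells)
    counts <- matrix(stats::rpois(ng * n_cells, lambda * u), ng, n_cells)
    # the detectable group is defined by positive target counts:
    # enforce by truncation at 1 (the mean shift is negligible)
    det <- which(grp == "detectable")
    counts[1, det] <- pmax(counts[1, det], 1L)
    counts[1, grp == "undetectable"] <- 0L
    dimnames(counts) <- list(gene_ids, cell_ids)

    kde <- KnockdownExperiment(counts, treatment = treatment, batch = batch)
    metadata(kde)$target_gene <- config$target_gene
    metadata(kde)$cell_cycle_genes <- gene_ids[is_cc]
    metadata(kde)$simulation_seed <- config$seed
    # CPM are defined relative to the simulated transcriptome's nominal
    # total (one million only at the full 15,351-gene scale)
    metadata(kde)$nominal_cpm_total <- sum(mean_cpm)

    truth <- DataFrame(gene_id = gene_ids, is_de = is_de,
                       true_lfc_detectable = lfc_det,
                       true_lfc_undetectable = lfc_undet,
                       is_dosage_monotone = monotone,
                       is_cell_cycle = is_cc,
                       baseline_alpha = alpha, baseline_beta = beta,
                       baseline_mean_cpm = mean_cpm,
                       row.names = gene_ids)
    cell_truth <- DataFrame(cell_id = cell_ids, group = grp, batch = batch,
                            factor_value = f, library_size = libsize,
                            row.names = cell_ids)
    list(kde = kde, truth = truth, cell_truth = cell_truth)
}
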