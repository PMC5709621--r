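# Latent-factor confounder correction and PCA diagnostics.

# build a log-expression matrix with a planted factor and optional
# treatment effect on a gene panel; orthogonal = TRUE removes any chance
# correlation between the factor and the treatment indicator
plantedPanel <- function(n_genes = 100, n_cells = 90, strength = 1,
                         treat_effect = 0, seed = 61, orthogonal = FALSE) {
    set.seed(seed)
    f <- rnorm(n_cells)
    tr <- rep(c("SCR", "siTARGET"), length.out = n_cells)
    if (orthogonal)
        f <- residuals(lm(f ~ as.numeric(tr == "siTARGET")))
    f <- (f - mean(f)) / sd(f)
    load <- runif(n_genes, 0.5, 1.5)
    base <- runif(n_genes, 2, 8)
    L <- base + strength * outer(load, f) +
        treat_effect * outer(rep(1, n_genes), as.numeric(tr == "siTARGET")) +
        matrix(rnorm(n_genes * n_cells, 0, 0.5), n_genes, n_cells)
    dimnames(L) <- list(sprintf("cc%03d", 1:n_genes),
                        sprintf("cell%03d", 1:n_cells))
    list(L = L, f = f, tr = tr, X = makeDesignMatrix(tr))
}

test_that("panel loading matches gene ids case-sensitively", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(sprintf("CCG%05d", 1:189), path)
    ids <- c(sprintf("CCG%05d", 1:102), sprintf("OTHER%03d", 1:50))
    cc <- loadCellCycleGenes(path, ids)
    expect_equal(cc$n_matched, 102)
    expect_equal(length(cc$gene_ids), 189)
    cc2 <- loadCellCycleGenes(path, sprintf("CCG%05d", 1:189))
    expect_equal(cc2$n_matched, 189)
    expect_error(loadCellCycleGenes(path, tolower(ids)), "no cell-cycle")
})

test_that("the planted factor is recovered from protected residuals", {
    pp <- plantedPanel(strength = 1, treat_effect = 0)
    m <- fitLatentFactor(pp$L, pp$X)
    expect_gt(abs(cor(m@factorScores, pp$f)), 0.9)
    expect_lt(abs(mean(m@factorScores)), 1e-8)
    expect_equal(sd(m@factorScores), 1, tolerance = 1e-8)
})

test_that("constant expression across cells is a rank-0 error", {
    L <- matrix(3, 10, 8, dimnames = list(paste0("g", 1:10),
                                          paste0("c", 1:8)))
    X <- makeDesignMatrix(rep(c("SCR", "siTARGET"), each = 4))
    expect_error(fitLatentFactor(L, X), "rank 0")
})

test_that("treatment coefficients are null when the factor is orthogonal to treatment", {
    pp <- plantedPanel(strength = 1.5, treat_effect = 0, seed = 62,
                       orthogonal = TRUE)
    m <- fitLatentFactor(pp$L, pp$X)
    cf <- m@treatmentCoefficients[, "I_siTARGET"]
    # residual noise is sd 0.5; the coefficient of a balanced indicator
    # over 90 cells has se = 0.5 * sqrt(2/45)
    se <- 0.5 * sqrt(1 / 45 + 1 / 45)
    expect_lt(max(abs(cf)), 3 * se)
})

test_that("genes carrying no factor signal pass through unchanged", {
    pp <- plantedPanel(n_genes = 100, n_cells = 90, strength = 0, seed = 63)
    m <- fitLatentFactor(pp$L, pp$X)
    # constant genes have zero factor loading: exact pass-through
    cpm_const <- matrix(rep(c(3, 8, 1, 0), 90 / 2 * 2), 4, 90,
                        dimnames = list(paste0("k", 1:4), colnames(pp$L)))
    expect_equal(regressOutFactor(cpm_const, m), cpm_const,
                 tolerance = 1e-8)
    # with no planted confounder the whole matrix barely moves
    cpm <- 2^pp$L - 1
    corrected <- regressOutFactor(cpm, m)
    expect_lt(norm(log2(corrected + 1) - pp$L, "F") / norm(pp$L, "F"),
              0.05)
    # cell mismatch is a hard error
    expect_error(regressOutFactor(cpm[, 1:6], m), "do not match")
})

test_that("correction removes planted confounder variance but preserves treatment signal", {
    set.seed(64)
    n_genes <- 300; n_cells <- 150
    pp <- plantedPanel(n_genes = 80, n_cells = n_cells, strength = 1.2,
                       seed = 64)
    # full matrix: panel genes confounded, the rest clean, some treated
    tr_ind <- as.numeric(pp$tr == "siTARGET")
    base <- runif(n_genes, 2, 8)
    lfc <- ifelse(seq_len(n_genes) <= 50, 1, 0)  # planted treatment LFC
    L_rest <- base + outer(lfc, tr_ind) +
        matrix(rnorm(n_genes * n_cells, 0, 0.4), n_genes, n_cells)
    dimnames(L_rest) <- list(sprintf("g%04d", 1:n_genes), colnames(pp$L))
    L_all <- rbind(pp$L, L_rest)
    cpm <- 2^L_all - 1
    model <- fitLatentFactor(pp$L, pp$X)
    corrected <- regressOutFactor(cpm, model)
    expect_identical(dim(corrected), dim(cpm))
    # factor-attributable variance on the panel drops by >= 80%
    Lc <- log2(corrected + 1)
    r2 <- function(M) {
        v <- apply(M[rownames(pp$L), ], 1, function(g)
            summary(lm(g ~ pp$f + tr_ind))$coefficients["pp$f", 1]^2)
        mean(v)
    }
    expect_lt(r2(Lc), 0.2 * r2(L_all))
    # treatment log-ratios move by < 0.1 log2 units on average
    gm <- function(M) rowMeans(M[, tr_ind == 1]) - rowMeans(M[, tr_ind == 0])
    shift <- abs(gm(Lc[rownames(L_rest), ]) - gm(L_rest))
    expect_lt(mean(shift), 0.1)
    # near-idempotence on the model's native log scale: a refitted
    # factor finds only residual noise, so re-correcting changes little
    model2 <- fitLatentFactor(Lc[rownames(pp$L), ], pp$X)
    corrected2 <- regressOutFactor(corrected, model2)
    expect_lt(norm(log2(corrected2 + 1) - Lc, "F") / norm(Lc, "F"), 0.01)
})

test_that("PCA summary reports non-increasing percentages and permutation invariance", {
    set.seed(65)
    cpm <- matrix(rpois(50 * 12, 30), 50, 12,
                  dimnames = list(paste0("g", 1:50), paste0("c", 1:12)))
    s <- pcaSummary(cpm, 3)
    fr <- s$component_variance_fractions
    expect_true(all(diff(fr) <= 1e-9))
    expect_lte(sum(fr), 100 + 1e-6)
    perm <- sample(12)
    s2 <- pcaSummary(cpm[, perm], 3)
    expect_equal(s2$component_variance_fractions, fr, tolerance = 1e-8)
    expect_error(pcaSummary(cpm, 40), "exceeds")
    # one direction of variation: first component takes 100%
    one <- outer(seq_len(20), c(rep(1, 5), rep(3, 5)))
    dimnames(one) <- list(paste0("g", 1:20), paste0("c", 1:10))
    s3 <- pcaSummary(2^one - 1, 2)
    expect_equal(s3$component_variance_fractions[1], 100, tolerance = 1e-6)
})

test_that("correction turns the leading axis from batch to treatment", {
    sim <- generateDataset(simulationConfig(n_genes = 600, frac_de = 0.05,
                                            confounder_strength = 1.5,
                                            seed = 66))
    kde <- filterByDetection(sim$kde, 0.05)
    kde <- normalizeCPM(kde)
    panel <- intersect(S4Vectors::metadata(kde)$cell_cycle_genes,
                       rownames(kde))
    L <- log2(SummarizedExperiment::assay(kde, "cpm")[panel, ] + 1)
    X <- makeDesignMatrix(SummarizedExperiment::colData(kde)$treatment)
    model <- fitLatentFactor(L, X)
    corrected <- regressOutFactor(kde, model)
    pb <- function(scores, lab) abs(cor(scores, as.numeric(lab)))
    cd <- SummarizedExperiment::colData(kde)
    scr <- cd$treatment == "SCR"
    batch_lab <- ifelse(cd$batch == "SCR1", 1, 0)
    treat_lab <- as.numeric(cd$treatment == "siTARGET")
    before <- pcaSummary(kde, 2, assay_name = "cpm")
    after <- pcaSummary(corrected, 2, assay_name = "corrected")
    # before: PC1 tracks the batch split among SCR cells
    expect_gt(pb(before$cell_scores[scr, 1], batch_lab[scr]), 0.8)
    # after: PC1 separates treatment better than it separates batch
    expect_gt(pb(after$cell_scores[, 1], treat_lab),
              pb(after$cell_scores[scr, 1], batch_lab[scr]))
})
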