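# Dosage grouping, Fisher combination, FDR, overlap, direction bias.

test_that("dosage groups follow the zero-count definition on raw counts", {
    kde <- makeToyKde(n_genes = 10, n_scr = 4, n_kd = 6, seed = 81)
    cts <- SummarizedExperiment::assay(kde, "counts")
    cts["g001", ] <- c(5, 3, 2, 4, 0, 1, 0, 2, 0, 7)
    SummarizedExperiment::assay(kde, "counts") <- cts
    S4Vectors::metadata(kde)$target_gene <- "g001"
    kde <- assignDosageGroups(kde)
    dg <- SummarizedExperiment::colData(kde)$dosage_group
    expect_identical(dg[1:4], rep("SCR", 4))
    expect_identical(dg[5:10], c("undetectable", "detectable",
                                 "undetectable", "detectable",
                                 "undetectable", "detectable"))
    expect_error(assignDosageGroups(kde, "nope"), "absent")
})

test_that("the study-scale simulation yields dosage groups of 46, 20 and 25", {
    sim <- generateDataset(simulationConfig(n_genes = 200, seed = 82))
    kde <- assignDosageGroups(sim$kde)
    tb <- table(SummarizedExperiment::colData(kde)$dosage_group)
    expect_identical(as.integer(tb[c("SCR", "detectable", "undetectable")]),
                     c(46L, 20L, 25L))
})

test_that("Fisher combination reproduces closed-form worked values", {
    r <- fisherCombine(1, 1)
    expect_equal(r$statistic, 0)
    expect_equal(r$p_combined, 1)
    r2 <- fisherCombine(0.05, 0.05)
    expect_equal(r2$statistic, -4 * log(0.05), tolerance = 1e-12)
    # survival function of chi^2_4: exp(-F/2) (1 + F/2)
    Fstar <- r2$statistic
    expect_equal(r2$p_combined, exp(-Fstar / 2) * (1 + Fstar / 2),
                 tolerance = 1e-12)
    expect_equal(r2$p_combined, 0.01747866, tolerance = 1e-6)
})

test_that("Fisher combination is symmetric and monotone", {
    set.seed(83)
    p1 <- runif(50); p2 <- runif(50)
    expect_equal(fisherCombine(p1, p2)$p_combined,
                 fisherCombine(p2, p1)$p_combined)
    pc <- fisherCombine(p1, p2)$p_combined
    pc_dec <- fisherCombine(p1 * 0.5, p2)$p_combined
    expect_true(all(pc_dec <= pc + 1e-12))
    expect_error(fisherCombine(1.2, 0.5), "0, 1")
    expect_warning(fisherCombine(0, 0.5), "floored")
})

test_that("combined p-values are uniform under independent uniform inputs", {
    set.seed(84)
    pc <- fisherCombine(runif(1e5), runif(1e5))$p_combined
    expect_gt(ks.test(pc, "punif")$p.value, 0.01)
})

test_that("BH q-values match a brute-force step-up oracle", {
    expect_identical(fdrAdjust(numeric(0)), numeric(0))
    q1 <- fdrAdjust(rep(1, 5))
    expect_true(all(q1 == 1))
    q2 <- fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
    expect_true(all(q2 <= 0.05))  # every sorted p_i <= 0.05 i / 4
    set.seed(85)
    for (i in 1:1000) {
        p <- runif(sample(3:60, 1))^sample(1:3, 1)
        expect_equal(as.numeric(fdrAdjust(p)), bruteForceBH(p),
                     tolerance = 1e-12)
    }
    # missing values are excluded and reported
    q3 <- fdrAdjust(c(0.01, NA, 0.5))
    expect_true(is.na(q3[2]))
    expect_equal(attr(q3, "n_missing"), 1L)
})

test_that("q-value significance sets are nested across FDR levels", {
    set.seed(86)
    p <- c(runif(300)^3, runif(200))
    q <- fdrAdjust(p)
    s05 <- which(q <= 0.05)
    s10 <- which(q <= 0.10)
    expect_true(all(s05 %in% s10))
})

test_that("overlap counts equal a brute-force enumeration of Venn regions", {
    mk <- function(ids, sig, design) {
        df <- S4Vectors::DataFrame(
            gene_id = ids, p1 = NA_real_, p2 = NA_real_,
            pvalue = ifelse(ids %in% sig, 0.001, 0.9),
            qvalue = ifelse(ids %in% sig, 0.01, 0.9),
            log2_fc = 0, direction = "down",
            significant = ids %in% sig, converged = TRUE, boundary = FALSE)
        new("DEResults", df, design = design, fdrLevel = 0.05)
    }
    uni <- sprintf("g%03d", 1:60)
    set.seed(87)
    A <- sample(uni, 25); B <- sample(uni, 30); C <- sample(uni, 10)
    ov <- overlapSets(mk(uni, A, "two_group"), mk(uni, B, "three_group"),
                      mk(uni, C, "detectable_vs_undetectable"))
    # brute force over all genes
    inA <- uni %in% A; inB <- uni %in% B; inC <- uni %in% C
    expect_equal(unname(ov$regions["all_three"]), sum(inA & inB & inC))
    expect_equal(unname(ov$regions["only_two_group"]),
                 sum(inA & !inB & !inC))
    expect_equal(unname(ov$pairwise["two_and_three"]), sum(inA & inB))
    # inclusion-exclusion: union from the 7 disjoint regions
    expect_equal(sum(ov$regions), sum(inA | inB | inC))
    expect_identical(ov$genes_in_all, sort(uni[inA & inB & inC]))
    # identical sets: triple intersection is the set itself
    ov2 <- overlapSets(mk(uni, A, "two_group"), mk(uni, A, "three_group"),
                       mk(uni, A, "detectable_vs_undetectable"))
    expect_equal(ov2$triple, length(A))
    # disjoint sets: all intersections empty
    ov3 <- overlapSets(mk(uni, uni[1:5], "two_group"),
                       mk(uni, uni[6:10], "three_group"),
                       mk(uni, uni[11:15], "detectable_vs_undetectable"))
    expect_true(all(ov3$pairwise == 0) && ov3$triple == 0)
    expect_error(overlapSets(mk(uni, A, "two_group"),
                             mk(uni[-1], B[B %in% uni[-1]], "three_group"),
                             mk(uni, C, "detectable_vs_undetectable")),
                 "universe")
})

test_that("direction-bias p equals the exhaustive hypergeometric enumeration", {
    mkres <- function(tab) {
        ids <- sprintf("g%03d", seq_len(sum(tab)))
        deg <- rep(c(TRUE, FALSE), c(sum(tab[1, ]), sum(tab[2, ])))
        dir <- c(rep(c("down", "up"), tab[1, ]), rep(c("down", "up"), tab[2, ]))
        df <- S4Vectors::DataFrame(
            gene_id = ids, p1 = NA_real_, p2 = NA_real_,
            pvalue = ifelse(deg, 0.001, 0.9),
            qvalue = ifelse(deg, 0.01, 0.9), log2_fc = 0,
            direction = dir, significant = deg, converged = TRUE,
            boundary = FALSE)
        new("DEResults", df, design = "two_group", fdrLevel = 0.05)
    }
    tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
    r <- directionBiasTest(mkres(tab))
    expect_equal(r$p_value, 34 / 70, tolerance = 1e-12)
    expect_equal(r$p_value, exhaustiveFisherP(tab), tolerance = 1e-12)
    expect_identical(unname(as.vector(r$table)), c(3L, 1L, 1L, 3L))
    # proportional table: no association, p = 1
    r2 <- directionBiasTest(mkres(matrix(c(4, 4, 8, 8), 2, byrow = TRUE)))
    expect_equal(r2$p_value, 1)
    # random tables against the oracle
    set.seed(88)
    for (i in 1:10) {
        tb <- matrix(rpois(4, 8) + 1, 2)
        expect_equal(directionBiasTest(mkres(tb))$p_value,
                     exhaustiveFisherP(tb), tolerance = 1e-9)
    }
    # zero margin: degenerate, p = 1 with a warning
    expect_warning(r3 <- directionBiasTest(mkres(matrix(c(0, 0, 5, 5), 2,
                                                        byrow = TRUE))),
                   "zero margin")
    expect_equal(r3$p_value, 1)
})

test_that("the paper-margin contingency table is astronomically one-sided", {
    # 1950 DEGs with 71.7% down; 15,351 genes with 58.5% down overall
    deg_down <- round(1950 * 0.717)
    all_down <- round(15351 * 0.585)
    tab <- matrix(c(deg_down, 1950 - deg_down,
                    all_down - deg_down, (15351 - 1950) - (all_down - deg_down)),
                  2, byrow = TRUE)
    p <- fisher.test(tab)$p.value
    expect_lt(p, 1e-16)
})
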