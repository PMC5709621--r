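# Shared fixture builders. All fixtures are generated in code.

# small two-group count matrix wrapped in the experiment container
makeToyKde <- function(n_genes = 30, n_scr = 8, n_kd = 8, seed = 42,
                       mean_rate = 10) {
    set.seed(seed)
    n <- n_scr + n_kd
    m <- matrix(rpois(n_genes * n, mean_rate), n_genes, n,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n))))
    KnockdownExperiment(m,
                        treatment = rep(c("SCR", "siTARGET"), c(n_scr, n_kd)),
                        batch = rep(c("b1", "b2"), length.out = n))
}

# brute-force Riemann-sum evaluation of the beta-Poisson pmf
riemannBpPmf <- function(k, alpha, beta, lambda, n_points = 1e5) {
    u <- (seq_len(n_points) - 0.5) / n_points
    vapply(k, function(ki)
        mean(dpois(ki, lambda * u) * dbeta(u, alpha, beta)), numeric(1))
}

# brute-force Benjamini-Hochberg step-up q-values
bruteForceBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    sorted <- p[o] * n / seq_len(n)
    q[o] <- rev(cummin(rev(sorted)))
    pmin(q, 1)
}

# exhaustive two-sided Fisher exact p for a 2x2 table: sum of
# hypergeometric outcomes with probability <= the observed one
exhaustiveFisherP <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    xs <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- dhyper(xs, c1, n - c1, r1)
    obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(pr[pr <= obs * (1 + 1e-7)])
}
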