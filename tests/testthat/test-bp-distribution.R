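# Beta-Poisson distribution: PMF, sampler, likelihood.

test_that("PMF matches the closed form for uniform mixing at rate 1", {
    p <- BetaPoissonParams(1, 1, 1)
    # P(X=0) = int_0^1 exp(-u) du = 1 - exp(-1)
    expect_equal(bpPMF(0, p), 1 - exp(-1), tolerance = 1e-10)
    expect_equal(bpPMF(0, p, method = "series"), 1 - exp(-1),
                 tolerance = 1e-12)
})

test_that("degenerate rate scale gives a point mass at zero", {
    p <- BetaPoissonParams(2, 3, 0)
    expect_identical(bpPMF(0:4, p), c(1, 0, 0, 0, 0))
    expect_identical(sampleBetaPoisson(p, 10, seed = 1), integer(10))
})

test_that("quadrature PMF matches an adaptive-quadrature oracle on random parameters", {
    set.seed(11)
    # shapes >= 1: the integrand is bounded, so adaptive quadrature is a
    # trustworthy oracle; endpoint-singular shapes (< 1) are checked
    # against frozen arbitrary-precision values below
    for (i in 1:20) {
        a <- runif(1, 1, 4); b <- runif(1, 1, 5)
        lam <- runif(1, 0.5, 40)
        p <- BetaPoissonParams(a, b, lam)
        ks <- 0:15
        oracle <- vapply(ks, function(k)
            integrate(function(u) dpois(k, lam * u) * dbeta(u, a, b),
                      0, 1, rel.tol = 1e-11)$value, numeric(1))
        expect_lt(max(abs(bpPMF(ks, p) - oracle)), 1e-8)
        expect_lt(max(abs(bpPMF(ks, p, method = "series") - oracle)), 1e-8)
    }
})

test_that("PMF handles endpoint-singular shapes and huge rates", {
    # frozen values from an arbitrary-precision evaluation (mpmath,
    # 40 digits) of lambda^k/k! B(k+a,b)/B(a,b) 1F1(k+a; k+a+b; -lambda)
    # at alpha = 0.7, beta = 2.5
    p400 <- BetaPoissonParams(0.7, 2.5, 400)
    expect_equal(bpPMF(c(0, 1, 3), p400, method = "series"),
                 c(0.02743518739211469, 0.01913257816597358,
                   0.01452638912847857), tolerance = 1e-10)
    p1e6 <- BetaPoissonParams(0.7, 2.5, 1e6)
    expect_equal(bpPMF(c(0, 1, 3), p1e6, method = "series"),
                 c(1.150508349887356e-04, 8.053546368871401e-05,
                   6.160944489280146e-05), tolerance = 1e-9)
    # the fixed-order Jacobi rule absorbs the u^(alpha-1) singularity
    expect_equal(bpPMF(c(0, 1, 3), p400, order = 512),
                 bpPMF(c(0, 1, 3), p400, method = "series"),
                 tolerance = 1e-7)
})

test_that("PMF matches Monte-Carlo frequencies within 3 standard errors", {
    p <- BetaPoissonParams(2, 3, 10)
    n <- 1e6
    x <- sampleBetaPoisson(p, n, seed = 7)
    pmf <- bpPMF(0:20, p)
    emp <- tabulate(x + 1, 21) / n
    se <- sqrt(pmf * (1 - pmf) / n)
    expect_true(all(abs(emp - pmf) <= 3 * se + 1e-12))
})

test_that("PMF mass sums to one over a documented support", {
    for (pars in list(c(1, 1, 5), c(0.5, 2, 30), c(3, 0.7, 80))) {
        p <- BetaPoissonParams(pars[1], pars[2], pars[3])
        K <- ceiling(pars[3] + 10 * sqrt(pars[3]) + 20)
        expect_gte(sum(bpPMF(0:K, p, method = "series")), 1 - 1e-6)
    }
})

test_that("series and quadrature evaluations agree at large rate scales", {
    p <- BetaPoissonParams(0.7, 2.5, 400)
    ks <- c(0, 1, 5, 50, 200)
    # order raised with the rate: the fixed default rule is documented
    # for moderate rates, the series is exact everywhere
    q <- bpPMF(ks, p, order = 512)
    s <- bpPMF(ks, p, method = "series")
    expect_equal(q, s, tolerance = 1e-7)
})

test_that("sampler moments match the analytic mean", {
    a <- 2; b <- 3; lam <- 30
    n <- 2e5
    x <- sampleBetaPoisson(BetaPoissonParams(a, b, lam), n, seed = 3)
    mu <- lam * a / (a + b)
    v <- mu + lam^2 * a * b / ((a + b)^2 * (a + b + 1))
    expect_lt(abs(mean(x) - mu), 3 * sqrt(v / n))
})

test_that("empirical zero probability matches the closed form for (1,1,1)", {
    n <- 1e6
    x <- sampleBetaPoisson(BetaPoissonParams(1, 1, 1), n, seed = 5)
    p0 <- 1 - exp(-1)
    expect_lt(abs(mean(x == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("invalid shape parameters are rejected", {
    expect_error(BetaPoissonParams(-1, 1, 1), "alpha")
    expect_error(BetaPoissonParams(1, 0, 1), "beta")
    expect_error(BetaPoissonParams(1, 1, -2), "rateScale")
    expect_error(bpPMF(c(-1, 2), BetaPoissonParams(1, 1, 1)),
                 "non-negative integers")
})

test_that("log-likelihood matches a brute-force Riemann-sum oracle", {
    set.seed(21)
    X <- makeDesignMatrix(rep(c("SCR", "siTARGET"), each = 3))
    # shapes >= 1 keep the integrand bounded, which the midpoint rule
    # needs; singular shapes are covered by the frozen-value test above
    for (i in 1:20) {
        a <- runif(1, 1, 3); b <- runif(1, 1, 4)
        cf <- c(intercept = runif(1, 0, 3), I_siTARGET = runif(1, -1, 1))
        mu <- exp(drop(X %*% cf))
        lam <- mu * (a + b) / a
        y <- rpois(6, pmin(mu, 50))
        oracle <- sum(log(vapply(seq_len(6), function(j)
            riemannBpPmf(y[j], a, b, lam[j]), numeric(1))))
        expect_lt(abs(bpLogLik(y, X, cf, c(a, b)) - oracle), 6 * 1e-6)
    }
})

test_that("saturated single-cell likelihood equals the log PMF", {
    X <- matrix(1, 1, 1, dimnames = list(NULL, "intercept"))
    y <- 7
    a <- 1.5; b <- 2.5
    lam <- 7 * (a + b) / a
    expect_equal(bpLogLik(y, X, log(7), c(a, b)),
                 log(bpPMF(7, BetaPoissonParams(a, b, lam),
                           method = "series")),
                 tolerance = 1e-10)
})

test_that("the log link scales all fitted means by exp(c)", {
    X <- makeDesignMatrix(rep(c("SCR", "siTARGET"), each = 4))
    cf <- c(intercept = 1, I_siTARGET = 0.5)
    mu1 <- exp(drop(X %*% cf))
    cf2 <- cf + c(0.7, 0)
    mu2 <- exp(drop(X %*% cf2))
    expect_equal(mu2, mu1 * exp(0.7), tolerance = 1e-12)
})

test_that("non-finite linear predictors yield -Inf with a warning", {
    X <- makeDesignMatrix(rep(c("SCR", "siTARGET"), each = 2))
    expect_warning(ll <- bpLogLik(c(1, 2, 3, 4), X, c(1e4, 0), c(1, 1)),
                   "non-finite")
    expect_identical(ll, -Inf)
})
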