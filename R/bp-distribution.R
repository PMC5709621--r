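#' @useDynLib knockdownDE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dpois rbeta rpois optim pchisq sd var
NULL

# Gauss-Jacobi nodes and weights on [-1, 1] for the weight
# (1-x)^a (1+x)^b, a, b > -1, by the Golub-Welsch algorithm (eigenvalues
# of the symmetric tridiagonal recurrence matrix). k=1 off-diagonal term
# is the usual special case of the three-term recurrence.
gaussJacobi <- function(n, a, b) {
    stopifnot(n >= 1, a > -1, b > -1)
    mu0 <- exp((a + b + 1) * log(2) + lbeta(a + 1, b + 1))
    if (n == 1) {
        x <- (b - a) / (a + b + 2)
        return(list(nodes = x, weights = mu0))
    }
    k <- seq_len(n - 1)
    nab <- 2 * k + a + b
    diag0 <- c((b - a) / (a + b + 2),
               (b^2 - a^2) / (nab * (nab + 2)))
    off2 <- numeric(n - 1)
    off2[1] <- 4 * (a + 1) * (b + 1) / ((a + b + 2)^2 * (a + b + 3))
    if (n > 2) {
        k2 <- 2:(n - 1)
        nab2 <- 2 * k2 + a + b
        off2[k2] <- 4 * k2 * (k2 + a) * (k2 + b) * (k2 + a + b) /
            (nab2^2 * (nab2 + 1) * (nab2 - 1))
    }
    J <- diag(diag0)
    off <- sqrt(off2)
    for (i in seq_len(n - 1)) {
        J[i, i + 1] <- off[i]
        J[i + 1, i] <- off[i]
    }
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    list(nodes = e$values[ord],
         weights = mu0 * e$vectors[1, ord]^2)
}

# Quadrature nodes u in (0,1) and weights normalized to sum to one, so
# that P(X=k) = sum(w * dpois(k, rateScale * u)). The Jacobi weight
# absorbs the Beta(alpha, beta) endpoint behaviour exactly.
.bpQuadRule <- function(alpha, beta, order) {
    gj <- gaussJacobi(order, a = beta - 1, b = alpha - 1)
    u <- (gj$nodes + 1) / 2
    w <- exp(log(gj$weights) + (1 - alpha - beta) * log(2) -
             lbeta(alpha, beta))
    list(u = u, wn = w / sum(w))
}

#' Beta-Poisson probability mass function
#'
#' Evaluates \eqn{P(X=k) = \int_0^1 Pois(k; \lambda u)\,
#' Beta(u; \alpha, \beta)\, du} with \eqn{\lambda} the rate scale.
#' The default evaluation is fixed-order Gauss-Jacobi quadrature (the
#' Jacobi weight matches the Beta kernel, so endpoint singularities for
#' shapes below one are handled exactly); \code{method = "series"} uses
#' an exact cancellation-free Kummer-series evaluation of the same
#' integral, which stays accurate for arbitrarily large rate scales and
#' backs the GLM likelihood.
#'
#' @param k vector of non-negative integer counts.
#' @param params a \code{\link{BetaPoissonParams}} object.
#' @param order quadrature order (default 64).
#' @param method \code{"quadrature"} (default) or \code{"series"}.
#' @return numeric vector of probabilities, one per element of \code{k}.
#' @examples
#' bpPMF(0, BetaPoissonParams(1, 1, 1))  # 1 - exp(-1)
#' @export
bpPMF <- function(k, params, order = 64,
                  method = c("quadrature", "series")) {
    method <- match.arg(method)
    stopifnot(is(params, "BetaPoissonParams"))
    validObject(params)
    if (any(k < 0) || any(k != floor(k)))
        stop("k must contain non-negative integers")
    if (params@rateScale == 0)
        return(as.numeric(k == 0))
    if (method == "series")
        return(exp(.bpLogPmfSeries(as.numeric(k), params@alpha, params@beta,
                                   params@rateScale)))
    rule <- .bpQuadRule(params@alpha, params@beta, order)
    lam <- params@rateScale * rule$u
    vapply(k, function(ki) sum(rule$wn * dpois(ki, lam)), numeric(1))
}

#' Sample from the beta-Poisson distribution
#'
#' Two-stage sampling: a Beta mixing proportion, then a Poisson draw at
#' the scaled rate.
#'
#' @param params a \code{\link{BetaPoissonParams}} object.
#' @param n number of draws (\eqn{\ge 1}).
#' @param seed optional integer seed set before drawing.
#' @return integer vector of \code{n} counts.
#' @examples
#' x <- sampleBetaPoisson(BetaPoissonParams(2, 3, 30), 5, seed = 1)
#' @export
sampleBetaPoisson <- function(params, n, seed = NULL) {
    stopifnot(is(params, "BetaPoissonParams"), n >= 1)
    validObject(params)
    if (!is.null(seed)) set.seed(seed)
    if (params@rateScale == 0) return(integer(n))
    u <- rbeta(n, params@alpha, params@beta)
    rpois(n, params@rateScale * u)
}

#' Beta-Poisson regression log-likelihood
#'
#' Log-likelihood of counts under the beta-Poisson GLM: the cell mean is
#' \eqn{\mu_i = \exp(x_i^T \beta)} (log link), Beta shapes are shared
#' across cells, and the per-cell rate scale is solved from the mean,
#' \eqn{\lambda_i = \mu_i (\alpha+\beta)/\alpha}.
#'
#' @param y vector of non-negative integer counts.
#' @param X design matrix (cells x covariates).
#' @param coefficients coefficient vector, length \code{ncol(X)}.
#' @param shapes numeric \code{c(alpha, beta)}, both positive.
#' @return the summed log-likelihood; \code{-Inf} (with a warning) when
#'   the linear predictor is non-finite.
#' @export
bpLogLik <- function(y, X, coefficients, shapes) {
    X <- as.matrix(X)
    stopifnot(length(y) == nrow(X), length(coefficients) == ncol(X),
              length(shapes) == 2, all(shapes > 0))
    if (any(y < 0) || any(y != floor(y)))
        stop("y must contain non-negative integers")
    eta <- drop(X %*% coefficients)
    if (any(!is.finite(eta)) || any(!is.finite(exp(eta)))) {
        warning("non-finite linear predictor; returning -Inf")
        return(-Inf)
    }
    mu <- exp(eta)
    lam <- mu * (shapes[1] + shapes[2]) / shapes[1]
    sum(.bpLogPmfSeries(as.numeric(y), shapes[1], shapes[2],
                        as.numeric(lam)))
}
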