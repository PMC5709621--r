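#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Beta-Poisson log-PMF via a positive-term Kummer series.
//
// X | u ~ Poisson(lambda * u), u ~ Beta(alpha, beta).
// P(X = k) = lambda^k / (k! B(alpha,beta)) *
//            int_0^1 u^(k+alpha-1) (1-u)^(beta-1) exp(-lambda u) du
//          = lambda^k B(k+alpha, beta) / (k! B(alpha, beta)) *
//            1F1(k+alpha; k+alpha+beta; -lambda).
// Kummer's transformation gives 1F1(k+alpha; c; -lambda) =
// exp(-lambda) * 1F1(beta; c; +lambda) whose series has all-positive
// terms, so the evaluation is cancellation-free for every lambda >= 0.
// Terms are accumulated with periodic rescaling to dodge overflow
// (the sum grows like exp(lambda)).

static double log_kummer_pos(double a, double c, double x) {
    // log 1F1(a; c; x) for a > 0, c > 0, x >= 0.
    if (x == 0.0) return 0.0;
    if (x > 500.0 && x > 50.0 * c) {
        // Large-argument asymptotic: 1F1(a;c;x) ~ Gamma(c)/Gamma(a) *
        // exp(x) x^(a-c) * sum_n (c-a)_n (1-a)_n / (n! x^n). With
        // x > 50 c the correction terms decay superlinearly, so the
        // truncation error is far below the series round-off.
        double term = 1.0, sum = 1.0;
        for (int n = 0; n < 60; ++n) {
            term *= (c - a + n) * (1.0 - a + n) / ((n + 1.0) * x);
            sum += term;
            if (std::fabs(term) < sum * 1e-16) break;
        }
        return x + (a - c) * std::log(x) + R::lgammafn(c) - R::lgammafn(a)
             + std::log(sum);
    }
    // positive-term series (cancellation-free), O(x) iterations
    const double BIG = 1e280, LOGBIG = std::log(1e280);
    double term = 1.0, sum = 1.0, logscale = 0.0;
    double n = 0.0;
    for (;;) {
        double ratio = (a + n) * x / ((c + n) * (n + 1.0));
        term *= ratio;
        sum += term;
        n += 1.0;
        if (ratio < 1.0 && term < sum * 1e-17) break;
        if (sum > BIG) { sum /= BIG; term /= BIG; logscale += LOGBIG; }
        if (n > 1e8) break;  // unreachable for sane inputs; hard stop
    }
    return std::log(sum) + logscale;
}

// 64-point Gauss-Legendre nodes/weights on [-1, 1], computed once by
// Newton iteration on the Legendre recurrence.
static const int GLN = 64;
static double gl_x[GLN], gl_w[GLN];
static bool gl_ready = false;
static void gl_init() {
    if (gl_ready) return;
    int m = (GLN + 1) / 2;
    for (int i = 0; i < m; ++i) {
        double x = std::cos(M_PI * (i + 0.75) / (GLN + 0.5));
        double pp = 0.0;
        for (int it = 0; it < 100; ++it) {
            double p1 = 1.0, p2 = 0.0;
            for (int j = 0; j < GLN; ++j) {
                double p3 = p2; p2 = p1;
                p1 = ((2.0 * j + 1.0) * x * p2 - j * p3) / (j + 1.0);
            }
            pp = GLN * (x * p1 - p2) / (x * x - 1.0);
            double x1 = x;
            x = x1 - p1 / pp;
            if (std::fabs(x - x1) < 1e-15) break;
        }
        gl_x[i] = -x; gl_x[GLN - 1 - i] = x;
        gl_w[i] = gl_w[GLN - 1 - i] = 2.0 / ((1.0 - x * x) * pp * pp);
    }
    gl_ready = true;
}

// Laplace-windowed Gauss-Legendre evaluation of
// log int_0^1 u^A (1-u)^B exp(-lam u) du for an interior, near-Gaussian
// mode (A >= ~30). Returns NaN when the mode geometry is unsuitable and
// the caller must fall back to the series.
static double log_integral_window(double A, double B, double lam) {
    gl_init();
    double S = lam + A + B;
    double disc = S * S - 4.0 * lam * A;
    if (disc <= 0.0) return R_NaN;
    double ustar = 2.0 * A / (S + std::sqrt(disc));
    if (!(ustar > 0.0 && ustar < 1.0)) return R_NaN;
    double g2 = -A / (ustar * ustar) - B / ((1.0 - ustar) * (1.0 - ustar));
    if (!(g2 < 0.0)) return R_NaN;
    double sigma = 1.0 / std::sqrt(-g2);
    double lo = std::max(ustar - 10.0 * sigma, 1e-12);
    double hi = std::min(ustar + 10.0 * sigma, 1.0 - 1e-12);
    // a negative B makes the integrand singular at 1: require the
    // window to stay clear of that endpoint
    if (B < 0.0 && hi > 1.0 - 1e-9) return R_NaN;
    double g0 = A * std::log(ustar) + B * std::log1p(-ustar) - lam * ustar;
    double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
    double s = 0.0;
    for (int i = 0; i < GLN; ++i) {
        double u = mid + half * gl_x[i];
        double g = A * std::log(u) + B * std::log1p(-u) - lam * u;
        s += gl_w[i] * std::exp(g - g0);
    }
    return g0 + std::log(s * half);
}

// [[Rcpp::export(name = ".bpLogPmfSeries")]]
NumericVector bp_log_pmf_series(NumericVector k, double alpha, double beta,
                                NumericVector lambda) {
    if (!(alpha > 0.0) || !(beta > 0.0))
        stop("beta-Poisson shape parameters must be positive");
    R_xlen_t n = k.size();
    if (lambda.size() != n && lambda.size() != 1)
        stop("lambda must have length 1 or length(k)");
    NumericVector out(n);
    double lb_ab = R::lbeta(alpha, beta);
    for (R_xlen_t i = 0; i < n; ++i) {
        double ki = k[i];
        double li = (lambda.size() == 1) ? lambda[0] : lambda[i];
        if (ki < 0.0 || ki != std::floor(ki)) { out[i] = R_NegInf; continue; }
        if (!(li >= 0.0)) stop("lambda must be non-negative");
        if (li == 0.0) { out[i] = (ki == 0.0) ? 0.0 : R_NegInf; continue; }
        double c = ki + alpha + beta;
        double A = ki + alpha - 1.0;
        double lead = ki * std::log(li) - R::lgammafn(ki + 1.0) - lb_ab;
        // sharp interior peak: O(1) windowed Laplace quadrature
        // instead of the O(lambda) series
        if (li > 500.0 && !(li > 50.0 * c) && A >= 30.0) {
            double lw = log_integral_window(A, beta - 1.0, li);
            if (R_finite(lw)) { out[i] = lead + lw; continue; }
        }
        out[i] = lead + R::lbeta(ki + alpha, beta)
               - li + log_kummer_pos(beta, c, li);
    }
    return out;
}

// Weighted log-likelihood on tabulated (count, rate) pairs: sum of
// w * logPMF. Used by the per-gene fitter, where cells sharing a design
// group share a rate and repeated counts collapse to weights.
// [[Rcpp::export(name = ".bpLogLikTab")]]
double bp_loglik_tab(NumericVector k, NumericVector w, double alpha,
                     double beta, NumericVector lambda) {
    NumericVector lp = bp_log_pmf_series(k, alpha, beta, lambda);
    double ll = 0.0;
    for (R_xlen_t i = 0; i < lp.size(); ++i) {
        if (lp[i] == R_NegInf) return R_NegInf;
        ll += w[i] * lp[i];
    }
    return ll;
}
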