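#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// EM for a univariate two-component Gaussian mixture from a given start.
// Log-likelihood is evaluated at each E-step; convergence is declared when
// its change drops below tol (the parameters then stay at the last M-step).
// [[Rcpp::export(name = ".emMix2Cpp")]]
List emMix2Cpp(NumericVector x, double w1, double mu1, double s1,
               double w2, double mu2, double s2, int maxIter, double tol) {
    const int n = x.size();
    const double tiny = std::numeric_limits<double>::min();
    const double log2pi_half = 0.9189385332046727; // log(sqrt(2*pi))
    std::vector<double> g1(n);
    double ll = R_NegInf;
    bool converged = false;
    int used = 0;

    for (int it = 1; it <= maxIter; ++it) {
        used = it;
        // E-step and log-likelihood under the current parameters
        double lc1 = std::log(w1 > 0 ? w1 : tiny) - std::log(s1) - log2pi_half;
        double lc2 = std::log(w2 > 0 ? w2 : tiny) - std::log(s2) - log2pi_half;
        double inv2v1 = 1.0 / (2.0 * s1 * s1), inv2v2 = 1.0 / (2.0 * s2 * s2);
        double llNew = 0.0, n1 = 0.0;
        // log-sum-exp per point: one exp + one log1p instead of
        // two exps + one log
        for (int i = 0; i < n; ++i) {
            double a = x[i] - mu1, b = x[i] - mu2;
            double l1 = lc1 - a * a * inv2v1;
            double l2 = lc2 - b * b * inv2v2;
            double hi = l1 >= l2 ? l1 : l2;
            double e = std::exp(-std::fabs(l1 - l2)); // exp(lo - hi) <= 1
            llNew += hi + std::log1p(e);
            double gHi = 1.0 / (1.0 + e); // responsibility of the larger term
            g1[i] = (l1 >= l2) ? gHi : 1.0 - gHi;
            n1 += g1[i];
        }
        if (std::isfinite(llNew) && std::fabs(llNew - ll) < tol) {
            ll = llNew;
            converged = true;
            break;
        }
        ll = llNew;
        double n2 = n - n1;
        if (n1 < 1e-8 || n2 < 1e-8) break; // a component emptied out
        // M-step
        double m1 = 0.0, m2 = 0.0;
        for (int i = 0; i < n; ++i) {
            m1 += g1[i] * x[i];
            m2 += (1.0 - g1[i]) * x[i];
        }
        mu1 = m1 / n1;
        mu2 = m2 / n2;
        double v1 = 0.0, v2 = 0.0;
        for (int i = 0; i < n; ++i) {
            double a = x[i] - mu1, b = x[i] - mu2;
            v1 += g1[i] * a * a;
            v2 += (1.0 - g1[i]) * b * b;
        }
        s1 = std::sqrt(std::max(v1 / n1, 1e-12));
        s2 = std::sqrt(std::max(v2 / n2, 1e-12));
        w1 = n1 / n;
        w2 = n2 / n;
    }
    return List::create(_["w1"] = w1, _["mu1"] = mu1, _["sigma1"] = s1,
                        _["w2"] = w2, _["mu2"] = mu2, _["sigma2"] = s2,
                        _["loglik"] = ll, _["converged"] = converged,
                        _["iter"] = used);
}
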