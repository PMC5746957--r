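#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled-probability forward-backward for one chain.
// log_emis: T x S matrix of log emission probabilities (may contain -Inf),
// trans: S x S row-stochastic transition matrix, init: length-S initial
// distribution. Returns smoothed posteriors (T x S), the summed expected
// transition counts (S x S) and the chain log-likelihood. Per-position
// scaling keeps everything in double range for chains of arbitrary length.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix log_emis, NumericMatrix trans, NumericVector init) {
    const int T = log_emis.nrow();
    const int S = log_emis.ncol();

    // Per-row max-shifted emission likelihoods: e[t][s] = exp(logE - rowmax).
    NumericMatrix e(T, S);
    std::vector<double> rowmax(T);
    for (int t = 0; t < T; ++t) {
        double m = R_NegInf;
        for (int s = 0; s < S; ++s) m = std::max(m, log_emis(t, s));
        if (!R_FINITE(m))
            stop("all emission probabilities are zero at position %d", t + 1);
        rowmax[t] = m;
        for (int s = 0; s < S; ++s) e(t, s) = std::exp(log_emis(t, s) - m);
    }

    NumericMatrix alpha(T, S), beta(T, S);
    std::vector<double> scale(T);

    // forward
    double norm = 0.0;
    for (int s = 0; s < S; ++s) {
        alpha(0, s) = init[s] * e(0, s);
        norm += alpha(0, s);
    }
    if (norm <= 0.0) stop("forward pass underflow at position 1");
    scale[0] = norm;
    for (int s = 0; s < S; ++s) alpha(0, s) /= norm;
    for (int t = 1; t < T; ++t) {
        norm = 0.0;
        for (int s = 0; s < S; ++s) {
            double acc = 0.0;
            for (int r = 0; r < S; ++r) acc += alpha(t - 1, r) * trans(r, s);
            alpha(t, s) = acc * e(t, s);
            norm += alpha(t, s);
        }
        if (norm <= 0.0) stop("forward pass underflow at position %d", t + 1);
        scale[t] = norm;
        for (int s = 0; s < S; ++s) alpha(t, s) /= norm;
    }

    // backward
    for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
        for (int s = 0; s < S; ++s) {
            double acc = 0.0;
            for (int r = 0; r < S; ++r)
                acc += trans(s, r) * e(t + 1, r) * beta(t + 1, r);
            beta(t, s) = acc / scale[t + 1];
        }
    }

    // posteriors and expected transition counts
    NumericMatrix gamma(T, S);
    for (int t = 0; t < T; ++t) {
        double tot = 0.0;
        for (int s = 0; s < S; ++s) {
            gamma(t, s) = alpha(t, s) * beta(t, s);
            tot += gamma(t, s);
        }
        for (int s = 0; s < S; ++s) gamma(t, s) /= tot;
    }
    NumericMatrix xi(S, S);
    for (int t = 0; t < T - 1; ++t) {
        for (int r = 0; r < S; ++r) {
            if (alpha(t, r) == 0.0) continue;
            for (int s = 0; s < S; ++s) {
                xi(r, s) += alpha(t, r) * trans(r, s) * e(t + 1, s) *
                            beta(t + 1, s) / scale[t + 1];
            }
        }
    }

    double loglik = 0.0;
    for (int t = 0; t < T; ++t) loglik += std::log(scale[t]) + rowmax[t];

    return List::create(_["gamma"] = gamma, _["xi"] = xi,
                        _["loglik"] = loglik);
}
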