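#include <Rcpp.h>
using namespace Rcpp;

// Two-hemisphere brain-state random walk. The joint state (i, j) lives on
// {0..L} x {0..L}; the bout ends when either coordinate reaches 0 (wake
// boundary). Dwell times are exponential with mean theta = (i^2+j^2)^(a/2).
// Past the sleep threshold the bout is marked slept; in "continue" dynamics
// an independent wake clock of rate eps competes with further transitions
// while the walker is inside the sleep region, in "absorb" dynamics the
// bout ends at the first crossing plus an Exp(mean 1/eps) sleep time.

// [[Rcpp::export]]
List simulate_bouts_cpp(int L, double a, double w_thresh, double eps,
                        int start_i, int start_j, int n_bouts,
                        bool continue_walk, bool euclidean) {
    NumericVector dur(n_bouts), lat(n_bouts);
    LogicalVector slept(n_bouts);
    const double w2 = w_thresh * w_thresh;
    for (int b = 0; b < n_bouts; ++b) {
        int i = start_i, j = start_j;
        double tt = 0.0, la = NA_REAL;
        bool sl = false;
        while (i != 0 && j != 0) {
            const double r2 = (double)(i * i + j * j);
            const bool insleep = euclidean ? (r2 > w2)
                                           : ((double)(i + j) > w_thresh);
            if (insleep && !sl) { sl = true; la = tt; }
            const double theta = std::pow(r2, a / 2.0);
            if (insleep) {
                if (!continue_walk) {          // absorb at the threshold
                    tt += R::rexp(1.0 / eps);
                    break;
                }
                const double total = 1.0 / theta + eps;
                tt += R::rexp(1.0 / total);
                if (unif_rand() < eps * theta / (1.0 + eps * theta))
                    break;                     // wake clock fired first
            } else {
                tt += R::rexp(theta);
            }
            // uniform move among admissible von Neumann neighbors
            // (steps to 0 are admissible; steps beyond L are reflected away)
            int ni[4] = {i - 1, i + 1, i, i};
            int nj[4] = {j, j, j - 1, j + 1};
            int adm[4], na = 0;
            for (int k = 0; k < 4; ++k)
                if (ni[k] <= L && nj[k] <= L) adm[na++] = k;
            int pick = (int)(unif_rand() * na);
            if (pick == na) pick = na - 1;
            i = ni[adm[pick]];
            j = nj[adm[pick]];
        }
        dur[b] = tt;
        slept[b] = sl;
        lat[b] = la;
    }
    return List::create(_["durations"] = dur, _["slept"] = slept,
                        _["latency"] = lat);
}
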