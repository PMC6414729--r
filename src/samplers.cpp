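#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-compartment event tables shared by both samplers.
// tgt codes: >= 0 transfer target, -1 radiative decay, -2 nonradiative decay.
struct EventTables {
    std::vector< std::vector<double> > wt;  // per-state event weights (rates)
    std::vector< std::vector<int> >    tgt;
    std::vector<double> rtot;               // total exit rate per state
};

static EventTables build_tables(const NumericMatrix& K,
                                const LogicalVector& sink,
                                const NumericVector& g_rad,
                                const NumericVector& g_nr) {
    int n = K.nrow();
    EventTables et;
    et.wt.resize(n); et.tgt.resize(n); et.rtot.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
        if (sink[i]) continue;
        double tot = 0.0;
        for (int j = 0; j < n; ++j) {
            double k = K(i, j);
            if (k > 0.0) { et.wt[i].push_back(k); et.tgt[i].push_back(j); tot += k; }
        }
        if (g_rad[i] > 0.0) { et.wt[i].push_back(g_rad[i]); et.tgt[i].push_back(-1); tot += g_rad[i]; }
        if (g_nr[i]  > 0.0) { et.wt[i].push_back(g_nr[i]);  et.tgt[i].push_back(-2); tot += g_nr[i]; }
        et.rtot[i] = tot;
    }
    return et;
}

// Fixed-step random walk: one categorical draw per dt step, decay and
// transfer compete within the step. Returns step counts; delay = steps * dt.
// [[Rcpp::export]]
List walk_fixed_step_cpp(NumericMatrix K, LogicalVector sink,
                         NumericVector g_rad, NumericVector g_nr,
                         IntegerVector start, double dt) {
    int ne = start.size();
    EventTables et = build_tables(K, sink, g_rad, g_nr);
    int n = K.nrow();
    // cumulative per-step probabilities
    std::vector< std::vector<double> > cum(n);
    std::vector<double> ptot(n, 0.0);
    for (int i = 0; i < n; ++i) {
        double c = 0.0;
        for (size_t m = 0; m < et.wt[i].size(); ++m) {
            c += et.wt[i][m] * dt;
            cum[i].push_back(c);
        }
        ptot[i] = c;
        if (c > 1.0) stop("dt too large: total per-step probability exceeds 1");
    }
    IntegerVector terminal(ne), outcome(ne);
    NumericVector steps(ne);
    for (int e = 0; e < ne; ++e) {
        int s = start[e];
        double st = 0.0;
        int out = 0, term = s;
        for (;;) {
            st += 1.0;
            double u = unif_rand();
            if (u < ptot[s]) {
                const std::vector<double>& c = cum[s];
                int k = 0;
                while (u >= c[k]) ++k;
                int t = et.tgt[s][k];
                if (t == -1)      { out = 1; term = s; break; }
                else if (t == -2) { out = 2; term = s; break; }
                else if (sink[t]) { out = 3; term = t; break; }
                else s = t;
            }
            if (((long long)st) % 4194304 == 0) checkUserInterrupt();
        }
        terminal[e] = term + 1;  // 1-based for R
        outcome[e]  = out;
        steps[e]    = st;
    }
    return List::create(_["terminal"] = terminal, _["outcome"] = outcome,
                        _["steps"] = steps);
}

// Exact continuous-time sampler: exponential waiting times, categorical jumps.
// [[Rcpp::export]]
List walk_exact_cpp(NumericMatrix K, LogicalVector sink,
                    NumericVector g_rad, NumericVector g_nr,
                    IntegerVector start) {
    int ne = start.size();
    EventTables et = build_tables(K, sink, g_rad, g_nr);
    IntegerVector terminal(ne), outcome(ne);
    NumericVector delay(ne);
    for (int e = 0; e < ne; ++e) {
        int s = start[e];
        double t = 0.0;
        int out = 0, term = s;
        long jumps = 0;
        for (;;) {
            double rt = et.rtot[s];
            if (rt <= 0.0) stop("compartment with zero exit rate: chain cannot absorb");
            t += exp_rand() / rt;
            double u = unif_rand() * rt;
            const std::vector<double>& w = et.wt[s];
            double c = 0.0;
            int k = 0;
            for (size_t m = 0; m < w.size(); ++m) { c += w[m]; if (u < c) { k = (int)m; break; } }
            int tg = et.tgt[s][k];
            if (tg == -1)      { out = 1; term = s; break; }
            else if (tg == -2) { out = 2; term = s; break; }
            else if (sink[tg]) { out = 3; term = tg; break; }
            else s = tg;
            if (++jumps % 1048576 == 0) checkUserInterrupt();
        }
        terminal[e] = term + 1;
        outcome[e]  = out;
        delay[e]    = t;
    }
    return List::create(_["terminal"] = terminal, _["outcome"] = outcome,
                        _["delay"] = delay);
}
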