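#include <Rcpp.h>
using namespace Rcpp;

// Occupancy coding: 0 = resident (A), 1 = mutant (B).
// nbr is n_sites x 4, 0-based site indices, -1 padding; deg gives the number
// of valid entries per row. All randomness comes from R's RNG (unif_rand), so
// set.seed() at the R level makes trajectories reproducible and lets the pure-R
// reference implementation replay the identical draw sequence.

// One death-birth update. Returns the change in the mutant count and adds the
// number of elementary events drawn to *n_elem. When migration_kernel is true
// the four-event kernel (divide/migrate per occupied neighbour) is used with a
// vacancy cascade; with m_A = m_B = 0 the interleaved zero-width migration
// entries leave the cumulative cutoffs of the division entries unchanged, so
// both kernels consume the same draws and produce identical trajectories.
static inline int one_update(std::vector<unsigned char>& occ,
                             const IntegerMatrix& nbr, const IntegerVector& deg,
                             const NumericVector& rA, const NumericVector& rB,
                             double mA, double mB, bool migration_kernel,
                             double cascade_cap, double* n_elem) {
    const int N = static_cast<int>(occ.size());
    int d = static_cast<int>(N * unif_rand());
    if (d >= N) d = N - 1;
    const int orig = occ[d];

    if (!migration_kernel) {
        const int k = deg[d];
        double w[4], tot = 0.0;
        for (int t = 0; t < k; ++t) {
            const int j = nbr(d, t);
            w[t] = occ[j] ? rB[j] : rA[j];
            tot += w[t];
        }
        if (tot <= 0.0) return 0;  // nobody can reproduce: null update
        const double u = tot * unif_rand();
        *n_elem += 1.0;
        int pick = k - 1;
        double acc = 0.0;
        for (int t = 0; t < k; ++t) {
            acc += w[t];
            if (u <= acc) { pick = t; break; }
        }
        const int winner = nbr(d, pick);
        occ[d] = occ[winner];
        return static_cast<int>(occ[d]) - orig;
    }

    int vac = d;
    double events = 0.0;
    for (;;) {
        const int k = deg[vac];
        double w[8], tot = 0.0;
        for (int t = 0; t < k; ++t) {
            const int j = nbr(vac, t);
            const double rdiv = occ[j] ? rB[j] : rA[j];
            const double rmig = occ[j] ? mB : mA;
            w[2 * t] = rdiv;
            w[2 * t + 1] = rmig;
            tot += rdiv + rmig;
        }
        if (tot <= 0.0) {
            if (vac == d) { return 0; }  // null update, dead cell restored
            stop("vacancy cascade is stuck: every neighbour has zero fitness and zero motility");
        }
        const double u = tot * unif_rand();
        *n_elem += 1.0;
        events += 1.0;
        if (events > cascade_cap)
            stop("elementary-event cap (%.0f) exceeded within a single update; "
                 "raise cascade_cap or check the motility regime", cascade_cap);
        int pick = 2 * k - 1;
        double acc = 0.0;
        for (int t = 0; t < 2 * k; ++t) {
            acc += w[t];
            if (u <= acc) { pick = t; break; }
        }
        const int j = nbr(vac, pick / 2);
        if ((pick & 1) == 0) {  // division fills the vacancy, update complete
            occ[vac] = occ[j];
            return static_cast<int>(occ[vac]) - orig;
        }
        occ[vac] = occ[j];  // migration relocates the vacancy
        vac = j;
    }
}

// [[Rcpp::export]]
List cpp_run_to_absorption(const IntegerMatrix& nbr, const IntegerVector& deg,
                           const NumericVector& rA, const NumericVector& rB,
                           double mA, double mB, const IntegerVector& occ0,
                           double max_updates, double cascade_cap,
                           bool migration_kernel) {
    const int N = occ0.size();
    std::vector<unsigned char> occ(N);
    int countB = 0;
    for (int i = 0; i < N; ++i) {
        occ[i] = static_cast<unsigned char>(occ0[i]);
        countB += occ[i];
    }
    double n_updates = 0.0, n_elem = 0.0;
    while (countB > 0 && countB < N) {
        if (n_updates >= max_updates) break;
        countB += one_update(occ, nbr, deg, rA, rB, mA, mB,
                             migration_kernel, cascade_cap, &n_elem);
        n_updates += 1.0;
        if (static_cast<long long>(n_updates) % 65536 == 0) checkUserInterrupt();
    }
    IntegerVector occ_out(N);
    for (int i = 0; i < N; ++i) occ_out[i] = occ[i];
    const bool absorbed = (countB == 0 || countB == N);
    return List::create(_["absorbed"] = absorbed,
                        _["fixed"] = absorbed ? LogicalVector::create(countB == N)
                                              : LogicalVector::create(NA_LOGICAL),
                        _["n_updates"] = n_updates,
                        _["n_elementary"] = n_elem,
                        _["occupancy"] = occ_out);
}

// Batch of independent absorption runs, each starting from all-A with a single
// mutant at start_sites[r] (0-based). Runs that hit max_updates abort the batch.
// [[Rcpp::export]]
List cpp_estimate_runs(const IntegerMatrix& nbr, const IntegerVector& deg,
                       const NumericVector& rA, const NumericVector& rB,
                       double mA, double mB, const IntegerVector& start_sites,
                       double max_updates, double cascade_cap,
                       bool migration_kernel) {
    const int N = deg.size();
    const int n_runs = start_sites.size();
    LogicalVector fixed(n_runs);
    NumericVector upd(n_runs), elem(n_runs);
    std::vector<unsigned char> occ(N);
    for (int r = 0; r < n_runs; ++r) {
        std::fill(occ.begin(), occ.end(), 0);
        occ[start_sites[r]] = 1;
        int countB = 1;
        double n_updates = 0.0, n_elem = 0.0;
        while (countB > 0 && countB < N) {
            if (n_updates >= max_updates)
                stop("run %d did not absorb within max_updates = %.0f",
                     r + 1, max_updates);
            countB += one_update(occ, nbr, deg, rA, rB, mA, mB,
                                 migration_kernel, cascade_cap, &n_elem);
            n_updates += 1.0;
        }
        fixed[r] = (countB == N);
        upd[r] = n_updates;
        elem[r] = n_elem;
        if (r % 256 == 0) checkUserInterrupt();
    }
    return List::create(_["fixed"] = fixed,
                        _["n_updates"] = upd,
                        _["n_elementary"] = elem);
}
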