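#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Population state is an N x 4 integer matrix of per-group strategy counts,
// columns in fixed order: defector, contributor, punisher, nonparticipant.
//
// Within a period each participant falls into one of six behavioural
// subclasses (canonical within-group order, used both for payoff columns and
// for mapping a drawn model index to an individual):
//   0 defector | 1 contributor_ok | 2 contributor_err |
//   3 punisher_ok | 4 punisher_err | 5 nonparticipant
//
// All randomness is consumed from R's RNG stream (unif_rand) in a documented
// canonical order so that an agent-level reference implementation written in
// plain R can reproduce every trajectory bit-for-bit.  The canonical order
// per period is:
//   stage 1  groups in index order; within a group one uniform per
//            contributor, then one per punisher (u < e means erroneous
//            defection)
//   stage 3  individuals in canonical order (groups in index order, within a
//            group subclasses 0..5, within a subclass by position); per
//            individual: one uniform for the mixing decision; if between-
//            group, one index draw for the other group then one for the
//            model inside it; otherwise one index draw over the n-1 other
//            group members; finally one uniform for the adoption decision
//   stage 4  one uniform per group in index order for conflict initiation,
//            plus one index draw for the opponent when initiated; then a
//            Fisher-Yates permutation of the N groups (N-1 index draws);
//            conflicts resolved in permuted order with one uniform each
//   stage 5  individuals in canonical order (strategy classes 0..3); one
//            uniform each; on mutation one index draw over the alternative
//            strategies (in fixed strategy order, excluding self and, in the
//            compulsory scenario, excluding nonparticipant)
// Index draws are floor(unif_rand() * k).

enum Strat { sD = 0, sC = 1, sP = 2, sZ = 3 };
enum Cls { cD = 0, cCok = 1, cCerr = 2, cPok = 3, cPerr = 4, cZ = 5 };

static const int cls2strat[6] = { sD, sC, sC, sP, sP, sZ };
static const double W_FLOOR = 1e-9;

static inline int idx_draw(int k) {
    int j = (int)(unif_rand() * k);
    if (j >= k) j = k - 1; // unreachable with the default RNG; rounding guard
    return j;
}

static inline int group_size(const IntegerMatrix& cnt, int g) {
    return cnt(g, 0) + cnt(g, 1) + cnt(g, 2) + cnt(g, 3);
}

// ---- stage 1: erroneous defection ------------------------------------------

static void do_realize(const IntegerMatrix& cnt, double e, IntegerMatrix& errs) {
    int N = cnt.nrow();
    for (int g = 0; g < N; g++) {
        int ce = 0, pe = 0;
        for (int t = 0; t < cnt(g, sC); t++) if (unif_rand() < e) ce++;
        for (int t = 0; t < cnt(g, sP); t++) if (unif_rand() < e) pe++;
        errs(g, 0) = ce;
        errs(g, 1) = pe;
    }
}

// ---- stage 2: punishment and payoffs ---------------------------------------

// Fills w (N x 6) with the subclass payoffs; returns the number of occupied
// subclasses whose payoff had to be clamped at the positivity floor.
static int do_payoffs(const IntegerMatrix& cnt, const IntegerMatrix& errs,
                      double b, double c, double p, double k, double omega,
                      NumericMatrix& w) {
    int N = cnt.nrow();
    int clamped = 0;
    for (int g = 0; g < N; g++) {
        int nD = cnt(g, sD), nC = cnt(g, sC), nP = cnt(g, sP), nZ = cnt(g, sZ);
        int n = nD + nC + nP + nZ;
        int ce = errs(g, 0), pe = errs(g, 1);
        double dn = (double)n;
        double A = (double)((nC - ce) + (nP - pe));   // realized contributors
        double Dhat = (double)(nD + ce + pe);         // realized defectors
        double xhat = A / dn;
        double y = (double)nP / dn;
        double base = 1.0 + b * xhat;
        w(g, cD)    = base - p * y;
        w(g, cCok)  = base - c;
        w(g, cCerr) = base - p * y;
        w(g, cPok)  = base - c - k * (Dhat / dn);
        w(g, cPerr) = base - p * ((double)(nP - 1) / dn)
                           - k * ((Dhat - 1.0) / dn);
        w(g, cZ)    = omega;
        int occ[6] = { nD, nC - ce, ce, nP - pe, pe, nZ };
        for (int q = 0; q < 6; q++) {
            if (w(g, q) < W_FLOOR) {
                if (occ[q] > 0) clamped++;
                w(g, q) = W_FLOOR;
            }
        }
    }
    return clamped;
}

// ---- stage 3: payoff-biased imitation --------------------------------------

static IntegerMatrix do_imitation(const IntegerMatrix& cnt,
                                  const IntegerMatrix& errs,
                                  const NumericMatrix& w, double m) {
    int N = cnt.nrow();
    IntegerMatrix sub(N, 6);
    for (int g = 0; g < N; g++) {
        sub(g, cD)    = cnt(g, sD);
        sub(g, cCok)  = cnt(g, sC) - errs(g, 0);
        sub(g, cCerr) = errs(g, 0);
        sub(g, cPok)  = cnt(g, sP) - errs(g, 1);
        sub(g, cPerr) = errs(g, 1);
        sub(g, cZ)    = cnt(g, sZ);
    }
    int n = group_size(cnt, 0);
    IntegerMatrix out(N, 4);
    for (int g = 0; g < N; g++) {
        int pos = 0; // canonical within-group index of the focal individual
        for (int q = 0; q < 6; q++) {
            double wi = w(g, q);
            for (int t = 0; t < sub(g, q); t++) {
                int mg, jidx;
                if (unif_rand() < m) {
                    mg = idx_draw(N - 1);
                    if (mg >= g) mg++;
                    jidx = idx_draw(n);
                } else {
                    mg = g;
                    jidx = idx_draw(n - 1);
                    if (jidx >= pos) jidx++; // skip self
                }
                int jq = 0, acc = sub(mg, 0);
                while (jidx >= acc) { jq++; acc += sub(mg, jq); }
                double wj = w(mg, jq);
                int snew = (unif_rand() < wj / (wj + wi))
                               ? cls2strat[jq] : cls2strat[q];
                out(g, snew)++;
                pos++;
            }
        }
    }
    return out;
}

// ---- stage 4: group conflict ------------------------------------------------

static void do_conflict(IntegerMatrix& cnt, double s) {
    int N = cnt.nrow();
    if (N < 2) return;
    double dn = (double)group_size(cnt, 0);
    std::vector<int> opp(N, -1);
    for (int g = 0; g < N; g++) {
        if (unif_rand() < s) {
            int o = idx_draw(N - 1);
            if (o >= g) o++;
            opp[g] = o;
        }
    }
    std::vector<int> perm(N);
    for (int g = 0; g < N; g++) perm[g] = g;
    for (int i = 0; i < N - 1; i++) {
        int j = i + idx_draw(N - i);
        std::swap(perm[i], perm[j]);
    }
    for (int t = 0; t < N; t++) {
        int i = perm[t], j = opp[perm[t]];
        if (j < 0) continue;
        double xi = (double)(cnt(i, sC) + cnt(i, sP)) / dn;
        double xj = (double)(cnt(j, sC) + cnt(j, sP)) / dn;
        int win, lose;
        if (unif_rand() < 0.5 * (1.0 + (xi - xj))) { win = i; lose = j; }
        else                                        { win = j; lose = i; }
        for (int q = 0; q < 4; q++) cnt(lose, q) = cnt(win, q);
    }
}

// ---- stage 5: mutation -------------------------------------------------------

static IntegerMatrix do_mutation(const IntegerMatrix& cnt, double mu,
                                 bool voluntary) {
    int N = cnt.nrow();
    IntegerMatrix out(N, 4);
    int nstrat = voluntary ? 4 : 3;
    int nalt = nstrat - 1;
    for (int g = 0; g < N; g++) {
        for (int q = 0; q < 4; q++) {
            for (int t = 0; t < cnt(g, q); t++) {
                int snew = q;
                if (unif_rand() < mu) {
                    int a = idx_draw(nalt);
                    int seen = 0;
                    for (int r = 0; r < nstrat; r++) {
                        if (r == q) continue;
                        if (seen == a) { snew = r; break; }
                        seen++;
                    }
                }
                out(g, snew)++;
            }
        }
    }
    return out;
}

// ---- exported single-stage entry points -------------------------------------

// [[Rcpp::export]]
IntegerMatrix pg_realize_cpp(IntegerMatrix counts, double e) {
    IntegerMatrix errs(counts.nrow(), 2);
    do_realize(counts, e, errs);
    return errs;
}

// [[Rcpp::export]]
List pg_payoffs_cpp(IntegerMatrix counts, IntegerMatrix errs,
                    double b, double c, double p, double k, double omega) {
    NumericMatrix w(counts.nrow(), 6);
    int clamped = do_payoffs(counts, errs, b, c, p, k, omega, w);
    return List::create(_["payoffs"] = w, _["clamped"] = clamped);
}

// [[Rcpp::export]]
IntegerMatrix pg_imitation_cpp(IntegerMatrix counts, IntegerMatrix errs,
                               NumericMatrix payoffs, double m) {
    return do_imitation(counts, errs, payoffs, m);
}

// [[Rcpp::export]]
IntegerMatrix pg_conflict_cpp(IntegerMatrix counts, double s) {
    IntegerMatrix cnt = clone(counts);
    do_conflict(cnt, s);
    return cnt;
}

// [[Rcpp::export]]
IntegerMatrix pg_mutation_cpp(IntegerMatrix counts, double mu, bool voluntary) {
    return do_mutation(counts, mu, voluntary);
}

// ---- full run ----------------------------------------------------------------

// Runs `periods` applications of the five-stage update and records the four
// global strategy frequencies plus the cooperation frequency after stage 5 of
// each period.  Returns the record matrix, the final counts and the number of
// payoff-positivity clamps applied across the whole run.
// [[Rcpp::export]]
List pg_run_cpp(IntegerMatrix counts, int periods,
                double b, double c, double p, double k,
                double m, double mu, double s, double e, double omega,
                bool voluntary) {
    int N = counts.nrow();
    IntegerMatrix cnt = clone(counts);
    IntegerMatrix errs(N, 2);
    NumericMatrix w(N, 6);
    NumericMatrix rec(periods, 5);
    double total = 0.0;
    for (int g = 0; g < N; g++) total += group_size(cnt, g);
    long clamped = 0;
    for (int t = 0; t < periods; t++) {
        do_realize(cnt, e, errs);
        clamped += do_payoffs(cnt, errs, b, c, p, k, omega, w);
        cnt = do_imitation(cnt, errs, w, m);
        do_conflict(cnt, s);
        cnt = do_mutation(cnt, mu, voluntary);
        double nd = 0, nc = 0, np = 0, nz = 0;
        for (int g = 0; g < N; g++) {
            nd += cnt(g, sD); nc += cnt(g, sC);
            np += cnt(g, sP); nz += cnt(g, sZ);
        }
        rec(t, 0) = nd / total;
        rec(t, 1) = nc / total;
        rec(t, 2) = np / total;
        rec(t, 3) = nz / total;
        rec(t, 4) = (nc + np) / total;
        if (t % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["records"] = rec, _["counts"] = cnt,
                        _["clamped"] = (double)clamped);
}
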