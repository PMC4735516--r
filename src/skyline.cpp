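#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Joint MCMC over (genealogy, grouped piecewise-constant thetas) for the
// Bayesian skyline model on a single non-recombining haplotype block.
//
// Conventions (documented in the R-level help):
//  - node indices are 0-based; tips are 0..n-1 at height 0, internals n..2n-2;
//  - heights are in substitutions/site (the strict clock is folded in);
//  - theta is the pairwise-coalescence scale: an interval with k lineages and
//    governing theta has total coalescent rate k(k-1)/(2 theta);
//  - the per-group theta hyperprior is uniform on log(theta) in [lo, hi].

// ---------------------------------------------------------------------------
// JC69 pruning likelihood over compressed site patterns.
// patterns: n_tips x P, codes 0..3; counts: pattern multiplicities.
static double jc69_loglik(const IntegerMatrix& pat, const NumericVector& cnt,
                          const std::vector<int>& left,
                          const std::vector<int>& right,
                          const std::vector<double>& height,
                          int root, int n_tips,
                          std::vector<double>& partials)
{
    const int P = pat.ncol();
    const int tot = (int) height.size();
    const int ni = tot - n_tips;
    // ultrametric tree: processing internals by increasing height guarantees
    // children are done before parents
    std::vector<std::pair<double,int> > ord(ni);
    for (int v = n_tips; v < tot; ++v)
        ord[v - n_tips] = std::make_pair(height[v], v);
    std::sort(ord.begin(), ord.end());

    for (int o = 0; o < ni; ++o) {
        const int v = ord[o].second;
        double* pv = &partials[(size_t)(v - n_tips) * P * 4];
        for (int c = 0; c < 2; ++c) {
            const int ch = (c == 0) ? left[v] : right[v];
            const double d = height[v] - height[ch];
            const double e = std::exp(-4.0 / 3.0 * d);
            const double ps = 0.25 + 0.75 * e;   // P(no net change)
            const double pd = 0.25 - 0.25 * e;   // P(specific other base)
            if (ch < n_tips) {
                for (int p = 0; p < P; ++p) {
                    const int code = pat(ch, p);
                    double* q = pv + (size_t)p * 4;
                    if (c == 0)
                        for (int x = 0; x < 4; ++x) q[x]  = (x == code) ? ps : pd;
                    else
                        for (int x = 0; x < 4; ++x) q[x] *= (x == code) ? ps : pd;
                }
            } else {
                const double* pc = &partials[(size_t)(ch - n_tips) * P * 4];
                for (int p = 0; p < P; ++p) {
                    const double* qc = pc + (size_t)p * 4;
                    const double S = qc[0] + qc[1] + qc[2] + qc[3];
                    double* q = pv + (size_t)p * 4;
                    if (c == 0)
                        for (int x = 0; x < 4; ++x)
                            q[x]  = ps * qc[x] + pd * (S - qc[x]);
                    else
                        for (int x = 0; x < 4; ++x)
                            q[x] *= ps * qc[x] + pd * (S - qc[x]);
                }
            }
        }
    }
    double ll = 0.0;
    const double* pr = &partials[(size_t)(root - n_tips) * P * 4];
    for (int p = 0; p < P; ++p) {
        const double* q = pr + (size_t)p * 4;
        ll += cnt[p] * std::log(0.25 * (q[0] + q[1] + q[2] + q[3]));
    }
    return ll;
}

// [[Rcpp::export(name = ".jc69_loglik_cpp")]]
double jc69_loglik_cpp(IntegerMatrix patterns, NumericVector counts,
                       IntegerVector left, IntegerVector right,
                       NumericVector height, int root, int n_tips)
{
    const int tot = height.size();
    std::vector<int> L(left.begin(), left.end());
    std::vector<int> R(right.begin(), right.end());
    std::vector<double> H(height.begin(), height.end());
    std::vector<double> partials((size_t)(tot - n_tips) * patterns.ncol() * 4);
    return jc69_loglik(patterns, counts, L, R, H, root, n_tips, partials);
}

// ---------------------------------------------------------------------------
// Generalized-skyline coalescent log density + theta hyperprior.
// Interval with k lineages, duration d, governing theta contributes
//   -k(k-1)d/(2 theta), plus log(k(k-1)/(2 theta)) at its closing event.
// Hyperprior (prior_type):
//   0 = none (pure coalescent density; thetas only checked positive)
//   1 = independent scale-invariant: uniform on log(theta) in [lo, hi]
//   2 = exponential Markov smoothing: theta_1 uniform on log within
//       [lo, hi], theta_g | theta_{g-1} ~ Exponential(mean theta_{g-1})
static double skyline_logprior(const std::vector<double>& height, int n_tips,
                               const std::vector<double>& theta,
                               const std::vector<int>& gsz,
                               double lo, double hi, int prior_type,
                               std::vector<double>& times)
{
    const int tot = (int) height.size();
    const int ni = tot - n_tips;
    const int m = (int) theta.size();
    for (int g = 0; g < m; ++g)
        if (!(theta[g] > 0.0)) return R_NegInf;
    if (prior_type == 1) {
        for (int g = 0; g < m; ++g)
            if (!(theta[g] >= lo && theta[g] <= hi)) return R_NegInf;
    } else if (prior_type == 2) {
        if (!(theta[0] >= lo && theta[0] <= hi)) return R_NegInf;
    }

    times.resize(ni);
    for (int v = n_tips; v < tot; ++v) times[v - n_tips] = height[v];
    std::sort(times.begin(), times.end());

    double lp = 0.0, tprev = 0.0;
    int g = 0, used = 0, k = n_tips;
    for (int e = 0; e < ni; ++e) {
        const double th = theta[g];
        const double d = times[e] - tprev;
        const double kk = (double)k * (double)(k - 1);
        lp += -kk * d / (2.0 * th) + std::log(kk / (2.0 * th));
        tprev = times[e];
        --k;
        if (++used == gsz[g]) { ++g; used = 0; }
    }
    if (prior_type == 1) {
        for (int gg = 0; gg < m; ++gg) lp -= std::log(theta[gg]);
    } else if (prior_type == 2) {
        lp -= std::log(theta[0]);
        for (int gg = 1; gg < m; ++gg)
            lp += -std::log(theta[gg - 1]) - theta[gg] / theta[gg - 1];
    }
    return lp;
}

// [[Rcpp::export(name = ".skyline_logprior_cpp")]]
double skyline_logprior_cpp(NumericVector height, int n_tips,
                            NumericVector theta, IntegerVector group_sizes,
                            double theta_lo, double theta_hi,
                            int prior_type)
{
    std::vector<double> H(height.begin(), height.end());
    std::vector<double> T(theta.begin(), theta.end());
    std::vector<int> G(group_sizes.begin(), group_sizes.end());
    std::vector<double> buf;
    return skyline_logprior(H, n_tips, T, G, theta_lo, theta_hi,
                            prior_type, buf);
}

// ---------------------------------------------------------------------------
// Metropolis-Hastings chain. Uses R's RNG (unif_rand) so set.seed() on the
// R side makes runs bit-reproducible.

enum MoveType { THETA_SCALE = 0, JOINT_SCALE, NODE_SLIDE, ROOT_SCALE,
                NARROW_EXCH, GROUP_MOVE, GROUP_SCALE, N_MOVES };

// [[Rcpp::export(name = ".skyline_mcmc_cpp")]]
List skyline_mcmc_cpp(IntegerMatrix patterns, NumericVector counts,
                      IntegerVector parent0, IntegerVector left0,
                      IntegerVector right0, NumericVector height0, int root,
                      NumericVector theta0, IntegerVector gsizes0,
                      double theta_lo, double theta_hi, int prior_type,
                      double chain_length_d, int thin, double burn_in_fraction,
                      bool sample_prior, NumericVector move_weights)
{
    RNGScope scope;
    const int n_tips = patterns.nrow();
    const int tot = height0.size();
    const int ni = tot - n_tips;
    const int m = theta0.size();
    const long long chain_length = (long long) chain_length_d;
    const long long burn = (long long) std::floor(chain_length * burn_in_fraction);

    std::vector<int> parent(parent0.begin(), parent0.end());
    std::vector<int> left(left0.begin(), left0.end());
    std::vector<int> right(right0.begin(), right0.end());
    std::vector<double> height(height0.begin(), height0.end());
    std::vector<double> theta(theta0.begin(), theta0.end());
    std::vector<int> gsz(gsizes0.begin(), gsizes0.end());

    std::vector<double> partials((size_t)ni * patterns.ncol() * 4);
    std::vector<double> tbuf;

    // proposal tuning constants (multiplier windows); the group-scale
    // window is wide because rescaling a group's durations together with
    // its theta leaves the coalescent density almost unchanged
    const double lam_theta = 2.0, lam_joint = 0.7, lam_root = 0.8;
    const double lam_group = 5.0;

    double cw[N_MOVES];
    {
        double s = 0.0;
        for (int i = 0; i < N_MOVES; ++i) s += move_weights[i];
        double c = 0.0;
        for (int i = 0; i < N_MOVES; ++i) { c += move_weights[i] / s; cw[i] = c; }
        cw[N_MOVES - 1] = 1.0;
    }

    double cur_ll = sample_prior ? 0.0 :
        jc69_loglik(patterns, counts, left, right, height, root, n_tips, partials);
    double cur_lp = skyline_logprior(height, n_tips, theta, gsz,
                                     theta_lo, theta_hi, prior_type, tbuf);
    if (!R_finite(cur_ll + cur_lp))
        stop("non-finite posterior at the initial state");

    const long long n_keep = (chain_length - burn) / thin +
        (((chain_length - burn) % thin) ? 1 : 0);
    // record at steps s in (burn, chain] with s % thin == 0
    long long n_rec_expect = chain_length / thin - burn / thin;
    NumericMatrix rec_theta(n_rec_expect, m);
    NumericMatrix rec_times(n_rec_expect, ni);
    IntegerMatrix rec_gsz(n_rec_expect, m);
    NumericVector rec_lp(n_rec_expect);
    (void) n_keep;

    std::vector<long long> prop_cnt(N_MOVES, 0), acc_cnt(N_MOVES, 0);
    long long rec = 0;

    for (long long step = 1; step <= chain_length; ++step) {
        const double u = unif_rand();
        int mv = 0;
        while (u > cw[mv]) ++mv;
        ++prop_cnt[mv];

        double lhr = 0.0;          // log Hastings ratio
        bool tree_changed = false, ok = true;

        // undo buffers
        int ug = -1; double uth = 0.0;
        int uv = -1; double uh = 0.0;
        std::vector<double> uheight; std::vector<double> utheta;
        int sw_a = -1, sw_b = -1, sw_pa = -1, sw_pb = -1;
        int ug2 = -1, gdir = 0;

        switch (mv) {
        case THETA_SCALE: {
            ug = (int)(unif_rand() * m); if (ug >= m) ug = m - 1;
            const double s = std::exp(lam_theta * (unif_rand() - 0.5));
            uth = theta[ug];
            theta[ug] *= s;
            lhr = std::log(s);
            break;
        }
        case JOINT_SCALE: {
            const double s = std::exp(lam_joint * (unif_rand() - 0.5));
            uheight = height; utheta = theta;
            for (int v = n_tips; v < tot; ++v) height[v] *= s;
            for (int g = 0; g < m; ++g) theta[g] *= s;
            lhr = (ni + m) * std::log(s);
            tree_changed = true;
            break;
        }
        case NODE_SLIDE: {
            // uniform slide of one non-root internal node between its
            // children's max height and its parent's height (symmetric)
            if (ni <= 1) { ok = false; break; }
            int v;
            do {
                v = n_tips + (int)(unif_rand() * ni);
                if (v >= tot) v = tot - 1;
            } while (v == root);
            const double lb = std::max(height[left[v]], height[right[v]]);
            const double ub = height[parent[v]];
            uv = v; uh = height[v];
            height[v] = lb + unif_rand() * (ub - lb);
            tree_changed = true;
            break;
        }
        case ROOT_SCALE: {
            const double s = std::exp(lam_root * (unif_rand() - 0.5));
            const double lb = std::max(height[left[root]], height[right[root]]);
            const double h = height[root] * s;
            if (h <= lb) { ok = false; break; }
            uv = root; uh = height[root];
            height[root] = h;
            lhr = std::log(s);
            tree_changed = true;
            break;
        }
        case NARROW_EXCH: {
            // swap a random child of a non-root internal node with its uncle
            if (ni <= 1) { ok = false; break; }
            int p;
            do {
                p = n_tips + (int)(unif_rand() * ni);
                if (p >= tot) p = tot - 1;
            } while (p == root);
            const int gp = parent[p];
            const int uncle = (left[gp] == p) ? right[gp] : left[gp];
            if (height[uncle] >= height[p]) { ok = false; break; }
            const int c = (unif_rand() < 0.5) ? left[p] : right[p];
            // swap c <-> uncle
            if (left[p] == c) left[p] = uncle; else right[p] = uncle;
            if (left[gp] == uncle) left[gp] = c; else right[gp] = c;
            parent[c] = gp; parent[uncle] = p;
            sw_a = c; sw_b = uncle; sw_pa = p; sw_pb = gp;
            tree_changed = true;
            break;
        }
        case GROUP_MOVE: {
            // move one coalescent interval between adjacent groups
            if (m <= 1) { ok = false; break; }
            ug2 = (int)(unif_rand() * (m - 1)); if (ug2 >= m - 1) ug2 = m - 2;
            const int dir = (unif_rand() < 0.5) ? 1 : -1;
            if (dir > 0) {
                if (gsz[ug2] <= 1) { ok = false; break; }
                --gsz[ug2]; ++gsz[ug2 + 1];
            } else {
                if (gsz[ug2 + 1] <= 1) { ok = false; break; }
                ++gsz[ug2]; --gsz[ug2 + 1];
            }
            gdir = dir;
            break;
        }
        case GROUP_SCALE: {
            // scale one group's theta together with the durations of the
            // coalescent intervals it governs, translating older events by
            // the net change (order-preserving in all node heights)
            const int g = std::min((int)(unif_rand() * m), m - 1);
            const double s = std::exp(lam_group * (unif_rand() - 0.5));
            // group g's time span [b_lo, b_hi] from sorted event times
            tbuf.resize(ni);
            for (int v = n_tips; v < tot; ++v) tbuf[v - n_tips] = height[v];
            std::sort(tbuf.begin(), tbuf.end());
            int first = 0;
            for (int gg = 0; gg < g; ++gg) first += gsz[gg];
            const double b_lo = (first == 0) ? 0.0 : tbuf[first - 1];
            const double b_hi = tbuf[first + gsz[g] - 1];
            const double shift = (s - 1.0) * (b_hi - b_lo);
            uheight = height; utheta = theta;
            for (int v = n_tips; v < tot; ++v) {
                if (height[v] > b_hi) height[v] += shift;
                else if (height[v] > b_lo)
                    height[v] = b_lo + s * (height[v] - b_lo);
            }
            theta[g] *= s;
            lhr = (gsz[g] + 1) * std::log(s);
            tree_changed = true;
            break;
        }
        }

        bool accepted = false;
        if (ok) {
            const double new_lp = skyline_logprior(height, n_tips, theta, gsz,
                                                   theta_lo, theta_hi,
                                                   prior_type, tbuf);
            double new_ll = cur_ll;
            if (R_finite(new_lp) && tree_changed && !sample_prior)
                new_ll = jc69_loglik(patterns, counts, left, right, height,
                                     root, n_tips, partials);
            if (R_finite(new_lp)) {
                const double logr = (new_ll + new_lp) - (cur_ll + cur_lp) + lhr;
                if (logr >= 0.0 || std::log(unif_rand()) < logr) {
                    accepted = true;
                    cur_ll = new_ll; cur_lp = new_lp;
                    ++acc_cnt[mv];
                }
            }
        }
        if (!accepted) {
            switch (mv) {
            case THETA_SCALE: if (ug >= 0) theta[ug] = uth; break;
            case JOINT_SCALE:
            case GROUP_SCALE:
                if (!uheight.empty()) { height = uheight; theta = utheta; }
                break;
            case NODE_SLIDE:
            case ROOT_SCALE: if (uv >= 0) height[uv] = uh; break;
            case NARROW_EXCH:
                if (sw_a >= 0) {
                    // reverse the swap: sw_a currently under sw_pb, sw_b under sw_pa
                    if (left[sw_pb] == sw_a) left[sw_pb] = sw_b; else right[sw_pb] = sw_b;
                    if (left[sw_pa] == sw_b) left[sw_pa] = sw_a; else right[sw_pa] = sw_a;
                    parent[sw_a] = sw_pa; parent[sw_b] = sw_pb;
                }
                break;
            case GROUP_MOVE:
                if (gdir != 0) {
                    if (gdir > 0) { ++gsz[ug2]; --gsz[ug2 + 1]; }
                    else          { --gsz[ug2]; ++gsz[ug2 + 1]; }
                }
                break;
            }
        }

        if (step > burn && step % thin == 0 && rec < n_rec_expect) {
            tbuf.resize(ni);
            for (int v = n_tips; v < tot; ++v) tbuf[v - n_tips] = height[v];
            std::sort(tbuf.begin(), tbuf.end());
            for (int e = 0; e < ni; ++e) rec_times(rec, e) = tbuf[e];
            for (int g = 0; g < m; ++g) {
                rec_theta(rec, g) = theta[g];
                rec_gsz(rec, g) = gsz[g];
            }
            rec_lp[rec] = cur_ll + cur_lp;
            ++rec;
        }
        if (step % 100000 == 0) Rcpp::checkUserInterrupt();
    }

    NumericVector acc(N_MOVES), props(N_MOVES);
    for (int i = 0; i < N_MOVES; ++i) {
        props[i] = (double) prop_cnt[i];
        acc[i] = prop_cnt[i] ? (double) acc_cnt[i] / prop_cnt[i] : NA_REAL;
    }
    return List::create(
        _["theta"] = rec_theta,
        _["coal_times"] = rec_times,
        _["group_sizes"] = rec_gsz,
        _["log_posterior"] = rec_lp,
        _["n_retained"] = (double) rec,
        _["acceptance"] = acc,
        _["proposals"] = props);
}
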