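// Wiener first-passage-time machinery for two-boundary diffusion.
//
// Convention: accumulation starts at relative position w in (0,1) between an
// absorbing lower boundary at 0 and an upper boundary at a; drift v, diffusion
// coefficient sigma = 1. Densities are "defective": each boundary's branch
// integrates to that boundary's absorption probability.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// log of the standardized (a = 1, v = 0) lower-boundary FPT density at
// normalized time tt = t / a^2, start w. Chooses between the small-time and
// large-time series by the number of terms each needs for truncation error
// below `eps` (adaptive rule after Navarro & Fuss 2009).
static double logfw(double tt, double w, double eps = 1e-10) {
    if (tt <= 0.0) return R_NegInf;

    // terms needed by each representation
    double ks = 2.0, kl = 1.0 / (M_PI * std::sqrt(tt));
    if (M_PI * tt * eps < 1.0) {
        kl = std::max(kl, std::sqrt(-2.0 * std::log(M_PI * tt * eps) /
                                    (M_PI * M_PI * tt)));
    }
    double tmp = 2.0 * std::sqrt(2.0 * M_PI * tt) * eps;
    if (tmp < 1.0) {
        ks = std::max(2.0 + std::sqrt(-2.0 * tt * std::log(tmp)),
                      std::sqrt(tt) + 1.0);
    }

    double f;
    if (ks < kl) {  // small-time expansion
        int K = (int)std::ceil(ks);
        double s = 0.0;
        for (int k = -((K - 1) / 2); k <= K / 2; ++k) {
            double u = w + 2.0 * k;
            s += u * std::exp(-u * u / (2.0 * tt));
        }
        f = s / std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {        // large-time expansion
        int K = (int)std::ceil(kl);
        double s = 0.0;
        for (int k = 1; k <= K; ++k) {
            s += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        f = M_PI * s;
    }
    if (f <= 0.0 || !R_FINITE(f)) return R_NegInf;  // deep-tail underflow
    return std::log(f);
}

// log density of hitting the LOWER boundary at decision time td (> 0)
static double wfpt_log_lower(double td, double v, double a, double w) {
    if (td <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return R_NegInf;
    double tt = td / (a * a);
    return logfw(tt, w) - 2.0 * std::log(a) - v * a * w - v * v * td / 2.0;
}

// upper boundary by reflection: (v, w) -> (-v, 1 - w)
static double wfpt_log(double td, bool upper, double v, double a, double w) {
    return upper ? wfpt_log_lower(td, -v, a, 1.0 - w)
                 : wfpt_log_lower(td, v, a, w);
}

// [[Rcpp::export]]
NumericVector cpp_fpt_log_density(NumericVector t, IntegerVector upper,
                                  NumericVector v, NumericVector a,
                                  NumericVector tau, NumericVector w) {
    R_xlen_t n = std::max({t.size(), upper.size(), v.size(), a.size(),
                           tau.size(), w.size()});
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        double td = t[i % t.size()] - tau[i % tau.size()];
        out[i] = wfpt_log(td, upper[i % upper.size()] != 0, v[i % v.size()],
                          a[i % a.size()], w[i % w.size()]);
    }
    return out;
}

// Sum of trialwise log densities for one subject-by-condition cell in the
// kappa-scaled evidence parameterisation: drift = kappa * E, accuracy coded
// (upper boundary = correct choice), fixed start fraction w.
// [[Rcpp::export]]
double cpp_loglik_cell(NumericVector rt, IntegerVector correct,
                       NumericVector ev, double kappa, double alpha,
                       double tau, double w) {
    if (!R_FINITE(kappa) || !R_FINITE(alpha) || !R_FINITE(tau) ||
        alpha <= 0.0 || tau < 0.0)
        return R_NegInf;
    double s = 0.0;
    R_xlen_t n = rt.size();
    for (R_xlen_t i = 0; i < n; ++i) {
        double td = rt[i] - tau;
        if (td <= 0.0) return R_NegInf;
        s += wfpt_log(td, correct[i] != 0, kappa * ev[i], alpha, w);
        if (!R_FINITE(s)) return R_NegInf;
    }
    return s;
}

// Neural-modulated cell likelihood: effective boundary alpha + gamma_a*theta
// (floored at `floor_a`, clip count returned) and effective drift
// kappa*E + gamma_d*theta.
// [[Rcpp::export]]
NumericVector cpp_loglik_cell_neural(NumericVector rt, IntegerVector correct,
                                     NumericVector ev, NumericVector theta,
                                     double kappa, double alpha, double tau,
                                     double gamma_a, double gamma_d,
                                     double w, double floor_a) {
    NumericVector out(2);
    if (!R_FINITE(kappa) || !R_FINITE(alpha) || !R_FINITE(tau) ||
        alpha <= 0.0 || tau < 0.0) {
        out[0] = R_NegInf;
        return out;
    }
    double s = 0.0;
    int nclip = 0;
    R_xlen_t n = rt.size();
    for (R_xlen_t i = 0; i < n; ++i) {
        double td = rt[i] - tau;
        if (td <= 0.0) { out[0] = R_NegInf; out[1] = nclip; return out; }
        double ai = alpha + gamma_a * theta[i];
        if (ai < floor_a) { ai = floor_a; ++nclip; }
        double vi = kappa * ev[i] + gamma_d * theta[i];
        s += wfpt_log(td, correct[i] != 0, vi, ai, w);
        if (!R_FINITE(s)) { out[0] = R_NegInf; out[1] = nclip; return out; }
    }
    out[0] = s;
    out[1] = nclip;
    return out;
}

// ---------------------------------------------------------------------------
// Path simulation: Euler-Maruyama with a self-contained counter-free RNG so
// that very long simulations do not go through R's RNG call overhead.
// xoshiro256++ seeded via splitmix64; standard normals by Marsaglia's polar
// method.

struct Xoshiro {
    uint64_t s[4];
    explicit Xoshiro(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {  // splitmix64 expansion
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
    uint64_t next() {
        uint64_t r = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return r;
    }
    double unif() {  // (0, 1)
        return (next() >> 11) * 1.1102230246251565e-16 +
               5.551115123125783e-17;
    }
    bool have_spare = false;
    double spare = 0.0;
    double norm() {
        if (have_spare) { have_spare = false; return spare; }
        double u, v, q;
        do {
            u = 2.0 * unif() - 1.0;
            v = 2.0 * unif() - 1.0;
            q = u * u + v * v;
        } while (q >= 1.0 || q == 0.0);
        double f = std::sqrt(-2.0 * std::log(q) / q);
        spare = v * f;
        have_spare = true;
        return u * f;
    }
};

// Simulate first-passage outcomes for n trials with per-trial parameters
// (recycled if length 1). Returns rt (tau + decision time), upper hit flag,
// and a censored flag for paths not absorbed by t_max. `bshift` moves both
// boundaries inward (continuity correction for the discrete-time overshoot,
// 0.5826 * sigma * sqrt(dt); pass 0 for the uncorrected scheme).
// [[Rcpp::export]]
List cpp_sim_trials(NumericVector v, NumericVector a, NumericVector w,
                    NumericVector tau, int n, double dt, double t_max,
                    double seed, double bshift = 0.0) {
    Xoshiro rng((uint64_t)seed);
    NumericVector rt(n);
    IntegerVector up(n), cens(n);
    double sdt = std::sqrt(dt);
    long max_steps = (long)std::ceil(t_max / dt);
    for (int i = 0; i < n; ++i) {
        double vi = v[i % v.size()], ai = a[i % a.size()];
        double x = w[i % w.size()] * ai, ti = tau[i % tau.size()];
        double hi = ai - bshift, lo = bshift;
        if (hi <= x || lo >= x) { hi = ai; lo = 0.0; }  // shift too large
        double drift_step = vi * dt;
        long k = 0;
        int hit = -1;
        while (k < max_steps) {
            x += drift_step + sdt * rng.norm();
            ++k;
            if (x >= hi) { hit = 1; break; }
            if (x <= lo) { hit = 0; break; }
        }
        if (hit < 0) {
            rt[i] = NA_REAL; up[i] = NA_INTEGER; cens[i] = 1;
        } else {
            rt[i] = ti + k * dt; up[i] = hit; cens[i] = 0;
        }
    }
    return List::create(_["rt"] = rt, _["upper"] = up, _["censored"] = cens);
}
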