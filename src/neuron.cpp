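#include <Rcpp.h>
#include <vector>
#include "fx.h"

using namespace Rcpp;
using namespace srfixp;

// Izhikevich model stepped by unrolled fixed-timestep solvers.  The solver
// algebra below is written once, templated over an arithmetic policy, so
// binary64, binary32 and fixed-point backends execute the *same* expression
// tree and differ only in how each elementary operation rounds.  Observed
// spike-time differences between backends are therefore pure arithmetic
// error.
//
// Right-hand side (mV/ms conventions of the model):
//   dv/dt = 0.04 v^2 + 5 v + 140 - u + I
//   du/dt = a (b v - u)
// evaluated in Horner form (0.04 v + 5) v + 140 - u + I so that no
// intermediate exceeds the range of the 16-bit state format, and with the
// recovery increment multiplied by fused sub-unity constants (a*h etc.)
// held at full fraction precision.

// constant slots, mirrored by make_constants() on the R side
enum {
    K_C004 = 0, K_FIVE, K_C140, K_B, K_A, K_C008,
    K_H, K_H2, K_H3, K_T2H3, K_H4, K_T3H4, K_HH8, K_HH6, K_HH3,
    K_AH, K_AH2, K_AH3, K_A2H3, K_AH4, K_A3H4,
    N_CONST
};

enum { SOLV_RK2MID = 0, SOLV_RK2TRAP, SOLV_RK3HEUN, SOLV_CHANTSAI };

// ------------------------------------------------------------ policies ----

template <typename T>
struct PolFloat {
    typedef T S;
    T K[N_CONST];
    T thr, vreset, dinc;
    long n_mul = 0, n_add = 0, sat = 0;

    void begin_step(Rng*) {}
    S mul_ss(S a, S b) { n_mul++; return a * b; }
    S mul_c(S a, int ci) { n_mul++; return a * K[ci]; }
    S add(S a, S b) { n_add++; return a + b; }
    S sub(S a, S b) { n_add++; return a - b; }
    S add_c(S a, int ci) { n_add++; return a + K[ci]; }
    bool spike(S v) const { return v >= thr; }
    S from_real(double x, Rng*) { return static_cast<S>(x); }
    double to_real(S x) const { return static_cast<double>(x); }
};

struct PolFixed {
    typedef int64_t S;
    FmtI sfmt;          // state format (s16.15 or s8.7)
    int p_c;            // fraction bits of the sub-unity constant format
    int mode, srk;
    Rng* g = nullptr;
    int64_t Kraw[N_CONST];
    int cfmt[N_CONST];  // 1 = constant held in the u0.p_c format, 0 = state format
    bool ssel = false;  // stochastic constant selection
    int64_t slo[N_CONST];
    double sp[N_CONST];
    int64_t thr, vreset, dinc;
    long n_mul = 0, n_add = 0, sat = 0;

    void begin_step(Rng* gen) {
        if (!ssel) return;
        for (int ci = 0; ci < N_CONST; ci++) {
            if (sp[ci] > 0) {
                double pdraw =
                    static_cast<double>(rng_next(*gen)) / 4294967296.0;
                Kraw[ci] = slo[ci] + (pdraw < sp[ci] ? 1 : 0);
            }
        }
    }
    S mul_ss(S a, S b) {
        n_mul++;
        return mul_raw(a, sfmt.p, b, sfmt.p, sfmt, mode, srk, g, sat);
    }
    S mul_c(S a, int ci) {
        n_mul++;
        int pc = cfmt[ci] ? p_c : sfmt.p;
        return mul_raw(a, sfmt.p, Kraw[ci], pc, sfmt, mode, srk, g, sat);
    }
    S add(S a, S b) { n_add++; return clamp_raw(a + b, sfmt, sat); }
    S sub(S a, S b) { n_add++; return clamp_raw(a - b, sfmt, sat); }
    S add_c(S a, int ci) { n_add++; return clamp_raw(a + Kraw[ci], sfmt, sat); }
    bool spike(S v) const { return v >= thr; }
    // runtime inputs are converted with RN and saturate (flagged) rather
    // than raise: an out-of-range dithered current must not kill a run
    S from_real(double x, Rng*) {
        double xs = std::ldexp(x, sfmt.p);
        double fl = std::floor(xs);
        int64_t raw = static_cast<int64_t>(fl);
        if (xs - fl >= 0.5) raw++;
        return clamp_raw(raw, sfmt, sat);
    }
    double to_real(S x) const { return std::ldexp(static_cast<double>(x), -sfmt.p); }
};

// -------------------------------------------------------------- solvers ----

template <class P>
inline void rhs_eval(P& ar, typename P::S v, typename P::S u,
                     typename P::S I, typename P::S& kv,
                     typename P::S& w) {
    typedef typename P::S S;
    S t = ar.mul_c(v, K_C004);     // 0.04 v        (state x sub-unity const)
    t = ar.add_c(t, K_FIVE);       // 0.04 v + 5
    t = ar.mul_ss(t, v);           // (0.04 v + 5) v
    t = ar.add_c(t, K_C140);
    t = ar.sub(t, u);
    kv = ar.add(t, I);             // dv/dt
    w = ar.sub(ar.mul_c(v, K_B), u); // b v - u; du/dt = a w
}

template <class P>
inline void step_once(P& ar, int solver, typename P::S& v,
                      typename P::S& u, typename P::S I) {
    typedef typename P::S S;
    S k1, w1, k2, w2, k3, w3;
    switch (solver) {
    case SOLV_RK2MID: {
        rhs_eval(ar, v, u, I, k1, w1);
        S vm = ar.add(v, ar.mul_c(k1, K_H2));
        S um = ar.add(u, ar.mul_c(w1, K_AH2));
        rhs_eval(ar, vm, um, I, k2, w2);
        v = ar.add(v, ar.mul_c(k2, K_H));
        u = ar.add(u, ar.mul_c(w2, K_AH));
        break;
    }
    case SOLV_RK2TRAP: {
        rhs_eval(ar, v, u, I, k1, w1);
        S ve = ar.add(v, ar.mul_c(k1, K_H));
        S ue = ar.add(u, ar.mul_c(w1, K_AH));
        rhs_eval(ar, ve, ue, I, k2, w2);
        v = ar.add(v, ar.mul_c(ar.add(k1, k2), K_H2));
        u = ar.add(u, ar.mul_c(ar.add(w1, w2), K_AH2));
        break;
    }
    case SOLV_RK3HEUN: {
        rhs_eval(ar, v, u, I, k1, w1);
        S v2 = ar.add(v, ar.mul_c(k1, K_H3));
        S u2 = ar.add(u, ar.mul_c(w1, K_AH3));
        rhs_eval(ar, v2, u2, I, k2, w2);
        S v3 = ar.add(v, ar.mul_c(k2, K_T2H3));
        S u3 = ar.add(u, ar.mul_c(w2, K_A2H3));
        rhs_eval(ar, v3, u3, I, k3, w3);
        v = ar.add(ar.add(v, ar.mul_c(k1, K_H4)), ar.mul_c(k3, K_T3H4));
        u = ar.add(ar.add(u, ar.mul_c(w1, K_AH4)), ar.mul_c(w3, K_A3H4));
        break;
    }
    default: {
        // Two-derivative Runge-Kutta variant (one f and two g evaluations
        // per step) with g = f' f computed analytically:
        //   g_v = (0.08 v + 5) f_v - f_u,  g_u = a (b f_v - f_u)
        //   y1 = y + h/2 f + h^2/8 g(y)
        //   y' = y + h f + h^2/6 g(y) + h^2/3 g(y1)
        rhs_eval(ar, v, u, I, k1, w1);
        S fu1 = ar.mul_c(w1, K_A);
        S q1 = ar.add_c(ar.mul_c(v, K_C008), K_FIVE);
        S gv1 = ar.sub(ar.mul_ss(q1, k1), fu1);
        S gu1 = ar.mul_c(ar.sub(ar.mul_c(k1, K_B), fu1), K_A);
        S v1 = ar.add(ar.add(v, ar.mul_c(k1, K_H2)), ar.mul_c(gv1, K_HH8));
        S u1 = ar.add(ar.add(u, ar.mul_c(fu1, K_H2)), ar.mul_c(gu1, K_HH8));
        rhs_eval(ar, v1, u1, I, k2, w2);
        S fu2 = ar.mul_c(w2, K_A);
        S q2 = ar.add_c(ar.mul_c(v1, K_C008), K_FIVE);
        S gv2 = ar.sub(ar.mul_ss(q2, k2), fu2);
        S gu2 = ar.mul_c(ar.sub(ar.mul_c(k2, K_B), fu2), K_A);
        v = ar.add(ar.add(v, ar.mul_c(k1, K_H)),
                   ar.add(ar.mul_c(gv1, K_HH6), ar.mul_c(gv2, K_HH3)));
        u = ar.add(ar.add(u, ar.mul_c(fu1, K_H)),
                   ar.add(ar.mul_c(gu1, K_HH6), ar.mul_c(gu2, K_HH3)));
        break;
    }
    }
}

// ------------------------------------------------------------ run loop ----

struct RunSpec {
    int solver;
    double h;
    long max_steps;
    int target_spikes;     // 0 = run to max_steps
    int input_kind;        // 0 DC, 1 exponential decay
    double I0, tau;
    double dither_sd;      // absolute units, 0 = off
    bool trace;
};

template <class P>
static List run_loop(P& ar, const RunSpec& rs, Rng* g, double v0,
                     double u0) {
    typedef typename P::S S;
    S v = ar.from_real(v0, g);
    S u = ar.from_real(u0, g);
    std::vector<double> spikes;
    std::vector<double> tv, tu;
    if (rs.trace) {
        tv.reserve(rs.max_steps);
        tu.reserve(rs.max_steps);
    }
    bool fixed_I = (rs.input_kind == 0) && rs.dither_sd <= 0;
    S I = ar.from_real(rs.I0, g);
    long n = 0;
    for (; n < rs.max_steps; n++) {
        if (!fixed_I) {
            double id = rs.I0;
            if (rs.input_kind == 1)
                id *= std::exp(-(static_cast<double>(n) * rs.h) / rs.tau);
            if (rs.dither_sd > 0) id += rs.dither_sd * rng_gauss(*g);
            I = ar.from_real(id, g);
        }
        ar.begin_step(g);
        step_once(ar, rs.solver, v, u, I);
        bool fired = ar.spike(v);
        if (rs.trace) { // pre-reset value, so traces show the spike peak
            tv.push_back(ar.to_real(v));
            tu.push_back(ar.to_real(u));
        }
        if (fired) {
            spikes.push_back(static_cast<double>(n + 1));
            v = ar.vreset;
            u = ar.add(u, ar.dinc);
            if (rs.target_spikes > 0 &&
                static_cast<int>(spikes.size()) >= rs.target_spikes) {
                n++;
                break;
            }
        }
    }
    return List::create(
        _["spike_steps"] = NumericVector(spikes.begin(), spikes.end()),
        _["n_steps"] = static_cast<double>(n),
        _["saturations"] = static_cast<double>(ar.sat),
        _["n_mul"] = static_cast<double>(ar.n_mul),
        _["n_add"] = static_cast<double>(ar.n_add),
        _["v_trace"] = NumericVector(tv.begin(), tv.end()),
        _["u_trace"] = NumericVector(tu.begin(), tu.end()));
}

// [[Rcpp::export(name = "C_izh_run")]]
List C_izh_run(List a) {
    RunSpec rs;
    rs.solver = as<int>(a["solver"]);
    rs.h = as<double>(a["h"]);
    rs.max_steps = static_cast<long>(as<double>(a["max_steps"]));
    rs.target_spikes = as<int>(a["target_spikes"]);
    rs.input_kind = as<int>(a["input_kind"]);
    rs.I0 = as<double>(a["I0"]);
    rs.tau = as<double>(a["tau"]);
    rs.dither_sd = as<double>(a["dither_sd"]);
    rs.trace = as<bool>(a["trace"]);
    int backend = as<int>(a["backend"]);
    double v0 = as<double>(a["v0"]), u0 = as<double>(a["u0"]);
    NumericVector cval = a["cval"];
    Rng* g = nullptr;
    if (!Rf_isNull(a["rng"])) {
        XPtr<Rng> gp(as<SEXP>(a["rng"]));
        g = gp.get();
    }

    if (backend == 0 || backend == 1) {
        if (backend == 0) {
            PolFloat<double> ar;
            for (int ci = 0; ci < N_CONST; ci++) ar.K[ci] = cval[ci];
            ar.thr = as<double>(a["thr"]);
            ar.vreset = as<double>(a["vreset"]);
            ar.dinc = as<double>(a["d"]);
            return run_loop(ar, rs, g, v0, u0);
        }
        PolFloat<float> ar;
        for (int ci = 0; ci < N_CONST; ci++)
            ar.K[ci] = static_cast<float>(cval[ci]);
        ar.thr = static_cast<float>(as<double>(a["thr"]));
        ar.vreset = static_cast<float>(as<double>(a["vreset"]));
        ar.dinc = static_cast<float>(as<double>(a["d"]));
        return run_loop(ar, rs, g, v0, u0);
    }

    PolFixed ar;
    ar.sfmt = FmtI{true, as<int>(a["i_s"]), as<int>(a["p_s"])};
    ar.p_c = as<int>(a["p_c"]);
    ar.mode = as<int>(a["mode"]);
    ar.srk = as<int>(a["srk"]);
    ar.g = g;
    NumericVector craw = a["craw"];
    IntegerVector cfmt = a["cfmt"];
    for (int ci = 0; ci < N_CONST; ci++) {
        ar.Kraw[ci] = static_cast<int64_t>(craw[ci]);
        ar.cfmt[ci] = cfmt[ci];
        ar.sp[ci] = 0;
        ar.slo[ci] = ar.Kraw[ci];
    }
    ar.ssel = as<bool>(a["ssel"]);
    if (ar.ssel) {
        NumericVector slo = a["slo"];
        NumericVector sp = a["sp"];
        for (int ci = 0; ci < N_CONST; ci++) {
            ar.slo[ci] = static_cast<int64_t>(slo[ci]);
            ar.sp[ci] = sp[ci];
        }
    }
    ar.thr = static_cast<int64_t>(as<double>(a["thr_raw"]));
    ar.vreset = static_cast<int64_t>(as<double>(a["vreset_raw"]));
    ar.dinc = static_cast<int64_t>(as<double>(a["d_raw"]));
    if (ar.mode == MODE_SR && g == nullptr)
        stop("stochastic rounding backend needs a generator");
    return run_loop(ar, rs, g, v0, u0);
}
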