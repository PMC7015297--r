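#include <Rcpp.h>
#include "fx.h"

using namespace Rcpp;
using namespace srfixp;

// Raw values cross the R boundary as doubles; they must be integral and
// small enough to be exact (|x| < 2^53).  Inside src/ everything is int64
// or int128, so nothing here ever rounds in binary64.

static int64_t as_i64(double x, const char* what) {
    if (!R_finite(x) || std::floor(x) != x || std::fabs(x) >= 9007199254740992.0)
        stop("%s must be an exact integer below 2^53", what);
    return static_cast<int64_t>(x);
}

static Rng* rng_or_null(SEXP ptr) {
    if (Rf_isNull(ptr)) return nullptr;
    XPtr<Rng> g(ptr);
    return g.get();
}

// [[Rcpp::export(name = "C_round_raw")]]
NumericVector C_round_raw(NumericVector x, int f, int mode, int k,
                          SEXP rng, SEXP draws) {
    Rng* g = rng_or_null(rng);
    bool have_draws = !Rf_isNull(draws);
    NumericVector dr = have_draws ? NumericVector(draws) : NumericVector(0);
    if (mode == MODE_SR && !have_draws && g == nullptr)
        stop("stochastic rounding needs a generator or explicit draws");
    int n = x.size();
    NumericVector out(n);
    for (int j = 0; j < n; j++) {
        int64_t ext = as_i64(x[j], "extended value");
        int64_t r;
        if (have_draws)
            r = round_ext_draw(ext, f, mode, k,
                               static_cast<uint64_t>(as_i64(dr[j % dr.size()], "draw")));
        else
            r = round_ext(ext, f, mode, k, g);
        out[j] = static_cast<double>(r);
    }
    return out;
}

// comparator-style k-bit SR: round up iff rand_k < top k bits of the residual
// [[Rcpp::export(name = "C_sr_kbit")]]
NumericVector C_sr_kbit(NumericVector x, int f, int k, NumericVector rand_k) {
    int n = x.size();
    NumericVector out(n);
    for (int j = 0; j < n; j++) {
        int64_t ext = as_i64(x[j], "extended value");
        uint64_t draw =
            static_cast<uint64_t>(as_i64(rand_k[j % rand_k.size()], "draw"));
        out[j] = static_cast<double>(round_ext_draw(ext, f, MODE_SR, k, draw));
    }
    return out;
}

// add-then-truncate SR: (x + rand_f) arithmetically shifted right by f
// [[Rcpp::export(name = "C_sr_add_truncate")]]
NumericVector C_sr_add_truncate(NumericVector x, int f, NumericVector rand_f) {
    int n = x.size();
    NumericVector out(n);
    for (int j = 0; j < n; j++) {
        int128_t_ ext = as_i64(x[j], "extended value");
        int128_t_ r = as_i64(rand_f[j % rand_f.size()], "draw");
        out[j] = static_cast<double>(static_cast<int64_t>((ext + r) >> f));
    }
    return out;
}

// Encode a real (binary64) value onto the 2^-p grid.  Out-of-range results
// raise an error: silent saturation belongs to the multiply stage only.
// For SR the draw has k bits (FULL = 32) and rounds up iff draw < resid*2^k,
// the integer-comparison form of the rounding law on a real residual.
// [[Rcpp::export(name = "C_encode")]]
NumericVector C_encode(NumericVector x, bool sgn, int i, int p, int mode,
                       int k, SEXP rng, SEXP draws) {
    Rng* g = rng_or_null(rng);
    bool have_draws = !Rf_isNull(draws);
    NumericVector dr = have_draws ? NumericVector(draws) : NumericVector(0);
    if (mode == MODE_SR && !have_draws && g == nullptr)
        stop("stochastic rounding needs a generator or explicit draws");
    FmtI fmt{sgn, i, p};
    int64_t lo = fmt_raw_min(fmt), hi = fmt_raw_max(fmt);
    int n = x.size();
    NumericVector out(n);
    for (int j = 0; j < n; j++) {
        double xs = std::ldexp(x[j], p); // exact scaling by a power of two
        if (!R_finite(xs) || std::fabs(xs) >= 9007199254740992.0)
            stop("value %g is not representable at this precision", x[j]);
        double fl = std::floor(xs);
        double resid = xs - fl;
        int64_t raw = static_cast<int64_t>(fl);
        if (resid > 0) {
            switch (mode) {
            case MODE_RD:
                break;
            case MODE_RN:
                if (resid >= 0.5) raw++;
                break;
            default: {
                int kk = (k == SR_FULL) ? 32 : k;
                uint64_t draw = have_draws
                    ? static_cast<uint64_t>(as_i64(dr[j % dr.size()], "draw"))
                    : rng_bits(*g, kk);
                if (static_cast<double>(draw) < resid * std::ldexp(1.0, kk))
                    raw++;
                break;
            }
            }
        }
        if (raw < lo || raw > hi)
            stop("value %g is outside the representable range of the format",
                 x[j]);
        out[j] = static_cast<double>(raw);
    }
    return out;
}

// [[Rcpp::export(name = "C_mul_vec")]]
List C_mul_vec(NumericVector ra, int pa, NumericVector rb, int pb,
               bool sgn, int i, int p, int mode, int k, SEXP rng,
               SEXP draws) {
    Rng* g = rng_or_null(rng);
    bool have_draws = !Rf_isNull(draws);
    NumericVector dr = have_draws ? NumericVector(draws) : NumericVector(0);
    if (mode == MODE_SR && !have_draws && g == nullptr)
        stop("stochastic rounding needs a generator or explicit draws");
    FmtI out_fmt{sgn, i, p};
    int f = pa + pb - p;
    if (f < 0) stop("output format has more fraction bits than the product");
    int n = ra.size();
    NumericVector out(n);
    LogicalVector sat(n);
    long nsat;
    for (int j = 0; j < n; j++) {
        int64_t a = as_i64(ra[j], "raw value");
        int64_t b = as_i64(rb[j % rb.size()], "raw value");
        int128_t_ pr = static_cast<int128_t_>(a) * static_cast<int128_t_>(b);
        int64_t r;
        if (have_draws)
            r = round_ext_draw(pr, f, mode, k,
                               static_cast<uint64_t>(as_i64(dr[j % dr.size()], "draw")));
        else
            r = round_ext(pr, f, mode, k, g);
        nsat = 0;
        out[j] = static_cast<double>(clamp_raw(r, out_fmt, nsat));
        sat[j] = nsat > 0;
    }
    return List::create(_["raw"] = out, _["saturated"] = sat);
}

// exact add/sub with saturate-and-flag on overflow
// [[Rcpp::export(name = "C_addsub_vec")]]
List C_addsub_vec(NumericVector ra, NumericVector rb, bool sgn, int i,
                  int p, int op) {
    FmtI fmt{sgn, i, p};
    int n = ra.size();
    NumericVector out(n);
    LogicalVector sat(n);
    long nsat;
    for (int j = 0; j < n; j++) {
        int64_t a = as_i64(ra[j], "raw value");
        int64_t b = as_i64(rb[j % rb.size()], "raw value");
        int64_t r = (op >= 0) ? a + b : a - b;
        nsat = 0;
        out[j] = static_cast<double>(clamp_raw(r, fmt, nsat));
        sat[j] = nsat > 0;
    }
    return List::create(_["raw"] = out, _["saturated"] = sat);
}

// round each value to the nearest binary32 and return it as binary64
// [[Rcpp::export(name = "C_to_float")]]
NumericVector C_to_float(NumericVector x) {
    NumericVector out(x.size());
    for (int j = 0; j < x.size(); j++)
        out[j] = static_cast<double>(static_cast<float>(x[j]));
    return out;
}
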