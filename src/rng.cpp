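#include <Rcpp.h>
#include "fx.h"

using namespace Rcpp;
using namespace srfixp;

// Generator objects live behind an external pointer so the simulation loop
// can advance them without copying state back and forth through R.

// [[Rcpp::export(name = "C_rng_new")]]
SEXP C_rng_new(int alg, double seed, double lfsr_state, bool have_state) {
    Rng* g = new Rng();
    // seed arrives already reduced mod 2^32 by the R wrapper
    rng_seed(*g, alg, static_cast<uint32_t>(static_cast<uint64_t>(seed)));
    if (have_state) {
        if (alg != ALG_LFSR33)
            stop("explicit state override is only supported for lfsr33");
        uint64_t st = static_cast<uint64_t>(lfsr_state) & 0x1FFFFFFFFULL;
        if (st == 0) {
            delete g;
            stop("lfsr33 state must be a nonzero 33-bit integer");
        }
        g->lfsr = st;
    }
    XPtr<Rng> p(g, true);
    return p;
}

// [[Rcpp::export(name = "C_rng_next")]]
NumericVector C_rng_next(SEXP ptr, int n) {
    XPtr<Rng> g(ptr);
    NumericVector out(n);
    for (int j = 0; j < n; j++) out[j] = static_cast<double>(rng_next(*g));
    return out;
}

// [[Rcpp::export(name = "C_rng_bits")]]
NumericVector C_rng_bits(SEXP ptr, int k, int n) {
    XPtr<Rng> g(ptr);
    NumericVector out(n);
    for (int j = 0; j < n; j++) out[j] = static_cast<double>(rng_bits(*g, k));
    return out;
}

// [[Rcpp::export(name = "C_rng_gauss")]]
NumericVector C_rng_gauss(SEXP ptr, int n) {
    XPtr<Rng> g(ptr);
    NumericVector out(n);
    for (int j = 0; j < n; j++) out[j] = rng_gauss(*g);
    return out;
}

// [[Rcpp::export(name = "C_rng_draws")]]
double C_rng_draws(SEXP ptr) {
    XPtr<Rng> g(ptr);
    return static_cast<double>(g->draws);
}

// [[Rcpp::export(name = "C_rng_state")]]
List C_rng_state(SEXP ptr) {
    XPtr<Rng> g(ptr);
    return List::create(
        _["alg"] = g->alg, _["z"] = static_cast<double>(g->z),
        _["w"] = static_cast<double>(g->w),
        _["jsr"] = static_cast<double>(g->jsr),
        _["jcong"] = static_cast<double>(g->jcong),
        _["lfsr"] = static_cast<double>(g->lfsr),
        _["ranqd"] = static_cast<double>(g->ranqd),
        _["draws"] = static_cast<double>(g->draws));
}

// [[Rcpp::export(name = "C_rng_clone")]]
SEXP C_rng_clone(SEXP ptr) {
    XPtr<Rng> g(ptr);
    Rng* h = new Rng(*g);
    XPtr<Rng> p(h, true);
    return p;
}
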