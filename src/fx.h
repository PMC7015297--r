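#pragma once

#include <cstdint>
#include <cmath>
#include <stdexcept>

// Core of the fixed-point emulator: rounding primitives operate on exact
// integers carrying f extra fraction bits; products are taken in 128-bit
// integers so no intermediate ever wraps.  All state consumed by stochastic
// rounding comes from one explicit generator, never from R's RNG.

namespace srfixp {

constexpr int MODE_RD = 0;
constexpr int MODE_RN = 1;
constexpr int MODE_SR = 2;
constexpr int SR_FULL = -1; // use all residual bits (capped at 32, the draw width)

// ---------------------------------------------------------------- PRNG ----

constexpr int ALG_KISS99 = 0;
constexpr int ALG_LFSR33 = 1;
constexpr int ALG_RANQD1 = 2;

struct Rng {
    int alg;
    // KISS99 component states (two 16-bit multiply-with-carry generators,
    // a 3-shift register and a congruential generator)
    uint32_t z, w, jsr, jcong;
    uint64_t lfsr;   // 33-bit Galois LFSR state, never zero
    uint32_t ranqd;  // Knuth-Lewis LCG state
    uint64_t draws;  // number of 32-bit outputs produced so far
};

// 32-bit avalanche mixer used only to expand a user seed into state words.
inline uint32_t splitmix32(uint32_t& s) {
    s += 0x9E3779B9u;
    uint32_t t = s;
    t ^= t >> 16; t *= 0x85EBCA6Bu;
    t ^= t >> 13; t *= 0xC2B2AE35u;
    t ^= t >> 16;
    return t;
}

// Documented seeding fixture: state words come from splitmix32(seed); a
// zero word falls back to the classic 1999 default for that component so
// every component state is valid for any 32-bit seed.
inline void rng_seed(Rng& g, int alg, uint32_t seed) {
    g.alg = alg;
    g.draws = 0;
    uint32_t s = seed;
    uint32_t a = splitmix32(s), b = splitmix32(s), c = splitmix32(s),
             d = splitmix32(s);
    g.z     = a ? a : 362436069u;
    g.w     = b ? b : 521288629u;
    g.jsr   = c ? c : 123456789u;
    g.jcong = d;
    uint64_t st = (static_cast<uint64_t>(a) << 1 | (b & 1u)) & 0x1FFFFFFFFULL;
    g.lfsr  = st ? st : 1ULL;
    g.ranqd = a;
}

inline uint32_t rng_next(Rng& g) {
    g.draws++;
    switch (g.alg) {
    case ALG_KISS99: {
        // Marsaglia's 1999 KISS: MWC pair + SHR3 + CONG, combined as
        // (MWC ^ CONG) + SHR3.  Component update order is fixed here so the
        // stream is reproducible across compilers.
        g.z = 36969u * (g.z & 65535u) + (g.z >> 16);
        g.w = 18000u * (g.w & 65535u) + (g.w >> 16);
        uint32_t mwc = (g.z << 16) + g.w;
        g.jcong = 69069u * g.jcong + 1234567u;
        g.jsr ^= g.jsr << 17;
        g.jsr ^= g.jsr >> 13;
        g.jsr ^= g.jsr << 5;
        return (mwc ^ g.jcong) + g.jsr;
    }
    case ALG_LFSR33: {
        // Galois form of the maximum-cycle 33-bit LFSR with taps 33 and 20
        // (x^33 + x^20 + 1); the output word is the low 32 bits of state.
        uint64_t lsb = g.lfsr & 1ULL;
        g.lfsr >>= 1;
        if (lsb) g.lfsr ^= 0x100080000ULL;
        return static_cast<uint32_t>(g.lfsr & 0xFFFFFFFFULL);
    }
    default: {
        // ranqd1: x <- 1664525 x + 1013904223 mod 2^32 (Knuth-Lewis).
        g.ranqd = 1664525u * g.ranqd + 1013904223u;
        return g.ranqd;
    }
    }
}

// top k bits of one fresh 32-bit output, 1 <= k <= 32
inline uint32_t rng_bits(Rng& g, int k) {
    uint32_t x = rng_next(g);
    return (k >= 32) ? x : (x >> (32 - k));
}

// Box-Muller on two fresh uniforms; two 32-bit draws per variate, none cached.
inline double rng_gauss(Rng& g) {
    double u1 = (static_cast<double>(rng_next(g)) + 0.5) / 4294967296.0;
    double u2 = static_cast<double>(rng_next(g)) / 4294967296.0;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ------------------------------------------------------------- rounding ----

typedef __int128 int128_t_;

// Shared rounding primitive: drop f fraction bits from an extended integer.
// RD is an arithmetic right shift (floor, toward -inf); RN adds the MSB of
// the discarded field (ties round up); SR compares the top k residual bits
// against a fresh k-bit uniform draw and rounds up on rand < residual.
// A zero residual returns early and consumes no random draw.
inline int64_t round_ext(int128_t_ ext, int f, int mode, int srk, Rng* g) {
    if (f <= 0) return static_cast<int64_t>(ext);
    int64_t fl = static_cast<int64_t>(ext >> f);
    uint64_t resid =
        static_cast<uint64_t>(ext - (static_cast<int128_t_>(fl) << f));
    if (resid == 0) return fl;
    switch (mode) {
    case MODE_RD:
        return fl;
    case MODE_RN:
        return fl + static_cast<int64_t>((resid >> (f - 1)) & 1u);
    default: {
        int k = (srk == SR_FULL) ? (f < 32 ? f : 32) : (srk < f ? srk : f);
        uint64_t top = resid >> (f - k);
        uint32_t r = rng_bits(*g, k);
        return fl + (static_cast<uint64_t>(r) < top ? 1 : 0);
    }
    }
}

// same primitive, but the k-bit draw is supplied by the caller (test paths
// and the add-then-truncate equivalence use this)
inline int64_t round_ext_draw(int128_t_ ext, int f, int mode, int srk,
                              uint64_t draw) {
    if (f <= 0) return static_cast<int64_t>(ext);
    int64_t fl = static_cast<int64_t>(ext >> f);
    uint64_t resid =
        static_cast<uint64_t>(ext - (static_cast<int128_t_>(fl) << f));
    if (resid == 0) return fl;
    switch (mode) {
    case MODE_RD:
        return fl;
    case MODE_RN:
        return fl + static_cast<int64_t>((resid >> (f - 1)) & 1u);
    default: {
        int k = (srk == SR_FULL) ? (f < 32 ? f : 32) : (srk < f ? srk : f);
        uint64_t top = resid >> (f - k);
        return fl + (draw < top ? 1 : 0);
    }
    }
}

// -------------------------------------------------------------- formats ----

struct FmtI {
    bool sgn;
    int i, p;
};

inline int64_t fmt_raw_min(const FmtI& f) {
    return f.sgn ? -(static_cast<int64_t>(1) << (f.i + f.p)) : 0;
}
inline int64_t fmt_raw_max(const FmtI& f) {
    return (static_cast<int64_t>(1) << (f.i + f.p)) - 1;
}

inline int64_t clamp_raw(int64_t x, const FmtI& f, long& sat) {
    int64_t lo = fmt_raw_min(f), hi = fmt_raw_max(f);
    if (x < lo) { sat++; return lo; }
    if (x > hi) { sat++; return hi; }
    return x;
}

// full-precision integer product, rounded by (p_a + p_b - p_out) bits and
// saturated to the destination format
inline int64_t mul_raw(int64_t ra, int pa, int64_t rb, int pb,
                       const FmtI& out, int mode, int srk, Rng* g,
                       long& sat) {
    int128_t_ pr = static_cast<int128_t_>(ra) * static_cast<int128_t_>(rb);
    int f = pa + pb - out.p;
    int64_t r = round_ext(pr, f, mode, srk, g);
    return clamp_raw(r, out, sat);
}

} // namespace srfixp
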