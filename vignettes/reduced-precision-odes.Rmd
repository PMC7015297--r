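---
title: "Reduced-precision fixed-point ODE solving with stochastic rounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-precision fixed-point ODE solving with stochastic rounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srfixp)
```

## What this package studies

Energy- and memory-constrained hardware often replaces binary64 floating
point with fixed-point arithmetic: an optional sign bit, `i` integer bits
and `p` fraction bits, written `<s,i,p>`. Every representable value is an
integer multiple of the machine epsilon `eps = 2^-p`, and the gap is
*absolute* — it does not shrink near zero the way floating-point gaps do.
Each elementary multiply must drop fraction bits to return to the working
format, and *how* those bits are dropped is the subject of this package:

* **RD** (round down) — two's-complement truncation, toward minus
  infinity. The cheapest option and the default behaviour of common
  fixed-point toolchains, but biased by half an LSB per operation.
* **RN** (round to nearest, ties up) — unbiased over a symmetric operand
  distribution, maximum error `eps/2`. The tie is broken upward because
  that decision needs only the MSB of the discarded field.
* **SR** (stochastic rounding) — round up with probability equal to the
  residual fraction. Individual errors are larger than RN's, but they are
  *zero-mean conditional on the operand*, so they cancel along a long
  computation instead of accumulating.

The test vehicle is the Izhikevich spiking neuron,

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with the hybrid rule: when `v >= 30`, record a spike and reset `v <- c`,
`u <- u + d`. A neuron integrated for minutes of simulated time performs
millions of multiplies, which makes spike timing an extraordinarily
sensitive integrator of per-operation rounding error. All experiments
measure **arithmetic error**: the same discrete algorithm is run in
binary64 and in a reduced-precision arithmetic, and the signed difference
in the n-th spike time (positive = lag, negative = lead) is the outcome.
This isolates arithmetic from discretization; no claim is made about the
solver's algorithmic error against the continuous system.

## The arithmetic layer

`fx_format()` builds `<s,i,p>` descriptors (`"s16.15"` is the 32-bit
*accum* format, `"u0.32"` the unsigned *long fract*, `"s8.7"`/`"u0.16"`
their 16-bit counterparts). All rounding is defined on exact integers:
`round_raw(x, f, mode)` drops `f` fraction bits from an extended integer,
and both `fx_encode()` (reals onto a grid) and `fx_mul()` (full-precision
integer product onto the output grid) reduce to it. Tiny formats
(word length up to 10) are first-class, purely so that properties can be
verified *exhaustively* — every raw value, every residual — rather than
statistically.

Two deliberate behavioural asymmetries:

* `fx_encode()` **raises** on out-of-range values. A constant that does
  not fit its format is a configuration bug and must fail loudly.
* `fx_mul()`, `fx_add()` and `fx_sub()` **saturate** and flag the result,
  like the hardware multipliers they emulate; simulations count these
  saturations and report them (the 16-bit runs rely on this diagnostic).

The multiply takes the exact product (128-bit internally), rounds once by
`p_a + p_b - p_out` bits, then clamps. Re-alignment therefore never
rounds twice. Ten named cases (five per word length, e.g.
`s16.15 x u0.32 -> s16.15`) are registered configurations of this one
engine, see `fx_mul_cases()`.

### k-bit stochastic rounding

Hardware SR can compare only the top `k` residual bits against a `k`-bit
uniform integer (`sr_kbit()`), rounding up when `rand < residual_topk`.
With `k = f` this is bit-identical to the full-width law. The residual is
*truncated* to `k` bits, not rounded — the comparator framing — and the
comparison is strict, so an all-ones residual still rounds down for the
maximal draw. The alternative construction, adding the random number and
truncating (`sr_add_truncate()`), is strictly equivalent: a draw `r`
carries into the result exactly when `r >= 2^f - residual`, which is the
comparator acceptance event for the complemented draw `2^f - 1 - r`. The
test suite asserts this bijection exhaustively for `f <= 8`. One draw is
consumed per rounding event, taken from the top bits of a fresh 32-bit
generator word; a zero residual short-circuits and consumes nothing, so
exact operations remain deterministic under SR.

## Random number generators

Three deterministic generators of deliberately different quality stand
behind one handle (`fx_rng()`): KISS99 (two 16-bit multiply-with-carry
generators, a 3-shift xorshift and an LCG, combined), a 33-bit
maximum-cycle Galois LFSR with taps 33 and 20 (output = low 32 state
bits), and the Knuth–Lewis `ranqd1` LCG. The package's seeding convention
expands the user seed through a splitmix32 mixer into the component
words, with classic defaults as fallback for a zero word; the identical
convention is re-implemented in pure R inside the test suite and the two
are compared word for word. Because the original experiments' seeds are
not published, bit-identical streams to those runs are out of reach and
not attempted; what the tests do establish is that the *science is
insensitive to the generator*: SR spike-lag summaries from the three
generators overlap within one SD.

Gaussian dither comes from a Box–Muller transform of two uniform draws
per variate, generator-agnostic and cache-free.

## Unrolled solvers and the placement of precision

Four fixed-step solvers are unrolled together with the right-hand side
into a single per-step expression tree: midpoint RK2, trapezoid RK2
(Heun's 2nd-order), Heun's 3rd-order RK3, and a two-derivative
Runge–Kutta variant ("chantsai") that evaluates the analytic
`g = f'f` twice per step (the cited scheme's exact coefficients are not
printed anywhere recoverable, so the package implements the standard
explicit two-stage two-derivative method — order 4, verified by the
convergence test — and isolates it behind the solver registry so
coefficients are swappable). The published operation ordering of the
original unrolled solvers is likewise not recoverable; the orderings here
were chosen from first principles and are documented below. A
consequence worth stating plainly: **absolute lag magnitudes are
reproduction targets in sign and order of magnitude only**; the
qualitative ordering of rounding modes is the reproducible object.

The precision-placement rules, applied uniformly:

1. **Sub-unity constants live in unsigned fract formats** (`u0.32`, or
   `u0.16` in the 16-bit set), giving them fraction error `2^-33`
   (`2^-17`) instead of the state format's `2^-16` (`2^-8`). Mixed-format
   multiplies (`s16.15 x u0.32 -> s16.15`) bring them back to the state
   format with a single rounding.
2. **Solver coefficients fuse with model constants**: `a*h/2` is one
   pre-encoded constant, not a chain of two or three runtime multiplies.
   The recovery update `u += (a*h) * (b*v - u)` performs exactly one
   rounding. This matters enormously in 16 bits: the fused update
   underflows at RN only when `|bv - u| < eps/(2*a*h)`, and when it does,
   the three rounding modes separate cleanly (see below).
3. **Horner form for the quadratic**: `(0.04 v + 5) v + 140` keeps every
   intermediate inside the 16-bit state range (`v^2` alone would
   saturate `s8.7`, and `5v` would too).
4. Every elementary operation of the binary32 backend rounds to the
   nearest single-precision value — the C++ backend computes in `float`,
   which is exactly that contract.

The same templated expression tree runs on every backend; a structural
test asserts that per-run multiply/add counts are identical across
backends, so observed spike-time differences are arithmetic, never
algebraic.

### Constants

Decimal constants like 0.04 and 0.1 are not representable in binary
fixed point; encoding them with RN instead of truncation halves the
worst-case constant error and is the package default
(`constants_mode = "exact"`; the nearest `s16.15` neighbours of 0.04 and
0.1 are 0.040008544921875 and 0.100006103515625 — the acceptance script
recomputes both). Two further modes exist: `"f32"` passes every constant
through binary32 first, which equalizes constant error across backends
and is the protocol for the dither experiments; `"stochastic"` draws
each fixed-point constant per integration step from its two adjacent
representable values, with upper-selection probability taken from the
binary64 value (one draw per inexact constant per step, drawn after the
dither draw and before the step's SR draws).

### Hybrid-system handling

The threshold `v >= 30` is checked after each full step; the spike time
is the step index times `h`, with no sub-step interpolation — lag is
measured in whole-step multiples, matching the fixed-grid setting.
Recorded traces keep the *pre-reset* value at spike steps so spike peaks
are visible; this is also why an SR ensemble's per-step SD inflates
sharply at a spike step (some realizations hold the threshold value,
others the reset value).

Initial conditions default to `v0 = -65`, `u0 = b*v0` (on the recovery
nullcline), the conventional start for this model; the original
experiments do not state theirs, which is one reason spike *counts* near
the start of a run are not a comparison target.

## The stated experimental world

The experiment drivers reproduce a fixed protocol: DC input of exactly
4.775 current units into RS (`a=0.02, b=0.2, c=-65, d=8`) and FS
(`a=0.1, b=0.2, c=-65, d=2`) cells, timestep `h = 0.1` ms, 650 spikes
tracked, lags measured against the binary64 run of the same solver.
Stochastic configurations run as ensembles with seeds `base_seed + r`
(default desk scale `R = 10`; the summaries are insensitive between
tens and hundreds of repeats, so the desk scale does not change any
qualitative conclusion, only the smoothness of the SD estimates).
Exponentially decaying input (`I0 exp(-t/tau)`, defaults `I0 = 20`,
`tau = 5` ms — a plausible single-synapse transient; these two defaults
are package choices, the protocol names only the shape) and the CH cell
are available but undemanding: every arithmetic solves them essentially
perfectly, so the acceptance battery concentrates on DC/RS and DC/FS.

The dither experiments add zero-mean Gaussian noise to the input current
at the start of every step, with SD expressed in multiples of the s16.15
LSB (`2^-15 = 3.05e-5`) regardless of backend, from 1 LSB up to 10^4
LSBs; the reference run for dither comparisons is binary64 with the same
binary32-rounded constants, so constant error cancels out of the
comparison.

What a green acceptance suite establishes — and what it does not: the
arithmetic layer is exact (verified exhaustively on tiny formats and
against an independent pure-R big-integer oracle on the 32-bit cases);
the BED harness reproduces the three rounding-mode error distributions
at `n = 50000`; and the solver testbench reproduces the qualitative
structure of the published results: RD's large systematic spike lead on
RS, RN and SR within tens-to-hundreds of steps of the reference, SR's
ensemble mean among the smallest-magnitude backends in most
solver-by-neuron cells, 6-bit SR indistinguishable from full-width,
16-bit RN silenced by recovery-variable underflow while 16-bit SR
recovers, and binary32 improved by the smallest dither level but
degraded by very large ones. It does *not* establish agreement with the
published lag values in milliseconds, which depend on an unrecoverable
operation ordering, and it does not validate the solvers against the
continuous-time system.

## Numerical choices and edge cases

* Raw values cross the R boundary as doubles; formats are capped at
  word length 50 so every raw value and every decoded value is exact in
  binary64. Inside the compiled core, products are 128-bit.
* BED errors are computed as `fixed - reference` in output-LSB units
  (so RD errors lie in `(-1, 0]`), from the exact integer
  quotient/residual — the reference is exact rational arithmetic, not
  binary64, so the oracle itself cannot double-round.
* BED operands are drawn uniformly on the representable grid —
  `[-256, 256]` when both operands are `s16.15`, `[-16, 16]` for the
  16-bit analogue, full format ranges otherwise — so every operand is
  exact and the multiply's rounding is the only error source.
* Ensemble SDs use the sample (n-1) denominator.
* The SR-bit sweep reuses seeds across widths (paired comparison), so
  width differences are not confounded with stream differences.
* Degenerate inputs: a zero-residual SR rounding consumes no draw; an
  LFSR seeded to the all-zero state is rejected at construction; add/sub
  overflow saturates and flags; runtime input conversion saturates
  (counted) rather than raising, so a wildly dithered current cannot
  abort a run.

## Limitations

Single neurons only — no networks, synapses or plasticity; no refractory
period (absent from this model); fixed time grid only, no adaptive
stepping or sub-step threshold crossing; no fixed-point division or
square root; no posit/bfloat16 formats; round-to-even tie-breaking is
deliberately out of scope (the MSB tie-up rule is the object of study).
Hardware deployment concerns — speed, energy, on-chip PRNG latency — are
outside the package's remit.
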