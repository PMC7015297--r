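# The Izhikevich hybrid neuron and its unrolled fixed-timestep solvers.
#
# Model (mV/ms conventions):
#   dv/dt = 0.04 v^2 + 5 v + 140 - u + I
#   du/dt = a (b v - u)
#   if v >= 30:  v <- c,  u <- u + d    (spike and reset)
#
# Solvers are run in "explicit solver reduction" form: the solver stages
# and the right-hand side are unrolled into one per-step expression tree,
# ordered so that (a) every constant smaller than one is held in an
# unsigned fract format at full fraction precision (u0.32, or u0.16 in the
# 16-bit set), (b) solver coefficients are fused with model constants
# (a*h/2 is one constant, not two multiplies), and (c) the quadratic term
# is evaluated in Horner form (0.04 v + 5) v so no intermediate leaves the
# range of the 16-bit state format.  The identical expression tree runs on
# every backend; see src/neuron.cpp.

.SOLVERS <- c(rk2mid = 0L, rk2trap = 1L, rk3heun = 2L, chantsai = 3L)
.BACKENDS <- c(f64 = 0L, f32 = 1L, fixed = 2L)

#' Izhikevich neuron parameter sets
#'
#' Ships the three standard parameterizations: RS (regular spiking,
#' a=0.02, b=0.2, c=-65, d=8), FS (fast spiking, a=0.1, b=0.2, c=-65,
#' d=2) and CH (chattering, a=0.02, b=0.2, c=-50, d=2).  Individual
#' fields can be overridden for custom cells.
#'
#' @param label `"RS"`, `"FS"` or `"CH"`
#' @param a,b,c,d optional overrides of the model constants
#' @param v0,u0 initial state; defaults `v0 = -65`, `u0 = b * v0` (on the
#'   recovery nullcline, the conventional start for this model)
#' @return an `izh_params` object
#' @export
izh_params <- function(label = c("RS", "FS", "CH"), a = NULL, b = NULL,
                       c = NULL, d = NULL, v0 = -65, u0 = NULL) {
  label <- match.arg(label)
  preset <- switch(label,
    RS = list(a = 0.02, b = 0.2, c = -65, d = 8),
    FS = list(a = 0.1,  b = 0.2, c = -65, d = 2),
    CH = list(a = 0.02, b = 0.2, c = -50, d = 2))
  pp <- modifyList(preset, Filter(Negate(is.null),
                                  list(a = a, b = b, c = c, d = d)))
  if (is.null(u0)) u0 <- pp$b * v0
  structure(c(pp, list(label = label, v0 = v0, u0 = u0)),
            class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich %s: a=%g b=%g c=%g d=%g, start (v,u)=(%g, %g)\n",
              x$label, x$a, x$b, x$c, x$d, x$v0, x$u0))
  invisible(x)
}

#' Input current specification
#'
#' DC or exponentially decaying input, with optional Gaussian dither.  The
#' dither SD is given in multiples of the s16.15 LSB (`2^-15 = 3.05e-5`),
#' the unit used throughout the dither experiments regardless of backend;
#' a fresh variate is added to the input current at the start of every
#' integration step.
#'
#' @param kind `"dc"` (default) or `"exp"` (`I(t) = I0 exp(-t/tau)`,
#'   a single-synapse approximation)
#' @param magnitude input current `I0` (model units, nA-equivalent);
#'   default 4.775, the demanding DC test case
#' @param tau decay time constant in ms (`"exp"` only)
#' @param dither_sd_lsb Gaussian dither SD in s16.15 LSB units; 0 = off
#' @return an `izh_input` object
#' @export
izh_input <- function(kind = c("dc", "exp"), magnitude = 4.775, tau = 5,
                      dither_sd_lsb = 0) {
  kind <- match.arg(kind)
  stopifnot(dither_sd_lsb >= 0, tau > 0)
  structure(list(kind = kind, magnitude = magnitude, tau = tau,
                 dither_sd_lsb = dither_sd_lsb),
            class = "izh_input")
}

#' Solver and arithmetic backend configuration
#'
#' @param solver `"rk2mid"` (midpoint), `"rk2trap"` (trapezoid / Heun 2),
#'   `"rk3heun"` (third-order Heun) or `"chantsai"` (two-derivative
#'   Runge-Kutta variant; one f and two g evaluations per step)
#' @param backend `"f64"` (binary64, the arithmetic reference), `"f32"`
#'   (binary32: every elementary operation rounds to the nearest single
#'   precision value) or `"fixed"`
#' @param rounding fixed-point rounding mode: `"rd"`, `"rn"` or `"sr"`
#' @param sr_bits SR comparison width: `"full"` or an integer 1..32
#' @param format_set `"32"` (state s16.15, sub-unity constants u0.32) or
#'   `"16"` (state s8.7, sub-unity constants u0.16)
#' @param h timestep in ms (default 0.1)
#' @param constants_mode `"exact"`: every decimal constant rounds to its
#'   nearest representable value (RN); `"f32"`: constants pass through
#'   binary32 first (the dither-protocol convention, so constant error is
#'   identical across backends); `"stochastic"`: on every integration step
#'   each fixed-point constant is drawn from its two adjacent representable
#'   values with probability taken from the binary64 value
#' @return a `solver_config` object
#' @export
solver_config <- function(solver = c("rk2mid", "rk2trap", "rk3heun",
                                     "chantsai"),
                          backend = c("f64", "f32", "fixed"),
                          rounding = "rn", sr_bits = "full",
                          format_set = c("32", "16"), h = 0.1,
                          constants_mode = c("exact", "f32",
                                             "stochastic")) {
  solver <- match.arg(solver)
  backend <- match.arg(backend)
  format_set <- match.arg(as.character(format_set), c("32", "16"))
  constants_mode <- match.arg(constants_mode)
  stopifnot(h > 0)
  rounding <- match.arg(rounding, c("rd", "rn", "sr"))
  if (constants_mode == "stochastic" && backend != "fixed")
    stop("stochastic constant selection is defined for the fixed backend")
  k_int <- if (identical(sr_bits, "full")) -1L else as.integer(sr_bits)
  structure(list(solver = solver, backend = backend, rounding = rounding,
                 sr_bits = sr_bits, k_int = k_int,
                 format_set = format_set, h = h,
                 constants_mode = constants_mode,
                 state_fmt = fx_format(if (format_set == "32") "s16.15"
                                       else "s8.7"),
                 const_fmt = fx_format(if (format_set == "32") "u0.32"
                                       else "u0.16")),
            class = "solver_config")
}

#' Izhikevich right-hand side
#'
#' Plain double-precision evaluation of the two derivatives; the reference
#' form used by oracles and by anyone inspecting the model.
#' @param v,u state variables (membrane potential mV, recovery variable)
#' @param I input current
#' @param params an [izh_params()]
#' @return list with `dv` and `du`
#' @export
izh_rhs <- function(v, u, I, params) {
  list(dv = 0.04 * v^2 + 5 * v + 140 - u + I,
       du = params$a * (params$b * v - u))
}

# decimal values of every constant slot, in the fixed order the C++ core
# expects; sub-unity constants end up in the unsigned fract format
.const_table <- function(params, h) {
  a <- params$a; b <- params$b
  c(c004 = 0.04, five = 5, c140 = 140, b = b, a = a, c008 = 0.08,
    h = h, h2 = h / 2, h3 = h / 3, t2h3 = 2 * h / 3, h4 = h / 4,
    t3h4 = 3 * h / 4, hh8 = h^2 / 8, hh6 = h^2 / 6, hh3 = h^2 / 3,
    ah = a * h, ah2 = a * h / 2, ah3 = a * h / 3, a2h3 = 2 * a * h / 3,
    ah4 = a * h / 4, a3h4 = 3 * a * h / 4)
}

#' Backend-typed constant set for a solver configuration
#'
#' Builds every constant the unrolled solvers use (model constants 0.04,
#' 5, 140, a, b, 0.08 and the fused solver coefficients h/2, a*h, ...)
#' in the representation the backend will consume:
#' * `"exact"` — each decimal rounds to the nearest representable value
#'   of its destination format (RN), halving the worst-case constant error
#'   relative to truncating conversion;
#' * `"f32"` — each decimal first rounds to the nearest binary32;
#' * `"stochastic"` — fixed backend only; the two adjacent representable
#'   values plus the probability of selecting the upper one.
#'
#' Constants smaller than one live in the unsigned fract format (u0.32 or
#' u0.16), everything else in the state format (s16.15 or s8.7).
#'
#' @param cfg a [solver_config()]
#' @param params an [izh_params()]
#' @return data frame with one row per constant: decimal, backend value,
#'   raw integer, format, and (stochastic mode) lower raw + upper-select
#'   probability
#' @examples
#' cfg <- solver_config("rk2mid", "fixed", "rn")
#' k <- make_constants(cfg, izh_params("RS"))
#' k[k$name == "c004", "value"] # 0.040008544921875
#' @export
make_constants <- function(cfg, params) {
  stopifnot(inherits(cfg, "solver_config"), inherits(params, "izh_params"))
  dec <- .const_table(params, cfg$h)
  src <- if (cfg$constants_mode == "f32") C_to_float(dec) else dec
  is_c <- abs(src) < 1 & src >= 0   # sub-unity constants -> unsigned fract
  fmt_of <- function(j) if (is_c[j]) cfg$const_fmt else cfg$state_fmt
  n <- length(dec)
  raw <- value <- slo <- sp <- numeric(n)
  for (j in seq_len(n)) {
    fmt <- fmt_of(j)
    raw[j] <- fx_encode(src[j], fmt, "rn")$raw
    value[j] <- raw[j] * 2^(-fmt$p)
    fl <- floor(src[j] * 2^fmt$p)
    slo[j] <- fl
    sp[j] <- src[j] * 2^fmt$p - fl
  }
  if (cfg$constants_mode != "stochastic") sp[] <- 0
  data.frame(name = names(dec), decimal = dec, backend = src,
             value = value, raw = raw,
             fmt = vapply(seq_len(n), function(j) format(fmt_of(j)), ""),
             sub_unity = is_c, sel_lo = slo, sel_p = sp,
             row.names = NULL)
}

#' Run an Izhikevich simulation
#'
#' Iterates the configured unrolled solver from the initial state, adding
#' per-step dither to the input when requested, until the duration or the
#' target spike count is reached.  Spike times are whole-step multiples of
#' `h`: the threshold `v >= 30` is checked after each full step and no
#' sub-step interpolation is attempted, matching how lags are counted.
#'
#' @param params an [izh_params()]
#' @param input an [izh_input()]
#' @param cfg a [solver_config()]
#' @param duration simulated time in ms (cap when `spikes` is also given;
#'   default cap 500000 ms)
#' @param spikes stop after this many spikes
#' @param seed integer seed for the run's generator (SR rounding, dither
#'   and stochastic constant selection all draw from this one stream)
#' @param rng optionally a ready [fx_rng()], overriding `seed`
#' @param algorithm generator algorithm when seeding internally
#' @param trace record per-step `v` and `u` traces (pre-reset values, so
#'   spikes show their peaks)
#' @return an `izh_sim`: `spike_times` (ms), `n_steps`, `saturations`,
#'   traces when requested, and metadata
#' @export
izh_run <- function(params, input, cfg, duration = NULL, spikes = NULL,
                    seed = 1L, rng = NULL, algorithm = "kiss99",
                    trace = FALSE) {
  stopifnot(inherits(params, "izh_params"), inherits(input, "izh_input"),
            inherits(cfg, "solver_config"))
  if (is.null(duration) && is.null(spikes))
    stop("give a duration, a spike target, or both")
  max_steps <- ceiling((if (is.null(duration)) 5e5 else duration) / cfg$h)
  needs_rng <- (cfg$backend == "fixed" && cfg$rounding == "sr") ||
    input$dither_sd_lsb > 0 || cfg$constants_mode == "stochastic"
  if (is.null(rng) && needs_rng) rng <- fx_rng(algorithm, seed)
  kt <- make_constants(cfg, params)
  sfmt <- cfg$state_fmt
  enc_s <- function(x) fx_encode(x, sfmt, "rn")$raw
  args <- list(
    solver = .SOLVERS[[cfg$solver]], backend = .BACKENDS[[cfg$backend]],
    mode = .MODE_INT[[cfg$rounding]], srk = cfg$k_int,
    i_s = sfmt$i, p_s = sfmt$p, p_c = cfg$const_fmt$p,
    h = cfg$h, max_steps = as.numeric(max_steps),
    target_spikes = if (is.null(spikes)) 0L else as.integer(spikes),
    input_kind = if (input$kind == "dc") 0L else 1L,
    I0 = input$magnitude, tau = input$tau,
    dither_sd = input$dither_sd_lsb * 2^-15,
    trace = isTRUE(trace),
    v0 = params$v0, u0 = params$u0,
    thr = 30, vreset = params$c, d = params$d,
    thr_raw = enc_s(30), vreset_raw = enc_s(params$c),
    d_raw = enc_s(params$d),
    cval = kt$backend, craw = kt$raw,
    cfmt = as.integer(kt$sub_unity),
    ssel = cfg$constants_mode == "stochastic",
    slo = kt$sel_lo, sp = kt$sel_p,
    rng = if (is.null(rng)) NULL else rng$ptr)
  res <- C_izh_run(args)
  structure(list(
    spike_times = res$spike_steps * cfg$h,
    n_steps = res$n_steps, h = cfg$h,
    saturations = res$saturations,
    n_mul = res$n_mul, n_add = res$n_add,
    v_trace = if (isTRUE(trace)) res$v_trace,
    u_trace = if (isTRUE(trace)) res$u_trace,
    params = params, input = input, cfg = cfg,
    seed = if (is.null(rng)) NA_integer_ else seed),
    class = "izh_sim")
}

#' @export
print.izh_sim <- function(x, ...) {
  cat(sprintf(
    "izh_sim %s/%s %s: %d spikes in %.1f ms (%d saturations)\n",
    x$params$label, x$cfg$solver,
    if (x$cfg$backend == "fixed")
      paste0("fixed-", x$cfg$format_set, "/", toupper(x$cfg$rounding))
    else x$cfg$backend,
    length(x$spike_times), x$n_steps * x$h, x$saturations))
  invisible(x)
}

#' Double-precision arithmetic reference run
#'
#' The same unrolled solver executed in binary64: the arithmetic reference
#' all spike-lag measurements compare against (it is *not* an algorithmic
#' reference — it shares every discretization property of the test runs).
#'
#' @param params an [izh_params()]
#' @param input an [izh_input()]
#' @param solver solver name (see [solver_config()])
#' @param h timestep in ms
#' @param duration,spikes stopping rule, as in [izh_run()]
#' @param ... passed to [izh_run()]
#' @return an `izh_sim`
#' @export
izh_reference_run <- function(params, input, solver = "rk2mid", h = 0.1,
                              duration = NULL, spikes = NULL, ...) {
  cfg <- solver_config(solver, "f64", h = h)
  izh_run(params, input, cfg, duration = duration, spikes = spikes, ...)
}
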