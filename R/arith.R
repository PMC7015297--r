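# Mixed-format fixed-point multiplication with full-precision intermediate
# product, selectable rounding and saturation, plus exact add/sub.
#
# One generic engine covers every format combination; the named 32- and
# 16-bit cases used by the neuron solvers are registered configurations of
# it.  The product of <s,ia,pa> and <s,ib,pb> carries pa+pb fraction bits;
# conversion to the destination format drops pa+pb-p_out bits through the
# shared rounding primitive and then clamps to the destination range,
# flagging saturation on the result instead of raising.

.MUL_CASES <- list(
  s16.15xs16.15 = c("s16.15", "s16.15", "s16.15"),
  s16.15xs0.31  = c("s16.15", "s0.31",  "s16.15"),
  s16.15xu0.32  = c("s16.15", "u0.32",  "s16.15"),
  u0.32xu0.32   = c("u0.32",  "u0.32",  "s0.31"),
  u0.32xs0.31   = c("u0.32",  "s0.31",  "s0.31"),
  s8.7xs8.7     = c("s8.7",   "s8.7",   "s8.7"),
  s8.7xs0.15    = c("s8.7",   "s0.15",  "s8.7"),
  s8.7xu0.16    = c("s8.7",   "u0.16",  "s8.7"),
  u0.16xu0.16   = c("u0.16",  "u0.16",  "s0.15"),
  u0.16xs0.15   = c("u0.16",  "s0.15",  "s0.15")
)

#' Registry of the named multiply cases
#'
#' The five 32-bit and five 16-bit mixed-format multiply configurations
#' used throughout the solvers.  The first three of each word length
#' saturate into the wide state format (`s16.15` / `s8.7`), the last two
#' into the signed fract format (`s0.31` / `s0.15`).
#'
#' @return a data frame with columns `name`, `fmt_a`, `fmt_b`, `fmt_out`
#' @export
fx_mul_cases <- function() {
  data.frame(name = names(.MUL_CASES),
             fmt_a = vapply(.MUL_CASES, `[`, "", 1L),
             fmt_b = vapply(.MUL_CASES, `[`, "", 2L),
             fmt_out = vapply(.MUL_CASES, `[`, "", 3L),
             row.names = NULL)
}

#' Look up a named multiply case
#' @param name a case name from [fx_mul_cases()], e.g. `"s16.15xu0.32"`
#' @return list with `fmt_a`, `fmt_b`, `fmt_out` as [fx_format()] objects
#' @export
fx_case <- function(name) {
  cc <- .MUL_CASES[[name]]
  if (is.null(cc)) stop("unknown multiply case '", name, "'")
  list(fmt_a = fx_format(cc[1]), fmt_b = fx_format(cc[2]),
       fmt_out = fx_format(cc[3]))
}

#' Fixed-point multiply with rounding and saturation
#'
#' Computes the exact integer product, drops `p_a + p_b - p_out` fraction
#' bits under the rounding spec, and clamps to the destination range.  A
#' clamped result is flagged in the `"saturated"` attribute rather than
#' raising, mirroring hardware saturating multipliers.  Under SR a zero
#' residual consumes no random draw, so exact products stay deterministic.
#'
#' @param a,b [fx_value()] operands (raws recycled to a common length)
#' @param fmt_out destination [fx_format()]
#' @param rs an [fx_rounding()] spec or mode string
#' @param draws optional explicit k-bit draws (test hook)
#' @return an `fx_value` with a logical `"saturated"` attribute
#' @examples
#' a <- fx_encode(2, "s16.15"); b <- fx_encode(3.5, "s16.15")
#' fx_decode(fx_mul(a, b, "s16.15", "rd")) # 7, exact
#' @export
fx_mul <- function(a, b, fmt_out, rs = fx_rounding("rd"), draws = NULL) {
  stopifnot(inherits(a, "fx_value"), inherits(b, "fx_value"))
  fmt_out <- fx_format(fmt_out)
  rs <- as_fx_rounding(rs)
  if (fmt_out$p > a$fmt$p + b$fmt$p)
    stop("output format has more fraction bits than the product")
  n <- max(length(a$raw), length(b$raw))
  ra <- rep_len(a$raw, n); rb <- rep_len(b$raw, n)
  res <- C_mul_vec(ra, a$fmt$p, rb, b$fmt$p,
                   fmt_out$signed, fmt_out$i, fmt_out$p,
                   rs$mode_int, rs$k_int, rs$rng, draws)
  out <- fx_value(res$raw, fmt_out)
  attr(out, "saturated") <- res$saturated
  out
}

.fx_addsub <- function(a, b, op) {
  stopifnot(inherits(a, "fx_value"), inherits(b, "fx_value"))
  if (format(a$fmt) != format(b$fmt))
    stop("add/sub operands must share one format")
  n <- max(length(a$raw), length(b$raw))
  res <- C_addsub_vec(rep_len(a$raw, n), rep_len(b$raw, n),
                      a$fmt$signed, a$fmt$i, a$fmt$p, op)
  out <- fx_value(res$raw, a$fmt)
  attr(out, "saturated") <- res$saturated
  out
}

#' Exact fixed-point addition and subtraction
#'
#' Same-format add/sub are exact integer operations; on overflow the result
#' saturates to the format boundary and is flagged in the `"saturated"`
#' attribute.
#' @param a,b [fx_value()] operands in the same format
#' @return an `fx_value` with a logical `"saturated"` attribute
#' @export
fx_add <- function(a, b) .fx_addsub(a, b, 1L)

#' @rdname fx_add
#' @export
fx_sub <- function(a, b) .fx_addsub(a, b, -1L)

# ---------------------------------------------------------------------------
# Independent reference multiply, pure R.
#
# Exact integer product via 16-bit limb arithmetic in doubles (no int64,
# no C++), then the mathematical rounding laws applied to the exact
# quotient and residual.  This is the oracle route used by the test suite
# against the compiled engine; it shares no code with it.

# floor(ra*rb / 2^f) and the residual, exactly, for |raw| < 2^34, f <= 40
.exact_mulshift <- function(ra, rb, f) {
  sgn <- sign(ra) * sign(rb)
  ma <- abs(ra); mb <- abs(rb)
  a1 <- ma %/% 65536; a0 <- ma %% 65536
  b1 <- mb %/% 65536; b0 <- mb %% 65536
  p0 <- a0 * b0                       # < 2^32
  p1 <- a0 * b1 + a1 * b0             # < 2^35
  p2 <- a1 * b1                       # < 2^36
  lo <- p0 + (p1 %% 65536) * 65536    # < 2^34
  hi <- p2 + p1 %/% 65536 + lo %/% 4294967296
  lo <- lo %% 4294967296              # |product| = hi*2^32 + lo, exact
  if (f <= 32) {
    resid_m <- lo %% 2^f
    q_m <- hi * 2^(32 - f) + lo %/% 2^f
  } else {
    s2 <- f - 32
    resid_m <- (hi %% 2^s2) * 4294967296 + lo
    q_m <- hi %/% 2^s2
  }
  q <- ifelse(sgn >= 0, q_m, -q_m - (resid_m > 0))
  resid <- ifelse(sgn >= 0, resid_m, ifelse(resid_m > 0, 2^f - resid_m, 0))
  list(q = q, resid = resid)
}

#' Reference multiply in exact integer arithmetic (oracle)
#'
#' Computes the exact product of the two decoded values, applies the
#' mathematical definition of the rounding law to the exact residual, and
#' saturates.  Implemented in pure R limb arithmetic, fully independent of
#' the compiled multiply path; its purpose is to stand on the other side
#' of equivalence tests.  For SR the draws must be supplied explicitly so
#' that both routes see the same random bits; the comparison uses the top
#' `k` residual bits (`k = min(f, 32)` by default), the package's
#' documented k-bit SR convention.
#'
#' @param a,b [fx_value()] operands
#' @param fmt_out destination [fx_format()]
#' @param mode `"rd"`, `"rn"` or `"sr"`
#' @param draws k-bit integer draws, required for `"sr"`
#' @param k SR comparison width (default `min(f, 32)`)
#' @return an `fx_value` with a logical `"saturated"` attribute
#' @export
fx_mul_reference <- function(a, b, fmt_out, mode = c("rd", "rn", "sr"),
                             draws = NULL, k = NULL) {
  stopifnot(inherits(a, "fx_value"), inherits(b, "fx_value"))
  mode <- match.arg(mode)
  fmt_out <- fx_format(fmt_out)
  f <- a$fmt$p + b$fmt$p - fmt_out$p
  stopifnot(f >= 0, f <= 40)
  n <- max(length(a$raw), length(b$raw))
  ms <- .exact_mulshift(rep_len(a$raw, n), rep_len(b$raw, n), f)
  q <- ms$q
  if (f > 0) {
    if (mode == "rn") {
      q <- q + (ms$resid >= 2^(f - 1))
    } else if (mode == "sr") {
      if (is.null(draws)) stop("reference SR needs explicit draws")
      if (is.null(k)) k <- min(f, 32)
      top <- ms$resid %/% 2^(f - k)
      q <- q + (rep_len(as.numeric(draws), n) < top)
    }
  }
  lo <- if (fmt_out$signed) -(2^(fmt_out$i + fmt_out$p)) else 0
  hi <- 2^(fmt_out$i + fmt_out$p) - 1
  sat <- q < lo | q > hi
  out <- fx_value(pmin(pmax(q, lo), hi), fmt_out)
  attr(out, "saturated") <- sat
  out
}
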