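# Bit Error Distribution (BED) harness.
#
# Draw exactly representable operand pairs, run a fixed-point multiply next
# to the exact reference product, and express each error in LSB units of
# the *output* format (absolute error times 2^p_out).  The resulting
# distributions characterize an atomic multiply under each rounding mode:
# a one-sided block in (-1, 0] for RD, a centred half-width block for RN,
# and a centred, wider, zero-mean spread for SR.

#' Draw exactly representable operand pairs
#'
#' Operands are drawn uniformly from the format's representable grid
#' restricted to `[lo, hi]`, so every operand is exact in its format and
#' the only error under study is the multiply's rounding step.  A 53-bit
#' uniform index (two 32-bit draws per operand) selects the grid point.
#'
#' @param fmt_a,fmt_b operand formats ([fx_format()] or strings)
#' @param lo,hi range bounds, must lie inside both formats' ranges
#' @param n number of pairs
#' @param g an [fx_rng()]
#' @return list of `fx_value`s `a` and `b`, each of length `n`
#' @export
bed_sample_pairs <- function(fmt_a, fmt_b, lo, hi, n, g) {
  fmt_a <- fx_format(fmt_a); fmt_b <- fx_format(fmt_b)
  draw_one <- function(fmt) {
    r <- fx_range(fmt)
    stopifnot(lo >= r[1], hi <= r[2], lo <= hi)
    rlo <- ceiling(lo * 2^fmt$p); rhi <- floor(hi * 2^fmt$p)
    span <- rhi - rlo + 1
    if (n == 0L) return(fx_value(numeric(0), fmt))
    u <- (rng_u32(g, n) * 2097152 + rng_u32(g, n) %/% 2048) / 2^53
    fx_value(rlo + floor(u * span), fmt)
  }
  list(a = draw_one(fmt_a), b = draw_one(fmt_b))
}

.bed_default_range <- function(case) {
  fa <- format(case$fmt_a); fb <- format(case$fmt_b)
  if (fa == "s16.15" && fb == "s16.15") return(c(-256, 256))
  if (fa == "s8.7" && fb == "s8.7") return(c(-16, 16))
  # other cases: one operand is a fract type, products cannot overflow,
  # so the full ranges of both formats are safe
  rr <- rbind(fx_range(case$fmt_a), fx_range(case$fmt_b))
  c(max(rr[, 1]), min(rr[, 2]))
}

#' Run a bit-error-distribution experiment
#'
#' @param case a case name from [fx_mul_cases()] or a list with `fmt_a`,
#'   `fmt_b`, `fmt_out`
#' @param mode rounding mode `"rd"`, `"rn"` or `"sr"`
#' @param n number of operand pairs (default 50000)
#' @param seed generator seed
#' @param range optional `c(lo, hi)` operand range overriding the
#'   per-case default (`[-256, 256]` when both operands are `s16.15`,
#'   `[-16, 16]` for the 16-bit equivalent, full ranges otherwise)
#' @param sr_bits SR comparison width (default `"full"`)
#' @param algorithm generator algorithm
#' @return a `bed_result`: the LSB-normalized errors plus summary
#'   statistics (`mean`, `sd`, `min`, `max`) and the seed
#' @examples
#' b <- bed_run("s16.15xs16.15", "rn", n = 1000, seed = 7)
#' b$mean # close to 0: RN is symmetric around the exact product
#' @export
bed_run <- function(case, mode = c("rd", "rn", "sr"), n = 50000L,
                    seed = 1L, range = NULL, sr_bits = "full",
                    algorithm = "kiss99") {
  mode <- match.arg(mode)
  case_name <- if (is.character(case)) case else "custom"
  if (is.character(case)) case <- fx_case(case)
  g <- fx_rng(algorithm, seed)
  if (is.null(range)) range <- .bed_default_range(case)
  pairs <- bed_sample_pairs(case$fmt_a, case$fmt_b, range[1], range[2], n, g)
  rs <- if (mode == "sr") fx_rounding("sr", sr_bits, g) else fx_rounding(mode)
  fixed <- fx_mul(pairs$a, pairs$b, case$fmt_out, rs)
  # LSB error = raw_fixed - exact product scaled to output LSBs, computed
  # from the exact quotient/residual so no double rounding sneaks in
  f <- case$fmt_a$p + case$fmt_b$p - case$fmt_out$p
  ms <- .exact_mulshift(pairs$a$raw, pairs$b$raw, f)
  errors <- (fixed$raw - ms$q) - ms$resid / 2^f
  structure(list(case = case, case_name = case_name, mode = mode, n = n,
                 errors = errors, mean = mean(errors), sd = sd(errors),
                 min = min(errors), max = max(errors), seed = seed,
                 saturated = sum(attr(fixed, "saturated"))),
            class = "bed_result")
}

#' @export
print.bed_result <- function(x, ...) {
  cat(sprintf(
    "BED %s, %s, n = %d: mean %+0.4f LSB, sd %0.4f, range [%+0.4f, %+0.4f]\n",
    x$case_name, toupper(x$mode), x$n, x$mean, x$sd, x$min, x$max))
  if (x$saturated > 0) cat(x$saturated, "saturated results\n")
  invisible(x)
}

#' @export
as.data.frame.bed_result <- function(x, ...) {
  data.frame(error_lsb = x$errors)
}
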