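# Rounding specifications and the shared integer rounding primitives.
#
# All rounding is defined on exact integers carrying f extra fraction bits;
# real numbers only ever appear at the encode/decode boundary.  This is what
# makes the emulator bit-exact and exhaustively testable on tiny formats.

.MODE_INT <- c(rd = 0L, rn = 1L, sr = 2L)

#' Rounding specification
#'
#' Bundles a rounding mode with, for stochastic rounding, the comparison
#' bit-width `k` and the generator that supplies the random bits.
#'
#' * `"rd"` — round down: two's-complement truncation, toward minus
#'   infinity (not toward zero).
#' * `"rn"` — round to nearest, ties rounded up (the cheap tie rule that
#'   only inspects the MSB of the discarded field).
#' * `"sr"` — stochastic rounding: round up with probability equal to the
#'   residual fraction.  With `k = "full"` all residual bits take part
#'   (capped at the 32-bit draw width); with integer `k` only the top `k`
#'   bits of the residual are compared against a `k`-bit uniform draw.
#'
#' @param mode `"rd"`, `"rn"` or `"sr"`
#' @param k SR comparison width: `"full"` or a positive integer
#' @param rng an [fx_rng()] generator; required for `"sr"` unless explicit
#'   draws are supplied to the consuming operation
#' @return an object of class `fx_rounding`
#' @export
fx_rounding <- function(mode = c("rn", "rd", "sr"), k = "full", rng = NULL) {
  mode <- match.arg(mode)
  if (identical(k, "full")) {
    k_int <- -1L
  } else {
    k_int <- as.integer(k)
    stopifnot(k_int >= 1L, k_int <= 32L)
  }
  if (!is.null(rng)) stopifnot(inherits(rng, "fx_rng"))
  structure(list(mode = mode, mode_int = .MODE_INT[[mode]],
                 k = k, k_int = k_int,
                 rng = if (is.null(rng)) NULL else rng$ptr,
                 rng_obj = rng),
            class = "fx_rounding")
}

as_fx_rounding <- function(rs) {
  if (inherits(rs, "fx_rounding")) return(rs)
  if (is.character(rs)) return(fx_rounding(rs))
  stop("not a rounding specification")
}

#' @export
print.fx_rounding <- function(x, ...) {
  cat("rounding mode ", toupper(x$mode),
      if (x$mode == "sr") paste0(", k = ", x$k), "\n", sep = "")
  invisible(x)
}

#' Round an extended integer by dropping f fraction bits
#'
#' The shared primitive behind [fx_encode()] and [fx_mul()]: `x` is an
#' exact integer carrying `f` extra fraction bits; the result drops them
#' under the requested mode.  RD is an arithmetic right shift; RN adds
#' `2^(f-1)` before the shift (so ties round up); SR rounds up with
#' probability `residual / 2^f`, consuming no draw when the residual is
#' zero.
#'
#' @param x integer-valued numeric vector (the extended value)
#' @param f number of extra fraction bits, `f >= 0`
#' @param rs an [fx_rounding()] spec or mode string
#' @param draws optional explicit k-bit draws (test hook)
#' @return rounded integers as a numeric vector
#' @examples
#' round_raw(c(22, 23), 2, "rd") # 5 5
#' round_raw(22, 2, "rn")        # 6: residual 0b10 is a tie, rounds up
#' @export
round_raw <- function(x, f, rs, draws = NULL) {
  rs <- as_fx_rounding(rs)
  C_round_raw(as.numeric(x), as.integer(f), rs$mode_int, rs$k_int,
              rs$rng, draws)
}

#' k-bit stochastic rounding, comparator form
#'
#' Compares the top `k` bits of the `f`-bit residual against a supplied
#' `k`-bit uniform integer and rounds up iff `rand_k` is strictly smaller.
#' With `k = f` and the same draw this is bit-identical to full stochastic
#' rounding.
#'
#' @param x integer-valued numeric vector carrying `f` fraction bits
#' @param f residual width, bits
#' @param k comparison width, `1 <= k <= f`
#' @param rand_k `k`-bit unsigned integer draws (recycled)
#' @return rounded integers
#' @export
sr_kbit <- function(x, f, k, rand_k) {
  stopifnot(k >= 1, k <= f)
  C_sr_kbit(as.numeric(x), as.integer(f), as.integer(k),
            as.numeric(rand_k))
}

#' Stochastic rounding, add-then-truncate form
#'
#' Adds an `f`-bit uniform integer to the extended value and truncates
#' (arithmetic right shift by `f`).  Strictly equivalent to the comparator
#' form for the same draw: draws at or above `2^f - residual` carry into
#' the result bits.
#'
#' @param x integer-valued numeric vector carrying `f` fraction bits
#' @param f residual width, bits
#' @param rand_f `f`-bit unsigned integer draws (recycled)
#' @return rounded integers
#' @export
sr_add_truncate <- function(x, f, rand_f) {
  C_sr_add_truncate(as.numeric(x), as.integer(f), as.numeric(rand_f))
}
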