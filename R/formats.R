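# <s,i,p> fixed-point format descriptors and exact encode/decode.
#
# A format is an optional sign bit, i integer bits and p fraction bits; all
# representable values are integer multiples of epsilon = 2^-p.  Raw values
# cross the R boundary as doubles, so word lengths are capped at 50 bits
# (far beyond the named 16/32-bit formats) to keep every raw value exact.

.FMT_ALIASES <- list(
  accum         = "s16.15",
  `long fract`  = "s0.31",
  lf            = "s0.31",
  ulf           = "u0.32",
  `short accum` = "s8.7",
  uf            = "u0.16",
  f             = "s0.15"
)

#' Fixed-point format descriptor
#'
#' Creates a `<s,i,p>` format: an optional sign bit, `i` integer bits and
#' `p` fraction bits.  Formats can be given as a compact string in the
#' `"sI.P"` / `"uI.P"` dialect (`"s16.15"`, `"u0.32"`, ...) or by the ISO
#' 18037 names `"accum"` (s16.15), `"long fract"`/`"lf"` (s0.31), `"ulf"`
#' (u0.32), `"short accum"` (s8.7), `"uf"` (u0.16) and `"f"` (s0.15).
#'
#' @param spec a format string, or an existing `fx_format` (returned as is)
#' @param signed,i,p alternatively, the three fields given directly
#' @return an object of class `fx_format` with fields `signed`, `i`, `p`
#' @examples
#' fx_format("s16.15")
#' fx_format(signed = TRUE, i = 3, p = 4)
#' @export
fx_format <- function(spec = NULL, signed = NULL, i = NULL, p = NULL) {
  if (inherits(spec, "fx_format")) return(spec)
  if (is.character(spec)) {
    s <- .FMT_ALIASES[[tolower(spec)]]
    if (is.null(s)) s <- spec
    m <- regmatches(s, regexec("^([su])([0-9]+)\\.([0-9]+)$", s))[[1]]
    if (length(m) != 4L)
      stop("cannot parse fixed-point format '", spec, "'")
    signed <- m[2] == "s"
    i <- as.integer(m[3])
    p <- as.integer(m[4])
  }
  if (is.null(signed) || is.null(i) || is.null(p))
    stop("give either a format string or all of signed, i, p")
  i <- as.integer(i); p <- as.integer(p)
  stopifnot(i >= 0, p >= 0, i + p >= if (signed) 0 else 1, i + p <= 50)
  structure(list(signed = isTRUE(signed), i = i, p = p),
            class = "fx_format")
}

#' @export
format.fx_format <- function(x, ...) {
  paste0(if (x$signed) "s" else "u", x$i, ".", x$p)
}

#' @export
print.fx_format <- function(x, ...) {
  cat("<", format(x), "> fixed-point format, w = ", fx_wordlength(x),
      " bits, epsilon = 2^-", x$p, "\n", sep = "")
  invisible(x)
}

#' Word length of a format
#'
#' `w = i + p + 1` for signed formats, `i + p` for unsigned ones.
#' @param fmt an [fx_format()]
#' @export
fx_wordlength <- function(fmt) {
  fmt <- fx_format(fmt)
  fmt$i + fmt$p + as.integer(fmt$signed)
}

#' Machine epsilon of a fixed-point format
#'
#' The constant gap `2^-p` between neighbouring representable values (the
#' value of one LSB).  Unlike floating point the gap is absolute: it does
#' not scale with the magnitude of the number.
#' @param fmt an [fx_format()] or format string
#' @return `2^-p`, exactly
#' @examples
#' fx_epsilon("s16.15") # 2^-15
#' @export
fx_epsilon <- function(fmt) {
  fmt <- fx_format(fmt)
  2^(-fmt$p)
}

#' Representable range of a fixed-point format
#'
#' `[-2^i, 2^i - 2^-p]` for signed formats, `[0, 2^i - 2^-p]` unsigned.
#' @param fmt an [fx_format()] or format string
#' @return numeric vector `c(min, max)`, exact in binary64
#' @export
fx_range <- function(fmt) {
  fmt <- fx_format(fmt)
  hi <- 2^fmt$i - 2^(-fmt$p)
  c(if (fmt$signed) -(2^fmt$i) else 0, hi)
}

#' Fixed-point values: an exact raw integer plus its format
#'
#' @param raw integer-valued numeric vector (two's-complement raw value,
#'   i.e. the represented value times `2^p`)
#' @param fmt an [fx_format()] or format string
#' @return an `fx_value`
#' @examples
#' fx_value(1311, "s16.15") # 0.040008544921875
#' @export
fx_value <- function(raw, fmt) {
  fmt <- fx_format(fmt)
  raw <- as.numeric(raw)
  if (any(raw != floor(raw)))
    stop("raw values must be integers")
  lo <- if (fmt$signed) -(2^(fmt$i + fmt$p)) else 0
  hi <- 2^(fmt$i + fmt$p) - 1
  if (any(raw < lo | raw > hi))
    stop("raw value outside the range of ", format(fmt))
  structure(list(raw = raw, fmt = fmt), class = "fx_value")
}

#' @export
length.fx_value <- function(x) length(x$raw)

#' @export
print.fx_value <- function(x, ...) {
  cat("<", format(x$fmt), "> fixed-point value(s):\n", sep = "")
  print(utils::head(data.frame(raw = x$raw, value = fx_decode(x)), 10L))
  if (length(x$raw) > 10L) cat("... (", length(x$raw), " values)\n", sep = "")
  invisible(x)
}

#' Decode a fixed-point value to its exact real value
#'
#' @param v an [fx_value()]
#' @return `raw * 2^-p`, exact in binary64
#' @export
fx_decode <- function(v) {
  stopifnot(inherits(v, "fx_value"))
  v$raw * 2^(-v$fmt$p)
}

#' Encode real values onto a fixed-point grid
#'
#' Rounds `x` to a multiple of `2^-p` under the requested rounding mode and
#' returns the result as an [fx_value()].  Round-down truncates toward
#' minus infinity (two's-complement truncation), round-to-nearest breaks
#' ties upward, and stochastic rounding rounds up with probability equal to
#' the residual fraction, consuming one draw from the generator per value
#' with a nonzero residual.
#'
#' Values that land outside the representable range raise an error: silent
#' saturation is deliberately reserved for the multiply stage
#' ([fx_mul()]), so that a mis-specified constant fails loudly.
#'
#' @param x numeric vector of values to encode
#' @param fmt destination [fx_format()]
#' @param rs an [fx_rounding()] spec (default round-to-nearest)
#' @param draws optional explicit k-bit integer draws replacing the
#'   generator (test hook; one draw per element)
#' @return an `fx_value`
#' @examples
#' fx_decode(fx_encode(0.04, "s16.15")) # 0.040008544921875
#' @export
fx_encode <- function(x, fmt, rs = fx_rounding("rn"), draws = NULL) {
  fmt <- fx_format(fmt)
  rs <- as_fx_rounding(rs)
  raw <- C_encode(as.numeric(x), fmt$signed, fmt$i, fmt$p,
                  rs$mode_int, rs$k_int, rs$rng, draws)
  fx_value(raw, fmt)
}
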