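# Formats, encode/decode, and the three rounding laws.

test_that("format descriptors expose epsilon, range and word length", {
  acc <- fx_format("accum")
  expect_equal(format(acc), "s16.15")
  expect_identical(fx_epsilon(acc), 2^-15)
  expect_identical(fx_range(acc), c(-65536, 65536 - 2^-15))
  lf <- fx_format("long fract")
  expect_identical(fx_epsilon(lf), 2^-31)
  expect_identical(fx_range(lf), c(-1, 1 - 2^-31))
  expect_identical(fx_range("u0.16"), c(0, 1 - 2^-16))
  expect_identical(fx_epsilon("s8.7"), 2^-7)
  expect_identical(fx_wordlength(acc), 32L)
  expect_identical(fx_wordlength("u0.32"), 32L)
  expect_error(fx_format("q4.4"), "cannot parse")
})

test_that("encode matches the solver constants and floors toward -inf", {
  # nearest-representable forms of the model constants 0.04 and 0.1
  v <- fx_encode(0.04, "s16.15", "rn")
  expect_identical(v$raw, 1311)
  expect_identical(fx_decode(v), 0.040008544921875)
  expect_identical(fx_encode(0.1, "s16.15", "rn")$raw, 3277)
  expect_identical(fx_decode(fx_encode(0.1, "s16.15", "rn")),
                   0.100006103515625)
  # RD truncates toward minus infinity, also for negatives
  expect_identical(fx_encode(0.04, "s16.15", "rd")$raw, 1310)
  expect_identical(fx_decode(fx_encode(0.04, "s16.15", "rd")),
                   0.03997802734375)
  expect_identical(fx_encode(-0.04, "s16.15", "rd")$raw, -1311)
  # representable input is exact under every mode
  g <- fx_rng("kiss99", 1)
  for (rs in list(fx_rounding("rd"), fx_rounding("rn"),
                  fx_rounding("sr", rng = g)))
    expect_identical(fx_decode(fx_encode(0.5, "s16.15", rs)), 0.5)
  # out-of-range encode raises instead of saturating
  expect_error(fx_encode(70000, "s16.15", "rn"), "range")
  expect_error(fx_encode(1, "s0.31", "rn"), "range")
})

test_that("decode is raw * 2^-p, exactly", {
  expect_identical(fx_decode(fx_value(1311, "s16.15")), 0.040008544921875)
  expect_identical(fx_decode(fx_value(0, "u0.32")), 0)
  expect_identical(fx_decode(fx_value(-2^31, "s0.31")), -1)
  expect_error(fx_value(2^31, "s0.31"), "range")
})

test_that("round-trip is exact for every representable value (w <= 10)", {
  g <- fx_rng("kiss99", 2)
  for (fmt in tiny_formats()) {
    raws <- all_raws(fmt)
    x <- raws * 2^(-fmt$p)
    for (rs in list(fx_rounding("rd"), fx_rounding("rn"),
                    fx_rounding("sr", rng = g),
                    fx_rounding("sr", k = 3, rng = g))) {
      expect_identical(fx_encode(x, fmt, rs)$raw, raws,
                       label = paste("round-trip", format(fmt), rs$mode))
    }
  }
})

test_that("RD brackets, RN is within eps/2 with ties up, exhaustively", {
  for (fmt in tiny_formats()) {
    eps <- fx_epsilon(fmt)
    raws <- all_raws(fmt)
    raws <- raws[-length(raws)] # leave head room for the upward modes
    for (t in c(0, 1 / 8, 3 / 8, 1 / 2, 5 / 8, 7 / 8)) {
      x <- (raws + t) * eps
      rd <- fx_decode(fx_encode(x, fmt, "rd"))
      expect_true(all(rd <= x & x < rd + eps))
      rn <- fx_decode(fx_encode(x, fmt, "rn"))
      expect_true(all(abs(rn - x) <= eps / 2 + 1e-18))
      # the tie rounds up, all other cases to the strictly nearest value
      expect_identical(fx_encode(x, fmt, "rn")$raw,
                       raws + (t >= 0.5))
    }
  }
})

test_that("SR lands on the two bracketing values with the right frequency", {
  n <- 1e5
  for (t in c(1 / 4, 1 / 2, 117 / 128)) {
    g <- fx_rng("kiss99", 31 + round(128 * t))
    x <- rep((5 + t) * 2^-4, n)
    raw <- fx_encode(x, "s3.4", fx_rounding("sr", rng = g))$raw
    expect_true(all(raw %in% c(5, 6)))
    freq <- mean(raw == 6)
    expect_lt(abs(freq - t), 4 * sqrt(t * (1 - t) / n))
  }
})

test_that("round_raw implements shift, MSB tie-up and SR short-circuit", {
  expect_identical(round_raw(22, 2, "rd"), 5)  # 0b101_10 -> 0b101
  expect_identical(round_raw(22, 2, "rn"), 6)  # tie on MSB rounds up
  expect_identical(round_raw(20, 2, "rn"), 5)  # zero residual: no change
  expect_identical(round_raw(-22, 2, "rd"), -6) # toward -inf, not zero
  expect_identical(round_raw(-22, 2, "rn"), -5)
  expect_identical(round_raw(c(-1, 1), 3, "rd"), c(-1, 0))
  # zero residual consumes no random draw
  g <- fx_rng("kiss99", 4)
  expect_identical(round_raw(16, 4, fx_rounding("sr", rng = g)), 1)
  expect_identical(rng_draws(g), 0)
  # nonzero residual consumes exactly one draw, predictable from a clone
  pred <- 1 + (rng_bits(rng_clone(g), 4) < 1)
  expect_identical(round_raw(17, 4, fx_rounding("sr", rng = g)), pred)
  expect_identical(rng_draws(g), 1)
})

test_that("k-bit SR: top-k comparator, k = f identical to full SR", {
  f <- 8
  ext <- -300:300
  for (k in c(1, 3, 8)) {
    draws <- floor(seq(0, 2^k - 1, length.out = length(ext)))
    got <- sr_kbit(ext, f, k, draws)
    resid <- ext %% 2^f
    top <- resid %/% 2^(f - k)
    want <- (ext - resid) / 2^f + (resid > 0 & draws < top)
    expect_identical(got, want)
  }
  # k = f with the same draw is bit-identical to the full-width law
  draws <- o_rng_stream("ranqd1", 5, length(ext)) %% 2^f
  expect_identical(sr_kbit(ext, f, f, draws),
                   round_raw(ext, f, fx_rounding("sr", k = f), draws = draws))
  # all-zero top bits always round down
  expect_identical(sr_kbit(4, 8, 2, 0), 0)   # residual 0b00000100, k=2
  # half-scale residual with k=1 behaves like a fair coin
  n <- 1e5
  g <- fx_rng("kiss99", 77)
  up <- sr_kbit(rep(128, n), 8, 1, rng_bits(g, 1, n))
  expect_lt(abs(mean(up) - 0.5), 4 * sqrt(0.25 / n))
})

test_that("comparator SR and add-then-truncate SR are equivalent", {
  # The two constructions are strictly equivalent under the draw
  # correspondence r <-> 2^f-1-r: adding r and truncating carries exactly
  # when r >= 2^f - residual, i.e. when the complemented draw is below the
  # residual.  Exhaustive over all (value, draw) pairs for f <= 8.
  for (f in c(1, 4, 8)) {
    ext <- rep(-2^9:(2^9), each = 2^f)
    draw <- rep(0:(2^f - 1), times = 2 * 2^9 + 1)
    add <- sr_add_truncate(ext, f, draw)
    comp <- sr_kbit(ext, f, f, 2^f - 1 - draw)
    expect_identical(add, comp)
    # literal carry rule: up iff draw >= 2^f - residual (and residual > 0)
    resid <- ext %% 2^f
    want <- (ext - resid) / 2^f + (resid > 0 & draw >= 2^f - resid)
    expect_identical(add, want)
  }
  # forced carry: maximal draw plus any nonzero residual rounds up
  expect_identical(sr_add_truncate(c(8, 9, 15), 3, 7), c(1, 2, 2))
  # zero residual is exact for every draw
  expect_identical(sr_add_truncate(rep(24, 8), 3, 0:7), rep(3, 8))
  # randomized 32-bit spot check against the pure-R oracle
  set.seed(NULL) # draws come from the package generator, not R's
  g <- fx_rng("kiss99", 123)
  f <- 20
  ext <- floor(rng_u32(g, 1e4) / 2^4) - 2^27
  draw <- rng_bits(g, f, 1e4)
  ms <- o_mulshift(ext, rep(1, 1e4), f)
  expect_identical(sr_add_truncate(ext, f, draw),
                   ms$q + (ms$resid > 0 & draw >= 2^f - ms$resid))
})
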