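# Independent oracles, pure R.  Nothing in this file touches the compiled
# code: 32-bit modular arithmetic is done on doubles split into 16-bit
# halves, so these re-implementations sit on the other side of every
# dual-route equivalence test.

u32 <- function(x) x %% 4294967296

xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

mul32 <- function(a, b) {
  u32((a %% 65536) * b + ((a %/% 65536 * b) %% 65536) * 65536)
}

shl32 <- function(a, k) u32(a * 2^k)
shr32 <- function(a, k) a %/% 2^k

# seeding mixer (documented fixture shared with the compiled generators)
o_splitmix32 <- function(s) {
  s <- u32(s + 2654435769)           # 0x9E3779B9
  t <- s
  t <- xor32(t, shr32(t, 16)); t <- mul32(t, 2246822507)   # 0x85EBCA6B
  t <- xor32(t, shr32(t, 13)); t <- mul32(t, 3266489909)   # 0xC2B2AE35
  t <- xor32(t, shr32(t, 16))
  list(s = s, out = t)
}

# replicate the seeding convention: four mixer outputs -> component states,
# zero words fall back to the classic defaults
o_seed <- function(alg, seed) {
  s <- u32(seed)
  a <- o_splitmix32(s); b <- o_splitmix32(a$s)
  cc <- o_splitmix32(b$s); d <- o_splitmix32(cc$s)
  st <- list(alg = alg,
             z = if (a$out != 0) a$out else 362436069,
             w = if (b$out != 0) b$out else 521288629,
             jsr = if (cc$out != 0) cc$out else 123456789,
             jcong = d$out)
  lf <- (a$out * 2 + b$out %% 2) %% 2^33
  st$lfsr <- if (lf != 0) lf else 1
  st$ranqd <- a$out
  st
}

o_rng_next <- function(st) {
  if (st$alg == "kiss99") {
    st$z <- u32(36969 * (st$z %% 65536) + st$z %/% 65536)
    st$w <- u32(18000 * (st$w %% 65536) + st$w %/% 65536)
    mwc <- u32(shl32(st$z, 16) + st$w)
    st$jcong <- u32(69069 * st$jcong + 1234567)
    st$jsr <- xor32(st$jsr, shl32(st$jsr, 17))
    st$jsr <- xor32(st$jsr, shr32(st$jsr, 13))
    st$jsr <- xor32(st$jsr, shl32(st$jsr, 5))
    out <- u32(xor32(mwc, st$jcong) + st$jsr)
  } else if (st$alg == "lfsr33") {
    lsb <- st$lfsr %% 2
    st$lfsr <- st$lfsr %/% 2
    if (lsb == 1) {
      lo <- xor32(st$lfsr %% 2^32, 524288)              # bit 19
      hi <- bitwXor(as.integer(st$lfsr %/% 2^32), 1L)   # bit 32
      st$lfsr <- hi * 2^32 + lo
    }
    out <- st$lfsr %% 2^32
  } else {
    st$ranqd <- u32(1664525 * st$ranqd + 1013904223)
    out <- st$ranqd
  }
  list(st = st, out = out)
}

o_rng_stream <- function(alg, seed, n) {
  st <- o_seed(alg, seed)
  out <- numeric(n)
  for (j in seq_len(n)) {
    r <- o_rng_next(st)
    st <- r$st
    out[j] <- r$out
  }
  out
}

# ----- exact product-and-shift oracle (16-bit limbs in doubles) -----------

# floor(ra*rb / 2^f) and residual, exactly, |raw| < 2^34, f <= 40; this is
# a second, independent implementation of the arithmetic the package's
# fx_mul_reference uses, kept deliberately separate from it
o_mulshift <- function(ra, rb, f) {
  sgn <- sign(ra) * sign(rb)
  ma <- abs(ra); mb <- abs(rb)
  a1 <- ma %/% 65536; a0 <- ma %% 65536
  b1 <- mb %/% 65536; b0 <- mb %% 65536
  p0 <- a0 * b0
  p1 <- a0 * b1 + a1 * b0
  p2 <- a1 * b1
  lo <- p0 + (p1 %% 65536) * 65536
  hi <- p2 + p1 %/% 65536 + lo %/% 2^32
  lo <- lo %% 2^32
  if (f <= 32) {
    resid_m <- lo %% 2^f
    q_m <- hi * 2^(32 - f) + lo %/% 2^f
  } else {
    resid_m <- (hi %% 2^(f - 32)) * 2^32 + lo
    q_m <- hi %/% 2^(f - 32)
  }
  q <- ifelse(sgn >= 0, q_m, -q_m - (resid_m > 0))
  resid <- ifelse(sgn >= 0, resid_m, ifelse(resid_m > 0, 2^f - resid_m, 0))
  list(q = q, resid = resid)
}

# mathematical rounding laws on an exact (q, resid, f) decomposition
o_round <- function(q, resid, f, mode, draws = NULL, k = NULL) {
  if (f == 0) return(q)
  switch(mode,
    rd = q,
    rn = q + (resid >= 2^(f - 1)),
    sr = {
      if (is.null(k)) k <- min(f, 32)
      q + (draws < resid %/% 2^(f - k))
    })
}

# textbook solver steps in plain double arithmetic, staged (not unrolled),
# for single-step comparison against the compiled binary64 backend
o_step <- function(solver, v, u, I, pp, h) {
  f <- function(y) {
    list(dv = 0.04 * y[1]^2 + 5 * y[1] + 140 - y[2] + I,
         du = pp$a * (pp$b * y[1] - y[2]))
  }
  fg <- function(y) {
    d <- f(y)
    list(dv = d$dv, du = d$du,
         gv = (0.08 * y[1] + 5) * d$dv - d$du,
         gu = pp$a * (pp$b * d$dv - d$du))
  }
  y <- c(v, u)
  k1 <- f(y)
  if (solver == "rk2mid") {
    k2 <- f(y + h / 2 * c(k1$dv, k1$du))
    y + h * c(k2$dv, k2$du)
  } else if (solver == "rk2trap") {
    k2 <- f(y + h * c(k1$dv, k1$du))
    y + h / 2 * (c(k1$dv, k1$du) + c(k2$dv, k2$du))
  } else if (solver == "rk3heun") {
    k2 <- f(y + h / 3 * c(k1$dv, k1$du))
    k3 <- f(y + 2 * h / 3 * c(k2$dv, k2$du))
    y + h / 4 * c(k1$dv, k1$du) + 3 * h / 4 * c(k3$dv, k3$du)
  } else {
    s1 <- fg(y)
    y1 <- y + h / 2 * c(s1$dv, s1$du) + h^2 / 8 * c(s1$gv, s1$gu)
    s2 <- fg(y1)
    y + h * c(s1$dv, s1$du) + h^2 / 6 * c(s1$gv, s1$gu) +
      h^2 / 3 * c(s2$gv, s2$gu)
  }
}

# small format zoo for exhaustive properties (all word lengths <= 10)
tiny_formats <- function() {
  lapply(c("s3.4", "s0.7", "u0.8", "s4.2", "u3.3", "s2.0", "u0.3", "s5.4"),
         fx_format)
}

all_raws <- function(fmt) {
  lo <- if (fmt$signed) -(2^(fmt$i + fmt$p)) else 0
  as.numeric(seq(lo, 2^(fmt$i + fmt$p) - 1))
}
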