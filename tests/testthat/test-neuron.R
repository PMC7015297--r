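# Izhikevich model, unrolled solvers, backends.

test_that("the right-hand side matches direct substitution", {
  p <- izh_params("RS")
  # on the recovery nullcline u = b v the recovery derivative vanishes
  expect_identical(izh_rhs(-65, -13, 0, p)$du, 0)
  expect_identical(izh_rhs(0, 0, 0, p)$dv, 140)
  r <- izh_rhs(-70, -14, 4.775, p)
  expect_equal(r$dv, 0.04 * 4900 - 350 + 140 + 14 + 4.775)
  expect_equal(r$du, 0.02 * (0.2 * -70 + 14))
  fs <- izh_params("FS")
  expect_identical(c(fs$a, fs$b, fs$c, fs$d), c(0.1, 0.2, -65, 2))
  ch <- izh_params("CH")
  expect_identical(c(ch$c, ch$d), c(-50, 2))
})

test_that("one binary64 step equals the staged textbook update", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  for (sv in c("rk2mid", "rk2trap", "rk3heun", "chantsai")) {
    sim <- izh_run(p, inp, solver_config(sv, "f64"), duration = 0.1,
                   trace = TRUE)
    want <- o_step(sv, -65, -13, 4.775, p, 0.1)
    # unrolled (Horner) vs staged evaluation: equal up to double roundoff
    expect_equal(sim$v_trace[1], want[1], tolerance = 1e-10)
    expect_equal(sim$u_trace[1], want[2], tolerance = 1e-10)
  }
})

test_that("one fixed-point RD step stays within the per-multiply bound", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  for (sv in c("rk2mid", "rk2trap")) {
    f64 <- izh_run(p, inp, solver_config(sv, "f64"), duration = 0.1,
                   trace = TRUE)
    frd <- izh_run(p, inp, solver_config(sv, "fixed", "rd"),
                   duration = 0.1, trace = TRUE)
    # <= 10 multiplies each off by < eps, plus rounded constants/inputs
    expect_lt(abs(f64$v_trace[1] - frd$v_trace[1]), 16 * 2^-15)
  }
})

test_that("solver accuracy orders: >= 2 for RK2s, >= 3 for the others", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  v_at <- function(sv, h) {
    izh_run(p, inp, solver_config(sv, "f64", h = h),
            duration = 4, trace = TRUE)$v_trace[round(4 / h)]
  }
  for (sv in c("rk2mid", "rk2trap", "rk3heun", "chantsai")) {
    vref <- v_at(sv, 1 / 256) # rich grid of the same solver
    ord <- log2(abs(v_at(sv, 0.5) - vref) / abs(v_at(sv, 0.25) - vref))
    expect_gt(ord, if (sv %in% c("rk2mid", "rk2trap")) 1.7 else 2.6)
  }
})

test_that("spike-and-reset behaves as a hybrid system on the time grid", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  sim <- izh_run(p, inp, solver_config("rk2mid", "f64"), duration = 1000,
                 trace = TRUE)
  st <- sim$spike_times
  expect_gt(length(st), 5)
  expect_true(all(diff(st) > 0))
  expect_equal(st / sim$h, round(st / sim$h)) # whole-step spike times
  idx <- round(st / sim$h)
  expect_true(all(sim$v_trace[idx] >= 30))    # traces keep the peak
  nxt <- idx[idx < length(sim$v_trace)] + 1
  expect_true(all(abs(sim$v_trace[nxt] - p$c) < 5)) # restart from v = c
  # regular spiking: ISI variation collapses after the transient
  isi <- diff(st)[-(1:3)]
  expect_lt(sd(isi) / mean(isi), 0.05)
})

test_that("no input from rest means no spikes; DC response is monotone", {
  p <- izh_params("RS")
  quiet <- izh_run(p, izh_input("dc", 0), solver_config("rk2mid", "f64"),
                   duration = 2000)
  expect_identical(length(quiet$spike_times), 0L)
  counts <- vapply(c(3, 4.775, 6, 8), function(I) {
    length(izh_run(p, izh_input("dc", I), solver_config("rk2mid", "f64"),
                   duration = 2000)$spike_times)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("exponentially decaying input produces finitely many spikes", {
  p <- izh_params("CH")
  sim <- izh_run(p, izh_input("exp", magnitude = 20, tau = 5),
                 solver_config("rk2trap", "f64"), duration = 2000)
  n_early <- sum(sim$spike_times < 100)
  expect_gt(n_early, 0)               # the burst rides the input
  expect_identical(sum(sim$spike_times > 500), 0L) # input has decayed away
})

test_that("identical configuration and seed reproduce a run exactly", {
  p <- izh_params("FS")
  inp <- izh_input("dc", 4.775)
  cfg <- solver_config("rk3heun", "fixed", "sr", sr_bits = 6)
  a <- izh_run(p, inp, cfg, spikes = 50, seed = 77)
  b <- izh_run(p, inp, cfg, spikes = 50, seed = 77)
  expect_identical(a$spike_times, b$spike_times)
  cc <- izh_run(p, inp, cfg, spikes = 50, seed = 78)
  expect_false(identical(a$spike_times, cc$spike_times))
})

test_that("every backend executes the same expression tree", {
  # structural check: per-run operation counts agree exactly across
  # backends (run below threshold so no reset arithmetic intervenes)
  p <- izh_params("RS")
  inp <- izh_input("dc", 0)
  for (sv in c("rk2mid", "rk2trap", "rk3heun", "chantsai")) {
    cfgs <- list(solver_config(sv, "f64"), solver_config(sv, "f32"),
                 solver_config(sv, "fixed", "rd"),
                 solver_config(sv, "fixed", "sr"),
                 solver_config(sv, "fixed", "rn", format_set = "16"))
    ops <- lapply(cfgs, function(cfg) {
      s <- izh_run(p, inp, cfg, duration = 1, seed = 3)
      c(s$n_mul, s$n_add)
    })
    for (j in 2:length(ops))
      expect_identical(ops[[j]], ops[[1]],
                       label = paste(sv, "backend", j, "op counts"))
  }
})

test_that("constants are built per backend mode", {
  p <- izh_params("RS")
  cfg <- solver_config("rk2mid", "fixed", "rn")
  k <- make_constants(cfg, p)
  # 0.04 is sub-unity, so it is held in u0.32 at full fraction precision
  expect_identical(k$raw[k$name == "c004"], round(0.04 * 2^32))
  expect_lt(abs(k$value[k$name == "c004"] - 0.04), 2^-33)
  # sub-unity constants live in u0.32, others in the state format
  expect_identical(unique(k$fmt[k$sub_unity]), "u0.32")
  expect_identical(k$fmt[k$name == "c140"], "s16.15")
  expect_identical(k$raw[k$name == "five"], 5 * 2^15) # exactly representable
  # binary32-rounded constants differ where 23 bits cannot hold the value
  k32 <- make_constants(solver_config("rk2mid", "fixed", "rn",
                                      constants_mode = "f32"), p)
  expect_false(k32$backend[k32$name == "c004"] == 0.04)
  expect_identical(k32$backend[k32$name == "five"], 5)
  # stochastic selection: exact constants have coinciding candidates
  ks <- make_constants(solver_config("rk2mid", "fixed", "rn",
                                     constants_mode = "stochastic"), p)
  expect_identical(ks$sel_p[ks$name == "five"], 0)
  expect_true(all(ks$sel_p >= 0 & ks$sel_p < 1))
  expect_true(all(ks$sel_p[ks$name %in% c("c004", "ah2")] > 0))
  # 16-bit set re-encodes into s8.7 / u0.16
  k16 <- make_constants(solver_config("rk2mid", "fixed", "rn",
                                      format_set = "16"), p)
  expect_identical(unique(k16$fmt[k16$sub_unity]), "u0.16")
  expect_identical(k16$raw[k16$name == "c004"], round(0.04 * 2^16))
})

test_that("reference_run is the binary64 backend, definitionally", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  a <- izh_reference_run(p, inp, "rk2trap", spikes = 20)
  b <- izh_run(p, inp, solver_config("rk2trap", "f64"), spikes = 20)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("SR ensemble mean voltage tracks binary64 between spikes", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  ref <- izh_run(p, inp, solver_config("rk2mid", "f64"), duration = 40,
                 trace = TRUE)
  vm <- rowMeans(vapply(1:10, function(r) {
    izh_run(p, inp, solver_config("rk2mid", "fixed", "sr"),
            duration = 40, seed = 600 + r, trace = TRUE)$v_trace
  }, numeric(400)))
  win <- 100:400 # inter-spike segment (spikes sit near 8 and 103 ms)
  expect_lt(mean(abs(vm[win] - ref$v_trace[win])), 0.05)
})

test_that("16-bit runs count their saturations", {
  p <- izh_params("RS")
  inp <- izh_input("dc", 4.775)
  s <- izh_run(p, inp, solver_config("rk2mid", "fixed", "rd",
                                     format_set = "16"),
               duration = 5000)
  expect_gt(s$saturations, 0)
  s32 <- izh_run(p, inp, solver_config("rk2mid", "fixed", "rd"),
                 duration = 5000)
  expect_identical(s32$saturations, 0)
})
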