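# Reproduction drivers: spike-lag analysis against the binary64 arithmetic
# reference, SR ensembles, SR-bit-width sweeps, 16-bit runs, input-dither
# sweeps and aligned membrane-potential traces.
#
# Lag convention, fixed and tested: lag(n) = t_test(n) - t_ref(n); positive
# means the test run spikes late (lag), negative means early (lead).

#' Spike lag of a test run against a reference run
#'
#' @param test,ref `izh_sim` results
#' @param n spike index (vectorized); `NULL` = all common spikes
#' @return lag in ms; `NA` marks a spike the test or reference run never
#'   produced (e.g. underflow-silenced 16-bit runs)
#' @export
spike_lag <- function(test, ref, n = NULL) {
  stopifnot(inherits(test, "izh_sim"), inherits(ref, "izh_sim"))
  if (is.null(n)) n <- seq_len(min(length(test$spike_times),
                                   length(ref$spike_times)))
  tt <- test$spike_times[n]
  tr <- ref$spike_times[n]
  unname(tt - tr)
}

# shared ensemble machinery: R runs with explicit seeds, lag per spike index
.lag_ensemble <- function(params, input, cfg, seeds, spikes, ref,
                          algorithm = "kiss99") {
  if (anyDuplicated(seeds))
    stop("ensemble seeds must be distinct (one stream per run)")
  lags <- matrix(NA_real_, nrow = length(seeds), ncol = spikes)
  for (r in seq_along(seeds)) {
    run <- izh_run(params, input, cfg, spikes = spikes, seed = seeds[r],
                   algorithm = algorithm)
    k <- min(length(run$spike_times), spikes, length(ref$spike_times))
    if (k > 0)
      lags[r, seq_len(k)] <-
        run$spike_times[seq_len(k)] - ref$spike_times[seq_len(k)]
  }
  structure(list(lags = lags, mean = colMeans(lags),
                 sd = apply(lags, 2, sd),   # sample SD, n - 1 denominator
                 seeds = seeds, R = length(seeds), spikes = spikes,
                 params = params, input = input, cfg = cfg, ref = ref),
            class = "lag_ensemble")
}

#' @export
print.lag_ensemble <- function(x, ...) {
  n <- max(which(!is.na(x$mean)))
  cat(sprintf(
    "lag ensemble, R = %d runs: lag(%d) = %+0.2f ms (SD %0.2f)\n",
    x$R, n, x$mean[n], x$sd[n]))
  invisible(x)
}

#' Stochastic-rounding ensemble of spike lags
#'
#' Runs the fixed/SR configuration `R` times with seeds `base_seed + 1 ...
#' base_seed + R` (one independent random stream per run) and reports the
#' per-spike mean and sample SD of the lag against the binary64 reference.
#'
#' @param params an [izh_params()]
#' @param input an [izh_input()]
#' @param cfg a fixed-backend SR [solver_config()]
#' @param R ensemble size (default 10, a desk-scale stand-in for the
#'   100-run protocol; reported summaries are insensitive to this choice)
#' @param base_seed run r uses seed `base_seed + r`
#' @param spikes number of spikes to track (default 650)
#' @param seeds explicit distinct seeds, overriding `base_seed`
#' @param ref optional precomputed reference run
#' @return a `lag_ensemble` with per-spike `mean` and `sd`
#' @export
sr_ensemble <- function(params, input, cfg, R = 10L, base_seed = 1000L,
                        spikes = 650L, seeds = NULL, ref = NULL) {
  stopifnot(inherits(cfg, "solver_config"))
  if (!(cfg$backend == "fixed" && cfg$rounding == "sr"))
    stop("sr_ensemble expects a fixed-point SR configuration")
  if (is.null(seeds)) seeds <- base_seed + seq_len(R)
  if (length(seeds) < 2L) stop("an ensemble needs R >= 2 runs")
  if (is.null(ref))
    ref <- izh_reference_run(params, input, cfg$solver, cfg$h,
                             spikes = spikes)
  .lag_ensemble(params, input, cfg, seeds, spikes, ref)
}

#' Sweep the stochastic-rounding comparison width
#'
#' Re-runs an SR ensemble for each residual bit-width `k`, reusing the
#' same seeds across widths (variance reduction: differences between
#' widths are then not confounded with stream differences).
#'
#' @param params,input,cfg,R,base_seed,spikes as in [sr_ensemble()]
#' @param k_list widths to test; `"full"` uses all residual bits
#' @return list with `summary` (data frame: one row per k with the
#'   final-spike mean and SD of the lag) and `ensembles`
#' @export
sr_bits_sweep <- function(params, input, cfg,
                          k_list = list(2, 4, 6, 12, "full"), R = 10L,
                          base_seed = 1000L, spikes = 650L) {
  ref <- izh_reference_run(params, input, cfg$solver, cfg$h,
                           spikes = spikes)
  ens <- lapply(k_list, function(k) {
    cfg_k <- solver_config(cfg$solver, "fixed", "sr", sr_bits = k,
                           format_set = cfg$format_set, h = cfg$h,
                           constants_mode = cfg$constants_mode)
    sr_ensemble(params, input, cfg_k, R = R, base_seed = base_seed,
                spikes = spikes, ref = ref)
  })
  names(ens) <- vapply(k_list, as.character, "")
  summary <- data.frame(
    k = names(ens),
    mean_lag = vapply(ens, function(e) e$mean[spikes], 0),
    sd_lag = vapply(ens, function(e) e$sd[spikes], 0),
    row.names = NULL)
  list(summary = summary, ensembles = ens)
}

#' Sweep Gaussian input dither levels
#'
#' For each dither SD (in s16.15 LSB units) runs `repeats` simulations and
#' summarizes the lag of the chosen spike against the binary64 reference.
#' Following the dither protocol, constants must pass through binary32
#' (`constants_mode = "f32"`) so that constant-precision offsets are
#' identical across backends and the measured differences are purely due
#' to arithmetic operations under dither; the reference run uses the same
#' constants.
#'
#' @param params an [izh_params()]
#' @param input base input (its `dither_sd_lsb` is overridden per level)
#' @param cfg a [solver_config()] with `constants_mode = "f32"`
#' @param sd_lsb_list dither levels, in s16.15 LSB units, level 0 allowed
#' @param repeats runs per level (default 10, desk scale)
#' @param base_seed repeat r uses seed `base_seed + r`
#' @param spikes spike horizon (default 650)
#' @param spike_index which spike's lag to summarize (default `spikes`)
#' @return list with `summary` (per-level mean/SD of the lag) and
#'   `ensembles`
#' @export
dither_sweep <- function(params, input, cfg,
                         sd_lsb_list = c(0, 1, 10, 100, 1000, 10000),
                         repeats = 10L, base_seed = 2000L, spikes = 650L,
                         spike_index = NULL) {
  stopifnot(inherits(cfg, "solver_config"))
  if (cfg$constants_mode != "f32")
    stop("the dither protocol uses binary32-rounded constants; ",
         "build cfg with constants_mode = 'f32'")
  if (is.null(spike_index)) spike_index <- spikes
  ref_cfg <- solver_config(cfg$solver, "f64", h = cfg$h,
                           constants_mode = "f32")
  ref <- izh_run(params, input, ref_cfg, spikes = spikes)
  ens <- lapply(sd_lsb_list, function(lv) {
    inp <- input
    inp$dither_sd_lsb <- lv
    .lag_ensemble(params, inp, cfg, base_seed + seq_len(repeats), spikes,
                  ref)
  })
  names(ens) <- as.character(sd_lsb_list)
  summary <- data.frame(
    dither_sd_lsb = as.numeric(sd_lsb_list),
    mean_lag = vapply(ens, function(e) e$mean[spike_index], 0),
    sd_lag = vapply(ens, function(e) e$sd[spike_index], 0),
    row.names = NULL)
  list(summary = summary, ensembles = ens, spike_index = spike_index)
}

#' Aligned membrane-potential traces around a spike
#'
#' Runs each configuration with tracing on and returns per-step `v`
#' aligned on a window around the reference run's `around_spike`-th spike.
#' Stochastic configurations are run `R` times and reported as mean and SD
#' per step (the SD inflates sharply at the spike step when realizations
#' fire one step apart, because threshold and reset values mix).
#'
#' @param params an [izh_params()]
#' @param input an [izh_input()]
#' @param cfgs named list of [solver_config()]s to overlay
#' @param around_spike reference spike to centre on (default 3)
#' @param window `c(before, after)` in ms around the reference spike
#' @param R runs per stochastic configuration
#' @param base_seed seeds `base_seed + r`
#' @return data frame with columns `t`, `config`, `v_mean`, `v_sd`
#' @export
trace_compare <- function(params, input, cfgs, around_spike = 3L,
                          window = c(-5, 10), R = 10L,
                          base_seed = 3000L) {
  ref <- izh_reference_run(params, input, cfgs[[1]]$solver, cfgs[[1]]$h,
                           spikes = around_spike + 1L, trace = TRUE)
  if (length(ref$spike_times) < around_spike)
    stop("reference run produced fewer than ", around_spike, " spikes")
  t0 <- ref$spike_times[around_spike]
  h <- cfgs[[1]]$h
  steps <- seq(floor((t0 + window[1]) / h), ceiling((t0 + window[2]) / h))
  steps <- steps[steps >= 1]
  dur <- max(steps) * h + h
  out <- lapply(names(cfgs), function(nm) {
    cfg <- cfgs[[nm]]
    stochastic <- (cfg$backend == "fixed" && cfg$rounding == "sr") ||
      input$dither_sd_lsb > 0
    runs <- if (stochastic) R else 1L
    vm <- matrix(NA_real_, nrow = runs, ncol = length(steps))
    for (r in seq_len(runs)) {
      sim <- izh_run(params, input, cfg, duration = dur,
                     seed = base_seed + r, trace = TRUE)
      vm[r, ] <- sim$v_trace[steps]
    }
    data.frame(t = steps * h, config = nm, v_mean = colMeans(vm),
               v_sd = if (runs > 1) apply(vm, 2, sd) else 0)
  })
  do.call(rbind, out)
}
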