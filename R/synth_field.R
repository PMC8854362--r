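# Synthetic evoked field-potential experiments: a sigmoidal input-output
# relation for the population spike, a linear stimulus-slope relation for the
# field EPSP, and an exponential approach to the post-TBS potentiated level.

#' Parameters of the synthetic field-potential generator
#'
#' The population-spike amplitude follows a sigmoid of stimulus intensity,
#' `A(S) = A_max / (1 + exp(-(S - S_50)/k_S))`, and the fEPSP initial slope
#' grows linearly as `epsp_gain * S`; intensities below `threshold_v` evoke
#' no response. After theta-burst stimulation all responses are multiplied by
#' `1 + (ltp_factor - 1) (1 - exp(-dt/ltp_tau))`.
#'
#' @param A_max Population-spike ceiling amplitude, mV.
#' @param S_50 Sigmoid midpoint, V.
#' @param k_S Sigmoid steepness, V (> 0).
#' @param threshold_v Stimulation threshold, V; weaker stimuli evoke nothing.
#' @param noise_floor_sd Additive white noise SD on both channels, mV.
#' @param epsp_gain fEPSP initial slope per stimulation volt, (mV/s)/V.
#' @param epsp_rise_ms fEPSP rise time (20-80% chord region is linear), ms.
#' @param ltp_factor Asymptotic post-TBS multiplier (> 0); 1 = no change.
#' @param ltp_tau Approach time constant of the potentiation, s.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return A list of class `"field_gen_params"`.
#' @export
field_gen_params <- function(A_max = 7, S_50 = 2.2, k_S = 0.35,
                             threshold_v = 1.25, noise_floor_sd = 0,
                             epsp_gain = 0.8, epsp_rise_ms = 40,
                             ltp_factor = 1.3, ltp_tau = 180,
                             sampling_rate = 10000, seed = 1L) {
  stopifnot(A_max > 0, k_S > 0, ltp_factor > 0, ltp_tau > 0,
            noise_floor_sd >= 0)
  structure(list(A_max = A_max, S_50 = S_50, k_S = k_S,
                 threshold_v = threshold_v, noise_floor_sd = noise_floor_sd,
                 epsp_gain = epsp_gain, epsp_rise_ms = epsp_rise_ms,
                 ltp_factor = ltp_factor, ltp_tau = ltp_tau,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "field_gen_params")
}

#' Timing skeleton of an LTP experiment
#'
#' Default schedule: an input-output pass, a 10-min baseline of test stimuli
#' every 20 s, TBS, and a 30-min follow-up.
#'
#' @param io_intensities Intensities of the input-output pass, V, increasing.
#' @param baseline_s Baseline length, s.
#' @param followup_s Follow-up length after TBS, s.
#' @param sweep_interval_s Test-stimulus interval, s.
#' @return A list of class `"field_schedule"`.
#' @export
field_schedule <- function(io_intensities = seq(0.5, 5, by = 0.25),
                           baseline_s = 600, followup_s = 1800,
                           sweep_interval_s = 20) {
  if (baseline_s <= 0 || followup_s <= 0 || sweep_interval_s <= 0)
    stop("schedule: durations must be positive", call. = FALSE)
  structure(list(io_intensities = io_intensities, baseline_s = baseline_s,
                 followup_s = followup_s,
                 sweep_interval_s = sweep_interval_s),
            class = "field_schedule")
}

sigmoid_amp <- function(S, p) {
  a <- p$A_max / (1 + exp(-(S - p$S_50) / p$k_S))
  a[S < p$threshold_v] <- 0
  a
}

# one dual-channel sweep: pre-stimulus baseline, then a triphasic population
# spike (two positive flanks at +0.1 A around a -0.9 A trough, so the
# flank-mean-minus-trough amplitude is exactly A) and a linear-rise fEPSP
# whose 20-80% chord slope is exactly `slope` mV/s
synth_field_sweep <- function(pop_amp, epsp_slope, intensity, p,
                              wall_time = NA_real_) {
  fs <- p$sampling_rate
  n <- round(0.100 * fs)            # 100 ms sweep
  stim_i <- round(0.010 * fs) + 1L  # stimulus at 10 ms
  t_ms <- ((seq_len(n) - stim_i)) * 1000 / fs  # ms relative to stimulus

  pop <- numeric(n)
  if (pop_amp > 0) {
    knots_t <- c(3, 5, 8, 11, 14, 20)
    knots_v <- c(0, 0.1, -0.9, 0.1, 0.02, 0) * pop_amp
    seg <- t_ms >= 3 & t_ms <= 20
    pop[seg] <- stats::approx(knots_t, knots_v, xout = t_ms[seg])$y
  }

  epsp <- numeric(n)
  if (epsp_slope > 0) {
    rise <- p$epsp_rise_ms
    amp <- epsp_slope * rise / 1000  # mV; chord slope of a linear rise
    on <- 2                          # EPSP onset 2 ms after the stimulus
    kt <- c(on, on + rise, on + rise + 30, on + rise + 31)
    kv <- c(0, amp, 0, 0)
    seg <- t_ms >= on & t_ms <= on + rise + 30
    epsp[seg] <- stats::approx(kt, kv, xout = t_ms[seg])$y
  }
  if (p$noise_floor_sd > 0) {
    pop <- pop + stats::rnorm(n, 0, p$noise_floor_sd)
    epsp <- epsp + stats::rnorm(n, 0, p$noise_floor_sd)
  }
  ep <- list(pre = c(1L, stim_i), step = c(stim_i, n + 1L),
             post = c(n + 1L, n + 1L))
  field_sweep(new_sweep(epsp, fs, "field_potential", ep),
              new_sweep(pop, fs, "field_potential", ep),
              stimulus_intensity = intensity,
              stimulus_time = (stim_i - 1) / fs,
              wall_time = wall_time)
}

#' Simulate a full evoked field-potential / LTP experiment
#'
#' Builds the input-output pass over `schedule$io_intensities`, picks the
#' test intensity evoking 70% of the maximal population-spike amplitude
#' (analytically, from the generating sigmoid), and renders the baseline and
#' post-TBS time course with the potentiation ramp of
#' [field_gen_params()].
#'
#' @param params A [field_gen_params()].
#' @param schedule A [field_schedule()].
#' @return An `"ltp_experiment"`; the attribute `"test_intensity"` records
#'   the intensity used for the time course.
#' @export
simulate_field_experiment <- function(params, schedule = field_schedule()) {
  set.seed(params$seed)
  io <- lapply(schedule$io_intensities, function(S)
    synth_field_sweep(sigmoid_amp(S, params),
                      if (S >= params$threshold_v) params$epsp_gain * S else 0,
                      S, params))
  # analytic 70%-of-max test intensity, clamped to the tested range
  s70 <- params$S_50 + params$k_S * log(7 / 3)
  s70 <- min(max(s70, params$threshold_v, min(schedule$io_intensities)),
             max(schedule$io_intensities))
  a70 <- sigmoid_amp(s70, params)
  e70 <- params$epsp_gain * s70

  tbs <- schedule$baseline_s
  times <- seq(schedule$sweep_interval_s,
               schedule$baseline_s + schedule$followup_s,
               by = schedule$sweep_interval_s)
  tc <- lapply(times, function(t) {
    f <- if (t > tbs)
      1 + (params$ltp_factor - 1) * (1 - exp(-(t - tbs) / params$ltp_tau))
    else 1
    synth_field_sweep(a70 * f, e70 * f, s70, params, wall_time = t)
  })
  exp <- ltp_experiment(io, tc,
                        baseline_window = c(0, tbs), tbs_time = tbs,
                        followup_window = c(tbs,
                                            tbs + schedule$followup_s))
  attr(exp, "test_intensity") <- s70
  exp
}
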