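# Evoked field-potential measurements: population-spike amplitude, fEPSP
# initial slope, stimulation thresholds, 70%-of-max calibration, LTP% and
# binned time courses.

#' Field-potential measurement configuration
#'
#' @param popspike_window_ms Post-stimulus search window for the population
#'   spike, ms.
#' @param detect_k Detectability criterion: a response must exceed
#'   `detect_k` times the pre-stimulus noise SD.
#' @param chord 20-80% rising-phase chord fractions for the fEPSP slope.
#' @param popspike_convention `"flank_mean"` (trough to mean of the two
#'   positive flanking peaks, the default hippocampal convention) or
#'   `"baseline_trough"` (pre-stimulus baseline to trough).
#' @return A list of class `"field_config"`.
#' @export
field_config <- function(popspike_window_ms = c(3, 40), detect_k = 3,
                         chord = c(0.2, 0.8),
                         popspike_convention = c("flank_mean",
                                                 "baseline_trough")) {
  popspike_convention <- match.arg(popspike_convention)
  structure(list(popspike_window_ms = popspike_window_ms,
                 detect_k = detect_k, chord = chord,
                 popspike_convention = popspike_convention),
            class = "field_config")
}

prestim_segment <- function(chan, stim_time) {
  fs <- chan$sampling_rate
  stim_i <- round(stim_time * fs) + 1L
  if (stim_i < 2) stop("no pre-stimulus samples", call. = FALSE)
  chan$samples[seq_len(stim_i - 1L)]
}

#' Population-spike amplitude of one field sweep
#'
#' Within the post-stimulus window on the stratum pyramidale channel, the
#' amplitude is the mean of the two positive peaks flanking the negative
#' trough, minus the trough. Returns 0 when no trough deeper than
#' `detect_k` x pre-stimulus noise SD below baseline exists.
#'
#' @param fs A `"field_sweep"`.
#' @param config A [field_config()].
#' @return mV (>= 0).
#' @export
measure_popspike_amplitude <- function(fs, config = field_config()) {
  chan <- fs$popspike_channel
  sr <- chan$sampling_rate
  stim_i <- round(fs$stimulus_time * sr) + 1L
  w <- stim_i + round(config$popspike_window_ms / 1000 * sr)
  if (w[2] > length(chan$samples))
    stop("population spike: post-stimulus window extends past the sweep",
         call. = FALSE)
  pre <- prestim_segment(chan, fs$stimulus_time)
  baseline <- mean(pre)
  noise <- stats::sd(pre)
  v <- chan$samples[w[1]:w[2]]
  ti <- which.min(v)
  if (v[ti] >= baseline - config$detect_k * noise) return(0)
  if (config$popspike_convention == "baseline_trough")
    return(baseline - v[ti])
  f1 <- if (ti > 1) max(v[1:(ti - 1L)]) else baseline
  f2 <- if (ti < length(v)) max(v[(ti + 1L):length(v)]) else baseline
  (f1 + f2) / 2 - v[ti]
}

# fEPSP amplitude and 20-80% chord slope of the rising phase; list(amp, slope)
epsp_response <- function(fs, config = field_config()) {
  chan <- fs$epsp_channel
  sr <- chan$sampling_rate
  stim_i <- round(fs$stimulus_time * sr) + 1L
  pre <- prestim_segment(chan, fs$stimulus_time)
  baseline <- mean(pre)
  noise <- stats::sd(pre)
  post <- chan$samples[(stim_i + 1L):length(chan$samples)] - baseline
  m <- which.max(abs(post))
  amp <- abs(post[m])
  if (amp <= config$detect_k * noise || amp == 0)
    return(list(amplitude = amp, slope = NA_real_))
  y <- abs(post[seq_len(m)])        # rising phase, magnitude
  lo <- config$chord[1] * amp
  hi <- config$chord[2] * amp
  t_lo <- crossing_time(y, lo)
  t_hi <- crossing_time(y, hi)
  if (is.na(t_lo) || is.na(t_hi) || t_hi <= t_lo)
    return(list(amplitude = amp, slope = NA_real_))
  list(amplitude = amp,
       slope = (hi - lo) / ((t_hi - t_lo) / sr))  # mV / s
}

# last upward crossing of `level` before the maximum, linearly interpolated
# (in samples, 0-based)
crossing_time <- function(y, level) {
  idx <- which(y[-1] >= level & y[-length(y)] < level)
  if (!length(idx)) {
    if (y[1] >= level) return(0)
    return(NA_real_)
  }
  i <- idx[length(idx)]
  i - 1 + (level - y[i]) / (y[i + 1] - y[i])
}

#' fEPSP initial slope of one field sweep
#'
#' Slope of the straight line between the 20% and 80% points of the fEPSP
#' rising phase on the stratum radiatum channel (amplitude-normalized chord),
#' reported as a magnitude in mV/s. `NA` when no EPSP exceeds `detect_k` x
#' the pre-stimulus noise SD.
#'
#' @param fs A `"field_sweep"`.
#' @param config A [field_config()].
#' @return mV/s, or `NA`.
#' @export
measure_epsp_slope <- function(fs, config = field_config()) {
  epsp_response(fs, config)$slope
}

#' Stimulation threshold of an input-output series
#'
#' Smallest tested intensity whose response (fEPSP presence for the EPSP
#' channel, population-spike amplitude for the POP-spike channel) exceeds
#' `detect_k` x the pre-stimulus noise SD; `NA` when none does.
#'
#' @param io List of `"field_sweep"` sorted by increasing intensity.
#' @param channel `"epsp"` or `"popspike"`.
#' @param noise_sd Optional noise-SD override (otherwise estimated per sweep
#'   from the pre-stimulus segment).
#' @param config A [field_config()].
#' @return V, or `NA`.
#' @export
determine_threshold <- function(io, channel = c("epsp", "popspike"),
                                noise_sd = NULL, config = field_config()) {
  channel <- match.arg(channel)
  intens <- vapply(io, function(s) s$stimulus_intensity, numeric(1))
  if (length(intens) < 3)
    stop("threshold: need at least 3 tested intensities", call. = FALSE)
  if (any(diff(intens) <= 0))
    stop("threshold: series must be sorted by increasing intensity",
         call. = FALSE)
  for (s in io) {
    floor_sd <- if (is.null(noise_sd))
      stats::sd(prestim_segment(
        if (channel == "epsp") s$epsp_channel else s$popspike_channel,
        s$stimulus_time))
    else noise_sd
    resp <- if (channel == "epsp") epsp_response(s, config)$amplitude
            else measure_popspike_amplitude(s, config)
    if (resp > config$detect_k * floor_sd) return(s$stimulus_intensity)
  }
  NA_real_
}

#' Intensity evoking 70% of the maximal population-spike amplitude
#'
#' Linearly interpolates between the two tested intensities bracketing
#' 70% of the maximal observed amplitude. When the series is still rising at
#' its end (last increment above `saturation_tol` of the maximum and the
#' bracket falling in the final interval), the maximum is considered not
#' attained: a calibration warning is raised and the top intensity returned.
#'
#' @param io List of `"field_sweep"` sorted by increasing intensity.
#' @param fraction Amplitude fraction to calibrate to.
#' @param saturation_tol Relative final-increment tolerance for saturation.
#' @param config A [field_config()].
#' @return V.
#' @export
calibrate_70pct_intensity <- function(io, fraction = 0.7,
                                      saturation_tol = 0.05,
                                      config = field_config()) {
  intens <- vapply(io, function(s) s$stimulus_intensity, numeric(1))
  if (length(intens) < 3)
    stop("calibration: need at least 3 tested intensities", call. = FALSE)
  amps <- vapply(io, measure_popspike_amplitude, numeric(1), config = config)
  target <- fraction * max(amps)
  n <- length(amps)
  if (amps[1] >= target) return(intens[1])
  i <- which(amps[-n] <= target & amps[-1] >= target)
  if (!length(i)) {
    warning("maximal amplitude not attained; returning top intensity")
    return(intens[n])
  }
  i <- i[1]
  rising_end <- amps[n] == max(amps) &&
    (amps[n] - amps[n - 1]) > saturation_tol * amps[n]
  if (i == n - 1 && rising_end) {
    warning("input-output series still rising at its end; ",
            "returning top intensity")
    return(intens[n])
  }
  if (amps[i + 1] == amps[i]) return(intens[i])
  intens[i] + (target - amps[i]) / (amps[i + 1] - amps[i]) *
    (intens[i + 1] - intens[i])
}

timecourse_measures <- function(exp, config = field_config()) {
  wt <- vapply(exp$timecourse, function(s) s$wall_time, numeric(1))
  pop <- vapply(exp$timecourse, measure_popspike_amplitude, numeric(1),
                config = config)
  ep <- vapply(exp$timecourse, measure_epsp_slope, numeric(1),
               config = config)
  data.frame(wall_time_s = wt, popspike_mV = pop, epsp_mV_per_s = ep)
}

#' LTP% of an experiment
#'
#' The change of the fEPSP slope and the population-spike amplitude after
#' LTP induction, as a percentage of the pre-induction baseline: 100 x mean
#' over the final `final_bin` sweeps of the follow-up window, divided by the
#' mean over all baseline-window sweeps (per channel).
#'
#' @param exp An `"ltp_experiment"`.
#' @param final_bin Number of terminal follow-up sweeps averaged.
#' @param config A [field_config()].
#' @return Named numeric `c(epsp_ltp_percent = , popspike_ltp_percent = )`.
#' @export
compute_ltp_percent <- function(exp, final_bin = 6, config = field_config()) {
  tm <- timecourse_measures(exp, config)
  base <- tm[tm$wall_time_s >= exp$baseline_window[1] &
               tm$wall_time_s <= exp$tbs_time, ]
  post <- tm[tm$wall_time_s > exp$tbs_time &
               tm$wall_time_s <= exp$followup_window[2], ]
  if (!nrow(base)) stop("LTP: empty baseline window", call. = FALSE)
  if (!nrow(post)) stop("LTP: empty follow-up window", call. = FALSE)
  tail_rows <- post[max(1, nrow(post) - final_bin + 1):nrow(post), ]
  pct <- function(b, p) {
    mb <- mean(b, na.rm = TRUE)
    if (!is.finite(mb) || mb == 0) return(NA_real_)
    100 * mean(p, na.rm = TRUE) / mb
  }
  c(epsp_ltp_percent = pct(base$epsp_mV_per_s, tail_rows$epsp_mV_per_s),
    popspike_ltp_percent = pct(base$popspike_mV, tail_rows$popspike_mV))
}

#' Binned LTP time course
#'
#' Averages the time course in consecutive non-overlapping bins of
#' `bin_size` sweeps, expressed as % of the baseline mean per channel. The
#' trailing partial bin (if any) is averaged as-is and flagged.
#'
#' @param exp An `"ltp_experiment"`.
#' @param bin_size Sweeps per bin (>= 1).
#' @param config A [field_config()].
#' @return `data.frame` with `bin_time_s` (mean wall time of the bin),
#'   `epsp_pct`, `popspike_pct`, `n_sweeps` and `partial`.
#' @export
bin_timecourse <- function(exp, bin_size = 6, config = field_config()) {
  if (bin_size < 1) stop("bin_size must be >= 1", call. = FALSE)
  tm <- timecourse_measures(exp, config)
  if (!nrow(tm)) stop("empty time course", call. = FALSE)
  base <- tm[tm$wall_time_s >= exp$baseline_window[1] &
               tm$wall_time_s <= exp$tbs_time, ]
  if (!nrow(base)) stop("LTP: empty baseline window", call. = FALSE)
  b_pop <- mean(base$popspike_mV, na.rm = TRUE)
  b_ep <- mean(base$epsp_mV_per_s, na.rm = TRUE)
  bins <- split(seq_len(nrow(tm)), (seq_len(nrow(tm)) - 1) %/% bin_size)
  out <- do.call(rbind, lapply(bins, function(ix) {
    data.frame(bin_time_s = mean(tm$wall_time_s[ix]),
               epsp_pct = 100 * mean(tm$epsp_mV_per_s[ix], na.rm = TRUE) /
                 b_ep,
               popspike_pct = 100 * mean(tm$popspike_mV[ix], na.rm = TRUE) /
                 b_pop,
               n_sweeps = length(ix),
               partial = length(ix) < bin_size)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize one field-potential experiment
#'
#' Runs threshold determination on the input-output pass, the 70%-of-max
#' calibration, per-sweep measurements at the test intensity, and LTP%.
#'
#' @param exp An `"ltp_experiment"`.
#' @param config A [field_config()].
#' @return One-row `data.frame` in the conventional column layout:
#'   EPSP threshold (V), EPSP slope (mV/s), EPSP LTP (%), POP-spike
#'   threshold (V), amplitude (mV), POP-spike LTP (%).
#' @export
summarize_field_experiment <- function(exp, config = field_config()) {
  ltp <- compute_ltp_percent(exp, config = config)
  base <- timecourse_measures(exp, config)
  base <- base[base$wall_time_s <= exp$tbs_time, ]
  data.frame(
    epsp_threshold_V = determine_threshold(exp$io_series, "epsp",
                                           config = config),
    epsp_slope_mV_per_s = mean(base$epsp_mV_per_s, na.rm = TRUE),
    epsp_ltp_percent = unname(ltp["epsp_ltp_percent"]),
    popspike_threshold_V = determine_threshold(exp$io_series, "popspike",
                                               config = config),
    popspike_amplitude_mV = mean(base$popspike_mV, na.rm = TRUE),
    popspike_ltp_percent = unname(ltp["popspike_ltp_percent"]))
}
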