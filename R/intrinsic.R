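#' Spike-detection configuration
#'
#' Constants of the action-potential detector. The criteria are conventional
#' for somatic CA1 recordings: a spike is a local maximum exceeding
#' `peak_min_mV`, preceded within `cross_window_ms` by an upward crossing of
#' `cross_mV`; peaks closer than `merge_ms` are merged (higher peak kept);
#' the per-spike threshold is the voltage at the first sample of the final
#' rapid upstroke, i.e. the earliest sample before the peak from which the
#' two-point dV/dt stays above `dvdt_crit_mV_per_ms`.
#'
#' @param peak_min_mV Minimum peak voltage, mV.
#' @param cross_mV Upstroke crossing level, mV.
#' @param cross_window_ms Maximum peak-to-crossing lag, ms.
#' @param merge_ms Merge window for nearby maxima, ms.
#' @param dvdt_crit_mV_per_ms Threshold-detection slope criterion, mV/ms.
#' @param average_over One of `"suprathreshold"` (spike threshold/amplitude
#'   averaged over every sweep at and above rheobase, the default) or
#'   `"rheobase"` (rheobase sweep only).
#' @return A list of class `"spike_config"`.
#' @export
spike_config <- function(peak_min_mV = 0, cross_mV = -20, cross_window_ms = 5,
                         merge_ms = 2, dvdt_crit_mV_per_ms = 20,
                         average_over = c("suprathreshold", "rheobase")) {
  average_over <- match.arg(average_over)
  structure(list(peak_min_mV = peak_min_mV, cross_mV = cross_mV,
                 cross_window_ms = cross_window_ms, merge_ms = merge_ms,
                 dvdt_crit_mV_per_ms = dvdt_crit_mV_per_ms,
                 average_over = average_over),
            class = "spike_config")
}

#' Detect action potentials in a membrane-potential sweep
#'
#' @param sweep An `"ephys_sweep"` with `channel_kind = "membrane_potential"`.
#' @param config A [spike_config()].
#' @return `data.frame` with one row per spike: `peak_index`, `peak_time_s`,
#'   `peak_value_mV`, `threshold_index`, `threshold_time_s`,
#'   `threshold_value_mV`. Zero rows when no spike is found.
#' @export
detect_spikes <- function(sweep, config = spike_config()) {
  if (sweep$channel_kind != "membrane_potential")
    stop("spike detection requires a membrane_potential sweep", call. = FALSE)
  v <- sweep$samples
  n <- length(v)
  fs <- sweep$sampling_rate
  dt_ms <- 1000 / fs
  empty <- quick_df(list(peak_index = integer(0), peak_time_s = numeric(0),
                         peak_value_mV = numeric(0),
                         threshold_index = integer(0),
                         threshold_time_s = numeric(0),
                         threshold_value_mV = numeric(0)))
  if (n < 3) return(empty)
  core <- 2:(n - 1)
  is_peak <- v[core] > config$peak_min_mV &
    v[core] > v[core - 1] & v[core] >= v[core + 1]
  peaks <- core[is_peak]
  if (!length(peaks)) return(empty)

  # require a recent upward crossing of cross_mV
  up <- which(v[-1] >= config$cross_mV & v[-n] < config$cross_mV) + 1L
  if (!length(up)) return(empty)
  w <- max(1L, round(config$cross_window_ms / dt_ms))
  fi <- findInterval(peaks, up)
  keep <- fi > 0
  keep[keep] <- peaks[keep] - up[fi[keep]] <= w
  peaks <- peaks[keep]
  if (!length(peaks)) return(empty)

  # merge maxima closer than merge_ms, keeping the higher peak
  gap <- max(1L, round(config$merge_ms / dt_ms))
  merged <- peaks[1]
  for (p in peaks[-1]) {
    lastp <- merged[length(merged)]
    if (p - lastp < gap) {
      if (v[p] > v[lastp]) merged[length(merged)] <- p
    } else merged <- c(merged, p)
  }
  peaks <- merged

  # threshold: start of the final suprathreshold-slope run before each peak
  crit <- config$dvdt_crit_mV_per_ms * dt_ms  # mV per sample
  thr_idx <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    m <- p
    lim <- max(1L, p - w)
    while (m > lim && (v[m] - v[m - 1]) > crit) m <- m - 1L
    thr_idx[i] <- m
  }
  quick_df(list(peak_index = peaks,
                peak_time_s = (peaks - 1) / fs,
                peak_value_mV = v[peaks],
                threshold_index = thr_idx,
                threshold_time_s = (thr_idx - 1) / fs,
                threshold_value_mV = v[thr_idx]))
}

#' Detect spikes on every sweep of a current-step recording
#'
#' @param rec A `"current_step_recording"`.
#' @param config A [spike_config()].
#' @return Named list (by stimulus level, pA) of per-sweep spike tables as
#'   returned by [detect_spikes()].
#' @export
detect_spikes_recording <- function(rec, config = spike_config()) {
  out <- lapply(rec$sweeps, detect_spikes, config = config)
  names(out) <- format(recording_levels(rec), trim = TRUE)
  out
}

#' Resting membrane potential
#'
#' Mean of all pre-step-epoch samples pooled across sweeps.
#'
#' @param rec A `"current_step_recording"`.
#' @return mV.
#' @export
measure_resting_potential <- function(rec) {
  pre <- unlist(lapply(rec$sweeps, epoch_samples, which = "pre"))
  if (!length(pre))
    stop("resting potential: all pre-step epochs are empty", call. = FALSE)
  mean(pre)
}

# steady-state deflection of one sweep: mean over the final window_ms of the
# step epoch, minus the pre-epoch baseline
steady_state_deflection <- function(sweep, window_ms = 50) {
  step <- epoch_samples(sweep, "step")
  k <- max(1L, round(window_ms * sweep$sampling_rate / 1000))
  k <- min(k, length(step))
  tail_mean <- mean(step[(length(step) - k + 1L):length(step)])
  tail_mean - mean(epoch_samples(sweep, "pre"))
}

#' Membrane (input) resistance
#'
#' Ordinary least-squares slope of the steady-state voltage deflection (mean
#' over the final 50 ms of the step, minus the pre-step baseline) against
#' injected current over all hyperpolarizing (negative) levels, in MOhm.
#' Negative levels only, to avoid contamination by the subthreshold
#' spike-initiation nonlinearity of positive steps.
#'
#' @param rec A `"current_step_recording"`.
#' @param window_ms Steady-state window at the step end, ms.
#' @return MOhm.
#' @export
measure_membrane_resistance <- function(rec, window_ms = 50) {
  lev <- recording_levels(rec)
  neg <- which(lev < 0)
  if (length(neg) < 2)
    stop("membrane resistance: need at least 2 negative-level sweeps",
         call. = FALSE)
  dv <- vapply(rec$sweeps[neg], steady_state_deflection, numeric(1),
               window_ms = window_ms)
  i <- lev[neg]
  ols_slope(i, dv) * 1000  # mV/pA -> MOhm
}

# slope of y ~ x with fitted intercept
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Voltage sag of one hyperpolarizing step
#'
#' Difference between the most negative point of the step-epoch response and
#' its end value (mean over the final `end_window_ms`); non-positive by
#' construction and independent of any constant baseline offset.
#'
#' @param sweep An `"ephys_sweep"` with negative `stimulus_level`.
#' @param end_window_ms End-value window, ms.
#' @return mV (<= 0).
#' @export
compute_voltage_sag <- function(sweep, end_window_ms = 10) {
  if (is.na(sweep$stimulus_level) || sweep$stimulus_level >= 0)
    stop("voltage sag is defined for hyperpolarizing (negative) steps",
         call. = FALSE)
  step <- epoch_samples(sweep, "step")
  if (!length(step)) stop("voltage sag: empty step epoch", call. = FALSE)
  k <- max(1L, round(end_window_ms * sweep$sampling_rate / 1000))
  k <- min(k, length(step))
  min(step) - mean(step[(length(step) - k + 1L):length(step)])
}

#' Voltage-sag index
#'
#' Slope (with fitted intercept) of the per-step voltage sag, in mV, regressed
#' on the hyperpolarizing current magnitude in nA, over all negative levels.
#' With the min-minus-end sag convention the index is negative for cells with
#' an h-current-mediated sag, as conventionally reported. The algebraically
#' equivalent convention (positive sag magnitude against signed current)
#' yields the same slope value.
#'
#' @param rec A `"current_step_recording"`.
#' @param end_window_ms Passed to [compute_voltage_sag()].
#' @return mV/nA.
#' @export
compute_sag_index <- function(rec, end_window_ms = 10) {
  lev <- recording_levels(rec)
  neg <- which(lev < 0)
  if (length(neg) < 2)
    stop("sag index: need at least 2 negative-level sweeps", call. = FALSE)
  sag <- vapply(rec$sweeps[neg], compute_voltage_sag, numeric(1),
                end_window_ms = end_window_ms)
  ols_slope(abs(lev[neg]) / 1000, sag)
}

#' Rheobase
#'
#' Smallest positive stimulus level with at least one detected spike; `NA`
#' when no positive-level sweep spikes.
#'
#' @param rec A `"current_step_recording"`.
#' @param spikes Per-sweep spike tables from [detect_spikes_recording()].
#' @return pA, or `NA`.
#' @export
measure_rheobase <- function(rec, spikes) {
  lev <- recording_levels(rec)
  counts <- vapply(spikes, nrow, integer(1))
  firing <- lev[lev > 0 & counts > 0]
  if (!length(firing)) return(NA_real_)
  min(firing)
}

#' Mean spike threshold and amplitude
#'
#' Threshold is the mean per-spike threshold voltage and amplitude the mean
#' peak-minus-threshold height, over all spikes at and above rheobase (or at
#' the rheobase sweep only, per `config$average_over`).
#'
#' @param rec A `"current_step_recording"`.
#' @param spikes Per-sweep spike tables from [detect_spikes_recording()].
#' @param config A [spike_config()].
#' @return Named numeric `c(spike_threshold = , spike_amplitude = )`, both
#'   `NA` when no spikes exist.
#' @export
measure_spike_properties <- function(rec, spikes, config = spike_config()) {
  rheo <- measure_rheobase(rec, spikes)
  if (is.na(rheo))
    return(c(spike_threshold = NA_real_, spike_amplitude = NA_real_))
  lev <- recording_levels(rec)
  use <- if (config$average_over == "rheobase") which(lev == rheo)
         else which(lev >= rheo)
  tab <- do.call(rbind, spikes[use])
  c(spike_threshold = mean(tab$threshold_value_mV),
    spike_amplitude = mean(tab$peak_value_mV - tab$threshold_value_mV))
}

#' Current-spike (I-V) curve and cumulative spike number
#'
#' @param rec A `"current_step_recording"`.
#' @param spikes Per-sweep spike tables from [detect_spikes_recording()].
#' @return `data.frame` with `current_pA` (positive levels present in the
#'   recording) and `n_spikes`; the attribute `cumulative` holds the total
#'   spike count over positive steps.
#' @export
compute_iv_curve <- function(rec, spikes) {
  lev <- recording_levels(rec)
  pos <- which(lev > 0)
  counts <- vapply(spikes[pos], nrow, integer(1))
  iv <- quick_df(list(current_pA = lev[pos], n_spikes = as.integer(counts)))
  attr(iv, "cumulative") <- sum(iv$n_spikes)
  iv
}

#' Extract the full set of intrinsic membrane properties
#'
#' Runs spike detection and all scalar extractors on a current-step recording
#' and assembles an [intrinsic_properties()] record: resting potential,
#' membrane resistance, sag index, spike threshold, rheobase, spike
#' amplitude, I-V curve and cumulative spike number. Spike-dependent fields
#' are `NA` for non-spiking cells.
#'
#' @param rec A `"current_step_recording"`.
#' @param config A [spike_config()].
#' @return An `"intrinsic_properties"` object.
#' @export
extract_intrinsic_properties <- function(rec, config = spike_config()) {
  spikes <- detect_spikes_recording(rec, config)
  iv <- compute_iv_curve(rec, spikes)
  sp <- measure_spike_properties(rec, spikes, config)
  intrinsic_properties(
    resting_potential = measure_resting_potential(rec),
    membrane_resistance = measure_membrane_resistance(rec),
    sag_index = compute_sag_index(rec),
    spike_threshold = sp[["spike_threshold"]],
    rheobase = measure_rheobase(rec, spikes),
    spike_amplitude = sp[["spike_amplitude"]],
    iv_curve = iv)
}
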