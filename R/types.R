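#' Construct a single recorded sweep
#'
#' A sweep is one contiguous trace at a fixed sampling rate, together with
#' half-open epoch boundaries (pre-step, step, post-step) expressed as sample
#' indices, and the stimulus level that was delivered during the step epoch.
#' Canonical units are used throughout the package: membrane potential and
#' field potentials in mV, clamp current in pA, time in seconds, stimulus
#' intensity of field stimulation in V.
#'
#' @param samples Numeric vector of samples (mV for `membrane_potential` and
#'   `field_potential` channels, pA for `clamp_current`). All values must be
#'   finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_kind One of `"membrane_potential"`, `"clamp_current"`,
#'   `"field_potential"`.
#' @param epochs Named list with elements `pre`, `step`, `post`, each a
#'   half-open sample-index interval `c(start, end)` (1-based, `start <= end`,
#'   samples `start .. end - 1` belong to the epoch). Epochs must be disjoint,
#'   ordered, and jointly cover at most the sample count. Any epoch may be
#'   empty (`start == end`).
#' @param stimulus_level Injected current in pA (current steps) or stimulus
#'   intensity in V (field stimulation); `NA` when not applicable.
#' @return An object of class `"ephys_sweep"`.
#' @export
new_sweep <- function(samples, sampling_rate,
                      channel_kind = c("membrane_potential", "clamp_current",
                                       "field_potential"),
                      epochs = NULL, stimulus_level = NA_real_) {
  channel_kind <- match.arg(channel_kind)
  samples <- as.numeric(samples)
  if (is.null(epochs)) {
    epochs <- list(pre = c(1L, 1L), step = c(1L, length(samples) + 1L),
                   post = c(length(samples) + 1L, length(samples) + 1L))
  }
  x <- structure(list(
    samples = samples,
    sampling_rate = as.numeric(sampling_rate),
    channel_kind = channel_kind,
    epochs = lapply(epochs, function(e) as.integer(e)),
    stimulus_level = as.numeric(stimulus_level)
  ), class = "ephys_sweep")
  validate_sweep(x)
}

#' @rdname new_sweep
#' @param x An `"ephys_sweep"` object.
#' @export
validate_sweep <- function(x) {
  stopifnot(inherits(x, "ephys_sweep"))
  if (!is.finite(x$sampling_rate) || x$sampling_rate <= 0)
    stop("sweep: sampling_rate must be a positive number", call. = FALSE)
  if (anyNA(x$samples) || any(!is.finite(x$samples)))
    stop("sweep: all samples must be finite", call. = FALSE)
  ep <- x$epochs
  if (!all(c("pre", "step", "post") %in% names(ep)))
    stop("sweep: epochs must contain pre, step and post", call. = FALSE)
  n <- length(x$samples)
  bounds <- c(ep$pre, ep$step, ep$post)
  if (any(bounds < 1L) || any(bounds > n + 1L))
    stop("sweep: epoch indices out of range", call. = FALSE)
  ok <- ep$pre[1] <= ep$pre[2] && ep$pre[2] <= ep$step[1] &&
    ep$step[1] <= ep$step[2] && ep$step[2] <= ep$post[1] &&
    ep$post[1] <= ep$post[2]
  if (!ok)
    stop("sweep: epochs must be ordered, disjoint half-open intervals",
         call. = FALSE)
  x
}

#' Extract the samples of one epoch of a sweep
#'
#' @param sweep An `"ephys_sweep"` object.
#' @param which One of `"pre"`, `"step"`, `"post"`.
#' @return Numeric vector (possibly empty).
#' @export
epoch_samples <- function(sweep, which = c("pre", "step", "post")) {
  which <- match.arg(which)
  e <- sweep$epochs[[which]]
  if (e[2] <= e[1]) return(numeric(0))
  sweep$samples[e[1]:(e[2] - 1L)]
}

#' Current-step stimulation protocol
#'
#' Describes a family of constant-level current steps. The defaults follow the
#' standard CA1 pyramidal-cell characterization protocol: 350-ms steps from
#' -160 pA to +300 pA in 5 pA increments, sampled at 20 kHz.
#'
#' @param step_duration Step length in ms.
#' @param start_level First (most hyperpolarizing) level in pA.
#' @param end_level Last level in pA.
#' @param increment Level increment in pA (> 0).
#' @param pre_ms,post_ms Baseline lengths before and after the step, ms.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `"step_protocol"`.
#' @export
step_protocol <- function(step_duration = 350, start_level = -160,
                          end_level = 300, increment = 5,
                          pre_ms = 100, post_ms = 100,
                          sampling_rate = 20000) {
  if (increment <= 0) stop("protocol: increment must be > 0", call. = FALSE)
  if (start_level > end_level)
    stop("protocol: start_level must be <= end_level", call. = FALSE)
  if (step_duration <= 0)
    stop("protocol: step_duration must be > 0", call. = FALSE)
  structure(list(step_duration = step_duration, start_level = start_level,
                 end_level = end_level, increment = increment,
                 pre_ms = pre_ms, post_ms = post_ms,
                 sampling_rate = sampling_rate),
            class = "step_protocol")
}

#' Stimulus levels of a step protocol
#'
#' @param protocol A `"step_protocol"`.
#' @return Numeric vector of levels in pA, strictly increasing.
#' @export
protocol_levels <- function(protocol) {
  seq(protocol$start_level, protocol$end_level, by = protocol$increment)
}

#' Ordered family of current-step sweeps for one cell
#'
#' @param cell_id Character cell identifier.
#' @param sweeps List of `"ephys_sweep"` objects, one per delivered level,
#'   with strictly increasing `stimulus_level` on the protocol grid.
#' @param protocol The `"step_protocol"` used.
#' @param metadata Named list of free-text labels (e.g. `sex`, `age`,
#'   `treatment`, provenance such as hardware filter settings).
#' @return An object of class `"current_step_recording"`.
#' @export
current_step_recording <- function(cell_id, sweeps, protocol,
                                   metadata = list()) {
  levels <- vapply(sweeps, function(s) s$stimulus_level, numeric(1))
  if (length(levels) && any(diff(levels) <= 0))
    stop("recording: sweep stimulus levels must be strictly increasing",
         call. = FALSE)
  grid <- protocol_levels(protocol)
  if (length(levels) && !all(vapply(levels, function(l)
    any(abs(grid - l) < 1e-9), logical(1))))
    stop("recording: sweep levels must lie on the protocol grid",
         call. = FALSE)
  structure(list(cell_id = cell_id, sweeps = sweeps, protocol = protocol,
                 metadata = metadata),
            class = "current_step_recording")
}

#' Stimulus levels actually present in a current-step recording
#' @param rec A `"current_step_recording"`.
#' @return Numeric vector of levels in pA.
#' @export
recording_levels <- function(rec) {
  vapply(rec$sweeps, function(s) s$stimulus_level, numeric(1))
}

#' Voltage-clamp recording of holding current
#'
#' A long continuous clamp-current trace at a fixed holding potential, the
#' substrate of spontaneous EPSC detection.
#'
#' @param trace An `"ephys_sweep"` with `channel_kind = "clamp_current"`.
#' @param holding_potential Holding potential in mV (conventionally -70 mV for
#'   AMPA-mediated sEPSC recordings).
#' @param metadata Named list of free-text labels.
#' @return An object of class `"voltage_clamp_recording"` with a `duration`
#'   field in seconds.
#' @export
voltage_clamp_recording <- function(trace, holding_potential = -70,
                                    metadata = list()) {
  if (trace$channel_kind != "clamp_current")
    stop("voltage-clamp recording requires a clamp_current trace",
         call. = FALSE)
  structure(list(trace = trace,
                 holding_potential = holding_potential,
                 duration = length(trace$samples) / trace$sampling_rate,
                 metadata = metadata),
            class = "voltage_clamp_recording")
}

#' Evoked field-potential sweep (dual channel)
#'
#' One stimulus-locked sweep with simultaneous recordings from stratum
#' radiatum (field EPSP) and stratum pyramidale (population spike).
#'
#' @param epsp_channel,popspike_channel `"ephys_sweep"` objects with
#'   `channel_kind = "field_potential"`, equal length and sampling rate.
#' @param stimulus_intensity Stimulation intensity in V (>= 0).
#' @param stimulus_time Stimulus time in s relative to sweep start.
#' @param wall_time Time in s since the start of the experiment (`NA` for
#'   input-output calibration sweeps).
#' @return An object of class `"field_sweep"`.
#' @export
field_sweep <- function(epsp_channel, popspike_channel, stimulus_intensity,
                        stimulus_time, wall_time = NA_real_) {
  if (length(epsp_channel$samples) != length(popspike_channel$samples) ||
      epsp_channel$sampling_rate != popspike_channel$sampling_rate)
    stop("field sweep: channels must share length and sampling rate",
         call. = FALSE)
  if (stimulus_intensity < 0)
    stop("field sweep: stimulus_intensity must be >= 0", call. = FALSE)
  structure(list(epsp_channel = epsp_channel,
                 popspike_channel = popspike_channel,
                 stimulus_intensity = stimulus_intensity,
                 stimulus_time = stimulus_time,
                 wall_time = wall_time),
            class = "field_sweep")
}

#' Long-term potentiation experiment
#'
#' Bundles the input-output calibration pass and the stimulus-locked time
#' course around theta-burst stimulation (TBS): a baseline window, the TBS
#' time, and a follow-up window.
#'
#' @param io_series List of `"field_sweep"` at increasing stimulus intensity.
#' @param timecourse List of `"field_sweep"` at fixed intensity with strictly
#'   increasing `wall_time`.
#' @param baseline_window Numeric `c(start, end)` in s; must precede
#'   `tbs_time`.
#' @param tbs_time TBS delivery time in s.
#' @param followup_window Numeric `c(start, end)` in s; must follow
#'   `tbs_time`.
#' @param metadata Named list of free-text labels.
#' @return An object of class `"ltp_experiment"`.
#' @export
ltp_experiment <- function(io_series, timecourse, baseline_window, tbs_time,
                           followup_window, metadata = list()) {
  if (baseline_window[2] > tbs_time)
    stop("ltp experiment: baseline window must precede TBS", call. = FALSE)
  if (followup_window[1] < tbs_time)
    stop("ltp experiment: follow-up window must follow TBS", call. = FALSE)
  wt <- vapply(timecourse, function(s) s$wall_time, numeric(1))
  if (length(wt) > 1 && any(diff(wt) <= 0))
    stop("ltp experiment: timecourse wall times must be strictly increasing",
         call. = FALSE)
  io_int <- vapply(io_series, function(s) s$stimulus_intensity, numeric(1))
  if (length(io_int) > 1 && any(diff(io_int) <= 0))
    stop("ltp experiment: io_series must be ordered by intensity",
         call. = FALSE)
  structure(list(io_series = io_series, timecourse = timecourse,
                 baseline_window = as.numeric(baseline_window),
                 tbs_time = tbs_time,
                 followup_window = as.numeric(followup_window),
                 metadata = metadata),
            class = "ltp_experiment")
}

#' Intrinsic membrane properties of one cell
#'
#' The full set of current-clamp parameters extracted from a step family:
#' resting potential (mV), membrane resistance (MOhm), voltage-sag index
#' (mV/nA), spike threshold (mV), rheobase (pA), spike amplitude (mV) and the
#' current-spike curve with its cumulative spike number. Spike-dependent
#' fields are `NA` for non-spiking cells.
#'
#' @param resting_potential mV.
#' @param membrane_resistance MOhm.
#' @param sag_index mV/nA (<= 0 with the min-minus-end sag convention).
#' @param spike_threshold mV, `NA` if no spikes.
#' @param rheobase pA, one of the protocol's positive levels, `NA` if no
#'   spikes.
#' @param spike_amplitude mV (>= 0), `NA` if no spikes.
#' @param iv_curve `data.frame` with columns `current_pA` (positive protocol
#'   levels) and `n_spikes` (integer counts).
#' @param cumulative_spike_number Total spikes over positive steps; computed
#'   from `iv_curve` when omitted.
#' @return An object of class `"intrinsic_properties"`.
#' @export
intrinsic_properties <- function(resting_potential, membrane_resistance,
                                 sag_index, spike_threshold = NA_real_,
                                 rheobase = NA_real_,
                                 spike_amplitude = NA_real_,
                                 iv_curve = data.frame(current_pA = numeric(0),
                                                       n_spikes = integer(0)),
                                 cumulative_spike_number = NULL) {
  iv_curve$n_spikes <- as.integer(iv_curve$n_spikes)
  cum <- sum(iv_curve$n_spikes[iv_curve$current_pA > 0])
  if (is.null(cumulative_spike_number)) cumulative_spike_number <- cum
  if (cumulative_spike_number != cum)
    stop("intrinsic properties: cumulative_spike_number must equal the sum ",
         "of iv_curve counts over positive levels", call. = FALSE)
  if (!is.na(spike_amplitude) && spike_amplitude < 0)
    stop("intrinsic properties: spike_amplitude must be >= 0", call. = FALSE)
  structure(list(resting_potential = resting_potential,
                 membrane_resistance = membrane_resistance,
                 sag_index = sag_index,
                 spike_threshold = spike_threshold,
                 rheobase = rheobase,
                 spike_amplitude = spike_amplitude,
                 cumulative_spike_number = as.integer(cumulative_spike_number),
                 iv_curve = iv_curve),
            class = "intrinsic_properties")
}

#' @export
print.intrinsic_properties <- function(x, ...) {
  cat("Intrinsic membrane properties\n")
  cat(sprintf("  resting potential     %8.2f mV\n", x$resting_potential))
  cat(sprintf("  membrane resistance   %8.2f MOhm\n", x$membrane_resistance))
  cat(sprintf("  voltage-sag index     %8.2f mV/nA\n", x$sag_index))
  cat(sprintf("  spike threshold       %8.2f mV\n", x$spike_threshold))
  cat(sprintf("  rheobase              %8.1f pA\n", x$rheobase))
  cat(sprintf("  spike amplitude       %8.2f mV\n", x$spike_amplitude))
  cat(sprintf("  cumulative spikes     %8d\n", x$cumulative_spike_number))
  invisible(x)
}

#' Flatten intrinsic properties to a one-row data frame
#'
#' Column names carry the canonical units, matching the feature-table layout
#' used by [write_features_table()].
#'
#' @param x An `"intrinsic_properties"` object.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.intrinsic_properties <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(resting_potential_mV = x$resting_potential,
             membrane_resistance_MOhm = x$membrane_resistance,
             sag_index_mV_per_nA = x$sag_index,
             spike_threshold_mV = x$spike_threshold,
             rheobase_pA = x$rheobase,
             spike_amplitude_mV = x$spike_amplitude,
             cumulative_spike_number = x$cumulative_spike_number)
}
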