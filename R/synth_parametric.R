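# Parametric construction of current-step families.
#
# Waveforms are assembled so that every intrinsic-property extractor, under
# the package's stated measurement conventions, returns the target values
# exactly (noise-free mode): baseline epochs sit at the resting potential,
# subthreshold steady deflections are I x R, per-step sag transients have
# min-minus-end equal to sag_index x |I| in nA, and stereotyped spikes with a
# controlled dV/dt profile are inserted at the counts dictated by the target
# I-V curve.

#' Construct a noiseless current-step family from target properties
#'
#' Exact-oracle generator mode: builds a [current_step_recording()] whose
#' extraction by [extract_intrinsic_properties()] reproduces `target`
#' field-for-field (continuous fields to floating-point accuracy, counts and
#' levels exactly).
#'
#' @param target An [intrinsic_properties()] record. Must be internally
#'   consistent: `rheobase` (if defined) is a positive protocol level, the
#'   I-V curve is zero below rheobase and has at least one spike at rheobase.
#' @param protocol A [step_protocol()].
#' @param config The [spike_config()] whose constants the inserted spike
#'   waveforms are built against (slow approach below, rapid upstroke above
#'   the dV/dt criterion).
#' @param cell_id,metadata Passed to [current_step_recording()].
#' @return A `"current_step_recording"`.
#' @export
construct_parametric_step_responses <- function(target, protocol,
                                                config = spike_config(),
                                                cell_id = "parametric",
                                                metadata = list()) {
  levels <- protocol_levels(protocol)
  fs <- protocol$sampling_rate
  n_pre <- round(protocol$pre_ms * fs / 1000)
  n_step <- round(protocol$step_duration * fs / 1000)
  n_post <- round(protocol$post_ms * fs / 1000)
  epochs <- list(pre = c(1L, n_pre + 1L),
                 step = c(n_pre + 1L, n_pre + n_step + 1L),
                 post = c(n_pre + n_step + 1L, n_pre + n_step + n_post + 1L))

  iv <- target$iv_curve
  check_target_consistency(target, levels)

  sweeps <- lapply(levels, function(I) {
    nsp <- 0L
    if (I > 0 && nrow(iv)) {
      hit <- which(abs(iv$current_pA - I) < 1e-9)
      if (length(hit)) nsp <- iv$n_spikes[hit]
    }
    step <- if (nsp > 0)
      spiking_step_samples(n_step, nsp, target, config, fs)
    else
      subthreshold_step_samples(n_step, I, target, fs)
    samples <- c(rep(target$resting_potential, n_pre), step,
                 rep(target$resting_potential, n_post))
    new_sweep(samples, fs, "membrane_potential", epochs, stimulus_level = I)
  })
  current_step_recording(cell_id, sweeps, protocol, metadata)
}

check_target_consistency <- function(target, levels) {
  iv <- target$iv_curve
  if (nrow(iv)) {
    on_grid <- vapply(iv$current_pA, function(l)
      any(abs(levels - l) < 1e-9), logical(1))
    if (!all(on_grid))
      stop("target: iv_curve levels must be positive protocol levels",
           call. = FALSE)
  }
  spiking <- iv$current_pA[iv$n_spikes > 0]
  if (is.na(target$rheobase)) {
    if (length(spiking))
      stop("target: iv_curve has spikes but rheobase is absent",
           call. = FALSE)
    return(invisible(TRUE))
  }
  if (!any(abs(levels[levels > 0] - target$rheobase) < 1e-9))
    stop("target: rheobase must be a positive protocol level", call. = FALSE)
  if (!length(spiking) || abs(min(spiking) - target$rheobase) > 1e-9)
    stop("target: smallest spiking iv_curve level must equal rheobase",
         call. = FALSE)
  if (is.na(target$spike_threshold) || is.na(target$spike_amplitude))
    stop("target: spiking targets need spike_threshold and spike_amplitude",
         call. = FALSE)
  invisible(TRUE)
}

# ohmic step with an early triangular sag transient; steady state untouched
# over the final 60 ms so the resistance (50 ms) and sag-end (10 ms) windows
# see the plateau exactly
subthreshold_step_samples <- function(n_step, I, target, fs) {
  v_ss <- target$resting_potential + I * target$membrane_resistance / 1000
  out <- rep(v_ss, n_step)
  if (I < 0 && !is.na(target$sag_index) && target$sag_index != 0) {
    dip <- target$sag_index * abs(I) / 1000  # mV, <= 0
    n_guard <- round(0.060 * fs)
    n_tri <- min(round(0.120 * fs), max(0L, n_step - n_guard - 2L))
    if (n_tri >= 3) {
      half <- n_tri %/% 2L
      ramp <- c(seq(0, 1, length.out = half + 1L),
                seq(1, 0, length.out = n_tri - half)[-1])
      out[seq_len(n_tri)] <- v_ss + dip * ramp
    }
  }
  out
}

# plateau below the upstroke-crossing level with nsp stereotyped spikes whose
# threshold kink and peak are exact under the detector's dV/dt criterion
spiking_step_samples <- function(n_step, nsp, target, config, fs) {
  dt_mV <- config$dvdt_crit_mV_per_ms * 1000 / fs   # criterion in mV/sample
  thr <- target$spike_threshold
  amp <- target$spike_amplitude
  peak <- thr + amp

  slow_step <- 0.8 * dt_mV
  n_slow <- 3L
  plateau <- min(thr - n_slow * slow_step, config$cross_mV - 2)
  # re-derive the slow approach from the plateau actually used
  slow <- seq(plateau, thr, length.out = n_slow + 1L)[-1]
  # ensure the approach stays subcritical per sample
  if (any(diff(c(plateau, slow)) >= dt_mV))
    slow <- seq(thr - n_slow * 0.8 * dt_mV, thr, length.out = n_slow)

  n_fast <- max(1L, floor(amp / (2.5 * dt_mV)))
  fast <- thr + seq_len(n_fast) * (amp / n_fast)       # ends exactly at peak
  n_down <- max(1L, ceiling((peak - plateau) / (4 * dt_mV)))
  down <- peak - seq_len(n_down) * ((peak - plateau) / n_down)
  wave <- c(slow, fast, down)                          # peak at n_slow+n_fast

  len <- length(wave)
  min_gap <- max(len + 2L, round(0.005 * fs))          # >= 5 ms peak spacing
  if (nsp * min_gap > n_step)
    stop("target: too many spikes for the step duration", call. = FALSE)
  out <- rep(plateau, n_step)
  starts <- round((seq_len(nsp) - 0.5) / nsp * (n_step - len)) + 1L
  if (nsp > 1 && any(diff(starts) < min_gap))
    starts <- seq(1L, by = min_gap, length.out = nsp)
  for (s in starts) out[s:(s + len - 1L)] <- wave
  out
}

#' Draw a random internally consistent intrinsic-properties target
#'
#' Samples a target in physiologically plausible CA1 pyramidal-cell ranges
#' (resting potential around -60 mV, input resistance around 100 MOhm,
#' negative sag indices, rheobase on the positive protocol grid, spike counts
#' non-decreasing with current). Uses the current RNG state.
#'
#' @param protocol A [step_protocol()].
#' @param spiking Logical; draw a spiking cell (default) or a passive one.
#' @return An [intrinsic_properties()] record consistent with `protocol`.
#' @export
random_intrinsic_target <- function(protocol, spiking = TRUE) {
  levels <- protocol_levels(protocol)
  pos <- levels[levels > 0]
  resting <- stats::runif(1, -70, -52)
  resistance <- stats::runif(1, 60, 150)
  sag <- -stats::runif(1, 0, 15)
  if (!spiking || !length(pos)) {
    return(intrinsic_properties(resting, resistance, sag,
                                iv_curve = data.frame(current_pA = pos,
                                                      n_spikes = 0L)))
  }
  thr <- stats::runif(1, -45, -30)
  amp <- stats::runif(1, 75, 95)
  max_count <- max(1L, floor(protocol$step_duration / 6))
  rheo_i <- sample(seq_len(max(1L, length(pos) - 1L)), 1)
  counts <- integer(length(pos))
  above <- seq(rheo_i, length(pos))
  counts[above] <- pmin(seq_along(above), max_count)
  intrinsic_properties(resting, resistance, sag,
                       spike_threshold = thr, rheobase = pos[rheo_i],
                       spike_amplitude = amp,
                       iv_curve = data.frame(current_pA = pos,
                                             n_spikes = counts))
}

#' Quantize a continuous rheobase onto the protocol grid
#'
#' Returns the smallest positive protocol level at or above `value` (the
#' protocol increment makes finer resolution meaningless); values beyond the
#' grid are clamped to its ends.
#'
#' @param value Rheobase in pA.
#' @param protocol A [step_protocol()].
#' @return pA, a positive protocol level.
#' @export
quantize_rheobase <- function(value, protocol) {
  pos <- protocol_levels(protocol)
  pos <- pos[pos > 0]
  if (!length(pos)) stop("protocol has no positive levels", call. = FALSE)
  at_or_above <- pos[pos >= value - 1e-9]
  if (!length(at_or_above)) return(max(pos))
  min(at_or_above)
}

#' Build a non-decreasing I-V spike-count curve with a given total
#'
#' Distributes `cumulative` spikes over the positive protocol levels at and
#' above `rheobase_level` as a non-decreasing count sequence starting at >= 1,
#' capped per level by what the step duration can hold.
#'
#' @param protocol A [step_protocol()].
#' @param rheobase_level A positive protocol level, pA.
#' @param cumulative Total spike count (>= 1).
#' @return `data.frame(current_pA, n_spikes)` over all positive levels.
#' @export
make_iv_curve <- function(protocol, rheobase_level, cumulative) {
  pos <- protocol_levels(protocol)
  pos <- pos[pos > 0]
  i0 <- which(abs(pos - rheobase_level) < 1e-9)
  if (!length(i0))
    stop("rheobase_level must be a positive protocol level", call. = FALSE)
  k <- length(pos) - i0 + 1L
  cap <- max(1L, as.integer(protocol$step_duration %/% 6))
  cumulative <- as.integer(round(cumulative))
  cumulative <- max(k, min(cumulative, k * cap))  # feasible range
  base <- cumulative %/% k
  extra <- cumulative %% k
  counts_above <- rep(base, k)
  if (extra > 0)
    counts_above[(k - extra + 1L):k] <- base + 1L
  counts <- integer(length(pos))
  counts[i0:length(pos)] <- counts_above
  data.frame(current_pA = pos, n_spikes = as.integer(counts))
}
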