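# Cohort assembly: draws per-cell intrinsic-property targets from group-level
# Gaussian designs and emits exact parametric recordings with group labels,
# so the construct -> extract -> compare pipeline can be exercised end to
# end.

#' Define one group of a cohort design
#'
#' @param label Group label (e.g. `"control"`, `"treated"`).
#' @param n Cells in the group (>= 2).
#' @param mean Named numeric of parameter means. Recognized names:
#'   `resting_potential` (mV), `membrane_resistance` (MOhm), `sag_index`
#'   (mV/nA), `spike_threshold` (mV), `rheobase` (pA), `spike_amplitude`
#'   (mV), `cumulative_spike_number`. Unspecified parameters use typical CA1
#'   pyramidal-cell values.
#' @param sd Named numeric of parameter SDs (>= 0; 0 gives identical cells).
#'   When group summaries are published as mean +/- SEM, reconstruct the SD
#'   as `SEM * sqrt(n)`.
#' @return A list of class `"cohort_group"`.
#' @export
cohort_group <- function(label, n, mean = numeric(0), sd = numeric(0)) {
  if (n < 2) stop("cohort group: n must be >= 2", call. = FALSE)
  if (length(sd) && any(sd < 0))
    stop("cohort group: SDs must be >= 0", call. = FALSE)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "cohort_group")
}

default_cell_means <- c(resting_potential = -60, membrane_resistance = 100,
                        sag_index = -9, spike_threshold = -39,
                        rheobase = 140, spike_amplitude = 85,
                        cumulative_spike_number = 120)

#' Generate a labeled cohort of parametric recordings
#'
#' For every group, draws cell-level [intrinsic_properties()] targets from
#' independent Gaussians (per the design means/SDs), quantizes rheobase to
#' the protocol grid, distributes the cumulative spike number over the
#' suprathreshold levels, and constructs noiseless recordings with
#' [construct_parametric_step_responses()].
#'
#' @param design List of [cohort_group()]s.
#' @param protocol A [step_protocol()].
#' @param seed Integer seed.
#' @return List of `"current_step_recording"` objects; each carries its
#'   group label and cell id in `metadata`.
#' @export
generate_cohort <- function(design, protocol = step_protocol(), seed = 1L) {
  set.seed(seed)
  unlist(lapply(design, function(g) {
    lapply(seq_len(g$n), function(i) {
      target <- draw_cell_target(g, protocol)
      construct_parametric_step_responses(
        target, protocol,
        cell_id = sprintf("%s_%03d", g$label, i),
        metadata = list(group = g$label))
    })
  }), recursive = FALSE)
}

draw_cell_target <- function(g, protocol) {
  p <- default_cell_means
  p[names(g$mean)] <- g$mean
  s <- setNames(rep(0, length(p)), names(p))
  s[names(g$sd)] <- g$sd
  draw <- stats::rnorm(length(p), p, s)
  names(draw) <- names(p)
  pos <- protocol_levels(protocol)
  pos <- pos[pos > 0]
  rheo <- quantize_rheobase(max(draw[["rheobase"]], min(pos)), protocol)
  cum <- max(1, round(draw[["cumulative_spike_number"]]))
  iv <- make_iv_curve(protocol, rheo, cum)
  intrinsic_properties(
    resting_potential = draw[["resting_potential"]],
    membrane_resistance = max(draw[["membrane_resistance"]], 10),
    sag_index = min(draw[["sag_index"]], 0),
    spike_threshold = min(draw[["spike_threshold"]], -25),
    rheobase = rheo,
    spike_amplitude = max(draw[["spike_amplitude"]], 40),
    iv_curve = iv)
}

#' Extract intrinsic features for a whole cohort
#'
#' @param recordings List of `"current_step_recording"` (from
#'   [generate_cohort()] or elsewhere); group labels are taken from
#'   `metadata$group`.
#' @param config A [spike_config()].
#' @return `data.frame` with `cell_id`, `group` and one column per intrinsic
#'   feature (canonical units in the names), one row per cell.
#' @export
extract_cohort_features <- function(recordings, config = spike_config()) {
  rows <- lapply(recordings, function(rec) {
    feats <- as.data.frame(extract_intrinsic_properties(rec, config))
    grp <- rec$metadata$group
    cbind(data.frame(cell_id = rec$cell_id,
                     group = if (is.null(grp)) NA_character_ else grp),
          feats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published group-level reference values for CA1 electrophysiology
#'
#' Group summaries (mean, SEM, n) reported for CA1 pyramidal cells and CA1
#' field potentials of control and prenatally VPA-exposed rats of both sexes
#' at two ages. They serve as realistic generator targets and cohort
#' designs: group SDs are reconstructed as `SEM * sqrt(n)`.
#'
#' @param which `"intrinsic"` (current-clamp membrane properties),
#'   `"epsc"` (spontaneous EPSC parameters) or `"field"` (evoked
#'   field-potential parameters).
#' @return `data.frame` keyed by `sex`, `age`, `treatment` with `n` and a
#'   `<parameter>_mean` / `<parameter>_sem` column pair per parameter.
#' @export
reference_group_values <- function(which = c("intrinsic", "epsc", "field")) {
  which <- match.arg(which)
  key <- data.frame(
    sex = rep(c("male", "female"), each = 4),
    age = rep(rep(c("6w", "3m"), each = 2), 2),
    treatment = rep(c("control", "treated"), 4))
  if (which == "intrinsic") {
    return(cbind(key, data.frame(
      n = c(19, 13, 22, 19, 16, 15, 18, 16),
      resting_potential_mean = c(-60.58, -60.87, -59.95, -57.31,
                                 -56.45, -57.58, -56.20, -61.93),
      resting_potential_sem = c(0.72, 1.15, 0.67, 0.62,
                                0.64, 0.83, 0.82, 1.34),
      membrane_resistance_mean = c(92.41, 95.42, 116.71, 123.40,
                                   99.68, 101.33, 113.13, 97.81),
      membrane_resistance_sem = c(5.59, 4.89, 6.87, 7.22,
                                  6.32, 10.24, 5.92, 5.06),
      sag_index_mean = c(-9.82, -10.93, -9.88, -12.09,
                         -5.44, -10.00, -8.30, -9.69),
      sag_index_sem = c(1.04, 0.91, 1.08, 1.07, 0.58, 1.56, 0.56, 0.69),
      spike_threshold_mean = c(-39.35, -38.84, -41.49, -41.36,
                               -35.45, -38.73, -36.59, -41.30),
      spike_threshold_sem = c(1.00, 1.20, 1.49, 1.07, 1.22, 1.82,
                              1.24, 1.14),
      rheobase_mean = c(167.69, 175.45, 135.98, 99.22,
                        148.43, 141.19, 124.29, 151.59),
      rheobase_sem = c(11.47, 16.35, 10.62, 12.19,
                       16.43, 21.66, 12.90, 19.21),
      spike_amplitude_mean = c(90.06, 85.33, 83.55, 87.10,
                               82.14, 82.35, 82.14, 86.95),
      spike_amplitude_sem = c(1.38, 1.49, 1.55, 1.63, 1.53, 2.88,
                              1.35, 1.23),
      cumulative_spike_number_mean = c(118.59, 96.77, 134.00, 221.42,
                                       117.06, 150.40, 121.06, 118.25),
      cumulative_spike_number_sem = c(20.27, 22.25, 17.19, 32.06,
                                      25.38, 40.07, 15.48, 32.28))))
  }
  if (which == "epsc") {
    return(cbind(key, data.frame(
      n = c(15, 14, 17, 12, 10, 11, 15, 13),
      area_mean = c(88.49, 59.21, 190.10, 67.66,
                    62.39, 58.07, 168.03, 170.81),
      area_sem = c(4.95, 5.36, 13.84, 2.44, 5.61, 2.91, 10.79, 6.36),
      amplitude_mean = c(54.90, 27.55, 25.94, 13.60,
                         28.17, 30.52, 19.61, 20.39),
      amplitude_sem = c(8.23, 1.44, 2.76, 0.94, 1.92, 1.59, 1.24, 1.34),
      frequency_mean = c(0.52, 1.33, 1.18, 4.19, 0.65, 2.25, 2.40, 0.71),
      frequency_sem = c(0.15, 0.39, 0.24, 0.89, 0.21, 0.69, 0.60, 0.18))))
  }
  cbind(key, data.frame(
    n = c(6, 6, 8, 8, 8, 6, 8, 8),
    epsp_threshold_mean = c(2.75, 2.14, 2.13, 1.94, 2.25, 2.42, 2.69, 2.00),
    epsp_threshold_sem = c(0.19, 0.18, 0.08, 0.11, 0.13, 0.20, 0.28, 0.00),
    epsp_slope_mean = c(1.78, 2.00, 2.35, 1.87, 2.10, 1.87, 2.10, 2.12),
    epsp_slope_sem = c(0.27, 0.31, 0.27, 0.27, 0.53, 0.58, 0.23, 0.35),
    epsp_ltp_mean = c(140.20, 138.15, 136.24, 142.84,
                      135.50, 126.61, 144.24, 134.44),
    epsp_ltp_sem = c(13.93, 18.59, 4.10, 23.97, 8.88, 16.83, 14.14, 9.89),
    popspike_threshold_mean = c(3.25, 2.50, 2.56, 2.13,
                                2.63, 3.00, 3.00, 2.31),
    popspike_threshold_sem = c(0.30, 0.11, 0.11, 0.13,
                               0.13, 0.13, 0.33, 0.13),
    popspike_amplitude_mean = c(5.75, 7.25, 6.97, 6.97,
                                5.60, 5.54, 7.39, 7.12),
    popspike_amplitude_sem = c(0.31, 0.41, 0.50, 0.72,
                               0.25, 0.49, 0.69, 0.38),
    popspike_ltp_mean = c(128.23, 138.79, 145.17, 129.40,
                          145.54, 123.22, 124.41, 112.57),
    popspike_ltp_sem = c(8.67, 15.35, 7.69, 15.89,
                         8.47, 8.57, 19.40, 14.53)))
}

#' Intrinsic-property targets for the eight reference groups
#'
#' Converts the group means of [reference_group_values("intrinsic")] into
#' consistent [intrinsic_properties()] targets on a protocol grid (rheobase
#' quantized upward to the nearest level, the cumulative spike number
#' rounded and distributed over suprathreshold levels).
#'
#' @param protocol A [step_protocol()].
#' @return Named list of eight `"intrinsic_properties"` targets
#'   (`sex_age_treatment`).
#' @export
reference_intrinsic_targets <- function(protocol = step_protocol()) {
  tab <- reference_group_values("intrinsic")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    rheo <- quantize_rheobase(tab$rheobase_mean[i], protocol)
    intrinsic_properties(
      resting_potential = tab$resting_potential_mean[i],
      membrane_resistance = tab$membrane_resistance_mean[i],
      sag_index = tab$sag_index_mean[i],
      spike_threshold = tab$spike_threshold_mean[i],
      rheobase = rheo,
      spike_amplitude = tab$spike_amplitude_mean[i],
      iv_curve = make_iv_curve(protocol, rheo,
                               round(tab$cumulative_spike_number_mean[i])))
  })
  names(out) <- paste(tab$sex, tab$age, tab$treatment, sep = "_")
  out
}
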