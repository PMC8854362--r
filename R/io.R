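# Plain-text persistence: trace tables (UTF-8 delimited, column 1 = time in
# s, remaining columns = sweeps/channels) with a JSON metadata sidecar that
# declares sampling rate, channel kind, units, protocol, epochs and group
# labels. Unit conversion to the canonical mV/pA/s/Hz happens only at this
# boundary. Hardware provenance (amplifier filters, gain) travels as
# free-text metadata and is never re-applied by the pipeline. Vendor binary
# formats (ABF, Igor, NWB) are out of scope; convert externally to delimited
# text and describe the result in the sidecar.

voltage_scale <- function(unit) {
  switch(unit, mV = 1, V = 1000, uV = 1e-3,
         stop("unsupported voltage unit: ", unit, call. = FALSE))
}
current_scale <- function(unit) {
  switch(unit, pA = 1, nA = 1000, A = 1e12,
         stop("unsupported current unit: ", unit, call. = FALSE))
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_trace_table <- function(path) {
  delim <- detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE)
  if (ncol(tab) < 2)
    stop("trace file needs a time column plus at least one sweep column",
         call. = FALSE)
  for (cn in names(tab)[-1]) {
    col <- tab[[cn]]
    if (!is.numeric(col) || anyNA(col) || any(!is.finite(col)))
      stop("non-finite samples in column '", cn, "'", call. = FALSE)
  }
  tab
}

#' Read a recording from a delimited trace table and its sidecar
#'
#' The sidecar is a JSON document with at least `type` (one of
#' `"current_step"`, `"voltage_clamp"`, `"ltp_experiment"`),
#' `sampling_rate_hz`, `channel_kind`, `units`, `epochs` and (per type) the
#' protocol, stimulus levels, holding potential or sweep schedule; `group`
#' carries free-text labels. [write_recording()] produces this layout.
#'
#' @param path Trace table (comma- or tab-delimited, autodetected; column 1
#'   is time in s, the remaining columns are sweeps/channels).
#' @param sidecar JSON metadata document.
#' @return A `"current_step_recording"`, `"voltage_clamp_recording"` or
#'   `"ltp_experiment"`, with all invariants validated and canonical units.
#' @export
read_recording <- function(path, sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz) || !is.numeric(meta$sampling_rate_hz) ||
      meta$sampling_rate_hz <= 0)
    stop("sidecar: missing or invalid sampling_rate_hz", call. = FALSE)
  tab <- read_trace_table(path)
  dt <- diff(tab[[1]])
  if (length(dt) &&
      any(abs(dt - 1 / meta$sampling_rate_hz) > 0.01 / meta$sampling_rate_hz))
    stop("time column inconsistent with sidecar sampling rate",
         call. = FALSE)
  switch(meta$type,
         current_step = read_current_step(tab, meta),
         voltage_clamp = read_voltage_clamp(tab, meta),
         ltp_experiment = read_ltp(tab, meta),
         stop("sidecar: unknown recording type '", meta$type, "'",
              call. = FALSE))
}

meta_epochs <- function(meta) {
  lapply(meta$epochs, function(e) as.integer(unlist(e)))
}

read_current_step <- function(tab, meta) {
  levels <- as.numeric(meta$stimulus_levels_pA)
  if (length(levels) != ncol(tab) - 1L)
    stop("sidecar declares ", length(levels), " sweeps but the trace file ",
         "has ", ncol(tab) - 1L, call. = FALSE)
  vs <- voltage_scale(meta$units$voltage %||% "mV")
  ep <- meta_epochs(meta)
  p <- meta$protocol
  protocol <- step_protocol(p$step_duration_ms, p$start_level_pA,
                            p$end_level_pA, p$increment_pA, p$pre_ms,
                            p$post_ms, meta$sampling_rate_hz)
  sweeps <- lapply(seq_along(levels), function(i)
    new_sweep(tab[[i + 1L]] * vs, meta$sampling_rate_hz,
              "membrane_potential", ep, stimulus_level = levels[i]))
  current_step_recording(meta$cell_id %||% "cell", sweeps, protocol,
                         metadata = as.list(meta$group))
}

read_voltage_clamp <- function(tab, meta) {
  if (ncol(tab) != 2L)
    stop("voltage-clamp trace file must have exactly one current column",
         call. = FALSE)
  cs <- current_scale(meta$units$current %||% "pA")
  trace <- new_sweep(tab[[2]] * cs, meta$sampling_rate_hz, "clamp_current",
                     meta_epochs(meta))
  voltage_clamp_recording(trace, as.numeric(meta$holding_potential_mV %||% -70),
                          metadata = as.list(meta$group))
}

read_ltp <- function(tab, meta) {
  sw <- meta$sweeps
  n_sw <- nrow(sw)
  if (ncol(tab) - 1L != 2L * n_sw)
    stop("sidecar declares ", n_sw, " dual-channel sweeps but the trace ",
         "file has ", ncol(tab) - 1L, " channel columns", call. = FALSE)
  vs <- voltage_scale(meta$units$voltage %||% "mV")
  ep <- meta_epochs(meta)
  fs_list <- lapply(seq_len(n_sw), function(i) {
    field_sweep(
      new_sweep(tab[[2L * i]] * vs, meta$sampling_rate_hz,
                "field_potential", ep),
      new_sweep(tab[[2L * i + 1L]] * vs, meta$sampling_rate_hz,
                "field_potential", ep),
      stimulus_intensity = sw$stimulus_intensity_V[i],
      stimulus_time = sw$stimulus_time_s[i],
      wall_time = sw$wall_time_s[i])
  })
  io <- fs_list[sw$role == "io"]
  tc <- fs_list[sw$role == "timecourse"]
  ltp_experiment(io, tc, as.numeric(meta$baseline_window_s),
                 meta$tbs_time_s, as.numeric(meta$followup_window_s),
                 metadata = as.list(meta$group))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording and its metadata sidecar
#'
#' Inverse of [read_recording()]; the round trip reproduces samples to full
#' precision (17 significant digits) and all metadata.
#'
#' @param rec A `"current_step_recording"`, `"voltage_clamp_recording"` or
#'   `"ltp_experiment"`.
#' @param path Output trace-table path (tab-delimited).
#' @param sidecar Output JSON sidecar path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, sidecar) {
  UseMethod("write_recording")
}

write_trace_table <- function(cols, fs, path) {
  n <- length(cols[[1]])
  tab <- c(list(time_s = (seq_len(n) - 1) / fs), cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(tab, format_full), list(sep = "\t")))
  writeLines(body, con)
}

format_full <- function(x) formatC(x, digits = 17, format = "g")

#' @export
write_recording.current_step_recording <- function(rec, path, sidecar) {
  p <- rec$protocol
  cols <- lapply(rec$sweeps, function(s) s$samples)
  names(cols) <- sprintf("sweep_%02d", seq_along(cols))
  write_trace_table(cols, p$sampling_rate, path)
  meta <- list(
    type = "current_step", cell_id = rec$cell_id,
    sampling_rate_hz = p$sampling_rate, channel_kind = "membrane_potential",
    units = list(voltage = "mV", current = "pA", time = "s"),
    protocol = list(step_duration_ms = p$step_duration,
                    start_level_pA = p$start_level,
                    end_level_pA = p$end_level,
                    increment_pA = p$increment,
                    pre_ms = p$pre_ms, post_ms = p$post_ms),
    epochs = rec$sweeps[[1]]$epochs,
    stimulus_levels_pA = recording_levels(rec),
    group = rec$metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_recording.voltage_clamp_recording <- function(rec, path, sidecar) {
  write_trace_table(list(current = rec$trace$samples),
                    rec$trace$sampling_rate, path)
  meta <- list(
    type = "voltage_clamp",
    sampling_rate_hz = rec$trace$sampling_rate,
    channel_kind = "clamp_current",
    units = list(current = "pA", time = "s"),
    epochs = rec$trace$epochs,
    holding_potential_mV = rec$holding_potential,
    duration_s = rec$duration,
    group = rec$metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_recording.ltp_experiment <- function(rec, path, sidecar) {
  all_sw <- c(rec$io_series, rec$timecourse)
  cols <- list()
  for (i in seq_along(all_sw)) {
    cols[[sprintf("epsp_%03d", i)]] <- all_sw[[i]]$epsp_channel$samples
    cols[[sprintf("pop_%03d", i)]] <- all_sw[[i]]$popspike_channel$samples
  }
  fs <- all_sw[[1]]$epsp_channel$sampling_rate
  write_trace_table(cols, fs, path)
  meta <- list(
    type = "ltp_experiment",
    sampling_rate_hz = fs, channel_kind = "field_potential",
    units = list(voltage = "mV", stimulus = "V", time = "s"),
    epochs = all_sw[[1]]$epsp_channel$epochs,
    sweeps = data.frame(
      role = rep(c("io", "timecourse"),
                 c(length(rec$io_series), length(rec$timecourse))),
      stimulus_intensity_V = vapply(all_sw, function(s)
        s$stimulus_intensity, numeric(1)),
      stimulus_time_s = vapply(all_sw, function(s) s$stimulus_time,
                               numeric(1)),
      wall_time_s = vapply(all_sw, function(s) s$wall_time, numeric(1))),
    baseline_window_s = rec$baseline_window,
    tbs_time_s = rec$tbs_time,
    followup_window_s = rec$followup_window,
    group = rec$metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a per-cell feature table
#'
#' One row per cell/slice, columns named with canonical units. All rows must
#' share one schema; mixing feature records of different kinds is a schema
#' error.
#'
#' @param rows A `data.frame`, or a list of one-row `data.frame`s /
#'   coercible records sharing one schema.
#' @param path Output path (tab-delimited text).
#' @return Invisibly, `path`.
#' @export
write_features_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    frames <- lapply(rows, as.data.frame)
    schemas <- lapply(frames, names)
    if (length(frames) > 1 &&
        !all(vapply(schemas[-1], identical, logical(1), schemas[[1]])))
      stop("feature rows do not share one schema", call. = FALSE)
    rows <- if (length(frames)) do.call(rbind, frames)
            else data.frame()
  }
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
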