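test_that("sweep construction validates epochs and sample finiteness", {
  expect_s3_class(new_sweep(rnorm(100), 1000, "membrane_potential"),
                  "ephys_sweep")
  expect_error(new_sweep(c(1, NA, 3), 1000, "membrane_potential"),
               "finite")
  expect_error(new_sweep(c(1, Inf, 3), 1000, "membrane_potential"),
               "finite")
  expect_error(new_sweep(rnorm(10), 0, "membrane_potential"),
               "sampling_rate")
  # overlapping epochs
  expect_error(new_sweep(rnorm(10), 1000, "membrane_potential",
                         epochs = list(pre = c(1L, 6L), step = c(4L, 9L),
                                       post = c(9L, 11L))),
               "ordered")
  # out-of-range epoch
  expect_error(new_sweep(rnorm(10), 1000, "membrane_potential",
                         epochs = list(pre = c(1L, 3L), step = c(3L, 15L),
                                       post = c(15L, 15L))),
               "out of range")
})

test_that("protocol and recording invariants are enforced", {
  expect_error(step_protocol(increment = 0), "increment")
  expect_error(step_protocol(start_level = 10, end_level = -10), "start")
  p <- step_protocol(start_level = -20, end_level = 20, increment = 20,
                     sampling_rate = 1000)
  sw <- lapply(c(-20, 0, 20), function(l)
    new_sweep(rep(-60, 100), 1000, "membrane_potential",
              stimulus_level = l))
  expect_s3_class(current_step_recording("c1", sw, p),
                  "current_step_recording")
  expect_error(current_step_recording("c1", rev(sw), p), "increasing")
  off <- new_sweep(rep(-60, 100), 1000, "membrane_potential",
                   stimulus_level = 25)
  expect_error(current_step_recording("c1", c(sw, list(off)), p), "grid")
})

test_that("round trip through trace table and sidecar is the identity", {
  prot <- step_protocol(start_level = -160, end_level = -150, increment = 5,
                        pre_ms = 10, post_ms = 10, sampling_rate = 2000)
  target <- intrinsic_properties(-60.58, 92.41, -9.82)
  rec <- construct_parametric_step_responses(
    target, prot, metadata = list(sex = "male", age = "6w",
                                  treatment = "control"))
  td <- withr::local_tempdir()
  write_recording(rec, file.path(td, "t.tsv"), file.path(td, "t.json"))
  back <- read_recording(file.path(td, "t.tsv"), file.path(td, "t.json"))
  expect_s3_class(back, "current_step_recording")
  expect_identical(recording_levels(back), recording_levels(rec))
  for (i in seq_along(rec$sweeps)) {
    expect_identical(back$sweeps[[i]]$samples, rec$sweeps[[i]]$samples)
    expect_identical(back$sweeps[[i]]$epochs, rec$sweeps[[i]]$epochs)
  }
  expect_identical(back$metadata$treatment, "control")
  # extraction is preserved through the round trip
  expect_equal(measure_membrane_resistance(back), 92.41, tolerance = 1e-9)

  vc <- make_kernel_recording(20, 0.5, duration = 2)
  write_recording(vc, file.path(td, "v.tsv"), file.path(td, "v.json"))
  vback <- read_recording(file.path(td, "v.tsv"), file.path(td, "v.json"))
  expect_identical(vback$trace$samples, vc$trace$samples)
  expect_identical(vback$holding_potential, -70)

  ex <- simulate_field_experiment(
    field_gen_params(noise_floor_sd = 0, seed = 1),
    field_schedule(io_intensities = seq(1, 4, 0.5), baseline_s = 120,
                   followup_s = 240, sweep_interval_s = 60))
  write_recording(ex, file.path(td, "l.tsv"), file.path(td, "l.json"))
  lback <- read_recording(file.path(td, "l.tsv"), file.path(td, "l.json"))
  expect_identical(length(lback$io_series), length(ex$io_series))
  expect_identical(lback$timecourse[[2]]$epsp_channel$samples,
                   ex$timecourse[[2]]$epsp_channel$samples)
  expect_identical(compute_ltp_percent(lback), compute_ltp_percent(ex))
})

test_that("corrupted sidecars and trace files are rejected", {
  prot <- step_protocol(start_level = -160, end_level = -155, increment = 5,
                        pre_ms = 10, post_ms = 10, sampling_rate = 2000)
  rec <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, 0), prot)
  td <- withr::local_tempdir()
  tsv <- file.path(td, "t.tsv"); js <- file.path(td, "t.json")
  write_recording(rec, tsv, js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)

  # sweep arity mismatch
  bad <- meta; bad$stimulus_levels_pA <- c(-160, -155, -150)
  jsonlite::write_json(bad, js2 <- file.path(td, "b1.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(tsv, js2), "declares 3 sweeps")

  # missing sampling rate
  bad <- meta; bad$sampling_rate_hz <- NULL
  jsonlite::write_json(bad, js3 <- file.path(td, "b2.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(tsv, js3), "sampling_rate_hz")

  # sampling rate inconsistent with the time column
  bad <- meta; bad$sampling_rate_hz <- 1000
  jsonlite::write_json(bad, js4 <- file.path(td, "b3.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(tsv, js4), "inconsistent")

  # unknown units
  bad <- meta; bad$units$voltage <- "furlong"
  jsonlite::write_json(bad, js5 <- file.path(td, "b4.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(tsv, js5), "unsupported voltage unit")

  # unsorted levels
  bad <- meta; bad$stimulus_levels_pA <- rev(meta$stimulus_levels_pA)
  jsonlite::write_json(bad, js6 <- file.path(td, "b5.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(tsv, js6), "increasing")

  # overlapping epochs
  bad <- meta; bad$epochs$step <- c(1, 40)
  jsonlite::write_json(bad, js7 <- file.path(td, "b6.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(tsv, js7), "ordered")

  # non-finite sample names the offending column
  tab <- readLines(tsv)
  tab[3] <- sub("\t[^\t]*$", "\tNaN", tab[3])
  writeLines(tab, tsv2 <- file.path(td, "bad.tsv"))
  expect_error(read_recording(tsv2, js), "sweep_02")
})

test_that("voltage units in the sidecar are converted to canonical mV", {
  td <- withr::local_tempdir()
  prot <- step_protocol(start_level = -160, end_level = -155, increment = 5,
                        pre_ms = 10, post_ms = 10, sampling_rate = 2000)
  rec <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, 0), prot)
  tsv <- file.path(td, "t.tsv"); js <- file.path(td, "t.json")
  write_recording(rec, tsv, js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  meta$units$voltage <- "V"
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  scaled <- read_recording(tsv, js)
  expect_equal(scaled$sweeps[[1]]$samples,
               rec$sweeps[[1]]$samples * 1000)
})

test_that("feature tables enforce a single schema", {
  td <- withr::local_tempdir()
  ip <- intrinsic_properties(-60, 100, -5)
  f <- write_features_table(list(ip), file.path(td, "f.tsv"))
  tab <- read.delim(f)
  expect_identical(nrow(tab), 1L)
  expect_identical(ncol(tab), 7L)
  expect_true("rheobase_pA" %in% names(tab))

  # empty data frame gives a header-only file
  write_features_table(as.data.frame(ip)[0, ], file.path(td, "e.tsv"))
  expect_identical(nrow(read.delim(file.path(td, "e.tsv"))), 0L)

  fsum <- data.frame(epsp_threshold_V = 2.5, popspike_threshold_V = 3)
  expect_error(write_features_table(list(ip, fsum), file.path(td, "m.tsv")),
               "schema")
})
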