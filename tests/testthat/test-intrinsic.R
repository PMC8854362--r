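test_that("resting potential pools pre-step epochs", {
  rec <- make_ohmic_recording(resting = -60)
  expect_identical(measure_resting_potential(rec), -60)
  # published group mean used as a generator parameter round-trips exactly
  rec2 <- make_ohmic_recording(resting = -56.45)
  expect_equal(measure_resting_potential(rec2), -56.45, tolerance = 1e-12)
})

test_that("membrane resistance is the OLS slope over negative steps", {
  # 0.1 mV per pA deflection = 100 MOhm, exact by construction
  rec <- make_ohmic_recording(r_mohm = 100)
  expect_equal(measure_membrane_resistance(rec), 100, tolerance = 1e-9)
  rec2 <- make_ohmic_recording(r_mohm = 92.41)
  expect_equal(measure_membrane_resistance(rec2), 92.41, tolerance = 1e-9)
  # fails with fewer than two hyperpolarizing sweeps
  prot <- step_protocol(start_level = -5, end_level = 20, increment = 5,
                        pre_ms = 10, post_ms = 10, sampling_rate = 2000)
  rec3 <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, 0), prot)
  expect_error(measure_membrane_resistance(rec3), "negative")
})

test_that("voltage sag is min minus end and baseline independent", {
  fs <- 5000
  # monotone relaxation: minimum at the step end gives zero sag
  relax <- seq(-70, -75, length.out = round(0.3 * fs))
  relax <- c(relax, rep(-75, round(0.05 * fs)))
  sw <- make_step_sweep(relax, level = -100, fs = fs)
  expect_equal(compute_voltage_sag(sw), 0, tolerance = 1e-12)
  # forced min -80, end plateau -75 -> -5.0
  dip <- c(seq(-75, -80, length.out = 100), seq(-80, -75, length.out = 100),
           rep(-75, round(0.1 * fs)))
  sw2 <- make_step_sweep(dip, level = -100, fs = fs)
  expect_equal(compute_voltage_sag(sw2), -5, tolerance = 1e-12)
  # undefined for non-negative steps
  sw3 <- make_step_sweep(rep(-60, 100), level = 50, fs = fs)
  expect_error(compute_voltage_sag(sw3), "negative")
  # adding a constant offset leaves the sag unchanged
  sw4 <- sw2
  sw4$samples <- sw4$samples + 12.3
  expect_equal(compute_voltage_sag(sw4), compute_voltage_sag(sw2))
})

test_that("sag index reproduces construction slopes and cancels symmetric noise", {
  prot <- small_protocol()
  rec <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, -9.82), prot)
  expect_equal(compute_sag_index(rec), -9.82, tolerance = 1e-9)
  rec0 <- make_ohmic_recording()
  expect_equal(compute_sag_index(rec0), 0, tolerance = 1e-12)

  # symmetric +/- perturbations at levels symmetric about the mean current
  # cancel in the OLS slope
  base <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, -12.09), prot)
  lev <- recording_levels(base)
  neg <- which(lev < 0)
  lo <- neg[1]; hi <- neg[length(neg)]
  perturb <- function(sweep, delta) {
    e <- sweep$epochs$step
    i <- which.min(sweep$samples[e[1]:(e[2] - 1)]) + e[1] - 1L
    sweep$samples[i] <- sweep$samples[i] + delta
    sweep
  }
  base$sweeps[[lo]] <- perturb(base$sweeps[[lo]], -0.2)
  base$sweeps[[hi]] <- perturb(base$sweeps[[hi]], -0.2)
  # equal sag perturbations at |I|-symmetric levels shift the intercept only
  expect_equal(compute_sag_index(base), -12.09, tolerance = 1e-6)
})

test_that("spike detection finds inserted spikes and ignores subthreshold traces", {
  prot <- small_protocol()
  sub <- make_ohmic_recording(protocol = prot)
  counts <- vapply(detect_spikes_recording(sub), nrow, integer(1))
  expect_true(all(counts == 0))

  iv <- make_iv_curve(prot, 150, 30)
  target <- intrinsic_properties(-60, 100, -8, spike_threshold = -40,
                                 rheobase = 150, spike_amplitude = 85,
                                 iv_curve = iv)
  rec <- construct_parametric_step_responses(target, prot)
  det <- detect_spikes_recording(rec)
  lev <- recording_levels(rec)
  for (i in seq_along(lev)) {
    want <- iv$n_spikes[match(lev[i], iv$current_pA)]
    if (is.na(want)) want <- 0L
    expect_identical(nrow(det[[i]]), want)
  }
  one <- det[[which(lev == 150)]]
  expect_true(all(one$threshold_time_s <= one$peak_time_s))
  expect_true(all(diff(one$peak_time_s) > 0))
  expect_equal(one$threshold_value_mV, rep(-40, nrow(one)),
               tolerance = 1e-12)
})

test_that("rheobase is the smallest spiking positive level", {
  prot <- small_protocol()
  iv <- make_iv_curve(prot, 150, 10)
  rec <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, 0, spike_threshold = -40, rheobase = 150,
                         spike_amplitude = 85, iv_curve = iv), prot)
  sp <- detect_spikes_recording(rec)
  expect_identical(measure_rheobase(rec, sp), 150)
  quiet <- make_ohmic_recording(protocol = prot)
  expect_true(is.na(measure_rheobase(quiet,
                                     detect_spikes_recording(quiet))))
  # a continuous target value quantizes upward onto the 5 pA grid
  expect_identical(quantize_rheobase(99.22, step_protocol()), 100)
  expect_identical(quantize_rheobase(135.98, step_protocol()), 140)
})

test_that("spike threshold and amplitude are means over suprathreshold spikes", {
  # hand-built: two spikes, thresholds -40/-38, peaks +44/+44 -> (-39, 83)
  fs <- 20000
  dt_mV <- 20 * 1000 / fs  # 1 mV per sample at the criterion slope
  spike_wave <- function(thr, peak) {
    # sub-criterion climb from the plateau to thr, then a rapid upstroke
    n_sl <- ceiling((thr + 55) / (0.8 * dt_mV))
    slow <- seq(-55, thr, length.out = n_sl + 1)[-1]
    nf <- max(1, floor((peak - thr) / (2 * dt_mV)))
    fast <- thr + seq_len(nf) * (peak - thr) / nf
    c(slow, fast, seq(peak, -55, length.out = 40)[-1])
  }
  gapv <- rep(-55, 200)
  step <- c(gapv, spike_wave(-40, 44), gapv, spike_wave(-38, 44), gapv)
  sw <- make_step_sweep(step, level = 200, fs = fs)
  prot <- step_protocol(start_level = 200, end_level = 200, increment = 5,
                        pre_ms = 50, post_ms = 50, sampling_rate = fs,
                        step_duration = length(step) / fs * 1000)
  rec <- current_step_recording("hand", list(sw), prot)
  sp <- detect_spikes_recording(rec)
  expect_identical(nrow(sp[[1]]), 2L)
  props <- measure_spike_properties(rec, sp)
  expect_equal(props[["spike_threshold"]], -39, tolerance = 1e-9)
  expect_equal(props[["spike_amplitude"]], 83, tolerance = 1e-9)
})

test_that("iv curve counts positive steps and sums to the cumulative number", {
  prot <- small_protocol()
  iv <- make_iv_curve(prot, 150, 37)
  rec <- construct_parametric_step_responses(
    intrinsic_properties(-60, 100, 0, spike_threshold = -40, rheobase = 150,
                         spike_amplitude = 85, iv_curve = iv), prot)
  sp <- detect_spikes_recording(rec)
  got <- compute_iv_curve(rec, sp)
  expect_identical(got$n_spikes, iv$n_spikes)
  expect_identical(attr(got, "cumulative"), sum(iv$n_spikes))
  expect_true(all(got$current_pA > 0))
  quiet <- make_ohmic_recording(protocol = prot)
  got0 <- compute_iv_curve(quiet, detect_spikes_recording(quiet))
  expect_true(all(got0$n_spikes == 0L))
  expect_identical(attr(got0, "cumulative"), 0L)
})

test_that("a constant offset shifts only the resting potential", {
  prot <- small_protocol()
  set.seed(11)
  target <- random_intrinsic_target(prot)
  rec <- construct_parametric_step_responses(target, prot)
  shifted <- rec
  shifted$sweeps <- lapply(rec$sweeps, function(s) {
    s$samples <- s$samples + 7.5
    s
  })
  a <- extract_intrinsic_properties(rec)
  b <- extract_intrinsic_properties(shifted)
  expect_equal(b$resting_potential, a$resting_potential + 7.5)
  expect_equal(b$membrane_resistance, a$membrane_resistance,
               tolerance = 1e-9)
  expect_equal(b$sag_index, a$sag_index, tolerance = 1e-9)
  expect_identical(b$iv_curve$n_spikes, a$iv_curve$n_spikes)
})

test_that("passive cells yield absent spike-dependent fields", {
  rec <- make_ohmic_recording()
  ip <- extract_intrinsic_properties(rec)
  expect_true(is.na(ip$spike_threshold))
  expect_true(is.na(ip$rheobase))
  expect_true(is.na(ip$spike_amplitude))
  expect_identical(ip$cumulative_spike_number, 0L)
  expect_equal(ip$sag_index, 0, tolerance = 1e-12)
})
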