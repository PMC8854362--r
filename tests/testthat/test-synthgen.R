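test_that("parametric construction is an exact oracle for extraction", {
  prot <- small_protocol()
  set.seed(101)
  for (i in 1:8) {
    target <- random_intrinsic_target(prot, spiking = i %% 4 != 0)
    rec <- construct_parametric_step_responses(target, prot)
    expect_fields_equal(extract_intrinsic_properties(rec), target)
  }
})

test_that("inconsistent parametric targets are rejected", {
  prot <- small_protocol()
  # spikes below the stated rheobase
  iv <- make_iv_curve(prot, 100, 10)
  expect_error(construct_parametric_step_responses(
    intrinsic_properties(-60, 100, 0, spike_threshold = -40, rheobase = 150,
                         spike_amplitude = 85, iv_curve = iv), prot),
    "rheobase")
  # rheobase off the positive grid
  expect_error(intrinsic_properties(-60, 100, 0, spike_threshold = -40,
                                    rheobase = 150, spike_amplitude = 85,
                                    iv_curve = make_iv_curve(prot, 150, 5),
                                    cumulative_spike_number = 99),
               "cumulative")
})

test_that("mechanistic passive limit matches the analytic RC response", {
  prot <- step_protocol(start_level = -120, end_level = -40, increment = 40,
                        pre_ms = 100, post_ms = 20, sampling_rate = 10000)
  p <- sim_cell_params(g_h = 0, noise_sd = 0, g_L = 8, E_L = -70)
  rec <- simulate_current_step_cell(p, prot, seed = 1)
  expect_equal(measure_resting_potential(rec), -70, tolerance = 0.1)
  # steady-state deflection I/g_L: resistance 1/g_L = 125 MOhm within 1%
  expect_equal(measure_membrane_resistance(rec), 1000 / 8,
               tolerance = 0.01)
})

test_that("h-conductance produces a sag that deepens with g_h", {
  prot <- step_protocol(start_level = -160, end_level = -40, increment = 40,
                        pre_ms = 100, post_ms = 20, sampling_rate = 10000)
  sag <- vapply(c(0, 2, 4), function(gh) {
    rec <- simulate_current_step_cell(
      sim_cell_params(g_h = gh, noise_sd = 0), prot, seed = 1)
    compute_sag_index(rec)
  }, numeric(1))
  expect_true(all(diff(sag) < 0))
  # with g_h > 0 the -160 pA response minimum precedes the step end
  rec <- simulate_current_step_cell(sim_cell_params(g_h = 4, noise_sd = 0),
                                    prot, seed = 1)
  sw <- rec$sweeps[[1]]
  step <- epoch_samples(sw, "step")
  expect_lt(which.min(step), length(step))
  expect_lt(compute_voltage_sag(sw), -0.5)
})

test_that("mechanistic spike counts match the simulator ground truth", {
  prot <- step_protocol(start_level = -60, end_level = 300, increment = 20,
                        pre_ms = 50, post_ms = 20, sampling_rate = 20000)
  rec <- simulate_current_step_cell(sim_cell_params(noise_sd = 0), prot,
                                    seed = 3)
  truth <- vapply(attr(rec, "spike_times"), length, integer(1))
  det <- vapply(detect_spikes_recording(rec), nrow, integer(1))
  expect_identical(unname(det), unname(truth))
  # counts are non-decreasing in current and rheobase sits at the boundary
  expect_true(all(diff(truth) >= 0))
  sp <- detect_spikes_recording(rec)
  rheo <- measure_rheobase(rec, sp)
  lev <- recording_levels(rec)
  expect_true(all(det[lev > 0 & lev < rheo] == 0))
  expect_gt(det[which(lev == rheo)], 0)
})

test_that("mechanistic simulation is reproducible for a fixed seed", {
  prot <- step_protocol(start_level = -80, end_level = 40, increment = 40,
                        pre_ms = 20, post_ms = 20, sampling_rate = 5000)
  p <- sim_cell_params(noise_sd = 0.5)
  a <- simulate_current_step_cell(p, prot, seed = 9)
  b <- simulate_current_step_cell(p, prot, seed = 9)
  expect_identical(a$sweeps[[2]]$samples, b$sweeps[[2]]$samples)
  c <- simulate_current_step_cell(p, prot, seed = 10)
  expect_false(identical(a$sweeps[[2]]$samples, c$sweeps[[2]]$samples))
})

test_that("EPSC generator obeys rate, kernel shape and analytic charge", {
  # rate 0: flat noise-free trace, empty ground truth
  p0 <- epsc_gen_params(rate = 0, noise_sd = 0, duration = 2,
                        sampling_rate = 5000, seed = 1)
  r0 <- simulate_epsc_recording(p0)
  expect_identical(nrow(attr(r0, "ground_truth")), 0L)
  expect_identical(length(unique(r0$trace$samples)), 1L)

  # single noiseless event: extremum -20 pA at the kernel peak time
  rec <- make_kernel_recording(20, 1, tau_rise = 1, tau_decay = 8,
                               duration = 3)
  x <- rec$trace$samples
  expect_equal(min(x) - (-30), -20, tolerance = 1e-4)
  t_peak <- ca1ephys:::epsc_kernel_norm(1, 8)$t_peak
  expect_equal((which.min(x) - 1) / 20000, 1 + t_peak / 1000,
               tolerance = 1e-4)
  # analytic charge equals the numerically integrated kernel
  numint <- sum(-(x - (-30))) / 20000 * 1000  # pA * ms = fC
  expect_equal(epsc_kernel_charge(20, 1, 8), numint, tolerance = 0.001)

  # Poisson event counts: within the 99% interval for the expected count
  counts <- vapply(1:20, function(s) {
    pp <- epsc_gen_params(rate = 1, duration = 200, sampling_rate = 1000,
                          noise_sd = 0, seed = s)
    nrow(attr(simulate_epsc_recording(pp), "ground_truth"))
  }, integer(1))
  bounds <- qpois(c(0.005, 0.995), 200)
  expect_true(mean(counts >= bounds[1] & counts <= bounds[2]) >= 0.9)
  expect_equal(mean(counts), 200, tolerance = 0.1)
})

test_that("field generator honors the LTP factor and the sigmoid inversion", {
  sched <- field_schedule(io_intensities = seq(0.5, 5, 0.25),
                          baseline_s = 300, followup_s = 600,
                          sweep_interval_s = 30)
  # no potentiation: post/baseline ratio converges to 1
  ex1 <- simulate_field_experiment(
    field_gen_params(ltp_factor = 1, ltp_tau = 1, noise_floor_sd = 0,
                     seed = 1), sched)
  expect_equal(unname(compute_ltp_percent(ex1)), c(100, 100),
               tolerance = 1e-6)
  # forced 140% with fast tau
  ex2 <- simulate_field_experiment(
    field_gen_params(ltp_factor = 1.4, ltp_tau = 1, noise_floor_sd = 0,
                     seed = 1), sched)
  expect_equal(unname(compute_ltp_percent(ex2)), c(140, 140),
               tolerance = 0.5)
  # dense noiseless grid: recovered 70% intensity near S_50 + k_S ln(7/3)
  p <- field_gen_params(A_max = 6, S_50 = 2.4, k_S = 0.3, threshold_v = 1,
                        noise_floor_sd = 0, seed = 1)
  dense <- field_schedule(io_intensities = seq(0.5, 6, 0.1),
                          baseline_s = 60, followup_s = 60,
                          sweep_interval_s = 30)
  ex3 <- simulate_field_experiment(p, dense)
  s70 <- calibrate_70pct_intensity(ex3$io_series)
  expect_equal(s70, 2.4 + 0.3 * log(7 / 3), tolerance = 0.1)
})

test_that("cohorts are labeled, sized and reproducible as designed", {
  prot <- coarse_protocol()
  design <- list(
    cohort_group("control", 3, mean = c(rheobase = 135.98),
                 sd = c(rheobase = 0)),
    cohort_group("treated", 2, mean = c(rheobase = 99.22),
                 sd = c(rheobase = 0)))
  coh <- generate_cohort(design, prot, seed = 4)
  expect_identical(length(coh), 5L)
  feats <- extract_cohort_features(coh)
  expect_identical(as.vector(table(feats$group)[c("control", "treated")]),
                   c(3L, 2L))
  # zero SD: identical cells within group, rheobase quantized upward
  expect_identical(unique(feats$rheobase_pA[feats$group == "control"]), 140)
  expect_identical(unique(feats$rheobase_pA[feats$group == "treated"]), 100)
  coh2 <- generate_cohort(design, prot, seed = 4)
  expect_identical(extract_cohort_features(coh2), feats)
  expect_error(cohort_group("x", 2, sd = c(rheobase = -1)), "SD")
  expect_error(cohort_group("x", 1), "n must be")

  # full eight-group design (2 sexes x 2 ages x 2 treatments)
  tab <- reference_group_values("intrinsic")
  design8 <- lapply(seq_len(nrow(tab)), function(i)
    cohort_group(paste(tab$sex[i], tab$age[i], tab$treatment[i], sep = "_"),
                 2, mean = c(rheobase = tab$rheobase_mean[i]),
                 sd = c(rheobase = 0)))
  coh8 <- generate_cohort(design8, prot, seed = 1)
  labs <- unique(vapply(coh8, function(r) r$metadata$group, character(1)))
  expect_identical(length(coh8), 16L)
  expect_identical(length(labs), 8L)
})
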