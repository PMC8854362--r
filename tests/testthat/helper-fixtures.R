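# Small protocols and hand-built sweeps shared across tests. All fixtures
# are generated in code; simulation sizes are scaled down from the full
# acquisition protocol where exactness does not depend on them.

# reduced step protocol: 10 pA grid at 5 kHz
small_protocol <- function(sampling_rate = 5000, increment = 10,
                           pre_ms = 50, post_ms = 50) {
  step_protocol(start_level = -160, end_level = 300,
                increment = increment, pre_ms = pre_ms, post_ms = post_ms,
                sampling_rate = sampling_rate)
}

# coarse protocol for cohort-scale runs: 20 pA grid at 2 kHz
coarse_protocol <- function() {
  step_protocol(start_level = -160, end_level = 300, increment = 20,
                pre_ms = 50, post_ms = 25, sampling_rate = 2000)
}

# a single flat-baseline sweep with given step-epoch samples substituted
make_step_sweep <- function(step_samples, level, baseline = -60,
                            fs = 5000, pre_ms = 50, post_ms = 50) {
  n_pre <- round(pre_ms * fs / 1000)
  n_post <- round(post_ms * fs / 1000)
  n_step <- length(step_samples)
  new_sweep(c(rep(baseline, n_pre), step_samples, rep(baseline, n_post)),
            fs, "membrane_potential",
            epochs = list(pre = c(1L, n_pre + 1L),
                          step = c(n_pre + 1L, n_pre + n_step + 1L),
                          post = c(n_pre + n_step + 1L,
                                   n_pre + n_step + n_post + 1L)),
            stimulus_level = level)
}

# purely ohmic recording: deflection = level * r_mohm / 1000 mV, no sag
make_ohmic_recording <- function(r_mohm = 100, resting = -60,
                                 protocol = small_protocol()) {
  target <- intrinsic_properties(resting, r_mohm, 0)
  construct_parametric_step_responses(target, protocol)
}

# voltage-clamp recording holding one or more noiseless biexponential
# kernels of given amplitudes (pA) at given onset times (s)
make_kernel_recording <- function(amps, onsets_s, tau_rise = 1,
                                  tau_decay = 8, duration = NULL,
                                  fs = 20000, baseline = -30,
                                  noise_sd = 0) {
  if (is.null(duration)) duration <- max(onsets_s) + 0.5
  n <- round(duration * fs)
  x <- rep(baseline, n)
  kn <- ca1ephys:::epsc_kernel_norm(tau_rise, tau_decay)
  len <- round(10 * tau_decay / 1000 * fs)
  t_ms <- (seq_len(len) - 1) * 1000 / fs
  kern <- (exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise)) / kn$N
  for (i in seq_along(amps)) {
    i0 <- round(onsets_s[i] * fs) + 1L
    i1 <- min(n, i0 + len - 1L)
    x[i0:i1] <- x[i0:i1] - amps[i] * kern[seq_len(i1 - i0 + 1L)]
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  voltage_clamp_recording(new_sweep(x, fs, "clamp_current"), -70)
}

# field sweep with an explicit piecewise-linear popspike waveform
make_popspike_sweep <- function(knots_t_ms, knots_v, fs = 10000,
                                sweep_ms = 100, stim_ms = 10) {
  n <- round(sweep_ms * fs / 1000)
  stim_i <- round(stim_ms * fs / 1000) + 1L
  t_ms <- (seq_len(n) - stim_i) * 1000 / fs
  v <- numeric(n)
  seg <- t_ms >= min(knots_t_ms) & t_ms <= max(knots_t_ms)
  v[seg] <- approx(knots_t_ms, knots_v, xout = t_ms[seg])$y
  ep <- list(pre = c(1L, stim_i), step = c(stim_i, n + 1L),
             post = c(n + 1L, n + 1L))
  field_sweep(new_sweep(numeric(n), fs, "field_potential", ep),
              new_sweep(v, fs, "field_potential", ep),
              stimulus_intensity = 1, stimulus_time = (stim_i - 1) / fs)
}

expect_fields_equal <- function(extracted, target, tol = 1e-9) {
  for (f in c("resting_potential", "membrane_resistance", "sag_index")) {
    expect_equal(extracted[[f]], target[[f]], tolerance = tol,
                 label = f)
  }
  if (is.na(target$rheobase)) {
    expect_true(is.na(extracted$rheobase))
  } else {
    expect_identical(extracted$rheobase, target$rheobase)
    expect_equal(extracted$spike_threshold, target$spike_threshold,
                 tolerance = tol)
    expect_equal(extracted$spike_amplitude, target$spike_amplitude,
                 tolerance = tol)
  }
  expect_identical(extracted$cumulative_spike_number,
                   target$cumulative_spike_number)
  expect_identical(extracted$iv_curve$n_spikes, target$iv_curve$n_spikes)
}
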