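# Mechanistic generator mode: an exponential-integrate-and-fire neuron with
# a slow hyperpolarization-activated (h) conductance, integrated on the
# recording grid with internal substeps. The model is the cheapest mechanism
# with a genuine rheobase, a threshold kink and an h-current voltage sag,
# which is all the downstream feature extractors exercise.

#' Parameters of the simulated CA1-like cell
#'
#' Membrane equation (voltages mV, conductances nS, capacitance pF, time ms):
#' `C dV/dt = -g_L (V - E_L) - g_h h (V - E_h)
#'            + g_L Delta_T exp((V - V_T)/Delta_T) + I(t) + noise`,
#' with first-order h-current gating
#' `dh/dt = (h_inf(V) - h)/tau_h`, `h_inf(V) = 1/(1 + exp((V - V_half_h)/k_h))`
#' (activated by hyperpolarization for `k_h > 0`). When `V >= V_peak` a spike
#' is logged, `V` is reset to `V_reset` and integration pauses for the
#' refractory period. Defaults give a resting potential near -65 mV, input
#' resistance near 100 MOhm and a visible sag at strong negative steps.
#'
#' @param C Membrane capacitance, pF.
#' @param g_L Leak conductance, nS.
#' @param E_L Leak reversal, mV.
#' @param g_h Maximal h-conductance, nS (>= 0).
#' @param E_h h-current reversal, mV.
#' @param tau_h h-gate time constant, ms.
#' @param V_half_h,k_h Half-activation voltage and slope of the h-gate
#'   sigmoid, mV.
#' @param V_T Spike-initiation threshold, mV.
#' @param Delta_T Spike sharpness, mV.
#' @param V_reset Post-spike reset voltage, mV.
#' @param V_peak Spike cutoff voltage, mV.
#' @param refractory Absolute refractory period, ms.
#' @param noise_sd Additive white voltage-noise intensity, mV/sqrt(ms).
#' @return A list of class `"sim_cell_params"`.
#' @export
sim_cell_params <- function(C = 150, g_L = 10, E_L = -65, g_h = 2,
                            E_h = -30, tau_h = 50, V_half_h = -80, k_h = 6,
                            V_T = -45, Delta_T = 2, V_reset = -55,
                            V_peak = 20, refractory = 2, noise_sd = 0) {
  stopifnot(C > 0, g_L > 0, tau_h > 0, Delta_T > 0, g_h >= 0, noise_sd >= 0)
  structure(list(C = C, g_L = g_L, E_L = E_L, g_h = g_h, E_h = E_h,
                 tau_h = tau_h, V_half_h = V_half_h, k_h = k_h, V_T = V_T,
                 Delta_T = Delta_T, V_reset = V_reset, V_peak = V_peak,
                 refractory = refractory, noise_sd = noise_sd),
            class = "sim_cell_params")
}

h_inf <- function(V, p) 1 / (1 + exp((V - p$V_half_h) / p$k_h))

# resting fixed point of the subthreshold system (exp term included)
resting_fixed_point <- function(p) {
  f <- function(V) {
    -p$g_L * (V - p$E_L) - p$g_h * h_inf(V, p) * (V - p$E_h) +
      p$g_L * p$Delta_T * exp(pmin((V - p$V_T) / p$Delta_T, 20))
  }
  lo <- min(p$E_L, p$E_h) - 40
  hi <- p$V_T - 2 * p$Delta_T
  if (f(lo) * f(hi) > 0) return(p$E_L)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a current-step family with the mechanistic neuron
#'
#' Integrates the model of [sim_cell_params()] for every protocol level
#' (vectorized across sweeps) with fixed-step Euler integration on the
#' recording sampling grid refined by `substeps` internal steps. The sample
#' at which a spike cutoff occurs is recorded at `V_peak`, so the spike is
#' visible to the waveform-level detector; ground-truth spike times are
#' attached as attribute `"spike_times"` (a list, per level, in s).
#'
#' @param params A [sim_cell_params()].
#' @param protocol A [step_protocol()].
#' @param seed Integer seed fixing the noise stream.
#' @param substeps Internal integration substeps per recorded sample.
#' @param cell_id,metadata Passed to [current_step_recording()].
#' @return A `"current_step_recording"` with attribute `"spike_times"`.
#' @export
simulate_current_step_cell <- function(params, protocol, seed = 1L,
                                       substeps = 4L, cell_id = "mechanistic",
                                       metadata = list()) {
  set.seed(seed)
  fs <- protocol$sampling_rate
  dt <- 1000 / fs / substeps   # ms
  n_pre <- round(protocol$pre_ms * fs / 1000)
  n_step <- round(protocol$step_duration * fs / 1000)
  n_post <- round(protocol$post_ms * fs / 1000)
  n_tot <- n_pre + n_step + n_post
  levels <- protocol_levels(protocol)
  nl <- length(levels)

  V0 <- resting_fixed_point(params)
  V <- rep(V0, nl)
  h <- rep(h_inf(V0, params), nl)
  refr <- integer(nl)
  refr_steps <- max(1L, round(params$refractory / dt))
  out <- matrix(NA_real_, nrow = n_tot, ncol = nl)
  spikes <- vector("list", nl)
  for (i in seq_len(nl)) spikes[[i]] <- numeric(0)
  noisy <- params$noise_sd > 0
  nsd <- params$noise_sd * sqrt(dt)

  for (s in seq_len(n_tot)) {
    I <- if (s > n_pre && s <= n_pre + n_step) levels else rep(0, nl)
    spiked <- rep(FALSE, nl)
    for (k in seq_len(substeps)) {
      active <- refr == 0L
      expterm <- params$g_L * params$Delta_T *
        exp(pmin((V - params$V_T) / params$Delta_T, 20))
      dV <- (-params$g_L * (V - params$E_L) -
               params$g_h * h * (V - params$E_h) + expterm + I) / params$C
      Vn <- V + dt * dV
      if (noisy) Vn <- Vn + nsd * stats::rnorm(nl)
      V <- ifelse(active, Vn, V)
      h <- h + dt * (h_inf(V, params) - h) / params$tau_h
      refr <- pmax(refr - 1L, 0L)
      fired <- active & (V >= params$V_peak)
      if (any(fired)) {
        spiked <- spiked | fired
        V[fired] <- params$V_reset
        refr[fired] <- refr_steps
      }
    }
    if (any(!is.finite(V)))
      stop("integration unstable (V diverged); reduce the sampling interval ",
           "or increase substeps", call. = FALSE)
    out[s, ] <- ifelse(spiked, params$V_peak, V)
    t_s <- (s - 1) / fs
    for (i in which(spiked)) spikes[[i]] <- c(spikes[[i]], t_s)
  }

  epochs <- list(pre = c(1L, n_pre + 1L),
                 step = c(n_pre + 1L, n_pre + n_step + 1L),
                 post = c(n_pre + n_step + 1L, n_tot + 1L))
  sweeps <- lapply(seq_len(nl), function(i)
    new_sweep(out[, i], fs, "membrane_potential", epochs,
              stimulus_level = levels[i]))
  rec <- current_step_recording(cell_id, sweeps, protocol, metadata)
  names(spikes) <- format(levels, trim = TRUE)
  attr(rec, "spike_times") <- spikes
  rec
}

#' Parameters of the synthetic sEPSC trace generator
#'
#' Events occur at Poisson times at `rate`; each adds an inward (negative)
#' biexponential kernel `a (exp(-t/tau_decay) - exp(-t/tau_rise)) / N` to the
#' holding current, where `N` normalizes the kernel peak to 1 and the peak
#' amplitude `a` is lognormal. The analytic charge of one event is
#' `a (tau_decay - tau_rise) / N` in fC (pA x ms).
#'
#' @param rate Event rate, Hz (>= 0).
#' @param amp_log_mu,amp_log_sigma Log-mean and log-SD of the peak amplitude
#'   in pA; the amplitude median is `exp(amp_log_mu)`.
#' @param tau_rise,tau_decay Kernel time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param noise_sd Additive white current noise SD, pA.
#' @param duration Recording length, s.
#' @param sampling_rate Hz.
#' @param baseline_pA Constant holding-current level, pA.
#' @param seed Integer seed.
#' @return A list of class `"epsc_gen_params"`.
#' @export
epsc_gen_params <- function(rate = 1, amp_log_mu = log(25),
                            amp_log_sigma = 0.25, tau_rise = 1,
                            tau_decay = 8, noise_sd = 1.5, duration = 200,
                            sampling_rate = 20000, baseline_pA = -30,
                            seed = 1L) {
  stopifnot(rate >= 0, tau_rise > 0, tau_decay > tau_rise, duration > 0,
            noise_sd >= 0, sampling_rate > 0)
  structure(list(rate = rate, amp_log_mu = amp_log_mu,
                 amp_log_sigma = amp_log_sigma, tau_rise = tau_rise,
                 tau_decay = tau_decay, noise_sd = noise_sd,
                 duration = duration, sampling_rate = sampling_rate,
                 baseline_pA = baseline_pA, seed = as.integer(seed)),
            class = "epsc_gen_params")
}

# peak time and peak-normalization of the biexponential kernel
epsc_kernel_norm <- function(tau_rise, tau_decay) {
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  N <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  list(t_peak = t_peak, N = N)
}

#' Analytic charge of one synthetic EPSC
#'
#' @param amplitude Peak amplitude, pA.
#' @param tau_rise,tau_decay Kernel time constants, ms.
#' @return Charge transfer in fC.
#' @export
epsc_kernel_charge <- function(amplitude, tau_rise, tau_decay) {
  amplitude * (tau_decay - tau_rise) /
    epsc_kernel_norm(tau_rise, tau_decay)$N
}

#' Simulate a voltage-clamp trace containing spontaneous EPSCs
#'
#' @param params An [epsc_gen_params()].
#' @return A `"voltage_clamp_recording"` with ground truth attached as
#'   attribute `"ground_truth"`: a `data.frame` with `onset_s`, `peak_s`,
#'   `amplitude_pA` and `area_fC` (analytic charge) per generated event.
#' @export
simulate_epsc_recording <- function(params) {
  if (params$rate * params$duration > 1e7)
    stop("rate x duration too large", call. = FALSE)
  set.seed(params$seed)
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  x <- rep(params$baseline_pA, n)
  n_ev <- stats::rpois(1, params$rate * params$duration)
  kn <- epsc_kernel_norm(params$tau_rise, params$tau_decay)
  truth <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude_pA = numeric(0), area_fC = numeric(0))
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, params$duration - 0.15))
    amps <- stats::rlnorm(n_ev, params$amp_log_mu, params$amp_log_sigma)
    len <- round(10 * params$tau_decay / 1000 * fs)
    t_ms <- (seq_len(len) - 1) * 1000 / fs
    kern <- (exp(-t_ms / params$tau_decay) - exp(-t_ms / params$tau_rise)) /
      kn$N
    for (i in seq_len(n_ev)) {
      i0 <- floor(onsets[i] * fs) + 1L
      i1 <- min(n, i0 + len - 1L)
      x[i0:i1] <- x[i0:i1] - amps[i] * kern[seq_len(i1 - i0 + 1L)]
    }
    truth <- data.frame(
      onset_s = (floor(onsets * fs)) / fs,
      peak_s = (floor(onsets * fs)) / fs + kn$t_peak / 1000,
      amplitude_pA = amps,
      area_fC = amps * (params$tau_decay - params$tau_rise) / kn$N)
  }
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
  trace <- new_sweep(x, fs, "clamp_current",
                     epochs = list(pre = c(1L, 1L), step = c(1L, n + 1L),
                                   post = c(n + 1L, n + 1L)),
                     stimulus_level = NA_real_)
  rec <- voltage_clamp_recording(trace, holding_potential = -70)
  attr(rec, "ground_truth") <- truth
  rec
}
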