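#' Reduced single-compartment neuron parameters
#'
#' Parameter set of the adaptive conductance-based leaky integrate-and-fire
#' model used for all three cell classes. The membrane equation is
#' `C dV/dt = -g_leak (V - E_L) - sum g_syn (V - E_rev) - (w_fast + g_KCa(Ca)) (V - E_K)`
#' with two spike-triggered adaptation variables: a fast AHP conductance
#' `w_fast` (incremented by `w_fast_jump` per spike, decaying with
#' `tau_fast`) standing in for the delayed-rectifier potassium current
#' ("KDR_analog"), and a calcium-gated potassium conductance
#' `g_KCa = g_kca_max * Ca/(Ca + k_half)` driven by a per-spike calcium
#' increment `ca_jump` decaying with `tau_ca` ("CAGK_analog"). The
#' interaction of the two — fast AHP pacing spikes at gamma intervals, slow
#' Ca-gated K terminating the burst and enforcing a theta-period silence —
#' produces the stutter-bursting phenotype of OLM cells near rheobase.
#'
#' @param c_m membrane capacitance (pF).
#' @param g_leak leak conductance (nS).
#' @param e_leak leak reversal (mV).
#' @param v_thresh spike threshold (mV).
#' @param v_reset post-spike reset (mV); must be below `v_thresh`.
#' @param refrac absolute refractory period (ms).
#' @param w_fast_jump fast AHP conductance increment per spike (nS).
#' @param tau_fast fast AHP decay time constant (ms), > 0.
#' @param e_k potassium reversal (mV) used by the potassium conductances.
#' @param g_kdr_tonic tonic (always-on) potassium conductance (nS), the
#'   subthreshold component of the delayed-rectifier analogue; it sets the
#'   resting potential and firing threshold and is removed together with the
#'   fast AHP by the `KDR_analog` knockout.
#' @param ca_jump dimensionless calcium increment per spike.
#' @param tau_ca calcium decay time constant (ms), > 0.
#' @param g_kca_max maximal Ca-gated K conductance (nS).
#' @param k_half calcium concentration of half-activation (dimensionless).
#' @param knockouts character vector, subset of
#'   `c("KDR_analog", "CAGK_analog")`; knocked-out conductances contribute
#'   zero current.
#' @return object of class `neuron_params`.
#' @seealso [neuron_defaults()], [apply_knockout()], [neuron_step()]
#' @export
neuron_params <- function(c_m, g_leak, e_leak, v_thresh, v_reset,
                          refrac = 2, w_fast_jump = 0, tau_fast = 50,
                          e_k = -90, g_kdr_tonic = 0, ca_jump = 0,
                          tau_ca = 200, g_kca_max = 0, k_half = 0.5,
                          knockouts = character()) {
  if (tau_fast <= 0 || tau_ca <= 0) stop("tau_fast and tau_ca must be > 0")
  if (g_leak < 0 || w_fast_jump < 0 || g_kca_max < 0 || g_kdr_tonic < 0)
    stop("conductances must be >= 0")
  if (v_reset >= v_thresh) stop("v_reset must be below v_thresh")
  bad <- setdiff(knockouts, c("KDR_analog", "CAGK_analog"))
  if (length(bad))
    stop("unknown knockout(s): ", paste(bad, collapse = ", "),
         "; valid names are KDR_analog, CAGK_analog")
  structure(list(c_m = c_m, g_leak = g_leak, e_leak = e_leak,
                 v_thresh = v_thresh, v_reset = v_reset, refrac = refrac,
                 w_fast_jump = w_fast_jump, tau_fast = tau_fast, e_k = e_k,
                 g_kdr_tonic = g_kdr_tonic,
                 ca_jump = ca_jump, tau_ca = tau_ca, g_kca_max = g_kca_max,
                 k_half = k_half, knockouts = unique(knockouts)),
            class = "neuron_params")
}

#' Default parameter sets for the three cell classes
#'
#' Calibrated so that the model phenotypes the circuit mechanism needs are
#' present: PYR fire regularly in the 10-30 Hz range under
#' Schaffer-collateral drive; PVBC are fast-spiking with negligible
#' adaptation and no bursting; OLM near rheobase stutter-fire bursts of
#' gamma-interval spikes recurring at theta intervals, and switch to tonic
#' gamma-interval firing far above rheobase.
#'
#' @param population one of `"PYR"`, `"OLM"`, `"PVBC"`.
#' @return a [neuron_params()].
#' @export
neuron_defaults <- function(population = c("PYR", "OLM", "PVBC")) {
  population <- match.arg(population)
  switch(population,
    PYR = neuron_params(c_m = 180, g_leak = 6, e_leak = -60,
                        v_thresh = -50, v_reset = -60, refrac = 2,
                        w_fast_jump = 0.5, tau_fast = 100),
    PVBC = neuron_params(c_m = 100, g_leak = 10, e_leak = -65,
                         v_thresh = -48, v_reset = -62, refrac = 1.5,
                         w_fast_jump = 0.6, tau_fast = 15),
    OLM = neuron_params(c_m = 80, g_leak = 4, e_leak = -60,
                        v_thresh = -47, v_reset = -56, refrac = 2,
                        w_fast_jump = 1.2, tau_fast = 15,
                        ca_jump = 0.12, tau_ca = 220,
                        g_kca_max = 5, k_half = 1.2)
  )
}

#' Fresh neuron state
#'
#' @param params a [neuron_params()]; the membrane starts at the leak
#'   reversal with both adaptation variables at zero.
#' @return object of class `neuron_state` with fields `v`, `w_fast`, `ca`,
#'   `t_last_spike`.
#' @export
neuron_state <- function(params) {
  structure(list(v = params$e_leak, w_fast = 0, ca = 0,
                 t_last_spike = -Inf), class = "neuron_state")
}

#' Advance a neuron by one time step
#'
#' Exponential-Euler update of the membrane potential under the instantaneous
#' total conductance, followed by exponential decay of the adaptation
#' variables. On threshold crossing the cell spikes, the membrane is reset,
#' `w_fast` and `ca` jump, and the membrane is clamped at `v_reset` for the
#' refractory period. Knocked-out conductances contribute zero current.
#'
#' This R stepper defines the model; the network simulator implements the
#' identical update in compiled code (see tests for the equivalence check).
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param syn_conductances list of `c(g, e_rev)` pairs (nS, mV), or a 2-column
#'   matrix; may be empty.
#' @param dt time step (ms), in (0, 0.1].
#' @param t current time (ms), used for refractory bookkeeping.
#' @return list with `state` (updated) and `spiked` (logical).
#' @export
neuron_step <- function(state, params, syn_conductances = list(), dt, t = 0) {
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] ms")
  if (!all(is.finite(c(state$v, state$w_fast, state$ca))))
    stop("non-finite neuron state at t = ", t)
  w <- state$w_fast * exp(-dt / params$tau_fast)
  ca <- state$ca * exp(-dt / params$tau_ca)
  g_w <- if ("KDR_analog" %in% params$knockouts) 0 else
    w + params$g_kdr_tonic
  g_kca <- if ("CAGK_analog" %in% params$knockouts) 0 else
    params$g_kca_max * ca / (ca + params$k_half)
  g_ad <- g_w + g_kca
  gt <- params$g_leak + g_ad
  num <- params$g_leak * params$e_leak + g_ad * params$e_k
  if (length(syn_conductances)) {
    m <- do.call(rbind, lapply(syn_conductances, function(x) x[1:2]))
    gt <- gt + sum(m[, 1])
    num <- num + sum(m[, 1] * m[, 2])
  }
  vinf <- num / gt
  v <- vinf + (state$v - vinf) * exp(-gt * dt / params$c_m)
  t1 <- t + dt
  spiked <- FALSE
  if (t1 < state$t_last_spike + params$refrac) {
    v <- params$v_reset
  } else if (v >= params$v_thresh) {
    spiked <- TRUE
    v <- params$v_reset
    w <- w + params$w_fast_jump
    ca <- ca + params$ca_jump
    state$t_last_spike <- t1
  }
  state$v <- v
  state$w_fast <- w
  state$ca <- ca
  list(state = state, spiked = spiked)
}

#' Knock out an adaptation conductance
#'
#' Returns the parameter set with the named channel's current zeroed;
#' idempotent. `KDR_analog` removes the fast AHP conductance and
#' `CAGK_analog` the Ca-gated K conductance (the reduced-model analogue of
#' zeroing a maximal channel conductance; a calcium-channel knock-out
#' collapses onto `CAGK_analog` in this model since calcium enters only
#' through the per-spike increment).
#'
#' @param params a [neuron_params()].
#' @param channel `"KDR_analog"` or `"CAGK_analog"`.
#' @return modified `neuron_params`.
#' @export
apply_knockout <- function(params, channel) {
  valid <- c("KDR_analog", "CAGK_analog")
  if (!channel %in% valid)
    stop("unknown channel '", channel, "'; valid names: ",
         paste(valid, collapse = ", "))
  params$knockouts <- unique(c(params$knockouts, channel))
  params
}

#' Single-cell drive sweep: f-I curve and ISI statistics
#'
#' Drives an isolated neuron with Poisson excitatory conductance input
#' (mimicking Schaffer-collateral-like drive) at each level of a sweep and
#' tabulates the mean firing rate, the coefficient of variation of the
#' inter-spike intervals, and a burstiness index: the fraction of ISIs
#' shorter than `burst_isi` ms whose neighbouring ISI exceeds `silence_isi`
#' ms. Used to document that the OLM stutter-burst phenotype and the PVBC
#' non-bursting phenotype hold.
#'
#' @param params a [neuron_params()].
#' @param drives numeric vector of drive levels: number of independent 34 Hz
#'   Poisson processes, each delivering `g_unit` nS AMPA-like events.
#' @param duration simulated time per level (ms).
#' @param g_unit unit conductance per event (nS).
#' @param tau_syn synaptic decay (ms).
#' @param slow_ratio,tau_slow optional NMDA-like slow conductance component.
#' @param seed integer seed.
#' @param burst_isi,silence_isi ms thresholds defining the burstiness index.
#' @return data.frame with columns `drive`, `rate_hz`, `isi_cv`, `burstiness`.
#' @export
calibrate_report <- function(params, drives, duration = 5000, g_unit = 0.6,
                             tau_syn = 3, slow_ratio = 0, tau_slow = 148.5,
                             seed = 1,
                             burst_isi = 60, silence_isi = 120) {
  if (!length(drives)) stop("drive sweep must be nonempty")
  out <- lapply(seq_along(drives), function(i) {
    spk <- single_cell_sim(params, n_proc = drives[i], duration = duration,
                           g_unit = g_unit, tau_syn = tau_syn,
                           slow_ratio = slow_ratio, tau_slow = tau_slow,
                           seed = seed + i - 1)
    isi <- diff(spk)
    burst <- NA_real_
    if (length(isi) >= 3) {
      short <- isi < burst_isi
      nb_long <- c(FALSE, isi[-length(isi)] > silence_isi) |
        c(isi[-1] > silence_isi, FALSE)
      burst <- if (any(short)) mean(short & nb_long) else 0
    }
    data.frame(drive = drives[i], rate_hz = length(spk) / duration * 1000,
               isi_cv = if (length(isi) >= 3) stats::sd(isi) / mean(isi)
                        else NA_real_,
               burstiness = burst)
  })
  do.call(rbind, out)
}

#' Simulate one neuron under Poisson conductance drive
#'
#' Thin wrapper over the compiled network core with a single cell and
#' `n_proc` independent 34 Hz Poisson drive processes (no short-term
#' plasticity), the configuration used for single-cell calibration.
#'
#' @inheritParams calibrate_report
#' @param n_proc number of Poisson processes.
#' @param rate_hz rate of each process (Hz).
#' @param slow_ratio,tau_slow optional NMDA-like slow component.
#' @param dt integration step (ms).
#' @return numeric vector of spike times (ms).
#' @export
single_cell_sim <- function(params, n_proc, duration = 5000, g_unit = 0.6,
                            tau_syn = 3, rate_hz = 34, slow_ratio = 0,
                            tau_slow = 148.5, dt = 0.05, seed = 1) {
  eff <- .effective_neuron(params)
  n_steps <- as.integer(round(duration / dt))
  chan_tau <- c(tau_syn, tau_slow)
  chan_erev <- c(0, 0)
  n_proc <- as.integer(n_proc)
  empty_i <- integer(0); empty_n <- numeric(0)
  res <- .sim_core(1L,
    eff$c_m, eff$g_leak, eff$e_leak, eff$v_thresh, eff$v_reset, eff$refrac,
    eff$w_fast_jump, eff$tau_fast, eff$e_k, eff$g_kdr_tonic, eff$ca_jump,
    eff$tau_ca, eff$g_kca_max, eff$k_half, eff$e_leak,
    chan_tau, chan_erev,
    empty_i, empty_i, empty_n, empty_n, empty_n, empty_n,
    empty_i, empty_i, empty_n, empty_i, empty_i, empty_i,
    0L, 0L, empty_i,
    drv_post = rep(0L, n_proc), drv_rate = rep(rate_hz, n_proc),
    drv_gpeak = rep(g_unit, n_proc), drv_chan_fast = rep(0L, n_proc),
    drv_chan_slow = rep(if (slow_ratio > 0) 1L else -1L, n_proc),
    drv_slow_ratio = rep(slow_ratio, n_proc),
    drv_syn_start = as.integer(seq(0L, by = 1L, length.out = n_proc)),
    drv_syn_count = rep(1L, n_proc),
    drv_syn_delay_steps = rep(10L, n_proc),
    dt = dt, n_steps = n_steps, seed = seed,
    record_cells = integer(0), record_stride = 1L)
  res$time
}

# fold knockouts into effective conductance parameters (vectors of length 1)
.effective_neuron <- function(params) {
  p <- params
  if ("KDR_analog" %in% p$knockouts) {
    p$w_fast_jump <- 0
    p$g_kdr_tonic <- 0
  }
  if ("CAGK_analog" %in% p$knockouts) p$g_kca_max <- 0
  p
}
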