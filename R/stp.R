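#' Tsodyks-Markram synapse parameters
#'
#' Constructs the parameter set of an event-driven Tsodyks-Markram (TM)
#' facilitating/depressing synapse together with its conductance-kernel and
#' wiring attributes. The TM pair (utilization `u`, resources `R`) evolves only
#' at presynaptic events: between events `u` relaxes to 0 with time constant
#' `F` and `R` recovers to 1 with time constant `D`; at an event `u` is
#' incremented by `U*(1-u)` and the released fraction is `u*R`, after which
#' `R` is depleted by the factor `(1-u)`. The first event of a quiescent
#' synapse therefore releases exactly `U`.
#'
#' @param U baseline utilization, in (0, 1].
#' @param F facilitation time constant (ms); 0 disables facilitation
#'   (`u` is pinned at `U`).
#' @param D depression recovery time constant (ms); 0 disables depression
#'   (`R` is pinned at 1).
#' @param tau_rise conductance rise time constant (ms); 0 gives an
#'   instantaneous-rise single-exponential kernel.
#' @param tau_decay_fast fast conductance decay time constant (ms),
#'   AMPA- or GABA-like.
#' @param tau_decay_slow slow decay time constant (ms), NMDA-like; 0 means no
#'   slow component.
#' @param slow_ratio slow:fast peak conductance ratio (dimensionless).
#' @param g_range length-2 numeric, `[g_min, g_max]` peak conductance in nS;
#'   one value per connection is drawn uniformly from this range at build time.
#' @param e_rev synaptic reversal potential (mV).
#' @param delay_range length-2 numeric, `[d_min, d_max]` axonal+synaptic delay
#'   in ms; one value per synaptic contact is drawn uniformly at build time.
#' @return object of class `tm_params`.
#' @seealso [tm_apply_spike()], [tm_periodic_steady_state()],
#'   [conductance_trace()], [synapse_registry()]
#' @export
tm_params <- function(U, F = 0, D = 0, tau_rise = 0,
                      tau_decay_fast = 2, tau_decay_slow = 0, slow_ratio = 0,
                      g_range = c(1, 1), e_rev = 0,
                      delay_range = c(0.5, 2)) {
  stopifnot(length(g_range) == 2, length(delay_range) == 2)
  if (!(U > 0 && U <= 1)) stop("U must satisfy 0 < U <= 1, got ", U)
  if (F < 0) stop("F must be >= 0, got ", F)
  if (D < 0) stop("D must be >= 0, got ", D)
  if (tau_rise < 0 || tau_decay_fast < 0 || tau_decay_slow < 0)
    stop("kinetic time constants must be >= 0")
  if (g_range[1] > g_range[2]) stop("g_range must satisfy g_min <= g_max")
  if (delay_range[1] > delay_range[2]) stop("delay_range must satisfy d_min <= d_max")
  structure(list(U = U, F = F, D = D, tau_rise = tau_rise,
                 tau_decay_fast = tau_decay_fast,
                 tau_decay_slow = tau_decay_slow, slow_ratio = slow_ratio,
                 g_range = as.numeric(g_range), e_rev = e_rev,
                 delay_range = as.numeric(delay_range)),
            class = "tm_params")
}

#' Fresh TM state
#'
#' @return object of class `tm_state` with `u = 0`, `R = 1` and no previous
#'   event, so that the first spike releases exactly `U`.
#' @export
tm_state <- function() {
  structure(list(u = 0, R = 1, t_last = NA_real_), class = "tm_state")
}

#' Apply one presynaptic spike to a TM synapse
#'
#' Decay-then-increment convention: with `dt = t - t_last`, utilization decays
#' (`u <- u*exp(-dt/F)`, or `u = U` exactly when `F = 0`), is incremented
#' (`u <- u + U*(1-u)`), resources recover
#' (`R <- 1 - (1-R)*exp(-dt/D)`, or `R = 1` when `D = 0`), the released
#' fraction is `u*R`, and resources are then depleted (`R <- R*(1-u)`).
#'
#' The conductance event amplitude associated with a release is
#' `g_peak * release / U`, so an unfacilitated, undepressed first event has
#' amplitude exactly `g_peak`.
#'
#' @param state a [tm_state()].
#' @param params a [tm_params()].
#' @param t event time in ms; must not precede the previous event.
#' @return list with elements `state` (updated `tm_state`) and `release`
#'   (fraction in `[0, 1]`).
#' @export
tm_apply_spike <- function(state, params, t) {
  stopifnot(inherits(state, "tm_state"), inherits(params, "tm_params"))
  if (!is.na(state$t_last) && t < state$t_last)
    stop("event time ", t, " precedes previous event at ", state$t_last)
  if (is.na(state$t_last)) {
    u <- params$U
    R <- 1
  } else {
    dt <- t - state$t_last
    u <- if (params$F > 0) state$u * exp(-dt / params$F) else 0
    u <- u + params$U * (1 - u)
    if (params$F == 0) u <- params$U
    R <- if (params$D > 0) 1 - (1 - state$R) * exp(-dt / params$D) else 1
  }
  release <- u * R
  state$u <- u
  state$R <- R * (1 - u)
  state$t_last <- t
  list(state = state, release = release)
}

#' Release fractions over a spike train
#'
#' Convenience wrapper iterating [tm_apply_spike()] over a sorted vector of
#' presynaptic spike times.
#'
#' @param params a [tm_params()].
#' @param times numeric vector of spike times (ms), nondecreasing.
#' @return numeric vector of released fractions, one per spike.
#' @export
tm_release_train <- function(params, times) {
  if (is.unsorted(times)) stop("spike times must be nondecreasing")
  st <- tm_state()
  rel <- numeric(length(times))
  for (i in seq_along(times)) {
    res <- tm_apply_spike(st, params, times[i])
    st <- res$state
    rel[i] <- res$release
  }
  rel
}

#' Steady-state TM release under a periodic train
#'
#' Fixed point of the [tm_apply_spike()] recursion under a periodic
#' presynaptic train with inter-spike interval `isi`. Both state variables
#' admit closed forms: with `f = exp(-isi/F)` (0 when `F = 0`) and
#' `d = exp(-isi/D)` (0 when `D = 0`),
#' `u* = U / (1 - (1-U) f)` and the pre-release resource level is
#' `R* = (1 - d) / (1 - (1 - u*) d)`, giving steady release `u* R*`.
#' For `F = 0` this reduces to `R* = (1 - d)/(1 - (1-U) d)`, `release = U R*`.
#'
#' @param params a [tm_params()].
#' @param isi inter-spike interval in ms, > 0.
#' @return list with `release`, `u`, and `R_pre` (resource level at spike
#'   time, before depletion).
#' @export
tm_periodic_steady_state <- function(params, isi) {
  stopifnot(inherits(params, "tm_params"))
  if (isi <= 0) stop("isi must be > 0, got ", isi)
  f <- if (params$F > 0) exp(-isi / params$F) else 0
  d <- if (params$D > 0) exp(-isi / params$D) else 0
  u_star <- params$U / (1 - (1 - params$U) * f)
  R_pre <- (1 - d) / (1 - (1 - u_star) * d)
  list(release = u_star * R_pre, u = u_star, R_pre = R_pre)
}

#' Superposed conductance trace from timed events
#'
#' Sums, over events `(time, amplitude)`, peak-normalized conductance kernels
#' evaluated on a time grid. The kernel is a single exponential decay with
#' instantaneous rise when `tau_rise = 0`, otherwise a difference of
#' exponentials rescaled to peak 1. A slow component scaled by
#' `params$slow_ratio` is added when `tau_decay_slow > 0`. Kernels start at
#' `event time + delay`; superposition is linear.
#'
#' @param events data.frame or matrix with columns `time` (ms) and
#'   `amplitude` (nS); may be empty.
#' @param params a [tm_params()].
#' @param grid numeric time grid (ms), monotone increasing.
#' @param delay scalar synaptic delay (ms) added to every event time; defaults
#'   to the lower end of `params$delay_range`.
#' @return numeric vector of conductance (nS) on `grid`.
#' @export
conductance_trace <- function(events, params, grid,
                              delay = params$delay_range[1]) {
  stopifnot(inherits(params, "tm_params"))
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be monotone increasing")
  g <- numeric(length(grid))
  if (NROW(events) == 0) return(g)
  events <- as.data.frame(events)
  stopifnot(all(c("time", "amplitude") %in% names(events)))
  for (i in seq_len(nrow(events))) {
    t0 <- events$time[i] + delay
    a <- events$amplitude[i]
    s <- grid >= t0
    if (!any(s)) next
    tt <- grid[s] - t0
    g[s] <- g[s] + a * .syn_kernel(tt, params$tau_rise, params$tau_decay_fast)
    if (params$tau_decay_slow > 0 && params$slow_ratio != 0)
      g[s] <- g[s] + a * params$slow_ratio *
        .syn_kernel(tt, params$tau_rise, params$tau_decay_slow)
  }
  g
}

# peak-normalized kernel on t >= 0
.syn_kernel <- function(t, tau_rise, tau_decay) {
  if (tau_rise <= 0) return(exp(-t / tau_decay))
  if (tau_rise >= tau_decay) stop("tau_rise must be < tau_decay")
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak
}

#' Registry of default synaptic parameter sets
#'
#' Named TM parameter sets for every projection in the microcircuit, with the
#' short-term plasticity constants, conductance kinetics, conductance ranges
#' and delays used by the network builder. PYR->OLM synapses are slowly
#' facilitating (U 0.07, F 470 ms, D 38 ms), PYR->PVBC rapidly depressing
#' (U 0.32, F 0, D 110 ms), OLM->PYR strongly depressing (U 0.3, F 6 ms,
#' D 1770 ms, GABA decay 18 ms), PVBC->PYR strongly depressing (U 0.16,
#' F 8.6 ms, D 965 ms, GABA decay 5.94 ms). PYR->PYR and PVBC->PVBC constants
#' are not published for this circuit, so they default to static synapses
#' (no STP); Schaffer-collateral inputs are likewise static with AMPA decay
#' 3 ms, NMDA decay 148.5 ms and NMDA ratio 1.22.
#'
#' @return named list of [tm_params()]: `PYR_OLM`, `PYR_PVBC`, `OLM_PYR`,
#'   `PVBC_PYR`, `PYR_PYR`, `PVBC_PVBC`, `SC_PYR`.
#' @export
synapse_registry <- function() {
  list(
    PYR_OLM = tm_params(U = 0.07, F = 470, D = 38,
                        tau_decay_fast = 1.7, tau_decay_slow = 148.5,
                        slow_ratio = 0.28, g_range = c(0.2, 0.4), e_rev = 0),
    PYR_PVBC = tm_params(U = 0.32, F = 0, D = 110,
                         tau_decay_fast = 4.12, tau_decay_slow = 298.75,
                         slow_ratio = 0.28, g_range = c(0.3, 0.7), e_rev = 0),
    OLM_PYR = tm_params(U = 0.3, F = 6, D = 1770,
                        tau_decay_fast = 18, g_range = c(1, 1.4), e_rev = -80),
    PVBC_PYR = tm_params(U = 0.16, F = 8.6, D = 965,
                         tau_decay_fast = 5.94, g_range = c(1, 1.2), e_rev = -80),
    PYR_PYR = tm_params(U = 1, F = 0, D = 0,
                        tau_decay_fast = 3, tau_decay_slow = 148.5,
                        slow_ratio = 1.22, g_range = c(0.5, 0.7), e_rev = 0),
    PVBC_PVBC = tm_params(U = 1, F = 0, D = 0,
                          tau_decay_fast = 5.94, g_range = c(4.2, 4.8),
                          e_rev = -80),
    SC_PYR = tm_params(U = 1, F = 0, D = 0,
                       tau_decay_fast = 3, tau_decay_slow = 148.5,
                       slow_ratio = 1.22, g_range = c(0.55, 0.65), e_rev = 0)
  )
}
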