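#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every generator in the package is seed-deterministic
#' without clobbering global state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic phase-amplitude coupled signal
#'
#' @param f_phase slow (phase) frequency in Hz.
#' @param f_amp fast (amplitude) frequency in Hz; must satisfy
#'   `f_phase < f_amp < fs/2`.
#' @param depth modulation depth in `[0, 1]`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param fs sampling rate (Hz).
#' @param duration duration in seconds; `duration * fs` must be integral.
#' @param seed integer seed.
#' @return object of class `pac_signal_spec`.
#' @export
pac_signal_spec <- function(f_phase, f_amp, depth = 1, noise_sd = 0,
                            fs = 500, duration = 60, seed = 1) {
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1], got ", depth)
  if (!(f_phase < f_amp)) stop("f_phase must be below f_amp")
  if (!(f_amp < fs / 2)) stop("f_amp must be below the Nyquist frequency")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) stop("duration * fs must be an integer sample count")
  structure(list(f_phase = f_phase, f_amp = f_amp, depth = depth,
                 noise_sd = noise_sd, fs = fs, duration = duration,
                 seed = as.integer(seed)),
            class = "pac_signal_spec")
}

#' Generate a theta-modulated gamma signal
#'
#' Returns the sampled signal
#' `x(t) = sin(2 pi f_phase t) +
#'   [1 - depth + depth (1 + sin(2 pi f_phase t))/2] sin(2 pi f_amp t) + e(t)`
#' with `e ~ N(0, noise_sd^2)`. The fast component's amplitude is a linear
#' function of the slow sinusoid, so the GLM comodulogram estimator has an
#' analytically predictable optimum at `(f_phase, f_amp)`; `depth = 0`
#' switches the coupling off entirely.
#'
#' @param spec a [pac_signal_spec()].
#' @return numeric vector of `duration * fs` samples, with attribute `fs`.
#' @export
gen_pac_signal <- function(spec) {
  stopifnot(inherits(spec, "pac_signal_spec"))
  n <- round(spec$duration * spec$fs)
  t <- seq(0, n - 1) / spec$fs
  slow <- sin(2 * pi * spec$f_phase * t)
  env <- 1 - spec$depth + spec$depth * (1 + slow) / 2
  x <- slow + env * sin(2 * pi * spec$f_amp * t)
  if (spec$noise_sd > 0)
    x <- x + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  attr(x, "fs") <- spec$fs
  x
}

#' Specification of stutter-bursting spike trains
#'
#' @param n_cells number of cells.
#' @param theta_f burst (theta) frequency in Hz.
#' @param gamma_f intra-burst (gamma) frequency in Hz; must exceed `theta_f`.
#' @param spikes_per_burst mean spikes per burst (Poisson count per cycle).
#' @param inter_burst_silence silent fraction of each theta cycle, in
#'   `[0, 1)`.
#' @param jitter_sd Gaussian jitter of spike times (ms).
#' @param duration duration in ms.
#' @param seed integer seed.
#' @return object of class `burst_spikes_spec`.
#' @export
burst_spikes_spec <- function(n_cells, theta_f = 5, gamma_f = 25,
                              spikes_per_burst = 2.5,
                              inter_burst_silence = 0.5, jitter_sd = 2,
                              duration = 60000, seed = 1) {
  if (n_cells < 0 || theta_f < 0 || gamma_f < 0 || spikes_per_burst < 0 ||
      jitter_sd < 0 || duration < 0)
    stop("rates, counts and durations must be nonnegative")
  if (gamma_f <= theta_f) stop("gamma_f must exceed theta_f")
  if (inter_burst_silence < 0 || inter_burst_silence >= 1)
    stop("inter_burst_silence must be in [0, 1)")
  structure(list(n_cells = as.integer(n_cells), theta_f = theta_f,
                 gamma_f = gamma_f, spikes_per_burst = spikes_per_burst,
                 inter_burst_silence = inter_burst_silence,
                 jitter_sd = jitter_sd, duration = duration,
                 seed = as.integer(seed)),
            class = "burst_spikes_spec")
}

#' Generate theta-nested gamma burst spike trains
#'
#' All cells share the theta envelope (cycle boundaries at multiples of
#' `1/theta_f`); within each cycle's active window — the first
#' `1 - inter_burst_silence` fraction — each cell independently draws a
#' Poisson(`spikes_per_burst`) spike count, truncated to the window's
#' gamma-beat capacity `1 + floor(active_ms * gamma_f / 1000)`, and places
#' the spikes at consecutive gamma-period beats from the window start,
#' jittered by `N(0, jitter_sd^2)` ms. Mean rate per cell is therefore
#' analytically `theta_f * E[min(N, capacity)]` Hz with
#' `N ~ Poisson(spikes_per_burst)`, intra-burst inter-spike intervals
#' concentrate at `1000/gamma_f` ms, and the population rate carries
#' spectral peaks at both frequencies.
#'
#' @param spec a [burst_spikes_spec()].
#' @return a [spike_table()] with population label `"SYN"`.
#' @export
gen_burst_spikes <- function(spec) {
  stopifnot(inherits(spec, "burst_spikes_spec"))
  empty <- spike_table(character(), integer(), numeric(),
                       n_cells = c(SYN = spec$n_cells),
                       duration = spec$duration)
  if (spec$n_cells == 0 || spec$duration == 0) return(empty)
  theta_period <- 1000 / spec$theta_f
  gamma_period <- 1000 / spec$gamma_f
  active_ms <- (1 - spec$inter_burst_silence) * theta_period
  capacity <- max(1, 1 + floor(active_ms / gamma_period))
  n_cycles <- ceiling(spec$duration / theta_period)
  with_seed(spec$seed, {
    cell <- integer(0); tms <- numeric(0)
    for (ci in seq_len(spec$n_cells)) {
      counts <- pmin(stats::rpois(n_cycles, spec$spikes_per_burst), capacity)
      tot <- sum(counts)
      if (tot == 0) next
      cyc <- rep(seq_len(n_cycles) - 1, counts)
      k <- sequence(counts[counts > 0]) - 1
      tt <- cyc * theta_period + k * gamma_period
      if (spec$jitter_sd > 0) tt <- tt + stats::rnorm(tot, 0, spec$jitter_sd)
      ok <- tt >= 0 & tt <= spec$duration
      cell <- c(cell, rep.int(ci, sum(ok)))
      tms <- c(tms, tt[ok])
    }
    o <- order(tms)
    spike_table(rep("SYN", length(tms)), cell[o], tms[o],
                n_cells = c(SYN = spec$n_cells), duration = spec$duration)
  })
}

#' Specification of covarying band-power series
#'
#' @param n_windows number of time windows (>= 3).
#' @param rho target correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return object of class `covarying_power_spec`.
#' @export
covarying_power_spec <- function(n_windows, rho, seed = 1) {
  if (abs(rho) > 1) stop("|rho| must be <= 1, got ", rho)
  if (n_windows < 3) stop("n_windows must be >= 3")
  structure(list(n_windows = as.integer(n_windows), rho = rho,
                 seed = as.integer(seed)),
            class = "covarying_power_spec")
}

#' Generate a correlated pair of standardized power series
#'
#' Bivariate-normal construction: `theta = z1`,
#' `gamma = rho z1 + sqrt(1 - rho^2) z2` with independent standard normal
#' `z1, z2`, so both series have population mean 0, variance 1 and
#' population correlation exactly `rho`.
#'
#' @param spec a [covarying_power_spec()].
#' @return list with numeric vectors `theta` and `gamma`.
#' @export
gen_covarying_powers <- function(spec) {
  stopifnot(inherits(spec, "covarying_power_spec"))
  with_seed(spec$seed, {
    z1 <- stats::rnorm(spec$n_windows)
    z2 <- stats::rnorm(spec$n_windows)
    list(theta = z1,
         gamma = spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
  })
}
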