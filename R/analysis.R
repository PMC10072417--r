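#' Population rate series from a spike table
#'
#' Converts spikes of one population into a firing-rate time series using
#' fixed-width bins (default 4 ms), after removing the initial equilibration
#' window. Rates are in Hz per cell: counts divided by
#' `bin_width/1000 * n_cells`.
#'
#' @param spikes a [spike_table()].
#' @param population population label present in the table (or declared in
#'   its metadata).
#' @param bin_width bin width in ms, > 0.
#' @param discard initial window to drop (ms).
#' @param duration total duration (ms); defaults to the table's metadata.
#' @param n_cells number of cells in the population; defaults to the table's
#'   metadata (falling back to the largest cell id seen).
#' @return object of class `rate_series`: list with `values` (Hz),
#'   `bin_width` (ms), `t0` (ms).
#' @export
bin_rates <- function(spikes, population, bin_width = 4, discard = 2000,
                      duration = NULL, n_cells = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  pops <- attr(spikes, "n_cells")
  known <- union(names(pops), unique(spikes$population))
  if (!population %in% known)
    stop("unknown population '", population, "'; table contains: ",
         paste(known, collapse = ", "))
  if (is.null(duration)) duration <- attr(spikes, "duration")
  if (is.null(duration))
    duration <- if (nrow(spikes)) max(spikes$time_ms) else discard
  if (is.null(n_cells)) n_cells <- unname(pops[population])
  sel <- spikes$population == population
  if (is.null(n_cells) || is.na(n_cells))
    n_cells <- if (any(sel)) max(spikes$cell_id[sel]) else 1L
  n_bins <- ceiling((duration - discard) / bin_width)
  if (n_bins < 1) stop("discard must leave a nonempty analysis window")
  t <- spikes$time_ms[sel]
  t <- t[t > discard & t <= duration]
  idx <- ceiling((t - discard) / bin_width)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(values = counts / (bin_width / 1000 * n_cells),
                 bin_width = bin_width, t0 = discard),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("rate_series:", length(x$values), "bins of", x$bin_width,
      "ms from t0 =", x$t0, "ms; mean", round(mean(x$values), 2), "Hz\n")
  invisible(x)
}

.rs_fs <- function(rate) 1000 / rate$bin_width

# coerce a rate_series or a plain numeric (+ fs) to (values, fs)
.as_signal <- function(x, fs = NULL) {
  if (inherits(x, "rate_series")) return(list(x = x$values, fs = .rs_fs(x)))
  if (is.null(fs)) stop("fs must be supplied for a plain numeric series")
  list(x = as.numeric(x), fs = fs)
}

#' Welch power spectral density of a rate series
#'
#' Averaged-periodogram spectral estimate with a Hann taper, 50% segment
#' overlap and per-segment mean removal, followed by a `smooth_points`-point
#' moving average of the power values (each point averaged with its
#' neighbours to the right, truncated at the end).
#'
#' @param rate a `rate_series`, or plain numeric with `fs` given.
#' @param window_ms segment length in ms (default 2048).
#' @param smooth_points moving-average length for power smoothing
#'   (default 2; 1 disables).
#' @param fs sampling rate in Hz when `rate` is a plain numeric.
#' @return object of class `psd`: list with `freqs` (Hz), `power`, `params`.
#' @export
welch_psd <- function(rate, window_ms = 2048, smooth_points = 2, fs = NULL) {
  s <- .as_signal(rate, fs)
  nperseg <- round(window_ms / 1000 * s$fs)
  n <- length(s$x)
  if (n < nperseg)
    stop("series length ", n, " is shorter than the ", nperseg,
         "-sample window")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  nfreq <- floor(nperseg / 2) + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- s$x[s0:(s0 + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  scale <- 1 / (s$fs * sum(win^2) * length(starts))
  p <- acc * scale
  if (nfreq > 2) p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
  if (smooth_points > 1) p <- .forward_ma(p, smooth_points)
  structure(list(freqs = seq(0, nfreq - 1) * s$fs / nperseg, power = p,
                 params = list(window = "hann", window_ms = window_ms,
                               nperseg = nperseg,
                               smooth_points = smooth_points)),
            class = "psd")
}

# k-point forward moving average, truncated at the series end
.forward_ma <- function(p, k) {
  n <- length(p)
  vapply(seq_len(n), function(i) mean(p[i:min(n, i + k - 1)]), numeric(1))
}

#' Peak frequency and strength within a band
#'
#' Frequency and power of the maximum of a PSD inside a closed band, with the
#' strength returned both raw and log10-transformed.
#'
#' @param psd a [welch_psd()] result.
#' @param band length-2 numeric `[f_lo, f_hi]` in Hz, closed interval.
#' @return list with `peak_freq`, `strength`, `log_strength`.
#' @export
peak_in_band <- function(psd, band) {
  stopifnot(length(band) == 2)
  if (band[1] > band[2]) stop("band must satisfy f_lo <= f_hi")
  sel <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  if (!length(sel)) stop("band [", band[1], ", ", band[2],
                         "] contains no frequency bins")
  i <- sel[which.max(psd$power[sel])]
  list(peak_freq = psd$freqs[i], strength = psd$power[i],
       log_strength = log10(psd$power[i]))
}

# zero-phase FFT-domain band-pass with cosine-tapered edges
.fft_bandpass <- function(x, fs, f_lo, f_hi, taper_frac = 0.25) {
  n <- length(x)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  bw <- f_hi - f_lo
  tp <- max(1e-9, taper_frac * bw)
  lo <- max(f_lo, 0)
  h <- numeric(n)
  pass <- f >= lo & f <= f_hi
  h[pass] <- 1
  rise <- f >= lo - tp & f < lo
  h[rise] <- 0.5 + 0.5 * cos(pi * (lo - f[rise]) / tp)
  fall <- f > f_hi & f <= f_hi + tp
  h[fall] <- 0.5 + 0.5 * cos(pi * (f[fall] - f_hi) / tp)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

# analytic signal via the frequency-domain Hilbert construction
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# R^2 of A ~ b0 + b1 cos(phi) + b2 sin(phi), via the 3x3 normal equations
.pac_r2 <- function(A, cph, sph) {
  n <- length(A)
  X <- cbind(1, cph, sph)
  XtX <- crossprod(X)
  XtY <- crossprod(X, A)
  beta <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  if (is.null(beta)) return(0)
  fit <- X %*% beta
  sst <- sum((A - mean(A))^2)
  if (sst <= 0) return(0)
  ssr <- sum((fit - mean(A))^2)
  max(0, min(1, ssr / sst))
}

#' Phase-amplitude coupling comodulogram
#'
#' For each pair of a phase frequency `f_theta` and an amplitude frequency
#' `f_gamma`, the series is band-passed around `f_theta` (half-width
#' `phase_hw` Hz) and its instantaneous phase `phi(t)` extracted from the
#' analytic signal, band-passed around `f_gamma` (half-width
#' `max(amp_hw_min, f_theta)` Hz, wide enough to pass the coupling
#' sidebands) and its amplitude envelope `A(t)` extracted, and the coupling
#' measured as the coefficient of determination of the regression
#' `A ~ b0 + b1 cos(phi) + b2 sin(phi)` — a GLM-style estimator bounded in
#' `[0, 1]`.
#'
#' @param x a `rate_series`, or plain numeric with `fs`.
#' @param phase_freqs phase (slow) frequency grid in Hz.
#' @param amp_freqs amplitude (fast) frequency grid in Hz.
#' @param fs sampling rate (Hz) for plain numeric input.
#' @param phase_hw phase band half-width (Hz).
#' @param amp_hw_min minimum amplitude band half-width (Hz).
#' @return object of class `comodulogram`: list with `phase_freqs`,
#'   `amp_freqs`, and `pac` matrix (`length(phase_freqs)` x
#'   `length(amp_freqs)`).
#' @export
comodulogram <- function(x, phase_freqs = seq(1, 12, by = 0.5),
                         amp_freqs = seq(12, 50, by = 1), fs = NULL,
                         phase_hw = 1, amp_hw_min = 4) {
  s <- .as_signal(x, fs)
  nyq <- s$fs / 2
  if (max(amp_freqs) + max(amp_hw_min, max(phase_freqs)) >= nyq)
    stop("amplitude band overlaps the Nyquist frequency ", nyq, " Hz")
  n <- length(s$x)
  if (n < 4 * s$fs / min(phase_freqs))
    stop("series too short to resolve the slowest phase frequency")
  pac <- matrix(0, length(phase_freqs), length(amp_freqs))
  amp_cache <- new.env(parent = emptyenv())
  for (i in seq_along(phase_freqs)) {
    fp <- phase_freqs[i]
    ph <- Arg(.analytic(.fft_bandpass(s$x, s$fs, fp - phase_hw,
                                      fp + phase_hw)))
    cph <- cos(ph); sph <- sin(ph)
    hw <- max(amp_hw_min, fp)
    for (j in seq_along(amp_freqs)) {
      fa <- amp_freqs[j]
      key <- paste0(fa, "@", hw)
      A <- amp_cache[[key]]
      if (is.null(A)) {
        A <- Mod(.analytic(.fft_bandpass(s$x, s$fs, fa - hw, fa + hw)))
        amp_cache[[key]] <- A
      }
      pac[i, j] <- .pac_r2(A, cph, sph)
    }
  }
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs, pac = pac),
            class = "comodulogram")
}

#' Band summary of a comodulogram
#'
#' Mean (`pac_band_mean`) or maximum (`pac_band_peak`) of the PAC matrix over
#' the grid points whose phase and amplitude frequencies fall inside the
#' given closed bands (defaults: theta 1-8 Hz, slow gamma 15-50 Hz).
#'
#' @param como a [comodulogram()].
#' @param phase_band,amp_band closed bands in Hz.
#' @return scalar.
#' @export
pac_band_mean <- function(como, phase_band = c(1, 8), amp_band = c(15, 50)) {
  sel <- .como_sel(como, phase_band, amp_band)
  mean(como$pac[sel$i, sel$j])
}

#' @rdname pac_band_mean
#' @export
pac_band_peak <- function(como, phase_band = c(1, 8), amp_band = c(15, 50)) {
  sel <- .como_sel(como, phase_band, amp_band)
  max(como$pac[sel$i, sel$j])
}

.como_sel <- function(como, phase_band, amp_band) {
  i <- which(como$phase_freqs >= phase_band[1] &
             como$phase_freqs <= phase_band[2])
  j <- which(como$amp_freqs >= amp_band[1] & como$amp_freqs <= amp_band[2])
  if (!length(i) || !length(j))
    stop("band selection is empty on the comodulogram grid")
  list(i = i, j = j)
}

#' Frequency pair at the comodulogram maximum
#'
#' @param como a [comodulogram()].
#' @return named numeric `c(phase_freq, amp_freq)`.
#' @export
como_argmax <- function(como) {
  ij <- arrayInd(which.max(como$pac), dim(como$pac))
  c(phase_freq = como$phase_freqs[ij[1]], amp_freq = como$amp_freqs[ij[2]])
}

#' Band-mean PAC with surrogate distribution
#'
#' Computes the band-mean PAC of a series on a scalar-statistic grid and a
#' surrogate distribution of the same statistic under the null of no
#' phase-amplitude relation. Three surrogate constructions are available:
#' `"timeshift"` circularly shifts every amplitude envelope against the
#' phase series by a random offset of at least `min_shift_s` seconds and
#' recomputes the regressions — the phase and amplitude spectra and their
#' autocorrelation are exactly preserved, making it the calibrated null for
#' significance testing; `"shuffle"` randomly permutes the amplitude
#' envelope samples, destroying the phase-amplitude alignment entirely
#' (note that the regression estimator fits the coupling phase freely, so
#' only alignment-destroying surrogates drive the statistic to its
#' regression floor on strongly periodic signals); `"phasescramble"`
#' randomizes the Fourier phases of the raw series and recomputes the full
#' statistic.
#'
#' @param x a `rate_series` or plain numeric with `fs`.
#' @param fs sampling rate (Hz) for plain numeric input.
#' @param n_surrogates number of surrogates.
#' @param method `"timeshift"` or `"phasescramble"`.
#' @param phase_freqs,amp_freqs scalar-statistic grid (defaults: 1-8 Hz in
#'   1 Hz steps, 15-50 Hz in 5 Hz steps).
#' @param phase_hw,amp_hw_min as in [comodulogram()].
#' @param min_shift_s minimum circular shift (s) for `"timeshift"`.
#' @param seed integer seed for the surrogate randomness.
#' @return list with `value` (observed band-mean PAC), `surrogates`
#'   (numeric vector), and `p` (fraction of surrogates >= value, with the
#'   +1 correction).
#' @export
pac_surrogate_test <- function(x, fs = NULL, n_surrogates = 200,
                               method = c("timeshift", "shuffle",
                                          "phasescramble"),
                               phase_freqs = seq(1, 8, by = 1),
                               amp_freqs = seq(15, 50, by = 5),
                               phase_hw = 1, amp_hw_min = 4,
                               min_shift_s = 1, seed = 1) {
  method <- match.arg(method)
  s <- .as_signal(x, fs)
  n <- length(s$x)
  if (method == "phasescramble") {
    obs <- pac_band_mean(comodulogram(s$x, phase_freqs, amp_freqs, fs = s$fs,
                                      phase_hw = phase_hw,
                                      amp_hw_min = amp_hw_min),
                         range(phase_freqs), range(amp_freqs))
    surr <- with_seed(seed, vapply(seq_len(n_surrogates), function(k) {
      xs <- phase_scramble(s$x)
      pac_band_mean(comodulogram(xs, phase_freqs, amp_freqs, fs = s$fs,
                                 phase_hw = phase_hw,
                                 amp_hw_min = amp_hw_min),
                    range(phase_freqs), range(amp_freqs))
    }, numeric(1)))
  } else {
    # precompute phase regressors and amplitude envelopes once
    regs <- lapply(phase_freqs, function(fp) {
      ph <- Arg(.analytic(.fft_bandpass(s$x, s$fs, fp - phase_hw,
                                        fp + phase_hw)))
      cbind(cos(ph), sin(ph))
    })
    amps <- lapply(seq_along(phase_freqs), function(i) {
      hw <- max(amp_hw_min, phase_freqs[i])
      lapply(amp_freqs, function(fa)
        Mod(.analytic(.fft_bandpass(s$x, s$fs, fa - hw, fa + hw))))
    })
    stat_for <- function(reindex) {
      tot <- 0
      for (i in seq_along(phase_freqs)) {
        X <- regs[[i]]
        for (j in seq_along(amp_freqs)) {
          A <- amps[[i]][[j]]
          if (!is.null(reindex)) A <- A[reindex]
          tot <- tot + .pac_r2(A, X[, 1], X[, 2])
        }
      }
      tot / (length(phase_freqs) * length(amp_freqs))
    }
    obs <- stat_for(NULL)
    if (method == "timeshift") {
      min_shift <- max(1L, round(min_shift_s * s$fs))
      if (2 * min_shift >= n) min_shift <- max(1L, floor(n / 4))
      surr <- with_seed(seed, {
        shifts <- sample.int(n - 2 * min_shift, n_surrogates,
                             replace = TRUE) + min_shift
        vapply(shifts, function(sh)
          stat_for(c((sh + 1):n, 1:sh)), numeric(1))
      })
    } else {
      surr <- with_seed(seed, vapply(seq_len(n_surrogates), function(k)
        stat_for(sample.int(n)), numeric(1)))
    }
  }
  list(value = obs, surrogates = surr,
       p = (sum(surr >= obs) + 1) / (n_surrogates + 1))
}

#' Fourier phase randomization
#'
#' Returns a surrogate series with the same amplitude spectrum as the input
#' but uniformly random Fourier phases (conjugate-symmetric, so the output
#' is real). Uses the current RNG state.
#'
#' @param x numeric series.
#' @return numeric series of the same length.
#' @export
phase_scramble <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)
  if (half >= 1) {
    ph <- stats::runif(half, 0, 2 * pi)
    idx <- 2:(half + 1)
    X[idx] <- Mod(X[idx]) * exp(1i * ph)
    X[n + 2 - idx] <- Conj(X[idx])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Theta-cycle averaged rate templates
#'
#' Implements trough-locked cycle averaging: (1) the theta peak frequency
#' `f_theta` is found in the reference PSD (1-8 Hz) unless supplied; (2) the
#' reference series is zero-phase band-passed in a 2 Hz band centred on
#' `f_theta` with a 5th-order Butterworth filter; (3) local troughs below the
#' filtered-series mean are located; (4) every population's rate series is
#' cut into trough-to-trough segments; (5) segments with duration outside
#' the closed interval `[0.9/f_theta, 1.1/f_theta]` are discarded; (6) the
#' retained segments are rescaled by moving-average decimation to the length
#' of the shortest retained segment; (7) segments are averaged per
#' population.
#'
#' @param rates named list of `rate_series`, one per population.
#' @param reference the `rate_series` defining the theta troughs (normally
#'   the OLM population).
#' @param f_theta optional theta frequency (Hz); found from the reference
#'   PSD when `NULL`.
#' @param tol fractional cycle-length tolerance (default 0.1).
#' @return object of class `theta_cycle_average`: list with `templates`
#'   (named list of numeric vectors, all the length of the shortest retained
#'   segment), `n_segments_used`, `f_theta`.
#' @export
theta_cycle_average <- function(rates, reference, f_theta = NULL, tol = 0.1) {
  stopifnot(inherits(reference, "rate_series"))
  fs <- .rs_fs(reference)
  if (is.null(f_theta)) {
    psd <- welch_psd(reference,
                     window_ms = min(2048, length(reference$values) *
                                       reference$bin_width))
    f_theta <- peak_in_band(psd, c(1, 8))$peak_freq
  }
  if (f_theta <= 0) stop("reference has no detectable theta peak")
  if (stats::sd(reference$values) == 0)
    stop("no valid theta cycles: reference series is constant")
  bp <- .butter_bandpass(reference$values, fs, f_theta - 1, f_theta + 1)
  # filter transients on an oscillation-free series produce spurious troughs
  if (stats::sd(bp) < 1e-10 * stats::sd(reference$values))
    stop("no valid theta cycles: reference has no oscillation at ", f_theta,
         " Hz")
  troughs <- .local_troughs(bp)
  troughs <- troughs[bp[troughs] < mean(bp)]
  if (length(troughs) < 2) stop("no valid theta cycles: no troughs found")
  seg_len <- diff(troughs) / fs                 # seconds
  lo <- (1 - tol) / f_theta
  hi <- (1 + tol) / f_theta
  keep <- which(seg_len >= lo & seg_len <= hi)
  if (!length(keep)) stop("no valid theta cycles: all segments outside [",
                          signif(lo, 3), ", ", signif(hi, 3), "] s")
  min_len <- min(diff(troughs)[keep])
  templates <- lapply(rates, function(r) {
    stopifnot(length(r$values) == length(reference$values))
    segs <- lapply(keep, function(k) {
      seg <- r$values[troughs[k]:(troughs[k + 1] - 1)]
      .ma_decimate(seg, min_len)
    })
    Reduce(`+`, segs) / length(segs)
  })
  structure(list(templates = templates, n_segments_used = length(keep),
                 f_theta = f_theta),
            class = "theta_cycle_average")
}

# 5th-order Butterworth band-pass applied forward-backward (zero phase)
.butter_bandpass <- function(x, fs, f_lo, f_hi, order = 5) {
  f_lo <- max(f_lo, 0.1)
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# indices of strict local minima
.local_troughs <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

# shrink a segment to m points by averaging over contiguous blocks
.ma_decimate <- function(x, m) {
  L <- length(x)
  if (L == m) return(x)
  b <- round(seq(0, L, length.out = m + 1))
  vapply(seq_len(m), function(j) mean(x[(b[j] + 1):b[j + 1]]), numeric(1))
}

#' Short-time spectrogram of a rate series
#'
#' Hann-tapered short-time power spectra over sliding windows (default
#' 256 ms, 50% overlap, per-window mean removal).
#'
#' @param rate a `rate_series` or plain numeric with `fs`.
#' @param window_ms window length (ms).
#' @param overlap fractional window overlap.
#' @param fs sampling rate (Hz) for plain numeric input.
#' @return object of class `spectrogram`: list with `times` (s, window
#'   centres), `freqs` (Hz), `power` matrix (freqs x times).
#' @export
spectrogram <- function(rate, window_ms = 256, overlap = 0.5, fs = NULL) {
  s <- .as_signal(rate, fs)
  nperseg <- round(window_ms / 1000 * s$fs)
  n <- length(s$x)
  if (n <= nperseg) stop("series must be longer than the window")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  nfreq <- floor(nperseg / 2) + 1
  pow <- matrix(0, nfreq, length(starts))
  for (k in seq_along(starts)) {
    seg <- s$x[starts[k]:(starts[k] + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2
    pow[, k] <- sp / (s$fs * sum(win^2))
  }
  if (nfreq > 2) pow[2:(nfreq - 1), ] <- 2 * pow[2:(nfreq - 1), ]
  structure(list(times = (starts - 1 + nperseg / 2) / s$fs,
                 freqs = seq(0, nfreq - 1) * s$fs / nperseg, power = pow),
            class = "spectrogram")
}

#' Standardized band-power time series from a spectrogram
#'
#' Averages spectrogram power over `[center - bandwidth/2,
#' center + bandwidth/2]` and standardizes the resulting series to zero mean
#' and unit variance. A band narrower than the spectrogram's frequency
#' spacing uses the single bin nearest the band centre; a band entirely
#' outside the frequency axis is rejected.
#'
#' @param spec a [spectrogram()].
#' @param center band centre (Hz).
#' @param bandwidth band width (Hz).
#' @return numeric series (one value per spectrogram window).
#' @export
band_power_timeseries <- function(spec, center, bandwidth) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (hi < min(spec$freqs) || lo > max(spec$freqs))
    stop("band [", lo, ", ", hi, "] Hz lies outside the frequency axis")
  sel <- which(spec$freqs >= lo & spec$freqs <= hi)
  # a band narrower than the spectrogram's frequency spacing falls back to
  # the bin nearest the band centre
  if (!length(sel)) sel <- which.min(abs(spec$freqs - center))
  p <- colMeans(spec$power[sel, , drop = FALSE])
  sdp <- stats::sd(p)
  if (sdp == 0) stop("band power has zero variance; cannot standardize")
  (p - mean(p)) / sdp
}

#' Theta/gamma power covariation
#'
#' Ordinary least-squares regression of the gamma band-power series on the
#' theta band-power series, returning the coefficient of determination and
#' the slope.
#'
#' @param theta_power,gamma_power equal-length numeric series (length >= 3).
#' @return object of class `covariation_result`: list with `r_squared`,
#'   `slope`, `n_windows`.
#' @export
power_covariation <- function(theta_power, gamma_power) {
  if (length(theta_power) != length(gamma_power))
    stop("series must have equal length")
  n <- length(theta_power)
  if (n < 3) stop("need at least 3 windows")
  if (stats::sd(theta_power) == 0 || stats::sd(gamma_power) == 0)
    stop("zero-variance input")
  fit <- stats::lm.fit(cbind(1, theta_power), gamma_power)
  r <- stats::cor(theta_power, gamma_power)
  structure(list(r_squared = r^2, slope = unname(fit$coefficients[2]),
                 n_windows = n),
            class = "covariation_result")
}

#' Three-point moving average across neighbouring sweep points
#'
#' Centred 3-point moving average with shortened windows at the ends, the
#' smoothing applied to metric curves across neighbouring input levels.
#'
#' @param x numeric vector.
#' @return smoothed vector of the same length.
#' @export
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - 1):min(n, i + 1)]), numeric(1))
}
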