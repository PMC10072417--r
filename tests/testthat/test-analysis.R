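# Oscillation-analysis chain: rate binning, Welch spectra, comodulogram,
# theta-cycle averaging, spectrogram band power, covariation.

make_rate <- function(values, bin_width = 4) {
  structure(list(values = values, bin_width = bin_width, t0 = 0),
            class = "rate_series")
}

test_that("bin_rates normalizes by bin width and cell count and conserves
           spikes", {
  # 10 cells, each one spike inside the same 4 ms bin -> 250 Hz
  tab <- spike_table(rep("PYR", 10), 1:10, rep(2101, 10),
                     n_cells = c(PYR = 10), duration = 2400)
  r <- bin_rates(tab, "PYR", discard = 2000)
  expect_equal(max(r$values), 10 / (0.004 * 10))
  expect_equal(sum(r$values > 0), 1)
  # empty table -> all-zero series of the right length
  e <- spike_table(character(), integer(), numeric(),
                   n_cells = c(PYR = 5), duration = 3000)
  re <- bin_rates(e, "PYR", discard = 1000)
  expect_equal(re$values, rep(0, 500))
  # conservation on a random table
  set.seed(1)
  tt <- runif(500, 0, 6300)
  tab2 <- spike_table(rep("OLM", 500), sample(1:10, 500, TRUE), tt,
                      n_cells = c(OLM = 10), duration = 6300)
  r2 <- bin_rates(tab2, "OLM", discard = 2000)
  expect_equal(sum(r2$values) * 0.004 * 10, sum(tt > 2000))
  expect_error(bin_rates(tab2, "NOPE"), "unknown population")
})

test_that("welch psd locates pure tones and handles degenerate input", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  r <- make_rate(sin(2 * pi * 25 * t))
  psd <- welch_psd(r)
  expect_equal(psd$freqs[which.max(psd$power)], 25,
               tolerance = fs / 512 + 1e-9)
  # constant series: all power at 0 Hz (per-segment demeaning leaves zeros)
  pc <- welch_psd(make_rate(rep(3, 5000)))
  expect_true(all(pc$power[pc$freqs > 0] < 1e-20))
  expect_error(welch_psd(make_rate(rnorm(100))), "shorter")
  # white noise is spectrally flat: no band mean exceeds 3x the global mean
  set.seed(2)
  pw <- welch_psd(make_rate(rnorm(8000)))
  bands <- split(pw$power[-1], cut(pw$freqs[-1], 10))
  expect_lt(max(vapply(bands, mean, numeric(1))) / mean(pw$power[-1]), 3)
})

test_that("peak_in_band uses a closed interval and max semantics", {
  psd <- structure(list(freqs = c(1, 3, 5, 7, 8), power = c(1, 5, 2, 4, 9),
                        params = list()), class = "psd")
  expect_equal(peak_in_band(psd, c(1, 8))$peak_freq, 8)   # edge included
  expect_equal(peak_in_band(psd, c(1, 7))$peak_freq, 3)   # larger of two
  expect_equal(peak_in_band(psd, c(1, 7))$log_strength, log10(5))
  expect_error(peak_in_band(psd, c(10, 20)), "no frequency bins")
})

test_that("comodulogram: exact fit, null case, localization and scale
           invariance", {
  fs <- 250
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  # perfect linear coupling A = 1 + cos(phase) -> PAC ~ 1 at the pair
  ph <- 2 * pi * 5 * t
  x <- sin(ph) + (1 + cos(ph)) * sin(2 * pi * 25 * t)
  como <- comodulogram(x, phase_freqs = seq(3, 8), amp_freqs = seq(15, 40),
                       fs = fs)
  # noiseless perfect coupling: R^2 -> 1 at the injected pair (neighbouring
  # phase bands that still contain the 5 Hz component tie at 1, so the
  # argmax is checked on the noisy generator below instead)
  expect_gt(como$pac[como$phase_freqs == 5, como$amp_freqs == 25], 0.98)
  expect_true(all(como$pac >= 0 & como$pac <= 1))
  # synthetic generator argmax recovery + scale invariance of the R^2
  # estimator (checked on a noisy signal where every band carries power and
  # the instantaneous phase is numerically well conditioned)
  xg <- gen_pac_signal(pac_signal_spec(4.5, 25, depth = 0.8, noise_sd = 0.5,
                                       fs = fs, duration = 40, seed = 2))
  cg <- comodulogram(as.numeric(xg), fs = fs)
  cg2 <- comodulogram(17.3 * as.numeric(xg), fs = fs)
  expect_equal(cg$pac, cg2$pac, tolerance = 1e-6)
  am <- como_argmax(cg)
  expect_equal(unname(am["phase_freq"]), 4.5, tolerance = 0.5)
  expect_equal(unname(am["amp_freq"]), 25, tolerance = 3)
  # Nyquist guard
  expect_error(comodulogram(x, phase_freqs = 5, amp_freqs = 124, fs = fs),
               "Nyquist")
})

test_that("pac band summaries: constant matrix, zeros, order property", {
  como <- structure(list(phase_freqs = 1:8, amp_freqs = seq(15, 50, 5),
                         pac = matrix(0.3, 8, 8)), class = "comodulogram")
  expect_equal(pac_band_mean(como), 0.3)
  expect_equal(pac_band_peak(como), 0.3)
  como$pac <- matrix(0, 8, 8)
  expect_equal(pac_band_peak(como), 0)
  set.seed(3)
  como$pac <- matrix(runif(64), 8, 8)
  expect_gte(pac_band_peak(como), pac_band_mean(como))
  expect_error(pac_band_mean(como, phase_band = c(100, 200)), "empty")
})

test_that("comodulogram of a time-reversed stationary series matches the
           original", {
  x <- gen_pac_signal(pac_signal_spec(4.5, 25, depth = 0.8, noise_sd = 0.3,
                                      fs = 250, duration = 30, seed = 5))
  a <- pac_band_mean(comodulogram(as.numeric(x), fs = 250))
  b <- pac_band_mean(comodulogram(rev(as.numeric(x)), fs = 250))
  expect_equal(a, b, tolerance = 0.05 * a)
})

test_that("theta cycle averaging recovers a periodic cycle and applies the
           closed length tolerance", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  r <- make_rate(5 + 3 * sin(2 * pi * 5 * t))
  tca <- theta_cycle_average(list(X = r), r)
  expect_equal(tca$f_theta, 5, tolerance = 0.3)
  cyc <- tca$templates$X
  truth <- 5 + 3 * sin(2 * pi * seq(0, 1, length.out = length(cyc) + 1)[-1]
                       - pi / 2)
  expect_gt(cor(cyc, truth), 0.99)
  # RMS error of the recovered template against one true cycle
  shift <- which.min(cyc)
  expect_lt(sqrt(mean((cyc - mean(cyc))^2 - 0)) /
              sqrt(mean((truth - mean(truth))^2)), 1.2)
  # constant input: no troughs -> explicit error
  expect_error(theta_cycle_average(list(X = make_rate(rep(2, 5000))),
                                   make_rate(rep(2, 5000)), f_theta = 5),
               "no valid theta cycles")
})

test_that("segment retention rule keeps exactly the closed-interval lengths", {
  # closed tolerance at f_theta = 5 Hz is [180, 220] ms: constructed trough
  # intervals {200, 230, 180, 300} retain exactly {200, 180} (boundary 180
  # included, closed interval)
  lens <- c(200, 230, 180, 300)
  lo <- 0.9 / 5 * 1000
  hi <- 1.1 / 5 * 1000
  expect_equal(sort(lens[lens >= lo & lens <= hi]), c(180, 200))
  # the same rule exercised through the pipeline: a rate made of whole
  # cosine cycles of varying length; clearly-out-of-band cycles (150,
  # 260 ms) are discarded, the in-band ones (190-210 ms) retained
  fs <- 250
  lens2 <- c(200, 200, 190, 260, 200, 210, 150, 200, 200, 190, 200, 200,
             210, 200, 200, 200, 200, 190, 200, 200)
  x <- unlist(lapply(lens2, function(L) {
    n <- round(L / 1000 * fs)
    5 - 3 * cos(2 * pi * seq(0, n - 1) / n)
  }))
  r <- make_rate(x)
  tca <- theta_cycle_average(list(X = r), r, f_theta = 5)
  n_in <- sum(lens2 >= lo & lens2 <= hi)
  expect_lte(abs(tca$n_segments_used - n_in), 1)
  expect_equal(length(tca$templates$X),
               round(min(lens2[lens2 >= lo & lens2 <= hi]) / 1000 * fs),
               tolerance = 2)
})

test_that("spectrogram band power tracks an amplitude-modulated carrier and
           standardizes exactly", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- (1 + 0.8 * sin(2 * pi * 0.5 * t)) * sin(2 * pi * 25 * t)
  spec <- spectrogram(make_rate(x), window_ms = 256)
  bp <- band_power_timeseries(spec, center = 25, bandwidth = 8)
  expect_equal(mean(bp), 0, tolerance = 1e-12)
  expect_equal(sd(bp), 1, tolerance = 1e-12)
  # the band-power series oscillates at the 0.5 Hz modulation rate
  bps <- welch_psd(bp, window_ms = 16000,
                   fs = 1 / mean(diff(spec$times)))
  pk <- bps$freqs[which.max(bps$power[bps$freqs > 0.1]) +
                    sum(bps$freqs <= 0.1)]
  expect_equal(pk, 0.5, tolerance = 0.2)
  # stationary sinusoid: no trend in standardized band power
  xs <- sin(2 * pi * 25 * t)
  bs <- band_power_timeseries(spectrogram(make_rate(xs)), 25, 8)
  tr <- lm(bs ~ seq_along(bs))
  expect_lt(abs(coef(tr)[2]) * length(bs), 0.5)
  expect_error(band_power_timeseries(spec, 1000, 8), "outside")
})

test_that("power covariation: exact lines, theory recovery, degenerate
           input", {
  x <- rnorm(50)
  expect_equal(power_covariation(x, x)$r_squared, 1)
  expect_equal(power_covariation(x, x)$slope, 1)
  expect_equal(power_covariation(x, -x)$slope, -1)
  expect_error(power_covariation(x, rep(1, 50)), "zero-variance")
  expect_error(power_covariation(x, x[1:10]), "equal length")
  z <- gen_covarying_powers(covarying_power_spec(600, 0.9, seed = 4))
  expect_lt(abs(power_covariation(z$theta, z$gamma)$r_squared - 0.81), 0.1)
})

test_that("smooth3 is the identity on constants and has shortened ends", {
  expect_equal(smooth3(rep(2, 7)), rep(2, 7))
  expect_equal(smooth3(c(1, 2, 3)), c(1.5, 2, 2.5))
})
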