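# Event-driven Tsodyks-Markram synapse: spike recursion, steady states,
# conductance kernels. Expected values frozen from hand recursion and the
# fine-step ODE oracle (.tm_ode_oracle, RK4 at 0.001 ms).

test_that("first spike releases exactly U for every registry parameter set", {
  reg <- synapse_registry()
  for (nm in names(reg)) {
    res <- tm_apply_spike(tm_state(), reg[[nm]], t = 5)
    expect_equal(res$release, reg[[nm]]$U, info = nm)
  }
})

test_that("two-spike depressing release matches the hand recursion", {
  p <- synapse_registry()$PYR_PVBC     # U = 0.32, F = 0, D = 110
  rel <- tm_release_train(p, c(0, 20))
  # rel2 = 0.32 * (1 - 0.32 * exp(-20/110)) = 0.2346237 (resources were
  # depleted to 0.68, so the unrecovered fraction is 0.32)
  expect_equal(rel[2], 0.32 * (1 - 0.32 * exp(-20 / 110)), tolerance = 1e-12)
  expect_equal(rel[2], 0.2346237, tolerance = 1e-6)
})

test_that("release relaxes back to U after a long pause", {
  p <- synapse_registry()$PYR_OLM
  rel <- tm_release_train(p, c(0, 10, 20, 30, 1e7))
  expect_equal(rel[5], p$U, tolerance = 1e-8)
})

test_that("time going backwards is rejected", {
  p <- synapse_registry()$PYR_OLM
  st <- tm_apply_spike(tm_state(), p, 10)$state
  expect_error(tm_apply_spike(st, p, 5), "precedes")
})

test_that("periodic steady state matches iterated recursion (both regimes)", {
  dep <- synapse_registry()$PYR_PVBC
  fac <- synapse_registry()$PYR_OLM
  for (p in list(dep, fac)) for (isi in c(5, 20, 100)) {
    rel <- tm_release_train(p, seq(0, by = isi, length.out = 500))
    ss <- tm_periodic_steady_state(p, isi)
    expect_equal(rel[500], ss$release, tolerance = 1e-9)
  }
  # frozen values, U = 0.32, D = 110 ms, isi = 20 ms: R* = 0.38390,
  # release* = 0.122848 (1000-step recursion agrees to 1e-15)
  ss <- tm_periodic_steady_state(dep, 20)
  expect_equal(ss$R_pre, 0.3838999, tolerance = 1e-6)
  expect_equal(ss$release, 0.1228480, tolerance = 1e-6)
})

test_that("closed-form F = 0 steady state agrees with the printed formula", {
  p <- tm_params(U = 0.32, F = 0, D = 110, tau_decay_fast = 4.12)
  e <- exp(-20 / 110)
  expect_equal(tm_periodic_steady_state(p, 20)$release,
               0.32 * (1 - e) / (1 - 0.68 * e), tolerance = 1e-12)
  expect_error(tm_periodic_steady_state(p, 0), "isi")
})

test_that("facilitating set potentiates and depressing set depresses at 50 Hz", {
  fac <- tm_release_train(synapse_registry()$PYR_OLM, seq(0, 180, by = 20))
  expect_gt(fac[3], fac[1])
  dep <- tm_release_train(synapse_registry()$PYR_PVBC, seq(0, 180, by = 20))
  expect_true(all(diff(dep) < 0))
})

test_that("u and R stay in [0, 1] over random trains and parameters", {
  set.seed(42)
  for (k in 1:30) {
    p <- tm_params(U = runif(1, 0.01, 1), F = runif(1, 0, 800),
                   D = runif(1, 0, 2000), tau_decay_fast = 2)
    st <- tm_state()
    times <- cumsum(rexp(50, rate = 1 / 25))
    for (t in times) {
      res <- tm_apply_spike(st, p, t)
      st <- res$state
      expect_true(st$u >= 0 && st$u <= 1)
      expect_true(st$R >= 0 && st$R <= 1)
      expect_true(res$release >= 0 && res$release <= 1)
    }
  }
})

test_that("event recursion equals fine-step ODE integration on Poisson trains", {
  set.seed(7)
  for (k in 1:10) {
    p <- tm_params(U = runif(1, 0.05, 0.9), F = runif(1, 0, 600),
                   D = runif(1, 10, 1500), tau_decay_fast = 2)
    times <- sort(cumsum(rexp(30, rate = 1 / 30)))
    rel <- tm_release_train(p, times)
    ode <- ca1pac:::.tm_ode_oracle(times, p$U, p$F, p$D, 0.001)
    expect_lt(max(abs(rel - ode) / pmax(ode, 1e-12)), 1e-6)
  }
})

test_that("conductance trace: kernel shape, linearity, depressing peaks", {
  p <- tm_params(U = 1, tau_decay_fast = 5, g_range = c(1, 1),
                 delay_range = c(0, 0))
  grid <- seq(0, 50, by = 0.5)
  ev <- data.frame(time = 10, amplitude = 2)
  tr <- conductance_trace(ev, p, grid, delay = 0)
  expect_equal(tr[grid < 10], rep(0, sum(grid < 10)))
  expect_equal(tr[grid >= 10], 2 * exp(-(grid[grid >= 10] - 10) / 5))
  # two coincident events double the trace
  tr2 <- conductance_trace(rbind(ev, ev), p, grid, delay = 0)
  expect_equal(tr2, 2 * tr)
  # empty event list -> zero trace
  expect_equal(conductance_trace(data.frame(time = numeric(0),
                                            amplitude = numeric(0)),
                                 p, grid), rep(0, length(grid)))
  # depressing 50 Hz train, fast kernel only: successive peaks strictly
  # decreasing (the slow NMDA component would accumulate across events)
  dep <- tm_params(U = 0.32, F = 0, D = 110, tau_decay_fast = 4.12,
                   g_range = c(0.3, 0.7), delay_range = c(0, 0))
  times <- seq(0, 160, by = 20)
  amps <- dep$g_range[1] * tm_release_train(dep, times) / dep$U
  grid2 <- seq(0, 200, by = 0.01)
  trd <- conductance_trace(data.frame(time = times, amplitude = amps),
                           dep, grid2, delay = 0)
  peaks <- vapply(times, function(t0)
    max(trd[grid2 >= t0 & grid2 < t0 + 20]), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("slow NMDA-like component adds with the stated peak ratio", {
  p <- tm_params(U = 1, tau_decay_fast = 1.7, tau_decay_slow = 148.5,
                 slow_ratio = 0.28, delay_range = c(0, 0))
  grid <- seq(0, 300, by = 0.1)
  tr <- conductance_trace(data.frame(time = 0, amplitude = 1), p, grid,
                          delay = 0)
  expect_equal(tr[1], 1 + 0.28, tolerance = 1e-9)   # both kernels peak at 1
  late <- grid > 50                                  # fast part long gone
  expect_equal(tr[late], 0.28 * exp(-grid[late] / 148.5), tolerance = 1e-3)
})

test_that("parameter validation names the violated constraint", {
  expect_error(tm_params(U = 0), "U must")
  expect_error(tm_params(U = 0.5, F = -1), "F must")
  expect_error(tm_params(U = 0.5, g_range = c(2, 1)), "g_range")
})
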