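test_that("constant light settles on the closed-form steady state", {
  p <- bhl()
  expect_equal(steady_state_response(0, p), 0)
  # saturation: |R| -> alpha / beta as I_B -> infinity
  expect_equal(abs(steady_state_response(1e9, p)), p$alpha / p$beta,
               tolerance = 1e-4)
  g <- time_grid(0, 0.1, 20000)
  for (I_B in c(0.5, 50, 5000)) {
    stim <- make_pulse_stimulus(pulse_protocol(background = I_B), g)
    r <- simulate_da(stim, p)
    expect_equal(r$response[g$n], steady_state_response(I_B, p),
                 tolerance = 1e-6 * abs(steady_state_response(I_B, p)))
  }
})

test_that("zero stimulus from the dark steady state stays at zero", {
  g <- time_grid(0, 0.5, 2000)
  r <- simulate_da(make_pulse_stimulus(pulse_protocol(background = 0), g),
                   bhl())
  expect_true(all(r$response == 0))
})

test_that("the beta = 0 limit is an exponential low-pass of the drive", {
  p <- da_params(1.5, 0, 0.9, 30, 2, 25, 7, 20)
  g <- time_grid(0, 0.1, 16000)
  stim <- make_flash_stimulus(100, onset = 200, duration = 10, grid = g)
  r <- simulate_da(stim, p)
  # quadrature oracle: R = -alpha * (1/tau_r) int y e^{-(t-t')/tau_r}
  idx <- seq(500, g$n, by = 500)
  oracle <- -p$alpha * lin_lowpass_oracle(r$y, g$dt, p$tau_r, idx)
  expect_lt(max(abs(r$response[idx] - oracle)), 1e-5 * max(abs(oracle)))
  # linearity: response to a sum of weak stimuli is the sum of responses
  s1 <- make_flash_stimulus(10, onset = 100, duration = 10, grid = g)
  s2 <- make_flash_stimulus(20, onset = 400, duration = 10, grid = g)
  s12 <- make_pulse_stimulus(pulse_protocol(flashes = data.frame(
    onset = c(100, 400), photons = c(10, 20), duration = 10)), g)
  r1 <- simulate_da(s1, p)$response
  r2 <- simulate_da(s2, p)$response
  r12 <- simulate_da(s12, p)$response
  expect_lt(max(abs(r12 - (r1 + r2))), 1e-8 * max(abs(r12)))
})

test_that("integrator and exact solution agree across stimulus classes", {
  p <- bhl()
  g <- time_grid(0, 0.1, 20000)
  stims <- list(
    flash = make_flash_stimulus(2000, onset = 100, duration = 10,
                                background = 5, grid = g),
    step = make_pulse_stimulus(pulse_protocol(
      background = 2, steps = data.frame(onset = 100, amplitude = 40)), g),
    sinusoid = make_sinusoid_stimulus(50, 0.5, 2.5, g),
    flicker = make_gaussian_flicker(
      flicker_spec(40, 0.35, "exp", tau_c_ms = 100, seed = 4), g))
  for (nm in names(stims)) {
    r1 <- simulate_da(stims[[nm]], p)
    r2 <- simulate_da_exact(stims[[nm]], p)
    expect_lt(max(abs(r1$response - r2$response)),
              1e-4 * max(abs(r1$response)), label = nm)
  }
})

test_that("the response is not time-reversal symmetric", {
  p <- bhl()
  g <- time_grid(0, 0.5, 6000)
  tm <- grid_times(g)
  # biphasic intensity profile on a background
  I <- 20 + 15 * sin(2 * pi * tm / 1000) * exp(-(tm - 1500)^2 / 4e5)
  I <- pmax(I, 0)
  fwd <- simulate_da(stimulus_trace(g, I), p)$response
  bwd <- simulate_da(stimulus_trace(g, rev(I)), p)$response
  # reversing the stimulus does not reverse the response
  expect_gt(max(abs(rev(bwd) - fwd)), 0.05 * max(abs(fwd)))
})

test_that("gain and bandwidth co-vary with background intensity", {
  p <- set_b()
  g <- time_grid(0, 0.25, 8000)
  probe <- 200
  peaks <- lapply(c(2, 60), function(I_B) {
    stim <- make_flash_stimulus(probe, onset = 100, duration = 5,
                                background = I_B, grid = g)
    r <- simulate_da(stim, p)
    inc <- response_trace(g, r$response - steady_state_response(I_B, p))
    response_peak(inc, after_ms = 100)
  })
  # brighter background: smaller incremental peak, earlier peak
  expect_lt(abs(peaks[[2]]$value), abs(peaks[[1]]$value))
  expect_lt(peaks[[2]]$time_ms, peaks[[1]]$time_ms)
})

test_that("responses never exceed the saturation scale", {
  p <- bhl()
  g <- time_grid(0, 0.1, 20000)
  # numerical bound on the Ky/Kz envelope ratio
  kp <- build_kernels(p, 0.1)
  pos <- kp$kz > 1e-12
  env_bound <- max(kp$ky[pos] / kp$kz[pos])
  for (F in c(1e4, 1e6, 1e8)) {
    stim <- make_flash_stimulus(F, onset = 100, duration = 10, grid = g)
    r <- simulate_da(stim, p)
    expect_lt(max(abs(r$response)), p$alpha / p$beta * env_bound * 1.001)
  }
  # constant inputs never exceed alpha/beta itself
  stim <- make_pulse_stimulus(pulse_protocol(background = 1e7), g)
  expect_lt(max(abs(simulate_da(stim, p)$response)),
            p$alpha / p$beta * 1.001)
})

test_that("an extreme dark flash produces the double-peaked response", {
  p <- bhl()
  g <- time_grid(0, 0.1, 25000)
  stim <- make_flash_stimulus(100 * 6.7e5, onset = 100, duration = 10,
                              grid = g)
  v <- simulate_da(stim, p)$response
  minima <- which(diff(sign(diff(v))) == 2) + 1
  deep <- minima[v[minima] < -1]   # distinct humps, not numerical ripples
  expect_gte(length(deep), 2)
})

test_that("the algebraic limit is reached as tau_r shrinks", {
  p <- set_b()
  g <- time_grid(0, 0.1, 30000)
  stim <- make_sinusoid_stimulus(30, 0.5, 1.25, g)
  alg <- algebraic_limit_response(stim, p)$response
  gap <- vapply(c(1, 100), function(f) {
    ps <- p; ps$tau_r <- p$tau_r / f
    ps <- da_params(ps$alpha, ps$beta, ps$gamma, ps$tau_r, ps$n_y,
                    ps$tau_y, ps$n_z, ps$tau_z)
    sel <- 5000:30000  # past the warm-up
    max(abs(simulate_da(stim, ps)$response[sel] - alg[sel]))
  }, numeric(1))
  # first-order convergence: gap shrinks ~100-fold for tau_r / 100
  expect_lt(gap[2], gap[1] / 30)
  # constant input: algebraic response equals the steady state
  stc <- make_pulse_stimulus(pulse_protocol(background = 25), g)
  expect_equal(algebraic_limit_response(stc, p)$response,
               rep(steady_state_response(25, p), g$n), tolerance = 1e-9)
})

test_that("in bright light the response depends only on the y/z ratio", {
  p <- bhl()
  g <- time_grid(0, 0.25, 12000)
  # same y/z ratio at two absolute levels deep in the bright regime
  s1 <- make_flash_stimulus(3e6, onset = 100, duration = 10,
                            background = 3e4, grid = g)
  s2 <- make_flash_stimulus(3e7, onset = 100, duration = 10,
                            background = 3e5, grid = g)
  r1 <- algebraic_limit_response(s1, p)
  r2 <- algebraic_limit_response(s2, p)
  d1 <- r1$response - steady_state_response(3e4, p)
  d2 <- r2$response - steady_state_response(3e5, p)
  expect_equal(d1, d2, tolerance = 0.02 * max(abs(d1)))
})
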