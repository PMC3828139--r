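test_that("the small-flash response has the right shape in each regime", {
  p <- set_b()
  g <- time_grid(0, 0.5, 2400)
  # dark: monophasic, single-signed, Ky-shaped
  dark <- small_flash_response(0, 10, p, g)
  expect_true(all(dark$response <= 1e-12))
  expect_lt(min(dark$response), 0)
  # very bright: biphasic with vanishing net area
  bright <- small_flash_response(1e6, 10, p, g)
  expect_gt(max(bright$response), 0)
  net <- abs(sum(bright$response)) / sum(abs(bright$response))
  expect_lt(net, 0.01)
  # amplitude exactly proportional to F
  twice <- small_flash_response(0, 20, p, g)
  expect_equal(twice$response, 2 * dark$response, tolerance = 1e-12)
})

test_that("the small-flash response matches the numerical-derivative oracle", {
  p <- set_b()
  I_B <- 5 / p$beta
  g <- time_grid(0, 0.5, 1600)
  an <- small_flash_response(I_B, 1, p, g, flash_ms = 0.5)
  # finite-difference oracle extrapolated to F -> 0
  gs <- time_grid(0, 0.5, 5600)
  base <- steady_state_response(I_B, p)
  num_deriv <- function(F) {
    stim <- make_flash_stimulus(F, onset = 1000, duration = 0.5,
                                background = I_B, grid = gs)
    (simulate_da(stim, p)$response - base)[2001:3600] / F
  }
  d1 <- num_deriv(2); d2 <- num_deriv(1)
  oracle <- 2 * d2 - d1   # Richardson extrapolation to F = 0
  expect_lt(max(abs(an$response[1:1600] - oracle)),
            0.01 * max(abs(oracle)))
})

test_that("bright-limit flash responses collapse onto the F/I_B ratio", {
  p <- bhl()
  g <- time_grid(0, 0.25, 4000)
  # node time is set by Ky = Kz and ignores the flash strength
  nt <- kernel_node_time(p)
  for (r in c(0.1, 1, 10)) {
    v <- bright_limit_flash_response(r, p, g)$response
    i <- which(v[-1] > 0 & v[-length(v)] <= 0)[1]
    expect_lt(abs(grid_times(g)[i] - nt), g$dt + 1e-9)
  }
  # full-model convergence deep into the bright regime (set B: its
  # kernels cancel less sharply, so the limit is reached sooner)
  pb <- set_b()
  gaps <- vapply(c(50, 200), function(bi) {
    I_B <- bi / pb$beta
    gs <- time_grid(0, 0.25, 12000)
    stim <- make_flash_stimulus(2 * I_B, onset = 1000, duration = 0.25,
                                background = I_B, grid = gs)
    sim <- simulate_da(stim, pb)$response - steady_state_response(I_B, pb)
    an <- bright_limit_flash_response(2, pb, g)$response
    max(abs(sim[4001:8000] - an)) / max(abs(an))
  }, numeric(1))
  expect_lt(gaps[2], 0.03)
  expect_lt(gaps[2], gaps[1] / 2)   # ~1/(beta I_B) convergence
})

test_that("step sensitivity follows the Weber-Fechner law over seven decades", {
  p <- set_b()
  curve <- weber_sensitivity_curve(p, 10^seq(-2, 5, by = 0.5))
  expect_equal(curve$normalized[curve$I_B == 0], 1)
  expect_true(all(diff(curve$normalized) <= 0))
  fit <- weber_fit(curve)
  expect_gt(fit$r_squared, 0.98)
  expect_lt(abs(fit$bright_slope + 1), 0.05)
})

test_that("frequency-dependent gain is band-pass at low contrast and low-pass at high contrast", {
  p <- set_b()
  I_B <- per_s(3.6e5)
  freqs <- c(0.1, 1.25, 2.5, 5)
  lo <- frequency_gain_curve(I_B, 0.01, freqs, p)
  expect_lt(lo$gain[1], 0.5 * max(lo$gain))        # band-pass: dip at 0.1 Hz
  hi <- frequency_gain_curve(I_B, 1, freqs, p)
  expect_gte(hi$gain[1], 0.5 * max(hi$gain))       # low-pass: strong at 0.1 Hz
  # tiny contrast reproduces the linearised transfer function
  lin <- linearized_transfer_gain(I_B, freqs, p)
  expect_lt(max(abs(lo$gain - lin) / lin), 0.02)
})

test_that("kernel overlaps interpolate between decoupled and coincident limits", {
  p <- set_b()
  kp <- build_kernels(p, 1)
  # infinite correlation: overlaps decouple to products of kernel areas = 1
  om_inf <- kernel_overlaps(kp, function(tau) rep(1, length(tau)))
  expect_equal(om_inf$yy, 1, tolerance = 1e-4)
  expect_equal(om_inf$yz, 1, tolerance = 1e-4)
  expect_equal(om_inf$zz, 1, tolerance = 1e-4)
  # near-delta correlation: overlaps equal direct kernel-product integrals
  tau_c <- 0.5
  om_d <- kernel_overlaps(kp, function(tau) exp(-abs(tau) / tau_c))
  direct_yz <- 2 * tau_c * sum(kp$ky * kp$kz) * kp$dt  # dense-quadrature oracle
  expect_equal(om_d$yz, direct_yz, tolerance = 0.02)
  # monotone and continuous in the correlation time
  oms <- vapply(c(5, 20, 80, 320, 1280), function(tc)
    kernel_overlaps(kp, function(tau) exp(-abs(tau) / tc))$zz, numeric(1))
  expect_true(all(diff(oms) > 0))
  expect_error(kernel_overlaps(kp, function(tau) 2 * exp(-abs(tau))),
               "C\\(0\\)")
})

test_that("flicker statistics reduce to the deterministic case at zero contrast", {
  p <- set_b()
  I_B <- 20 / p$beta
  sp0 <- flicker_spec(I_B, 0, "exp", tau_c_ms = 100, seed = 1)
  fm <- flicker_mean_response(sp0, p, method = "exact", dt = 1)
  # quadrature of the ensemble average is accurate to ~1e-4 relative
  expect_equal(fm$tonic_mean, steady_state_response(I_B, p),
               tolerance = 1e-3)
  fmp <- flicker_mean_response(sp0, p, method = "perturbative", dt = 1)
  expect_identical(fmp$tonic_mean, steady_state_response(I_B, p))
  fl <- flicker_flash_modulation(sp0, 100, p, method = "perturbative", dt = 1)
  expect_equal(fl$boost, 1)
  expect_true(all(fl$additive$response == 0))
  expect_equal(fl$phasic_mean$response, fl$flash_ref$response)
})

test_that("flicker depolarises the tonic response on a bright background", {
  p <- set_b()
  I_B <- 30 / p$beta
  sp <- flicker_spec(I_B, 0.35, "exp", tau_c_ms = 200, seed = 1)
  fm <- flicker_mean_response(sp, p, method = "perturbative", dt = 1)
  expect_gt(fm$tonic_mean, fm$R_B)   # less hyperpolarised than constant light
})

test_that("the flash-response boost exceeds one and tracks the correlation time", {
  p <- set_b()
  I_B <- 30 / p$beta
  boosts <- vapply(c(20, 2000), function(tc) {
    sp <- flicker_spec(I_B, 0.2, "exp", tau_c_ms = tc, seed = 1)
    flicker_flash_modulation(sp, 100, p, method = "perturbative", dt = 1)$boost
  }, numeric(1))
  expect_true(all(boosts >= 1))
  # adaptation to temporal structure: different correlation times give
  # different boost factors
  expect_gt(abs(diff(boosts)) / (boosts[1] - 1), 0.2)
})

test_that("dark events deflect the response more than equal bright events", {
  p <- set_b()
  I_B <- 30 / p$beta
  g <- time_grid(0, 0.5, 8000)
  mk <- function(sign) make_pulse_stimulus(pulse_protocol(
    background = I_B,
    flashes = data.frame(onset = 1000, photons = sign * 100 * I_B,
                         duration = 100)), g)
  base <- steady_state_response(I_B, p)
  up <- simulate_da(mk(1), p)$response - base
  dn <- simulate_da(mk(-1), p)$response - base
  expect_gt(max(abs(dn)), max(abs(up)))
})
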