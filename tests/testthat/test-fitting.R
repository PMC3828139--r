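mk_resp <- function(v, dt = 1) response_trace(time_grid(0, dt, length(v)), v)

test_that("Q matches its definition on hand-computed cases", {
  # perfect prediction
  o <- mk_resp(c(0, 1, 2))
  expect_equal(goodness_of_fit(o, o), 1)
  # predicting the per-trace mean gives Q = 0
  m <- mk_resp(rep(1, 3))
  expect_equal(goodness_of_fit(m, o), 0)
  # two-trace toy, by hand: SSE = (2-3)^2 = 1 over trace 1; trace 2 is
  # constant and therefore rejected
  p1 <- mk_resp(c(0, 1, 2)); o1 <- mk_resp(c(0, 1, 3))
  p2 <- mk_resp(c(1, 1));    o2 <- mk_resp(c(1, 1))
  expect_error(goodness_of_fit(list(p1, p2), list(o1, o2)), "zero variance")
  # replace the degenerate trace: obs {0,2}, pred {1,1}:
  # SSE = 1 + (1+1) = 3; SS about means = (14/3) + 2 = 20/3
  o2b <- mk_resp(c(0, 2)); p2b <- mk_resp(c(1, 1))
  q <- goodness_of_fit(list(p1, p2b), list(o1, o2b))
  expect_equal(q, 1 - 3 / (14 / 3 + 2), tolerance = 1e-12)
  # invariant to trace order
  expect_equal(goodness_of_fit(list(p2b, p1), list(o2b, o1)), q)
})

test_that("noiseless linear-regime traces are recovered exactly with beta fixed", {
  p_true <- da_params(1.8, 0, 0.4, 35, 3, 22, 7, 20, label = "lin")
  g <- time_grid(0, 2, 800)
  stims <- list(
    make_flash_stimulus(100, onset = 100, duration = 10, grid = g),
    make_flash_stimulus(300, onset = 100, duration = 50, grid = g))
  resps <- lapply(stims, function(s)
    simulate_da(s, p_true, keep_signals = FALSE))
  init <- da_params(1.2, 0, 0.5, 25, 2.4, 30, 7, 20, label = "init")
  fit <- fit_da_model(stims, resps, init,
                      free = c("alpha", "tau_r", "n_y", "tau_y"))
  # the overall gain is sharply identified; the relaxation time and the
  # kernel shape trade off along a nearly flat valley (a gamma kernel
  # composed with an exponential is almost another gamma kernel), so the
  # fit is judged on the identifiable quantities: gain, the composed
  # impulse-response shape, and near-perfect Q
  expect_equal(fit$params$alpha, p_true$alpha, tolerance = 2e-3)
  pred <- simulate_da(stims[[1]], fit$params, keep_signals = FALSE)
  truth <- resps[[1]]
  expect_lt(max(abs(pred$response - truth$response)),
            0.02 * max(abs(truth$response)))
  pk_fit <- response_peak(pred, after_ms = 100)
  pk_true <- response_peak(truth, after_ms = 100)
  expect_lt(abs(pk_fit$time_ms - pk_true$time_ms), 2)
  expect_gt(fit$Q, 1 - 1e-4)
})

test_that("synthetic parameters are recovered from noisy traces", {
  p_true <- set_b()
  d <- recovery_dataset(p_true, noise_seed = 1)
  fit <- fit_da_model(d$stims, d$resps, perturbed_init(p_true, seed = 11))
  rel <- function(a, b) abs(a - b) / b
  expect_lt(rel(fit$params$alpha, p_true$alpha), 0.1)
  expect_lt(rel(fit$params$beta, p_true$beta), 0.1)
  expect_lt(rel(fit$params$tau_r, p_true$tau_r), 0.1)
  expect_lt(rel(fit$params$n_y * fit$params$tau_y,
                p_true$n_y * p_true$tau_y), 0.1)
  expect_lt(rel(fit$params$n_z * fit$params$tau_z,
                p_true$n_z * p_true$tau_z), 0.1)
  expect_equal(fit$convergence, 0)
})

test_that("integer-shape mode returns integer exponents", {
  p_true <- set_b()
  d <- recovery_dataset(p_true, noise_seed = 2, n = 600)
  fit <- fit_da_model(d$stims, d$resps, perturbed_init(p_true, seed = 3),
                      integer_shapes = TRUE)
  expect_identical(fit$params$n_y, round(fit$params$n_y))
  expect_identical(fit$params$n_z, round(fit$params$n_z))
  expect_gt(fit$Q, 0.99)
})

test_that("per-trace gain profiling absorbs amplitude differences", {
  p_true <- set_b()
  g <- time_grid(0, 2, 700)
  stims <- list(
    make_flash_stimulus(2e3, onset = 100, duration = 10, grid = g),
    make_flash_stimulus(2e4, onset = 100, duration = 10, grid = g))
  scales <- c(0.7, 1.6)   # experiment-to-experiment gain variation
  resps <- lapply(seq_along(stims), function(i) {
    r <- simulate_da(stims[[i]], p_true, keep_signals = FALSE)
    r$response <- r$response * scales[i]
    r
  })
  fit <- fit_da_model(stims, resps, p_true, per_trace_alpha = TRUE,
                      free = c("alpha", "beta", "tau_r"))
  expect_equal(fit$alphas / p_true$alpha, scales, tolerance = 0.02)
  expect_gt(fit$Q, 0.999)
})

test_that("the goodness-of-fit surface is flat along compensating directions", {
  p_true <- set_b()
  d <- recovery_dataset(p_true, noise_seed = 4, n = 600)
  fit <- fit_da_model(d$stims, d$resps, p_true, maxit = 60)
  scan <- sensitivity_scan(fit, d$stims, d$resps,
                           pairs = list(c("n_y", "tau_y")), span = 0.25,
                           n = 7)
  # the optimum is maximal over each 1D profile
  for (nm in unique(scan$profiles$parameter)) {
    pr <- scan$profiles[scan$profiles$parameter == nm, ]
    expect_gte(scan$Q0 + 1e-9, max(pr$Q, na.rm = TRUE))
  }
  # sloppy valley: along the n_y/tau_y trade-off, a >= 10% move in n_y
  # degrades Q by less than 1% when tau_y compensates
  co <- scan$contours[["n_y:tau_y"]]
  shifted <- co[abs(co$n_y - 1.15 * fit$params$n_y) ==
                  min(abs(co$n_y - 1.15 * fit$params$n_y)), ]
  expect_gt(max(shifted$Q, na.rm = TRUE), scan$Q0 - 0.01)
  # the Hessian-based quadratic model reproduces the direct surface near
  # the optimum
  near <- abs(co$n_y / fit$params$n_y - 1) < 0.1 &
    abs(co$tau_y / fit$params$tau_y - 1) < 0.1
  expect_lt(max(abs(co$Q[near] - co$Q_quad[near]), na.rm = TRUE), 0.02)
})

test_that("dispersed starts converge to equivalent optima", {
  p_true <- set_b()
  d <- recovery_dataset(p_true, noise_seed = 5, n = 500)
  qs <- vapply(1:5, function(k) {
    fit_da_model(d$stims, d$resps, perturbed_init(p_true, seed = 20 + k),
                 maxit = 120)$Q
  }, numeric(1))
  expect_lt(diff(range(qs)) / max(qs), 0.005)
})
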