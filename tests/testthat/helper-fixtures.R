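# shared fixtures: built in code at test time

bhl <- function() da_preset("BHL")
set_b <- function() da_preset("B")

# brute-force O(N*K) causal convolution oracle, "hold" boundary
conv_oracle <- function(x, h, dt, pad = x[1]) {
  n <- length(x); K <- length(h)
  xp <- c(rep(pad, K - 1), x)
  vapply(seq_len(n), function(t)
    sum(h * xp[(t + K - 1):t]), numeric(1)) * dt
}

# direct-quadrature oracle for (1/tau) int y(t') e^{-(t-t')/tau} dt',
# evaluated at sample indices idx
lin_lowpass_oracle <- function(y, dt, tau, idx) {
  vapply(idx, function(t) {
    j <- seq_len(t)
    f <- y[j] * exp(-(t - j) * dt / tau)
    (sum(f) - (f[1] + f[t]) / 2) * dt / tau
  }, numeric(1))
}

# small noisy stimulus for oracle comparisons
random_stim <- function(grid, seed = 1, mean = 10, sd = 3) {
  set.seed(seed)
  I <- pmax(0, mean + sd * rnorm(grid$n))
  stimulus_trace(grid, I)
}

# synthetic-recovery data set: flashes, a step, a background flash and
# flicker generated from known parameters with proportional Gaussian noise
recovery_dataset <- function(p_true, noise_seed, dt = 2, n = 750,
                             noise = 0.01) {
  g <- time_grid(0, dt, n)
  stims <- list(
    make_flash_stimulus(2e3, onset = 100, duration = 10, grid = g),
    make_flash_stimulus(5e4, onset = 100, duration = 10, grid = g),
    make_pulse_stimulus(pulse_protocol(
      steps = data.frame(onset = 100, amplitude = 2 / p_true$beta)), g),
    make_gaussian_flicker(flicker_spec(2 / p_true$beta, 0.35, "exp",
                                       tau_c_ms = 100,
                                       seed = noise_seed + 500), g))
  set.seed(noise_seed)
  resps <- lapply(stims, function(s) {
    r <- simulate_da(s, p_true, keep_signals = FALSE)
    amp <- max(abs(r$response))
    r$response <- r$response + rnorm(length(r$response), sd = noise * amp)
    r
  })
  list(stims = stims, resps = resps)
}

# perturbed initial guess for fitting
perturbed_init <- function(p_true, seed, frac = 0.3) {
  set.seed(seed)
  v <- unclass(p_true)
  for (nm in c("alpha", "beta", "gamma", "tau_r", "n_y", "tau_y",
               "n_z", "tau_z"))
    v[[nm]] <- v[[nm]] * runif(1, 1 - frac, 1 + frac)
  v$gamma <- min(v$gamma, 0.95)
  da_params(v$alpha, v$beta, v$gamma, v$tau_r, v$n_y, v$tau_y,
            v$n_z, v$tau_z, label = "init")
}

# DA-generated frame-hold flicker with its fitted LN model (memoised per
# test file via local environments where needed)
ln_testbed <- function(duration_ms = 240000, dt = 4, nl_strength = 3,
                       seed = 7) {
  p <- da_preset("salamander")
  g <- time_grid(0, dt, duration_ms / dt)
  I_B <- nl_strength / p$beta
  stim <- make_gaussian_flicker(
    flicker_spec(I_B, 0.35, correlation = "hold", seed = seed), g)
  resp <- simulate_da(stim, p, keep_signals = FALSE)
  ln <- estimate_ln(stim, resp, filter_ms = 500, degree = 3)
  list(params = p, grid = g, stim = stim, resp = resp, ln = ln)
}
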