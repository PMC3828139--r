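#' Flash-family protocol: peak amplitude and delay vs flash strength
#'
#' Simulates a family of brief flashes on a common background and reports,
#' per flash, the peak hyperpolarisation and the peak delay (flash onset to
#' extremum, parabolic sub-grid refinement).  Reproduces the canonical
#' orderings: peak amplitude grows then saturates near \eqn{\alpha/\beta},
#' while the peak delay keeps decreasing even after the amplitude has
#' saturated.
#'
#' @param params a [da_params()] object.
#' @param photons vector of integrated flash strengths, photons/um^2.
#' @param background constant background, photons/um^2/ms.
#' @param flash_ms flash duration, ms.
#' @param dt,window_ms grid resolution and post-onset simulation window.
#' @param keep_traces return the response traces as well.
#' @return List with `summary` (data frame: photons, peak_mV, delay_ms,
#'   flat flag) and optionally `traces`.
#' @export
run_flash_family <- function(params, photons, background = 0, flash_ms = 10,
                             dt = 0.1, window_ms = 1500,
                             keep_traces = FALSE) {
  onset <- 100
  grid <- time_grid(0, dt, round((window_ms + onset) / dt))
  kernels <- build_kernels(params, dt)
  traces <- list()
  rows <- lapply(seq_along(photons), function(i) {
    stim <- make_flash_stimulus(photons[i], onset = onset,
                                duration = flash_ms,
                                background = background, grid = grid)
    r <- simulate_da(stim, params, kernels = kernels, keep_signals = FALSE)
    base <- steady_state_response(background, params)
    pk <- response_peak(r, after_ms = onset)
    flat <- abs(pk$value - base) < 1e-12
    if (keep_traces) traces[[i]] <<- r
    data.frame(photons = photons[i], peak_mV = pk$value - base,
               delay_ms = pk$time_ms - onset, flat = flat)
  })
  out <- list(summary = do.call(rbind, rows))
  if (keep_traces) out$traces <- traces
  out
}

#' Paired-flash protocol: incremental response vs delay
#'
#' A conditioning flash is presented at time 0 and an identical test flash
#' at a signed delay (negative: test first).  The incremental response is
#' the paired-flash response minus the conditioning-only response; its
#' peak, normalised by the conditioning-only peak, approaches 1 at large
#' separations and dips below 1 within a few hundred ms of the
#' conditioning flash — including at small negative delays, because the
#' conditioning flash shapes the gain during the extended test response.
#'
#' @param params a [da_params()] object.
#' @param delays_ms vector of signed delays, ms.
#' @param photons integrated strength of each flash, photons/um^2
#'   (default the 10 ms, 560 photons/um^2/s conditioning flash, i.e. 5.6).
#' @param flash_ms flash duration, ms.
#' @param dt grid step, ms.
#' @return Data frame with `delay_ms` and `norm_peak`.
#' @export
run_paired_flash <- function(params, delays_ms, photons = 5.6,
                             flash_ms = 10, dt = 0.5) {
  pad <- max(0, -min(delays_ms)) + 200
  window <- max(delays_ms) + 1500 + pad
  grid <- time_grid(0, dt, round(window / dt))
  kernels <- build_kernels(params, dt)
  cond_onset <- pad
  cond <- make_flash_stimulus(photons, onset = cond_onset,
                              duration = flash_ms, grid = grid)
  r_cond <- simulate_da(cond, params, kernels = kernels,
                        keep_signals = FALSE)
  peak_cond <- response_peak(r_cond, after_ms = cond_onset)
  norm <- vapply(delays_ms, function(d) {
    both <- make_pulse_stimulus(
      pulse_protocol(flashes = data.frame(
        onset = c(cond_onset, cond_onset + d),
        photons = c(photons, photons), duration = flash_ms)), grid)
    r_both <- simulate_da(both, params, kernels = kernels,
                          keep_signals = FALSE)
    inc <- response_trace(grid, r_both$response - r_cond$response)
    pk <- response_peak(inc, after_ms = cond_onset + d)
    pk$value / peak_cond$value
  }, numeric(1))
  data.frame(delay_ms = delays_ms, norm_peak = norm)
}

#' Background protocols: step families, Weber curve, delay saturation
#'
#' Bundles the constant-background characterisations: (i) step-response
#' families in the dark and on backgrounds (bright and dark steps), with
#' peak and steady-state hyperpolarisation per step; (ii) the normalised
#' Weber-Fechner sensitivity curve; (iii) the peak delay of a fixed flash
#' against background intensity, which decreases and then saturates.
#'
#' @param params a [da_params()] object.
#' @param step_intensities step amplitudes for the dark-step family,
#'   photons/um^2/ms.
#' @param backgrounds background intensities for the Weber and delay
#'   curves, photons/um^2/ms.
#' @param probe_photons integrated strength of the fixed delay-probe
#'   flash, photons/um^2.
#' @param dt grid step, ms.
#' @return List with `steps` (photons-intensity, peak and steady-state
#'   response), `weber` (curve + [weber_fit()] summary), and `delay`
#'   (data frame I_B, delay_ms).
#' @export
run_background_protocols <- function(params,
                                     step_intensities = 10^seq(-2, 4, by = 0.5),
                                     backgrounds = 10^seq(-2, 5, by = 0.5),
                                     probe_photons = NULL, dt = 0.5) {
  grid <- time_grid(0, dt, round(2500 / dt))
  kernels <- build_kernels(params, dt)
  steps <- do.call(rbind, lapply(step_intensities, function(A) {
    stim <- make_pulse_stimulus(
      pulse_protocol(steps = data.frame(onset = 100, amplitude = A)), grid)
    r <- simulate_da(stim, params, kernels = kernels, keep_signals = FALSE)
    pk <- response_peak(r, after_ms = 100)
    data.frame(intensity = A, peak_mV = pk$value,
               steady_mV = steady_state_response(A, params),
               overshoot = pk$value < steady_state_response(A, params) - 1e-9)
  }))
  weber_curve <- weber_sensitivity_curve(params, backgrounds, dt = dt)
  weber <- list(curve = weber_curve, fit = weber_fit(weber_curve))
  if (is.null(probe_photons)) probe_photons <- 0.05 / params$beta
  delay <- do.call(rbind, lapply(backgrounds, function(I_B) {
    stim <- make_flash_stimulus(probe_photons, onset = 100, duration = 10,
                                background = I_B, grid = grid)
    r <- simulate_da(stim, params, kernels = kernels, keep_signals = FALSE)
    base <- steady_state_response(I_B, params)
    rr <- response_trace(grid, r$response - base)
    pk <- response_peak(rr, after_ms = 100)
    data.frame(I_B = I_B, delay_ms = pk$time_ms - 100)
  }))
  list(steps = steps, weber = weber, delay = delay)
}

#' Flicker protocols: probe ensembles and variance switching
#'
#' Monte-Carlo bundles for fluctuating inputs. `probe_ensemble` delivers
#' identical probe flashes at many times on a naturalistic surrogate
#' background and collects the probe-subtraction responses (paired-run
#' workflow); their peak amplitudes spread over a wide range and their
#' mean exceeds the mean-matched constant-background response.
#' `variance_switch` alternates the flicker contrast between two values
#' and averages the response over replicates, exposing the over/undershoot
#' transients at each switch.
#'
#' @param params a [da_params()] object.
#' @param mean_intensity background mean, photons/um^2/ms.
#' @param probe_photons probe strength, photons/um^2 (100-photon probes in
#'   the reference protocol).
#' @param n_probes number of probe times.
#' @param seed integer seed.
#' @param sd_high,sd_low contrasts for the variance-switch protocol.
#' @param switch_period_ms full period of the square-wave envelope.
#' @param n_reps replicates for the variance-switch average.
#' @param dt grid step, ms.
#' @return List with `probe_ensemble` (peaks, percentile spread, constant-
#'   background reference peak) and `variance_switch` (time, mean, sem).
#' @export
run_flicker_protocols <- function(params, mean_intensity = 100,
                                  probe_photons = 100, n_probes = 60,
                                  seed = 1, sd_high = 0.35, sd_low = 0.05,
                                  switch_period_ms = 2000, n_reps = 100,
                                  dt = 1) {
  # --- probe ensemble on the naturalistic surrogate --------------------
  dur <- 60000
  base <- make_naturalistic_surrogate(seed, dur, mean_intensity, dt = dt)
  kernels <- build_kernels(params, dt)
  r_base <- simulate_da(base, params, kernels = kernels,
                        keep_signals = FALSE)
  probe_times <- seq(2000, dur - 1500, length.out = n_probes)
  peaks <- vapply(probe_times, function(t0) {
    with_probe <- superimpose_probes(base, probe_photons, t0)
    r_p <- simulate_da(with_probe, params, kernels = kernels,
                       keep_signals = FALSE)
    inc <- response_trace(base$grid, r_p$response - r_base$response)
    response_peak(inc, after_ms = t0)$value
  }, numeric(1))
  grid_ref <- time_grid(0, dt, round(3000 / dt))
  ref_stim <- make_flash_stimulus(probe_photons, onset = 500, duration = 10,
                                  background = mean_intensity,
                                  grid = grid_ref)
  r_ref <- simulate_da(ref_stim, params, kernels = kernels,
                       keep_signals = FALSE)
  ref_peak <- response_peak(
    response_trace(grid_ref,
                   r_ref$response - steady_state_response(mean_intensity,
                                                          params)),
    after_ms = 500)$value
  qs <- stats::quantile(abs(peaks), c(0.01, 0.5, 0.99))
  probe_ensemble <- list(peaks_mV = peaks, mean_peak = mean(peaks),
                         ref_peak = ref_peak,
                         p01 = qs[[1]], p50 = qs[[2]], p99 = qs[[3]],
                         spread = qs[[3]] / qs[[1]])
  # --- variance switching ---------------------------------------------
  half <- switch_period_ms / 2
  env <- function(t) ifelse((t %% switch_period_ms) < half, sd_high, sd_low)
  n_per <- round(3 * switch_period_ms / dt)
  gridv <- time_grid(0, dt, n_per)
  acc <- matrix(0, nrow = n_per, ncol = n_reps)
  for (k in seq_len(n_reps)) {
    spec <- flicker_spec(mean_intensity, env, correlation = "exp",
                         tau_c_ms = 50, seed = seed + 7919L * k)
    stim <- make_gaussian_flicker(spec, gridv)
    acc[, k] <- simulate_da(stim, params, kernels = kernels,
                            keep_signals = FALSE)$response
  }
  variance_switch <- data.frame(
    time_ms = grid_times(gridv),
    mean_mV = rowMeans(acc),
    sem_mV = apply(acc, 1, stats::sd) / sqrt(n_reps),
    envelope = env(grid_times(gridv)))
  list(probe_ensemble = probe_ensemble, variance_switch = variance_switch)
}

#' Run a named protocol from a configuration list
#'
#' Thin dispatcher used by the command-line interface: every entry of
#' `config` is passed as an argument to the corresponding `run_*`
#' function; `config$params` may be a preset name or a parameter JSON
#' path.
#'
#' @param name one of `"flash_family"`, `"paired_flash"`, `"background"`,
#'   `"flicker"`.
#' @param config named list of arguments.
#' @return The protocol result list.
#' @export
run_protocol <- function(name = c("flash_family", "paired_flash",
                                  "background", "flicker"),
                         config = list()) {
  name <- match.arg(name)
  if (!is.null(config$params) && is.character(config$params)) {
    config$params <- if (file.exists(config$params))
      read_da_params(config$params) else da_preset(config$params)
  }
  fn <- switch(name,
               flash_family = run_flash_family,
               paired_flash = run_paired_flash,
               background = run_background_protocols,
               flicker = run_flicker_protocols)
  do.call(fn, config)
}
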