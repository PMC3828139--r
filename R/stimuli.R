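#' Flash/step pulse protocol
#'
#' Describes a constant background plus a list of pulse events.  Flashes are
#' specified by their *integrated* photon count (photons/um^2) and a
#' duration; they are rendered as boxcars whose time-integral equals the
#' requested count.  Steps are specified by an amplitude (photons/um^2/ms)
#' and persist to the end of the trace.  Negative amounts describe dark
#' flashes/steps and may not exceed the background.
#'
#' @param background constant background intensity, photons/um^2/ms.
#' @param flashes data frame with columns `onset` (ms), `photons`
#'   (integrated photons/um^2, may be negative) and optional `duration`
#'   (ms, default 10).
#' @param steps data frame with columns `onset` (ms) and `amplitude`
#'   (photons/um^2/ms, may be negative).
#' @param clip `"warn"` floors negative intensities at zero with a warning;
#'   `"error"` rejects them.
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(background = 0, flashes = NULL, steps = NULL,
                           clip = c("warn", "error")) {
  clip <- match.arg(clip)
  if (!is.null(flashes)) {
    stopifnot(all(c("onset", "photons") %in% names(flashes)))
    if (is.null(flashes$duration)) flashes$duration <- 10
    flashes <- flashes[order(flashes$onset), , drop = FALSE]
  }
  if (!is.null(steps)) {
    stopifnot(all(c("onset", "amplitude") %in% names(steps)))
    steps <- steps[order(steps$onset), , drop = FALSE]
  }
  structure(list(background = background, flashes = flashes, steps = steps,
                 clip = clip),
            class = "pulse_protocol")
}

#' Render a pulse protocol on a time grid
#'
#' @param protocol a [pulse_protocol()].
#' @param grid a [time_grid()].
#' @return A [stimulus_trace()].
#' @examples
#' g <- time_grid(0, 0.5, 2000)
#' p <- pulse_protocol(flashes = data.frame(onset = 100, photons = 41))
#' stim <- make_pulse_stimulus(p, g)
#' sum(stim$intensity) * g$dt  # integrates to 41 photons/um^2
#' @export
make_pulse_stimulus <- function(protocol, grid) {
  stopifnot(inherits(protocol, "pulse_protocol"), inherits(grid, "time_grid"))
  tm <- grid_times(grid)
  I <- rep(protocol$background, grid$n)
  fl <- protocol$flashes
  if (!is.null(fl)) {
    for (i in seq_len(nrow(fl))) {
      if (fl$duration[i] < grid$dt)
        stop("flash duration ", fl$duration[i], " ms below grid dt")
      # boxcar covering [onset, onset + duration); the rate is chosen so the
      # *discrete* integral equals the requested photon count exactly
      sel <- tm >= fl$onset[i] & tm < fl$onset[i] + fl$duration[i]
      if (!any(sel)) stop("flash at ", fl$onset[i], " ms falls off the grid")
      I[sel] <- I[sel] + fl$photons[i] / (sum(sel) * grid$dt)
    }
  }
  st <- protocol$steps
  if (!is.null(st)) {
    for (i in seq_len(nrow(st)))
      I[tm >= st$onset[i]] <- I[tm >= st$onset[i]] + st$amplitude[i]
  }
  n_neg <- sum(I < 0)
  if (n_neg > 0) {
    if (protocol$clip == "error")
      stop("protocol drives intensity negative at ", n_neg, " samples")
    warning("dark event deeper than background: clipped ", n_neg,
            " samples at zero")
    I[I < 0] <- 0
  }
  stimulus_trace(grid, I,
                 meta = list(generator = "pulse", background = protocol$background,
                             clipped = n_neg))
}

#' Single flash on a constant background (convenience wrapper)
#'
#' @param photons integrated flash strength, photons/um^2.
#' @param onset flash onset, ms.
#' @param duration flash duration, ms (default 10).
#' @param background constant background, photons/um^2/ms.
#' @param grid a [time_grid()].
#' @return A [stimulus_trace()].
#' @export
make_flash_stimulus <- function(photons, onset, duration = 10,
                                background = 0, grid) {
  make_pulse_stimulus(
    pulse_protocol(background = background,
                   flashes = data.frame(onset = onset, photons = photons,
                                        duration = duration)),
    grid)
}

#' Sinusoidal stimulus
#'
#' \eqn{I(t) = I_B (1 + c \sin 2\pi f t)} with contrast `c` defined as the
#' fractional maximum deviation from the mean; `c = 1` (100% contrast)
#' touches zero intensity.
#'
#' @param I_B mean intensity, photons/um^2/ms.
#' @param contrast in \[0, 1\].
#' @param freq_hz frequency, Hz.
#' @param grid a [time_grid()].
#' @return A [stimulus_trace()].
#' @export
make_sinusoid_stimulus <- function(I_B, contrast, freq_hz, grid) {
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]; contrast > 1 implies negative light")
  if (1000 / freq_hz < 10 * grid$dt)
    stop("frequency ", freq_hz, " Hz unresolvable at dt = ", grid$dt, " ms")
  tm <- grid_times(grid)
  I <- I_B * (1 + contrast * sin(2 * pi * freq_hz * (tm - grid$t0) / 1000))
  I[I < 0] <- 0  # guards rounding at contrast = 1
  stimulus_trace(grid, I, meta = list(generator = "sinusoid", I_B = I_B,
                                      contrast = contrast, freq_hz = freq_hz))
}

#' Gaussian flicker specification
#'
#' Gaussian flicker about a mean intensity with a deterministic
#' contrast envelope and one of two temporal-correlation models:
#' `"hold"` draws an independent Gaussian value every `hold_ms` (the CRT
#' frame-pair protocol: 2 frames at 67 Hz = 29.85 ms), `"exp"` uses a
#' stationary Ornstein-Uhlenbeck process with correlation
#' \eqn{C(\tau)=e^{-|\tau|/\tau_c}}.
#'
#' @param mean mean intensity, photons/um^2/ms.
#' @param sd_frac contrast: either a single fraction of the mean (e.g. 0.35)
#'   or a function of time (ms) returning the fractional envelope, for
#'   variance-switching protocols.
#' @param correlation `"hold"` or `"exp"`.
#' @param hold_ms hold interval for `"hold"` mode, ms.
#' @param tau_c_ms correlation time for `"exp"` mode, ms.
#' @param seed integer seed; identical seeds give identical traces.
#' @param clip `"clip"` floors negative draws at zero (counted in the trace
#'   metadata), `"error"` rejects them.
#' @return An object of class `flicker_spec`.
#' @export
flicker_spec <- function(mean, sd_frac = 0.35,
                         correlation = c("hold", "exp"),
                         hold_ms = 1000 / 67 * 2, tau_c_ms = 200,
                         seed = 1, clip = c("clip", "error")) {
  correlation <- match.arg(correlation)
  clip <- match.arg(clip)
  if (mean < 0) stop("mean intensity must be >= 0")
  if (!is.function(sd_frac) && any(sd_frac < 0)) stop("sd_frac must be >= 0")
  structure(list(mean = mean, sd_frac = sd_frac, correlation = correlation,
                 hold_ms = hold_ms, tau_c_ms = tau_c_ms,
                 seed = as.integer(seed), clip = clip),
            class = "flicker_spec")
}

#' Generate a Gaussian flicker stimulus
#'
#' Seeded and reproducible; the generated intensities have (before
#' clipping) per-sample mean `spec$mean` and standard deviation
#' `sd_frac(t) * mean`.
#'
#' @param spec a [flicker_spec()].
#' @param grid a [time_grid()].
#' @return A [stimulus_trace()]; `meta$clipped` counts floored samples and
#'   `meta$xi` is not stored (regenerate from the seed).
#' @export
make_gaussian_flicker <- function(spec, grid) {
  stopifnot(inherits(spec, "flicker_spec"), inherits(grid, "time_grid"))
  tm <- grid_times(grid)
  xi <- flicker_unit_noise(spec, grid)
  sdv <- if (is.function(spec$sd_frac)) spec$sd_frac(tm) else spec$sd_frac
  I <- spec$mean * (1 + sdv * xi)
  n_clip <- sum(I < 0)
  if (n_clip > 0 && spec$clip == "error")
    stop("flicker drove intensity negative at ", n_clip, " samples")
  I[I < 0] <- 0
  stimulus_trace(grid, I,
                 meta = list(generator = "gaussian_flicker",
                             correlation = spec$correlation,
                             hold_ms = spec$hold_ms, tau_c_ms = spec$tau_c_ms,
                             seed = spec$seed, clipped = n_clip))
}

# unit-variance correlated noise for a flicker spec (seeded, deterministic)
flicker_unit_noise <- function(spec, grid) {
  n <- grid$n
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  if (spec$correlation == "hold") {
    if (spec$hold_ms < grid$dt) stop("hold interval below grid dt")
    per <- max(1L, as.integer(round(spec$hold_ms / grid$dt)))
    n_blocks <- ceiling(n / per)
    rep(stats::rnorm(n_blocks), each = per)[seq_len(n)]
  } else {
    # stationary AR(1) = exact discretisation of an OU process:
    # xi[k] = a xi[k-1] + sqrt(1-a^2) eta[k], xi[1] ~ N(0,1)
    a <- exp(-grid$dt / spec$tau_c_ms)
    innov <- stats::rnorm(n)
    as.numeric(stats::filter(c(innov[1], sqrt(1 - a^2) * innov[-1]), a,
                             method = "recursive"))
  }
}

#' Synthetic naturalistic intensity surrogate
#'
#' A positive, heavy-tailed intensity series emulating the *stated
#' properties* of measured natural light sequences: variation over close to
#' three orders of magnitude on time scales from tens of milliseconds to
#' seconds.  Constructed as the exponential of the sum of two
#' Ornstein-Uhlenbeck processes (correlation times ~30 ms and ~3 s) in the
#' log domain, rescaled to the requested mean.  This is a synthetic
#' stand-in for (not a reproduction of) recorded natural time series.
#'
#' @param seed integer seed.
#' @param duration_ms trace duration, ms (>= 10 s recommended for the
#'   multi-scale statistics to be meaningful).
#' @param mean target mean intensity, photons/um^2/ms.
#' @param dt sample step, ms.
#' @param log_sd total standard deviation of the log-intensity (natural
#'   log); the default 1.49 gives a 1st-99th percentile span of about three
#'   decades.
#' @param tau_fast_ms,tau_slow_ms correlation times of the two log-domain
#'   components.
#' @return A [stimulus_trace()].
#' @export
make_naturalistic_surrogate <- function(seed, duration_ms, mean,
                                        dt = 1, log_sd = 1.49,
                                        tau_fast_ms = 30, tau_slow_ms = 3000) {
  grid <- time_grid(0, dt, round(duration_ms / dt))
  s_comp <- log_sd / sqrt(2)
  u1 <- flicker_unit_noise(
    flicker_spec(1, 0, "exp", tau_c_ms = tau_fast_ms, seed = seed), grid)
  u2 <- flicker_unit_noise(
    flicker_spec(1, 0, "exp", tau_c_ms = tau_slow_ms, seed = seed + 1000003L),
    grid)
  L <- s_comp * (u1 + u2)
  I <- exp(L)
  I <- I * (mean / base::mean(I))
  stimulus_trace(grid, I,
                 meta = list(generator = "naturalistic_surrogate", seed = seed,
                             log_sd = log_sd, tau_fast_ms = tau_fast_ms,
                             tau_slow_ms = tau_slow_ms,
                             synthetic = TRUE))
}

#' Superimpose probe flashes on a base stimulus
#'
#' Adds identical boxcar probe flashes at the given times, for the
#' paired-run subtraction workflow: gain is probed by subtracting the
#' response to the base trace from the response to the base trace with
#' probes.
#'
#' @param base a [stimulus_trace()].
#' @param photons integrated probe strength, photons/um^2 (100 photons on
#'   a 1 um^2 cross-section in the reference protocol).
#' @param times probe onset times, ms.
#' @param duration probe duration, ms (default 10).
#' @return A [stimulus_trace()].
#' @export
superimpose_probes <- function(base, photons, times, duration = 10) {
  stopifnot(inherits(base, "stimulus_trace"))
  tm <- grid_times(base$grid)
  if (any(times < tm[1] | times > tm[length(tm)]))
    stop("probe times outside the base trace support")
  if (length(times) > 1 && any(diff(sort(times)) < duration))
    warning("probes closer than their duration overlap")
  I <- base$intensity
  for (t0 in times) {
    sel <- tm >= t0 & tm < t0 + duration
    I[sel] <- I[sel] + photons / (sum(sel) * base$grid$dt)
  }
  meta <- base$meta
  meta$probes <- list(photons = photons, times = times, duration = duration)
  stimulus_trace(base$grid, I, meta = meta)
}
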