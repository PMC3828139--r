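#' Unit-area gamma filter
#'
#' The causal kernel \eqn{K(t) = \Theta(t)\, (t/\tau)^n e^{-t/\tau} /
#' (\Gamma(n+1)\,\tau)}, which integrates to one for any shape `n >= 0`
#' (the gamma-function generalisation of the factorial normaliser allows
#' non-integer shapes) and peaks at \eqn{t = n\tau}.
#'
#' @param t times, ms (values < 0 give 0).
#' @param n shape exponent, >= 0.
#' @param tau time constant, ms.
#' @return Kernel values, 1/ms.
#' @export
gamma_kernel <- function(t, n, tau) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(n * log(t[pos] / tau) - t[pos] / tau -
                    lgamma(n + 1)) / tau
  if (n == 0) out[t == 0] <- 1 / tau
  out
}

#' Discretise the DA model kernels
#'
#' Builds the discretised response kernel `ky` and gain-control kernel
#' `kz = gamma * ky + (1 - gamma) * ks` on a uniform grid of lag offsets
#' `0, dt, 2 dt, ...`.  The support is extended until the analytic tail mass
#' of every component falls below `tail_tol`, and each component is then
#' renormalised so its discrete sum times `dt` is exactly one; consequently
#' `kz` inherits unit normalisation for any `gamma` and equals `ky`
#' samplewise when `gamma = 1`.
#'
#' @param params a [da_params()] object.
#' @param dt sample step, ms.  Must satisfy `dt <= tau_y / 4` so the fast
#'   kernel is resolved.
#' @param tail_tol maximum analytic tail mass dropped by truncation.
#' @param t_max optional support override, ms; an error is raised if the
#'   implied tail mass exceeds `tail_tol`.
#' @return An object of class `kernel_pair`: list with `lags`, `ky`, `kz`,
#'   `dt`, and `tail_mass` (the analytic mass beyond the support, per
#'   component, before renormalisation).
#' @examples
#' kp <- build_kernels(da_preset("BHL"), dt = 0.5)
#' sum(kp$ky) * kp$dt  # exactly 1
#' @export
build_kernels <- function(params, dt, tail_tol = 1e-6, t_max = NULL) {
  stopifnot(inherits(params, "da_params"))
  if (dt > params$tau_y / 4 || dt > params$tau_z / 4)
    stop("dt = ", dt, " ms is too coarse: require dt <= min(tau_y, tau_z)/4")
  t_need <- max(
    stats::qgamma(tail_tol, shape = params$n_y + 1, scale = params$tau_y,
                  lower.tail = FALSE),
    stats::qgamma(tail_tol, shape = params$n_z + 1, scale = params$tau_z,
                  lower.tail = FALSE))
  if (is.null(t_max)) {
    t_max <- t_need
  } else if (t_max < t_need) {
    tm <- max(
      stats::pgamma(t_max, shape = params$n_y + 1, scale = params$tau_y,
                    lower.tail = FALSE),
      stats::pgamma(t_max, shape = params$n_z + 1, scale = params$tau_z,
                    lower.tail = FALSE))
    stop("kernel support t_max = ", t_max, " ms leaves analytic tail mass ",
         signif(tm, 3), " > ", tail_tol)
  }
  lags <- seq(0, t_max + dt, by = dt)
  ky_raw <- gamma_kernel(lags, params$n_y, params$tau_y)
  ks_raw <- gamma_kernel(lags, params$n_z, params$tau_z)
  tail_y <- stats::pgamma(max(lags), shape = params$n_y + 1,
                          scale = params$tau_y, lower.tail = FALSE)
  tail_s <- stats::pgamma(max(lags), shape = params$n_z + 1,
                          scale = params$tau_z, lower.tail = FALSE)
  ky <- ky_raw / (sum(ky_raw) * dt)
  ks <- ks_raw / (sum(ks_raw) * dt)
  kz <- params$gamma * ky + (1 - params$gamma) * ks
  structure(list(lags = lags, ky = ky, kz = kz, ks = ks, dt = dt,
                 tail_mass = c(ky = tail_y, ks = tail_s)),
            class = "kernel_pair")
}

#' @export
print.kernel_pair <- function(x, ...) {
  cm <- function(k) sum(x$lags * k) * x$dt
  cat(sprintf(
    "kernel_pair: %d taps, dt = %g ms, support %g ms\n", length(x$ky),
    x$dt, max(x$lags)))
  cat(sprintf("  centre of mass: ky %.1f ms, kz %.1f ms\n",
              cm(x$ky), cm(x$kz)))
  invisible(x)
}

# Causal FIR filtering by FFT; x is padded on the left with `pad` so that
# the first output sample sees a constant pre-history.
causal_fir_fft <- function(x, h, pad) {
  n <- length(x)
  k <- length(h)
  xp <- c(rep(pad, k - 1), x)
  m <- length(xp) + k - 1
  nf <- 2^ceiling(log2(m))
  X <- stats::fft(c(xp, rep(0, nf - length(xp))))
  H <- stats::fft(c(h, rep(0, nf - k)))
  conv <- Re(stats::fft(X * H, inverse = TRUE)) / nf
  conv[k:(k + n - 1)]
}

#' Filter a stimulus through the DA kernels
#'
#' Computes the filtered signals \eqn{y = K_y * I} and \eqn{z = K_z * I}
#' by causal discrete convolution (scaled by `dt`).  Because the kernels
#' integrate to one, a constant input `I_B` yields `y = z = I_B`.
#'
#' @param stim a [stimulus_trace()].
#' @param kernels a [build_kernels()] result on the same `dt`.
#' @param boundary pre-history policy for the first kernel-length of
#'   samples: `"hold"` extends the initial intensity backwards in time
#'   (consistent with a steady pre-stimulus state), `"zero"` assumes
#'   darkness before the trace.
#' @return A list with numeric vectors `y` and `z` on the stimulus grid.
#' @export
filter_signals <- function(stim, kernels, boundary = c("hold", "zero")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(stim, "stimulus_trace"), inherits(kernels, "kernel_pair"))
  if (abs(stim$grid$dt - kernels$dt) > 1e-9 * kernels$dt)
    stop("stimulus dt (", stim$grid$dt, ") != kernel dt (", kernels$dt, ")")
  pad <- if (boundary == "hold") stim$intensity[1] else 0
  dt <- kernels$dt
  list(y = causal_fir_fft(stim$intensity, kernels$ky, pad) * dt,
       z = causal_fir_fft(stim$intensity, kernels$kz, pad) * dt)
}

#' Zero-crossing (node) time of the biphasic bright-background response
#'
#' In a very bright background the flash response is proportional to
#' \eqn{K_y - K_z} (for weak flashes), so its zero crossing sits where the
#' two kernels intersect; the node time is located on the discretised
#' kernels with local linear interpolation, and is independent of flash
#' strength.
#'
#' @param params a [da_params()] object.
#' @param dt internal resolution, ms.
#' @return Node time in ms (NA when `gamma = 1`, where the kernels
#'   coincide).
#' @export
kernel_node_time <- function(params, dt = 0.05) {
  if (params$gamma >= 1) return(NA_real_)
  kp <- build_kernels(params, dt)
  d <- kp$ky - kp$kz
  # first sign change after the early positive lobe
  i0 <- which(d > 0)[1]
  if (is.na(i0)) return(NA_real_)
  idx <- which(d[-1] <= 0 & d[-length(d)] > 0)
  idx <- idx[idx >= i0]
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  # linear interpolation between lag i and i+1
  frac <- d[i] / (d[i] - d[i + 1])
  kp$lags[i] + frac * dt
}
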