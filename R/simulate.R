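#' Closed-form steady-state response to constant light
#'
#' Setting \eqn{dR/dt = 0} with \eqn{y = z = I_B} gives
#' \eqn{R_\infty = \alpha_s I_B / (1 + \beta I_B)} (with the hyperpolarising
#' sign \eqn{\alpha_s = -\alpha}): linear in dim light, saturating at
#' \eqn{-\alpha/\beta} for bright light.
#'
#' @param I_B constant background intensity, photons/um^2/ms (>= 0).
#' @param params a [da_params()] object.
#' @return Steady-state response, mV (<= 0).
#' @examples
#' steady_state_response(1e6, da_preset("BHL"))  # ~ -25 mV
#' @export
steady_state_response <- function(I_B, params) {
  if (any(I_B < 0)) stop("I_B must be nonnegative")
  alpha_signed(params) * I_B / (1 + params$beta * I_B)
}

da_prepare <- function(stim, params, kernels = NULL,
                       boundary = "hold") {
  if (is.null(kernels)) kernels <- build_kernels(params, stim$grid$dt)
  sig <- filter_signals(stim, kernels, boundary = boundary)
  R0 <- if (boundary == "hold")
    steady_state_response(stim$intensity[1], params) else 0
  list(kernels = kernels, y = sig$y, z = sig$z, R0 = R0)
}

#' Simulate the DA model (exponential-Euler integrator)
#'
#' Integrates \eqn{\tau_r\, dR/dt = \alpha_s y - (1+\beta z) R} with an
#' exponential-Euler update that is exact for signals held constant across
#' a step and unconditionally stable: when the effective time constant
#' \eqn{\tau_r/(1+\beta z)} falls below the step the update relaxes to the
#' local algebraic response \eqn{\alpha_s y/(1+\beta z)} instead of
#' diverging.  The default initial condition is the steady state for the
#' stimulus value at the first sample (`boundary = "hold"`).
#'
#' @param stim a [stimulus_trace()].
#' @param params a [da_params()] object.
#' @param kernels optional precomputed [build_kernels()] (must share `dt`).
#' @param boundary pre-history policy, see [filter_signals()].
#' @param keep_signals attach the filtered signals `y`, `z` to the result.
#' @return A [response_trace()].
#' @examples
#' g <- time_grid(0, 0.5, 4000)
#' stim <- make_flash_stimulus(1000, onset = 100, grid = g)
#' r <- simulate_da(stim, da_preset("BHL"))
#' min(r$response)  # peak hyperpolarisation, mV
#' @export
simulate_da <- function(stim, params, kernels = NULL,
                        boundary = c("hold", "zero"), keep_signals = TRUE) {
  boundary <- match.arg(boundary)
  dt <- stim$grid$dt
  if (dt > params$tau_r / 4)
    stop("dt = ", dt, " ms too coarse for tau_r = ", params$tau_r, " ms")
  pre <- da_prepare(stim, params, kernels, boundary)
  R <- da_integrate_expeuler(pre$y, pre$z, dt, params$tau_r,
                             alpha_signed(params), params$beta, pre$R0)
  response_trace(stim$grid, R,
                 y = if (keep_signals) pre$y else NULL,
                 z = if (keep_signals) pre$z else NULL,
                 meta = list(method = "expeuler", params = params$label))
}

#' Simulate the DA model from its exact solution
#'
#' Evaluates the closed-form solution
#' \deqn{R(t) = \frac{\alpha_s}{\tau_r}\int_{-\infty}^{t} y(t')\,
#'   \exp\!\Big(-\frac{1}{\tau_r}\int_{t'}^{t}\big(1+\beta z(s)\big)\,ds\Big)
#'   dt'}
#' by trapezoidal quadrature with incremental (O(n)) accumulation of the
#' exponent.  Serves as the primary cross-oracle for [simulate_da()]; the
#' two integrators discretise differently and agree to O(dt^2).
#'
#' @inheritParams simulate_da
#' @return A [response_trace()].
#' @export
simulate_da_exact <- function(stim, params, kernels = NULL,
                              boundary = c("hold", "zero"),
                              keep_signals = TRUE) {
  boundary <- match.arg(boundary)
  dt <- stim$grid$dt
  if (dt > params$tau_r / 4)
    stop("dt = ", dt, " ms too coarse for tau_r = ", params$tau_r, " ms")
  pre <- da_prepare(stim, params, kernels, boundary)
  R <- da_integrate_exact(pre$y, pre$z, dt, params$tau_r,
                          alpha_signed(params), params$beta, pre$R0)
  response_trace(stim$grid, R,
                 y = if (keep_signals) pre$y else NULL,
                 z = if (keep_signals) pre$z else NULL,
                 meta = list(method = "exact", params = params$label))
}

#' Instantaneous algebraic (small relaxation-time) response
#'
#' In the limit of small \eqn{\tau_r/(1+\beta z)} relative to the stimulus
#' time scales the DA equation becomes algebraic:
#' \eqn{R(t) = \alpha_s y(t) / (1 + \beta z(t))}.  The same form governs
#' the bright-background regime, where the response depends on the input
#' only through the ratio \eqn{y/z}.
#'
#' @inheritParams simulate_da
#' @return A [response_trace()].
#' @export
algebraic_limit_response <- function(stim, params, kernels = NULL,
                                     boundary = c("hold", "zero"),
                                     keep_signals = TRUE) {
  boundary <- match.arg(boundary)
  pre <- da_prepare(stim, params, kernels, boundary)
  R <- alpha_signed(params) * pre$y / (1 + params$beta * pre$z)
  response_trace(stim$grid, R,
                 y = if (keep_signals) pre$y else NULL,
                 z = if (keep_signals) pre$z else NULL,
                 meta = list(method = "algebraic", params = params$label))
}

#' Locate a response extremum with sub-grid refinement
#'
#' Finds the global extremum of the (hyperpolarising) response after a
#' given onset and refines its position by a local parabolic fit, so that
#' peak-delay comparisons are meaningful below the grid step.
#'
#' @param resp a [response_trace()].
#' @param after_ms only consider samples at or after this time.
#' @param sign `-1` for the hyperpolarising extremum (minimum, default),
#'   `+1` for a depolarising one.
#' @return List with `time_ms`, `value` (mV) and `index`.
#' @export
response_peak <- function(resp, after_ms = -Inf, sign = -1) {
  tm <- grid_times(resp$grid)
  ok <- which(tm >= after_ms)
  if (!length(ok)) stop("no samples at or after after_ms")
  v <- sign * resp$response[ok]
  i <- ok[which.max(v)]
  t_pk <- tm[i]
  v_pk <- resp$response[i]
  if (i > 1 && i < length(tm)) {
    a <- resp$response[i - 1]; b <- resp$response[i]; c <- resp$response[i + 1]
    den <- a - 2 * b + c
    if (abs(den) > 0) {
      delta <- 0.5 * (a - c) / den
      if (abs(delta) <= 1) {
        t_pk <- tm[i] + delta * resp$grid$dt
        v_pk <- b - 0.25 * (a - c) * delta
      }
    }
  }
  list(time_ms = t_pk, value = v_pk, index = i)
}
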