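#' Fit a linear-nonlinear (LN) cascade model
#'
#' Estimates a causal linear filter by (optionally ridge-regularised)
#' least squares on lagged copies of the stimulus — the whitened
#' cross-correlation estimator — followed by a static polynomial
#' nonlinearity fitted between the linear prediction and the response.
#' For white (uncorrelated) stimuli, `method = "xcorr"` provides the plain
#' cross-correlation estimate.
#'
#' @param stim a [stimulus_trace()].
#' @param resp a [response_trace()] on the same grid.
#' @param filter_ms filter duration, ms (500 ms in the reference
#'   analysis).
#' @param degree degree of the static polynomial (3 in the reference
#'   analysis).
#' @param method `"ridge"` (regularisation chosen by generalised
#'   cross-validation) or `"xcorr"`.
#' @param lambda optional fixed ridge penalty (overrides GCV).
#' @return An object of class `ln_model`: the filter (units
#'   mV per photons/um^2/ms per ms), the training stimulus mean, the
#'   polynomial coefficients (intercept first), and fit diagnostics
#'   (`r_squared`, `rms_resid` in response-s.d. units).
#' @export
estimate_ln <- function(stim, resp, filter_ms = 500, degree = 3,
                        method = c("ridge", "xcorr"), lambda = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stim, "stimulus_trace"), inherits(resp, "response_trace"))
  if (!same_grid(stim$grid, resp$grid)) stop("stim and resp must share a grid")
  dt <- stim$grid$dt
  K <- as.integer(round(filter_ms / dt))
  n <- stim$grid$n
  if (n < 4 * K) stop("trace too short relative to the filter duration")
  x <- stim$intensity - mean(stim$intensity)
  r <- resp$response
  X <- lag_matrix(x, K)              # rows K..n, cols = lags 0..K-1
  ruse <- r[K:n]
  XtX <- crossprod(X)
  Xtr <- crossprod(X, ruse - mean(ruse))
  sv <- svd(XtX, nu = 0, nv = 0)$d
  if (max(sv) <= 0 || (min(sv) < 1e-12 * max(sv) && method == "xcorr"))
    stop("stimulus covariance is near-singular (constant input?)")
  if (method == "xcorr") {
    f <- as.numeric(Xtr) / diag(XtX)
  } else {
    if (is.null(lambda)) {
      lambdas <- max(sv) * 10^seq(-10, -1, length.out = 12)
      gcv <- vapply(lambdas, function(l) {
        A <- XtX + diag(l, K)
        fl <- solve(A, Xtr)
        fit <- X %*% fl
        res <- (ruse - mean(ruse)) - fit
        edf <- sum(sv / (sv + l))
        sum(res^2) / (length(ruse) * (1 - edf / length(ruse))^2)
      }, numeric(1))
      lambda <- lambdas[which.min(gcv)]
    }
    f <- as.numeric(solve(XtX + diag(lambda, K), Xtr))
  }
  u <- as.numeric(X %*% f)
  # static nonlinearity: degree-3 polynomial of the linear prediction
  pf <- stats::lm(ruse ~ stats::poly(u, degree, raw = TRUE))
  coefs <- unname(stats::coef(pf))
  pred <- as.numeric(stats::fitted(pf))
  r2 <- 1 - sum((ruse - pred)^2) / sum((ruse - mean(ruse))^2)
  rms <- sqrt(mean((ruse - pred)^2)) / stats::sd(ruse)
  structure(list(filter = f, dt = dt, filter_ms = filter_ms,
                 stim_mean = mean(stim$intensity), degree = degree,
                 poly_coef = coefs, lambda = lambda, method = method,
                 r_squared = r2, rms_resid = rms),
            class = "ln_model")
}

lag_matrix <- function(x, K) {
  n <- length(x)
  idx <- outer(K:n, 0:(K - 1), `-`)
  matrix(x[idx], nrow = n - K + 1L)
}

eval_poly <- function(coefs, u) {
  out <- rep(coefs[1], length(u))
  up <- u
  for (j in seq_along(coefs)[-1]) {
    out <- out + coefs[j] * up
    up <- up * u
  }
  out
}

#' Predict a response with an LN model
#'
#' Convolves the (mean-subtracted) stimulus with the fitted filter and
#' evaluates the static polynomial on the linear prediction.  Causal and
#' deterministic.
#'
#' @param model an [estimate_ln()] result.
#' @param stim a [stimulus_trace()] at the model's `dt`.
#' @return A [response_trace()].
#' @export
ln_predict <- function(model, stim) {
  stopifnot(inherits(model, "ln_model"), inherits(stim, "stimulus_trace"))
  if (abs(stim$grid$dt - model$dt) > 1e-9 * model$dt)
    stop("stimulus dt does not match the LN model dt")
  u <- ln_linear_prediction(model, stim)
  response_trace(stim$grid, eval_poly(model$poly_coef, u),
                 meta = list(method = "ln"))
}

# linear stage only (used by both prediction and gain analyses)
ln_linear_prediction <- function(model, stim) {
  x <- stim$intensity - model$stim_mean
  causal_fir_fft(x, model$filter, pad = 0)
}

#' Instantaneous-gain time series
#'
#' The instantaneous gain at a time t is the OLS slope of the scatter of
#' the observed response against the model's linear prediction, with
#' scatter points drawn from the `flank_ms` windows flanking t.  Gains are
#' then averaged over `window_ms` windows spaced every `every_ms`, and
#' each window is paired with the mean light intensity over the
#' `window_ms` immediately preceding its centre.
#'
#' @param stim,resp the stimulus and observed response (shared grid).
#' @param model an [estimate_ln()] result (its linear stage is used).
#' @param flank_ms half-window for the local slope (150 ms in the
#'   reference analysis, i.e. 300 ms of scatter per time point).
#' @param window_ms,every_ms averaging window and spacing (300/100 ms).
#' @return An object of class `gain_profile`: data frame with columns
#'   `center_ms`, `gain`, `mean_prev_intensity`; windows whose scatter is
#'   degenerate carry `NA` gain.
#' @export
instantaneous_gain_series <- function(stim, resp, model, flank_ms = 150,
                                      window_ms = 300, every_ms = 100) {
  stopifnot(inherits(model, "ln_model"))
  if (!same_grid(stim$grid, resp$grid)) stop("stim and resp must share a grid")
  dt <- stim$grid$dt
  u <- ln_linear_prediction(model, stim)
  r <- resp$response
  tm <- grid_times(stim$grid)
  K <- as.integer(round(model$filter_ms / dt))
  half <- as.integer(round(flank_ms / dt))
  # evaluation times: every `every_ms`, leaving room for the filter
  # warm-up, the flanking window, and the preceding-intensity window
  lead <- max(K, half, as.integer(round(window_ms / dt)))
  centers <- seq(from = tm[1] + (lead + 1) * dt,
                 to = tm[length(tm)] - (half + 1) * dt, by = every_ms)
  rows <- lapply(centers, function(tc) {
    i <- which.min(abs(tm - tc))
    sel <- max(1, i - half):min(length(r), i + half)
    uu <- u[sel]; rr <- r[sel]
    g <- if (stats::var(uu) < .Machine$double.eps * 100) NA_real_ else
      stats::cov(uu, rr) / stats::var(uu)
    prev <- (i - as.integer(round(window_ms / dt))):(i - 1)
    data.frame(center_ms = tm[i], gain = g,
               mean_prev_intensity = mean(stim$intensity[prev]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gain_profile", class(out))
  out
}

#' Percentile-grouped gain analysis
#'
#' Splits the instantaneous-gain values into percentile groups and, per
#' group, computes (i) the average stimulus-response cross-correlation of
#' the zero-padded member windows and its peak-correlation lag, and (ii) a
#' group linear filter (cross-correlation estimate restricted to member
#' windows).  Also reports the corrective-gain slopes of response against
#' prediction for the windows whose preceding mean intensity falls in the
#' dimmest and brightest `percentile` fraction: on adapting data the
#' dim-history slope exceeds the bright-history slope when the prediction
#' lacks dynamical gain control.
#'
#' @param profile an [instantaneous_gain_series()] result.
#' @param stim,resp the traces used to build the profile.
#' @param prediction a [response_trace()] of model predictions (linear,
#'   LN or DA) used for the corrective-gain slopes.
#' @param percentile fraction defining the extreme history groups
#'   (default 0.1).
#' @param n_groups number of percentile groups (default 10).
#' @param window_ms member-window length for cross-correlations.
#' @param min_windows below this many windows per group, the timing
#'   statistics are flagged unreliable.
#' @return A list with `groups` (per-group gain, peak cross-correlation
#'   lag in ms, window count, reliability flag), `filters` (matrix, one
#'   column per group), `corrective` (slopes for dim/bright history) and
#'   `slope_diff` (dim minus bright).
#' @export
grouped_gain_analysis <- function(profile, stim, resp, prediction,
                                  percentile = 0.1, n_groups = 10,
                                  window_ms = 300, min_windows = 30) {
  stopifnot(inherits(profile, "gain_profile"))
  ok <- !is.na(profile$gain)
  prof <- profile[ok, ]
  dt <- stim$grid$dt
  tm <- grid_times(stim$grid)
  half <- as.integer(round(window_ms / dt / 2))
  qs <- stats::quantile(prof$gain, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- cut(prof$gain, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  x <- stim$intensity - mean(stim$intensity)
  r <- resp$response - mean(resp$response)
  max_lag <- half
  lags <- (-max_lag):max_lag
  xcors <- matrix(0, nrow = length(lags), ncol = max(grp))
  filters <- matrix(0, nrow = half + 1, ncol = max(grp))
  counts <- integer(max(grp))
  for (g in seq_len(max(grp))) {
    idx <- which(grp == g)
    counts[g] <- length(idx)
    acc <- numeric(length(lags))
    facc <- numeric(half + 1)
    for (i in idx) {
      c0 <- which.min(abs(tm - prof$center_ms[i]))
      sel <- (c0 - half):(c0 + half)
      sel <- sel[sel >= 1 & sel <= length(x)]
      xs <- numeric(2 * half + 1)
      rs <- numeric(2 * half + 1)
      xs[sel - (c0 - half) + 1] <- x[sel]   # zero-padded windows
      rs[sel - (c0 - half) + 1] <- r[sel]
      cc <- vapply(lags, function(L) {
        if (L >= 0) sum(xs[1:(length(xs) - L)] * rs[(1 + L):length(rs)])
        else sum(xs[(1 - L):length(xs)] * rs[1:(length(rs) + L)])
      }, numeric(1))
      acc <- acc + cc
      facc <- facc + vapply(0:half, function(L)
        sum(xs[1:(length(xs) - L)] * rs[(1 + L):length(rs)]), numeric(1))
    }
    xcors[, g] <- acc / max(1, counts[g])
    filters[, g] <- facc / max(1, counts[g])
  }
  # peak lag of the averaged (negated: hyperpolarising) cross-correlation
  peak_lag <- vapply(seq_len(ncol(xcors)), function(g) {
    lags[which.max(abs(xcors[, g]))] * dt
  }, numeric(1))
  gain_mean <- vapply(seq_len(max(grp)), function(g)
    mean(prof$gain[grp == g]), numeric(1))
  groups <- data.frame(group = seq_len(max(grp)), gain = gain_mean,
                       peak_xcorr_ms = peak_lag, n_windows = counts,
                       reliable = counts >= min_windows)
  corrective <- corrective_gain_slopes(profile, resp, prediction,
                                       percentile = percentile)
  list(groups = groups, filters = filters, filter_lags_ms = (0:half) * dt,
       corrective = corrective$slopes,
       slope_diff = corrective$slope_diff)
}

#' Corrective-gain slopes for extreme intensity histories
#'
#' Response-versus-prediction regression slopes restricted to the sample
#' windows whose preceding mean intensity lies in the dimmest and
#' brightest `percentile` fraction of the trace.
#'
#' @param profile an [instantaneous_gain_series()] result.
#' @param resp observed [response_trace()].
#' @param prediction model-prediction [response_trace()].
#' @param percentile extreme fraction (default 0.1).
#' @param window_ms scatter window around each profile centre.
#' @return List with `slopes` (data frame: subset dim/bright, slope, n)
#'   and `slope_diff` (dim minus bright).
#' @export
corrective_gain_slopes <- function(profile, resp, prediction,
                                   percentile = 0.1, window_ms = 300) {
  ok <- !is.na(profile$gain)
  prof <- profile[ok, ]
  dt <- resp$grid$dt
  tm <- grid_times(resp$grid)
  half <- as.integer(round(window_ms / dt / 2))
  lo <- stats::quantile(prof$mean_prev_intensity, percentile)
  hi <- stats::quantile(prof$mean_prev_intensity, 1 - percentile)
  slope_for <- function(centers) {
    sel <- unique(unlist(lapply(centers, function(tc) {
      i <- which.min(abs(tm - tc))
      max(1, i - half):min(length(tm), i + half)
    })))
    p <- prediction$response[sel]
    o <- resp$response[sel]
    if (stats::var(p) < .Machine$double.eps * 100) return(c(NA_real_, length(sel)))
    c(stats::cov(p, o) / stats::var(p), length(sel))
  }
  dim_s <- slope_for(prof$center_ms[prof$mean_prev_intensity <= lo])
  bri_s <- slope_for(prof$center_ms[prof$mean_prev_intensity >= hi])
  slopes <- data.frame(subset = c("dim", "bright"),
                       slope = c(dim_s[1], bri_s[1]),
                       n = c(dim_s[2], bri_s[2]))
  list(slopes = slopes, slope_diff = dim_s[1] - bri_s[1])
}

#' Circular-shift Monte-Carlo p-value
#'
#' Significance of a stimulus-response statistic by circular-shift
#' shuffling: the response is rotated by random temporal offsets (circular
#' boundary conditions) and the two-sided empirical p-value is the
#' add-one-corrected frequency with which the shuffled statistic's
#' absolute value reaches the observed one:
#' `(1 + #\{|shuffled| >= |observed|\}) / (1 + n_shuffles)`.  The add-one
#' correction avoids p = 0 artifacts and is negligible at thousands of
#' shuffles.
#'
#' @param statistic_fn pure function of `(stim, resp)` returning a scalar.
#' @param stim,resp the traces.
#' @param n_shuffles number of random shifts (3000 in the reference
#'   analysis; >= 100 required).
#' @param seed integer seed.
#' @param exclude_ms shifts within this distance of zero (and of the trace
#'   length) are excluded, so shuffles are genuinely decorrelated; defaults
#'   to 500 ms.
#' @return List with `p_value`, `observed`, and the shuffled statistics.
#' @export
circular_shift_pvalue <- function(statistic_fn, stim, resp, n_shuffles = 1000,
                                  seed = 1, exclude_ms = 500) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  observed <- statistic_fn(stim, resp)
  n <- resp$grid$n
  excl <- as.integer(round(exclude_ms / resp$grid$dt))
  if (2 * excl >= n) stop("trace too short for the requested exclusion zone")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  shifts <- sample((excl + 1):(n - excl - 1), n_shuffles, replace = TRUE)
  shuffled <- vapply(shifts, function(s) {
    r2 <- resp
    r2$response <- c(resp$response[(s + 1):n], resp$response[1:s])
    statistic_fn(stim, r2)
  }, numeric(1))
  p <- (1 + sum(abs(shuffled) >= abs(observed))) / (1 + n_shuffles)
  list(p_value = p, observed = observed, shuffled = shuffled)
}
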