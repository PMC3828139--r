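#' Goodness-of-fit Q
#'
#' \eqn{Q = 1 - \sum_i \mathrm{SSE}_i \,/\, \sum_i n_i \mathrm{Var}_i}:
#' the total squared error across traces, normalised by the total
#' variance of the observed traces (each trace's variance weighted by its
#' sample count, i.e. the sum of squares about per-trace means).  Q = 1
#' for a perfect prediction; predicting each trace's mean gives Q = 0.
#' Invariant to the order of the traces.
#'
#' @param predictions a [response_trace()] or list of them.
#' @param observations matching observed trace(s).
#' @return Q (dimensionless, <= 1).
#' @export
goodness_of_fit <- function(predictions, observations) {
  preds <- if (inherits(predictions, "response_trace")) list(predictions)
  else predictions
  obs <- if (inherits(observations, "response_trace")) list(observations)
  else observations
  if (length(preds) != length(obs)) stop("trace sets differ in length")
  sse <- 0; ssv <- 0
  for (i in seq_along(preds)) {
    p <- preds[[i]]$response; o <- obs[[i]]$response
    if (length(p) != length(o)) stop("trace ", i, ": length mismatch")
    v <- sum((o - mean(o))^2)
    if (v == 0) stop("trace ", i, " has zero variance; Q is undefined")
    sse <- sse + sum((p - o)^2)
    ssv <- ssv + v
  }
  1 - sse / ssv
}

da_free_names <- c("alpha", "beta", "gamma", "tau_r",
                   "n_y", "tau_y", "n_z", "tau_z")

da_default_bounds <- function() {
  list(lower = c(alpha = 1e-4, beta = 1e-7, gamma = 1e-3, tau_r = 0.5,
                 n_y = 0.1, tau_y = 0.5, n_z = 0.1, tau_z = 0.5),
       upper = c(alpha = 1e4, beta = 10, gamma = 1 - 1e-3, tau_r = 1e3,
                 n_y = 40, tau_y = 1e3, n_z = 40, tau_z = 1e3))
}

# log transform for positive parameters, logit for gamma
to_theta <- function(vals, names) {
  vapply(names, function(nm)
    if (nm == "gamma") stats::qlogis(vals[[nm]]) else log(vals[[nm]]),
    numeric(1))
}
from_theta <- function(theta, names, fixed) {
  out <- fixed
  for (i in seq_along(names)) {
    nm <- names[i]
    out[[nm]] <- unname(if (nm == "gamma") stats::plogis(theta[[i]])
                        else exp(theta[[i]]))
  }
  out
}

da_predict_for_fit <- function(vals, stims, kernels_dt_cache = NULL) {
  p <- da_params(alpha = 1, beta = vals$beta, gamma = vals$gamma,
                 tau_r = vals$tau_r, n_y = vals$n_y, tau_y = vals$tau_y,
                 n_z = vals$n_z, tau_z = vals$tau_z)
  lapply(stims, function(s) {
    simulate_da(s, p, keep_signals = FALSE)$response  # alpha = 1 basis
  })
}

da_fit_objective <- function(vals, stims, resps, per_trace_alpha) {
  base <- tryCatch(da_predict_for_fit(vals, stims),
                   error = function(e) NULL)
  if (is.null(base)) return(list(sse = 1e12, alphas = NULL))
  sse <- 0
  alphas <- numeric(length(stims))
  for (i in seq_along(stims)) {
    o <- resps[[i]]$response
    p1 <- base[[i]]
    a <- if (per_trace_alpha) {
      denom <- sum(p1^2)
      if (denom == 0) 0 else max(0, sum(o * p1) / denom)
    } else vals$alpha
    alphas[i] <- a
    sse <- sse + sum((o - a * p1)^2)
  }
  list(sse = sse, alphas = alphas)
}

#' Fit the DA model to stimulus/response trace pairs
#'
#' Bounded quasi-Newton least squares over the free parameters, on a
#' log/logit-transformed scale, with optional multi-start.  The response
#' is exactly proportional to `alpha`, so with `per_trace_alpha = TRUE`
#' the gain of each trace is profiled out in closed form (the
#' experiment-to-experiment gain adjustment used with shared kernels).
#' `integer_shapes = TRUE` constrains `n_y` and `n_z` to integers by
#' refitting the remaining parameters over the neighbouring integer
#' combinations of the continuous optimum.
#'
#' @param stims list of [stimulus_trace()]s.
#' @param resps matching list of observed [response_trace()]s.
#' @param init a [da_params()] starting point.
#' @param free character vector of parameters to optimise (default: all
#'   eight).
#' @param bounds list with named `lower`/`upper` vectors (defaults span
#'   the physiological range).
#' @param per_trace_alpha profile a separate gain per trace.
#' @param integer_shapes constrain `n_y`, `n_z` to integers.
#' @param n_starts number of optimisation starts (the first is `init`,
#'   the rest are seeded log-normal jitters of it).
#' @param seed seed for the start jitter.
#' @param maxit iteration cap per start.
#' @return An object of class `da_fit`: `params` (fitted [da_params()]),
#'   `Q`, `sse`, `alphas` (per-trace gains when profiled), `convergence`
#'   (0 = converged), `at_bounds` (names of parameters pinned at a
#'   bound), `starts` (per-start summary).
#' @export
fit_da_model <- function(stims, resps, init, free = da_free_names,
                         bounds = da_default_bounds(),
                         per_trace_alpha = FALSE, integer_shapes = FALSE,
                         n_starts = 1, seed = 1, maxit = 300) {
  stopifnot(length(stims) >= 1, length(stims) == length(resps),
            inherits(init, "da_params"))
  free <- match.arg(free, da_free_names, several.ok = TRUE)
  if (per_trace_alpha) free <- setdiff(free, "alpha")
  fixed <- unclass(init)[da_free_names]
  # the integrator requires time constants resolved by the trace step
  dt_max <- max(vapply(stims, function(s) s$grid$dt, numeric(1)))
  for (nm in c("tau_r", "tau_y", "tau_z"))
    bounds$lower[nm] <- max(bounds$lower[nm], 4.05 * dt_max)
  obj <- function(theta) {
    vals <- from_theta(theta, free, fixed)
    da_fit_objective(vals, stims, resps, per_trace_alpha)$sse
  }
  lo <- to_theta(as.list(bounds$lower[free]), free)
  hi <- to_theta(as.list(bounds$upper[free]), free)
  theta0 <- pmin(pmax(to_theta(fixed[free], free), lo), hi)
  starts <- list(theta0)
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- pmin(pmax(theta0 + stats::rnorm(length(theta0),
                                                         sd = 0.3), lo), hi)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  runs <- lapply(starts, function(th) {
    stats::optim(th, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = maxit, factr = 1e9))
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]

  if (integer_shapes && any(c("n_y", "n_z") %in% free)) {
    vals <- from_theta(best$par, free, fixed)
    cand_ny <- if ("n_y" %in% free)
      unique(pmax(1, c(floor(vals$n_y), ceiling(vals$n_y)))) else vals$n_y
    cand_nz <- if ("n_z" %in% free)
      unique(pmax(1, c(floor(vals$n_z), ceiling(vals$n_z)))) else vals$n_z
    sub_free <- setdiff(free, c("n_y", "n_z"))
    best_int <- NULL
    for (ny in cand_ny) for (nz in cand_nz) {
      fx <- fixed; fx$n_y <- ny; fx$n_z <- nz
      for (nm in sub_free) fx[[nm]] <- vals[[nm]]
      o2 <- function(theta) {
        v <- from_theta(theta, sub_free, fx)
        da_fit_objective(v, stims, resps, per_trace_alpha)$sse
      }
      r2 <- stats::optim(to_theta(fx[sub_free], sub_free), o2,
                         method = "L-BFGS-B",
                         lower = to_theta(as.list(bounds$lower[sub_free]),
                                          sub_free),
                         upper = to_theta(as.list(bounds$upper[sub_free]),
                                          sub_free),
                         control = list(maxit = maxit, factr = 1e9))
      if (is.null(best_int) || r2$value < best_int$value)
        best_int <- list(value = r2$value, par = r2$par, n_y = ny, n_z = nz,
                         convergence = r2$convergence)
    }
    fixed$n_y <- best_int$n_y; fixed$n_z <- best_int$n_z
    free_out <- setdiff(free, c("n_y", "n_z"))
    vals <- from_theta(best_int$par, free_out, fixed)
    conv <- best_int$convergence
    final_par <- best_int$par; final_free <- free_out
  } else {
    vals <- from_theta(best$par, free, fixed)
    conv <- best$convergence
    final_par <- best$par; final_free <- free
  }

  fin <- da_fit_objective(vals, stims, resps, per_trace_alpha)
  if (per_trace_alpha) vals$alpha <- mean(fin$alphas)
  pars <- da_params(alpha = vals$alpha, beta = vals$beta, gamma = vals$gamma,
                    tau_r = vals$tau_r, n_y = vals$n_y, tau_y = vals$tau_y,
                    n_z = vals$n_z, tau_z = vals$tau_z,
                    label = paste0("fit:", init$label))
  preds <- da_predict_traces(pars, stims, fin$alphas, per_trace_alpha)
  Q <- goodness_of_fit(preds, resps)
  at_bounds <- final_free[final_par <= to_theta(as.list(bounds$lower[final_free]),
                                               final_free) + 1e-6 |
                          final_par >= to_theta(as.list(bounds$upper[final_free]),
                                                final_free) - 1e-6]
  structure(list(params = pars, Q = Q, sse = fin$sse, alphas = fin$alphas,
                 per_trace_alpha = per_trace_alpha,
                 convergence = conv, at_bounds = at_bounds,
                 starts = data.frame(start = seq_along(values),
                                     sse = values),
                 free = final_free, seed = seed),
            class = "da_fit")
}

da_predict_traces <- function(params, stims, alphas = NULL,
                              per_trace_alpha = FALSE) {
  lapply(seq_along(stims), function(i) {
    r <- simulate_da(stims[[i]], params, keep_signals = FALSE)
    if (per_trace_alpha && !is.null(alphas)) {
      # rescale from the fitted mean gain to the per-trace gain
      r$response <- r$response / params$alpha * alphas[i]
    }
    r
  })
}

#' @export
print.da_fit <- function(x, ...) {
  cat(sprintf("DA model fit: Q = %.4f (sse = %.4g), convergence = %d\n",
              x$Q, x$sse, x$convergence))
  if (length(x$at_bounds))
    cat("  parameters at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Goodness-of-fit sensitivity around a fitted optimum
#'
#' One-dimensional Q profiles by direct re-evaluation along each free
#' parameter, and two-dimensional contour data for parameter pairs from
#' the quadratic form of the finite-difference Hessian of Q at the
#' optimum (in log/logit space), alongside a direct grid evaluation.
#' Successive contours correspond to fixed decrements in Q, exposing the
#' stiff and sloppy directions of the parameter space.
#'
#' @param fit a [fit_da_model()] result.
#' @param stims,resps the traces used in the fit.
#' @param pairs list of 2-vectors of parameter names for 2D scans.
#' @param span fractional half-range of the 1D scans.
#' @param n grid points per dimension.
#' @return List with `profiles` (long data frame: parameter, value, Q),
#'   `hessian` (matrix in transformed space, with attribute `"names"`),
#'   and `contours` (per pair: grid data frame with direct Q and the
#'   quadratic-form approximation `Q_quad`).
#' @export
sensitivity_scan <- function(fit, stims, resps,
                             pairs = list(c("n_y", "tau_y")),
                             span = 0.3, n = 9) {
  stopifnot(inherits(fit, "da_fit"))
  vals0 <- unclass(fit$params)[da_free_names]
  q_at <- function(vals) {
    r <- da_fit_objective(vals, stims, resps, fit$per_trace_alpha)
    if (!is.finite(r$sse)) return(NA_real_)
    ssv <- sum(vapply(resps, function(o)
      sum((o$response - mean(o$response))^2), numeric(1)))
    1 - r$sse / ssv
  }
  Q0 <- q_at(vals0)
  scan_names <- setdiff(fit$free, if (fit$per_trace_alpha) "alpha" else NULL)
  profiles <- do.call(rbind, lapply(scan_names, function(nm) {
    grid <- vals0[[nm]] * seq(1 - span, 1 + span, length.out = n)
    if (nm == "gamma") grid <- pmin(grid, 0.999)
    qs <- vapply(grid, function(v) {
      vv <- vals0; vv[[nm]] <- v; q_at(vv)
    }, numeric(1))
    data.frame(parameter = nm, value = grid, Q = qs)
  }))
  # Hessian in transformed space
  th0 <- to_theta(vals0[scan_names], scan_names)
  h <- 0.02
  qth <- function(th) q_at(from_theta(th, scan_names, vals0))
  m <- length(th0)
  H <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    ei <- ej <- numeric(m); ei[i] <- h; ej[j] <- h
    if (i == j) {
      H[i, i] <- (qth(th0 + ei) - 2 * Q0 + qth(th0 - ei)) / h^2
    } else {
      H[i, j] <- H[j, i] <-
        (qth(th0 + ei + ej) - qth(th0 + ei - ej) -
           qth(th0 - ei + ej) + qth(th0 - ei - ej)) / (4 * h^2)
    }
  }
  attr(H, "names") <- scan_names
  contours <- lapply(pairs, function(pr) {
    i <- match(pr[1], scan_names); j <- match(pr[2], scan_names)
    if (anyNA(c(i, j))) stop("pair names must be free parameters")
    g1 <- vals0[[pr[1]]] * seq(1 - span, 1 + span, length.out = n)
    g2 <- vals0[[pr[2]]] * seq(1 - span, 1 + span, length.out = n)
    if (pr[1] == "gamma") g1 <- pmin(g1, 0.999)
    if (pr[2] == "gamma") g2 <- pmin(g2, 0.999)
    gr <- expand.grid(v1 = g1, v2 = g2)
    gr$Q <- mapply(function(a, b) {
      vv <- vals0; vv[[pr[1]]] <- a; vv[[pr[2]]] <- b; q_at(vv)
    }, gr$v1, gr$v2)
    # quadratic approximation in transformed coordinates
    t1 <- if (pr[1] == "gamma") stats::qlogis(gr$v1) else log(gr$v1)
    t2 <- if (pr[2] == "gamma") stats::qlogis(gr$v2) else log(gr$v2)
    d1 <- t1 - th0[i]; d2 <- t2 - th0[j]
    gr$Q_quad <- Q0 + 0.5 * (H[i, i] * d1^2 + 2 * H[i, j] * d1 * d2 +
                               H[j, j] * d2^2)
    names(gr)[1:2] <- pr
    gr
  })
  names(contours) <- vapply(pairs, paste, "", collapse = ":")
  list(Q0 = Q0, profiles = profiles, hessian = H, contours = contours)
}
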