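#' DA model parameters
#'
#' Container for the eight parameters of the dynamical adaptation (DA) model.
#' The response kernel \eqn{K_y(t) \propto (t/\tau_y)^{n_y} e^{-t/\tau_y}} is
#' a unit-normalised gamma filter; the gain-control kernel is the mixture
#' \eqn{K_z = \gamma K_y + (1-\gamma) K_s} where \eqn{K_s} is a second gamma
#' filter with shape `n_z` and time constant `tau_z`, broader than `K_y` and
#' somewhat delayed.  The membrane-potential response obeys
#' \deqn{\tau_r \frac{dR}{dt} = \alpha\, y(t) - \big(1 + \beta z(t)\big) R(t),}
#' with \eqn{y = K_y * I} and \eqn{z = K_z * I}.
#'
#' Vertebrate photoreceptors hyperpolarise in response to light, so the gain
#' `alpha` acts with a negative sign inside the model; it is *stored* as a
#' positive magnitude so that published values can be used verbatim.
#'
#' Canonical internal units are milliseconds and photons/um^2/ms.  `beta` is
#' an inverse intensity, (photons/um^2/ms)^-1, which makes `beta * z`
#' dimensionless and gives the saturation level `alpha / beta` in mV.
#'
#' @param alpha response gain magnitude, mV um^2 ms / photon (>= 0).
#' @param beta strength of the divisive nonlinearity, (photons/um^2/ms)^-1.
#' @param gamma weight of the fast component of `Kz`, in \[0, 1\].
#' @param tau_r relaxation time of the response, ms.
#' @param n_y,tau_y shape exponent (>= 0, non-integer allowed) and time
#'   constant (ms) of `Ky`.
#' @param n_z,tau_z shape and time constant of the slow component of `Kz`.
#' @param label optional name for the parameter set.
#' @return An object of class `da_params` (a named list).
#' @examples
#' p <- da_params(alpha = 1.1, beta = 0.044, gamma = 0.93, tau_r = 39,
#'                n_y = 1.5, tau_y = 38, n_z = 7, tau_z = 20, label = "BHL")
#' p$alpha / p$beta  # saturation amplitude, mV
#' @export
da_params <- function(alpha, beta, gamma, tau_r, n_y, tau_y, n_z, tau_z,
                      label = "") {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, tau_r = tau_r,
            n_y = n_y, tau_y = tau_y, n_z = n_z, tau_z = tau_z)
  if (any(!is.finite(vals)))
    stop("all DA parameters must be finite numbers")
  if (any(vals < 0))
    stop("all DA parameters must be >= 0 (alpha is stored as a magnitude): ",
         paste(names(vals)[vals < 0], collapse = ", "))
  if (gamma > 1) stop("gamma must lie in [0, 1]")
  if (tau_y <= 0 || tau_z <= 0 || tau_r <= 0)
    stop("tau_y, tau_z and tau_r must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau_r = tau_r,
                 n_y = n_y, tau_y = tau_y, n_z = n_z, tau_z = tau_z,
                 label = as.character(label)),
            class = "da_params")
}

#' @export
print.da_params <- function(x, ...) {
  cat("DA model parameters", if (nzchar(x$label)) paste0("(", x$label, ")"),
      "\n")
  cat(sprintf("  alpha = %g mV um^2 ms/photon   beta = %g (photons/um^2/ms)^-1\n",
              x$alpha, x$beta))
  cat(sprintf("  gamma = %g   tau_r = %g ms\n", x$gamma, x$tau_r))
  cat(sprintf("  Ky: n_y = %g, tau_y = %g ms (n_y*tau_y = %g ms)\n",
              x$n_y, x$tau_y, x$n_y * x$tau_y))
  cat(sprintf("  Kz slow: n_z = %g, tau_z = %g ms (n_z*tau_z = %g ms)\n",
              x$n_z, x$tau_z, x$n_z * x$tau_z))
  invisible(x)
}

#' Published DA parameter sets
#'
#' The four fitted parameter sets shipped with the package: `"salamander"`
#' (salamander cone flicker recordings; integer shape exponents), `"BHL"`
#' (turtle cone flash data of Baylor, Hodgkin and Lamb), `"B"` (Burkhardt's
#' step-sensitivity data; values in parentheses in the source were set to
#' typical values rather than fitted, including `alpha ~ 2.1`) and `"DN"`
#' (Daly and Normann's flash-on-background data).  The salamander set has no
#' published absolute gain (`a.u.`); its `alpha` defaults to the typical
#' single-photon value of 2 mV um^2 ms/photon.
#'
#' @param name one of `"salamander"`, `"BHL"`, `"B"`, `"DN"`.
#' @return A [da_params()] object.
#' @examples
#' da_preset("BHL")
#' @export
da_preset <- function(name = c("salamander", "BHL", "B", "DN")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("params_", tolower(name), ".json"),
                      package = "photodyn")
  if (!nzchar(path)) stop("packaged parameter file not found for ", name)
  read_da_params(path)
}

#' Write DA parameters to JSON
#'
#' @param params a [da_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_da_params <- function(params, path) {
  stopifnot(inherits(params, "da_params"))
  obj <- unclass(params)
  obj$units <- list(alpha = "mV*um^2*ms/photon",
                    beta = "(photons/um^2/ms)^-1",
                    tau_r = "ms", tau_y = "ms", tau_z = "ms")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read DA parameters from JSON
#'
#' @param path a JSON file with keys `alpha`, `beta`, `gamma`, `tau_r`,
#'   `n_y`, `tau_y`, `n_z`, `tau_z` and optionally `label`.
#' @return A [da_params()] object.
#' @export
read_da_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("alpha", "beta", "gamma", "tau_r", "n_y", "tau_y", "n_z", "tau_z")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("parameter JSON is missing fields: ", paste(missing, collapse = ", "))
  da_params(alpha = obj$alpha, beta = obj$beta, gamma = obj$gamma,
            tau_r = obj$tau_r, n_y = obj$n_y, tau_y = obj$tau_y,
            n_z = obj$n_z, tau_z = obj$tau_z,
            label = if (is.null(obj$label)) "" else obj$label)
}

# signed gain: the model applies the hyperpolarising sign internally
alpha_signed <- function(params) -params$alpha
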