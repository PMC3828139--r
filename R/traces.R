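#' Uniform time grid
#'
#' All traces taking part in one computation share a single uniform grid.
#'
#' @param t0 start time, ms.
#' @param dt sample step, ms (> 0).
#' @param n number of samples (>= 1).
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(0, 0.1, 5000)   # 500 ms at 0.1 ms resolution
#' @export
time_grid <- function(t0 = 0, dt = 0.1, n) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1")
  structure(list(t0 = t0, dt = dt, n = n), class = "time_grid")
}

#' Sample times of a grid
#' @param grid a [time_grid()].
#' @return Numeric vector of length `grid$n`, in ms.
#' @export
grid_times <- function(grid) grid$t0 + grid$dt * (seq_len(grid$n) - 1L)

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$dt - b$dt) < tol * max(a$dt, b$dt) && a$n == b$n &&
    abs(a$t0 - b$t0) < tol * max(1, abs(a$t0))
}

#' Light-intensity trace
#'
#' A uniformly sampled, nonnegative light-intensity time series in the
#' package's canonical unit, photons/um^2/ms.  Generators record their
#' provenance (name, seed, declared original unit) in `meta`.
#'
#' @param grid a [time_grid()].
#' @param intensity numeric vector of length `grid$n`, photons/um^2/ms,
#'   all values >= 0.
#' @param meta named list of provenance metadata.
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(grid, intensity, meta = list()) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(intensity) != grid$n)
    stop("intensity length (", length(intensity), ") != grid n (", grid$n, ")")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  structure(list(grid = grid, intensity = as.numeric(intensity), meta = meta),
            class = "stimulus_trace")
}

#' Convert a per-second intensity to the canonical per-ms unit
#'
#' Exact factor-1000 rescaling, recorded in the trace metadata when applied
#' through the generators.
#'
#' @param x intensity value(s) in photons/um^2/s.
#' @return Values in photons/um^2/ms.
#' @examples
#' per_s(3.6e5)   # 360 photons/um^2/ms
#' @export
per_s <- function(x) x / 1000

#' Membrane-potential response trace
#'
#' The photoreceptor response R(t): the deviation of the membrane potential
#' from its dark resting value, in mV (<= 0 under the hyperpolarising sign
#' convention for nonnegative light).
#'
#' @param grid a [time_grid()].
#' @param response numeric vector, mV.
#' @param y,z optional filtered-signal companions on the same grid.
#' @param meta named list of metadata.
#' @return An object of class `response_trace`.
#' @export
response_trace <- function(grid, response, y = NULL, z = NULL, meta = list()) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(response) != grid$n) stop("response length != grid n")
  structure(list(grid = grid, response = as.numeric(response),
                 y = y, z = z, meta = meta),
            class = "response_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("stimulus_trace: %d samples, dt = %g ms (%.3g s), t0 = %g ms\n",
              x$grid$n, x$grid$dt, x$grid$n * x$grid$dt / 1000, x$grid$t0))
  cat(sprintf("  intensity [photons/um^2/ms]: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$intensity), min(x$intensity), max(x$intensity)))
  if (!is.null(x$meta$generator))
    cat("  generator:", x$meta$generator, "\n")
  invisible(x)
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("response_trace: %d samples, dt = %g ms, t0 = %g ms\n",
              x$grid$n, x$grid$dt, x$grid$t0))
  cat(sprintf("  response [mV]: min %.4g, max %.4g\n",
              min(x$response), max(x$response)))
  invisible(x)
}

#' Write a trace to CSV (with a unit/provenance sidecar)
#'
#' Writes `time_ms,value` rows with full double precision, plus a JSON
#' sidecar `<path>.json` recording the unit and any metadata, so that a
#' write/read round trip is bit-exact.
#'
#' @param trace a [stimulus_trace()] or [response_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "stimulus_trace")) {
    value <- trace$intensity
    unit <- "photons/um^2/ms"
    kind <- "stimulus"
  } else if (inherits(trace, "response_trace")) {
    value <- trace$response
    unit <- "mV"
    kind <- "response"
  } else stop("trace must be a stimulus_trace or response_trace")
  df <- data.frame(time_ms = grid_times(trace$grid), value = value)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,value", con)
  writeLines(paste(sprintf("%.17g", df$time_ms), sprintf("%.17g", df$value),
                   sep = ","), con)
  sidecar <- list(kind = kind, unit = unit, t0 = trace$grid$t0,
                  dt = trace$grid$dt, n = trace$grid$n, meta = trace$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path; the `<path>.json` sidecar is consulted for the unit
#'   and grid.  Without a sidecar, `assume_unit` must name the value unit.
#' @param assume_unit `"photons/um^2/ms"`, `"photons/um^2/s"` or `"mV"`;
#'   only used when the sidecar is absent.
#' @return A [stimulus_trace()] or [response_trace()].
#' @export
read_trace_csv <- function(path, assume_unit = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("trace CSV has no data rows: ", path)
  if (!identical(trimws(lines[1]), "time_ms,value"))
    stop("line 1: expected header 'time_ms,value' in ", path)
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("line ", bad[1] + 1L, ": malformed row (expected 2 fields) in ", path)
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tm) || anyNA(val)) {
    bad <- which(is.na(tm) | is.na(val))[1]
    stop("line ", bad + 1L, ": non-numeric field in ", path)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    unit <- sc$unit
    meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  } else {
    if (is.null(assume_unit))
      stop("no unit sidecar found for ", path,
           "; pass assume_unit explicitly")
    unit <- assume_unit
    meta <- list()
  }
  dt <- if (length(tm) > 1) tm[2] - tm[1] else 1
  grid <- time_grid(tm[1], dt, length(tm))
  if (identical(unit, "mV")) {
    response_trace(grid, val, meta = meta)
  } else if (identical(unit, "photons/um^2/ms")) {
    stimulus_trace(grid, val, meta = meta)
  } else if (identical(unit, "photons/um^2/s")) {
    meta$original_unit <- "photons/um^2/s"
    stimulus_trace(grid, per_s(val), meta = meta)
  } else stop("unknown trace unit: ", unit)
}
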