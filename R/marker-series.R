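# Longitudinal marker time series for one organ/session.

#' Recognised quantitative marker identifiers
#' @export
MARKER_IDS <- c("T1_liver", "T1_spleen", "T2star", "PDFF", "ADC", "LSM",
                "vol_liver", "vol_spleen")

#' A single marker time series
#'
#' One quantitative marker's timestamped values for one organ and session.
#' Times are in seconds relative to the start of drink ingestion; negative
#' times are pre-ingestion baseline scans.
#'
#' @param times Strictly increasing times in seconds; at least one must be
#'   negative (a baseline sample) for fitting and change analysis.
#' @param values Finite marker values, same length as `times`.
#' @param marker One of `MARKER_IDS`.
#' @param unit Unit string (e.g. `"ms"`, `"kPa"`, `"1e-6 mm^2/s"`).
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(times, values, marker, unit) {
  marker <- match.arg(marker, MARKER_IDS)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L || any(diff(times) <= 0)) {
    stop("`times` must be non-empty and strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must all be finite", call. = FALSE)
  }
  if (!any(times < 0)) {
    stop("at least one pre-ingestion (negative-time) sample is required",
         call. = FALSE)
  }
  structure(list(times = times, values = values, marker = marker,
                 unit = as.character(unit)),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %s [%s], %d samples, t in [%g, %g] s\n",
              x$marker, x$unit, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
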