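# Closed-form responses of a first-order linear time-invariant system
# tau * dy/dt + y = u(t), expressed as organ T1 deviations from baseline.

#' Dynamic parameters of a first-order organ response
#'
#' Bundles the parameters of the first-order linear time-invariant (LTI)
#' model used for organ T1 dynamics after drink ingestion: a gain `k`
#' (the amplitude of the input plateau, in marker units, e.g. ms for T1),
#' the system time constant `tau` (s), the onset delay `delay` (s, time
#' between the start of ingestion and the first response), and the
#' pre-ingestion baseline value `baseline` (marker units).
#'
#' @param gain Input-plateau amplitude (marker units). May be negative for
#'   markers that decrease (e.g. stiffness); T1 fits constrain it >= 0.
#' @param tau System time constant in seconds; must be positive.
#' @param delay Onset delay in seconds; must be non-negative.
#' @param baseline Pre-ingestion marker value; must be positive.
#' @return An object of class `lti_params`.
#' @examples
#' p <- lti_params(gain = 150, tau = 2614, delay = 758, baseline = 740)
#' step_response(c(0, 758, 758 + 2614), p)
#' @export
lti_params <- function(gain, tau, delay, baseline) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(delay) || length(delay) != 1L || !is.finite(delay) || delay < 0) {
    stop("`delay` must be a single non-negative number (seconds)", call. = FALSE)
  }
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline) ||
      baseline <= 0) {
    stop("`baseline` must be a single positive number", call. = FALSE)
  }
  structure(
    list(gain = as.numeric(gain), tau = as.numeric(tau),
         delay = as.numeric(delay), baseline = as.numeric(baseline)),
    class = "lti_params"
  )
}

#' @export
print.lti_params <- function(x, ...) {
  cat(sprintf(
    "<lti_params> gain = %.4g, tau = %.4g s, delay = %.4g s, baseline = %.4g\n",
    x$gain, x$tau, x$delay, x$baseline))
  invisible(x)
}

#' Rectangular (top-hat) input shape
#'
#' The liver receives the absorbed drink from the portal circulation as a
#' prolonged bolus, idealised as a rectangular pulse of duration `delta`
#' seconds starting at the onset delay.
#'
#' @param delta Pulse duration in seconds; must be positive.
#' @return An object of class `rect_shape`.
#' @export
rect_shape <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop("`delta` must be a single positive number (seconds)", call. = FALSE)
  }
  structure(list(delta = as.numeric(delta)), class = "rect_shape")
}

#' Trapezoidal input shape
#'
#' The spleen sees the excess fluid arrive through the systemic circulation
#' gradually; the input is idealised as a trapezoid with an up-slope of
#' `delta1` s, a flat top of `delta2` s and a down-slope of `delta3` s.
#'
#' @param delta1 Up-slope duration (s), positive.
#' @param delta2 Flat-top duration (s), non-negative.
#' @param delta3 Down-slope duration (s), positive.
#' @return An object of class `trapezoid_shape`.
#' @export
trapezoid_shape <- function(delta1, delta2, delta3) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok(delta1) || delta1 <= 0) stop("`delta1` must be positive", call. = FALSE)
  if (!ok(delta2) || delta2 < 0) stop("`delta2` must be non-negative", call. = FALSE)
  if (!ok(delta3) || delta3 <= 0) stop("`delta3` must be positive", call. = FALSE)
  structure(
    list(delta1 = as.numeric(delta1), delta2 = as.numeric(delta2),
         delta3 = as.numeric(delta3)),
    class = "trapezoid_shape"
  )
}

# Heaviside step with the right-continuous convention u(0) = 1.
heaviside <- function(x) as.numeric(x >= 0)

#' Response to a delayed step input
#'
#' Closed-form response of the first-order system to a delayed Heaviside
#' input of amplitude `gain`: baseline before the delay, then an
#' exponential approach to `baseline + gain` with time constant `tau`.
#'
#' @param t Times in seconds (vectorised); time zero is the start of
#'   drink ingestion, negative times are pre-ingestion.
#' @param p An [lti_params] object.
#' @return Response values in marker units, same length as `t`.
#' @export
step_response <- function(t, p) {
  stopifnot(inherits(p, "lti_params"))
  x <- t - p$delay
  p$baseline + p$gain * (1 - exp(-pmax(x, 0) / p$tau)) * heaviside(x)
}

#' Response to a rectangular input
#'
#' Closed form obtained by superposing two delayed step responses of
#' opposite sign: the pulse switches on at `delay` and off `delta` seconds
#' later, so the response rises towards `baseline + gain` during the pulse
#' and relaxes back to baseline afterwards.
#'
#' @inheritParams step_response
#' @param shape A [rect_shape] object.
#' @return Response values in marker units.
#' @export
rect_response <- function(t, p, shape) {
  stopifnot(inherits(p, "lti_params"), inherits(shape, "rect_shape"))
  x1 <- t - p$delay
  x2 <- x1 - shape$delta
  on  <- p$gain * (1 - exp(-pmax(x1, 0) / p$tau)) * heaviside(x1)
  off <- p$gain * (1 - exp(-pmax(x2, 0) / p$tau)) * heaviside(x2)
  on - off + p$baseline
}

# Normalised response to a finite ramp of duration d starting at x = 0:
# (1/d) * [r(x) - r(x - d)], written so the difference never cancels
# catastrophically, even for d orders of magnitude below tau.
ramp_pair <- function(x, d, tau) {
  out <- numeric(length(x))
  ramp <- x > 0 & x < d
  out[ramp] <- (x[ramp] + tau * expm1(-x[ramp] / tau)) / d
  done <- x >= d
  out[done] <- 1 - (tau / d) * (-expm1(-d / tau)) * exp(-(x[done] - d) / tau)
  out
}

#' Response to a trapezoidal input
#'
#' Closed form obtained by superposing four ramp responses (up-slope on,
#' up-slope off, down-slope on, down-slope off), the unique causal solution
#' of the first-order system for a trapezoidal input.
#'
#' @inheritParams step_response
#' @param shape A [trapezoid_shape] object.
#' @return Response values in marker units.
#' @export
trapezoid_response <- function(t, p, shape) {
  stopifnot(inherits(p, "lti_params"), inherits(shape, "trapezoid_shape"))
  d1 <- shape$delta1; d2 <- shape$delta2; d3 <- shape$delta3
  tau <- p$tau
  x <- t - p$delay
  p$baseline + p$gain * (ramp_pair(x, d1, tau) -
                           ramp_pair(x - d1 - d2, d3, tau))
}

#' Input-signal generators for the reference integrator
#'
#' Build the idealised input time course (in marker units, amplitude =
#' `gain`) matching a shape, for use with [ode_oracle()].
#'
#' @inheritParams rect_response
#' @return A vectorised function of time returning input amplitude.
#' @export
lti_input <- function(p, shape) {
  stopifnot(inherits(p, "lti_params"))
  if (inherits(shape, "rect_shape")) {
    function(t) {
      x <- t - p$delay
      p$gain * (heaviside(x) - heaviside(x - shape$delta))
    }
  } else if (inherits(shape, "trapezoid_shape")) {
    d1 <- shape$delta1; d2 <- shape$delta2; d3 <- shape$delta3
    function(t) {
      x <- t - p$delay
      up   <- pmin(pmax(x / d1, 0), 1)
      down <- pmin(pmax((x - d1 - d2) / d3, 0), 1)
      p$gain * (up - down)
    }
  } else {
    stop("`shape` must be a rect_shape or trapezoid_shape", call. = FALSE)
  }
}

#' Numerical reference solution of the first-order system
#'
#' Integrates `tau * dy/dt + y = u(t)` with a fixed-step fourth-order
#' Runge-Kutta scheme and returns `baseline + y(t)` on the requested grid.
#' The state is the deviation from baseline with zero initial condition at
#' the first grid time, so the grid must start at or before the input
#' onset. Serves as the independent oracle for the closed forms.
#'
#' The RK4 update for this scalar linear ODE is an affine recurrence
#' `y[n+1] = A * y[n] + B[n]` with constant `A`; it is evaluated as a
#' vectorised recursive filter, which is algebraically identical to the
#' stepwise loop.
#'
#' Steps are aligned with the input's breakpoints (`breaks`): the
#' integration is carried out segment by segment so that no RK4 step
#' straddles a jump or kink of the input, where the scheme would lose its
#' order. [lti_breaks()] returns the breakpoints of the standard shapes.
#'
#' @param input_fn Vectorised function of time (s) returning the input
#'   amplitude in marker units; must be bounded.
#' @param p An [lti_params] object (only `tau` and `baseline` are used).
#' @param t_grid Strictly increasing times (s) at which to return the
#'   solution.
#' @param dt Maximum internal step size in seconds (default 0.1).
#' @param breaks Optional times (s) at which the input jumps or kinks.
#' @return Numeric vector of response values at `t_grid`.
#' @export
ode_oracle <- function(input_fn, p, t_grid, dt = 0.1, breaks = NULL) {
  stopifnot(inherits(p, "lti_params"), is.function(input_fn))
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0)) {
    stop("`t_grid` must be strictly increasing", call. = FALSE)
  }
  if (length(t_grid) == 1L) return(p$baseline)
  t0 <- t_grid[1L]; t1 <- t_grid[length(t_grid)]
  cuts <- sort(unique(c(t0, breaks[breaks > t0 & breaks < t1], t1)))
  t_all <- t0
  y_all <- 0
  y_cur <- 0
  for (s in seq_len(length(cuts) - 1L)) {
    s0 <- cuts[s]; s1 <- cuts[s + 1L]
    n_steps <- max(1L, as.integer(ceiling((s1 - s0) / dt)))
    h <- (s1 - s0) / n_steps
    a <- h / p$tau
    # exact RK4 coefficients for y' = (u - y)/tau over one step of size h
    A <- 1 - a + a^2 / 2 - a^3 / 6 + a^4 / 24
    t_steps <- s0 + h * (0:n_steps)
    # evaluate the input one-sidedly at the segment ends: right-continuous
    # at s0, left limit at s1, so jumps at breakpoints are honoured
    eps <- h * 1e-9
    u_lo  <- input_fn(t_steps[-(n_steps + 1L)])
    u_mid <- input_fn(t_steps[-(n_steps + 1L)] + h / 2)
    t_hi <- t_steps[-1L]
    t_hi[n_steps] <- t_hi[n_steps] - eps
    u_hi <- input_fn(t_hi)
    B <- (a / 6) * ((1 - a + a^2 / 2 - a^3 / 4) * u_lo +
                      (4 - 2 * a + a^2 / 2) * u_mid +
                      u_hi)
    y_seg <- as.numeric(stats::filter(B, A, method = "recursive",
                                      init = y_cur))
    y_cur <- y_seg[n_steps]
    t_all <- c(t_all, t_steps[-1L])
    y_all <- c(y_all, y_seg)
  }
  stats::approx(t_all, p$baseline + y_all, xout = t_grid)$y
}

#' Breakpoints of a standard input shape
#'
#' Times at which the rectangular input jumps, or the trapezoidal input
#' kinks; used to align [ode_oracle()] integration steps.
#'
#' @inheritParams peak
#' @return Numeric vector of times in seconds.
#' @export
lti_breaks <- function(p, shape) {
  stopifnot(inherits(p, "lti_params"))
  if (inherits(shape, "rect_shape")) {
    p$delay + c(0, shape$delta)
  } else if (inherits(shape, "trapezoid_shape")) {
    p$delay + cumsum(c(0, shape$delta1, shape$delta2, shape$delta3))
  } else {
    stop("`shape` must be a rect_shape or trapezoid_shape", call. = FALSE)
  }
}

#' Peak of the response curve
#'
#' Time and value of the response extremum. For a rectangular input the
#' peak is analytic: it occurs when the pulse switches off, at
#' `delay + delta`, with deviation `gain * (1 - exp(-delta/tau))`. For a
#' trapezoidal input the closed form is maximised numerically
#' (grid-then-refine golden-section search). A zero gain is degenerate:
#' the curve is flat and `(delay, baseline)` is returned with
#' `degenerate = TRUE`.
#'
#' @inheritParams rect_response
#' @param shape A [rect_shape] or [trapezoid_shape].
#' @return A list with `t_peak` (s), `y_peak` (marker units) and
#'   `degenerate` (logical).
#' @export
peak <- function(p, shape) {
  stopifnot(inherits(p, "lti_params"))
  if (p$gain == 0) {
    return(list(t_peak = p$delay, y_peak = p$baseline, degenerate = TRUE))
  }
  if (inherits(shape, "rect_shape")) {
    t_pk <- p$delay + shape$delta
    y_pk <- p$baseline + p$gain * (1 - exp(-shape$delta / p$tau))
    return(list(t_peak = t_pk, y_peak = y_pk, degenerate = FALSE))
  }
  if (!inherits(shape, "trapezoid_shape")) {
    stop("`shape` must be a rect_shape or trapezoid_shape", call. = FALSE)
  }
  # work with |gain|: the extremum location does not depend on the sign
  pp <- p; pp$gain <- abs(p$gain)
  d_tot <- shape$delta1 + shape$delta2 + shape$delta3
  hi <- p$delay + d_tot + 10 * p$tau
  grid <- seq(p$delay, hi, length.out = 2048L)
  dev <- trapezoid_response(grid, pp, shape) - p$baseline
  i <- which.max(dev)
  lo_i <- max(1L, i - 1L); hi_i <- min(length(grid), i + 1L)
  opt <- stats::optimize(
    function(t) trapezoid_response(t, pp, shape),
    lower = grid[lo_i], upper = grid[hi_i], maximum = TRUE, tol = 1e-8)
  y_dev <- opt$objective - p$baseline
  list(t_peak = opt$maximum,
       y_peak = p$baseline + sign(p$gain) * y_dev,
       degenerate = FALSE)
}

#' Serialize dynamic parameters to JSON
#'
#' Field names are unit-tagged: `gain_ms`, `tau_s`, `delay_s`,
#' `baseline_ms`, plus `delta_s` (rectangle) or `delta1_s`, `delta2_s`,
#' `delta3_s` (trapezoid).
#'
#' @inheritParams peak
#' @return A JSON string.
#' @export
lti_params_to_json <- function(p, shape) {
  stopifnot(inherits(p, "lti_params"))
  out <- list(gain_ms = p$gain, tau_s = p$tau, delay_s = p$delay,
              baseline_ms = p$baseline)
  if (inherits(shape, "rect_shape")) {
    out$delta_s <- shape$delta
  } else if (inherits(shape, "trapezoid_shape")) {
    out$delta1_s <- shape$delta1
    out$delta2_s <- shape$delta2
    out$delta3_s <- shape$delta3
  } else {
    stop("`shape` must be a rect_shape or trapezoid_shape", call. = FALSE)
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}

#' Deserialize dynamic parameters from JSON
#'
#' @param json A JSON string produced by [lti_params_to_json()].
#' @return A list with elements `params` ([lti_params]) and `shape`.
#' @export
lti_params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  p <- lti_params(x$gain_ms, x$tau_s, x$delay_s, x$baseline_ms)
  shape <- if (!is.null(x$delta_s)) {
    rect_shape(x$delta_s)
  } else {
    trapezoid_shape(x$delta1_s, x$delta2_s, x$delta3_s)
  }
  list(params = p, shape = shape)
}
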