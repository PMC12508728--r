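# Study-shaped synthetic cohort: participants x drink volumes x the eight
# marker time series, calibrated to published group-level dynamics and
# maximum-change magnitudes.

# Group-mean dynamic parameters for each ingested volume (seconds).
reference_dynamics <- function() {
  list(
    liver = list(
      `0.5` = list(tau = 2614, delay = 758, delta = 1303),
      `1`   = list(tau = 3007, delay = 821, delta = 1534),
      `1.5` = list(tau = 6573, delay = 632, delta = 1521)),
    spleen = list(
      `0.5` = list(tau = 616,  delay = 609, delta1 = 267, delta2 = 992,  delta3 = 129),
      `1`   = list(tau = 1700, delay = 745, delta1 = 286, delta2 = 894,  delta3 = 232),
      `1.5` = list(tau = 2917, delay = 568, delta1 = 160, delta2 = 1008, delta3 = 141))
  )
}

# Group-mean maximum absolute changes per marker and volume (marker units;
# LSM decreases). ADC is carried in 1e-6 mm^2/s.
reference_change_targets <- function() {
  list(
    T1_liver   = c(`0.5` = 58,   `1` = 60,    `1.5` = 90),
    T1_spleen  = c(`0.5` = 45,   `1` = 70,    `1.5` = 150),
    T2star     = c(`0.5` = 2.5,  `1` = 3.2,   `1.5` = 3.3),
    vol_liver  = c(`0.5` = 90,   `1` = 120,   `1.5` = 140),
    ADC        = c(`0.5` = 90,   `1` = 140,   `1.5` = 200),
    PDFF       = c(`0.5` = 0.07, `1` = 0.09,  `1.5` = 0.07),
    LSM        = c(`0.5` = -0.4, `1` = -0.45, `1.5` = -0.5),
    vol_spleen = c(`0.5` = 16,   `1` = 21,    `1.5` = 30)
  )
}

marker_units <- function() {
  c(T1_liver = "ms", T1_spleen = "ms", T2star = "ms", PDFF = "%",
    ADC = "1e-6 mm^2/s", LSM = "kPa", vol_liver = "mL", vol_spleen = "mL")
}

#' Synthetic-cohort generator configuration
#'
#' Defaults encode the study conditions the generator emulates: per-volume
#' liver (rectangular) and spleen (trapezoidal) dynamic parameters, target
#' maximum changes per marker, measurement noise levels, baselines, and
#' the per-marker sampling cadences (T1 every 300 s; T2*/PDFF/ADC and
#' volumes every 900 s; stiffness every 1800 s), each with pre-ingestion
#' baseline samples.
#'
#' @param post_duration Post-ingestion scan duration in seconds.
#' @param jitter_sigma Lognormal sigma applied multiplicatively to each
#'   dynamic parameter per participant-session (between-participant
#'   variability).
#' @param gain_cv Coefficient of variation of the per-participant
#'   maximum-change targets (normal, truncated at 20% of the mean).
#' @param noise_sd Named per-marker measurement noise SDs (marker units).
#' @param baselines Named per-marker baseline values.
#' @param change_targets Named list of per-volume maximum-change targets.
#' @param dynamics Per-volume dynamic parameters for liver and spleen.
#' @param tau_volume_beta Optional built-in covariate effect: the liver
#'   time constant is multiplied by `(volume / 1 L)^beta` (default 0, no
#'   effect beyond the per-volume reference values).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(post_duration = 3600,
                             jitter_sigma = 0.15,
                             gain_cv = 0.2,
                             noise_sd = c(T1_liver = 5, T1_spleen = 7,
                                          T2star = 0.4, ADC = 15, PDFF = 0.15,
                                          LSM = 0.12, vol_liver = 32,
                                          vol_spleen = 4),
                             baselines = c(T1_liver = 740, T1_spleen = 1300,
                                           T2star = 27, ADC = 1000, PDFF = 2,
                                           LSM = 2.6, vol_liver = 1600,
                                           vol_spleen = 200),
                             change_targets = reference_change_targets(),
                             dynamics = reference_dynamics(),
                             tau_volume_beta = 0) {
  structure(list(post_duration = post_duration, jitter_sigma = jitter_sigma,
                 gain_cv = gain_cv, noise_sd = noise_sd, baselines = baselines,
                 change_targets = change_targets, dynamics = dynamics,
                 tau_volume_beta = tau_volume_beta),
            class = "generator_config")
}

#' Per-marker sampling schedules
#'
#' Times in seconds relative to ingestion start. T1 is sampled every
#' 300 s, T2*/PDFF/ADC and organ volumes every 900 s, stiffness every
#' 1800 s; each schedule includes pre-ingestion baseline samples.
#'
#' @param post_duration Last post-ingestion time (s).
#' @return Named list of numeric time vectors, one per marker.
#' @export
default_schedules <- function(post_duration = 3600) {
  t1 <- seq(-600, post_duration, by = 300)
  q15 <- seq(-900, post_duration, by = 900)
  q30 <- seq(-1800, post_duration, by = 1800)
  list(T1_liver = t1, T1_spleen = t1,
       T2star = q15, PDFF = q15, ADC = q15,
       vol_liver = q15, vol_spleen = q15,
       LSM = q30)
}

#' Calibrate the gain to a target peak change
#'
#' Returns the gain `k` for which the response peak deviates from
#' baseline by exactly `target_peak_change`. For a rectangular input the
#' closed form is `k = target / (1 - exp(-delta/tau))`; for a trapezoid
#' the peak deviation is proportional to `k`, so the unit-gain numeric
#' peak is computed and scaled, which solves the calibration equation
#' exactly.
#'
#' @param p An [lti_params] object (its gain is ignored).
#' @param shape A [rect_shape] or [trapezoid_shape].
#' @param target_peak_change Desired peak deviation (> 0, marker units).
#' @return The calibrated gain (marker units).
#' @export
calibrate_gain <- function(p, shape, target_peak_change) {
  if (!is.numeric(target_peak_change) || length(target_peak_change) != 1L ||
      !is.finite(target_peak_change) || target_peak_change <= 0) {
    stop("`target_peak_change` must be a single positive number", call. = FALSE)
  }
  if (inherits(shape, "rect_shape")) {
    return(target_peak_change / (1 - exp(-shape$delta / p$tau)))
  }
  p1 <- lti_params(1, p$tau, p$delay, p$baseline)
  unit_peak <- peak(p1, shape)$y_peak - p$baseline
  target_peak_change / unit_peak
}

#' Generate one T1 series from the forward model
#'
#' Evaluates the closed-form response at the schedule times and adds
#' i.i.d. Gaussian measurement noise; pre-onset times evaluate to
#' baseline + noise. Uses the current RNG state: seed before calling for
#' reproducibility.
#'
#' @inheritParams peak
#' @param schedule Times in seconds (strictly increasing, at least one
#'   negative).
#' @param noise_sd Measurement noise SD (marker units).
#' @param marker Marker id for the returned series.
#' @return A [marker_series].
#' @export
generate_t1_series <- function(p, shape, schedule, noise_sd,
                               marker = c("T1_liver", "T1_spleen")) {
  marker <- match.arg(marker)
  clean <- if (inherits(shape, "rect_shape")) {
    rect_response(schedule, p, shape)
  } else {
    trapezoid_response(schedule, p, shape)
  }
  marker_series(schedule, clean + stats::rnorm(length(schedule), 0, noise_sd),
                marker, "ms")
}

#' Generate a secondary-marker series
#'
#' Secondary markers (T2*, ADC, PDFF, stiffness, organ volumes) are
#' modelled as `baseline + A * g(t) + noise`, where `g` is the session's
#' liver rectangular response normalised to unit peak (only the extrema
#' of these markers are characterised, so they share the liver's temporal
#' shape) and `A` is the signed maximum-change amplitude (negative for
#' stiffness).
#'
#' @param marker One of `T2star`, `ADC`, `PDFF`, `LSM`, `vol_liver`,
#'   `vol_spleen`.
#' @param volume Session drink volume in litres (0.5, 1 or 1.5); selects
#'   the default amplitude and liver dynamics from `cfg`.
#' @param schedule Times in seconds.
#' @param cfg A [generator_config].
#' @param liver_params,liver_shape Optional session-specific liver
#'   dynamics overriding the per-volume defaults in `cfg`.
#' @param amplitude Optional signed amplitude overriding the `cfg` target.
#' @return A [marker_series].
#' @export
generate_secondary_marker <- function(marker, volume, schedule, cfg = generator_config(),
                                      liver_params = NULL, liver_shape = NULL,
                                      amplitude = NULL) {
  marker <- match.arg(marker, c("T2star", "ADC", "PDFF", "LSM",
                                "vol_liver", "vol_spleen"))
  vkey <- as.character(volume)
  if (is.null(liver_params) || is.null(liver_shape)) {
    d <- cfg$dynamics$liver[[vkey]]
    if (is.null(d)) stop("no liver dynamics configured for volume ", volume,
                         call. = FALSE)
    liver_params <- lti_params(1, d$tau, d$delay, cfg$baselines[["T1_liver"]])
    liver_shape <- rect_shape(d$delta)
  }
  if (is.null(amplitude)) {
    amplitude <- cfg$change_targets[[marker]][[vkey]]
    if (is.null(amplitude)) stop("no change target for ", marker, " at volume ",
                                 volume, call. = FALSE)
  }
  baseline <- cfg$baselines[[marker]]
  noise_sd <- cfg$noise_sd[[marker]]
  # unit-peak liver shape
  gp <- lti_params(1, liver_params$tau, liver_params$delay, liver_params$baseline)
  unit_peak <- 1 - exp(-liver_shape$delta / gp$tau)
  g <- (rect_response(schedule, gp, liver_shape) - gp$baseline) / unit_peak
  values <- baseline + amplitude * g + stats::rnorm(length(schedule), 0, noise_sd)
  marker_series(schedule, values, marker, marker_units()[[marker]])
}

# lognormal multiplicative jitter around 1
jitter_ln <- function(n, sigma) {
  if (sigma <= 0) rep(1, n) else stats::rlnorm(n, meanlog = 0, sdlog = sigma)
}

# normal jitter with CV, truncated away from zero / sign flips
jitter_cv <- function(x, cv) {
  if (cv <= 0) return(x)
  x * pmax(stats::rnorm(length(x), 1, cv), 0.2)
}

#' Generate a full synthetic cohort
#'
#' Draws participant covariates uniformly within the study's eligibility
#' ranges (age 18-60 years, BMI 18.5-30 kg/m^2), then, per participant
#' and session volume, jitters the reference dynamic parameters by
#' lognormal factors, calibrates gains so each participant's noiseless
#' peak T1 change hits a (jittered) per-marker target, and emits all
#' eight marker series with Gaussian measurement noise. Identical seed
#' and configuration give a bit-identical cohort.
#'
#' @param n_participants Number of participants (>= 2).
#' @param volumes Drink volumes in litres for the sessions.
#' @param cfg A [generator_config].
#' @param seed Integer RNG seed.
#' @return An object of class `hydration_cohort`: a list with
#'   `covariates` (tibble), `series` (long tibble: participant_id,
#'   session_volume_L, marker, time_s, value, unit), `truth` (per-session
#'   generating parameters) and `config`.
#' @export
generate_cohort <- function(n_participants = 6, volumes = c(0.5, 1, 1.5),
                            cfg = generator_config(), seed = 42) {
  if (n_participants < 2) stop("`n_participants` must be >= 2", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("P%02d", seq_len(n_participants))
    covariates <- tibble::tibble(
      participant_id = ids,
      age = stats::runif(n_participants, 18, 60),
      bmi = stats::runif(n_participants, 18.5, 30),
      baseline_liver_volume_mL = stats::runif(n_participants, 1300, 1900),
      baseline_spleen_volume_mL = stats::runif(n_participants, 150, 250),
      ivc_ao_ratio = stats::runif(n_participants, 0.8, 1.2)
    )
    schedules <- default_schedules(cfg$post_duration)
    series_rows <- list()
    truth_rows <- list()
    secondary <- c("T2star", "PDFF", "ADC", "LSM", "vol_liver", "vol_spleen")
    for (pid in ids) {
      for (vol in volumes) {
        vkey <- as.character(vol)
        dl <- cfg$dynamics$liver[[vkey]]
        ds <- cfg$dynamics$spleen[[vkey]]
        if (is.null(dl) || is.null(ds)) {
          stop("no reference dynamics for volume ", vol, call. = FALSE)
        }
        jl <- jitter_ln(3, cfg$jitter_sigma)
        tau_l <- dl$tau * jl[1] * (vol / 1.0)^cfg$tau_volume_beta
        liver_shape <- rect_shape(dl$delta * jl[3])
        liver_target <- jitter_cv(cfg$change_targets$T1_liver[[vkey]], cfg$gain_cv)
        liver_p <- lti_params(1, tau_l, dl$delay * jl[2],
                              cfg$baselines[["T1_liver"]])
        liver_p$gain <- calibrate_gain(liver_p, liver_shape, liver_target)
        js <- jitter_ln(5, cfg$jitter_sigma)
        spleen_shape <- trapezoid_shape(ds$delta1 * js[3], ds$delta2 * js[4],
                                        ds$delta3 * js[5])
        spleen_target <- jitter_cv(cfg$change_targets$T1_spleen[[vkey]], cfg$gain_cv)
        spleen_p <- lti_params(1, ds$tau * js[1], ds$delay * js[2],
                               cfg$baselines[["T1_spleen"]])
        spleen_p$gain <- calibrate_gain(spleen_p, spleen_shape, spleen_target)
        sers <- list(
          T1_liver = generate_t1_series(liver_p, liver_shape,
                                        schedules$T1_liver,
                                        cfg$noise_sd[["T1_liver"]], "T1_liver"),
          T1_spleen = generate_t1_series(spleen_p, spleen_shape,
                                         schedules$T1_spleen,
                                         cfg$noise_sd[["T1_spleen"]], "T1_spleen")
        )
        for (mk in secondary) {
          amp <- jitter_cv(cfg$change_targets[[mk]][[vkey]], cfg$gain_cv)
          sers[[mk]] <- generate_secondary_marker(
            mk, vol, schedules[[mk]], cfg,
            liver_params = liver_p, liver_shape = liver_shape,
            amplitude = amp)
        }
        for (mk in names(sers)) {
          s <- sers[[mk]]
          series_rows[[length(series_rows) + 1L]] <- tibble::tibble(
            participant_id = pid, session_volume_L = vol, marker = mk,
            time_s = s$times, value = s$values, unit = s$unit)
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          participant_id = pid, session_volume_L = vol,
          organ = c("liver", "spleen"),
          gain = c(liver_p$gain, spleen_p$gain),
          tau = c(liver_p$tau, spleen_p$tau),
          delay = c(liver_p$delay, spleen_p$delay),
          delta = c(liver_shape$delta, NA_real_),
          delta1 = c(NA_real_, spleen_shape$delta1),
          delta2 = c(NA_real_, spleen_shape$delta2),
          delta3 = c(NA_real_, spleen_shape$delta3),
          target_change = c(liver_target, spleen_target))
      }
    }
    structure(list(covariates = covariates,
                   series = dplyr::bind_rows(series_rows),
                   truth = dplyr::bind_rows(truth_rows),
                   config = cfg, seed = as.integer(seed)),
              class = "hydration_cohort")
  })
}

#' @export
print.hydration_cohort <- function(x, ...) {
  cat(sprintf("<hydration_cohort> %d participants, %d sessions, %d series rows\n",
              nrow(x$covariates),
              nrow(dplyr::distinct(x$series, .data$participant_id,
                                   .data$session_volume_L)),
              nrow(x$series)))
  invisible(x)
}

#' Extract one marker series from a cohort
#'
#' @param cohort A `hydration_cohort` (or its long `series` tibble).
#' @param participant_id Participant identifier.
#' @param volume Session volume (L).
#' @param marker Marker id.
#' @return A [marker_series].
#' @export
cohort_series <- function(cohort, participant_id, volume, marker) {
  df <- if (inherits(cohort, "hydration_cohort")) cohort$series else cohort
  rows <- df[df$participant_id == participant_id &
               df$session_volume_L == volume & df$marker == marker, ]
  if (nrow(rows) == 0L) {
    stop("no such series in cohort: ", participant_id, " / ", volume, " L / ",
         marker, call. = FALSE)
  }
  rows <- rows[order(rows$time_s), ]
  marker_series(rows$time_s, rows$value, marker, rows$unit[1L])
}
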