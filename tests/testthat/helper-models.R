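# Shared fixtures: reference parameter sets and small generators.

# Reference liver dynamics (rectangular input) per drink volume.
ref_liver <- function(volume, gain = 150, baseline = 740) {
  d <- reference_dynamics()$liver[[as.character(volume)]]
  list(params = lti_params(gain, d$tau, d$delay, baseline),
       shape = rect_shape(d$delta))
}

# Reference spleen dynamics (trapezoidal input) per drink volume.
ref_spleen <- function(volume, gain = 50, baseline = 1300) {
  d <- reference_dynamics()$spleen[[as.character(volume)]]
  list(params = lti_params(gain, d$tau, d$delay, baseline),
       shape = trapezoid_shape(d$delta1, d$delta2, d$delta3))
}

# reference_dynamics/reference_change_targets are internal; reach them
# through the installed namespace so tests run against the installed
# package.
reference_dynamics <- function() hydromark:::reference_dynamics()
reference_change_targets <- function() hydromark:::reference_change_targets()

# Standard T1 sampling schedule used in recovery tests: every 5 min from
# -10 to +70 min.
t1_schedule <- function() seq(-600, 4200, by = 300)

# Noiseless series from a model.
noiseless_series <- function(model, schedule = t1_schedule(),
                             marker = "T1_liver") {
  vals <- if (inherits(model$shape, "rect_shape")) {
    rect_response(schedule, model$params, model$shape)
  } else {
    trapezoid_response(schedule, model$params, model$shape)
  }
  marker_series(schedule, vals, marker, "ms")
}

# Simulated LMM input tables at the study size (6 participants x 3
# volumes), with a configurable volume effect.
sim_covariates <- function(n = 6) {
  data.frame(participant = sprintf("P%02d", seq_len(n)),
             age = stats::runif(n, 18, 60), bmi = stats::runif(n, 18.5, 30),
             baseline_organ_volume_mL = stats::runif(n, 1300, 1900),
             ivc_ao_ratio = stats::runif(n, 0.8, 1.2))
}

sim_lmm_table <- function(volume_effect = 0, icpt_sd = 200, noise_sd = 150,
                          n = 6) {
  cov <- sim_covariates(n)
  cov$icpt <- stats::rnorm(n, 0, icpt_sd)
  tab <- merge(expand.grid(participant = cov$participant,
                           volume_L = c(0.5, 1, 1.5)), cov)
  tab$response <- 2000 + volume_effect * tab$volume_L + tab$icpt +
    stats::rnorm(nrow(tab), 0, noise_sd)
  tab
}

# Random draw of LTI parameters + both shapes for property tests.
random_model <- function() {
  tau <- stats::runif(1, 100, 1e4)
  delay <- stats::runif(1, 0, 1200)
  k <- stats::runif(1, 10, 500)
  d <- stats::runif(3, 60, 3600)
  p <- lti_params(k, tau, delay, 700)
  list(params = p,
       rect = rect_shape(d[1]),
       trap = trapezoid_shape(d[1], d[2], d[3]))
}
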