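# Per-session maximum-change statistics and across-participant paired
# t-tests, the descriptive stage of the analysis.

#' Signed maximum change of a series
#'
#' Baseline is the mean of pre-ingestion (t < 0) samples. Over
#' post-ingestion samples (t > 0), the sample with the largest absolute
#' deviation from baseline is selected (earliest wins ties) and the
#' signed deviation, the relative deviation in percent of baseline, and
#' its time are returned. Markers that decrease (e.g. stiffness) thus
#' yield negative changes.
#'
#' @param series A [marker_series] with >= 1 pre- and >= 2 post-ingestion
#'   samples.
#' @return A list with `change` (marker units), `relative_pct`, `t_at`
#'   (s), `baseline` and `value_at_max`.
#' @export
max_change <- function(series) {
  stopifnot(inherits(series, "marker_series"))
  pre <- series$values[series$times < 0]
  post_i <- which(series$times > 0)
  if (length(pre) < 1L || length(post_i) < 2L) {
    stop("need >= 1 pre- and >= 2 post-ingestion samples", call. = FALSE)
  }
  b <- mean(pre)
  if (b == 0) stop("zero baseline: relative change undefined", call. = FALSE)
  dev <- series$values[post_i] - b
  i_star <- post_i[which.max(abs(dev))]   # which.max returns earliest tie
  ch <- series$values[i_star] - b
  list(change = ch, relative_pct = 100 * ch / b, t_at = series$times[i_star],
       baseline = b, value_at_max = series$values[i_star])
}

#' Paired two-sided t-test
#'
#' Classical paired t statistic on n matched pre/post values with n - 1
#' degrees of freedom. Zero-variance differences leave the statistic
#' undefined and raise an error.
#'
#' @param pre,post Equal-length numeric vectors, n >= 2.
#' @return A list with `t_stat`, `p_value` and `df`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    stop("`pre` and `post` must be equal-length with n >= 2", call. = FALSE)
  }
  d <- post - pre
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Cohort-level maximum-change summary
#'
#' One row per marker and session volume: the across-participant mean and
#' SD of the signed maximum absolute change and of the relative change,
#' and the p-value of a paired t-test of baseline values against the
#' values at each participant's own extremum time.
#'
#' @param cohort A `hydration_cohort` or its long series tibble.
#' @param markers Marker ids to summarise (default: all present).
#' @return A tibble with columns marker, volume_L, n, abs_mean, abs_sd,
#'   rel_mean_pct, rel_sd_pct, p_value, t_at_mean_s.
#' @export
summarize_cohort <- function(cohort, markers = NULL) {
  df <- if (inherits(cohort, "hydration_cohort")) cohort$series else cohort
  if (is.null(markers)) markers <- unique(df$marker)
  combos <- dplyr::distinct(df[df$marker %in% markers, ],
                            .data$marker, .data$session_volume_L)
  out <- purrr::pmap(combos, function(marker, session_volume_L) {
    pids <- unique(df$participant_id[df$marker == marker &
                                       df$session_volume_L == session_volume_L])
    if (length(pids) < 2L) {
      stop("need >= 2 participants per marker/volume for a summary",
           call. = FALSE)
    }
    per <- purrr::map(pids, function(pid) {
      max_change(cohort_series(df, pid, session_volume_L, marker))
    })
    ch <- vapply(per, `[[`, numeric(1), "change")
    rel <- vapply(per, `[[`, numeric(1), "relative_pct")
    bl <- vapply(per, `[[`, numeric(1), "baseline")
    vmx <- vapply(per, `[[`, numeric(1), "value_at_max")
    tat <- vapply(per, `[[`, numeric(1), "t_at")
    pv <- tryCatch(paired_t(bl, vmx)$p_value, error = function(e) NA_real_)
    tibble::tibble(marker = marker, volume_L = session_volume_L,
                   n = length(pids),
                   abs_mean = mean(ch), abs_sd = stats::sd(ch),
                   rel_mean_pct = mean(rel), rel_sd_pct = stats::sd(rel),
                   p_value = pv, t_at_mean_s = mean(tat))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$marker, .data$volume_L)
}
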