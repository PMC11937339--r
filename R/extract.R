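# Time-intensity parameter extraction.
#
# All thresholds are relative to the per-trace maximum. Threshold crossings
# are located by linear interpolation between adjacent samples, which removes
# the sampling-interval quantization and makes piecewise-linear test cases
# exact. Ties for the maximum break to the earliest sample.

#' Extract the ten TI parameters from one intensity trace
#'
#' Definitions (with `f_on = onset_fraction`, `f_pl = plateau_fraction`):
#' * `i_max`: maximum intensity; `t_max`: earliest time attaining it.
#' * `t_onset`: first time the intensity exceeds `f_on * i_max`.
#' * `t_extinction`: first time after `t_max` the intensity falls below
#'   `f_on * i_max`; if it never does, the last sample time (flagged
#'   `ext_censored`).
#' * `plateau_s`: length of the maximal contiguous interval containing
#'   `t_max` where intensity exceeds `f_pl * i_max`.
#' * `slope_pre`, `slope_post`: least-squares slopes of intensity on time
#'   over `[t_onset, t_max]` and `[t_max, t_extinction]` (`NA` when fewer
#'   than two samples fall in the interval).
#' * `auc_total`, `auc_pre`, `auc_post`: trapezoidal areas over the whole
#'   trace, before `t_max`, and after `t_max`; `auc_pre + auc_post ==
#'   auc_total` exactly because the split point is a sample time.
#'
#' An all-zero trace (non-perceiver) yields all-`NA` parameters.
#'
#' @param trace Trace tibble (or data frame) with `time_s` and `intensity`
#'   for a single subject-by-condition recording, sorted by time.
#' @param config A [ti_config()].
#' @return One-row tibble: ten parameters plus `ext_censored`.
#' @export
extract_ti <- function(trace, config = ti_config()) {
  t <- trace$time_s
  v <- trace$intensity
  if (length(t) < 2) stop("trace has fewer than 2 samples")
  if (is.unsorted(t, strictly = TRUE)) stop("trace times must be strictly increasing")
  out <- ti_extract_core(t, v, config$onset_fraction, config$plateau_fraction)
  tibble::as_tibble(out)
}

# Vector core shared by extract_ti and the table wrapper.
ti_extract_core <- function(t, v, f_on, f_pl) {
  nas <- list(i_max = NA_real_, t_max = NA_real_, t_onset = NA_real_,
              t_extinction = NA_real_, plateau_s = NA_real_,
              slope_pre = NA_real_, slope_post = NA_real_,
              auc_total = NA_real_, auc_pre = NA_real_, auc_post = NA_real_,
              ext_censored = NA)
  if (all(v == 0)) return(nas)

  imax <- max(v)
  im <- which(v == imax)[1L]   # earliest attainment
  t_max <- t[im]

  thr_on <- f_on * imax
  j <- which(v > thr_on)[1L]
  t_onset <- if (j == 1L) t[1L] else cross_up(t, v, j, thr_on)

  after <- which(v < thr_on & seq_along(v) > im)
  if (length(after) > 0) {
    j2 <- after[1L]
    t_ext <- cross_down(t, v, j2, thr_on)
    censored <- FALSE
  } else {
    t_ext <- t[length(t)]
    censored <- TRUE
  }

  thr_pl <- f_pl * imax
  above <- v > thr_pl
  L <- im; while (L > 1L && above[L - 1L]) L <- L - 1L
  R <- im; while (R < length(v) && above[R + 1L]) R <- R + 1L
  pl_lo <- if (L == 1L) t[1L] else cross_up(t, v, L, thr_pl)
  pl_hi <- if (R == length(v)) t[length(t)] else cross_down(t, v, R + 1L, thr_pl)
  plateau_s <- pl_hi - pl_lo

  slope_pre <- ols_slope_window(t, v, t_onset, t_max)
  slope_post <- ols_slope_window(t, v, t_max, t_ext)

  auc_pre <- trapz_idx(t, v, 1L, im)
  auc_post <- trapz_idx(t, v, im, length(t))

  list(i_max = imax, t_max = t_max, t_onset = t_onset, t_extinction = t_ext,
       plateau_s = plateau_s, slope_pre = slope_pre, slope_post = slope_post,
       auc_total = auc_pre + auc_post, auc_pre = auc_pre, auc_post = auc_post,
       ext_censored = censored)
}

# Interpolated upward crossing of `thr` between samples j-1 and j
# (v[j-1] <= thr < v[j]).
cross_up <- function(t, v, j, thr) {
  t[j - 1L] + (t[j] - t[j - 1L]) * (thr - v[j - 1L]) / (v[j] - v[j - 1L])
}

# Interpolated downward crossing of `thr` between samples j-1 and j
# (v[j-1] >= thr > v[j]).
cross_down <- function(t, v, j, thr) {
  t[j - 1L] + (t[j] - t[j - 1L]) * (v[j - 1L] - thr) / (v[j - 1L] - v[j])
}

ols_slope_window <- function(t, v, a, b) {
  in_win <- t >= a & t <= b
  if (sum(in_win) < 2L) return(NA_real_)
  tw <- t[in_win]; vw <- v[in_win]
  tc <- tw - mean(tw)
  den <- sum(tc^2)
  if (den == 0) return(NA_real_)
  sum(tc * (vw - mean(vw))) / den
}

trapz_idx <- function(t, v, i, j) {
  if (j <= i) return(0)
  idx <- i:j
  sum(diff(t[idx]) * (v[idx][-1] + v[idx][-length(idx)])) / 2
}

#' Extract TI parameters for every trace in a set
#'
#' @param traces Validated long trace tibble (see [validate_trace_set()]).
#' @param config A [ti_config()].
#' @return Tibble: one row per subject-by-condition trace, columns `subject`,
#'   `condition`, the ten TI parameters, and `ext_censored`. The number of
#'   all-zero (non-perceiver) traces is reported in a message.
#' @export
extract_ti_table <- function(traces, config = ti_config()) {
  grp <- dplyr::group_by(traces, .data$subject, .data$condition)
  out <- dplyr::reframe(grp, tibble::as_tibble(
    ti_extract_core(.data$time_s, .data$intensity,
                    config$onset_fraction, config$plateau_fraction)))
  n_zero <- sum(is.na(out$i_max))
  if (n_zero > 0) {
    message(sprintf("%d all-zero trace(s): TI parameters undefined (non-perceivers)",
                    n_zero))
  }
  out
}

#' Trapezoidal area under a trace between two times
#'
#' Integrates the linearly interpolated trace over `[t_from, t_to]` using the
#' actual (possibly non-uniform) timestamps; the endpoints need not be sample
#' times.
#'
#' @param trace Trace tibble with `time_s` and `intensity`.
#' @param t_from,t_to Integration bounds (seconds), `t_from < t_to`, both
#'   within the trace span.
#' @return Area in cm*s.
#' @export
trace_auc <- function(trace, t_from, t_to) {
  t <- trace$time_s; v <- trace$intensity
  if (t_from >= t_to) stop("t_from must be < t_to")
  if (t_from < t[1] || t_to > t[length(t)]) {
    stop("integration bounds outside the trace span")
  }
  inner <- t > t_from & t < t_to
  tt <- c(t_from, t[inner], t_to)
  vv <- c(stats::approx(t, v, xout = t_from)$y, v[inner],
          stats::approx(t, v, xout = t_to)$y)
  sum(diff(tt) * (vv[-1] + vv[-length(vv)])) / 2
}

#' Least-squares slope of a trace over a time window
#'
#' Ordinary least-squares slope of intensity on time using the samples in the
#' closed interval `[t_from, t_to]`. Returns `NA` (not an error) when fewer
#' than two samples fall in the window, e.g. for plateau-free spikes.
#'
#' @inheritParams trace_auc
#' @return Slope in cm/s, or `NA`.
#' @export
fit_slope <- function(trace, t_from, t_to) {
  if (t_from >= t_to) stop("t_from must be < t_to")
  ols_slope_window(trace$time_s, trace$intensity, t_from, t_to)
}
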