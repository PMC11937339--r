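# Penalized-spline smoothing of perceived intensity over time, one smooth per
# condition (the by-condition smooth structure factorizes, so conditions are
# fitted independently). Cubic regression splines via mgcv::gam; smoothing
# parameter by REML (default) or GCV. Traces are thinned before fitting --
# 60 Hz pooling is statistically redundant -- while TI extraction always uses
# full resolution.

#' Thin traces to a lower sampling rate
#'
#' Keeps, per subject-by-condition trace, the first sample in each bin of
#' width `1/rate_hz`. Works on non-uniform timestamps.
#'
#' @param traces Long trace tibble.
#' @param rate_hz Target rate (Hz).
#' @return Thinned tibble.
#' @export
downsample_traces <- function(traces, rate_hz) {
  dt <- 1 / rate_hz
  traces |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::mutate(.bin = floor(.data$time_s / dt + 1e-9)) |>
    dplyr::group_by(.data$subject, .data$condition, .data$.bin) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".bin")
}

#' Fit a penalized-spline smooth of intensity over time for one condition
#'
#' Pools all subjects' (thinned) samples of the condition and fits
#' `intensity ~ s(time_s, bs = "cr", k = k)`. Optionally adds a per-subject
#' random intercept (`subject_intercept = TRUE`); note this changes the
#' effective degrees of freedom and Wald statistics.
#'
#' @param traces Long trace tibble (may contain several conditions).
#' @param condition Condition label to fit; `NULL` is allowed when `traces`
#'   holds a single condition.
#' @param k Spline basis dimension (>= 4).
#' @param method Smoothing-parameter criterion (`"REML"` or `"GCV.Cp"`).
#' @param downsample_hz Thinning rate before fitting (`NULL` to skip).
#' @param grid_dt Spacing of the prediction grid (seconds).
#' @param subject_intercept Add `s(subject, bs = "re")`.
#' @return Object of class `"smooth_fit"`: the fitted `gam`, the condition
#'   label, `k`, `edf`, the number of subjects, and a `grid` tibble with
#'   `time_s`, `fit`, `se`.
#' @export
fit_condition_smooth <- function(traces, condition = NULL, k = 10,
                                 method = "REML", downsample_hz = 1,
                                 grid_dt = 1, subject_intercept = FALSE) {
  if (!is.null(condition)) {
    traces <- traces[traces$condition == condition, , drop = FALSE]
  } else {
    cu <- unique(traces$condition)
    if (length(cu) != 1) stop("supply `condition` when traces hold several")
    condition <- cu
  }
  if (nrow(traces) == 0) stop("no data for condition ", condition)
  n_subj <- length(unique(traces$subject))
  if (n_subj < 2) stop("need at least 2 subjects to fit a condition smooth")
  if (!is.null(downsample_hz)) traces <- downsample_traces(traces, downsample_hz)
  if (k < 4) stop("k must be >= 4")
  if (k > length(unique(traces$time_s))) {
    stop("basis dimension k exceeds the number of distinct time points")
  }
  dat <- data.frame(time_s = traces$time_s, intensity = traces$intensity,
                    subject = factor(traces$subject))
  form <- if (subject_intercept && n_subj > 1) {
    intensity ~ s(time_s, bs = "cr", k = k) + s(subject, bs = "re")
  } else {
    intensity ~ s(time_s, bs = "cr", k = k)
  }
  # Smoothing-parameter criteria are undefined at zero residual variance
  # (e.g. an exactly constant condition); fall back to a fixed heavy penalty,
  # whose fit is the penalty-null-space (here: the least-squares line /
  # constant) the criterion would select in the limit.
  g <- tryCatch(
    mgcv::gam(form, data = dat, method = method),
    error = function(e) {
      nsp <- if (subject_intercept && n_subj > 1) c(1e8, 1e8) else 1e8
      mgcv::gam(form, data = dat, sp = nsp)
    }
  )
  grid_t <- seq(min(dat$time_s), max(dat$time_s), by = grid_dt)
  pred <- predict_population(g, grid_t, subject_intercept, dat)
  st <- summary(g)$s.table
  structure(list(
    condition = condition, k = k, method = method,
    n_subjects = n_subj, subject_intercept = subject_intercept,
    gam = g,
    edf = unname(st[1, "edf"]),
    sigma = sqrt(g$sig2),
    grid = tibble::tibble(time_s = grid_t, fit = pred$fit, se = pred$se)
  ), class = "smooth_fit")
}

# Population-level prediction (random-effect columns zeroed) with model-based
# standard errors from the coefficient covariance.
predict_population <- function(g, grid_t, subject_intercept, dat) {
  nd <- data.frame(time_s = grid_t)
  if (subject_intercept) nd$subject <- factor(dat$subject[1], levels(dat$subject))
  Xp <- stats::predict(g, nd, type = "lpmatrix")
  if (subject_intercept) {
    Xp[, grep("s\\(subject\\)", colnames(Xp))] <- 0
  }
  V <- stats::vcov(g)
  list(fit = as.numeric(Xp %*% stats::coef(g)),
       se = sqrt(pmax(rowSums((Xp %*% V) * Xp), 0)))
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("<smooth_fit> condition %s: cr k=%d (%s), %d subjects, edf=%.2f\n",
              x$condition, x$k, x$method, x$n_subjects, x$edf))
  invisible(x)
}

#' Wald-type test that a condition smooth is identically zero
#'
#' The approximate test of the smooth term reported by `summary.gam`
#' (penalized coefficients against their covariance, reference degrees of
#' freedom tied to the edf).
#'
#' @param fit A [fit_condition_smooth()] result.
#' @return Tibble: `condition`, `edf`, `ref_df`, `statistic`, `p_value`.
#' @export
wald_smooth_test <- function(fit) {
  stopifnot(inherits(fit, "smooth_fit"))
  st <- summary(fit$gam)$s.table
  stat_col <- intersect(c("F", "Chi.sq"), colnames(st))[1]
  tibble::tibble(
    condition = fit$condition,
    edf = unname(st[1, "edf"]),
    ref_df = unname(st[1, "Ref.df"]),
    statistic = unname(st[1, stat_col]),
    p_value = unname(st[1, "p-value"])
  )
}

#' Mean vertical offset between two condition smooths
#'
#' Averages (fitA - fitB) over a shared time grid. The standard error is
#' propagated from each fit's coefficient covariance (the grid average is a
#' linear functional of the coefficients), treating the fits as independent
#' -- appropriate for a between-subject design. `t = offset / SE` is referred
#' to a t distribution with `df` degrees of freedom (default: subjects in the
#' smaller condition minus one).
#'
#' @param fit_a,fit_b [fit_condition_smooth()] results with overlapping span.
#' @param grid Time grid (seconds); default: 1 s steps over the overlap.
#' @param df Reference degrees of freedom.
#' @return List with class `"smooth_contrast"`: `conditions`, `offset`, `se`,
#'   `t`, `df`, `p_value`.
#' @export
smooth_contrast <- function(fit_a, fit_b, grid = NULL, df = NULL) {
  stopifnot(inherits(fit_a, "smooth_fit"), inherits(fit_b, "smooth_fit"))
  lo <- max(min(fit_a$grid$time_s), min(fit_b$grid$time_s))
  hi <- min(max(fit_a$grid$time_s), max(fit_b$grid$time_s))
  if (lo >= hi) stop("the two fits have disjoint time spans")
  if (is.null(grid)) grid <- seq(lo, hi, by = 1)
  if (any(grid < lo) || any(grid > hi)) {
    stop("grid extends outside the shared time span")
  }
  est <- function(fit) {
    nd <- data.frame(time_s = grid)
    if (fit$subject_intercept) {
      nd$subject <- fit$gam$model$subject[1]
    }
    Xp <- stats::predict(fit$gam, nd, type = "lpmatrix")
    if (fit$subject_intercept) Xp[, grep("s\\(subject\\)", colnames(Xp))] <- 0
    cvec <- colMeans(Xp)
    list(mu = sum(cvec * stats::coef(fit$gam)),
         var = as.numeric(cvec %*% stats::vcov(fit$gam) %*% cvec))
  }
  ea <- est(fit_a); eb <- est(fit_b)
  offset <- ea$mu - eb$mu
  se <- sqrt(ea$var + eb$var)
  if (is.null(df)) df <- max(min(fit_a$n_subjects, fit_b$n_subjects) - 1, 1)
  tval <- if (se > 0) offset / se else 0
  structure(list(
    conditions = c(fit_a$condition, fit_b$condition),
    offset = offset, se = se, t = tval, df = df,
    p_value = 2 * stats::pt(-abs(tval), df)
  ), class = "smooth_contrast")
}

#' @export
print.smooth_contrast <- function(x, ...) {
  cat(sprintf("<smooth_contrast> %s - %s: offset %.3f (SE %.3f), t(%g) = %.2f, p = %.3g\n",
              x$conditions[1], x$conditions[2], x$offset, x$se, x$df, x$t,
              x$p_value))
  invisible(x)
}

#' Pointwise confidence band for a condition smooth
#'
#' `fit +/- z * SE` at each grid point, `z` the standard normal quantile for
#' the requested level (1.959964 at 95%). Pointwise, not simultaneous.
#'
#' @param fit A [fit_condition_smooth()] result.
#' @param level Coverage level in (0, 1).
#' @return The fit's grid tibble with `lower` and `upper` columns added.
#' @export
pointwise_band <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "smooth_fit"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  dplyr::mutate(fit$grid,
                lower = .data$fit - z * .data$se,
                upper = .data$fit + z * .data$se)
}
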