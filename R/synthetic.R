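# Synthetic perception-study generator.
#
# Ground-truth curve shape: zero before onset, linear rise to the peak,
# constant plateau, then exponential decay toward zero -- the simplest
# continuous shape whose TI parameters all have closed forms, emulating the
# typical time course (peak within the first minute, slow decay over five
# minutes, a fraction of non-perceivers, between-subject spread of the same
# order as the means).

#' Ground-truth profile parameters for one synthetic subject
#'
#' @param onset_latency_s Seconds before the percept starts (>= 0).
#' @param rise_duration_s Seconds of linear rise to the peak (> 0).
#' @param peak_intensity Peak intensity, VAS cm in \[0, 10\].
#' @param plateau_duration_s Seconds the profile stays at the peak (>= 0).
#' @param decay_rate Exponential decay rate (per second, > 0) after the
#'   plateau ends.
#' @param perceiver If `FALSE`, the noiseless profile is identically zero.
#' @return A list with class `"profile_params"`.
#' @export
profile_params <- function(onset_latency_s = 13,
                           rise_duration_s = 25,
                           peak_intensity = 5.5,
                           plateau_duration_s = 20,
                           decay_rate = 0.01,
                           perceiver = TRUE) {
  stopifnot(
    onset_latency_s >= 0, rise_duration_s > 0,
    peak_intensity >= 0, peak_intensity <= 10,
    plateau_duration_s >= 0, decay_rate > 0
  )
  structure(list(
    onset_latency_s = onset_latency_s, rise_duration_s = rise_duration_s,
    peak_intensity = peak_intensity, plateau_duration_s = plateau_duration_s,
    decay_rate = decay_rate, perceiver = isTRUE(perceiver)
  ), class = "profile_params")
}

#' Rating-noise parameters
#'
#' Additive first-order autoregressive noise emulating continuous slider
#' adjustment. The autocorrelation is parameterized per second of lag (so
#' its meaning does not depend on the sampling rate); the default
#' `exp(-1/10)` corresponds to a 10-second correlation time, reflecting the
#' slow pace at which raters re-evaluate a percept. White noise would be
#' unrealistic here: it crosses the 5% onset threshold almost immediately.
#'
#' @param sd Stationary standard deviation of the noise (VAS cm, >= 0).
#' @param ar Lag-one-second autocorrelation in \[0, 1).
#' @param subject_scale_sd Standard deviation of a log-normal multiplicative
#'   subject scale applied to the whole profile (0 disables; study-level
#'   between-subject variability is usually expressed through
#'   [study_design()] instead).
#' @return A list with class `"noise_params"`.
#' @export
noise_params <- function(sd = 0.2, ar = exp(-1 / 10), subject_scale_sd = 0) {
  stopifnot(sd >= 0, ar >= 0, ar < 1, subject_scale_sd >= 0)
  structure(list(sd = sd, ar = ar, subject_scale_sd = subject_scale_sd),
            class = "noise_params")
}

#' Evaluate the noiseless intensity profile
#'
#' Piecewise: 0 before onset; linear rise to `peak_intensity` over
#' `rise_duration_s`; constant over `plateau_duration_s`; then
#' `peak * exp(-decay_rate * (t - plateau_end))`. Continuous everywhere;
#' identically 0 for non-perceivers.
#'
#' @param params A [profile_params()].
#' @param t Vector of times in seconds (>= 0).
#' @return Intensities at `t`.
#' @export
profile_value <- function(params, t) {
  stopifnot(inherits(params, "profile_params"), all(t >= 0))
  if (!params$perceiver) return(rep(0, length(t)))
  on <- params$onset_latency_s
  rise <- params$rise_duration_s
  pk <- params$peak_intensity
  tpe <- on + rise + params$plateau_duration_s
  ifelse(t < on, 0,
  ifelse(t < on + rise, pk * (t - on) / rise,
  ifelse(t <= tpe, pk, pk * exp(-params$decay_rate * (t - tpe)))))
}

#' Closed-form TI parameters of a noiseless profile
#'
#' Applies the TI definitions (onset/extinction at `onset_fraction` of the
#' maximum, plateau above `plateau_fraction`, least-squares slopes, exact
#' areas) analytically to the continuous profile; this is the generative
#' ground truth that [extract_ti()] should recover from sampled traces.
#' The extinction time is truncated at the study duration when the decay has
#' not yet crossed the threshold (censoring).
#'
#' @param params A [profile_params()].
#' @param config A [ti_config()].
#' @return One-row tibble with the ten TI parameters plus `ext_censored`;
#'   all `NA` for non-perceivers.
#' @export
true_ti <- function(params, config = ti_config()) {
  stopifnot(inherits(params, "profile_params"))
  na_row <- tibble::as_tibble(stats::setNames(
    as.list(rep(NA_real_, 10)), ti_param_names()))
  if (!params$perceiver || params$peak_intensity <= 0) {
    na_row$ext_censored <- NA
    return(na_row)
  }
  on <- params$onset_latency_s; rise <- params$rise_duration_s
  pk <- params$peak_intensity; pl <- params$plateau_duration_s
  lam <- params$decay_rate; dur <- config$duration_s
  f_on <- config$onset_fraction; f_pl <- config$plateau_fraction
  if (on + rise + pl > dur) {
    stop("profile (onset + rise + plateau) exceeds the study duration")
  }
  t_max <- on + rise
  t_pe <- t_max + pl
  t_onset <- on + rise * f_on
  t_ext_raw <- t_pe + log(1 / f_on) / lam
  censored <- t_ext_raw > dur
  t_ext <- min(t_ext_raw, dur)
  pl_start <- on + rise * f_pl
  pl_end <- min(t_pe + log(1 / f_pl) / lam, dur)
  plateau_s <- pl_end - pl_start

  slope_pre <- pk / rise  # profile exactly linear on [t_onset, t_max]
  slope_post <- ols_slope_plateau_decay(pk, t_max, t_pe, lam, t_ext)

  auc_pre <- pk * rise / 2
  auc_total <- auc_pre + pk * pl + (pk / lam) * (1 - exp(-lam * (dur - t_pe)))

  tibble::tibble(
    i_max = pk, t_max = t_max, t_onset = t_onset, t_extinction = t_ext,
    plateau_s = plateau_s, slope_pre = slope_pre, slope_post = slope_post,
    auc_total = auc_total, auc_pre = auc_pre, auc_post = auc_total - auc_pre,
    ext_censored = censored
  )
}

# Continuous-time least-squares slope of x(t) on [a, b] where x is constant
# `pk` on [a, tpe] then pk*exp(-lam*(t - tpe)). Closed form from the moment
# integrals S0 = int x, S1 = int t x, Stt = (b - a)^3 / 12.
ols_slope_plateau_decay <- function(pk, a, tpe, lam, b) {
  if (b <= a) return(NA_real_)
  cc <- b - tpe
  E <- exp(-lam * cc)
  S0 <- pk * (tpe - a) + (pk / lam) * (1 - E)
  S1 <- pk * (tpe^2 - a^2) / 2 +
    pk * ((1 - E * (1 + lam * cc)) / lam^2 + tpe * (1 - E) / lam)
  tbar <- (a + b) / 2
  Stt <- (b - a)^3 / 12
  (S1 - tbar * S0) / Stt
}

#' Simulate one subject's intensity trace
#'
#' Samples the noiseless profile at the configured rate, adds stationary
#' AR(1) rating noise, optionally applies a log-normal subject scale, and
#' clamps to the VAS range \[0, 10\]. Deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param params A [profile_params()].
#' @param noise A [noise_params()].
#' @param config A [ti_config()].
#' @param seed Integer seed.
#' @param subject,condition Identifier strings stored in the output.
#' @return Trace tibble (`subject`, `condition`, `time_s`, `intensity`).
#' @export
simulate_subject <- function(params, noise = noise_params(),
                             config = ti_config(), seed = 1,
                             subject = "s01", condition = "cond") {
  t <- seq(0, config$duration_s, by = 1 / config$sample_rate_hz)
  prof <- profile_value(params, t)
  v <- with_local_seed(seed, {
    scale <- if (noise$subject_scale_sd > 0) {
      stats::rlnorm(1, -noise$subject_scale_sd^2 / 2, noise$subject_scale_sd)
    } else 1
    prof2 <- prof * scale
    if (noise$sd > 0) prof2 + ar1_noise(length(t), noise, config$sample_rate_hz)
    else prof2
  })
  tibble::tibble(subject = subject, condition = condition,
                 time_s = t, intensity = pmin(pmax(v, 0), 10))
}

# Stationary AR(1) sequence with sd `noise$sd`; `noise$ar` is the
# lag-one-second autocorrelation, converted to the per-sample coefficient.
ar1_noise <- function(n, noise, rate_hz) {
  a <- noise$ar^(1 / rate_hz)
  innov <- stats::rnorm(n, 0, noise$sd * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = stats::rnorm(1, 0, noise$sd)))
}

# Evaluate `expr` under set.seed(seed) and restore the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject sub-stream: adding a subject or condition never
# perturbs the draws of the others. Kept below 2^31.
derive_seed <- function(seed, cond_index, subj_index) {
  as.integer((abs(seed) %% 1000003L) * 1009L +
               cond_index * 10007L + subj_index * 101L) %% 2147483629L
}

#' Study design for the synthetic generator
#'
#' @param conditions Named list; each element describes one condition as a
#'   list with fields `profile` (a [profile_params()] of condition-mean
#'   parameters), `cv` (named list of log-normal `sdlog` values for the
#'   between-subject spread of `onset`, `rise`, `peak`, `plateau`, `decay`;
#'   0 disables variability for that parameter), and `word_probs` (named
#'   per-word selection probabilities over the vocabulary; missing words get
#'   0).
#' @param n_per_condition Subjects per condition (between-subject design).
#' @param nonperceiver_rate Probability a subject perceives nothing
#'   (zero-signal trace; TI ground truth undefined).
#' @return A list with class `"study_design"`.
#' @export
study_design <- function(conditions, n_per_condition = 20,
                         nonperceiver_rate = 0.125) {
  stopifnot(
    length(conditions) >= 1, !is.null(names(conditions)),
    n_per_condition >= 1,
    nonperceiver_rate >= 0, nonperceiver_rate < 1
  )
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    stopifnot(inherits(cond$profile, "profile_params"))
    if (any(unlist(cond$word_probs) < 0) || any(unlist(cond$word_probs) > 1)) {
      stop("word probabilities must lie in [0, 1] (condition ", cn, ")")
    }
  }
  structure(list(conditions = conditions, n_per_condition = n_per_condition,
                 nonperceiver_rate = nonperceiver_rate),
            class = "study_design")
}

#' Default four-condition study design
#'
#' A study-shaped default: four chemical stimulant conditions with 20
#' subjects each, condition-mean profiles whose noiseless TI parameters echo
#' typical reported scales (peak intensities ~3.8-5.7 cm, onsets ~10-30 s,
#' total AUC ~400-790 cm*s), log-normal between-subject variability of the
#' same order as the means, a 12.5% non-perceiver rate, and cool-dominant
#' word-selection probabilities with a distinct menthol pattern.
#'
#' @param n_per_condition Subjects per condition.
#' @return A [study_design()].
#' @export
ti_study_design <- function(n_per_condition = 20) {
  cv <- list(onset = 0.6, rise = 0.3, peak = 0.42, plateau = 0.5, decay = 0.3)
  wp <- function(...) {
    p <- list(...)
    stats::setNames(as.numeric(p), names(p))
  }
  study_design(
    conditions = list(
      capsaicin = list(
        profile = profile_params(18, 25, 5.7, 20, 0.008), cv = cv,
        word_probs = wp(cool = 0.35, warm = 0.45, sting = 0.55, itch = 0.20,
                        tingle = 0.30, numb = 0.10, pressure = 0.10,
                        wet = 0.05, vibration = 0.05)),
      cinnamal = list(
        profile = profile_params(12, 25, 5.5, 27, 0.0105), cv = cv,
        word_probs = wp(cool = 0.55, warm = 0.30, sting = 0.45, itch = 0.15,
                        tingle = 0.30, numb = 0.10, pressure = 0.10,
                        wet = 0.10, vibration = 0.05)),
      ethanol = list(
        profile = profile_params(10, 20, 4.0, 15, 0.011), cv = cv,
        word_probs = wp(cool = 0.60, warm = 0.15, sting = 0.40, itch = 0.10,
                        tingle = 0.25, numb = 0.10, pressure = 0.05,
                        wet = 0.25, vibration = 0.05)),
      menthol = list(
        profile = profile_params(28, 25, 3.8, 15, 0.012), cv = cv,
        word_probs = wp(cool = 0.90, warm = 0.05, sting = 0.30, itch = 0.10,
                        tingle = 0.40, numb = 0.25, pressure = 0.05,
                        wet = 0.15, vibration = 0.10))
    ),
    n_per_condition = n_per_condition,
    nonperceiver_rate = 0.125
  )
}

draw_profile <- function(mean_profile, cv, duration_s) {
  ln <- function(m, s) if (s > 0) m * stats::rlnorm(1, -s^2 / 2, s) else m
  p <- list(
    onset = ln(mean_profile$onset_latency_s, cv$onset),
    rise = ln(mean_profile$rise_duration_s, cv$rise),
    peak = min(ln(mean_profile$peak_intensity, cv$peak), 10),
    plateau = ln(mean_profile$plateau_duration_s, cv$plateau),
    decay = ln(mean_profile$decay_rate, cv$decay)
  )
  # keep onset + rise + plateau inside the study window
  tot <- p$onset + p$rise + p$plateau
  if (tot > 0.98 * duration_s) {
    sc <- 0.98 * duration_s / tot
    p$onset <- p$onset * sc; p$rise <- p$rise * sc; p$plateau <- p$plateau * sc
  }
  profile_params(p$onset, p$rise, p$peak, p$plateau, p$decay)
}

#' Simulate a complete between-subject study
#'
#' Draws per-subject profile parameters from the per-condition
#' distributions, simulates each trace with [simulate_subject()], draws word
#' selections independently per word from the condition probabilities, and
#' records the generative ground truth (profile parameters and closed-form
#' TI values). Each subject has a deterministic seed sub-stream derived from
#' `seed`, so the draw for one subject never depends on how many others
#' exist.
#'
#' @param design A [study_design()].
#' @param config A [ti_config()].
#' @param noise A [noise_params()].
#' @param seed Integer master seed.
#' @return List with class `"ti_study"`: `traces` (long tibble), `words`
#'   (selection tibble over the full vocabulary), `truth` (one row per
#'   subject: profile parameters, perceiver flag, true TI).
#' @export
simulate_study <- function(design = ti_study_design(), config = ti_config(),
                           noise = noise_params(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  vocab <- config$vocabulary
  traces <- list(); words <- list(); truth <- list()
  cond_names <- names(design$conditions)
  for (ci in seq_along(cond_names)) {
    cn <- cond_names[ci]
    cond <- design$conditions[[cn]]
    probs <- stats::setNames(rep(0, length(vocab)), vocab)
    known <- intersect(names(cond$word_probs), vocab)
    probs[known] <- cond$word_probs[known]
    for (si in seq_len(design$n_per_condition)) {
      sid <- sprintf("%s_%02d", cn, si)
      sseed <- derive_seed(seed, ci, si)
      drawn <- with_local_seed(sseed, {
        perceiver <- stats::runif(1) >= design$nonperceiver_rate
        prof <- if (perceiver) {
          draw_profile(cond$profile, cond$cv, config$duration_s)
        } else {
          pp <- cond$profile
          profile_params(pp$onset_latency_s, pp$rise_duration_s,
                         pp$peak_intensity, pp$plateau_duration_s,
                         pp$decay_rate, perceiver = FALSE)
        }
        sel <- stats::runif(length(vocab)) < probs
        list(prof = prof, sel = sel)
      })
      tr <- simulate_subject(drawn$prof, noise, config,
                             seed = derive_seed(seed + 1L, ci, si),
                             subject = sid, condition = cn)
      traces[[sid]] <- tr
      words[[sid]] <- tibble::tibble(subject = sid, condition = cn,
                                     word = vocab, selected = drawn$sel)
      tt <- true_ti(drawn$prof, config)
      truth[[sid]] <- dplyr::bind_cols(
        tibble::tibble(subject = sid, condition = cn,
                       perceiver = drawn$prof$perceiver,
                       onset_latency_s = drawn$prof$onset_latency_s,
                       rise_duration_s = drawn$prof$rise_duration_s,
                       peak_intensity = drawn$prof$peak_intensity,
                       plateau_duration_s = drawn$prof$plateau_duration_s,
                       decay_rate = drawn$prof$decay_rate),
        stats::setNames(tt, paste0("true_", names(tt)))
      )
    }
  }
  structure(list(
    traces = dplyr::bind_rows(traces),
    words = dplyr::bind_rows(words),
    truth = dplyr::bind_rows(truth)
  ), class = "ti_study")
}

#' Write a simulated study to a directory
#'
#' Emits `intensity.csv` and `words.csv` in the canonical formats plus
#' `ground_truth.csv`.
#'
#' @param study A `"ti_study"` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ti_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_table(study$traces, file.path(dir, "intensity.csv"))
  write_word_table(study$words, file.path(dir, "words.csv"))
  readr::write_csv(study$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
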