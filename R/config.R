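#' Default sensation-descriptor vocabulary
#'
#' Nine descriptor words used for the word-selection stage. The published
#' word list is not reproduced here; this is a configurable placeholder set
#' of the same size (so a chi-square comparison has 8 degrees of freedom).
#'
#' @return Character vector of descriptor words.
#' @export
ti_vocabulary <- function() {
  c("cool", "warm", "sting", "itch", "tingle",
    "numb", "pressure", "wet", "vibration")
}

#' Study configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' All downstream functions take a `ti_config`; every value can be
#' overridden, so the 5%/95% TI thresholds, smoothing basis, and vocabulary
#' are never hard-coded elsewhere.
#'
#' @param duration_s Study length in seconds rated by each subject.
#' @param sample_rate_hz Nominal sampling rate of the intensity logger (Hz).
#' @param onset_fraction Fraction of the per-trace maximal intensity whose
#'   first upward crossing defines perception onset, and whose first downward
#'   crossing after the maximum defines extinction. Default 0.05.
#' @param plateau_fraction Fraction of the maximal intensity above which the
#'   trace counts as plateaued around the maximum. Default 0.95.
#' @param vocabulary Character vector of descriptor words.
#' @param k Basis dimension for the penalized cubic regression spline smooth.
#' @param smooth_method Smoothing-parameter selection, `"REML"` or `"GCV.Cp"`.
#' @param downsample_hz Rate the traces are thinned to before smoothing
#'   (time-intensity extraction always uses full resolution).
#' @param p_adjust Multiple-testing adjustment for Dunn post-hoc p-values;
#'   any method of [stats::p.adjust()] (default `"none"`: raw two-sided).
#' @param alpha Significance level.
#'
#' @return A list with class `"ti_config"`.
#' @export
ti_config <- function(duration_s = 300,
                      sample_rate_hz = 60,
                      onset_fraction = 0.05,
                      plateau_fraction = 0.95,
                      vocabulary = ti_vocabulary(),
                      k = 10,
                      smooth_method = "REML",
                      downsample_hz = 1,
                      p_adjust = "none",
                      alpha = 0.05) {
  cfg <- list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    onset_fraction = onset_fraction, plateau_fraction = plateau_fraction,
    vocabulary = vocabulary, k = k, smooth_method = smooth_method,
    downsample_hz = downsample_hz, p_adjust = p_adjust, alpha = alpha
  )
  class(cfg) <- "ti_config"
  validate_ti_config(cfg)
}

validate_ti_config <- function(cfg) {
  stopifnot(
    "duration_s must be > 0" = is.numeric(cfg$duration_s) && cfg$duration_s > 0,
    "sample_rate_hz must be > 0" = cfg$sample_rate_hz > 0,
    "need 0 < onset_fraction < plateau_fraction < 1" =
      cfg$onset_fraction > 0 && cfg$onset_fraction < cfg$plateau_fraction &&
      cfg$plateau_fraction < 1,
    "vocabulary must be non-empty and unique" =
      length(cfg$vocabulary) > 0 && !anyDuplicated(cfg$vocabulary),
    "k must be >= 4" = cfg$k >= 4,
    "alpha in (0,1)" = cfg$alpha > 0 && cfg$alpha < 1
  )
  cfg$smooth_method <- match.arg(cfg$smooth_method, c("REML", "GCV.Cp", "ML"))
  cfg
}

#' Read a study configuration from a YAML file
#'
#' Any subset of the [ti_config()] fields may be present; missing fields get
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `ti_config`.
#' @export
read_ti_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ti_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("ignoring unknown config fields: ", paste(extra, collapse = ", "))
  }
  do.call(ti_config, raw[intersect(names(raw), known)])
}

#' @export
print.ti_config <- function(x, ...) {
  cat("<ti_config>\n")
  cat(sprintf("  duration %gs @ %g Hz; thresholds %g%%/%g%% of trace max\n",
              x$duration_s, x$sample_rate_hz,
              100 * x$onset_fraction, 100 * x$plateau_fraction))
  cat(sprintf("  smooth: cr basis k=%d, %s, downsample %g Hz\n",
              x$k, x$smooth_method, x$downsample_hz))
  cat(sprintf("  vocabulary (%d): %s\n", length(x$vocabulary),
              paste(x$vocabulary, collapse = ", ")))
  cat(sprintf("  Dunn adjust: %s; alpha = %g\n", x$p_adjust, x$alpha))
  invisible(x)
}
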