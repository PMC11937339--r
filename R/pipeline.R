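# End-to-end orchestration: io -> TI extraction -> group statistics, plus
# smoothing and word comparisons, with deterministic CSV outputs and a
# provenance block. All randomness lives in the synthetic generator; the
# analysis itself is seed-free.

#' Run the full study analysis
#'
#' Reads the canonical intensity and word CSVs, extracts TI parameters per
#' trace, runs the Kruskal-Wallis / Dunn / effect-size battery per parameter,
#' fits one penalized-spline smooth per condition (with Wald tests and all
#' pairwise mean-offset contrasts), tabulates and compares word
#' distributions, and assembles everything into a report. If `out_dir` is
#' given, tidy CSVs are written there; any stage error removes partial
#' outputs and is re-signalled with the stage name.
#'
#' When `truth` (a ground-truth table from [simulate_study()]) is supplied,
#' a validation sheet comparing per-condition extracted TI means to the
#' generative truth is added; deviations beyond `recovery_tol` raise an
#' error, so synthetic end-to-end runs fail loudly when recovery degrades.
#'
#' @param config A [ti_config()].
#' @param intensity_path,words_path Canonical CSV inputs.
#' @param out_dir Optional output directory for the report CSVs.
#' @param ref_condition Optional condition supplying expected word
#'   frequencies (see [compare_words_pairwise()]).
#' @param truth Optional ground-truth tibble (columns `condition` and
#'   `true_*` TI values).
#' @param recovery_tol Named numeric tolerances on
#'   `|mean(extracted) - mean(truth)|` per TI parameter; only used with
#'   `truth`.
#' @return List with class `"ti_report"`: `ti`, `comparison`
#'   (a `"ti_comparison"`), `smooths`, `smooth_tests`, `smooth_contrasts`,
#'   `word_counts`, `word_tests`, `validation` (or `NULL`), `provenance`.
#' @export
run_study_analysis <- function(config, intensity_path, words_path,
                               out_dir = NULL, ref_condition = NULL,
                               truth = NULL, recovery_tol = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) unlink(out_dir, recursive = TRUE)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  traces <- stage("io", read_intensity_table(intensity_path, config))
  words <- stage("io", read_word_table(words_path, config))

  ti <- stage("ti_extraction", extract_ti_table(traces, config))
  comparison <- stage("group_stats", summarize_ti(ti, config))

  conds <- sort(unique(traces$condition))
  smooths <- stage("smoothing", lapply(
    stats::setNames(conds, conds),
    function(cn) fit_condition_smooth(
      traces, cn, k = config$k, method = config$smooth_method,
      downsample_hz = config$downsample_hz)
  ))
  smooth_tests <- stage("smoothing",
                        dplyr::bind_rows(lapply(smooths, wald_smooth_test)))
  smooth_contrasts <- stage("smoothing", {
    if (length(conds) >= 2) {
      prs <- utils::combn(conds, 2)
      dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(i) {
        sc <- smooth_contrast(smooths[[prs[1, i]]], smooths[[prs[2, i]]])
        tibble::tibble(condition_a = prs[1, i], condition_b = prs[2, i],
                       offset = sc$offset, se = sc$se, t = sc$t, df = sc$df,
                       p_value = sc$p_value)
      }))
    } else tibble::tibble()
  })

  word_counts <- stage("word_stats", tabulate_words(words, config$vocabulary))
  word_tests <- stage("word_stats", {
    if (length(conds) >= 2) {
      compare_words_pairwise(word_counts, ref_condition,
                             on_zero_expected = "skip")
    } else tibble::tibble()
  })

  validation <- NULL
  if (!is.null(truth)) {
    validation <- stage("validation",
                        recovery_sheet(ti, truth, recovery_tol))
  }

  report <- structure(list(
    ti = ti, comparison = comparison,
    smooths = smooths, smooth_tests = smooth_tests,
    smooth_contrasts = smooth_contrasts,
    word_counts = word_counts, word_tests = word_tests,
    validation = validation,
    provenance = list(
      package = "titrace",
      version = as.character(utils::packageVersion("titrace")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = unclass(config),
      inputs = c(intensity = unname(tools::md5sum(intensity_path)),
                 words = unname(tools::md5sum(words_path)))
    )
  ), class = "ti_report")

  if (!is.null(out_dir)) stage("write", write_report(report, out_dir, config))
  report
}

recovery_sheet <- function(ti, truth, tol = NULL) {
  params <- intersect(ti_param_names(), names(ti))
  # compare on the same subjects: perceivers only (non-perceiver truth is NA
  # while their noise traces still yield extracted values)
  joined <- dplyr::inner_join(ti, truth, by = c("subject", "condition"),
                              suffix = c("", ".truth"))
  joined <- joined[joined$perceiver, , drop = FALSE]
  rows <- lapply(params, function(p) {
    em <- tapply(joined[[p]], joined$condition, mean, na.rm = TRUE)
    tm <- tapply(joined[[paste0("true_", p)]], joined$condition,
                 mean, na.rm = TRUE)
    conds <- intersect(names(em), names(tm))
    tibble::tibble(parameter = p, condition = conds,
                   extracted_mean = as.numeric(em[conds]),
                   true_mean = as.numeric(tm[conds]),
                   abs_error = abs(as.numeric(em[conds]) - as.numeric(tm[conds])))
  })
  sheet <- dplyr::bind_rows(rows)
  if (!is.null(tol)) {
    sheet$tolerance <- unname(tol[sheet$parameter])
    bad <- !is.na(sheet$tolerance) & sheet$abs_error > sheet$tolerance
    if (any(bad)) {
      stop("parameter recovery tolerance violated: ",
           paste(sprintf("%s/%s (|err| %.3g > %.3g)",
                         sheet$parameter[bad], sheet$condition[bad],
                         sheet$abs_error[bad], sheet$tolerance[bad]),
                 collapse = "; "))
    }
  }
  sheet
}

write_report <- function(report, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
  write_ti_table(report$ti, file.path(out_dir, "ti.csv"))
  w(report$comparison$summary, "ti_summary.csv")
  w(report$comparison$kruskal, "ti_tests.csv")
  w(report$comparison$pairwise, "ti_pairwise.csv")
  grids <- dplyr::bind_rows(lapply(report$smooths, function(f) {
    dplyr::bind_cols(tibble::tibble(condition = f$condition),
                     pointwise_band(f, 0.95))
  }))
  names(grids)[names(grids) == "lower"] <- "lo95"
  names(grids)[names(grids) == "upper"] <- "hi95"
  w(grids, "smooth_grid.csv")
  w(report$smooth_tests, "smooth_tests.csv")
  if (nrow(report$smooth_contrasts) > 0) w(report$smooth_contrasts, "smooth_contrasts.csv")
  w(report$word_counts, "word_counts.csv")
  if (nrow(report$word_tests) > 0) w(report$word_tests, "word_tests.csv")
  if (!is.null(report$validation)) w(report$validation, "validation.csv")
  prov <- report$provenance
  prov$config$vocabulary <- paste(prov$config$vocabulary, collapse = ";")
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' @export
print.ti_report <- function(x, ...) {
  cat("<ti_report>\n")
  cat(sprintf("  %d trace(s), %d condition(s); %d TI rows\n",
              nrow(x$ti), length(x$smooths), nrow(x$ti)))
  cat(sprintf("  smooth tests: %d; word tests: %d; validation: %s\n",
              nrow(x$smooth_tests), nrow(x$word_tests),
              if (is.null(x$validation)) "none" else "attached"))
  invisible(x)
}

#' Figures for an analysis report
#'
#' Builds (1) the per-condition smooths with 95% pointwise bands, (2) word
#' frequency bars per condition, and (3) the ten TI parameter panels with
#' SEM error bars and significance letters (same letter = significantly
#' different pair). Returns ggplot objects; writes PNGs when `out_dir` is
#' given.
#'
#' @param report A `"ti_report"`.
#' @param out_dir Optional directory for PNG files.
#' @return Named list of ggplot objects, invisibly.
#' @export
plot_report <- function(report, out_dir = NULL) {
  stopifnot(inherits(report, "ti_report"))
  grids <- dplyr::bind_rows(lapply(report$smooths, function(f) {
    dplyr::bind_cols(tibble::tibble(condition = f$condition),
                     pointwise_band(f, 0.95))
  }))
  p_smooth <- ggplot2::ggplot(grids, ggplot2::aes(
      x = .data$time_s, y = .data$fit,
      ymin = .data$lower, ymax = .data$upper,
      colour = .data$condition, fill = .data$condition)) +
    ggplot2::geom_ribbon(alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "perceived intensity (cm)",
                  title = "Condition smooths with 95% pointwise bands") +
    ggplot2::theme_minimal()

  wc <- report$word_counts
  p_words <- ggplot2::ggplot(wc, ggplot2::aes(
      x = factor(.data$word, levels = unique(.data$word)),
      y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "subjects selecting",
                  title = "Descriptor selections") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))

  summ <- report$comparison$summary
  p_ti <- ggplot2::ggplot(summ, ggplot2::aes(
      x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + .data$sem),
                       vjust = -0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean +/- SEM",
                  title = "TI parameters (same letter = significant pair)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))

  plots <- list(smooths = p_smooth, words = p_words, ti = p_ti)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), plots[[nm]],
                      width = 9, height = 6, dpi = 150)
    }
  }
  invisible(plots)
}
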