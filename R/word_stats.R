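# Sensation-descriptor tabulation and one-sample chi-square comparison of
# word distributions between conditions.

#' Tabulate word selections per condition
#'
#' Counts, for every condition and vocabulary word, how many subjects
#' selected it, plus the number of subjects per condition.
#'
#' @param words Word tibble (`subject`, `condition`, `word`, `selected`), as
#'   from [read_word_table()] or [simulate_study()].
#' @param vocabulary Descriptor list fixing the word order; defaults to the
#'   words present.
#' @return Tibble: `condition`, `word` (ordered per vocabulary), `count`,
#'   `n_subjects`.
#' @export
tabulate_words <- function(words, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- unique(words$word)
  conds <- unique(words$condition)
  out <- tidyr::expand_grid(condition = conds, word = vocabulary)
  cnt <- words |>
    dplyr::filter(.data$word %in% vocabulary) |>
    dplyr::group_by(.data$condition, .data$word) |>
    dplyr::summarise(count = sum(.data$selected), .groups = "drop")
  nsub <- words |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_subjects = dplyr::n_distinct(.data$subject),
                     .groups = "drop")
  out |>
    dplyr::left_join(cnt, by = c("condition", "word")) |>
    dplyr::left_join(nsub, by = "condition") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' One-sample chi-square comparison of two word distributions
#'
#' Tests the observed condition's counts against expected frequencies given
#' by the comparison condition's distribution rescaled to the observed total
#' (a one-sample goodness-of-fit construction, not a 2 x k independence
#' test). Degrees of freedom = number of vocabulary words - 1. The
#' construction is **not symmetric** in the two conditions; the first
#' argument is always the observed one.
#'
#' Cells where the expected frequency is zero but the observed count is not
#' are an error: silently continuity-correcting them would change the
#' statistic invisibly. Prune the vocabulary to words used in the comparison
#' condition (or pool rare words) before testing.
#'
#' @param observed,expected [tabulate_words()] rows for one condition each
#'   (same vocabulary, same word order).
#' @return List: `statistic`, `df`, `p_value`, `n` (subjects in the observed
#'   condition).
#' @export
compare_word_distributions <- function(observed, expected) {
  if (!identical(observed$word, expected$word)) {
    stop("the two conditions must share the same vocabulary in the same order")
  }
  o <- observed$count
  e_tot <- sum(expected$count)
  if (e_tot == 0) stop("comparison condition has zero total count")
  p <- expected$count / e_tot
  e <- p * sum(o)
  bad <- e == 0 & o > 0
  if (any(bad)) {
    stop("expected frequency 0 with non-zero observed count for word(s): ",
         paste(observed$word[bad], collapse = ", "),
         ". Prune the vocabulary to words present in the comparison condition.")
  }
  ok <- e > 0
  stat <- sum((o[ok] - e[ok])^2 / e[ok])
  df <- length(o) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n = unique(observed$n_subjects)[1])
}

#' Restrict two word-count tables to a testable vocabulary
#'
#' Drops words whose expected frequency would be zero (count 0 in the
#' comparison condition), the explicit pruning step
#' [compare_word_distributions()] directs users to. The degrees of freedom
#' of a subsequent test follow the pruned vocabulary; report the pruned word
#' list alongside the statistic.
#'
#' @param observed,expected [tabulate_words()] rows for one condition each.
#' @return List with pruned `observed` and `expected` tables and `dropped`,
#'   the words removed.
#' @export
prune_words <- function(observed, expected) {
  if (!identical(observed$word, expected$word)) {
    stop("the two conditions must share the same vocabulary in the same order")
  }
  keep <- expected$count > 0
  list(observed = observed[keep, , drop = FALSE],
       expected = expected[keep, , drop = FALSE],
       dropped = observed$word[!keep])
}

#' Pairwise word-distribution tests across conditions
#'
#' Runs [compare_word_distributions()] for ordered condition pairs. Because
#' the one-sample construction is asymmetric, both orders are reported unless
#' `ref_condition` fixes which condition supplies the expected frequencies.
#'
#' @param counts [tabulate_words()] output.
#' @param ref_condition Optional condition supplying expected frequencies for
#'   all comparisons.
#' @param on_zero_expected What to do when a pair has a zero-expected cell
#'   with non-zero observations: `"error"` (default, the single-pair
#'   behaviour) or `"skip"` (emit the row with `NA` statistics and warn),
#'   used by the pipeline so one untestable pair does not abort a study.
#' @return Tibble: `observed`, `expected`, `statistic`, `df`, `p_value`, `n`.
#' @export
compare_words_pairwise <- function(counts, ref_condition = NULL,
                                   on_zero_expected = c("error", "skip")) {
  on_zero_expected <- match.arg(on_zero_expected)
  conds <- unique(counts$condition)
  if (!is.null(ref_condition)) {
    if (!ref_condition %in% conds) stop("unknown ref_condition")
    pairs <- cbind(setdiff(conds, ref_condition), ref_condition)
  } else {
    pairs <- expand.grid(obs = conds, exp = conds,
                         stringsAsFactors = FALSE)
    pairs <- as.matrix(pairs[pairs$obs != pairs$exp, ])
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    oc <- counts[counts$condition == pairs[i, 1], ]
    ec <- counts[counts$condition == pairs[i, 2], ]
    res <- if (on_zero_expected == "skip") {
      tryCatch(compare_word_distributions(oc, ec), error = function(e) {
        warning(sprintf("pair %s vs %s untestable: %s",
                        pairs[i, 1], pairs[i, 2], conditionMessage(e)),
                call. = FALSE)
        list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
             n = unique(oc$n_subjects)[1])
      })
    } else {
      compare_word_distributions(oc, ec)
    }
    tibble::tibble(observed = pairs[i, 1], expected = pairs[i, 2],
                   statistic = res$statistic, df = res$df,
                   p_value = res$p_value, n = res$n)
  })
  dplyr::bind_rows(rows)
}
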