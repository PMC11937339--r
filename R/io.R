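# Canonical tabular formats:
#   intensity CSV: subject,condition,time_s,intensity   (long, one row/sample)
#   words CSV:     subject,condition,word,selected
#   TI CSV:        subject,condition + the ten TI parameter columns

#' Names of the ten time-intensity parameters
#'
#' Column order used throughout the package and in the TI output CSV.
#' @return Character vector of length 10.
#' @export
ti_param_names <- function() {
  c("i_max", "t_max", "t_onset", "t_extinction", "plateau_s",
    "slope_pre", "slope_post", "auc_total", "auc_pre", "auc_post")
}

# Exact CSV reader: data.table's parser round-trips doubles written at full
# (shortest round-trippable) precision bit-exactly, which the io contract
# requires; vroom's fast parser can be off by an ulp.
read_csv_exact <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tibble::as_tibble(data.table::fread(path, data.table = FALSE))
}

#' Validate a set of intensity traces
#'
#' Checks the trace-set invariants: required columns, intensities within the
#' VAS range \[0, 10\], strictly increasing time within each
#' subject-by-condition trace, at least two samples per trace, no duplicated
#' (subject, condition, time) rows, and duration within the configured study
#' length.
#'
#' @param traces Data frame with columns `subject`, `condition`, `time_s`,
#'   `intensity`.
#' @param config A [ti_config()].
#' @param between_subject If `TRUE`, additionally require each subject to
#'   appear under exactly one condition.
#' @return The validated traces as a tibble, sorted by subject, condition and
#'   time.
#' @export
validate_trace_set <- function(traces, config = ti_config(),
                               between_subject = TRUE) {
  need <- c("subject", "condition", "time_s", "intensity")
  miss <- setdiff(need, names(traces))
  if (length(miss) > 0) {
    stop("intensity table is missing column(s): ", paste(miss, collapse = ", "))
  }
  traces <- tibble::as_tibble(traces)
  bad <- which(!is.finite(traces$intensity) |
                 traces$intensity < 0 | traces$intensity > 10)
  if (length(bad) > 0) {
    stop(sprintf("intensity outside [0, 10] (or non-finite) at row %d (value %s)",
                 bad[1], format(traces$intensity[bad[1]])))
  }
  if (any(!is.finite(traces$time_s)) || any(traces$time_s < 0)) {
    stop("time_s must be finite and >= 0")
  }
  if (any(traces$time_s > config$duration_s)) {
    stop(sprintf("time_s exceeds configured study duration (%g s)",
                 config$duration_s))
  }
  traces <- dplyr::arrange(traces, .data$subject, .data$condition, .data$time_s)
  grp <- dplyr::group_by(traces, .data$subject, .data$condition)
  chk <- dplyr::summarise(grp,
    n = dplyr::n(),
    dup = anyDuplicated(.data$time_s) > 0,
    .groups = "drop"
  )
  if (any(chk$dup)) {
    i <- which(chk$dup)[1]
    stop(sprintf("duplicated (subject, condition, time) in trace %s / %s",
                 chk$subject[i], chk$condition[i]))
  }
  if (any(chk$n < 2)) {
    i <- which(chk$n < 2)[1]
    stop(sprintf("trace %s / %s has fewer than 2 samples",
                 chk$subject[i], chk$condition[i]))
  }
  if (between_subject) {
    nc <- tapply(traces$condition, traces$subject,
                 function(x) length(unique(x)))
    if (any(nc > 1)) {
      stop("between-subject design violated: subject ",
           names(nc)[which(nc > 1)[1]], " appears under multiple conditions")
    }
  }
  traces
}

#' Read a long-format intensity table
#'
#' @param path CSV file with header `subject,condition,time_s,intensity`.
#' @inheritParams validate_trace_set
#' @return Validated tibble of traces (see [validate_trace_set()]).
#' @export
read_intensity_table <- function(path, config = ti_config(),
                                 between_subject = TRUE) {
  df <- read_csv_exact(path)
  validate_trace_set(df, config, between_subject = between_subject)
}

#' Write an intensity table
#' @param traces Trace tibble as returned by [validate_trace_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(traces, path) {
  readr::write_csv(traces[, c("subject", "condition", "time_s", "intensity")],
                   path)
  invisible(path)
}

#' Read a word-selection table
#'
#' Rows whose `word` is not in the configured vocabulary (subjects could add
#' free-text descriptors) are split off into an "other" bucket available via
#' [other_words()]; a warning reports how many.
#'
#' @param path CSV file with header `subject,condition,word,selected`.
#' @param config A [ti_config()] supplying the vocabulary.
#' @return Tibble restricted to vocabulary words, with logical `selected`;
#'   free-text rows attached as the `"other"` attribute.
#' @export
read_word_table <- function(path, config = ti_config()) {
  df <- read_csv_exact(path)
  need <- c("subject", "condition", "word", "selected")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("word table is missing column(s): ", paste(miss, collapse = ", "))
  }
  sel <- parse_selected(df$selected)
  if (anyNA(sel)) {
    stop(sprintf("'selected' not interpretable as boolean at row %d (value %s)",
                 which(is.na(sel))[1], format(df$selected[which(is.na(sel))[1]])))
  }
  df$selected <- sel
  df <- tibble::as_tibble(df)
  unknown <- !(df$word %in% config$vocabulary)
  other <- df[unknown, , drop = FALSE]
  if (nrow(other) > 0) {
    warning(sprintf("%d row(s) with words outside the vocabulary routed to the 'other' bucket: %s",
                    nrow(other), paste(unique(other$word), collapse = ", ")))
  }
  out <- df[!unknown, , drop = FALSE]
  attr(out, "other") <- other
  out
}

parse_selected <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x == 1] <- TRUE
    out[x == 0] <- FALSE
    return(out)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Free-text descriptor rows split off by [read_word_table()]
#' @param word_table A table returned by [read_word_table()].
#' @return Tibble of out-of-vocabulary rows (possibly empty).
#' @export
other_words <- function(word_table) {
  o <- attr(word_table, "other")
  if (is.null(o)) {
    tibble::tibble(subject = character(), condition = character(),
                   word = character(), selected = logical())
  } else {
    o
  }
}

#' Write a word-selection table
#' @param words Word tibble (`subject,condition,word,selected`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_word_table <- function(words, path) {
  readr::write_csv(words[, c("subject", "condition", "word", "selected")], path)
  invisible(path)
}

#' Write an extracted TI parameter table
#'
#' Writes the canonical 12-column format (`subject`, `condition`, ten TI
#' parameters). Extra bookkeeping columns such as censoring flags are
#' dropped. Values round-trip through [read_ti_table()] at full double
#' precision.
#'
#' @param ti TI parameter tibble from [extract_ti_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ti_table <- function(ti, path) {
  if (is.null(ti) || nrow(ti) == 0) stop("empty TI parameter collection")
  cols <- c("subject", "condition", ti_param_names())
  miss <- setdiff(cols, names(ti))
  if (length(miss) > 0) {
    stop("TI table is missing column(s): ", paste(miss, collapse = ", "))
  }
  readr::write_csv(ti[, cols], path)
  invisible(path)
}

#' Read a TI parameter table written by [write_ti_table()]
#' @param path CSV path.
#' @return Tibble with subject, condition and the ten TI parameters.
#' @export
read_ti_table <- function(path) {
  df <- read_csv_exact(path)
  miss <- setdiff(c("subject", "condition", ti_param_names()), names(df))
  if (length(miss) > 0) {
    stop("TI table is missing column(s): ", paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}
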