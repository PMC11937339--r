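# Nonparametric comparison of TI parameters across conditions:
# Kruskal-Wallis omnibus, Dunn post-hoc z tests on pooled midranks with tie
# correction, common-language effect sizes, and the letter display used in
# the figures (same letter = significantly different pair, the inverse of
# the agronomy convention).

drop_unusable_groups <- function(groups) {
  usable <- vapply(groups, function(g) sum(!is.na(g)) > 0, logical(1))
  if (any(!usable)) {
    warning("excluding group(s) with no defined values: ",
            paste(names(groups)[!usable], collapse = ", "))
  }
  groups <- lapply(groups[usable], function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("fewer than 2 usable groups")
  groups
}

#' Kruskal-Wallis rank test across groups
#'
#' Midrank-based H with tie correction and a chi-square reference
#' distribution on k-1 degrees of freedom (delegates to
#' [stats::kruskal.test()]). Groups with no defined values are excluded with
#' a warning; `NA` values are dropped within groups.
#'
#' @param groups Named list of numeric vectors (>= 2 usable groups).
#' @return List: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- drop_unusable_groups(groups)
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(unlist(groups)))
}

#' Dunn post-hoc pairwise comparisons
#'
#' For each unordered pair of groups, the Dunn z statistic from pooled
#' midranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(tau^3 - tau) / (12 (N - 1))` over tie-group sizes `tau`.
#' Two-sided p-values from the standard normal; adjusted per `adjust`.
#' With exactly two groups this reduces to the tie-corrected
#' normal-approximation rank-sum test. The common-language effect size
#' (probability of superiority of the first-named group) is attached per
#' pair.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust A [stats::p.adjust()] method; default `"none"`.
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`, `cl`.
#' @export
dunn_posthoc <- function(groups, adjust = "none") {
  groups <- drop_unusable_groups(groups)
  k <- length(groups)
  gn <- names(groups)
  if (is.null(gn)) gn <- paste0("g", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1L
  rbar <- vapply(seq_len(k),
                 function(i) mean(r[idx_start[i]:idx_end[i]]), numeric(1))
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_corr

  pairs <- utils::combn(k, 2)
  zs <- vapply(seq_len(ncol(pairs)), function(cix) {
    i <- pairs[1, cix]; j <- pairs[2, cix]
    se <- sqrt(base_var * (1 / sizes[i] + 1 / sizes[j]))
    if (se > 0) (rbar[i] - rbar[j]) / se else 0
  }, numeric(1))
  pv <- 2 * stats::pnorm(-abs(zs))
  tibble::tibble(
    group1 = gn[pairs[1, ]],
    group2 = gn[pairs[2, ]],
    z = zs,
    p_value = pv,
    p_adjusted = stats::p.adjust(pv, method = adjust),
    cl = vapply(seq_len(ncol(pairs)), function(cix) {
      cl_effect_size(groups[[pairs[1, cix]]], groups[[pairs[2, cix]]])
    }, numeric(1))
  )
}

#' Common-language effect size (probability of superiority)
#'
#' Proportion, over all cross-pairs, of `a_i > b_j` plus half the ties:
#' the probability that a random observation from `a` exceeds one from `b`.
#' Satisfies `cl(a, b) + cl(b, a) == 1`.
#'
#' @param a,b Numeric vectors (NAs dropped).
#' @return Probability in \[0, 1\].
#' @export
cl_effect_size <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(cmp)
}

#' Letter display for pairwise significance
#'
#' Assigns letters so that two conditions share a letter **iff** their
#' pairwise difference is significant at `alpha` -- the convention of the
#' study figures (the inverse of the usual compact letter display, where a
#' shared letter means "not distinguishable"). Implemented as a greedy
#' clique cover of the significant-pair graph.
#'
#' @param pairwise Tibble from [dunn_posthoc()] (uses `group1`, `group2`,
#'   `p_adjusted`).
#' @param alpha Significance level.
#' @return Tibble: `condition`, `letters` (possibly empty string).
#' @export
significance_letters <- function(pairwise, alpha = 0.05) {
  conds <- sort(unique(c(pairwise$group1, pairwise$group2)))
  sig <- pairwise$p_adjusted < alpha
  edges <- pairwise[sig, c("group1", "group2")]
  adj <- function(u, w) {
    any((edges$group1 == u & edges$group2 == w) |
          (edges$group1 == w & edges$group2 == u))
  }
  cliques <- list()
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      u <- edges$group1[e]; w <- edges$group2[e]
      placed <- FALSE
      for (ci in seq_along(cliques)) {
        if (u %in% cliques[[ci]] && w %in% cliques[[ci]]) { placed <- TRUE; break }
      }
      if (placed) next
      for (ci in seq_along(cliques)) {
        cl <- cliques[[ci]]
        if (u %in% cl && all(vapply(setdiff(cl, u), adj, logical(1), u = w))) {
          cliques[[ci]] <- c(cl, w); placed <- TRUE; break
        }
        if (w %in% cl && all(vapply(setdiff(cl, w), adj, logical(1), u = u))) {
          cliques[[ci]] <- c(cl, u); placed <- TRUE; break
        }
      }
      if (!placed) cliques[[length(cliques) + 1]] <- c(u, w)
    }
  }
  lab <- vapply(conds, function(cn) {
    has <- vapply(cliques, function(cl) cn %in% cl, logical(1))
    paste(letters[which(has)], collapse = "")
  }, character(1))
  tibble::tibble(condition = conds, letters = unname(lab))
}

#' Summaries and full test battery for a TI parameter table
#'
#' For each of the ten TI parameters: per-condition n / mean / SD / SEM over
#' defined values, the Kruskal-Wallis omnibus test, Dunn post-hoc pairs with
#' common-language effect sizes, and the letter display. A parameter with no
#' defined value in some condition is skipped with a warning; undefined
#' values (non-perceivers, degenerate slopes) are excluded per parameter.
#' With a single condition only the summaries are produced.
#'
#' @param ti TI table from [extract_ti_table()].
#' @param config A [ti_config()] (Dunn adjustment and alpha).
#' @return List with class `"ti_comparison"`: `summary` (per parameter and
#'   condition, with letters), `kruskal`, `pairwise`.
#' @export
summarize_ti <- function(ti, config = ti_config()) {
  conds <- sort(unique(ti$condition))
  params <- intersect(ti_param_names(), names(ti))
  summaries <- list(); kw_rows <- list(); pw_rows <- list()
  for (p in params) {
    groups <- lapply(stats::setNames(conds, conds),
                     function(cn) ti[[p]][ti$condition == cn])
    defined <- vapply(groups, function(g) sum(!is.na(g)), integer(1))
    if (any(defined == 0) && length(conds) > 1) {
      warning(sprintf("parameter %s undefined for condition(s) %s: skipped",
                      p, paste(conds[defined == 0], collapse = ", ")))
      next
    }
    summ <- tibble::tibble(
      parameter = p,
      condition = conds,
      n = defined,
      mean = vapply(groups, function(g) mean(g, na.rm = TRUE), numeric(1)),
      sd = vapply(groups, function(g) stats::sd(g, na.rm = TRUE), numeric(1))
    )
    summ$sem <- summ$sd / sqrt(summ$n)
    if (length(conds) >= 2) {
      kw <- kruskal_wallis(groups)
      kw_rows[[p]] <- tibble::tibble(parameter = p, statistic = kw$statistic,
                                     df = kw$df, p_value = kw$p_value,
                                     n = kw$n)
      pw <- dunn_posthoc(groups, adjust = config$p_adjust)
      pw_rows[[p]] <- dplyr::bind_cols(tibble::tibble(parameter = p), pw)
      lt <- significance_letters(pw, alpha = config$alpha)
      summ <- dplyr::left_join(summ, lt, by = "condition")
    } else {
      summ$letters <- ""
    }
    summaries[[p]] <- summ
  }
  structure(list(
    summary = dplyr::bind_rows(summaries),
    kruskal = dplyr::bind_rows(kw_rows),
    pairwise = dplyr::bind_rows(pw_rows)
  ), class = "ti_comparison")
}

#' @export
print.ti_comparison <- function(x, ...) {
  cat("<ti_comparison>\n")
  if (nrow(x$kruskal) > 0) {
    cat("Kruskal-Wallis omnibus tests:\n")
    print(as.data.frame(x$kruskal), row.names = FALSE, digits = 4)
  }
  np <- length(unique(x$summary$parameter))
  cat(sprintf("summaries for %d parameter(s); pairwise table: %d row(s)\n",
              np, nrow(x$pairwise)))
  invisible(x)
}
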