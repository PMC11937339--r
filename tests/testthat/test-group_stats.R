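test_that("Kruskal-Wallis reproduces the hand-ranked example and handles edge cases", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  # rank sums 6/15/24 in the standard H formula give H = 7.2
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$statistic, kw_H_manual(g), tolerance = 1e-12)
  expect_equal(kw$df, 2)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  kws <- kruskal_wallis(same)
  expect_equal(kws$statistic, 0, tolerance = 1e-12)
  expect_gt(kws$p_value, 0.99)

  expect_warning(kw2 <- kruskal_wallis(list(a = 1:3, b = 4:6, c = c(NA, NA))),
                 "no defined values")
  expect_equal(kw2$df, 1)
  expect_error(suppressWarnings(kruskal_wallis(list(a = 1:3, b = c(NA_real_)))),
               "fewer than 2")
})

test_that("H is invariant under strictly monotone transformation of the pooled data", {
  set.seed(71)
  for (r in 1:20) {
    g <- list(a = rnorm(6), b = rnorm(5, 1), c = rnorm(7, -0.5))
    h1 <- kruskal_wallis(g)$statistic
    h2 <- kruskal_wallis(lapply(g, function(x) exp(2 * x) + 1))$statistic
    expect_equal(h1, h2, tolerance = 1e-12)
    # group order irrelevant
    h3 <- kruskal_wallis(g[c(3, 1, 2)])$statistic
    expect_equal(h1, h3, tolerance = 1e-12)
  }
})

test_that("two-group Dunn equals the tie-corrected normal rank-sum test", {
  set.seed(72)
  for (r in 1:25) {
    a <- sample(1:8, 6, replace = TRUE)  # force ties
    b <- sample(1:8, 9, replace = TRUE)
    dn <- dunn_posthoc(list(a = a, b = b))
    or <- ranksum_z_p(a, b)
    expect_equal(abs(dn$z), abs(or$z), tolerance = 1e-10)
    expect_equal(dn$p_value, or$p, tolerance = 1e-10)
  }
  idn <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(idn$z, 0)
  expect_equal(idn$p_value, 1)
})

test_that("Dunn adjustment is monotone and pairs cover all combinations", {
  set.seed(73)
  g <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
  raw <- dunn_posthoc(g, adjust = "none")
  holm <- dunn_posthoc(g, adjust = "holm")
  expect_equal(nrow(raw), 3)
  expect_true(all(holm$p_adjusted >= raw$p_adjusted - 1e-15))
  expect_equal(raw$p_value, raw$p_adjusted)
})

test_that("asymptotic KW and Dunn p-values are near permutation oracles at small n", {
  # At n <= 4 per group the chi-square/normal references are approximations;
  # the permutation oracle quantifies the gap, which stays modest.
  g <- list(a = c(1.2, 3.4, 2.2), b = c(4.1, 5.0, 3.9), c = c(2.8, 6.2, 5.5))
  kw <- kruskal_wallis(g)
  p_perm <- perm_pvalue(g, kw_H_manual, kw$statistic, B = 2e4, seed = 4)
  expect_lt(abs(kw$p_value - p_perm), 0.05)

  a <- c(1.2, 3.4, 2.2, 0.8); b <- c(4.1, 5.0, 3.9, 2.5)
  dn <- dunn_posthoc(list(a = a, b = b))
  # two-sided permutation p for |z| via the rank-sum statistic
  zstat <- function(gg) abs(ranksum_z_p(gg[[1]], gg[[2]])$z)
  p_perm2 <- perm_pvalue(list(a = a, b = b), zstat, abs(dn$z), B = 2e4, seed = 5)
  expect_lt(abs(dn$p_value - p_perm2), 0.05)
})

test_that("common-language effect size matches brute force and its complement identity", {
  expect_equal(cl_effect_size(c(1, 2, 3), c(0, 1.5, 2.5)), 6 / 9)
  expect_equal(cl_effect_size(1, 1), 0.5)
  set.seed(74)
  for (r in 1:20) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(1:6, 7, replace = TRUE)
    expect_equal(cl_effect_size(a, b), cl_brute(a, b))
    expect_equal(cl_effect_size(a, b) + cl_effect_size(b, a), 1)
  }
})

test_that("significance letters mark exactly the significant pairs", {
  pw <- tibble::tibble(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
                       p_adjusted = c(0.20, 0.60, 0.30))
  lt <- significance_letters(pw, alpha = 0.05)
  expect_true(all(lt$letters == ""))

  pw$p_adjusted <- c(0.01, 0.60, 0.30)
  lt <- significance_letters(pw, alpha = 0.05)
  expect_equal(lt$letters[lt$condition == "a"], "a")
  expect_equal(lt$letters[lt$condition == "b"], "a")
  expect_equal(lt$letters[lt$condition == "c"], "")

  # random p tables: decoded shared-letter pairs == significant pairs
  set.seed(75)
  for (r in 1:40) {
    k <- sample(3:6, 1)
    conds <- letters[seq_len(k)]
    prs <- utils::combn(conds, 2)
    pw <- tibble::tibble(group1 = prs[1, ], group2 = prs[2, ],
                         p_adjusted = runif(ncol(prs)))
    lt <- significance_letters(pw, alpha = 0.4)
    sig <- pw[pw$p_adjusted < 0.4, ]
    want <- sort(paste(pmin(sig$group1, sig$group2),
                       pmax(sig$group1, sig$group2), sep = "|"))
    expect_identical(letters_to_pairs(lt), want)
  }
})

test_that("summarize_ti produces consistent summaries, tests, and SEMs", {
  cfg <- ti_config(sample_rate_hz = 2)
  des <- ti_study_design(n_per_condition = 8)
  st <- simulate_study(des, cfg, seed = 31)
  ti <- suppressMessages(extract_ti_table(st$traces, cfg))
  cmp <- suppressWarnings(summarize_ti(ti, cfg))
  expect_s3_class(cmp, "ti_comparison")
  expect_true(all(cmp$summary$sem == cmp$summary$sd / sqrt(cmp$summary$n)))
  expect_equal(sort(unique(cmp$kruskal$df)), 3)
  # 4 conditions -> 6 pairs per tested parameter
  expect_true(all(table(cmp$pairwise$parameter) == 6))
  expect_true(all(cmp$pairwise$cl >= 0 & cmp$pairwise$cl <= 1))
  expect_true(all(cmp$pairwise$p_adjusted >= cmp$pairwise$p_value - 1e-15))

  # single condition: summaries only
  one <- summarize_ti(ti[ti$condition == "capsaicin", ], cfg)
  expect_equal(nrow(one$kruskal), 0)
  expect_gt(nrow(one$summary), 0)
})

test_that("a 2 cm peak separation at low noise is detected in >= 90% of replicates", {
  # Noise (sd 0.2) is the only stochastic element here: the example isolates
  # test power over measurement noise from between-subject spread.
  cfg <- ti_config(sample_rate_hz = 1)
  p_hi <- profile_params(15, 25, 5.5, 20, 0.01)
  p_lo <- profile_params(15, 25, 3.5, 20, 0.01)
  nz <- noise_params(sd = 0.2)
  n <- 20
  rej <- vapply(1:200, function(r) {
    g <- lapply(list(hi = p_hi, lo = p_lo), function(pp) {
      vapply(1:n, function(i) {
        tr <- simulate_subject(pp, nz, cfg,
                               seed = r * 1000 + i + (pp$peak_intensity > 4) * 500)
        extract_ti(tr, cfg)$i_max
      }, numeric(1))
    })
    kruskal_wallis(g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})
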