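# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (index scans, loops, brute force) and share no
# code with the implementation.

# The worked trapezoid curve: 0 until 10 s, linear to 6.0 cm at 40 s, flat to
# 100 s, linear back to 0 at 200 s, 0 afterwards.
trapezoid_value <- function(t) {
  ifelse(t < 10, 0,
  ifelse(t < 40, 6 * (t - 10) / 30,
  ifelse(t <= 100, 6,
  ifelse(t < 200, 6 * (200 - t) / 100, 0))))
}

make_trapezoid_trace <- function(rate = 60, duration = 300) {
  t <- seq(0, duration, by = 1 / rate)
  tibble::tibble(subject = "s1", condition = "c1", time_s = t,
                 intensity = trapezoid_value(t))
}

# Random plausible traces for oracle-equivalence checks: random piecewise
# profile plus clipped smooth noise, random rate and duration.
random_trace <- function(seed) {
  set.seed(seed)
  rate <- sample(c(2, 5, 10), 1)
  dur <- sample(60:240, 1)
  t <- seq(0, dur, by = 1 / rate)
  onset <- runif(1, 0, dur / 3)
  rise <- runif(1, 2, dur / 4)
  peak <- runif(1, 0.5, 9)
  pl <- runif(1, 0, dur / 4)
  dec <- runif(1, 0.005, 0.08)
  tpe <- onset + rise + pl
  prof <- ifelse(t < onset, 0,
          ifelse(t < onset + rise, peak * (t - onset) / rise,
          ifelse(t <= tpe, peak, peak * exp(-dec * (t - tpe)))))
  e <- as.numeric(stats::filter(rnorm(length(t), 0, 0.15), 0.9,
                                method = "recursive"))
  tibble::tibble(subject = "s1", condition = "c1", time_s = t,
                 intensity = pmin(pmax(prof + e, 0), 10))
}

# Literal index-scan TI extraction: walks every sample applying the verbal
# definitions directly, with the same linear-interpolation convention for
# threshold crossings.
naive_ti <- function(t, v, f_on = 0.05, f_pl = 0.95) {
  n <- length(v)
  if (all(v == 0)) {
    return(as.list(stats::setNames(rep(NA_real_, 10),
      c("i_max", "t_max", "t_onset", "t_extinction", "plateau_s",
        "slope_pre", "slope_post", "auc_total", "auc_pre", "auc_post"))))
  }
  imax <- v[1]
  for (i in 2:n) if (v[i] > imax) imax <- v[i]
  im <- NA
  for (i in 1:n) if (v[i] == imax) { im <- i; break }
  t_max <- t[im]

  thr <- f_on * imax
  t_on <- NA
  for (i in 1:n) {
    if (v[i] > thr) {
      t_on <- if (i == 1) t[1] else
        t[i - 1] + (t[i] - t[i - 1]) * (thr - v[i - 1]) / (v[i] - v[i - 1])
      break
    }
  }
  t_ext <- t[n]; censored <- TRUE
  if (im < n) {
    for (i in (im + 1):n) {
      if (v[i] < thr) {
        t_ext <- t[i - 1] + (t[i] - t[i - 1]) * (v[i - 1] - thr) / (v[i - 1] - v[i])
        censored <- FALSE
        break
      }
    }
  }

  thrp <- f_pl * imax
  L <- im
  while (L > 1 && v[L - 1] > thrp) L <- L - 1
  R <- im
  while (R < n && v[R + 1] > thrp) R <- R + 1
  lo <- if (L == 1) t[1] else
    t[L - 1] + (t[L] - t[L - 1]) * (thrp - v[L - 1]) / (v[L] - v[L - 1])
  hi <- if (R == n) t[n] else
    t[R] + (t[R + 1] - t[R]) * (v[R] - thrp) / (v[R] - v[R + 1])

  slope_in <- function(a, b) {
    sel <- t >= a & t <= b
    if (sum(sel) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(v[sel] ~ t[sel]))[2])
  }
  trap <- function(i, j) {
    s <- 0
    if (j > i) for (q in i:(j - 1)) s <- s + (t[q + 1] - t[q]) * (v[q] + v[q + 1]) / 2
    s
  }
  pre <- trap(1, im); post <- trap(im, n)
  list(i_max = imax, t_max = t_max, t_onset = t_on, t_extinction = t_ext,
       plateau_s = hi - lo, slope_pre = slope_in(t_on, t_max),
       slope_post = slope_in(t_max, t_ext),
       auc_total = pre + post, auc_pre = pre, auc_post = post)
}

# Independent Kruskal-Wallis H from the textbook formula with midranks and
# tie correction.
kw_H_manual <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  Rsum <- mapply(function(a, b) sum(r[a:b]), starts, ends)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Permutation oracle: distribution of H (or any statistic) over label
# permutations.
perm_pvalue <- function(groups, stat_fn, observed, B = 1e5, seed = 1) {
  set.seed(seed)
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  count <- 0
  for (b in seq_len(B)) {
    perm <- sample(pooled)
    g <- mapply(function(a, bb) perm[a:bb], starts, ends, SIMPLIFY = FALSE)
    if (stat_fn(g) >= observed - 1e-12) count <- count + 1
  }
  count / B
}

# Tie-corrected large-sample rank-sum z test (two-sided), the classical
# normal approximation, as an oracle for the two-group Dunn case.
ranksum_z_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(c(a, b))
  v <- n1 * n2 * (N + 1) / 12 -
    n1 * n2 * sum(ties^3 - ties) / (12 * N * (N - 1))
  z <- (W - mu) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

cl_brute <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# Decode a letter display back into the set of pairs sharing a letter.
letters_to_pairs <- function(lt) {
  out <- character(0)
  for (i in seq_len(nrow(lt) - 1)) {
    for (j in (i + 1):nrow(lt)) {
      li <- strsplit(lt$letters[i], "")[[1]]
      lj <- strsplit(lt$letters[j], "")[[1]]
      if (length(intersect(li, lj)) > 0) {
        out <- c(out, paste(sort(c(lt$condition[i], lt$condition[j])),
                            collapse = "|"))
      }
    }
  }
  sort(out)
}

# Tiny two-condition study on disk for io/pipeline tests.
write_mini_study <- function(dir, seed = 5, n = 4, rate = 2) {
  cfg <- ti_config(sample_rate_hz = rate)
  des <- study_design(
    conditions = list(
      a = list(profile = profile_params(10, 20, 5, 15, 0.01),
               cv = list(onset = 0, rise = 0, peak = 0.2, plateau = 0, decay = 0),
               word_probs = c(cool = 0.8, sting = 0.4)),
      b = list(profile = profile_params(25, 25, 3, 10, 0.015),
               cv = list(onset = 0, rise = 0, peak = 0.2, plateau = 0, decay = 0),
               word_probs = c(cool = 0.3, warm = 0.6))
    ),
    n_per_condition = n, nonperceiver_rate = 0
  )
  st <- simulate_study(des, cfg, seed = seed)
  write_study(st, dir)
  list(config = cfg, study = st, dir = dir)
}
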