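test_that("profile_value follows the piecewise rise/plateau/decay shape", {
  p <- profile_params(onset_latency_s = 10, rise_duration_s = 30,
                      peak_intensity = 6, plateau_duration_s = 60,
                      decay_rate = 0.02)
  expect_equal(profile_value(p, c(0, 5, 10)), c(0, 0, 0))
  expect_equal(profile_value(p, 40), 6)           # end of rise
  expect_equal(profile_value(p, 25), 3)           # midway up
  expect_equal(profile_value(p, 100), 6)          # plateau end
  expect_equal(profile_value(p, 150), 6 * exp(-0.02 * 50), tolerance = 1e-12)
  np <- profile_params(10, 30, 6, 60, 0.02, perceiver = FALSE)
  expect_equal(profile_value(np, c(0, 40, 150)), c(0, 0, 0))
  # continuity at the joins
  eps <- 1e-9
  for (tt in c(10, 40, 100)) {
    expect_equal(profile_value(p, tt - eps), profile_value(p, tt + eps),
                 tolerance = 1e-6)
  }
})

test_that("true_ti gives the closed-form TI parameters of the profile", {
  cfg <- ti_config()
  p <- profile_params(10, 30, 6, 60, 0.02)
  tt <- true_ti(p, cfg)
  expect_equal(tt$t_onset, 10 + 30 * 0.05)              # 11.5: crossing 0.3 cm
  expect_equal(tt$i_max, 6)
  expect_equal(tt$t_max, 40)
  # plateau starts where the rise crosses 95% (5.7 cm): 10 + 30*0.95 = 38.5
  pl_start <- 10 + 30 * 0.95
  pl_end <- 100 + log(1 / 0.95) / 0.02
  expect_equal(tt$plateau_s, pl_end - pl_start)
  # extinction: solve 6 exp(-0.02 (t - 100)) = 0.3 -> 100 + ln(20)/0.02
  expect_equal(tt$t_extinction, 100 + log(20) / 0.02, tolerance = 1e-9)
  expect_false(tt$ext_censored)
  expect_equal(tt$slope_pre, 6 / 30)
  expect_equal(tt$auc_pre, 0.5 * 30 * 6)
  expect_equal(tt$auc_total, tt$auc_pre + tt$auc_post)
  # slow decay censors the extinction at the study end
  slow <- true_ti(profile_params(10, 30, 6, 60, 0.005), cfg)
  expect_equal(slow$t_extinction, cfg$duration_s)
  expect_true(slow$ext_censored)
  # non-perceiver: undefined everywhere
  np <- true_ti(profile_params(perceiver = FALSE), cfg)
  expect_true(all(is.na(np[, 1:10])))
})

test_that("true_ti slope_post matches a dense least-squares oracle", {
  cfg <- ti_config()
  p <- profile_params(10, 30, 6, 60, 0.02)
  tt <- true_ti(p, cfg)
  tg <- seq(tt$t_max, tt$t_extinction, length.out = 2e5)
  vg <- profile_value(p, tg)
  oracle <- unname(coef(lm(vg ~ tg))[2])
  expect_equal(tt$slope_post, oracle, tolerance = 1e-5)
})

test_that("simulate_subject is seed-deterministic and exact at zero noise", {
  cfg <- ti_config(sample_rate_hz = 10)
  p <- profile_params(10, 30, 6, 20, 0.02)
  a <- simulate_subject(p, noise_params(sd = 0.3), cfg, seed = 42)
  b <- simulate_subject(p, noise_params(sd = 0.3), cfg, seed = 42)
  expect_identical(a, b)
  d <- simulate_subject(p, noise_params(sd = 0.3), cfg, seed = 43)
  expect_false(identical(a$intensity, d$intensity))

  clean <- simulate_subject(p, noise_params(sd = 0), cfg, seed = 1)
  expect_equal(clean$intensity, profile_value(p, clean$time_s))

  # clamping: a high peak with large noise never leaves [0, 10]
  wild <- simulate_subject(profile_params(5, 10, 9.8, 50, 0.01),
                           noise_params(sd = 1.5), cfg, seed = 7)
  expect_true(all(wild$intensity >= 0 & wild$intensity <= 10))

  # non-perceiver with zero noise: identically zero
  npz <- simulate_subject(profile_params(perceiver = FALSE),
                          noise_params(sd = 0), cfg, seed = 1)
  expect_true(all(npz$intensity == 0))

  # caller RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_subject(p, noise_params(), cfg, seed = 5))
  expect_identical(before, .Random.seed)
})

test_that("noisy i_max estimates carry the positive extreme-value bias seen by the oracle", {
  # Oracle: large-replicate simulation at these settings gives a mean
  # positive bias of ~0.26 cm (max of slow AR noise over the plateau).
  cfg <- ti_config()
  p <- profile_params(18, 25, 5.7, 20, 0.008)
  imax <- vapply(1:300, function(i) {
    tr <- simulate_subject(p, noise_params(sd = 0.2), cfg, seed = 10000 + i)
    extract_ti(tr, cfg)$i_max
  }, numeric(1))
  bias <- mean(imax) - p$peak_intensity
  expect_gt(bias, 0.2)
  expect_lt(bias, 0.33)
})

test_that("simulate_study lays out a between-subject design with per-subject streams", {
  cfg <- ti_config(sample_rate_hz = 2, duration_s = 120)
  des <- ti_study_design(n_per_condition = 5)
  st <- simulate_study(des, cfg, seed = 11)
  expect_equal(length(unique(st$traces$subject)), 20)
  tab <- unique(st$traces[, c("subject", "condition")])
  expect_equal(nrow(tab), 20)                       # each subject once
  expect_equal(as.vector(table(tab$condition)), rep(5L, 4))
  expect_equal(nrow(st$truth), 20)
  expect_true(all(st$words$word %in% cfg$vocabulary))

  # different seeds give different data
  st2 <- simulate_study(des, cfg, seed = 12)
  expect_false(identical(st$traces$intensity, st2$traces$intensity))

  # adding subjects never perturbs existing ones
  des6 <- ti_study_design(n_per_condition = 6)
  st6 <- simulate_study(des6, cfg, seed = 11)
  shared <- st$traces$subject %in% st6$traces$subject
  expect_true(all(shared))
  sub <- st6$traces[st6$traces$subject %in% st$traces$subject, ]
  expect_equal(sub$intensity, st$traces$intensity)

  # certain word selection
  des_w <- study_design(
    conditions = list(x = list(profile = profile_params(),
                               cv = list(onset = 0, rise = 0, peak = 0,
                                         plateau = 0, decay = 0),
                               word_probs = c(cool = 1.0))),
    n_per_condition = 6, nonperceiver_rate = 0)
  stw <- simulate_study(des_w, cfg, seed = 3)
  cool <- stw$words[stw$words$word == "cool", ]
  expect_true(all(cool$selected))
})

test_that("noiseless simulated traces reproduce the closed-form ground truth", {
  cfg <- ti_config()  # full 60 Hz resolution
  profiles <- list(
    profile_params(18, 25, 5.7, 20, 0.008),
    profile_params(12, 25, 5.5, 27, 0.0105),
    profile_params(28, 25, 3.8, 15, 0.012),
    profile_params(5, 40, 2.0, 0, 0.05)
  )
  for (p in profiles) {
    tr <- simulate_subject(p, noise_params(sd = 0), cfg, seed = 1)
    ext <- extract_ti(tr, cfg)
    tru <- true_ti(p, cfg)
    for (nm in c("t_max", "t_onset", "t_extinction")) {
      expect_lt(abs(ext[[nm]] - tru[[nm]]), 1 / 60 + 1e-9)
    }
    expect_lt(abs(ext$plateau_s - tru$plateau_s), 2 / 60 + 1e-9)
    expect_equal(ext$i_max, tru$i_max, tolerance = 1e-10)
    # trapezoid-vs-exact integration error on the curved tail is tiny
    expect_equal(ext$auc_total, tru$auc_total, tolerance = 1e-4)
    expect_equal(ext$auc_pre, tru$auc_pre, tolerance = 1e-4)
    expect_equal(ext$slope_pre, tru$slope_pre, tolerance = 1e-3)
    expect_equal(ext$slope_post, tru$slope_post, tolerance = 5e-3)
  }
})

test_that("parameter recovery under default noise meets the frozen oracle bounds", {
  # Oracle (pre-registered simulation at sd = 0.2, tau = 10 s): median
  # |t_onset error| ~ 1.3 s, median |i_max error| ~ 0.26 cm.
  cfg <- ti_config()
  p <- profile_params(18, 25, 5.7, 20, 0.008)
  tru <- true_ti(p, cfg)
  errs <- t(vapply(1:200, function(i) {
    tr <- simulate_subject(p, noise_params(sd = 0.2), cfg, seed = 20000 + i)
    e <- extract_ti(tr, cfg)
    c(abs(e$t_onset - tru$t_onset), abs(e$i_max - tru$i_max))
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 2)     # t_onset within 2 s
  expect_lt(median(errs[, 2]), 0.3)   # i_max within 0.3 cm
})
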