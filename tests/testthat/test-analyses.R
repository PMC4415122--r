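test_that("PSTH smoothing conserves spike mass and handles silence", {
  p <- pipeline_params()
  # single spike: Gaussian bump of SD 30 ms integrating to one spike
  grid <- seq(-200, 300, by = 1)
  r <- comdecode:::smoothed_rate(50, grid, 30, -400, 700)
  expect_equal(grid[which.max(r)], 50)
  expect_equal(sum(r) / 1000, 1, tolerance = 1e-3) # 1 ms grid integral
  expect_equal(comdecode:::smoothed_rate(numeric(0), grid, 30, -400, 700),
               numeric(length(grid)))
  # edge correction: a spike near the recorded edge still has unit mass
  r_edge <- comdecode:::smoothed_rate(-395, seq(-400, 0, 1), 30, -400, 700)
  expect_equal(sum(r_edge) / 1000, 1, tolerance = 2e-2)
})

test_that("a constant-rate Poisson unit yields a flat PSTH near truth", {
  sess <- fix_small()$session
  p <- pipeline_params()
  ids <- sess$trials$trial_id
  ps <- compute_psth(sess, ids, p, window = c(-280, -100), step = 20)
  # pre-maze rates equal the baseline tuning within a few SEM
  tuning <- sess$ground_truth$tuning
  for (u in c(1, 5, 9)) {
    d <- ps[ps$unit_id == u, ]
    expect_lt(abs(mean(d$rate) - tuning$baseline_rate[u]),
              4 * mean(d$sem) + 1)
  }
  expect_error(compute_psth(sess, ids[1], p), "at least 2")
})

test_that("SNR gating follows range over worst-case SEM", {
  expect_equal(unit_snr(c(0, 8), c(2, 1)), 4)
  expect_equal(unit_snr(rep(3, 5), rep(1, 5)), 0)
  expect_equal(unit_snr(c(1, 5), c(0, 0)), Inf)
  expect_equal(unit_snr(2 * c(0, 8), 2 * c(2, 1)), 4) # scale invariant
})

test_that("forced and free responses correlate on matched-tuning data", {
  fx <- fix_decoding()
  sess <- fix_session()
  out <- forced_free_correlation(sess, fx$traces, fx$params)
  expect_gte(out$n_included, 5)
  expect_gt(out$mean_r, 0.5)
  expect_lt(out$sign_test_p, 0.01)
  expect_true(all(out$units$r[out$units$included] <= 1, na.rm = TRUE))
})

test_that("tuned units keep their preference when tuning is shared", {
  cfg <- sim_config(n_trials = 80, n_units = 16,
                    baseline_range = c(8, 12), mod_range = c(25, 35),
                    tuned_frac = 1,
                    class_mix = c(forced = 0.5, free = 0.5, zero_forced = 0,
                                  zero_free = 0, free_to_forced = 0,
                                  encouraged_switch = 0, biasing_change = 0))
  sess <- simulate_session(cfg, seed = 41)
  out <- preference_consistency(sess)
  expect_gt(out$counts["n_tuned"], 10)
  expect_equal(unname(out$counts["n_maintained"]),
               unname(out$counts["n_tuned"]))
})

test_that("the tuning test is calibrated on untuned populations", {
  cfg <- sim_config(n_trials = 120, n_units = 60, tuned_frac = 0,
                    class_mix = c(forced = 0.5, free = 0.5, zero_forced = 0,
                                  zero_free = 0, free_to_forced = 0,
                                  encouraged_switch = 0, biasing_change = 0))
  sess <- simulate_session(cfg, seed = 43)
  out <- preference_consistency(sess)
  # about alpha of 60 null units flag as tuned: allow up to ~3x alpha
  expect_lte(unname(out$counts["n_tuned"]), qbinom(0.999, 60, 0.05) + 2)
})

test_that("baseline distances follow Euclidean geometry", {
  q <- 12; T <- 30
  centers <- seq(-290, by = 20, length.out = T)
  flat <- matrix(1, q, T)
  shifted <- flat; shifted[, 25] <- 1 + 0.5 # one point offset in all dims?
  shifted[, 25] <- 1.5
  lat <- make_latents(list(flat, shifted), list(centers, centers),
                      trial_id = 1:2)
  tr <- make_trials(delay = c(400, 400), trial_class = "free",
                    choice = c("R", "R"))
  ev <- tibble::tibble(trial_id = 1:2, is_com = FALSE,
                       last_crossing_time = NA_real_)
  d <- baseline_distance(lat, ev, tr, pipeline_params())
  base <- d[d$kind == "baseline", ]
  expect_true(all(base$distance == 0)) # states equal the mean baseline
  all2 <- d[d$kind == "all_times" & d$trial_id == 2, ]
  # the offset point is delta * sqrt(q) from baseline
  expect_equal(max(all2$distance), 0.5 * sqrt(12))
})

test_that("crossing states stay far from baseline on synthetic sessions", {
  fx <- fix_decoding()
  d <- baseline_distance(fx$latents, fx$events, fix_session()$trials,
                         fx$params)
  cross <- d$distance[d$kind == "crossing"]
  base <- d$distance[d$kind == "baseline"]
  expect_gte(length(cross), 4)
  wt <- wilcox.test(cross, base, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("crossing-window firing-rate categories use the tie rule", {
  fx <- fix_decoding()
  sess <- fix_session()
  out <- com_rate_comparison(sess, fx$events, fx$params)
  expect_equal(sum(out$counts), nrow(sess$units))
  expect_true(all(out$units$category %in% c("lower", "between", "higher")))
  # z statistic agrees with the closed form on the same counts
  want <- oracle_two_prop_z(out$counts["lower"], nrow(sess$units),
                            out$counts["higher"], nrow(sess$units))
  expect_equal(out$z, unname(want))
  # tie rule: equal to a comparator is "between"
  expect_equal(
    {
      r_ev <- 5; lo <- 5; hi <- 7
      ifelse(r_ev < lo, "lower", ifelse(r_ev > hi, "higher", "between"))
    }, "between")
})

test_that("Mann-Whitney contrasts match exhaustive enumeration", {
  tr <- make_trials(delay = rep(0, 6), rt = c(1, 2, 3, 4, 5, 6),
                    trial_class = rep(c("free", "forced"), each = 3),
                    choice = "L")
  out <- rt_stats(tr, grouping = "zero_free_vs_zero_forced")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1)
  expect_equal(out$p_value, oracle_mann_whitney(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$median_diff, -3)
  # identical groups: no shift, p = 1
  tr2 <- make_trials(delay = rep(0, 8), rt = rep(c(7, 8, 9, 10), 2),
                     trial_class = rep(c("free", "forced"), each = 4))
  out2 <- rt_stats(tr2, grouping = "zero_free_vs_zero_forced")
  expect_equal(out2$median_diff, 0)
  expect_equal(out2$p_value, 1)
  expect_match(out2$method, "tie")
})

test_that("a 50 ms shift is detected at n = 200 per group", {
  set.seed(15)
  rt1 <- rnorm(200, 350, 40) + 50
  rt2 <- rnorm(200, 350, 40)
  tr <- make_trials(delay = rep(0, 400), rt = c(rt1, rt2),
                    trial_class = rep(c("free", "forced"), each = 200))
  out <- rt_stats(tr, grouping = "zero_free_vs_zero_forced")
  expect_lt(out$p_value, 1e-6)
  expect_lt(abs(out$median_diff - 50), 15)
})

test_that("near-Go free-to-forced trials split by the decoded plan", {
  # two trials planned toward the blocked side (slow), two toward the
  # unchanged side (fast)
  tr <- make_trials(delay = rep(500, 4), rt = c(420, 430, 300, 310),
                    trial_class = "free_to_forced", choice = "L",
                    change_time = 480)
  # change_side is R (the blocked side); traces decode R for slow trials
  traces <- dplyr::bind_rows(
    make_trace(rep(0.5, 20), times = seq(90, 470, 20), trial_id = 1),
    make_trace(rep(0.6, 20), times = seq(90, 470, 20), trial_id = 2),
    make_trace(rep(-0.5, 20), times = seq(90, 470, 20), trial_id = 3),
    make_trace(rep(-0.6, 20), times = seq(90, 470, 20), trial_id = 4))
  out <- rt_stats(tr, traces, "blocked_vs_unchanged")
  expect_equal(out$groups$n, c(2L, 2L))
  expect_equal(out$median_diff, 425 - 305)
  expect_equal(out$groups$group, c("plan_to_blocked", "plan_to_unchanged"))
})

test_that("indecision regression recovers a noiseless linear rule", {
  # rt = 400 - 100 * aligned, with a left-choice sign flip
  vals <- c(0.8, -0.5, 0.2, -0.1, 0.6) # decoded values at the probe bin
  choice <- c("R", "L", "R", "L", "R")
  aligned <- vals * ifelse(choice == "R", 1, -1)
  rt <- 400 - 100 * aligned
  tr <- make_trials(delay = rep(0, 5), rt = rt, trial_class = "free",
                    choice = choice)
  traces <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_trace(c(0, vals[i], 0), times = c(90, 110, 130), trial_id = i)
  }))
  out <- suppressWarnings(indecision_regression(
    traces, tr, pipeline_params(indecision_min_rt = 0)))
  expect_equal(out$slope, -100)
  expect_equal(out$intercept, 400)
  expect_equal(unname(oracle_ols(aligned, rt)["slope"]), out$slope)
  # left-choice trial with decode -0.5 contributes aligned +0.5
  expect_equal(out$data$aligned[out$data$trial_id == 2], 0.5)
  expect_error(indecision_regression(traces[traces$trial_id < 3, ], tr,
                                     pipeline_params(indecision_min_rt = 0)),
               "at least 3")
})

test_that("behavioral choice tables recover the configured probabilities", {
  tr <- make_trials(delay = rep(400, 10), trial_class = "free",
                    choice = c(rep("L", 6), rep("R", 4)))
  out <- behavior_choice_stats(tr)
  expect_equal(out$p_left$p_left[out$p_left$config == "easy_easy"], 0.6)
  expect_true(is.na(out$p_left$p_left[out$p_left$config == "hard_hard"]))
  # round-trip calibration at scale
  cfg <- sim_config(n_trials = 20000, n_units = 1)
  sch <- sample_trial_schedule(cfg, seed = 6)
  big <- behavior_choice_stats(sch)
  for (cc in c("easy_easy", "easy_hard", "hard_easy")) {
    row <- big$p_left[big$p_left$config == cc, ]
    ci <- wilson_interval(round(row$p_left * row$n), row$n, z = 2.576)
    expect_gte(cfg$p_left[[cc]], ci$lower)
    expect_lte(cfg$p_left[[cc]], ci$upper)
  }
  # biasing changes shift choice toward the eased side
  expect_gt(big$delta$delta_p[big$delta$favored == "L"], 0)
  expect_lt(big$delta$delta_p[big$delta$favored == "R"], 0)
})

test_that("statistics are invariant to trial order", {
  fx <- fix_decoding()
  sess <- fix_session()
  set.seed(3)
  perm <- sample(nrow(sess$trials))
  tr_perm <- sess$trials[perm, ]
  a <- rt_stats(sess$trials, grouping = "untaken_vs_forced",
                params = fx$params)
  b <- rt_stats(tr_perm, grouping = "untaken_vs_forced", params = fx$params)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$median_diff, b$median_diff)
  st1 <- category_frequency_stats(fx$events)
  st2 <- category_frequency_stats(fx$events[sample(nrow(fx$events)), ])
  expect_equal(st1$proportions, st2$proportions)
})
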