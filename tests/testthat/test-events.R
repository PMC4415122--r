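test_that("class conditionals use per-bin unbiased fits with pooling", {
  p <- pipeline_params()
  # two forced trials per side, values chosen by hand; all times < 600
  traces <- dplyr::bind_rows(
    make_trace(c(0, 2), times = c(90, 110), trial_id = 1),
    make_trace(c(0, 2), times = c(90, 110), trial_id = 2),
    make_trace(c(-1, -1), times = c(90, 110), trial_id = 3),
    make_trace(c(-1, -1), times = c(90, 110), trial_id = 4))
  tr <- make_trials(delay = rep(500, 4), choice = c("R", "R", "L", "L"))
  m <- fit_class_conditionals(traces, tr, p)
  r90 <- m$table[m$table$time == 90 & !m$table$pooled, ]
  expect_equal(r90$mu_R, 0)     # both R trials have 0 at 90 ms
  expect_equal(r90$mu_L, -1)
  expect_equal(r90$sd_R, sd(c(0, 0)) |> max(p$sigma_floor)) # floored
  r110 <- m$table[m$table$time == 110 & !m$table$pooled, ]
  expect_equal(r110$mu_R, 2)
  # identical samples floor at sigma_floor rather than zero
  expect_equal(r110$sd_L, p$sigma_floor)
  # hand check of the unbiased estimator on {0, 2}
  expect_equal(sd(c(0, 2)), sqrt(2))
})

test_that("late time points pool into one bin", {
  p <- pipeline_params()
  traces <- dplyr::bind_rows(
    make_trace(c(1, 1.4, 0.8), times = c(590, 600, 640), trial_id = 1),
    make_trace(c(1.1, 1.2, 0.9), times = c(590, 600, 640), trial_id = 2),
    make_trace(c(-1, -1.2, -0.8), times = c(590, 600, 640), trial_id = 3),
    make_trace(c(-0.9, -1.1, -1), times = c(590, 600, 640), trial_id = 4))
  tr <- make_trials(delay = rep(900, 4), choice = c("R", "R", "L", "L"))
  m <- fit_class_conditionals(traces, tr, p)
  pooled <- m$table[m$table$pooled, ]
  expect_equal(nrow(pooled), 1)
  # 600 and 640 ms values land in the same pooled bin
  expect_equal(pooled$n_R, 4)
  expect_equal(pooled$mu_R, mean(c(1.4, 0.8, 1.2, 0.9)))
  # lookups at any t >= 600 hit the pooled row
  expect_equal(likelihood_ratio(m, 600, pooled$mu_L, "L"),
               likelihood_ratio(m, 1000, pooled$mu_L, "L"))
})

test_that("sparse bins inherit the nearest earlier fit with a warning", {
  p <- pipeline_params()
  traces <- dplyr::bind_rows(
    make_trace(c(1, 1.2), times = c(90, 110), trial_id = 1),
    make_trace(c(0.8, 1.1), times = c(90, 110), trial_id = 2),
    make_trace(c(-1, -0.9), times = c(90, 110), trial_id = 3),
    make_trace(c(-1.2, -1, -1.1), times = c(90, 110, 130), trial_id = 4))
  tr <- make_trials(delay = rep(500, 4), choice = c("R", "R", "L", "L"))
  w <- capture_warnings(m <- fit_class_conditionals(traces, tr, p))
  expect_true(any(grepl("inherit", w)))
  r130 <- m$table[m$table$time == 130 & !m$table$pooled, ]
  r110 <- m$table[m$table$time == 110 & !m$table$pooled, ]
  expect_equal(r130$mu_R, r110$mu_R) # inherited
  # a single value is also sparse, so L inherits the 110 ms fit too
  expect_equal(r130$mu_L, r110$mu_L)
  expect_equal(r130$sd_L, r110$sd_L)
})

test_that("likelihood ratios follow the Gaussian densities", {
  m <- make_conditionals(mu_L = 0, mu_R = 0, sd = 1)
  expect_equal(likelihood_ratio(m, 200, 0.7, "L"), 1)
  m2 <- make_conditionals(mu_L = -1, mu_R = 1, sd = 0.2)
  expect_equal(likelihood_ratio(m2, 200, -1, "L"), exp(50), tolerance = 1e-6)
  expect_equal(likelihood_ratio(m2, 200, 0, "R"), 1) # equidistant
  expect_error(likelihood_ratio(m2, 40, 0, "L"), "before")
})

test_that("the three-criterion detector is conservative", {
  p <- pipeline_params()
  m <- make_conditionals(mu_L = -1, mu_R = 1, sd = 0.2)
  # constant trace: no sign change, no event
  call <- detect_change_of_mind(make_trace(rep(0.8, 10)), m, p)
  expect_false(call$is_com)
  expect_false(call$crit_sign)
  expect_true(call$crit_strong_R)
  # strong swing: all three criteria, direction L -> R
  swing <- make_trace(c(rep(-0.9, 6), rep(0.9, 6)))
  call2 <- detect_change_of_mind(swing, m, p)
  expect_true(call2$is_com)
  expect_equal(call2$direction, "L_to_R")
  expect_equal(call2$last_crossing_time,
               (swing$time[6] + swing$time[7]) / 2)
  # oscillation inside +-0.05: crossings but likelihood ratios below 10
  m_wide <- make_conditionals(mu_L = -1, mu_R = 1, sd = 0.5)
  osc <- make_trace(rep(c(0.05, -0.05), 6))
  expect_lt(likelihood_ratio(m_wide, 200, 0.05, "R"), 10)
  call3 <- detect_change_of_mind(osc, m_wide, p)
  expect_true(call3$crit_sign)
  expect_false(call3$is_com)
})

test_that("last crossing scans from the window start and keeps the latest", {
  p <- pipeline_params()
  tr <- make_trace(c(-1, -0.5, 0.3, 0.7))
  lc <- last_crossing(tr, p)
  expect_equal(lc$time, (tr$time[2] + tr$time[3]) / 2)
  expect_equal(lc$direction, "L_to_R")
  expect_equal(nrow(last_crossing(make_trace(c(0.2, 0.5, 0.9)), p)), 0)
  two <- make_trace(c(1, -1, -0.5, 0.4, 0.8))
  expect_equal(last_crossing(two, p)$time, (two$time[3] + two$time[4]) / 2)
  # exact zeros take the previous bin's sign: no crossing here
  z <- make_trace(c(1, 0, 0, 0.5))
  expect_equal(nrow(last_crossing(z, p)), 0)
})

test_that("detection is symmetric under label reflection", {
  p <- pipeline_params()
  m <- make_conditionals(mu_L = -1, mu_R = 1, sd = 0.25)
  m_swap <- make_conditionals(mu_L = -1, mu_R = 1, sd = 0.25)
  set.seed(6)
  for (i in 1:12) {
    v <- cumsum(rnorm(14, sd = 0.6))
    a <- detect_change_of_mind(make_trace(v), m, p)
    b <- detect_change_of_mind(make_trace(-v), m_swap, p)
    expect_equal(a$is_com, b$is_com)
    if (!is.na(a$direction)) {
      expect_true(a$direction != b$direction)
      expect_equal(a$last_crossing_time, b$last_crossing_time)
    }
  }
})

test_that("raising the likelihood threshold never creates events", {
  p10 <- pipeline_params(lr_threshold = 10)
  p50 <- pipeline_params(lr_threshold = 50)
  p500 <- pipeline_params(lr_threshold = 500)
  m <- make_conditionals(mu_L = -1, mu_R = 1, sd = 0.4)
  set.seed(9)
  flags <- sapply(1:30, function(i) {
    v <- cumsum(rnorm(12, sd = 0.5))
    c(detect_change_of_mind(make_trace(v), m, p10)$is_com,
      detect_change_of_mind(make_trace(v), m, p50)$is_com,
      detect_change_of_mind(make_trace(v), m, p500)$is_com)
  })
  expect_true(all(flags[2, ] <= flags[1, ]))
  expect_true(all(flags[3, ] <= flags[2, ]))
})

test_that("Wilson intervals match the closed form", {
  w <- wilson_interval(5, 10, z = 1)
  expect_equal(w$p, 0.5)
  expect_equal((w$lower + w$upper) / 2, 0.5) # symmetric center at 1/2
  expect_equal(c(w$lower, w$upper), oracle_wilson(5, 10, 1))
  w0 <- wilson_interval(0, 10, z = 1)
  expect_equal(w0$p, 0)
  expect_equal(w0$lower, 0)
  for (k in c(1, 3, 9)) {
    got <- wilson_interval(k, 12, z = 1.96)
    expect_equal(c(got$lower, got$upper), oracle_wilson(k, 12, 1.96))
  }
})

test_that("the 2x2 chi-square matches the textbook formula", {
  got <- chisq_2x2(13, 100, 2, 100)
  want <- oracle_chisq_2x2(13, 100, 2, 100)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p_value, want$p_value)
  # degenerate margins report NA
  expect_true(is.na(chisq_2x2(0, 10, 0, 10)$p_value))
})

test_that("two-proportion Z test matches its closed form", {
  got <- two_prop_z(37, 100, 36, 100)
  expect_equal(got$z, oracle_two_prop_z(37, 100, 36, 100))
  expect_equal(got$p_value, 2 * pnorm(-abs(got$z)))
})

test_that("category statistics assemble proportions and contrasts", {
  events <- tibble::tibble(
    trial_id = 1:40,
    is_com = c(rep(c(TRUE, FALSE, FALSE, FALSE), 5), rep(FALSE, 20)),
    trial_class = rep(c("free", "forced"), each = 20))
  st <- category_frequency_stats(events)
  free_row <- st$proportions[st$proportions$trial_class == "free", ]
  expect_equal(free_row$k, 5)
  expect_equal(free_row$p, 0.25)
  expect_equal(c(free_row$lower, free_row$upper), oracle_wilson(5, 20, 1))
  ct <- st$contrasts[st$contrasts$contrast == "forced_vs_free", ]
  want <- oracle_chisq_2x2(0, 20, 5, 20)
  expect_equal(ct$statistic, want$statistic)
  # absent categories yield NA contrasts, not errors
  expect_true(is.na(st$contrasts$p_value[
    st$contrasts$contrast == "taken_vs_untaken"]))
})
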