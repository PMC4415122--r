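# Two well-separated Gaussian clouds in a 2-D latent space, wrapped as
# latent trajectories with labels.
separable_latents <- function(n_trials = 20, T = 12, gap = 6, seed = 14) {
  set.seed(seed)
  choice <- rep(c("L", "R"), length.out = n_trials)
  mats <- lapply(seq_len(n_trials), function(i) {
    mu <- if (choice[i] == "R") c(gap / 2, 0) else c(-gap / 2, 0)
    m <- matrix(rnorm(2 * T, sd = 0.5), 2, T) + mu
    m[, 1:5] <- matrix(rnorm(2 * 5, sd = 0.5), 2, 5) # pre-plan bins
    m
  })
  centers <- replicate(n_trials, seq(-30, by = 20, length.out = T),
                       simplify = FALSE)
  trials <- make_trials(delay = rep(500, n_trials), choice = choice)
  list(latents = make_latents(mats, centers), trials = trials,
       choice = choice)
}

test_that("separable clouds are classified perfectly with a margin", {
  fx <- separable_latents()
  p <- pipeline_params(n_latents = 2)
  dec <- train_decoder(fx$latents, fx$trials, p)
  traces <- decode_trials(dec, fx$latents)
  summ <- trace_summary(traces, fx$trials)
  expect_true(all(summ$correct))
  # pooled eligible points are separated with positive margin
  pooled <- dplyr::filter(traces, .data$time >= p$train_start) |>
    dplyr::left_join(fx$trials[, c("trial_id", "choice")], by = "trial_id")
  expect_true(all(sign(pooled$value) == ifelse(pooled$choice == "R", 1, -1)))
  expect_gt(min(abs(pooled$value)), 0)
})

test_that("label permutation drives pooled training accuracy to chance", {
  fx <- separable_latents(n_trials = 40)
  set.seed(2)
  tr <- fx$trials
  tr$choice <- sample(tr$choice)
  p <- pipeline_params(n_latents = 2)
  dec <- train_decoder(fx$latents, tr, p)
  pooled <- decode_trials(dec, fx$latents) |>
    dplyr::filter(.data$time >= p$train_start) |>
    dplyr::left_join(tr[, c("trial_id", "choice")], by = "trial_id")
  acc <- mean(sign(pooled$value) == ifelse(pooled$choice == "R", 1, -1))
  n <- nrow(pooled)
  expect_lt(abs(acc - 0.5), 2.576 * sqrt(0.25 / n) + 0.05)
})

test_that("degenerate training sets are rejected", {
  fx <- separable_latents()
  tr <- fx$trials
  tr$choice <- "L"
  tr$diff_left <- "easy"; tr$diff_right <- "blocked"
  expect_error(train_decoder(fx$latents, tr, pipeline_params(n_latents = 2)),
               "single choice class")
})

test_that("decoded values are normalized signed distances", {
  w <- c(3, 4); b <- 1
  dec <- structure(list(w = w, b = b, norm_constant = 2, n_latents = 2,
                        train_ids = 1:2, trial_class = "forced",
                        train_start = 80, norm_quantile = 0.9,
                        n_train_points = 10),
                   class = "choice_decoder")
  # a point on the hyperplane decodes to zero
  x_on <- c(1, -1) # 3 - 4 + 1 = 0
  tr <- decode_trace(dec, cbind(x_on, c(2, 1)), c(100, 120))
  expect_equal(tr$value[1], 0)
  expect_equal(tr$value[2], (sum(w * c(2, 1)) + b) / (5 * 2))
  # halving the norm constant doubles every value
  dec2 <- dec; dec2$norm_constant <- 1
  tr2 <- decode_trace(dec2, cbind(x_on, c(2, 1)), c(100, 120))
  expect_equal(tr2$value, tr$value * 2)
  expect_error(decode_trace(dec, matrix(0, 3, 2), c(0, 20)), "mismatch")
})

test_that("the normalization constant is the stated quantile", {
  fx <- separable_latents()
  p <- pipeline_params(n_latents = 2)
  dec <- train_decoder(fx$latents, fx$trials, p)
  raw <- abs(unlist(lapply(fx$latents$latents, function(m) {
    (drop(crossprod(m, dec$w)) + dec$b) / sqrt(sum(dec$w^2))
  })))
  expect_equal(dec$norm_constant,
               unname(quantile(raw, 0.9, names = FALSE)))
})

test_that("the decoder is time invariant", {
  fx <- separable_latents()
  p <- pipeline_params(n_latents = 2)
  dec <- train_decoder(fx$latents, fx$trials, p)
  m <- fx$latents$latents[[1]]
  perm <- sample(ncol(m))
  v1 <- decode_trace(dec, m, fx$latents$centers[[1]])$value
  v2 <- decode_trace(dec, m[, perm], fx$latents$centers[[1]])$value
  expect_equal(v2, v1[perm])
})

test_that("decode value is an affine map of transformed counts", {
  fx <- fix_small()
  p <- fx$params
  sess <- fx$session
  p <- pipeline_params(n_latents = p$n_latents, min_delay = 40,
                       gpfa_max_iter = p$gpfa_max_iter)
  dec <- train_decoder(fx$latents, sess$trials, p)
  i <- 1
  counts <- fx$binned$counts[[i]]
  T <- ncol(counts); n <- nrow(counts)
  # dense affine operator assembled from the two model stages
  model <- fx$model
  sn2 <- model$sigma_n^2
  tt <- (seq_len(T) - 1) * model$bin_width
  Kbar <- matrix(0, model$n_latents * T, model$n_latents * T)
  for (j in seq_len(model$n_latents)) {
    idx <- (j - 1) * T + seq_len(T)
    Kbar[idx, idx] <- (1 - sn2) *
      exp(-outer(tt, tt, "-")^2 / (2 * model$tau[j]^2)) + sn2 * diag(T)
  }
  A <- matrix(0, n * T, model$n_latents * T)
  for (t in seq_len(T)) for (u in seq_len(n)) for (j in seq_len(model$n_latents)) {
    A[(t - 1) * n + u, (j - 1) * T + t] <- model$C[u, j]
  }
  S <- A %*% Kbar %*% t(A) + diag(rep(model$R, T))
  P <- Kbar %*% t(A) %*% solve(S) # latent posterior operator
  W <- matrix(0, T, model$n_latents * T)
  for (t in seq_len(T)) for (j in seq_len(model$n_latents)) {
    W[t, (j - 1) * T + t] <- dec$w[j]
  }
  scale <- sqrt(sum(dec$w^2)) * dec$norm_constant
  yc <- as.vector(sqrt(counts) - model$d)
  vals_oracle <- drop(W %*% P %*% yc + dec$b) / scale
  vals <- decode_trace(dec, fx$latents$latents[[i]],
                       fx$binned$centers[[i]])$value
  expect_lt(max(abs(vals - vals_oracle)), 1e-6)
})

test_that("accuracy-vs-time bins count trials by their last decoded point", {
  tr <- make_trials(delay = c(100, 100, 100, 100, 400),
                    rt = c(230, 240, 250, 260, 300),
                    choice = c("R", "R", "R", "L", "R"))
  # last decoded point = move_onset - 200 (single-bin traces suffice)
  traces <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_trace(c(0.5, if (i == 4) 0.6 else 0.2),
               times = c(tr$move_onset[i] - 220, tr$move_onset[i] - 210),
               trial_id = i)
  }))
  p <- pipeline_params()
  perf <- performance_vs_time(traces, tr, p)
  b2 <- perf[perf$bin_start == 120, ]
  expect_equal(b2$n, 4L)
  expect_equal(b2$accuracy, 0.75) # trial 4 chose L but decoded positive
  expect_equal(nrow(perf), 2) # empty bins are absent, not zero
  expect_equal(perf$accuracy[perf$bin_start == 480], 1)
})

test_that("the Monte-Carlo p-value tracks the exact binomial tail", {
  for (k in c(10, 5, 0)) {
    p_mc <- performance_pvalue(k, 10, 0.5, reps = 1e5, seed = 3)
    p_exact <- pbinom(k - 1, 10, 0.5, lower.tail = FALSE)
    se <- sqrt(p_exact * (1 - p_exact) / 1e5)
    expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 1e5)
  }
  expect_error(performance_pvalue(5, 10, 1.2), "prevalence")
})

test_that("decoder tidiers expose weights and training metadata", {
  fx <- separable_latents()
  dec <- train_decoder(fx$latents, fx$trials, pipeline_params(n_latents = 2))
  td <- tidy(dec)
  expect_equal(td$term, c("latent_1", "latent_2", "bias"))
  gl <- glance(dec)
  expect_equal(gl$trial_class, "forced")
  expect_gt(gl$norm_constant, 0)
})
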