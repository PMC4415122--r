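# Shared fixtures, built lazily and cached for the whole test run. The
# heavier fixtures (simulated sessions with a fitted latent model and
# decoder) are reused across unit and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_params <- function(...) {
  pipeline_params(n_latents = 8, gpfa_max_iter = 10, ...)
}

# Main decodable session: realistic timing/tuning defaults, weighted toward
# free trials so spontaneous vacillations occur in usable numbers.
fix_config <- function() {
  sim_config(n_trials = 420, n_units = 24,
             class_mix = c(forced = 0.25, free = 0.40, zero_forced = 0.05,
                           zero_free = 0.10, free_to_forced = 0.07,
                           encouraged_switch = 0.07, biasing_change = 0.06))
}

fix_session <- function() {
  fixture("session", function() simulate_session(fix_config(), seed = 20))
}

# Full decoding stack on the main session: binned counts, latent model,
# trajectories, LOO decoder, full-model traces (LOO rows patched in),
# class conditionals (session-level and per fold), event calls.
fix_decoding <- function() {
  fixture("decoding", function() {
    sess <- fix_session()
    p <- fix_params()
    binned <- bin_session(sess, p)
    model <- fit_gpfa(binned, params = p)
    latents <- infer_latents(model, binned)
    loo <- loo_cross_validate(latents, sess$trials, p)
    decoder <- train_decoder(latents, sess$trials, p)
    traces <- dplyr::rows_update(decode_trials(decoder, latents),
                                 loo$traces, by = c("trial_id", "time"))
    cond <- fit_class_conditionals(loo$traces, sess$trials, p)
    fold_conds <- suppressWarnings(lapply(loo$folds, function(f) {
      fit_class_conditionals(traces[traces$trial_id %in% f$train_ids, ],
                             sess$trials, p, fold = f$train_ids[1])
    }))
    events <- detect_events(traces, sess$trials, cond, p,
                            fold_models = fold_conds)
    list(params = p, binned = binned, model = model, latents = latents,
         loo = loo, decoder = decoder, traces = traces, cond = cond,
         fold_conds = fold_conds, events = events)
  })
}

# Session with a fixed 150 ms plan-formation latency and many zero/short
# delay trials, for the performance-vs-time curve.
fix_plateau <- function() {
  fixture("plateau", function() {
    cfg <- sim_config(n_trials = 280, n_units = 20,
                      plan_latency = c(150, 150),
                      class_mix = c(forced = 0.30, free = 0.25,
                                    zero_forced = 0.20, zero_free = 0.15,
                                    free_to_forced = 0.04,
                                    encouraged_switch = 0.03,
                                    biasing_change = 0.03))
    sess <- simulate_session(cfg, seed = 31)
    p <- fix_params()
    binned <- bin_session(sess, p)
    model <- fit_gpfa(binned, params = p)
    latents <- infer_latents(model, binned)
    loo <- loo_cross_validate(latents, sess$trials, p)
    decoder <- train_decoder(latents, sess$trials, p)
    traces <- dplyr::rows_update(decode_trials(decoder, latents),
                                 loo$traces, by = c("trial_id", "time"))
    list(session = sess, params = p, traces = traces, loo = loo)
  })
}

# Population of a realistic size (the early single-bin readout is only
# reliable with ~100 units), zero-delay heavy, for the indecision analyses.
# The uncoupled control runs at the scale of one recording day's zero-delay
# trials: the epoch-edge shrinkage of the latent posterior gives the probe
# a small mechanical association with reaction time, so the no-effect claim
# is a per-dataset-scale claim (see the methods vignette).
fix_indecision <- function(coupling = TRUE) {
  name <- paste0("indecision_", coupling)
  fixture(name, function() {
    cfg <- sim_config(n_trials = if (coupling) 360 else 200, n_units = 96,
                      indecision_coupling = coupling,
                      class_mix = c(forced = 0.28, free = 0.10,
                                    zero_forced = 0.10,
                                    zero_free = if (coupling) 0.35 else 0.30,
                                    free_to_forced = 0.06,
                                    encouraged_switch = 0.06,
                                    biasing_change = if (coupling) 0.05 else 0.10))
    sess <- simulate_session(cfg, seed = 57)
    p <- pipeline_params(gpfa_max_iter = 8)
    binned <- bin_session(sess, p)
    model <- fit_gpfa(binned, params = p)
    latents <- infer_latents(model, binned)
    decoder <- train_decoder(latents, sess$trials, p)
    list(session = sess, params = p,
         traces = decode_trials(decoder, latents))
  })
}

# Tiny session + loosely fitted model for operator-equivalence checks on
# short trials (the model need not be converged, only fixed).
fix_small <- function() {
  fixture("small", function() {
    cfg <- sim_config(n_trials = 14, n_units = 10, rt_base = 350,
                      timing = pipeline_params(delay_cap = 250),
                      class_mix = c(forced = 0.6, free = 0.4,
                                    zero_forced = 0, zero_free = 0,
                                    free_to_forced = 0,
                                    encouraged_switch = 0,
                                    biasing_change = 0))
    sess <- simulate_session(cfg, seed = 5)
    p <- pipeline_params(n_latents = 3, gpfa_max_iter = 3)
    binned <- bin_session(sess, p)
    model <- fit_gpfa(binned, params = p)
    list(session = sess, params = p, binned = binned, model = model,
         latents = infer_latents(model, binned))
  })
}

# Minimal hand-built trial tibble for rule-based tests.
make_trials <- function(delay, rt = 300, trial_class = "forced",
                        choice = NULL, success = TRUE,
                        change_time = NA_real_) {
  n <- length(delay)
  rt <- rep_len(rt, n)
  trial_class <- rep_len(trial_class, n)
  success <- rep_len(success, n)
  change_time <- rep_len(change_time, n)
  diff_left <- character(n); diff_right <- character(n)
  change_side <- rep(NA_character_, n); change_new <- rep(NA_character_, n)
  if (is.null(choice)) choice <- rep("L", n)
  choice <- rep_len(choice, n)
  for (i in seq_len(n)) {
    if (trial_class[i] == "forced") {
      diff_left[i] <- if (choice[i] == "L") "easy" else "blocked"
      diff_right[i] <- if (choice[i] == "L") "blocked" else "easy"
    } else if (trial_class[i] == "encouraged_switch_untaken") {
      blocked <- setdiff(c("L", "R"), choice[i])
      diff_left[i] <- if (blocked == "L") "blocked" else "easy"
      diff_right[i] <- if (blocked == "R") "blocked" else "easy"
      change_side[i] <- blocked; change_new[i] <- "easy"
      if (is.na(change_time[i])) change_time[i] <- 200
    } else if (trial_class[i] == "free_to_forced") {
      diff_left[i] <- "easy"; diff_right[i] <- "easy"
      change_side[i] <- setdiff(c("L", "R"), choice[i])
      change_new[i] <- "blocked"
      if (is.na(change_time[i])) change_time[i] <- delay[i]
    } else {
      diff_left[i] <- "easy"; diff_right[i] <- "easy"
    }
  }
  tibble::tibble(
    trial_id = seq_len(n), maze_family = "T",
    diff_left = diff_left, diff_right = diff_right,
    change_time = change_time, change_side = change_side,
    change_new = change_new, delay = delay, move_onset = delay + rt,
    rt = rt, choice = choice, success = success,
    trial_class = derive_trial_class(diff_left, diff_right, change_side,
                                     change_new, choice))
}

# Build a latent_trajectories object directly from a list of matrices.
make_latents <- function(mats, centers, trial_id = seq_along(mats),
                         bin_width = 20) {
  structure(list(latents = mats, centers = centers, trial_id = trial_id,
                 n_latents = nrow(mats[[1]]), bin_width = bin_width),
            class = "latent_trajectories")
}

# Single-trial trace tibble on the standard grid.
make_trace <- function(values, times = NULL, trial_id = 1L) {
  if (is.null(times)) times <- 170 + 20 * (seq_along(values) - 1)
  tibble::tibble(trial_id = trial_id, time = times, value = values)
}

# Class conditionals with constant well-separated Gaussians on a grid.
make_conditionals <- function(mu_L = -1, mu_R = 1, sd = 0.2,
                              params = pipeline_params()) {
  times <- c(seq(params$train_start + params$bin_width / 2, params$pool_from,
                 by = params$bin_width), Inf)
  tab <- tibble::tibble(time = times, pooled = is.infinite(times),
                        mu_L = mu_L, sd_L = sd, n_L = 10,
                        mu_R = mu_R, sd_R = sd, n_R = 10)
  structure(list(table = tab, train_start = params$train_start,
                 pool_from = params$pool_from, fold = NA),
            class = "class_conditionals")
}
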