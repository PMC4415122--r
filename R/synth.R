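#' Synthetic-session configuration
#'
#' Defines the study conditions emulated by the generator: session size,
#' trial-class mix, task timing distributions, Table-1-style choice
#' probabilities, internal-event rates, the reaction-time model, and the
#' population tuning profile.
#'
#' The reaction-time model is
#' `RT = rt_base + noise + hesitation penalty (untaken switch) +
#' indecision_gain * (plan latency - minimum latency)` (zero-delay free
#' trials, when `indecision_coupling` is on).
#'
#' @param n_trials,n_units Session size. Defaults mirror a ~1300-trial,
#'   ~100-unit recording day.
#' @param maze_family `"T"` or `"S"`.
#' @param class_mix Named proportions over trial archetypes `forced`,
#'   `free`, `zero_forced`, `zero_free`, `free_to_forced`,
#'   `encouraged_switch`, `biasing_change`.
#' @param p_left Named p(choose left) per barrier configuration
#'   (`easy_easy`, `hard_hard`, `easy_hard`, `hard_easy`) for free choices.
#' @param p_take Probability an encouraged-switch offer is taken (when there
#'   is time to re-plan).
#' @param p_switch Probability a biasing change induces a choice of the
#'   initially-hard side.
#' @param p_induced Among biasing-change trials ending at the initially-hard
#'   side, the probability the monkey first planned the easy side (a true
#'   induced change of mind) rather than choosing the hard side outright.
#' @param p_vac Vacillation probability among eligible free trials (delay at
#'   least `vac_min_delay`).
#' @param vac_min_delay,vac_window Eligibility threshold and sampling window
#'   (ms): vacillation times are uniform on
#'   `[vac_window[1], delay - vac_window[2]]`.
#' @param plan_latency Range (ms) of the none-to-plan formation latency.
#' @param replan_latency Range (ms) of the re-planning latency after a
#'   barrier change.
#' @param replan_exec_margin Minimum time (ms) between a completed re-plan
#'   and movement onset: a re-plan finishing near or after the Go cue
#'   delays the movement accordingly.
#' @param rt_base,rt_sd,rt_min Reaction-time base, Gaussian noise SD, and
#'   floor (ms).
#' @param hesitation_penalty Additive RT penalty on untaken-switch trials
#'   (ms).
#' @param indecision_coupling Couple zero-delay free-trial RT to the plan
#'   latency.
#' @param indecision_gain RT ms added per ms of plan-latency excess.
#' @param indecision_latency Plan-latency range (ms) on zero-delay free
#'   trials when coupling is on.
#' @param baseline_range,mod_range Per-unit baseline firing rate and
#'   choice-modulation depth ranges (spikes/s).
#' @param anti_mod Fraction of the modulation depth subtracted for the
#'   non-preferred side.
#' @param tuned_frac Fraction of units with choice tuning.
#' @param onset_jitter Range (ms) of per-unit response-onset latency.
#' @param ramp_tau_range Range (ms) of the exponential rate-ramp time
#'   constant.
#' @param forced_free_gain Multiplier on the modulation depth during free
#'   trials.
#' @param win_pad_start,win_pad_end Recorded window padding before maze
#'   onset and after movement onset (ms).
#' @param timing A [pipeline_params()] object supplying the delay and
#'   barrier-change truncated-exponential parameters.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_trials = 1302,
                       n_units = 101,
                       maze_family = "T",
                       class_mix = c(forced = 0.24, free = 0.18,
                                     zero_forced = 0.05, zero_free = 0.08,
                                     free_to_forced = 0.15,
                                     encouraged_switch = 0.15,
                                     biasing_change = 0.15),
                       p_left = c(easy_easy = 0.66, hard_hard = 0.5,
                                  easy_hard = 0.9, hard_easy = 0.1),
                       p_take = 0.4,
                       p_switch = 0.4,
                       p_induced = 0.7,
                       p_vac = 0.13,
                       vac_min_delay = 400,
                       vac_window = c(260, 80),
                       plan_latency = c(100, 200),
                       replan_latency = c(100, 200),
                       replan_exec_margin = 250,
                       rt_base = 340, rt_sd = 40, rt_min = 180,
                       hesitation_penalty = 25,
                       indecision_coupling = TRUE,
                       indecision_gain = 0.8,
                       indecision_latency = c(40, 300),
                       baseline_range = c(5, 15),
                       mod_range = c(8, 20),
                       anti_mod = 0.5,
                       tuned_frac = 0.85,
                       onset_jitter = c(0, 30),
                       ramp_tau_range = c(30, 70),
                       forced_free_gain = 1,
                       win_pad_start = 100,
                       win_pad_end = 100,
                       timing = pipeline_params()) {
  cfg <- as.list(environment())
  probs <- c(class_mix, p_left, p_take, p_switch, p_induced, p_vac,
             tuned_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config probabilities must lie in [0, 1]")
  }
  stopifnot(n_trials >= 1, n_units >= 1,
            abs(sum(class_mix) - 1) < 1e-6,
            all(c("forced", "free", "zero_forced", "zero_free",
                  "free_to_forced", "encouraged_switch",
                  "biasing_change") %in% names(class_mix)),
            all(c("easy_easy", "hard_hard", "easy_hard", "hard_easy") %in%
                  names(p_left)))
  class(cfg) <- "sim_config"
  cfg
}

# Inverse-CDF sampler for an exponential truncated at `cap`.
rtrunc_exp <- function(n, tau, cap) {
  u <- stats::runif(n)
  -tau * log(1 - u * (1 - exp(-cap / tau)))
}

# Closed-form CDF of the truncated exponential (used by tests and the
# distributional-fidelity checks).
ptrunc_exp <- function(q, tau, cap) {
  p <- (1 - exp(-pmin(pmax(q, 0), cap) / tau)) / (1 - exp(-cap / tau))
  p[q < 0] <- 0
  p[q >= cap] <- 1
  p
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Sample a trial schedule
#'
#' Draws a full trial table under the configured class mix: instructed
#' delays from a truncated exponential (`tau = 500 ms`, cap 1000 ms),
#' barrier-change latencies from an independent truncated exponential
#' (`tau = 500 ms`, cap 1200 ms), balanced barrier configurations, choices
#' from the configured probability table, and reaction times from the RT
#' model. All latent event variables needed by [simulate_intention()]
#' (plan latency, vacillation flag/time, re-plan latency, penalties) are
#' drawn here and carried as columns, so the downstream intention assembly
#' is deterministic.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A trial tibble (validated by [validate_trials()]) with latent
#'   event columns.
#' @export
sample_trial_schedule <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(seed, "schedule"))
  tp <- config$timing
  n <- config$n_trials
  classes <- rep(names(config$class_mix),
                 times = diff(round(cumsum(c(0, config$class_mix)) * n)))
  classes <- c(classes, rep("free", n - length(classes)))
  classes <- sample(classes)

  delay <- rtrunc_exp(n, tp$delay_tau, tp$delay_cap)
  delay[classes %in% c("zero_forced", "zero_free")] <- 0
  change_latency <- rtrunc_exp(n, tp$change_tau, tp$change_cap)

  plan_lat <- runif_range(n, config$plan_latency)
  replan_lat <- runif_range(n, config$replan_latency)
  rt_noise <- stats::rnorm(n, 0, config$rt_sd)

  diff_left <- character(n); diff_right <- character(n)
  change_side <- rep(NA_character_, n); change_new <- rep(NA_character_, n)
  change_time <- rep(NA_real_, n)
  choice <- character(n); success <- rep(TRUE, n)
  initial_plan <- character(n); vacillate <- rep(FALSE, n)
  vac_time <- rep(NA_real_, n); hes_pen <- numeric(n); ind_lat <- rep(NA_real_, n)
  rt <- numeric(n)

  config_of <- function(dl, dr) {
    paste(ifelse(dl == "easy", "easy", "hard"),
          ifelse(dr == "easy", "easy", "hard"), sep = "_")
  }
  draw_free_choice <- function(dl, dr) {
    key <- config_of(dl, dr)
    if (stats::runif(1) < config$p_left[[key]]) "L" else "R"
  }

  for (i in seq_len(n)) {
    cl <- classes[i]
    rt_i <- config$rt_base + rt_noise[i]
    if (cl %in% c("forced", "zero_forced")) {
      blocked <- sample(c("L", "R"), 1)
      open_diff <- sample(c("easy", "hard"), 1)
      diff_left[i] <- if (blocked == "L") "blocked" else open_diff
      diff_right[i] <- if (blocked == "R") "blocked" else open_diff
      choice[i] <- setdiff(c("L", "R"), blocked)
      initial_plan[i] <- choice[i]
      if (cl == "zero_forced") ind_lat[i] <- plan_lat[i]
    } else if (cl %in% c("free", "zero_free")) {
      cfg_pair <- sample(c("easy_easy", "hard_hard", "easy_hard", "hard_easy"), 1)
      parts <- strsplit(cfg_pair, "_")[[1]]
      diff_left[i] <- parts[1]; diff_right[i] <- parts[2]
      choice[i] <- draw_free_choice(parts[1], parts[2])
      initial_plan[i] <- choice[i]
      if (cl == "free") {
        eligible <- delay[i] >= config$vac_min_delay &&
          (delay[i] - config$vac_window[2]) > config$vac_window[1]
        if (eligible && stats::runif(1) < config$p_vac) {
          vacillate[i] <- TRUE
          vac_time[i] <- stats::runif(1, config$vac_window[1],
                                      delay[i] - config$vac_window[2])
          initial_plan[i] <- setdiff(c("L", "R"), choice[i])
        }
      } else {
        lat <- if (config$indecision_coupling) {
          runif_range(1, config$indecision_latency)
        } else {
          plan_lat[i]
        }
        ind_lat[i] <- lat
        plan_lat[i] <- lat
        if (config$indecision_coupling) {
          rt_i <- rt_i + config$indecision_gain *
            (lat - config$indecision_latency[1])
        }
      }
    } else if (cl == "free_to_forced") {
      sides <- sample(c("L", "R"))
      diff_left[i] <- "easy"; diff_right[i] <- "easy"
      change_side[i] <- sides[1]; change_new[i] <- "blocked"
      change_time[i] <- change_latency[i]
      surviving <- sides[2]
      init <- draw_free_choice("easy", "easy")
      initial_plan[i] <- init
      replan_by <- change_time[i] + replan_lat[i]
      if (init == change_side[i]) {
        # unlucky: planned the to-be-blocked side
        if (replan_by < delay[i] + max(rt_i, config$rt_min) - 100) {
          choice[i] <- surviving
          # movement cannot start until the new plan has settled
          rt_i <- max(rt_i, replan_by + config$replan_exec_margin - delay[i])
        } else {
          # change came too late to re-plan: reach toward the blocked target
          choice[i] <- init
          success[i] <- FALSE
        }
      } else {
        choice[i] <- surviving
      }
    } else if (cl == "encouraged_switch") {
      blocked <- sample(c("L", "R"), 1)
      diff_left[i] <- if (blocked == "L") "blocked" else "easy"
      diff_right[i] <- if (blocked == "R") "blocked" else "easy"
      change_side[i] <- blocked; change_new[i] <- "easy"
      change_time[i] <- change_latency[i]
      always <- setdiff(c("L", "R"), blocked)
      initial_plan[i] <- always
      replan_by <- change_time[i] + replan_lat[i]
      can_switch <- replan_by < delay[i] + max(rt_i, config$rt_min) - 100
      if (can_switch && stats::runif(1) < config$p_take) {
        choice[i] <- blocked
        rt_i <- max(rt_i, replan_by + config$replan_exec_margin - delay[i])
      } else {
        choice[i] <- always
        hes_pen[i] <- config$hesitation_penalty
        rt_i <- rt_i + hes_pen[i]
      }
    } else { # biasing_change
      hard_side <- sample(c("L", "R"), 1)
      diff_left[i] <- if (hard_side == "L") "hard" else "easy"
      diff_right[i] <- if (hard_side == "R") "hard" else "easy"
      change_side[i] <- hard_side; change_new[i] <- "easy"
      change_time[i] <- change_latency[i]
      easy_side <- setdiff(c("L", "R"), hard_side)
      replan_by <- change_time[i] + replan_lat[i]
      can_switch <- replan_by < delay[i] + max(rt_i, config$rt_min) - 100
      if (can_switch && stats::runif(1) < config$p_switch) {
        choice[i] <- hard_side
        if (stats::runif(1) < config$p_induced) {
          initial_plan[i] <- easy_side
          rt_i <- max(rt_i, replan_by + config$replan_exec_margin - delay[i])
        } else {
          initial_plan[i] <- hard_side
        }
      } else {
        choice[i] <- easy_side
        initial_plan[i] <- easy_side
      }
    }
    rt[i] <- max(rt_i, config$rt_min)
  }

  trials <- tibble::tibble(
    trial_id = seq_len(n),
    maze_family = config$maze_family,
    diff_left = diff_left, diff_right = diff_right,
    change_time = change_time, change_side = change_side,
    change_new = change_new,
    delay = delay, move_onset = delay + rt, rt = rt,
    choice = choice, success = success,
    trial_class = derive_trial_class(diff_left, diff_right, change_side,
                                     change_new, choice),
    plan_latency = plan_lat, replan_latency = replan_lat,
    initial_plan = initial_plan, vacillate = vacillate, vac_time = vac_time,
    hesitation_penalty = hes_pen, indecision_latency = ind_lat
  )
  validate_trials(trials)
  trials
}

#' Assemble the ground-truth intention trace of one trial
#'
#' Returns the piecewise-constant covert plan (`none`, `"L"`, `"R"`) over
#' the trial, with event labels. Given a trial row produced by
#' [sample_trial_schedule()] (which carries all latent draws) the assembly
#' is deterministic: the plan forms at `plan_latency`; vacillation trials
#' reverse plan at `vac_time`; "unlucky" free-to-forced and taken-switch
#' and induced biasing-change trials re-plan at
#' `change_time + replan_latency`; hesitation trials never change plan.
#'
#' @param trial One-row trial tibble with latent event columns.
#' @param config A [sim_config()].
#' @return Tibble with `seg_start` (ms), `side`, and a scalar attribute
#'   `event` naming the ground-truth event (`"none"`, `"vacillation"`,
#'   `"induced_switch"`, `"hesitation"`, `"indecision"`).
#' @export
simulate_intention <- function(trial, config) {
  stopifnot(nrow(trial) == 1)
  cl <- trial$trial_class
  init <- trial$initial_plan
  onset <- trial$plan_latency
  segs <- tibble::tibble(seg_start = -Inf, side = "none")
  add <- function(segs, t, side) {
    if (t <= segs$seg_start[nrow(segs)]) {
      stop("intention transitions must be strictly increasing (trial ",
           trial$trial_id, ")")
    }
    dplyr::bind_rows(segs, tibble::tibble(seg_start = t, side = side))
  }
  event <- "none"
  if (isTRUE(trial$vacillate)) {
    if (cl != "free") stop("vacillation is only defined for free trials")
    segs <- add(segs, onset, init)
    segs <- add(segs, trial$vac_time, trial$choice)
    event <- "vacillation"
  } else if (init != trial$choice) {
    if (is.na(trial$change_time)) {
      stop("plan reversal without a barrier change on trial ", trial$trial_id)
    }
    switch_t <- trial$change_time + trial$replan_latency
    if (switch_t > onset) {
      segs <- add(segs, onset, init)
      segs <- add(segs, switch_t, trial$choice)
      event <- "induced_switch"
    } else {
      # the barrier changed before the initial plan even formed: the plan
      # forms directly at the final choice, with no covert switch
      segs <- add(segs, onset, trial$choice)
    }
  } else if (!is.na(trial$hesitation_penalty) && trial$hesitation_penalty > 0) {
    event <- "hesitation"
    segs <- add(segs, onset, init)
  } else if (cl == "zero_free") {
    event <- "indecision"
    segs <- add(segs, onset, init)
  } else {
    segs <- add(segs, onset, init)
  }
  if (segs$side[nrow(segs)] != trial$choice) {
    stop("final intention segment must equal the recorded choice (trial ",
         trial$trial_id, ")")
  }
  attr(segs, "event") <- event
  segs
}

#' Sample population tuning
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble with one row per unit: array label, baseline and per-side
#'   target rates (spikes/s), response-onset latency and ramp time constant
#'   (ms), and the forced/free gain.
#' @export
sample_tuning <- function(config, seed) {
  set.seed(substream_seed(seed, "tuning"))
  n <- config$n_units
  baseline <- runif_range(n, config$baseline_range)
  mod <- runif_range(n, config$mod_range)
  tuned <- stats::runif(n) < config$tuned_frac
  pref <- rep_len(c("L", "R"), n)[sample.int(n)]
  left_rate <- ifelse(tuned,
                      ifelse(pref == "L", baseline + mod,
                             pmax(baseline - config$anti_mod * mod, 0.5)),
                      baseline)
  right_rate <- ifelse(tuned,
                       ifelse(pref == "R", baseline + mod,
                              pmax(baseline - config$anti_mod * mod, 0.5)),
                       baseline)
  tibble::tibble(
    unit_id = seq_len(n),
    array = rep_len(c("PMd", "M1"), n),
    baseline_rate = baseline,
    left_rate = left_rate,
    right_rate = right_rate,
    onset_latency = runif_range(n, config$onset_jitter),
    ramp_tau = runif_range(n, config$ramp_tau_range),
    forced_free_gain = config$forced_free_gain
  )
}

# Piecewise target rate with exponential relaxation; returns a vectorized
# rate function over the trial window for one unit.
make_rate_fun <- function(intention, tuning_row, free_trial, win_start) {
  gain <- if (free_trial) tuning_row$forced_free_gain else 1
  target_for <- function(side) {
    switch(side,
           none = tuning_row$baseline_rate,
           L = tuning_row$baseline_rate +
             gain * (tuning_row$left_rate - tuning_row$baseline_rate),
           R = tuning_row$baseline_rate +
             gain * (tuning_row$right_rate - tuning_row$baseline_rate))
  }
  starts <- intention$seg_start + tuning_row$onset_latency
  starts[1] <- win_start
  targets <- vapply(intention$side, target_for, numeric(1))
  if (any(targets < 0)) stop("negative target firing rate")
  tau <- tuning_row$ramp_tau
  # rate value at each segment start, chained through the relaxation
  r0 <- numeric(length(starts))
  r0[1] <- targets[1]
  for (k in seq_along(starts)[-1]) {
    r0[k] <- targets[k - 1] +
      (r0[k - 1] - targets[k - 1]) * exp(-(starts[k] - starts[k - 1]) / tau)
  }
  function(t) {
    k <- findInterval(t, starts)
    k[k < 1] <- 1
    targets[k] + (r0[k] - targets[k]) * exp(-(t - starts[k]) / tau)
  }
}

#' Emit spikes from an inhomogeneous Poisson process
#'
#' Thinning (rejection) sampler: the unit's rate follows the intention
#' trace, relaxing exponentially toward the side-dependent target rate with
#' time constant `ramp_tau` after a per-unit onset latency.
#'
#' @param intention Intention tibble from [simulate_intention()].
#' @param tuning Tuning tibble ([sample_tuning()]), one row per unit.
#' @param window Recorded window `[start, end]` in ms.
#' @param free_trial Apply the forced/free gain.
#' @return List of sorted spike-time vectors, one per unit. Draws from the
#'   current RNG state; seed externally for reproducibility.
#' @export
emit_spikes <- function(intention, tuning, window, free_trial = FALSE) {
  dur_s <- (window[2] - window[1]) / 1000
  lapply(seq_len(nrow(tuning)), function(u) {
    row <- tuning[u, ]
    if (any(c(row$baseline_rate, row$left_rate, row$right_rate) < 0)) {
      stop("negative firing rate for unit ", row$unit_id)
    }
    rate <- make_rate_fun(intention, row, free_trial, window[1])
    rmax <- max(row$baseline_rate, row$left_rate, row$right_rate) + 1e-9
    n_cand <- stats::rpois(1, rmax * dur_s)
    if (n_cand == 0) return(numeric(0))
    tt <- sort(stats::runif(n_cand, window[1], window[2]))
    keep <- stats::runif(n_cand) < rate(tt) / rmax
    st <- tt[keep]
    st[!duplicated(st)]
  })
}

#' Simulate a complete synthetic session
#'
#' Orchestrates [sample_trial_schedule()], [sample_tuning()],
#' [simulate_intention()] and [emit_spikes()] into a [spike_session()] with
#' ground truth attached. Each stage draws from its own named random
#' substream of `seed`, so e.g. regenerating spikes leaves the schedule
#' unchanged.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [spike_session()] with `ground_truth$intentions` (per-trial
#'   plan segments) and `ground_truth$events` (one row per trial: event
#'   label and timing).
#' @export
simulate_session <- function(config = sim_config(), seed = 1) {
  trials <- sample_trial_schedule(config, seed)
  tuning <- sample_tuning(config, seed)
  set.seed(substream_seed(seed, "spikes"))
  n <- nrow(trials)
  spikes <- vector("list", n)
  intent_list <- vector("list", n)
  events <- vector("list", n)
  windows <- tibble::tibble(
    trial_id = trials$trial_id,
    win_start = -abs(config$win_pad_start) - 300,
    win_end = trials$move_onset + abs(config$win_pad_end)
  )
  free_like <- trials$trial_class %in%
    c("free", "zero_free", "biasing_likely_change", "biasing_unlikely_change")
  for (i in seq_len(n)) {
    intent <- simulate_intention(trials[i, ], config)
    spikes[[i]] <- emit_spikes(intent, tuning,
                               c(windows$win_start[i], windows$win_end[i]),
                               free_trial = free_like[i])
    intent_list[[i]] <- dplyr::mutate(intent, trial_id = trials$trial_id[i],
                                      .before = 1)
    events[[i]] <- tibble::tibble(
      trial_id = trials$trial_id[i],
      event = attr(intent, "event"),
      plan_onset = trials$plan_latency[i],
      switch_time = dplyr::case_when(
        attr(intent, "event") == "vacillation" ~ trials$vac_time[i],
        attr(intent, "event") == "induced_switch" ~
          trials$change_time[i] + trials$replan_latency[i],
        TRUE ~ NA_real_),
      rt_penalty = dplyr::case_when(
        attr(intent, "event") == "hesitation" ~ trials$hesitation_penalty[i],
        attr(intent, "event") == "indecision" & config$indecision_coupling ~
          config$indecision_gain *
            (trials$indecision_latency[i] - config$indecision_latency[1]),
        TRUE ~ 0))
  }
  names(spikes) <- as.character(trials$trial_id)
  keep_cols <- setdiff(names(trials),
                       c("plan_latency", "replan_latency", "initial_plan",
                         "vacillate", "vac_time", "hesitation_penalty",
                         "indecision_latency"))
  spike_session(
    units = tuning[, c("unit_id", "array")],
    trials = trials[, keep_cols],
    spikes = spikes,
    windows = windows,
    ground_truth = list(intentions = strip_attr(dplyr::bind_rows(intent_list),
                                                "event"),
                        events = dplyr::bind_rows(events),
                        tuning = tuning,
                        schedule = trials)
  )
}

strip_attr <- function(x, which) {
  attr(x, which) <- NULL
  x
}
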