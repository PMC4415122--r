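#' Peri-stimulus time histogram with Gaussian smoothing
#'
#' Single-trial firing rates are obtained by convolving each spike train
#' with a Gaussian kernel (SD `psth_sd`, default 30 ms), edge-corrected
#' against the trial's recorded window so each spike contributes unit mass;
#' the PSTH is the across-trial mean with its SEM at each grid point.
#'
#' @param session A [spike_session()].
#' @param trial_ids Trials to average (one condition).
#' @param params A [pipeline_params()] object.
#' @param window Time window (ms pair); defaults to the correlation window.
#' @param step Grid step (ms).
#' @return Tibble with `unit_id`, `time`, `rate` (spikes/s), `sem`, `n_trials`.
#' @export
compute_psth <- function(session, trial_ids, params = pipeline_params(),
                         window = params$corr_window, step = 10) {
  if (length(trial_ids) < 2) stop("need at least 2 trials for a PSTH")
  grid <- seq(window[1], window[2], by = step)
  n_units <- nrow(session$units)
  win <- session$windows
  sd_ms <- params$psth_sd
  sum_r <- matrix(0, n_units, length(grid))
  sum_r2 <- matrix(0, n_units, length(grid))
  for (id in trial_ids) {
    i <- match(id, session$trials$trial_id)
    wlo <- win$win_start[match(id, win$trial_id)]
    whi <- win$win_end[match(id, win$trial_id)]
    trains <- session$spikes[[as.character(id)]]
    for (u in seq_len(n_units)) {
      st <- trains[[u]]
      r <- smoothed_rate(st, grid, sd_ms, wlo, whi)
      sum_r[u, ] <- sum_r[u, ] + r
      sum_r2[u, ] <- sum_r2[u, ] + r^2
    }
  }
  m <- length(trial_ids)
  mean_r <- sum_r / m
  var_r <- pmax(sum_r2 / m - mean_r^2, 0) * m / (m - 1)
  sem <- sqrt(var_r / m)
  tibble::tibble(
    unit_id = rep(session$units$unit_id, times = length(grid)),
    time = rep(grid, each = n_units),
    rate = as.vector(mean_r), sem = as.vector(sem), n_trials = m
  )
}

# Gaussian-smoothed rate (spikes/s) of one train at grid times; each spike's
# kernel is renormalized by its mass inside the recorded window.
smoothed_rate <- function(spikes, grid, sd_ms, win_lo, win_hi) {
  if (length(spikes) == 0) return(numeric(length(grid)))
  mass <- stats::pnorm(win_hi, spikes, sd_ms) -
    stats::pnorm(win_lo, spikes, sd_ms)
  r <- numeric(length(grid))
  for (k in seq_along(spikes)) {
    r <- r + stats::dnorm(grid, spikes[k], sd_ms) / mass[k]
  }
  r * 1000
}

#' Signal-to-noise ratio of a concatenated response vector
#'
#' `SNR = range(rates) / max(sems)`; a unit with an all-zero SEM vector has
#' infinite SNR and is included.
#'
#' @param rates Concatenated mean-rate vector.
#' @param sems SEM vector of the same length.
#' @return The SNR (possibly `Inf`).
#' @export
unit_snr <- function(rates, sems) {
  stopifnot(length(rates) == length(sems))
  noise <- max(sems)
  if (noise == 0) return(Inf)
  diff(range(rates)) / noise
}

#' Similarity of forced- and free-choice responses
#'
#' Per unit, the Pearson correlation between the concatenated
#' `[forced-left, forced-right]` and `[free-left, free-right]`
#' trial-averaged smoothed response vectors over the correlation window.
#' Only units whose concatenated forced+free vector passes the SNR gate are
#' included; free-trial averages exclude possible change-of-mind trials.
#' A sign test (exact binomial, alternative `r > 0`) is run across included
#' units.
#'
#' @param session A [spike_session()].
#' @param traces Choice-trace tibble used for the change-of-mind screen.
#' @param params A [pipeline_params()] object.
#' @return List with `units` (per-unit `r`, `snr`, `included`), `mean_r`
#'   (over included units), `sign_test_p`, `n_included`.
#' @export
forced_free_correlation <- function(session, traces,
                                    params = pipeline_params()) {
  trials <- session$trials
  base <- list(success = TRUE, has_change = FALSE,
               min_delay = params$psth_min_delay)
  sel <- function(cls, extra = list()) {
    select_trials(trials, c(base, list(trial_class = cls), extra), params)
  }
  forced_ids <- sel("forced")
  free_ids <- sel("free")
  free_keep <- exclude_possible_com(
    traces[traces$trial_id %in% free_ids, ],
    trials[trials$trial_id %in% free_ids, ], params)
  cond_ids <- list(
    forced_L = forced_ids[trials$choice[match(forced_ids, trials$trial_id)] == "L"],
    forced_R = forced_ids[trials$choice[match(forced_ids, trials$trial_id)] == "R"],
    free_L = free_keep[trials$choice[match(free_keep, trials$trial_id)] == "L"],
    free_R = free_keep[trials$choice[match(free_keep, trials$trial_id)] == "R"]
  )
  short <- names(cond_ids)[vapply(cond_ids, length, integer(1)) < 2]
  if (length(short) > 0) {
    stop("need at least 2 trials per condition; short: ",
         paste(short, collapse = ", "))
  }
  psths <- lapply(cond_ids, function(ids) compute_psth(session, ids, params))
  units <- session$units$unit_id
  per_unit <- lapply(units, function(u) {
    vecs <- lapply(psths, function(p) p[p$unit_id == u, ])
    forced_vec <- c(vecs$forced_L$rate, vecs$forced_R$rate)
    free_vec <- c(vecs$free_L$rate, vecs$free_R$rate)
    all_rates <- c(forced_vec, free_vec)
    all_sems <- c(vecs$forced_L$sem, vecs$forced_R$sem,
                  vecs$free_L$sem, vecs$free_R$sem)
    snr <- unit_snr(all_rates, all_sems)
    r <- if (stats::sd(forced_vec) == 0 || stats::sd(free_vec) == 0) {
      NA_real_
    } else {
      stats::cor(forced_vec, free_vec)
    }
    tibble::tibble(unit_id = u, r = r, snr = snr,
                   included = is.finite(snr) && snr >= params$snr_min ||
                     is.infinite(snr))
  })
  tab <- dplyr::bind_rows(per_unit)
  inc <- tab[tab$included & !is.na(tab$r), ]
  if (nrow(inc) < 1) stop("no unit passed the SNR gate")
  sign_p <- stats::binom.test(sum(inc$r > 0), sum(inc$r != 0),
                              alternative = "greater")$p.value
  list(units = tab, mean_r = mean(inc$r), sign_test_p = sign_p,
       n_included = nrow(inc))
}

count_rate <- function(spikes, lo, hi) {
  sum(spikes >= lo & spikes < hi) / ((hi - lo) / 1000)
}

#' Choice-preference consistency between forced and free trials
#'
#' A unit is "tuned" when its forced-left and forced-right delay-epoch mean
#' rates (from `train_start` to the Go cue) differ by a two-sided Wilcoxon
#' rank-sum test at `alpha`; a tuned unit "maintains" its preference when
#' the sign of its free-trial rate difference matches the forced-trial
#' sign.
#'
#' @param session A [spike_session()].
#' @param params A [pipeline_params()] object.
#' @param alpha Significance level of the tuning test.
#' @return List with `units` (per-unit statistics) and `counts`
#'   (`n_tuned`, `n_maintained`).
#' @export
preference_consistency <- function(session, params = pipeline_params(),
                                   alpha = 0.05) {
  trials <- session$trials
  base <- list(success = TRUE, has_change = FALSE,
               min_delay = params$psth_min_delay)
  ids_of <- function(cls, side) {
    ids <- select_trials(trials, c(base, list(trial_class = cls)), params)
    ids[trials$choice[match(ids, trials$trial_id)] == side]
  }
  sets <- list(forced_L = ids_of("forced", "L"),
               forced_R = ids_of("forced", "R"),
               free_L = ids_of("free", "L"), free_R = ids_of("free", "R"))
  delay_rates <- function(ids, u) {
    vapply(ids, function(id) {
      st <- session$spikes[[as.character(id)]][[u]]
      go <- trials$delay[match(id, trials$trial_id)]
      count_rate(st, params$train_start, go)
    }, numeric(1))
  }
  rows <- lapply(seq_len(nrow(session$units)), function(u) {
    fl <- delay_rates(sets$forced_L, u); fr <- delay_rates(sets$forced_R, u)
    p <- suppressWarnings(stats::wilcox.test(fl, fr)$p.value)
    forced_pref <- sign(mean(fl) - mean(fr))
    free_pref <- sign(mean(delay_rates(sets$free_L, u)) -
                        mean(delay_rates(sets$free_R, u)))
    tibble::tibble(unit_id = session$units$unit_id[u], p_tuning = p,
                   tuned = !is.na(p) && p < alpha,
                   forced_pref = forced_pref, free_pref = free_pref,
                   maintained = forced_pref != 0 & forced_pref == free_pref)
  })
  tab <- dplyr::bind_rows(rows)
  list(units = tab,
       counts = c(n_tuned = sum(tab$tuned),
                  n_maintained = sum(tab$tuned & tab$maintained)))
}

#' Distance of neural states from the mean baseline state
#'
#' The baseline state is the mean latent state over the baseline window
#' across all successful trials. Three distance distributions are
#' returned per trial group: `baseline` (every baseline-window point of
#' every successful trial; group `all`), `crossing` (the two latent states
#' flanking the last decoded-choice sign change of each change-of-mind
#' trial), and `all_times` (every point at or after the detection-window
#' start).
#'
#' @param latents A `latent_trajectories` object.
#' @param events Event-call tibble (defines change-of-mind trials).
#' @param trials Trial tibble.
#' @param params A [pipeline_params()] object.
#' @param groups Named list of trial-class vectors defining the groups.
#' @return Tibble with `group`, `kind`, `trial_id`, `time`, `distance`.
#' @export
baseline_distance <- function(latents, events, trials,
                              params = pipeline_params(),
                              groups = list(
                                free = "free",
                                biasing = c("biasing_likely_change",
                                            "biasing_unlikely_change"))) {
  ok <- trials$trial_id[trials$success]
  idx_ok <- which(latents$trial_id %in% ok)
  bw <- params$baseline_window
  base_pts <- lapply(idx_ok, function(i) {
    sel <- latents$centers[[i]] >= bw[1] & latents$centers[[i]] <= bw[2]
    latents$latents[[i]][, sel, drop = FALSE]
  })
  mu <- rowMeans(do.call(cbind, base_pts))
  dist_to <- function(m) sqrt(colSums((m - mu)^2))
  out <- list()
  for (i in idx_ok) {
    sel <- latents$centers[[i]] >= bw[1] & latents$centers[[i]] <= bw[2]
    out[[length(out) + 1]] <- tibble::tibble(
      group = "all", kind = "baseline", trial_id = latents$trial_id[i],
      time = latents$centers[[i]][sel],
      distance = dist_to(latents$latents[[i]][, sel, drop = FALSE]))
  }
  for (g in names(groups)) {
    ids <- trials$trial_id[trials$trial_class %in% groups[[g]] & trials$success]
    com_ids <- intersect(ids, events$trial_id[events$is_com])
    for (id in com_ids) {
      i <- match(id, latents$trial_id)
      ct <- events$last_crossing_time[match(id, events$trial_id)]
      if (is.na(ct)) next
      ctr <- latents$centers[[i]]
      before <- which(ctr < ct); after <- which(ctr > ct)
      pick <- c(if (length(before) > 0) max(before), if (length(after) > 0) min(after))
      out[[length(out) + 1]] <- tibble::tibble(
        group = g, kind = "crossing", trial_id = id, time = ctr[pick],
        distance = dist_to(latents$latents[[i]][, pick, drop = FALSE]))
    }
    for (id in intersect(ids, latents$trial_id)) {
      i <- match(id, latents$trial_id)
      sel <- latents$centers[[i]] >= params$com_window_start
      if (!any(sel)) next
      out[[length(out) + 1]] <- tibble::tibble(
        group = g, kind = "all_times", trial_id = id,
        time = latents$centers[[i]][sel],
        distance = dist_to(latents$latents[[i]][, sel, drop = FALSE]))
    }
  }
  dplyr::bind_rows(out)
}

#' Firing rates during changes of mind vs matched windows
#'
#' For each change-of-mind trial, takes the rate of every unit in the
#' window centered on the last decoded-choice crossing, and the mean rates
#' of the same unit in the same absolute window over comparison
#' (non-change-of-mind) left- and right-choice trials. After averaging over
#' change-of-mind trials, each unit is categorized as `lower` than both
#' comparison rates, `between` (ties count as between), or `higher`; the
#' proportions of lower vs higher units are compared with a two-proportion
#' Z test.
#'
#' @param session A [spike_session()].
#' @param events Event-call tibble.
#' @param params A [pipeline_params()] object.
#' @param event_classes Trial classes providing the change-of-mind trials.
#' @param comparison_classes Trial classes providing the comparison pool
#'   (non-event trials of these classes).
#' @return List with `units` (per-unit rates and category), `counts`
#'   (lower/between/higher), `z`, `p_value`.
#' @export
com_rate_comparison <- function(session, events,
                                params = pipeline_params(),
                                event_classes = "free",
                                comparison_classes = "free") {
  trials <- session$trials
  ev_ids <- events$trial_id[events$is_com &
                              events$trial_class %in% event_classes &
                              !is.na(events$last_crossing_time)]
  if (length(ev_ids) < 1) stop("no change-of-mind trials to analyze")
  comp_ids <- trials$trial_id[trials$trial_class %in% comparison_classes &
                                trials$success]
  comp_ids <- setdiff(comp_ids, events$trial_id[events$is_com])
  comp_L <- comp_ids[trials$choice[match(comp_ids, trials$trial_id)] == "L"]
  comp_R <- comp_ids[trials$choice[match(comp_ids, trials$trial_id)] == "R"]
  if (length(comp_L) == 0 || length(comp_R) == 0) {
    stop("need non-event comparison trials for both choices")
  }
  half <- params$com_rate_window / 2
  n_units <- nrow(session$units)
  rate_in <- function(id, lo, hi) {
    wrow <- match(id, session$windows$trial_id)
    lo2 <- max(lo, session$windows$win_start[wrow])
    hi2 <- min(hi, session$windows$win_end[wrow])
    if (hi2 <= lo2) return(rep(NA_real_, n_units))
    trains <- session$spikes[[as.character(id)]]
    vapply(trains, count_rate, numeric(1), lo = lo2, hi = hi2)
  }
  acc_ev <- matrix(0, n_units, 0)
  acc_L <- matrix(0, n_units, 0); acc_R <- matrix(0, n_units, 0)
  clipped <- FALSE
  for (id in ev_ids) {
    ct <- events$last_crossing_time[match(id, events$trial_id)]
    lo <- ct - half; hi <- ct + half
    wrow <- match(id, session$windows$trial_id)
    if (lo < session$windows$win_start[wrow] ||
        hi > session$windows$win_end[wrow]) clipped <- TRUE
    acc_ev <- cbind(acc_ev, rate_in(id, lo, hi))
    rl <- rowMeans(vapply(comp_L, rate_in, numeric(n_units), lo = lo, hi = hi),
                   na.rm = TRUE)
    rr <- rowMeans(vapply(comp_R, rate_in, numeric(n_units), lo = lo, hi = hi),
                   na.rm = TRUE)
    acc_L <- cbind(acc_L, rl); acc_R <- cbind(acc_R, rr)
  }
  if (clipped) warning("crossing window clipped to the recorded trial window")
  r_ev <- rowMeans(acc_ev, na.rm = TRUE)
  r_L <- rowMeans(acc_L, na.rm = TRUE)
  r_R <- rowMeans(acc_R, na.rm = TRUE)
  lo_cmp <- pmin(r_L, r_R); hi_cmp <- pmax(r_L, r_R)
  category <- ifelse(r_ev < lo_cmp, "lower",
                     ifelse(r_ev > hi_cmp, "higher", "between"))
  counts <- c(lower = sum(category == "lower"),
              between = sum(category == "between"),
              higher = sum(category == "higher"))
  zt <- two_prop_z(unname(counts["lower"]), n_units,
                   unname(counts["higher"]), n_units)
  list(units = tibble::tibble(unit_id = session$units$unit_id,
                              rate_event = r_ev, rate_comp_L = r_L,
                              rate_comp_R = r_R, category = category),
       counts = counts, z = zt$z, p_value = zt$p_value,
       n_event_trials = length(ev_ids))
}

#' Reaction-time contrasts
#'
#' Two-group Mann-Whitney U comparisons of reaction times, with exact
#' small-sample p-values (both groups of size at most 20 and no ties) and
#' the tie-corrected normal approximation otherwise. Groupings:
#'
#' * `"blocked_vs_unchanged"` — free-to-forced trials whose barrier change
#'   fell within the near-Go margin, split by whether the decoded plan at
#'   the change time pointed to the now-blocked or to the unchanging side;
#' * `"untaken_vs_forced"` — untaken-switch vs forced-choice trials
#'   (hesitation);
#' * `"zero_free_vs_zero_forced"` — zero-delay free vs zero-delay forced
#'   trials (indecision).
#'
#' @param trials Trial tibble.
#' @param traces Choice-trace tibble (needed by `"blocked_vs_unchanged"`).
#' @param grouping One of the grouping names above.
#' @param params A [pipeline_params()] object.
#' @return List with `groups` (per-group `n`, `median`), `median_diff`
#'   (first minus second group), `statistic` (U), `p_value`, `method`.
#' @export
rt_stats <- function(trials, traces = NULL,
                     grouping = c("blocked_vs_unchanged",
                                  "untaken_vs_forced",
                                  "zero_free_vs_zero_forced"),
                     params = pipeline_params()) {
  grouping <- match.arg(grouping)
  ok <- trials[trials$success, ]
  if (grouping == "blocked_vs_unchanged") {
    if (is.null(traces)) stop("traces are required for blocked_vs_unchanged")
    ids <- select_trials(ok, list(trial_class = "free_to_forced",
                                  near_go = TRUE), params)
    g1 <- numeric(0); g2 <- numeric(0)
    for (id in ids) {
      row <- ok[ok$trial_id == id, ]
      tr <- traces[traces$trial_id == id, ]
      tr <- tr[order(tr$time), ]
      at <- tr[tr$time <= row$change_time + params$bin_width / 2, ]
      if (nrow(at) == 0) next
      plan <- if (at$value[nrow(at)] >= 0) "R" else "L"
      if (plan == row$change_side) g1 <- c(g1, row$rt) else g2 <- c(g2, row$rt)
    }
    labels <- c("plan_to_blocked", "plan_to_unchanged")
  } else if (grouping == "untaken_vs_forced") {
    i1 <- select_trials(ok, list(trial_class = "encouraged_switch_untaken"),
                        params)
    i2 <- select_trials(ok, list(trial_class = "forced", has_change = FALSE,
                                 min_delay = params$min_delay), params)
    g1 <- ok$rt[match(i1, ok$trial_id)]
    g2 <- ok$rt[match(i2, ok$trial_id)]
    labels <- c("untaken_switch", "forced")
  } else {
    i1 <- select_trials(ok, list(trial_class = "free", zero_delay = TRUE),
                        params)
    i2 <- select_trials(ok, list(trial_class = "forced", zero_delay = TRUE),
                        params)
    g1 <- ok$rt[match(i1, ok$trial_id)]
    g2 <- ok$rt[match(i2, ok$trial_id)]
    labels <- c("zero_delay_free", "zero_delay_forced")
  }
  if (length(g1) == 0 || length(g2) == 0) {
    stop("empty group in rt_stats grouping '", grouping, "': ",
         labels[c(length(g1) == 0, length(g2) == 0)])
  }
  exact <- length(g1) <= 20 && length(g2) <= 20 &&
    !any(duplicated(c(g1, g2)))
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = exact,
                                            correct = FALSE))
  list(groups = tibble::tibble(group = labels,
                               n = c(length(g1), length(g2)),
                               median = c(stats::median(g1),
                                          stats::median(g2))),
       median_diff = stats::median(g1) - stats::median(g2),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Regression of reaction time on the early decoded choice
#'
#' On zero-delay free-choice trials with reaction time of at least
#' `indecision_min_rt`, regresses RT on the choice-aligned decoded value at
#' the bin containing `indecision_probe` (the decoded value's sign is
#' flipped on leftward-choice trials so positive always points toward the
#' eventual reach).
#'
#' @param traces Choice-trace tibble.
#' @param trials Trial tibble.
#' @param params A [pipeline_params()] object.
#' @return List with `slope`, `intercept`, `conf_int` (95% for the slope),
#'   `p_value`, `n`, `data`, and the `lm` fit.
#' @export
indecision_regression <- function(traces, trials,
                                  params = pipeline_params()) {
  ids <- select_trials(trials, list(trial_class = "free", zero_delay = TRUE,
                                    success = TRUE,
                                    rt_min = params$indecision_min_rt),
                       params)
  rows <- list()
  for (id in ids) {
    tr <- traces[traces$trial_id == id, ]
    probe_bin <- tr[tr$time > params$indecision_probe &
                      tr$time <= params$indecision_probe + params$bin_width, ]
    if (nrow(probe_bin) == 0) next
    row <- trials[trials$trial_id == id, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      trial_id = id, rt = row$rt,
      aligned = probe_bin$value[1] * choice_sign(row$choice))
  }
  df <- dplyr::bind_rows(rows)
  if (nrow(df) < 3) {
    stop("need at least 3 qualifying zero-delay free trials (have ",
         nrow(df), ")")
  }
  fit <- stats::lm(rt ~ aligned, data = df)
  ci <- stats::confint(fit, "aligned", level = 0.95)
  list(slope = unname(stats::coef(fit)["aligned"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       conf_int = unname(ci[1, ]),
       p_value = summary(fit)$coefficients["aligned", 4],
       n = nrow(df), data = df, fit = fit)
}

#' Split-array decoding and agreement
#'
#' Refits the latent model and decoder separately on the PMd and M1 units
#' (reducing the latent count when an array has fewer units, with a
#' warning), reports leave-one-out forced-choice accuracy per decoder, and
#' the mean per-trial fraction of time points (at or after the
#' detection-window start) on which each pair of decoders agrees in sign —
#' over all eligible successful trials and over free-choice trials alone.
#'
#' @param session A [spike_session()].
#' @param params A [pipeline_params()] object.
#' @return List with `performance` (decoder, LOO accuracy) and `agreement`
#'   (pair, scope, mean fraction of agreeing time points).
#' @export
split_array_agreement <- function(session, params = pipeline_params()) {
  fit_one <- function(unit_sel) {
    binned <- bin_session(session, params)
    binned$counts <- lapply(binned$counts,
                            function(m) m[unit_sel, , drop = FALSE])
    q <- params$n_latents
    if (sum(unit_sel) < q) {
      warning("array has fewer units than latents; reducing to ",
              sum(unit_sel))
      q <- sum(unit_sel)
    }
    model <- fit_gpfa(binned, n_latents = q, params = params)
    lat <- infer_latents(model, binned)
    dec <- train_decoder(lat, session$trials, params)
    loo <- loo_cross_validate(lat, session$trials, params)
    traces <- dplyr::rows_update(decode_trials(dec, lat), loo$traces,
                                 by = c("trial_id", "time"))
    list(loo = loo, traces = traces)
  }
  sets <- list(combined = rep(TRUE, nrow(session$units)),
               PMd = session$units$array == "PMd",
               M1 = session$units$array == "M1")
  fits <- lapply(sets, fit_one)
  perf <- tibble::tibble(decoder = names(fits),
                         loo_accuracy = vapply(fits, function(f)
                           f$loo$accuracy, numeric(1)))
  elig <- select_trials(session$trials,
                        list(success = TRUE, min_delay = params$min_delay),
                        params)
  free_ids <- select_trials(session$trials,
                            list(success = TRUE, trial_class = "free",
                                 min_delay = params$min_delay), params)
  pairs <- list(PMd_combined = c("PMd", "combined"),
                M1_combined = c("M1", "combined"),
                PMd_M1 = c("PMd", "M1"))
  agree_rows <- list()
  for (pn in names(pairs)) {
    a <- fits[[pairs[[pn]][1]]]$traces
    b <- fits[[pairs[[pn]][2]]]$traces
    joined <- dplyr::inner_join(a, b, by = c("trial_id", "time"),
                                suffix = c("_a", "_b")) |>
      dplyr::filter(.data$time >= params$com_window_start)
    per_trial <- joined |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::summarise(agree = mean(sign(.data$value_a) == sign(.data$value_b)),
                       .groups = "drop")
    for (scope in c("all", "free")) {
      ids <- if (scope == "all") elig else free_ids
      agree_rows[[length(agree_rows) + 1]] <- tibble::tibble(
        pair = pn, scope = scope,
        mean_agreement = mean(per_trial$agree[per_trial$trial_id %in% ids]))
    }
  }
  list(performance = perf, agreement = dplyr::bind_rows(agree_rows))
}

#' Behavioral choice-probability table
#'
#' p(choose left) per barrier configuration over no-change free trials,
#' plus the change in p(left) on biasing-change trials relative to the
#' configuration-matched no-change baseline, separated by whether the
#' change favored the left or the right target. Only barrier changes
#' landing in the preparation window (from 100 ms after maze onset to
#' `near_go_margin` after the Go cue) are counted.
#'
#' @param trials Trial tibble.
#' @param params A [pipeline_params()] object.
#' @return List with `p_left` (per configuration: `n`, `p_left`; empty
#'   cells reported with `NA`) and `delta` (per biasing direction:
#'   `n`, `p_left`, `baseline`, `delta_p`).
#' @export
behavior_choice_stats <- function(trials, params = pipeline_params()) {
  ok <- trials[trials$success, ]
  cfg <- paste(ifelse(ok$diff_left == "easy", "easy", "hard"),
               ifelse(ok$diff_right == "easy", "easy", "hard"), sep = "_")
  cfg[ok$diff_left == "blocked" | ok$diff_right == "blocked"] <- NA
  free_nc <- is.na(ok$change_time) & !is.na(cfg) &
    ok$diff_left != "blocked" & ok$diff_right != "blocked"
  cells <- c("easy_easy", "hard_hard", "easy_hard", "hard_easy")
  p_left <- dplyr::bind_rows(lapply(cells, function(cc) {
    sub <- ok[free_nc & cfg == cc & !is.na(cfg), ]
    tibble::tibble(config = cc, n = nrow(sub),
                   p_left = if (nrow(sub) > 0) mean(sub$choice == "L")
                   else NA_real_)
  }))
  in_prep <- !is.na(ok$change_time) & ok$change_time >= 100 &
    ok$change_time <= ok$delay + params$near_go_margin
  biasing <- ok$trial_class %in% c("biasing_likely_change",
                                   "biasing_unlikely_change") & in_prep
  baseline_for <- function(sub_cfg) {
    base <- vapply(sub_cfg, function(cc) {
      p_left$p_left[p_left$config == cc]
    }, numeric(1))
    mean(base, na.rm = TRUE)
  }
  delta <- dplyr::bind_rows(lapply(c(L = "L", R = "R"), function(side) {
    # a change favors the left target when the left barrier eased or the
    # right hardened; in this generator biasing changes are hard -> easy
    sub <- ok[biasing & ok$change_side == side, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(favored = side, n = 0, p_left = NA_real_,
                            baseline = NA_real_, delta_p = NA_real_))
    }
    scfg <- paste(ifelse(sub$diff_left == "easy", "easy", "hard"),
                  ifelse(sub$diff_right == "easy", "easy", "hard"), sep = "_")
    p <- mean(sub$choice == "L")
    base <- baseline_for(scfg)
    tibble::tibble(favored = side, n = nrow(sub), p_left = p,
                   baseline = base, delta_p = p - base)
  }))
  list(p_left = p_left, delta = delta)
}
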