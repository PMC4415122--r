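#' Fit per-time class-conditional distributions of the decoded value
#'
#' For each time bin from `train_start` up to `pool_from`, and one pooled
#' bin covering all later time points, fits a Gaussian to the forced-left
#' and forced-right decoded values (sample mean; unbiased SD floored at
#' `sigma_floor`). A bin with fewer than 2 values for a class inherits the
#' nearest earlier bin's fit, with a warning.
#'
#' @param traces Choice-trace tibble of the forced reference trials.
#' @param trials Trial tibble (for the choices).
#' @param params A [pipeline_params()] object.
#' @param fold Optional fold identifier carried in the result.
#' @return A `class_conditionals` object: tibble with `time` (bin center;
#'   `Inf` for the pooled bin), `pooled`, and `mu_L`, `sd_L`, `n_L`,
#'   `mu_R`, `sd_R`, `n_R`.
#' @export
fit_class_conditionals <- function(traces, trials,
                                   params = pipeline_params(), fold = NA) {
  df <- traces |>
    dplyr::left_join(trials[, c("trial_id", "choice")], by = "trial_id") |>
    dplyr::filter(.data$time >= params$train_start)
  for (side in c("L", "R")) {
    if (sum(df$choice == side) < 2) {
      stop("need at least 2 forced trials per side to fit class conditionals")
    }
  }
  df$key <- ifelse(df$time >= params$pool_from, Inf, df$time)
  fit_side <- function(d) {
    list(mu = mean(d), sd = if (length(d) >= 2) stats::sd(d) else NA_real_,
         n = length(d))
  }
  grid <- sort(unique(df$key))
  rows <- lapply(grid, function(k) {
    dk <- df[df$key == k, ]
    l <- fit_side(dk$value[dk$choice == "L"])
    r <- fit_side(dk$value[dk$choice == "R"])
    tibble::tibble(time = k, pooled = is.infinite(k),
                   mu_L = l$mu, sd_L = l$sd, n_L = l$n,
                   mu_R = r$mu, sd_R = r$sd, n_R = r$n)
  })
  tab <- dplyr::bind_rows(rows)
  # inherit sparse bins from the nearest earlier adequate bin
  for (side in c("L", "R")) {
    ncol_ <- paste0("n_", side)
    mucol <- paste0("mu_", side); sdcol <- paste0("sd_", side)
    bad <- which(tab[[ncol_]] < 2 | is.na(tab[[sdcol]]))
    if (length(bad) > 0) {
      warning(length(bad), " class-conditional bin(s) with < 2 ", side,
              " values inherit the nearest earlier bin")
      for (i in bad) {
        donor <- max(setdiff(seq_len(i - 1), bad), -Inf)
        if (!is.finite(donor)) {
          donor <- min(setdiff(seq_len(nrow(tab)), bad))
        }
        tab[[mucol]][i] <- tab[[mucol]][donor]
        tab[[sdcol]][i] <- tab[[sdcol]][donor]
      }
    }
    tab[[sdcol]] <- pmax(tab[[sdcol]], params$sigma_floor)
  }
  structure(list(table = tab, train_start = params$train_start,
                 pool_from = params$pool_from, fold = fold),
            class = "class_conditionals")
}

#' @export
print.class_conditionals <- function(x, ...) {
  cat(sprintf("<class_conditionals> %d time bins + pooled (>= %g ms)%s\n",
              nrow(x$table) - sum(x$table$pooled), x$pool_from,
              if (!is.na(x$fold)) paste0(", fold ", x$fold) else ""))
  invisible(x)
}

conditional_row <- function(model, t) {
  if (t < model$train_start) {
    stop("no class-conditional model before ", model$train_start, " ms")
  }
  tab <- model$table
  if (t >= model$pool_from) return(tab[tab$pooled, ][1, ])
  i <- which(!tab$pooled & abs(tab$time - t) < 1e-6)
  if (length(i) == 0) {
    # nearest non-pooled bin (grid mismatch guard)
    np <- which(!tab$pooled)
    i <- np[which.min(abs(tab$time[np] - t))]
  }
  tab[i[1], ]
}

#' Likelihood ratio of a decoded value under the forced-choice classes
#'
#' Ratio of Gaussian densities at `v` for the bin containing `t` (the
#' pooled bin for late time points). `direction = "L"` returns
#' p(v | left) / p(v | right); `"R"` the reciprocal.
#'
#' @param model A `class_conditionals` object.
#' @param t Time (ms).
#' @param v Decoded value.
#' @param direction `"L"` or `"R"`.
#' @return The density ratio.
#' @export
likelihood_ratio <- function(model, t, v, direction = c("L", "R")) {
  direction <- match.arg(direction)
  row <- conditional_row(model, t)
  log_l <- stats::dnorm(v, row$mu_L, row$sd_L, log = TRUE)
  log_r <- stats::dnorm(v, row$mu_R, row$sd_R, log = TRUE)
  if (direction == "L") exp(log_l - log_r) else exp(log_r - log_l)
}

#' Last sign change of a choice trace
#'
#' Scans the trace at or after the detection-window start and returns the
#' final sign change (time = midpoint of the flanking bins) and its
#' direction. Exact zeros take the sign of the previous bin.
#'
#' @param trace Single-trial trace tibble (`time`, `value`).
#' @param params A [pipeline_params()] object.
#' @return One-row tibble `time`, `direction` (`"L_to_R"`/`"R_to_L"`), or a
#'   zero-row tibble when the sign never changes.
#' @export
last_crossing <- function(trace, params = pipeline_params()) {
  tr <- trace[trace$time >= params$com_window_start, ]
  tr <- tr[order(tr$time), ]
  empty <- tibble::tibble(time = numeric(0), direction = character(0))
  if (nrow(tr) < 2) return(empty)
  s <- trace_signs(tr$value)
  flips <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
  if (length(flips) == 0) return(empty)
  i <- max(flips)
  tibble::tibble(time = (tr$time[i] + tr$time[i + 1]) / 2,
                 direction = if (s[i] < 0) "L_to_R" else "R_to_L")
}

#' Detect a covert change of mind on one trial
#'
#' Conservative three-criterion detector over time points at or after the
#' detection-window start: (1) the decoded choice changes sign at least
#' once; (2) at some time point the value is at least `lr_threshold` times
#' as likely under the forced-left as under the forced-right distribution;
#' (3) at some (possibly different) time point, the reverse. The trial is a
#' change of mind only when all three hold.
#'
#' @param trace Single-trial trace tibble (`trial_id`, `time`, `value`).
#' @param model A `class_conditionals` object.
#' @param params A [pipeline_params()] object.
#' @return One-row tibble: `trial_id`, `is_com`, `crit_sign`,
#'   `crit_strong_L`, `crit_strong_R`, `last_crossing_time`, `direction`.
#' @export
detect_change_of_mind <- function(trace, model,
                                  params = pipeline_params()) {
  tr <- trace[trace$time >= params$com_window_start, ]
  tr <- tr[order(tr$time), ]
  if (nrow(tr) == 0) {
    stop("trace has no time points in the detection window")
  }
  s <- trace_signs(tr$value)
  crit_sign <- any(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
  log_thr <- log(params$lr_threshold)
  lls <- vapply(seq_len(nrow(tr)), function(i) {
    row <- conditional_row(model, tr$time[i])
    stats::dnorm(tr$value[i], row$mu_L, row$sd_L, log = TRUE) -
      stats::dnorm(tr$value[i], row$mu_R, row$sd_R, log = TRUE)
  }, numeric(1))
  crit_L <- any(lls >= log_thr)
  crit_R <- any(-lls >= log_thr)
  cross <- last_crossing(tr, params)
  tibble::tibble(
    trial_id = trace$trial_id[1],
    is_com = crit_sign && crit_L && crit_R,
    crit_sign = crit_sign, crit_strong_L = crit_L, crit_strong_R = crit_R,
    last_crossing_time = if (nrow(cross) > 0) cross$time else NA_real_,
    direction = if (nrow(cross) > 0) cross$direction else NA_character_
  )
}

#' Detect changes of mind across a session
#'
#' Applies [detect_change_of_mind()] to every eligible trial (delay at
#' least `min_delay`, trace available). When per-fold models are supplied
#' (from [loo_cross_validate()]), a trial found among the fold keys is
#' evaluated strictly with its own fold's class conditionals.
#'
#' @param traces Choice-trace tibble for the candidate trials.
#' @param trials Trial tibble.
#' @param model Session-level `class_conditionals`.
#' @param params A [pipeline_params()] object.
#' @param fold_models Optional named list (by trial id) of per-fold
#'   `class_conditionals`.
#' @return Event-call tibble, one row per evaluated trial, joined with
#'   `trial_class`.
#' @export
detect_events <- function(traces, trials, model,
                          params = pipeline_params(), fold_models = NULL) {
  ids <- intersect(unique(traces$trial_id),
                   trials$trial_id[trials$delay >= params$min_delay])
  calls <- lapply(ids, function(id) {
    m <- if (!is.null(fold_models) && as.character(id) %in% names(fold_models)) {
      fold_models[[as.character(id)]]
    } else {
      model
    }
    detect_change_of_mind(traces[traces$trial_id == id, ], m, params)
  })
  dplyr::bind_rows(calls) |>
    dplyr::left_join(trials[, c("trial_id", "trial_class")], by = "trial_id")
}

#' Wilson score interval
#'
#' @param k Successes.
#' @param n Trials.
#' @param z Normal quantile (default 1, an interval "equivalent to
#'   1 s.e.m.", i.e. ~68.27% coverage).
#' @return Tibble with `p`, `lower`, `upper`.
#' @export
wilson_interval <- function(k, n, z = 1) {
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(p = p, lower = center - half, upper = center + half)
}

#' Chi-square 2x2 contingency test (no continuity correction)
#'
#' @param k1,n1,k2,n2 Event counts and totals of the two groups.
#' @return Tibble with `statistic`, `p_value`.
#' @export
chisq_2x2 <- function(k1, n1, k2, n2) {
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value))
}

#' Two-proportion Z test
#'
#' Pooled-variance two-sided Z test for `k1/n1` vs `k2/n2`.
#'
#' @param k1,n1,k2,n2 Counts and totals.
#' @return Tibble with `z`, `p_value`.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Change-of-mind frequencies by trial category
#'
#' Per-category event proportions with Wilson intervals at `z = 1`, plus
#' chi-square 2x2 contrasts (no continuity correction) for the stated
#' comparisons: forced vs free, taken vs untaken switch, likely vs
#' unlikely biasing change.
#'
#' @param events Event-call tibble from [detect_events()] (needs `is_com`
#'   and `trial_class`).
#' @param z Wilson interval z (default 1).
#' @return List with `proportions` (per class: `n`, `k`, `p`, `lower`,
#'   `upper`; empty classes reported with `NA` proportion) and `contrasts`
#'   (`contrast`, `statistic`, `p_value`).
#' @export
category_frequency_stats <- function(events, z = 1) {
  props <- events |>
    dplyr::group_by(.data$trial_class) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$is_com),
                     .groups = "drop") |>
    dplyr::mutate(wilson_interval(.data$k, .data$n, z))
  count_of <- function(classes) {
    sub <- events[events$trial_class %in% classes, ]
    c(k = sum(sub$is_com), n = nrow(sub))
  }
  contrast_defs <- list(
    forced_vs_free = list(c("forced"), c("free")),
    taken_vs_untaken = list(c("encouraged_switch_taken"),
                            c("encouraged_switch_untaken")),
    likely_vs_unlikely = list(c("biasing_likely_change"),
                              c("biasing_unlikely_change"))
  )
  contrasts <- dplyr::bind_rows(lapply(names(contrast_defs), function(nm) {
    a <- count_of(contrast_defs[[nm]][[1]])
    b <- count_of(contrast_defs[[nm]][[2]])
    if (a["n"] == 0 || b["n"] == 0) {
      return(tibble::tibble(contrast = nm, statistic = NA_real_,
                            p_value = NA_real_))
    }
    dplyr::mutate(chisq_2x2(a["k"], a["n"], b["k"], b["n"]),
                  contrast = nm, .before = 1)
  }))
  list(proportions = props, contrasts = contrasts)
}
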