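#' Derive the behavioral trial class
#'
#' The trial class is a pure function of the initial barrier difficulties,
#' the (optional) mid-trial barrier change, and the eventual choice:
#'
#' * `forced` — one target blocked throughout, no barrier change;
#' * `free` — both targets accessible, no barrier change;
#' * `free_to_forced` — both initially accessible, a change blocked one side;
#' * `encouraged_switch_taken` / `encouraged_switch_untaken` — began forced,
#'   a change opened the blocked side; "taken" when the newly available
#'   target was chosen;
#' * `biasing_likely_change` / `biasing_unlikely_change` — free throughout
#'   with one side initially hard and the other easy, the hard side became
#'   easy mid-trial; "likely" when the initially-hard side was chosen (a
#'   change of mind was likely), "unlikely" when the always-easy side was;
#' * `other` — every remaining configuration.
#'
#' @param diff_left,diff_right Initial difficulty per side: `"easy"`,
#'   `"hard"`, or `"blocked"`.
#' @param change_side Side whose key barrier changed (`"L"`, `"R"`, or `NA`
#'   for no change).
#' @param change_new New difficulty of the changed side (`NA` for no change).
#' @param choice Eventual reach target, `"L"` or `"R"`.
#' @return Character vector of trial classes.
#' @examples
#' derive_trial_class("easy", "blocked", NA, NA, "L")   # forced
#' derive_trial_class("easy", "hard", "R", "easy", "R") # biasing_likely_change
#' @export
derive_trial_class <- function(diff_left, diff_right, change_side,
                               change_new, choice) {
  n <- length(diff_left)
  stopifnot(length(diff_right) == n, length(choice) == n)
  change_side <- rep_len(change_side, n)
  change_new <- rep_len(change_new, n)
  out <- character(n)
  for (i in seq_len(n)) {
    dl <- diff_left[i]; dr <- diff_right[i]
    cs <- change_side[i]; cn <- change_new[i]; ch <- choice[i]
    blocked_l <- dl == "blocked"; blocked_r <- dr == "blocked"
    n_blocked <- blocked_l + blocked_r
    if (is.na(cs)) {
      out[i] <- if (n_blocked == 1) "forced" else if (n_blocked == 0) "free" else "other"
      next
    }
    changed_old <- if (cs == "L") dl else dr
    if (n_blocked == 1) {
      blocked_side <- if (blocked_l) "L" else "R"
      if (cs == blocked_side && cn != "blocked") {
        out[i] <- if (ch == cs) "encouraged_switch_taken" else "encouraged_switch_untaken"
      } else {
        out[i] <- "other"
      }
    } else if (n_blocked == 0) {
      if (cn == "blocked") {
        out[i] <- "free_to_forced"
      } else if (changed_old == "hard" && cn == "easy" &&
                 (if (cs == "L") dr else dl) == "easy") {
        out[i] <- if (ch == cs) "biasing_likely_change" else "biasing_unlikely_change"
      } else {
        out[i] <- "other"
      }
    } else {
      out[i] <- "other"
    }
  }
  out
}

trial_columns <- c("trial_id", "maze_family", "diff_left", "diff_right",
                   "change_time", "change_side", "change_new", "delay",
                   "move_onset", "rt", "choice", "success", "trial_class")

#' Validate a trial table
#'
#' Checks column presence, timing invariants (`rt >= 0`,
#' `move_onset > delay`), that `trial_class` re-derives from the barrier
#' configuration and choice, and that successful forced trials never chose
#' the blocked side.
#'
#' @param trials A trial tibble.
#' @return The (invisible) validated tibble.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(trials$rt < 0)) stop("trial table has negative reaction times")
  if (any(trials$move_onset <= trials$delay)) {
    stop("movement onset must follow the Go cue on every trial")
  }
  rederived <- derive_trial_class(trials$diff_left, trials$diff_right,
                                  trials$change_side, trials$change_new,
                                  trials$choice)
  bad <- which(rederived != trials$trial_class)
  if (length(bad) > 0) {
    stop("trial_class does not re-derive for trial_id ",
         paste(utils::head(trials$trial_id[bad], 5), collapse = ", "))
  }
  forced <- trials$trial_class == "forced" & trials$success
  blocked_side <- ifelse(trials$diff_left == "blocked", "L",
                         ifelse(trials$diff_right == "blocked", "R", NA))
  if (any(forced & !is.na(blocked_side) & trials$choice == blocked_side)) {
    stop("successful forced trial chose the blocked side")
  }
  invisible(trials)
}

#' Select trials by rule
#'
#' Deterministic, order-preserving filter over a documented criterion
#' vocabulary. Criteria are combined with AND.
#'
#' @param trials A trial tibble.
#' @param criteria Named list drawn from: `min_delay` (ms), `zero_delay`
#'   (logical), `success` (logical), `trial_class` (character vector),
#'   `has_change` (logical: barrier change present), `change_window`
#'   (ms pair: change time inside the half-open window), `near_go` (logical:
#'   change within `near_go_margin` of the Go cue), `rt_min`, `rt_max` (ms).
#' @param params A [pipeline_params()] object (used by `near_go`).
#' @return Integer vector of retained `trial_id`s, in input order.
#' @examples
#' tr <- tibble::tibble(
#'   trial_id = 1:4, maze_family = "T", diff_left = "easy",
#'   diff_right = "blocked", change_time = NA_real_, change_side = NA_character_,
#'   change_new = NA_character_, delay = c(0, 250, 300, 800),
#'   move_onset = c(0, 250, 300, 800) + 300, rt = 300, choice = "L",
#'   success = TRUE, trial_class = "forced")
#' select_trials(tr, list(min_delay = 300))
#' @export
select_trials <- function(trials, criteria, params = pipeline_params()) {
  known <- c("min_delay", "zero_delay", "success", "trial_class",
             "has_change", "change_window", "near_go", "rt_min", "rt_max")
  unknown <- setdiff(names(criteria), known)
  if (length(unknown) > 0) {
    stop("unknown trial-selection criteria: ", paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(trials))
  for (nm in names(criteria)) {
    val <- criteria[[nm]]
    keep <- keep & switch(
      nm,
      min_delay = trials$delay >= val,
      zero_delay = if (val) trials$delay == 0 else trials$delay > 0,
      success = trials$success == val,
      trial_class = trials$trial_class %in% val,
      has_change = if (val) !is.na(trials$change_time) else is.na(trials$change_time),
      change_window = !is.na(trials$change_time) &
        trials$change_time >= val[1] & trials$change_time < val[2],
      near_go = if (val) {
        !is.na(trials$change_time) &
          abs(trials$change_time - trials$delay) <= params$near_go_margin
      } else {
        is.na(trials$change_time) |
          abs(trials$change_time - trials$delay) > params$near_go_margin
      },
      rt_min = trials$rt >= val,
      rt_max = trials$rt <= val
    )
  }
  trials$trial_id[keep]
}

# +1 for rightward, -1 for leftward: the package-wide sign convention for
# the decoded choice axis.
choice_sign <- function(choice) ifelse(choice == "R", 1, -1)

# Sign of a decoded trace with the documented tie-break: exact zeros take
# the sign of the previous bin (a leading zero takes the first nonzero sign).
trace_signs <- function(values) {
  s <- sign(values)
  nz <- which(s != 0)
  if (length(nz) == 0) return(s)
  s[seq_len(nz[1] - 1)] <- s[nz[1]]
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  s
}

#' Exclude trials with possible changes of mind
#'
#' Aggressive screen used before PSTH-based analyses: a trial is retained
#' only if the decoded choice matches the eventual choice at every time
#' point later than the detection-window start.
#'
#' @param traces Choice-trace tibble (`trial_id`, `time`, `value`).
#' @param trials Trial tibble for the candidate trials.
#' @param params A [pipeline_params()] object.
#' @return Integer vector of retained `trial_id`s.
#' @export
exclude_possible_com <- function(traces, trials, params = pipeline_params()) {
  missing <- setdiff(trials$trial_id, unique(traces$trial_id))
  if (length(missing) > 0) {
    stop("missing choice traces for trial_id ",
         paste(missing, collapse = ", "))
  }
  keep <- logical(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    tr <- traces[traces$trial_id == id & traces$time > params$com_window_start, ]
    tr <- tr[order(tr$time), ]
    if (nrow(tr) == 0) { keep[i] <- TRUE; next }
    s <- trace_signs(tr$value)
    keep[i] <- all(s == choice_sign(trials$choice[i]))
  }
  trials$trial_id[keep]
}
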