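#' Spike session container
#'
#' A session bundles a unit table (`unit_id`, `array` in `{"PMd","M1"}`), a
#' trial table (see [validate_trials()]), per-trial per-unit spike-time
#' lists (ms relative to maze onset), the trial recording windows, and —
#' for synthetic sessions — the ground-truth intention traces.
#'
#' @param units Tibble with columns `unit_id`, `array`.
#' @param trials Trial tibble.
#' @param spikes Named list (by `trial_id`) of lists of sorted spike-time
#'   vectors, one per unit.
#' @param windows Tibble with `trial_id`, `win_start`, `win_end`: the
#'   recorded window of each trial (ms).
#' @param ground_truth Optional list with `intentions` and `events` tibbles.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(units, trials, spikes, windows,
                          ground_truth = NULL) {
  stopifnot(all(c("unit_id", "array") %in% names(units)),
            all(units$array %in% c("PMd", "M1")),
            nrow(units) >= 1, nrow(units) <= 1000)
  validate_trials(trials)
  stopifnot(setequal(names(spikes), as.character(trials$trial_id)))
  win <- windows[match(trials$trial_id, windows$trial_id), ]
  for (i in seq_len(nrow(trials))) {
    key <- as.character(trials$trial_id[i])
    trains <- spikes[[key]]
    if (length(trains) != nrow(units)) {
      stop("trial ", key, " has ", length(trains), " spike trains for ",
           nrow(units), " units")
    }
    for (u in seq_along(trains)) {
      st <- trains[[u]]
      if (length(st) > 1 && any(diff(st) <= 0)) {
        stop("spike times not strictly sorted (trial ", key, ", unit ", u, ")")
      }
      if (length(st) > 0 &&
          (min(st) < win$win_start[i] || max(st) > win$win_end[i])) {
        stop("spike time outside recorded window (trial ", key, ", unit ", u, ")")
      }
    }
  }
  structure(list(units = tibble::as_tibble(units),
                 trials = tibble::as_tibble(trials),
                 spikes = spikes,
                 windows = tibble::as_tibble(windows),
                 ground_truth = ground_truth),
            class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  n_spikes <- sum(vapply(x$spikes, function(tr) sum(lengths(tr)), numeric(1)))
  cat(sprintf("<spike_session> %d units (%d PMd, %d M1), %d trials, %s spikes\n",
              nrow(x$units), sum(x$units$array == "PMd"),
              sum(x$units$array == "M1"), nrow(x$trials),
              format(n_spikes, big.mark = ",")))
  cat("  trial classes: ",
      paste(sprintf("%s=%d", names(table(x$trials$trial_class)),
                    table(x$trials$trial_class)), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Save / load a session as a JSON-lines fixture
#'
#' The fixture is newline-delimited JSON: a `header` record (units, window
#' metadata), one `trial` record per trial (trial fields plus per-unit
#' spike-time arrays in ms), and optional `intention` / `event` records for
#' ground truth. Numbers are written at full precision so the round trip is
#' lossless.
#'
#' @param session A [spike_session()].
#' @param path File path.
#' @return `save_session` returns `path` invisibly; `load_session` returns
#'   the reconstructed session.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "spike_session"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  emit <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                                null = "null", na = "null"), con)
  }
  emit(list(type = "header", format = "comdecode-session-v1",
            units = session$units))
  for (i in seq_len(nrow(session$trials))) {
    key <- as.character(session$trials$trial_id[i])
    emit(list(type = "trial",
              trial = as.list(session$trials[i, ]),
              window = as.list(session$windows[
                match(session$trials$trial_id[i], session$windows$trial_id), ]),
              spikes_ms = lapply(session$spikes[[key]], as.numeric)))
  }
  if (!is.null(session$ground_truth)) {
    intents <- session$ground_truth$intentions
    # the leading "none" segment starts at -Inf, which JSON cannot carry
    intents$seg_start[is.infinite(intents$seg_start)] <- NA_real_
    emit(list(type = "ground_truth",
              intentions = intents,
              events = session$ground_truth$events))
  }
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty session file: ", path)
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed session record at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$type)) stop("malformed session record at line ", i,
                                ": missing type")
    rec
  })
  if (recs[[1]]$type != "header" ||
      !identical(recs[[1]]$format, "comdecode-session-v1")) {
    stop("malformed session record at line 1: expected comdecode-session-v1 header")
  }
  units <- tibble::as_tibble(recs[[1]]$units)
  trial_recs <- recs[vapply(recs, function(r) r$type == "trial", logical(1))]
  trials <- dplyr::bind_rows(lapply(trial_recs, function(r) {
    tr <- r$trial
    tr[vapply(tr, is.null, logical(1))] <- NA
    tibble::as_tibble(tr)
  }))
  # jsonlite null -> NA comes back logical for all-NA columns
  trials$change_time <- as.numeric(trials$change_time)
  trials$change_side <- as.character(trials$change_side)
  trials$change_new <- as.character(trials$change_new)
  windows <- dplyr::bind_rows(lapply(trial_recs, function(r) {
    tibble::as_tibble(r$window)
  }))
  spikes <- lapply(trial_recs, function(r) {
    trains <- r$spikes_ms
    if (is.matrix(trains)) trains <- split(trains, row(trains))
    lapply(trains, function(st) {
      st <- as.numeric(st)
      if (length(st) > 1 && any(diff(st) <= 0)) {
        stop("unsorted spike train in trial ", r$trial$trial_id, call. = FALSE)
      }
      st
    })
  })
  names(spikes) <- as.character(trials$trial_id)
  gt_rec <- recs[vapply(recs, function(r) r$type == "ground_truth", logical(1))]
  gt <- if (length(gt_rec) > 0) {
    intents <- tibble::as_tibble(gt_rec[[1]]$intentions)
    intents$seg_start[is.na(intents$seg_start)] <- -Inf
    list(intentions = intents,
         events = tibble::as_tibble(gt_rec[[1]]$events))
  }
  spike_session(units, trials, spikes, windows, ground_truth = gt)
}

#' Export the trial table as CSV
#'
#' @param session A [spike_session()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(session, path) {
  utils::write.csv(session$trials, path, row.names = FALSE)
  invisible(path)
}
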