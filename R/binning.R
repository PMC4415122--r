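#' Bin a spike train into counts
#'
#' Half-open, left-closed bins `[epoch[1] + (k-1) * bin_width,
#' epoch[1] + k * bin_width)` anchored at the epoch start; a trailing
#' partial bin is dropped and spikes outside the epoch are ignored, so the
#' binned counts conserve the number of in-window spikes.
#'
#' @param spikes Sorted spike times (ms relative to maze onset).
#' @param epoch Two-element epoch `[start, end)` in ms.
#' @param bin_width Bin width in ms.
#' @return Integer vector of counts, one per full bin.
#' @examples
#' bin_spikes(c(-295, -290, -250), c(-300, -240), 20)  # 2, 0, 1
#' @export
bin_spikes <- function(spikes, epoch, bin_width) {
  stopifnot(length(epoch) == 2, bin_width > 0,
            epoch[2] - epoch[1] >= bin_width)
  if (is.unsorted(spikes)) {
    stop("spike times must be sorted nondecreasing")
  }
  n_bins <- floor((epoch[2] - epoch[1]) / bin_width)
  edges <- epoch[1] + bin_width * (0:n_bins)
  inside <- spikes >= edges[1] & spikes < edges[n_bins + 1]
  idx <- floor((spikes[inside] - epoch[1]) / bin_width) + 1
  counts <- tabulate(idx, nbins = n_bins)
  as.integer(counts)
}

# Bin centers for a trial whose epoch runs [epoch_start, n_bins * width).
bin_centers <- function(epoch_start, n_bins, bin_width) {
  epoch_start + bin_width * (seq_len(n_bins) - 0.5)
}

#' Bin all spike trains of a session
#'
#' Each trial's epoch runs from `epoch_start` to the last full bin ending at
#' or before `move_onset - epoch_end_offset`, so trials have variable
#' numbers of bins on a shared grid.
#'
#' @param session A [spike_session] object.
#' @param params A [pipeline_params()] object.
#' @param trial_ids Optional subset of trials to bin (default: all).
#' @return A `binned_counts` object: a list with `counts` (per-trial
#'   unit-by-bin integer matrices), `centers` (per-trial bin-center vectors),
#'   `trial_id`, `bin_width` and `epoch_start`.
#' @export
bin_session <- function(session, params = pipeline_params(),
                        trial_ids = NULL) {
  stopifnot(inherits(session, "spike_session"))
  trials <- session$trials
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  dt <- params$bin_width
  n_units <- nrow(session$units)
  counts <- vector("list", nrow(trials))
  centers <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    epoch_end <- trials$move_onset[i] - params$epoch_end_offset
    n_bins <- floor((epoch_end - params$epoch_start) / dt)
    if (n_bins < 1) stop("trial ", id, " has no full bin in the epoch")
    ep <- c(params$epoch_start, params$epoch_start + n_bins * dt)
    key <- as.character(id)
    trains <- session$spikes[[key]]
    m <- matrix(0L, n_units, n_bins)
    for (u in seq_len(n_units)) {
      m[u, ] <- bin_spikes(trains[[u]], ep, dt)
    }
    counts[[i]] <- m
    centers[[i]] <- bin_centers(params$epoch_start, n_bins, dt)
  }
  structure(list(counts = counts, centers = centers,
                 trial_id = trials$trial_id,
                 bin_width = dt, epoch_start = params$epoch_start),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  nb <- vapply(x$counts, ncol, integer(1))
  cat(sprintf("<binned_counts> %d trials x %d units, %g ms bins, %d-%d bins/trial\n",
              length(x$counts), nrow(x$counts[[1]]), x$bin_width,
              min(nb), max(nb)))
  invisible(x)
}
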