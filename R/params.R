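#' Pipeline parameters
#'
#' Bundles every numeric constant used across the pipeline: binning and epoch
#' definitions, decoder training window, change-of-mind detector settings,
#' normalization, task timing distributions, and analysis windows. All times
#' are in milliseconds relative to maze onset (maze onset = 0, Go cue =
#' `delay`).
#'
#' @param bin_width Spike-count bin width (ms).
#' @param n_latents Latent dimensionality of the factor model.
#' @param epoch_start Start of the analyzed epoch (ms, relative to maze onset).
#' @param epoch_end_offset The epoch ends this many ms before movement onset.
#' @param train_start Decoder training uses time points at or after this (ms).
#' @param min_delay Minimum instructed delay for decoder-based analyses (ms).
#' @param psth_min_delay Minimum delay for PSTH-based analyses (ms).
#' @param com_window_start Change-of-mind detection considers time points at
#'   or after this (ms).
#' @param lr_threshold Likelihood-ratio threshold of the detector.
#' @param pool_from Forced-choice decoded-value distributions pool all time
#'   points at or beyond this (ms).
#' @param norm_quantile Quantile of absolute decoded values used as the
#'   normalization constant.
#' @param perf_bin Width of the delay bins for the performance-vs-time curve
#'   (ms).
#' @param baseline_window Two-element window defining the pre-maze baseline
#'   (ms).
#' @param com_rate_window Width of the firing-rate window centered on a
#'   decoded-choice crossing (ms).
#' @param psth_sd SD of the Gaussian PSTH smoothing kernel (ms).
#' @param corr_window Two-element window for the forced/free response
#'   correlation (ms).
#' @param snr_min Minimum signal-to-noise ratio for unit inclusion.
#' @param indecision_probe Time point probed by the indecision regression (ms).
#' @param indecision_min_rt Minimum reaction time for the indecision
#'   regression (ms).
#' @param near_go_margin Barrier changes within this margin of the Go cue
#'   count as "near Go" (ms).
#' @param delay_tau,delay_cap Truncated-exponential parameters of the
#'   instructed delay (ms).
#' @param change_tau,change_cap Truncated-exponential parameters of the
#'   barrier-change latency (ms).
#' @param mc_reps Monte-Carlo repetitions for the decoder performance p-value.
#' @param sigma_floor Floor on class-conditional standard deviations
#'   (normalized decoded units).
#' @param sqrt_transform Apply a square-root transform to spike counts before
#'   the factor model.
#' @param norm_signed If `TRUE`, the normalization quantile is taken over
#'   signed rather than absolute decoded values.
#' @param gpfa_tol Relative log-likelihood convergence tolerance of the EM
#'   fit.
#' @param gpfa_max_iter Maximum EM iterations.
#'
#' @return An object of class `pipeline_params` (a validated named list).
#' @examples
#' p <- pipeline_params()
#' p$bin_width
#' pipeline_params(n_latents = 8)$n_latents
#' @export
pipeline_params <- function(bin_width = 20,
                            n_latents = 12,
                            epoch_start = -300,
                            epoch_end_offset = 200,
                            train_start = 80,
                            min_delay = 300,
                            psth_min_delay = 350,
                            com_window_start = 160,
                            lr_threshold = 10,
                            pool_from = 600,
                            norm_quantile = 0.90,
                            perf_bin = 60,
                            baseline_window = c(-300, -40),
                            com_rate_window = 200,
                            psth_sd = 30,
                            corr_window = c(-200, 300),
                            snr_min = 4,
                            indecision_probe = 100,
                            indecision_min_rt = 300,
                            near_go_margin = 50,
                            delay_tau = 500,
                            delay_cap = 1000,
                            change_tau = 500,
                            change_cap = 1200,
                            mc_reps = 1e7,
                            sigma_floor = 1e-3,
                            sqrt_transform = TRUE,
                            norm_signed = FALSE,
                            gpfa_tol = 1e-8,
                            gpfa_max_iter = 500) {
  p <- list(
    bin_width = bin_width, n_latents = n_latents, epoch_start = epoch_start,
    epoch_end_offset = epoch_end_offset, train_start = train_start,
    min_delay = min_delay, psth_min_delay = psth_min_delay,
    com_window_start = com_window_start, lr_threshold = lr_threshold,
    pool_from = pool_from, norm_quantile = norm_quantile,
    perf_bin = perf_bin, baseline_window = baseline_window,
    com_rate_window = com_rate_window, psth_sd = psth_sd,
    corr_window = corr_window, snr_min = snr_min,
    indecision_probe = indecision_probe,
    indecision_min_rt = indecision_min_rt, near_go_margin = near_go_margin,
    delay_tau = delay_tau, delay_cap = delay_cap, change_tau = change_tau,
    change_cap = change_cap, mc_reps = mc_reps, sigma_floor = sigma_floor,
    sqrt_transform = sqrt_transform, norm_signed = norm_signed,
    gpfa_tol = gpfa_tol, gpfa_max_iter = gpfa_max_iter
  )
  class(p) <- "pipeline_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "pipeline_params"))
  check <- function(ok, msg) if (!ok) stop("invalid pipeline_params: ", msg, call. = FALSE)
  check(p$bin_width > 0, "bin_width must be > 0")
  check(p$n_latents >= 1, "n_latents must be >= 1")
  check(p$epoch_start < p$train_start, "epoch_start must precede train_start")
  check(p$train_start < p$pool_from, "train_start must precede pool_from")
  check(p$norm_quantile > 0 && p$norm_quantile < 1,
        "norm_quantile must lie strictly in (0, 1)")
  check(abs(p$com_window_start / p$bin_width -
              round(p$com_window_start / p$bin_width)) < 1e-9,
        "com_window_start must be a multiple of bin_width")
  check(length(p$baseline_window) == 2 &&
          p$baseline_window[1] < p$baseline_window[2],
        "baseline_window must be an increasing pair")
  check(length(p$corr_window) == 2 && p$corr_window[1] < p$corr_window[2],
        "corr_window must be an increasing pair")
  check(p$epoch_end_offset >= 0, "epoch_end_offset must be >= 0")
  check(p$lr_threshold > 0, "lr_threshold must be > 0")
  check(p$perf_bin > 0, "perf_bin must be > 0")
  check(p$delay_tau > 0 && p$delay_cap > 0, "delay distribution parameters must be > 0")
  check(p$change_tau > 0 && p$change_cap > 0, "change distribution parameters must be > 0")
  check(p$mc_reps >= 1, "mc_reps must be >= 1")
  check(p$sigma_floor > 0, "sigma_floor must be > 0")
  check(p$com_rate_window > 0, "com_rate_window must be > 0")
  check(p$psth_sd > 0, "psth_sd must be > 0")
  invisible(p)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  cat(sprintf("  binning: %g ms, %d latents, epoch [%g, move onset - %g) ms\n",
              x$bin_width, x$n_latents, x$epoch_start, x$epoch_end_offset))
  cat(sprintf("  decoder: train from %g ms, min delay %g ms, norm quantile %.2f\n",
              x$train_start, x$min_delay, x$norm_quantile))
  cat(sprintf("  detector: window from %g ms, LR threshold %g, pool from %g ms\n",
              x$com_window_start, x$lr_threshold, x$pool_from))
  cat(sprintf("  task timing: delay trunc-exp(tau=%g, cap=%g), change trunc-exp(tau=%g, cap=%g)\n",
              x$delay_tau, x$delay_cap, x$change_tau, x$change_cap))
  invisible(x)
}

# Derive a reproducible sub-seed for a named random substream, so that e.g.
# the spike-emission stream can change without disturbing the schedule stream.
substream_seed <- function(seed, stream) {
  offsets <- c(schedule = 101L, intention = 211L, spikes = 307L,
               mc = 401L, shuffle = 503L, tuning = 601L)
  if (!stream %in% names(offsets)) stop("unknown random substream: ", stream)
  (as.integer(seed) * 97L + offsets[[stream]]) %% 2147483647L
}
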