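#' Train the time-invariant linear choice decoder
#'
#' Fits one wide-margin linear classifier (linear-kernel SVM, soft-margin
#' cost 1, no rescaling) on the pooled `(trial x eligible bin)` latent
#' states of the training trials, labeled by the eventual choice. The same
#' weights apply at every time point. Decoded values are signed distances
#' from the separating hyperplane, normalized by the configured quantile of
#' absolute decoded values over *all* session trials and time points;
#' positive values indicate a rightward choice.
#'
#' Training trials are, by default, successful forced-choice trials with no
#' barrier change and delay of at least `min_delay`; only bins at or after
#' `train_start` enter the pooled training set.
#'
#' @param latents A `latent_trajectories` object covering the session.
#' @param trials The session trial tibble.
#' @param params A [pipeline_params()] object.
#' @param trial_class Training class: `"forced"` (default) or `"free"` (the
#'   retrain-on-free control).
#' @param train_ids Optional explicit training trial ids (overrides the
#'   class-based selection; still filtered to the eligible bins).
#' @return A `choice_decoder`: weights `w`, bias `b`, `norm_constant`, and
#'   training metadata.
#' @export
train_decoder <- function(latents, trials, params = pipeline_params(),
                          trial_class = "forced", train_ids = NULL) {
  if (is.null(train_ids)) {
    train_ids <- select_trials(trials, list(trial_class = trial_class,
                                            has_change = FALSE,
                                            success = TRUE,
                                            min_delay = params$min_delay),
                               params)
  }
  if (length(train_ids) < 2) stop("need at least 2 training trials")
  tr_idx <- match(train_ids, latents$trial_id)
  labels <- trials$choice[match(train_ids, trials$trial_id)]
  if (length(unique(labels)) < 2) {
    stop("training set contains a single choice class")
  }
  X <- list(); y <- list()
  for (k in seq_along(tr_idx)) {
    i <- tr_idx[k]
    sel <- latents$centers[[i]] >= params$train_start
    if (!any(sel)) next
    X[[k]] <- t(latents$latents[[i]][, sel, drop = FALSE])
    y[[k]] <- rep(labels[k], sum(sel))
  }
  X <- do.call(rbind, X)
  y <- factor(unlist(y), levels = c("L", "R"))
  if (length(unique(y)) < 2) {
    stop("pooled training points contain a single choice class ",
         "(short trials may contribute no eligible bins)")
  }
  fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # enforce the sign convention: positive decoded value = rightward
  right_mean <- mean(X[y == "R", , drop = FALSE] %*% w + b)
  if (right_mean < 0) {
    w <- -w
    b <- -b
  }
  dec <- structure(list(w = w, b = b, norm_constant = 1,
                        n_latents = length(w),
                        train_ids = train_ids, trial_class = trial_class,
                        train_start = params$train_start,
                        norm_quantile = params$norm_quantile,
                        n_train_points = nrow(X)),
                   class = "choice_decoder")
  raw <- unlist(lapply(seq_along(latents$latents), function(i) {
    raw_distances(dec, latents$latents[[i]])
  }))
  nc <- stats::quantile(if (params$norm_signed) raw else abs(raw),
                        params$norm_quantile, names = FALSE)
  if (!is.finite(nc) || nc <= 0) stop("degenerate normalization constant")
  dec$norm_constant <- nc
  dec
}

raw_distances <- function(decoder, latent_matrix) {
  unname(drop(crossprod(latent_matrix, decoder$w) + decoder$b)) /
    sqrt(sum(decoder$w^2))
}

#' @export
print.choice_decoder <- function(x, ...) {
  cat(sprintf("<choice_decoder> %d latents, trained on %d %s trials (%d pooled points)\n",
              x$n_latents, length(x$train_ids), x$trial_class,
              x$n_train_points))
  cat(sprintf("  norm constant %.4f (q%.2f of |signed distance|); positive = rightward\n",
              x$norm_constant, x$norm_quantile))
  invisible(x)
}

#' Decode the choice trace of one trial
#'
#' `value(t) = (w . x_t + b) / (||w|| * norm_constant)`: the normalized
#' signed distance of the latent state from the classifying hyperplane,
#' over the trial's full epoch (including pre-maze bins).
#'
#' @param decoder A `choice_decoder`.
#' @param latent_matrix `n_latents x bins` latent trajectory.
#' @param centers Bin-center times (ms).
#' @param trial_id Trial identifier for the output.
#' @return Tibble with `trial_id`, `time`, `value`.
#' @export
decode_trace <- function(decoder, latent_matrix, centers, trial_id = NA_integer_) {
  if (nrow(latent_matrix) != decoder$n_latents) {
    stop("latent dimensionality mismatch: decoder has ", decoder$n_latents,
         ", trajectory has ", nrow(latent_matrix))
  }
  tibble::tibble(trial_id = trial_id, time = centers,
                 value = raw_distances(decoder, latent_matrix) /
                   decoder$norm_constant)
}

#' Decode every trial of a session
#'
#' @param decoder A `choice_decoder`.
#' @param latents A `latent_trajectories` object.
#' @param trial_ids Optional subset.
#' @return Long tibble of choice traces (`trial_id`, `time`, `value`).
#' @export
decode_trials <- function(decoder, latents, trial_ids = NULL) {
  idx <- if (is.null(trial_ids)) seq_along(latents$trial_id) else
    match(trial_ids, latents$trial_id)
  dplyr::bind_rows(lapply(idx, function(i) {
    decode_trace(decoder, latents$latents[[i]], latents$centers[[i]],
                 latents$trial_id[i])
  }))
}

#' Summarize traces at the final decoded point
#'
#' @param traces Choice-trace tibble.
#' @param trials Trial tibble (for the eventual choice).
#' @return Tibble with `trial_id`, `last_time`, `last_value`, `predicted`,
#'   `choice`, `correct`.
#' @export
trace_summary <- function(traces, trials) {
  traces |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::slice_max(.data$time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(last_time = "time", last_value = "value") |>
    dplyr::mutate(predicted = ifelse(.data$last_value >= 0, "R", "L")) |>
    dplyr::left_join(trials[, c("trial_id", "choice")], by = "trial_id") |>
    dplyr::mutate(correct = .data$predicted == .data$choice)
}

#' Leave-one-out cross-validated decoding
#'
#' Each eligible training trial is decoded by a decoder trained without it;
#' the per-fold decoder (weights, bias, normalization constant, training
#' ids) is retained so downstream event detection can use strictly that
#' fold's models. The fold normalization constant is computed over all
#' session trials except the held-out one.
#'
#' @param latents A `latent_trajectories` object.
#' @param trials Session trial tibble.
#' @param params A [pipeline_params()] object.
#' @param trial_class Class defining the cross-validated set.
#' @return List with `traces` (held-out decoded traces), `summary`
#'   (final-point accuracy per trial), `accuracy` (fraction of trials whose
#'   last decoded point matches the choice), and `folds` (per-trial fold
#'   decoders, named by trial id).
#' @export
loo_cross_validate <- function(latents, trials, params = pipeline_params(),
                               trial_class = "forced") {
  ids <- select_trials(trials, list(trial_class = trial_class,
                                    has_change = FALSE, success = TRUE,
                                    min_delay = params$min_delay), params)
  if (length(ids) < 3) stop("need at least 3 eligible trials for leave-one-out")
  traces <- list()
  folds <- list()
  skipped <- integer(0)
  for (id in ids) {
    keep <- setdiff(ids, id)
    labels <- trials$choice[match(keep, trials$trial_id)]
    if (length(unique(labels)) < 2) {
      warning("fold for trial ", id, " has a single class; skipped")
      skipped <- c(skipped, id)
      next
    }
    sub <- latents_subset(latents, setdiff(latents$trial_id, id))
    dec <- train_decoder(sub, trials, params, trial_class = trial_class,
                         train_ids = keep)
    i <- match(id, latents$trial_id)
    traces[[as.character(id)]] <-
      decode_trace(dec, latents$latents[[i]], latents$centers[[i]], id)
    folds[[as.character(id)]] <- dec
  }
  traces <- dplyr::bind_rows(traces)
  summ <- trace_summary(traces, trials)
  list(traces = traces, summary = summ,
       accuracy = mean(summ$correct), folds = folds,
       trial_ids = setdiff(ids, skipped))
}

latents_subset <- function(latents, trial_ids) {
  idx <- match(trial_ids, latents$trial_id)
  structure(list(latents = latents$latents[idx],
                 centers = latents$centers[idx],
                 trial_id = latents$trial_id[idx],
                 n_latents = latents$n_latents,
                 bin_width = latents$bin_width),
            class = "latent_trajectories")
}

#' Decoder accuracy as a function of time
#'
#' Trials are assigned to fixed-width bins by the time of their *last*
#' decoded point (which ends a fixed offset before movement onset, so
#' short-delay trials probe early time points); the reported value is the
#' fraction of trials in each bin whose final decoded point matched the
#' choice. Bins with no trials are absent from the output rather than
#' reported as zero.
#'
#' @param traces Choice-trace tibble (typically cross-validated and/or
#'   full-model decodes pooled).
#' @param trials Trial tibble.
#' @param params A [pipeline_params()] object (`perf_bin` sets the width).
#' @return Tibble with `bin_start`, `bin_end`, `n`, `accuracy`.
#' @export
performance_vs_time <- function(traces, trials, params = pipeline_params()) {
  summ <- trace_summary(traces, trials)
  if (nrow(summ) == 0) return(tibble::tibble(bin_start = numeric(),
                                             bin_end = numeric(),
                                             n = integer(),
                                             accuracy = numeric()))
  summ |>
    dplyr::mutate(bin_start = floor(.data$last_time / params$perf_bin) *
                    params$perf_bin) |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(bin_end = .data$bin_start + params$perf_bin,
                  .after = "bin_start") |>
    dplyr::arrange(.data$bin_start)
}

#' Monte-Carlo p-value for decoder performance
#'
#' Simulates a null decoder that picks left or right by chance according to
#' the class prevalence, and estimates `P(null accuracy >= observed)` with
#' the add-one (Davison-Hinkley) correction. Under this null each trial is
#' matched with probability `prevalence^2 + (1 - prevalence)^2`.
#'
#' @param n_correct Observed number of correctly decoded trials.
#' @param n_trials Number of trials.
#' @param prevalence Prevalence of the majority-coded class in `[0, 1]`.
#' @param reps Number of Monte-Carlo runs.
#' @param seed Integer seed.
#' @return The estimated p-value.
#' @export
performance_pvalue <- function(n_correct, n_trials, prevalence = 0.5,
                               reps = 1e5, seed = 1) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence must lie in [0, 1]")
  stopifnot(n_correct >= 0, n_correct <= n_trials, reps >= 1)
  set.seed(substream_seed(seed, "mc"))
  q <- prevalence^2 + (1 - prevalence)^2
  hits <- 0
  left <- reps
  while (left > 0) {
    chunk <- min(left, 1e6)
    hits <- hits + sum(stats::rbinom(chunk, n_trials, q) >= n_correct)
    left <- left - chunk
  }
  (hits + 1) / (reps + 1)
}
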