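#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted latent model
#'
#' @param x A `gpfa_model`.
#' @param ... Unused.
#' @return Tibble with one row per latent: `latent`, `timescale_ms`,
#'   `loading_norm` (column norm of the loading matrix).
#' @method tidy gpfa_model
#' @export
tidy.gpfa_model <- function(x, ...) {
  tibble::tibble(latent = seq_len(x$n_latents),
                 timescale_ms = x$tau,
                 loading_norm = sqrt(colSums(x$C^2)))
}

#' @rdname tidy.gpfa_model
#' @return `glance()` returns a one-row tibble with fit-level summaries.
#' @method glance gpfa_model
#' @export
glance.gpfa_model <- function(x, ...) {
  tibble::tibble(n_units = nrow(x$C), n_latents = x$n_latents,
                 bin_width = x$bin_width,
                 log_lik = x$logLik[x$n_iter], n_iter = x$n_iter,
                 converged = x$converged)
}

#' Tidy a fitted choice decoder
#'
#' @param x A `choice_decoder`.
#' @param ... Unused.
#' @return Tibble of decoder terms (`latent_1` ... and `bias`) with their
#'   weights.
#' @method tidy choice_decoder
#' @export
tidy.choice_decoder <- function(x, ...) {
  tibble::tibble(term = c(paste0("latent_", seq_along(x$w)), "bias"),
                 estimate = c(x$w, x$b))
}

#' @rdname tidy.choice_decoder
#' @return `glance()` returns a one-row tibble of training metadata.
#' @method glance choice_decoder
#' @export
glance.choice_decoder <- function(x, ...) {
  tibble::tibble(n_latents = x$n_latents,
                 n_train_trials = length(x$train_ids),
                 n_train_points = x$n_train_points,
                 trial_class = x$trial_class,
                 norm_constant = x$norm_constant)
}
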