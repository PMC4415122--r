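#' Gaussian-process factor analysis of binned spike counts
#'
#' Fits the latent-variable model `y_t = C x_t + d + noise`, where `y_t` is
#' the (optionally square-root-transformed) spike-count vector in bin `t`,
#' the observation noise is independent Gaussian with diagonal covariance
#' `R`, and each latent `x_i(.)` is an a-priori independent Gaussian
#' process over time with a squared-exponential kernel
#' `K_i(t, u) = (1 - sigma_n^2) exp(-(t - u)^2 / (2 tau_i^2)) +
#' sigma_n^2 delta(t, u)`. Parameters `C`, `d`, `R` and the per-latent
#' timescales `tau_i` are estimated by expectation-maximization
#' (timescales by a guarded 1-D maximization of the expected complete-data
#' log-likelihood, so the marginal log-likelihood is non-decreasing on every
#' iteration). Variable-length trials are handled by per-length kernel
#' matrices on the shared bin grid; no padding is used.
#'
#' @param binned A `binned_counts` object from [bin_session()].
#' @param n_latents Latent dimensionality.
#' @param params A [pipeline_params()] object (bin width, square-root
#'   transform flag, convergence tolerance, iteration cap).
#' @param init `"fa"` (static factor-analysis initialization, the default)
#'   or `"random"`.
#' @param learn_tau Update the GP timescales during EM.
#' @param sigma_n GP innovation-noise standard deviation (kernel diagonal
#'   `sigma_n^2`).
#' @param verbose Print the log-likelihood every 10 iterations.
#' @return A `gpfa_model`: loading matrix `C`, offset `d`, noise variances
#'   `R`, timescales `tau` (ms), the log-likelihood trace, and fit metadata.
#' @export
fit_gpfa <- function(binned, n_latents = NULL, params = pipeline_params(),
                     init = c("fa", "random"), learn_tau = TRUE,
                     sigma_n = sqrt(1e-3), verbose = FALSE) {
  init <- match.arg(init)
  q <- if (is.null(n_latents)) params$n_latents else n_latents
  n_units <- nrow(binned$counts[[1]])
  if (n_units < q) {
    stop("fewer units (", n_units, ") than requested latents (", q, ")")
  }
  Ys <- lapply(binned$counts, function(m) {
    if (params$sqrt_transform) sqrt(m) else m * 1.0
  })
  dt <- binned$bin_width
  lens <- vapply(Ys, ncol, integer(1))
  ulens <- sort(unique(lens))
  Ypool <- do.call(cbind, Ys)
  Ttot <- ncol(Ypool)

  if (init == "fa") {
    fa <- fa_em(Ypool, q, n_iter = 75)
    C <- fa$C; d <- fa$d; R <- fa$R
    tau <- rep(100, q)
  } else {
    d <- rowMeans(Ypool)
    v <- apply(Ypool, 1, stats::var)
    C <- matrix(stats::rnorm(n_units * q, sd = sqrt(mean(v) / q)), n_units, q)
    R <- pmax(v, 1e-6)
    tau <- stats::runif(q, 50, 300)
  }

  sq_dist <- lapply(ulens, function(T) {
    tt <- (seq_len(T) - 1) * dt
    outer(tt, tt, "-")^2
  })
  names(sq_dist) <- as.character(ulens)
  sn2 <- sigma_n^2

  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(params$gpfa_max_iter)) {
    es <- gpfa_estep(Ys, lens, ulens, sq_dist, C, d, R, tau, sn2,
                     want_stats = TRUE)
    if (!is.finite(es$ll)) {
      stop("non-finite GPFA log-likelihood at iteration ", iter)
    }
    ll_trace <- c(ll_trace, es$ll)
    if (verbose && iter %% 10 == 1) {
      message(sprintf("GPFA iter %d: logLik %.4f", iter, es$ll))
    }
    if (iter > 1) {
      prev <- ll_trace[iter - 1]
      if (abs(es$ll - prev) < params$gpfa_tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
    # M-step: (C, d) row-wise regression, R residual variance
    Cd <- es$Syx %*% solve(es$Sxx)
    C <- Cd[, seq_len(q), drop = FALSE]
    d <- Cd[, q + 1]
    R <- pmax((es$Syy - rowSums(Cd * es$Syx)) / Ttot, 1e-6)
    if (learn_tau) {
      for (i in seq_len(q)) {
        Pi <- es$P[[i]]
        qfun <- function(log_tau) {
          t_i <- exp(log_tau)
          val <- 0
          for (k in seq_along(ulens)) {
            K <- (1 - sn2) * exp(-sq_dist[[k]] / (2 * t_i^2)) +
              sn2 * diag(ulens[k])
            ch <- chol(K)
            val <- val - es$len_count[k] * sum(log(diag(ch))) -
              0.5 * sum(chol2inv(ch) * Pi[[k]])
          }
          val
        }
        opt <- stats::optimize(qfun, interval = log(c(5, 1500)), maximum = TRUE)
        if (opt$objective > qfun(log(tau[i]))) tau[i] <- exp(opt$maximum)
      }
    }
  }

  structure(list(C = C, d = d, R = R, tau = tau, sigma_n = sigma_n,
                 n_latents = q, bin_width = dt,
                 sqrt_transform = params$sqrt_transform,
                 logLik = ll_trace, n_iter = length(ll_trace),
                 converged = converged),
            class = "gpfa_model")
}

#' @export
print.gpfa_model <- function(x, ...) {
  cat(sprintf("<gpfa_model> %d units -> %d latents, %g ms bins\n",
              nrow(x$C), x$n_latents, x$bin_width))
  cat(sprintf("  timescales (ms): %s\n",
              paste(round(sort(x$tau)), collapse = ", ")))
  cat(sprintf("  logLik %.2f after %d EM iterations (%s)\n",
              x$logLik[length(x$logLik)], x$n_iter,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

# E-step over all trials, grouped by trial length so the posterior operator
# is assembled once per unique length. Latent-major ordering within a trial:
# index (i - 1) * T + t for latent i, bin t.
gpfa_estep <- function(Ys, lens, ulens, sq_dist, C, d, R, tau, sn2,
                       want_stats = FALSE, want_posterior = FALSE) {
  q <- ncol(C)
  n_units <- nrow(C)
  G <- crossprod(C / sqrt(R)) # C' R^-1 C
  ll <- 0
  Syx <- matrix(0, n_units, q + 1)
  Sxx <- matrix(0, q + 1, q + 1)
  Syy <- numeric(n_units)
  P <- if (want_stats) {
    lapply(seq_len(q), function(i) {
      lapply(ulens, function(T) matrix(0, T, T))
    })
  }
  len_count <- integer(length(ulens))
  post <- if (want_posterior) vector("list", length(Ys))

  for (k in seq_along(ulens)) {
    T <- ulens[k]
    idx <- which(lens == T)
    len_count[k] <- length(idx)
    if (length(idx) == 0) next
    Kinv_blocks <- vector("list", q)
    logdetK <- 0
    Lambda <- matrix(0, q * T, q * T)
    for (i in seq_len(q)) {
      K <- (1 - sn2) * exp(-sq_dist[[k]] / (2 * tau[i]^2)) + sn2 * diag(T)
      ch <- chol(K)
      logdetK <- logdetK + 2 * sum(log(diag(ch)))
      Kinv_blocks[[i]] <- chol2inv(ch)
      rows <- (i - 1) * T + seq_len(T)
      Lambda[rows, rows] <- Kinv_blocks[[i]]
    }
    # add G scattered across same-time entries
    for (i in seq_len(q)) for (j in seq_len(q)) {
      ii <- (i - 1) * T + seq_len(T)
      jj <- (j - 1) * T + seq_len(T)
      Lambda[cbind(ii, jj)] <- Lambda[cbind(ii, jj)] + G[i, j]
    }
    chL <- chol(Lambda)
    logdetLambda <- 2 * sum(log(diag(chL)))
    Sigma <- chol2inv(chL)
    # sum over t of the q x q same-time posterior covariance block
    Sblock <- matrix(0, q, q)
    for (i in seq_len(q)) for (j in seq_len(q)) {
      Sblock[i, j] <- sum(Sigma[cbind((i - 1) * T + seq_len(T),
                                      (j - 1) * T + seq_len(T))])
    }
    const <- -0.5 * (n_units * T * log(2 * pi) + T * sum(log(R)) +
                       logdetK + logdetLambda)
    for (tr in idx) {
      Yc <- Ys[[tr]] - d
      H <- crossprod(C, Yc / R)          # q x T
      v <- as.vector(t(H))               # latent-major
      mu <- Sigma %*% v
      quad <- sum(Yc^2 / R) - sum(v * mu)
      ll <- ll + const - 0.5 * quad
      M <- matrix(mu, nrow = T, ncol = q) # column i = latent i over time
      if (want_stats) {
        Syx <- Syx + Ys[[tr]] %*% cbind(M, 1)
        Sxx[seq_len(q), seq_len(q)] <- Sxx[seq_len(q), seq_len(q)] +
          crossprod(M) + Sblock
        cs <- colSums(M)
        Sxx[q + 1, seq_len(q)] <- Sxx[q + 1, seq_len(q)] + cs
        Sxx[seq_len(q), q + 1] <- Sxx[seq_len(q), q + 1] + cs
        Sxx[q + 1, q + 1] <- Sxx[q + 1, q + 1] + T
        Syy <- Syy + rowSums(Ys[[tr]]^2)
        for (i in seq_len(q)) {
          rows <- (i - 1) * T + seq_len(T)
          P[[i]][[k]] <- P[[i]][[k]] + tcrossprod(M[, i])
        }
      }
      if (want_posterior) post[[tr]] <- t(M) # q x T
    }
    if (want_stats) {
      for (i in seq_len(q)) {
        rows <- (i - 1) * T + seq_len(T)
        P[[i]][[k]] <- P[[i]][[k]] + len_count[k] * Sigma[rows, rows]
      }
    }
  }
  list(ll = ll, Syx = Syx, Sxx = Sxx, Syy = Syy, P = P,
       len_count = len_count, post = post)
}

# Marginal log-likelihood of binned counts under a fixed model.
gpfa_loglik <- function(model, binned) {
  Ys <- lapply(binned$counts, function(m) {
    if (model$sqrt_transform) sqrt(m) else m * 1.0
  })
  lens <- vapply(Ys, ncol, integer(1))
  ulens <- sort(unique(lens))
  sq_dist <- lapply(ulens, function(T) {
    tt <- (seq_len(T) - 1) * model$bin_width
    outer(tt, tt, "-")^2
  })
  gpfa_estep(Ys, lens, ulens, sq_dist, model$C, model$d, model$R,
             model$tau, model$sigma_n^2)$ll
}

#' Infer posterior-mean latent trajectories
#'
#' Exact Gaussian posterior mean of the latents given a trial's
#' observations, for a fixed fitted model; linear in the centered
#' (transformed) observations.
#'
#' @param model A `gpfa_model`.
#' @param binned A `binned_counts` object on the model's bin grid.
#' @return A `latent_trajectories` object: per-trial `n_latents x bins`
#'   matrices plus the shared time grid.
#' @export
infer_latents <- function(model, binned) {
  stopifnot(inherits(model, "gpfa_model"))
  if (nrow(binned$counts[[1]]) != nrow(model$C)) {
    stop("unit count mismatch: model has ", nrow(model$C), ", counts have ",
         nrow(binned$counts[[1]]))
  }
  Ys <- lapply(binned$counts, function(m) {
    if (model$sqrt_transform) sqrt(m) else m * 1.0
  })
  lens <- vapply(Ys, ncol, integer(1))
  ulens <- sort(unique(lens))
  sq_dist <- lapply(ulens, function(T) {
    tt <- (seq_len(T) - 1) * model$bin_width
    outer(tt, tt, "-")^2
  })
  es <- gpfa_estep(Ys, lens, ulens, sq_dist, model$C, model$d, model$R,
                   model$tau, model$sigma_n^2, want_posterior = TRUE)
  structure(list(latents = es$post, centers = binned$centers,
                 trial_id = binned$trial_id, n_latents = model$n_latents,
                 bin_width = binned$bin_width),
            class = "latent_trajectories")
}

#' @export
print.latent_trajectories <- function(x, ...) {
  cat(sprintf("<latent_trajectories> %d trials, %d latents, %g ms bins\n",
              length(x$latents), x$n_latents, x$bin_width))
  invisible(x)
}

#' Orthonormalize the loading matrix
#'
#' Returns the model with `C` replaced by an orthonormal basis of its
#' column space (SVD), along with the linear map to apply to latents. Any
#' invertible linear change of the latent basis is absorbed by the linear
#' decoder, so this is a display convenience and is not applied before
#' decoding.
#'
#' @param model A `gpfa_model`.
#' @return The model with orthonormal `C` and a `latent_transform` field.
#' @export
orthonormalize_gpfa <- function(model) {
  sv <- svd(model$C)
  model$C <- sv$u
  model$latent_transform <- diag(sv$d, length(sv$d)) %*% t(sv$v)
  model
}

# Static factor analysis by EM (used to initialize GPFA).
fa_em <- function(Y, q, n_iter = 100) {
  n <- nrow(Y)
  d <- rowMeans(Y)
  Yc <- Y - d
  m <- ncol(Y)
  S <- tcrossprod(Yc) / m
  sv <- svd(S, nu = q, nv = 0)
  C <- sv$u %*% diag(sqrt(pmax(sv$d[seq_len(q)], 1e-8)), q)
  R <- pmax(diag(S) - rowSums(C^2), 1e-6)
  for (it in seq_len(n_iter)) {
    G <- diag(q) + crossprod(C / R, C)
    Ginv <- solve(G)
    B <- Ginv %*% t(C / R)          # q x n posterior operator
    Ex <- B %*% Yc                   # q x m
    Sxx <- m * Ginv + tcrossprod(Ex)
    Syx <- tcrossprod(Yc, Ex)        # n x q
    C <- Syx %*% solve(Sxx)
    R <- pmax(diag(S) - rowSums(C * Syx) / m, 1e-6)
  }
  list(C = C, d = d, R = R)
}
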