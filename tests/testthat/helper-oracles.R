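# Independent oracles: brute-force or closed-form reference computations
# kept deliberately separate from the package's own code paths.

# Brute-force interval counting for spike binning.
oracle_bin <- function(spikes, epoch, dt) {
  n_bins <- floor((epoch[2] - epoch[1]) / dt)
  vapply(seq_len(n_bins), function(k) {
    lo <- epoch[1] + (k - 1) * dt
    sum(spikes >= lo & spikes < lo + dt)
  }, numeric(1))
}

# Mean of an exponential(tau) truncated at cap.
oracle_trunc_exp_mean <- function(tau, cap) {
  tau - cap * exp(-cap / tau) / (1 - exp(-cap / tau))
}

# Dense GPFA posterior mean by explicit joint-Gaussian conditioning,
# assembled from first principles (observation stack is time-major, latents
# latent-major, matched through an explicitly built loading matrix).
oracle_gpfa_posterior <- function(model, counts) {
  Y <- if (model$sqrt_transform) sqrt(counts) else counts
  n <- nrow(Y); T <- ncol(Y); q <- model$n_latents
  sn2 <- model$sigma_n^2
  tt <- (seq_len(T) - 1) * model$bin_width
  Kbar <- matrix(0, q * T, q * T)
  for (i in seq_len(q)) {
    K <- (1 - sn2) * exp(-outer(tt, tt, "-")^2 / (2 * model$tau[i]^2)) +
      sn2 * diag(T)
    idx <- (i - 1) * T + seq_len(T)
    Kbar[idx, idx] <- K
  }
  A <- matrix(0, n * T, q * T)
  for (t in seq_len(T)) for (u in seq_len(n)) for (i in seq_len(q)) {
    A[(t - 1) * n + u, (i - 1) * T + t] <- model$C[u, i]
  }
  Rbig <- diag(rep(model$R, times = T))
  S <- A %*% Kbar %*% t(A) + Rbig
  ycent <- as.vector(Y - model$d) # column-major = time-major stacking
  post <- Kbar %*% t(A) %*% solve(S, ycent)
  matrix(post, nrow = T, ncol = q) |> t() # q x T
}

# Chi-square 2x2 statistic and p from the textbook formula.
oracle_chisq_2x2 <- function(k1, n1, k2, n2) {
  O <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Wilson score interval from the closed-form formula.
oracle_wilson <- function(k, n, z) {
  p <- k / n
  c((p + z^2 / (2 * n)) / (1 + z^2 / n) -
      z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n),
    (p + z^2 / (2 * n)) / (1 + z^2 / n) +
      z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n))
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# assignments of the pooled sample to the two groups.
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  U_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- U_of(seq_len(n1))
  splits <- utils::combn(length(pooled), n1)
  Us <- apply(splits, 2, U_of)
  min(1, 2 * min(mean(Us <= obs), mean(Us >= obs)))
}

# Two-proportion pooled Z statistic.
oracle_two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

# OLS slope/intercept by the normal equations.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Largest principal angle (degrees) between the column spaces of A and B.
oracle_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s)))) * 180 / pi
}

# Leave-one-unit-out prediction error of a fitted latent model: predict
# each unit's (transformed) counts from the posterior inferred without it.
oracle_louo_error <- function(model, binned) {
  n <- nrow(model$C)
  errs <- numeric(0)
  for (u in seq_len(n)) {
    sub_model <- model
    sub_model$C <- model$C[-u, , drop = FALSE]
    sub_model$d <- model$d[-u]
    sub_model$R <- model$R[-u]
    sub_binned <- binned
    sub_binned$counts <- lapply(binned$counts,
                                function(m) m[-u, , drop = FALSE])
    lat <- infer_latents(sub_model, sub_binned)
    for (i in seq_along(binned$counts)) {
      y <- if (model$sqrt_transform) sqrt(binned$counts[[i]][u, ]) else
        binned$counts[[i]][u, ]
      pred <- drop(model$C[u, , drop = FALSE] %*% lat$latents[[i]]) +
        model$d[u]
      errs <- c(errs, mean((y - pred)^2))
    }
  }
  mean(errs)
}
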