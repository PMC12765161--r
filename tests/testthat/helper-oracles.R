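# Independent oracles and small fixture builders used across the suite.
# These re-derive quantities from first principles and never call the code
# paths they are used to check.

# ZIP observation log-density, written independently of the package internals
zip_obs_ll_oracle <- function(y, lam, pi) {
  ifelse(y == 0,
         log(pi + (1 - pi) * exp(-lam)),
         log(1 - pi) + dpois(y, lam, log = TRUE))
}

# Marginal log-likelihood of the ZIP mixed model by fine trapezoid
# integration over the per-file random intercept
zip_marginal_ll_trapezoid <- function(beta, pi, sigma, d, half_width = 10,
                                      n_grid = 20001) {
  ll <- 0
  for (fl in unique(d$file_id)) {
    sub <- d[d$file_id == fl, ]
    eta <- beta[sub$bin] + log(sub$bin_width)
    u <- seq(-half_width * sigma, half_width * sigma, length.out = n_grid)
    integrand <- vapply(u, function(uu) {
      exp(sum(zip_obs_ll_oracle(sub$count, exp(eta + uu), pi)) +
            dnorm(uu, 0, sigma, log = TRUE))
    }, numeric(1))
    ll <- ll + log(sum((integrand[-1] + integrand[-n_grid]) / 2) * diff(u)[1])
  }
  ll
}

# Central-difference Hessian, independent implementation (different step)
fd_hessian_oracle <- function(fn, x, eps = 5e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  h <- pmax(abs(x), 1) * eps
  f0 <- fn(x)
  for (i in 1:n) {
    for (j in i:n) {
      ei <- ej <- numeric(n); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <- (fn(x + ei + ej) - fn(x + ei - ej) -
                                 fn(x - ei + ej) + fn(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Order-1 Granger F test from scratch via normal equations (no lm())
granger_F_oracle <- function(x, y) {
  n <- length(x)
  one_dir <- function(cause, effect) {
    yt <- effect[-1]; ylag <- effect[-n]; xlag <- cause[-n]
    Xr <- cbind(1, ylag)
    Xu <- cbind(1, ylag, xlag)
    br <- solve(t(Xr) %*% Xr, t(Xr) %*% yt)
    bu <- solve(t(Xu) %*% Xu, t(Xu) %*% yt)
    rss_r <- sum((yt - Xr %*% br)^2)
    rss_u <- sum((yt - Xu %*% bu)^2)
    df2 <- (n - 1) - 3
    Fs <- (rss_r - rss_u) / (rss_u / df2)
    c(F = Fs, p = pf(Fs, 1, df2, lower.tail = FALSE))
  }
  rbind(xy = one_dir(x, y), yx = one_dir(y, x))
}

# Quick canonical event table from parallel vectors
make_events <- function(file_id, call_id, kind, onset_s,
                        duration_s = 0.3, provenance = "fixture") {
  n <- length(onset_s)
  event_table(
    data.frame(file_id = rep_len(file_id, n), call_id = rep_len(call_id, n),
               kind = rep_len(kind, n), onset_s = onset_s,
               duration_s = rep_len(duration_s, n)),
    provenance = provenance
  )
}

# Random valid event table for round-trip property tests
random_event_table <- function(seed, n_files = 2, calls_per_file = 2) {
  set.seed(seed)
  rows <- list()
  for (fi in seq_len(n_files)) {
    for (ci in seq_len(calls_per_file)) {
      n <- sample(3:12, 1)
      onsets <- round(cumsum(runif(n, 0.5, 3)), 6)
      kind <- ifelse(runif(n) < 0.3, "pant", "pulse")
      kind[1:2] <- "pulse"  # keep >= 2 pulses so no flag warnings
      rows[[length(rows) + 1]] <- data.frame(
        file_id = sprintf("f%d", fi), call_id = sprintf("c%d", ci),
        kind = kind, onset_s = onsets,
        duration_s = round(runif(n, 0.1, 0.4), 6)
      )
    }
  }
  event_table(do.call(rbind, rows), provenance = "random fixture")
}

# Default study-condition beta used by the simulation tests
sim_beta <- function() {
  stats::setNames(log(c(30, 60, 15, 25, 12, 20)), bin_levels())
}
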