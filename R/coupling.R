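#' Build pulse/pant coupling series pairs per section
#'
#' For each alternating pulse/pant section, extracts the pulses-only and
#' pants-only series and pairs them index-wise, truncated to the shorter
#' series. The default mode pairs inter-onset interval durations (the t_k
#' sequences): onset times are monotone trends whose cross-correlation is
#' near 1 regardless of coupling, so intervals are the scientifically
#' meaningful default; `mode = "onset_times"` is provided for literal
#' replication of timing-based analyses.
#'
#' @param events An [event_table()].
#' @param mode `"interval_durations"` (default) or `"onset_times"`.
#' @param max_gap_s Section gap threshold, see [find_sections()].
#' @return List of pairs; each has `section_id`, `x` (pulses), `y` (pants),
#'   `mode`, `n` (paired length).
#' @export
coupling_pairs <- function(events,
                           mode = c("interval_durations", "onset_times"),
                           max_gap_s = 5) {
  mode <- match.arg(mode)
  pul <- build_series(events, "pulses_within_series", max_gap_s = max_gap_s)
  pan <- suppressWarnings(
    build_series(events, "pants_within_series", max_gap_s = max_gap_s)
  )
  secs <- intersect(unique(pul$series_id), unique(pan$series_id))
  pairs <- lapply(secs, function(s) {
    x <- pul$onset_s[pul$series_id == s]
    y <- pan$onset_s[pan$series_id == s]
    if (mode == "interval_durations") {
      if (length(x) < 2 || length(y) < 2) return(NULL)
      x <- diff(x); y <- diff(y)
    }
    n <- min(length(x), length(y))
    if (n < 2) return(NULL)
    list(section_id = s, x = x[seq_len(n)], y = y[seq_len(n)],
         mode = mode, n = n)
  })
  Filter(Negate(is.null), pairs)
}

#' Lagged cross-correlation of a coupling pair
#'
#' Sample cross-correlation `r(h) = sum((x_t - xbar)(y_{t+h} - ybar)) /
#' (n s_x s_y)` with full-series means and sample SDs: the biased estimator,
#' equal to `stats::ccf` scaled by the exact factor `(n - 1)/n` (so
#' `r(0) = (n - 1)/n * Pearson`, and identical series give `(n - 1)/n`, not
#' 1). Lag-sign convention: positive lag means x leads y (x at time t aligns
#' with y at time t + h).
#'
#' @param x,y Numeric series of equal length.
#' @param max_lag Maximum lag; the effective maximum is `min(max_lag, n - 1)`.
#' @return List: `lag`, `ccf` (vectors over -L..L), `best_lag`, `best_ccf`
#'   (lag maximizing the cross-correlation), `n`.
#' @export
cross_correlate <- function(x, y, max_lag = 20) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2) stop_callrhythm("need at least 2 paired observations", "data_error")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_callrhythm("constant series: cross-correlation undefined",
                    "degenerate_series_error")
  }
  L <- min(max_lag, n - 1)
  # stats::ccf(y, x) at lag h estimates cor(y[t+h], x[t]): positive h = x leads;
  # rescale from ccf's n-denominator SDs to sample SDs
  cc <- ccf(y, x, lag.max = L, plot = FALSE, demean = TRUE)
  lag <- as.numeric(cc$lag)
  val <- as.numeric(cc$acf) * (n - 1) / n
  best <- which.max(val)
  list(lag = lag, ccf = val, best_lag = lag[best], best_ccf = val[best], n = n)
}

#' Order-1 Granger causality test, both directions
#'
#' Direction x -> y: restricted OLS `y_t ~ 1 + y_{t-1}`, unrestricted
#' `y_t ~ 1 + y_{t-1} + x_{t-1}`, F test on the single added regressor with
#' `n - 1` usable rows and 3 unrestricted coefficients, i.e.
#' `F(1, n - 4)`; symmetric for y -> x. Series shorter than 5 paired points
#' leave no residual degrees of freedom and raise an error.
#'
#' @param x,y Numeric series of equal length `n >= 5`.
#' @return Tibble: `direction` (`"x->y"`, `"y->x"`), `F`, `df1`, `df2`,
#'   `p_value`. Collinear regressors yield `NA` p with a warning.
#' @export
granger_order1 <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) {
    stop_callrhythm(
      sprintf("order-1 Granger test needs >= 5 paired observations (got %d): no residual df",
              n),
      "data_error"
    )
  }
  one_dir <- function(cause, effect) {
    yt <- effect[-1]
    ylag <- effect[-n]
    xlag <- cause[-n]
    restricted <- lm(yt ~ ylag)
    unres <- tryCatch(lm(yt ~ ylag + xlag), error = function(e) NULL)
    if (is.null(unres) || any(is.na(coef(unres)))) {
      warning("collinear regressors in Granger regression: p reported as NA",
              call. = FALSE)
      return(c(F = NA_real_, p = NA_real_))
    }
    rss_r <- sum(stats::residuals(restricted)^2)
    rss_u <- sum(stats::residuals(unres)^2)
    df2 <- (n - 1) - 3
    Fstat <- ((rss_r - rss_u) / 1) / (rss_u / df2)
    c(F = Fstat, p = pf(Fstat, 1, df2, lower.tail = FALSE))
  }
  xy <- one_dir(x, y)
  yx <- one_dir(y, x)
  tibble::tibble(direction = c("x->y", "y->x"),
                 F = c(xy[["F"]], yx[["F"]]),
                 df1 = 1L, df2 = (n - 1L) - 3L,
                 p_value = c(xy[["p"]], yx[["p"]]))
}

#' Per-section synchrony and causality analysis
#'
#' Runs [cross_correlate()] on every coupling pair and [granger_order1()] on
#' pairs with enough observations.
#'
#' @param pairs List of coupling pairs from [coupling_pairs()] or
#'   [generate_coupled_sections()].
#' @param max_lag Cross-correlation maximum lag.
#' @return Tibble: `section_id`, `n`, `best_lag`, `best_ccf`, `granger_xy_p`,
#'   `granger_yx_p` (`NA` where the series is too short or degenerate).
#' @export
coupling_analysis <- function(pairs, max_lag = 20) {
  rows <- lapply(pairs, function(p) {
    cc <- tryCatch(cross_correlate(p$x, p$y, max_lag = max_lag),
                   callrhythm_error = function(e) NULL)
    gr <- tryCatch(granger_order1(p$x, p$y),
                   callrhythm_error = function(e) NULL)
    tibble::tibble(
      section_id = p$section_id %||% NA_character_,
      n = p$n %||% length(p$x),
      best_lag = if (is.null(cc)) NA_real_ else cc$best_lag,
      best_ccf = if (is.null(cc)) NA_real_ else cc$best_ccf,
      granger_xy_p = if (is.null(gr)) NA_real_ else gr$p_value[1],
      granger_yx_p = if (is.null(gr)) NA_real_ else gr$p_value[2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Tally significant Granger directions
#'
#' Counts sections whose x->y, respectively y->x, Granger p-value falls below
#' `alpha`; a section may count in both directions (bi-directional
#' causality). Sections with fewer than `min_n` observations are excluded
#' from the denominator.
#'
#' @param results Tibble from [coupling_analysis()].
#' @param alpha Significance threshold (default 0.001).
#' @param min_n Minimum paired observations for inclusion (default 3).
#' @return Tibble: `n_xy`, `n_yx`, `n_none`, `n_total`.
#' @export
tally_causality <- function(results, alpha = 0.001, min_n = 3) {
  stopifnot(alpha > 0, alpha < 1)
  if (!nrow(results)) {
    return(tibble::tibble(n_xy = 0L, n_yx = 0L, n_none = 0L, n_total = 0L))
  }
  keep <- results[results$n >= min_n, ]
  sig_xy <- !is.na(keep$granger_xy_p) & keep$granger_xy_p < alpha
  sig_yx <- !is.na(keep$granger_yx_p) & keep$granger_yx_p < alpha
  tibble::tibble(
    n_xy = sum(sig_xy),
    n_yx = sum(sig_yx),
    n_none = sum(!sig_xy & !sig_yx),
    n_total = nrow(keep)
  )
}
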