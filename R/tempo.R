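#' Tempo comparison across interval types
#'
#' Linear mixed model on log inter-onset intervals contrasting the three
#' interval types of the pulse/pant sections: `series` (interval from any
#' element to the next, pulses and pants mixed), `pants` (pant-to-pant) and
#' `pulses` (pulse-to-pulse). Fixed effect: interval type (cell-means
#' coding); random intercept: the section the intervals came from; Gaussian
#' errors; maximum likelihood (not REML, so the full-vs-null likelihood-ratio
#' test is valid). With midpoint pants the series tempo doubles, so the
#' expected series-minus-pulses contrast is `log(1/2)`.
#'
#' @param intervals Data frame with columns `t_k` (> 0, seconds), `tk_type`
#'   (`series`/`pants`/`pulses`) and `section_id`.
#' @param df_method `"residual"` (t tests on n - 3 df) or `"satterthwaite"`
#'   (requires the lmerTest package).
#' @return Object of class `tempo_fit`: named coefficients (mean log-interval
#'   per type), their covariance, residual df, the ML fits, the full-vs-null
#'   LRT and the three pairwise contrasts ([posthoc_contrasts()] layout).
#' @export
fit_tempo_model <- function(intervals, df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  req <- c("t_k", "tk_type", "section_id")
  missing_cols <- setdiff(req, names(intervals))
  if (length(missing_cols)) {
    stop_callrhythm(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  if (any(intervals$t_k <= 0 | !is.finite(intervals$t_k))) {
    stop_callrhythm("t_k must be positive and finite before log transform",
                    "validation_error")
  }
  types <- c("series", "pants", "pulses")
  if (!all(types %in% intervals$tk_type)) {
    stop_callrhythm(
      sprintf("all three tk_type levels required; missing: %s",
              paste(setdiff(types, unique(intervals$tk_type)), collapse = ", ")),
      "validation_error"
    )
  }
  d <- data.frame(
    log_tk = log(intervals$t_k),
    tk_type = factor(intervals$tk_type, levels = types),
    section_id = as.character(intervals$section_id),
    stringsAsFactors = FALSE
  )
  n <- nrow(d)
  use_re <- length(unique(d$section_id)) >= 2

  if (use_re) {
    full <- lme4::lmer(log_tk ~ 0 + tk_type + (1 | section_id), data = d,
                       REML = FALSE)
    null <- lme4::lmer(log_tk ~ 1 + (1 | section_id), data = d, REML = FALSE)
    beta <- lme4::fixef(full)
    V <- as.matrix(vcov(full))
    sigma_sec <- sqrt(lme4::VarCorr(full)$section_id[1])
    ll_full <- as.numeric(logLik(full)); np_full <- attr(logLik(full), "df")
    ll_null <- as.numeric(logLik(null)); np_null <- attr(logLik(null), "df")
  } else {
    warning("fewer than 2 sections: random intercept dropped", call. = FALSE)
    full <- lm(log_tk ~ 0 + tk_type, data = d)
    null <- lm(log_tk ~ 1, data = d)
    beta <- coef(full)
    V <- vcov(full)
    sigma_sec <- 0
    ll_full <- as.numeric(logLik(full)); np_full <- attr(logLik(full), "df")
    ll_null <- as.numeric(logLik(null)); np_null <- attr(logLik(null), "df")
  }
  names(beta) <- sub("^tk_type", "", names(beta))
  dimnames(V) <- list(names(beta), names(beta))

  df_resid <- n - length(beta)
  fitres <- list(coefficients = beta, vcov = V, df = df_resid,
                 loglik = ll_full, n_par = np_full, n_obs = n,
                 sigma_section = sigma_sec, converged = TRUE)
  nullres <- list(loglik = ll_null, n_par = np_null)
  lrt <- lrt_full_vs_null(fitres, nullres)

  pairs <- list(c("series", "pants"), c("series", "pulses"),
                c("pants", "pulses"))
  contrasts <- if (df_method == "satterthwaite" && use_re) {
    satterthwaite_contrasts(d, pairs)
  } else {
    posthoc_contrasts(fitres, pairs)
  }

  structure(c(fitres, list(lrt = lrt, contrasts = contrasts, model = full,
                           null_model = null, df_method = df_method)),
            class = "tempo_fit")
}

satterthwaite_contrasts <- function(d, pairs) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    stop_callrhythm("df_method = 'satterthwaite' requires the lmerTest package",
                    "dependency_error")
  }
  mod <- lmerTest::lmer(log_tk ~ 0 + tk_type + (1 | section_id), data = d,
                        REML = FALSE)
  lev <- sub("^tk_type", "", names(lme4::fixef(mod)))
  rows <- lapply(pairs, function(pr) {
    cvec <- setNames(numeric(length(lev)), lev)
    cvec[pr[1]] <- 1; cvec[pr[2]] <- -1
    ct <- lmerTest::contest1D(mod, unname(cvec))
    tibble::tibble(contrast = paste(pr[1], "-", pr[2]),
                   estimate = ct$Estimate, se = ct$`Std. Error`,
                   statistic = ct$`t value`, df = ct$df,
                   p_value = ct$`Pr(>|t|)`)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.tempo_fit <- function(x, ...) {
  cat("Tempo linear mixed model on log(t_k) (ML)\n")
  cat(sprintf("  n = %d intervals | section SD = %.4f | logLik %.4f\n",
              x$n_obs, x$sigma_section, x$loglik))
  cat(sprintf("  full vs null: chi2 = %.4f, df = %d, p = %.3g\n",
              x$lrt$chi2, x$lrt$df, x$lrt$p_value))
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Assemble tempo-model input from section interval tables
#'
#' Binds the level (ii)-(iv) interval tables into the tempo model's input,
#' labelling them `series`, `pulses` and `pants` respectively.
#'
#' @param events An [event_table()].
#' @param max_gap_s Section gap threshold.
#' @return Tibble with `t_k`, `tk_type`, `section_id` (plus keys).
#' @export
tempo_intervals <- function(events, max_gap_s = 5) {
  lv <- c(pulse_pant_series = "series", pulses_within_series = "pulses",
          pants_within_series = "pants")
  pieces <- lapply(names(lv), function(l) {
    iv <- rhythm_intervals(events, level = l, max_gap_s = max_gap_s)
    if (!nrow(iv)) return(NULL)
    iv$tk_type <- lv[[l]]
    iv
  })
  dplyr::bind_rows(pieces)
}
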