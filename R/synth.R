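#' Configuration for the synthetic long-call generator
#'
#' Defaults emulate the field conditions of the long-call corpus the pipeline
#' targets: 47 calls (one per recording file), pulse trains near 0.5 Hz
#' (period 2 s), 10-45 pulses per call, lognormal inter-onset jitter with
#' coefficient of variation 0.2, pants inserted near pulse-cycle midpoints
#' with probability 0.5, and a pant-position profile concentrating pants in
#' the early and late thirds of the call ("edges", a Beta-mixture weight).
#'
#' @param n_calls Number of calls (one call per file).
#' @param pulses_per_call Integer count, or length-2 range sampled uniformly.
#' @param pulse_period_s Base pulse period in seconds.
#' @param jitter_cv Coefficient of variation of lognormal interval jitter
#'   (0 = deterministic).
#' @param pant_insertion_prob Mean probability that a pulse cycle receives a
#'   pant.
#' @param pant_phase Pant position within its cycle, as a fraction of the
#'   interval (0.5 = midpoint, halving the cycle and doubling the tempo).
#' @param pant_phase_sd SD of the per-pant phase (truncated to
#'   `[0.15, 0.85]`).
#' @param pant_position_profile `"uniform"` (constant insertion probability)
#'   or `"edges"` (Beta(2,8)/Beta(8,2)-mixture weighting over normalized call
#'   position, scaled to the mean insertion probability).
#' @param tempo_drift Multiplicative period change per cycle (1 = steady).
#' @param pulse_duration_s,pant_duration_s Event durations, seconds (capped
#'   below the interval so onsets never collide).
#' @param seed RNG seed; the generator is deterministic given config + seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_calls = 47,
                         pulses_per_call = c(10, 45),
                         pulse_period_s = 2.0,
                         jitter_cv = 0.2,
                         pant_insertion_prob = 0.5,
                         pant_phase = 0.5,
                         pant_phase_sd = 0.05,
                         pant_position_profile = c("edges", "uniform"),
                         tempo_drift = 1.0,
                         pulse_duration_s = 0.4,
                         pant_duration_s = 0.2,
                         seed = 1) {
  pant_position_profile <- match.arg(pant_position_profile)
  cfg <- list(n_calls = n_calls, pulses_per_call = pulses_per_call,
              pulse_period_s = pulse_period_s, jitter_cv = jitter_cv,
              pant_insertion_prob = pant_insertion_prob,
              pant_phase = pant_phase, pant_phase_sd = pant_phase_sd,
              pant_position_profile = pant_position_profile,
              tempo_drift = tempo_drift,
              pulse_duration_s = pulse_duration_s,
              pant_duration_s = pant_duration_s, seed = seed)
  if (n_calls < 1) stop_callrhythm("n_calls must be >= 1", "config_error")
  if (any(pulses_per_call < 2)) {
    stop_callrhythm("pulses_per_call must be >= 2", "config_error")
  }
  if (pulse_period_s <= 0 || tempo_drift <= 0) {
    stop_callrhythm("periods and drift must be positive", "config_error")
  }
  if (jitter_cv < 0) stop_callrhythm("jitter_cv must be >= 0", "config_error")
  if (pant_insertion_prob < 0 || pant_insertion_prob > 1 ||
      pant_phase <= 0 || pant_phase >= 1) {
    stop_callrhythm("probabilities/phases must lie in (0, 1)", "config_error")
  }
  # a pant placed at phase*interval must start after the pulse ends
  min_interval <- pulse_period_s * min(1, tempo_drift)^max(pulses_per_call)
  if (jitter_cv == 0 && pant_phase * min_interval <= pulse_duration_s) {
    stop_callrhythm(
      "config implies event collisions: pant_phase * interval <= pulse duration",
      "config_error"
    )
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic annotated long-call corpus with ground truth
#'
#' Pulse onsets follow a renewal process with lognormal intervals (mean the
#' current period, coefficient of variation `jitter_cv`); the period is
#' multiplied by `tempo_drift` each cycle. Each pulse cycle independently
#' receives a pant at `onset + phase * interval` with a probability governed
#' by `pant_insertion_prob` and the position profile. Output is byte-stable:
#' identical config and seed give an identical event table.
#'
#' @param config A [synth_config()].
#' @return List with `events` (an [event_table()]) and `truth`: per-event
#'   tibble (`kind`, `cycle`, `inserted_pant`), per-call period sequences,
#'   and the true alternating-section boundaries (`section_id` per event, as
#'   [find_sections()] should recover them).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cv <- config$jitter_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog_adj <- -0.5 * log(1 + cv^2)  # lognormal mean 1 multiplier

  with_seed(config$seed, {
    calls <- lapply(seq_len(config$n_calls), function(ci) {
      n_pulse <- if (length(config$pulses_per_call) == 2) {
        sample(seq(config$pulses_per_call[1], config$pulses_per_call[2]), 1)
      } else config$pulses_per_call[1]
      n_iv <- n_pulse - 1
      periods <- config$pulse_period_s * config$tempo_drift^(seq_len(n_iv) - 1)
      mult <- if (cv > 0) rlnorm(n_iv, meanlog_adj, sdlog) else rep(1, n_iv)
      intervals <- periods * mult
      onsets <- cumsum(c(0, intervals))

      pos <- (seq_len(n_iv) - 0.5) / n_iv
      prob <- if (config$pant_position_profile == "uniform") {
        rep(config$pant_insertion_prob, n_iv)
      } else {
        w <- 0.5 * dbeta(pos, 2, 8) + 0.5 * dbeta(pos, 8, 2)
        pmin(1, w / mean(w) * config$pant_insertion_prob)
      }
      panted <- runif(n_iv) < prob

      phase <- config$pant_phase +
        if (config$pant_phase_sd > 0) rnorm(n_iv, 0, config$pant_phase_sd)
        else 0
      phase <- pmin(pmax(phase, 0.15), 0.85)
      pant_onset <- onsets[seq_len(n_iv)] + phase * intervals

      pulse_dur <- pmin(config$pulse_duration_s, 0.45 * intervals[c(seq_len(n_iv), n_iv)])
      if (any(panted & phase * intervals <= pulse_dur[seq_len(n_iv)])) {
        stop_callrhythm("generated pant collides with its pulse", "config_error")
      }

      fid <- sprintf("file%03d", ci)
      cid <- sprintf("call%03d", ci)
      ev <- tibble::tibble(
        file_id = fid, call_id = cid,
        kind = c(rep("pulse", n_pulse), rep("pant", sum(panted))),
        onset_s = c(onsets, pant_onset[panted]),
        duration_s = c(pulse_dur, rep(config$pant_duration_s, sum(panted))),
        cycle = c(seq_len(n_pulse), which(panted)),
        inserted_pant = c(rep(FALSE, n_pulse), rep(TRUE, sum(panted)))
      )
      ev <- ev[order(ev$onset_s), ]

      # ground-truth sections: maximal runs of consecutive panted cycles;
      # the section spans pulse i .. pulse j+1 of a run of panted cycles i..j
      sec <- rep(NA_character_, nrow(ev))
      if (any(panted)) {
        runs <- rle(panted)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        sn <- 0L
        for (ri in seq_along(runs$values)) {
          if (!runs$values[ri]) next
          sn <- sn + 1L
          i <- starts[ri]; j <- ends[ri]
          in_sec <- (ev$kind == "pulse" & ev$cycle >= i & ev$cycle <= j + 1) |
            (ev$kind == "pant" & ev$cycle >= i & ev$cycle <= j)
          sec[in_sec] <- sprintf("%s::%s::s%d", fid, cid, sn)
        }
      }
      ev$true_section <- sec
      ev
    })
    all_ev <- dplyr::bind_rows(calls)

    events <- event_table(
      all_ev[, c("file_id", "call_id", "kind", "onset_s", "duration_s")],
      provenance = sprintf("synthetic corpus (seed %d)", config$seed)
    )
    truth <- list(
      events = all_ev[order(all_ev$file_id, all_ev$call_id, all_ev$onset_s),
                      c("file_id", "call_id", "kind", "onset_s", "cycle",
                        "inserted_pant", "true_section")],
      config = config
    )
    list(events = events, truth = truth)
  })
}

#' Generate coupled pulse/pant interval-series pairs
#'
#' Test-bench generator for the coupling analyses. `shared_tempo`: both
#' series equal a common AR(1) tempo process plus independent noise (zero
#' noise gives identical series, best lag 0). `x_leads`:
#' `y_t = a * x_{t-1} + noise`; `y_leads` symmetric; `none`: independent
#' white noise around the base tempo.
#'
#' @param n Number of sections.
#' @param coupling `"none"`, `"x_leads"`, `"y_leads"` or `"shared_tempo"`.
#' @param n_points Paired series length per section.
#' @param a Lead coefficient for the `*_leads` mechanisms.
#' @param noise_sd Innovation/noise SD (seconds).
#' @param base_s Base interval level, seconds.
#' @param seed RNG seed.
#' @return List of pairs shaped like [coupling_pairs()] output.
#' @export
generate_coupled_sections <- function(n,
                                      coupling = c("none", "x_leads",
                                                   "y_leads", "shared_tempo"),
                                      n_points = 30, a = 0.9, noise_sd = 0.1,
                                      base_s = 1.0, seed = 1) {
  coupling <- match.arg(coupling)
  stopifnot(n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- n_points
      if (coupling == "shared_tempo") {
        z <- as.numeric(stats::filter(rnorm(m, 0, 0.2), 0.8,
                                      method = "recursive"))
        x <- base_s + z + rnorm(m, 0, noise_sd)
        y <- base_s + z + rnorm(m, 0, noise_sd)
      } else if (coupling == "none") {
        x <- base_s + rnorm(m, 0, 0.2)
        y <- base_s + rnorm(m, 0, 0.2)
      } else {
        lead <- rnorm(m, 0, 0.2)
        follow <- c(0, a * lead[-m]) + rnorm(m, 0, noise_sd)
        if (coupling == "x_leads") {
          x <- base_s + lead; y <- base_s + follow
        } else {
          y <- base_s + lead; x <- base_s + follow
        }
      }
      list(section_id = sprintf("sec%03d", i), x = x, y = y,
           mode = "interval_durations", n = m)
    })
  })
}
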