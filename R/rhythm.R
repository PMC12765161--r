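#' The four analysis levels of long-call temporal organization
#'
#' Level (i) `all_pulses` uses every pulse onset along a call (pants ignored);
#' (ii) `pulse_pant_series` uses all onsets inside contiguous alternating
#' pulse/pant sections; (iii) `pulses_within_series` and (iv)
#' `pants_within_series` use only the pulses, respectively pants, of those
#' sections.
#' @return Character vector of the four level names.
#' @export
analysis_levels <- function() {
  c("all_pulses", "pulse_pant_series", "pulses_within_series",
    "pants_within_series")
}

#' Identify alternating pulse/pant sections within calls
#'
#' A section is a maximal run of at least three events that strictly
#' alternate pulse-pant-pulse-... (either phase first) with no inter-onset
#' gap exceeding `max_gap_s`. Sections are the unit of analysis for levels
#' (ii)-(iv) and for pulse-pant coupling.
#'
#' @param events An [event_table()].
#' @param max_gap_s Maximum allowed inter-onset gap inside a section, seconds.
#' @return The event table with `section_id` filled for events belonging to a
#'   section (`"<file>::<call>::s<k>"`) and `NA` elsewhere.
#' @export
find_sections <- function(events, max_gap_s = 5) {
  stopifnot(inherits(events, "event_table"))
  ev <- tibble::as_tibble(events)
  ev$section_id <- NA_character_
  if (!nrow(ev)) return(restore_event_class(ev, events))

  key <- paste(ev$file_id, ev$call_id, sep = "::")
  for (k in unique(key)) {
    idx <- which(key == k)
    kind <- ev$kind[idx]
    onset <- ev$onset_s[idx]
    n <- length(idx)
    # break between consecutive events when kinds repeat or the gap is long
    brk <- c(TRUE, kind[-1] == kind[-n] | diff(onset) > max_gap_s)
    run <- cumsum(brk)
    sec_n <- 0L
    for (r in unique(run)) {
      members <- idx[run == r]
      if (length(members) >= 3) {
        sec_n <- sec_n + 1L
        ev$section_id[members] <- sprintf("%s::s%d", k, sec_n)
      }
    }
  }
  restore_event_class(ev, events)
}

restore_event_class <- function(ev, template) {
  structure(ev, class = class(template),
            provenance = attr(template, "provenance"),
            flagged_calls = attr(template, "flagged_calls"))
}

#' Build onset series for one analysis level
#'
#' @param events An [event_table()].
#' @param level One of [analysis_levels()].
#' @param max_gap_s Section gap threshold, see [find_sections()].
#' @return Tibble of onsets with columns `file_id`, `call_id`, `section_id`,
#'   `series_id`, `level`, `kind`, `onset_s`; one `series_id` per call (level
#'   i) or per section (levels ii-iv), ordered by onset within series.
#' @export
build_series <- function(events, level = analysis_levels(), max_gap_s = 5) {
  level <- match.arg(level)
  stopifnot(inherits(events, "event_table"))
  ev <- tibble::as_tibble(events)

  if (level == "all_pulses") {
    out <- ev[ev$kind == "pulse", ]
    out$series_id <- paste(out$file_id, out$call_id, sep = "::")
    out$level <- level
    return(out[, c("file_id", "call_id", "section_id", "series_id",
                   "level", "kind", "onset_s")])
  }

  if (!any(ev$kind == "pant")) {
    warning(sprintf("no pant events: level '%s' series are empty", level),
            call. = FALSE)
    return(tibble::tibble(file_id = character(), call_id = character(),
                          section_id = character(), series_id = character(),
                          level = character(), kind = character(),
                          onset_s = numeric()))
  }

  sec <- tibble::as_tibble(find_sections(events, max_gap_s = max_gap_s))
  sec <- sec[!is.na(sec$section_id), ]
  if (level == "pulses_within_series") sec <- sec[sec$kind == "pulse", ]
  if (level == "pants_within_series") sec <- sec[sec$kind == "pant", ]
  sec$series_id <- sec$section_id
  sec$level <- level
  sec[, c("file_id", "call_id", "section_id", "series_id", "level",
          "kind", "onset_s")]
}

#' Inter-onset intervals of one onset sequence
#'
#' `t_k` is the time from the start of one element to the start of the next.
#'
#' @param onsets Numeric vector of onset times in seconds, strictly
#'   increasing.
#' @return Numeric vector of length `length(onsets) - 1`; `numeric(0)` (with
#'   a warning) when fewer than two onsets are supplied.
#' @export
#' @examples
#' compute_tk(c(0, 2, 4))  # 2 2
compute_tk <- function(onsets) {
  if (length(onsets) < 2) {
    warning("fewer than 2 onsets: empty interval series", call. = FALSE)
    return(numeric(0))
  }
  if (any(diff(onsets) <= 0)) {
    stop_callrhythm("onsets must be strictly increasing", "validation_error")
  }
  diff(onsets)
}

#' Interval ratios of one interval sequence
#'
#' `r_k = t_k / (t_k + t_{k+1})`: 0.5 is isochrony (1:1), 1/3 the 1:2 and
#' 2/3 the 2:1 rhythmic ratio. Ratios are never chained across call or
#' section boundaries; compute them per series.
#'
#' @param t_k Numeric vector of positive intervals.
#' @return Numeric vector of length `length(t_k) - 1`; `numeric(0)` (with a
#'   warning) when fewer than two intervals are supplied.
#' @export
#' @examples
#' compute_rk(c(2, 2))  # 0.5
#' compute_rk(c(1, 2))  # 1/3
compute_rk <- function(t_k) {
  if (length(t_k) < 2) {
    warning("fewer than 2 intervals: empty ratio series", call. = FALSE)
    return(numeric(0))
  }
  if (any(t_k <= 0)) {
    stop_callrhythm("intervals must be positive", "validation_error")
  }
  n <- length(t_k)
  t_k[-n] / (t_k[-n] + t_k[-1])
}

#' Tidy interval table for one analysis level
#'
#' @inheritParams build_series
#' @return Tibble of class `interval_table`: one row per t_k with series keys,
#'   the interval index `k` and `onset_s` (start of the interval).
#' @export
rhythm_intervals <- function(events, level = analysis_levels(), max_gap_s = 5) {
  level <- match.arg(level)
  ser <- build_series(events, level = level, max_gap_s = max_gap_s)
  pieces <- lapply(split(ser, ser$series_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    tk <- diff(s$onset_s)
    tibble::tibble(
      file_id = s$file_id[1], call_id = s$call_id[1],
      section_id = s$section_id[1], series_id = s$series_id[1],
      level = level, k = seq_along(tk),
      onset_s = s$onset_s[-nrow(s)], t_k = tk
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) {
    out <- tibble::tibble(file_id = character(), call_id = character(),
                          section_id = character(), series_id = character(),
                          level = character(), k = integer(),
                          onset_s = numeric(), t_k = numeric())
  }
  structure(dplyr::arrange(out, .data$series_id, .data$k),
            class = c("interval_table", class(tibble::tibble())))
}

#' Tidy ratio table with classification and within-call position
#'
#' Computes `r_k` per series, classifies each ratio against the bin scheme
#' and attaches `rel_pos`, the position of the ratio's first interval within
#' its call as a fraction of the call's span (first onset to last event end).
#'
#' @inheritParams build_series
#' @param scheme Bin scheme, see [bin_scheme()].
#' @return Tibble of class `ratio_table`: series keys, `k`, `t_k` (first
#'   interval), `r_k`, `bin`, `category`, `zone`, `rel_pos`.
#' @export
rhythm_ratios <- function(events, level = analysis_levels(),
                          scheme = bin_scheme(), max_gap_s = 5) {
  level <- match.arg(level)
  iv <- rhythm_intervals(events, level = level, max_gap_s = max_gap_s)
  spans <- call_spans(events)
  pieces <- lapply(split(iv, iv$series_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    rk <- compute_rk(s$t_k)
    tibble::tibble(
      file_id = s$file_id[1], call_id = s$call_id[1],
      section_id = s$section_id[1], series_id = s$series_id[1],
      level = level, k = seq_along(rk),
      onset_s = s$onset_s[seq_along(rk)],
      t_k = s$t_k[seq_along(rk)], r_k = rk
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) {
    out <- tibble::tibble(file_id = character(), call_id = character(),
                          section_id = character(), series_id = character(),
                          level = character(), k = integer(), onset_s = numeric(),
                          t_k = numeric(), r_k = numeric())
  }
  cls <- classify_ratio(out$r_k, scheme)
  out$bin <- cls$bin
  out$category <- cls$category
  out$zone <- cls$zone
  out <- dplyr::left_join(out, spans, by = c("file_id", "call_id"))
  out$rel_pos <- ifelse(out$call_end > out$call_start,
                        (out$onset_s - out$call_start) /
                          (out$call_end - out$call_start),
                        NA_real_)
  out$call_start <- NULL
  out$call_end <- NULL
  structure(dplyr::arrange(out, .data$series_id, .data$k),
            class = c("ratio_table", class(tibble::tibble())))
}

call_spans <- function(events) {
  ev <- tibble::as_tibble(events)
  dplyr::summarise(dplyr::group_by(ev, .data$file_id, .data$call_id),
                   call_start = min(.data$onset_s),
                   call_end = max(.data$onset_s + .data$duration_s),
                   .groups = "drop")
}

#' Per-file bin counts of classified ratios
#'
#' Tallies the classified ratios of each file into the six on/off-integer
#' bins. Zero counts are retained (the downstream count model is
#' zero-inflated precisely because structural zeros occur). Unclassified
#' ratios (outside the covered range) contribute to `n_ratios_in_file` but to
#' no bin.
#'
#' @param ratios A `ratio_table` (possibly several levels bound together).
#' @param scheme Bin scheme, for the widths.
#' @param files Optional character vector of file ids that must appear even
#'   with zero ratios.
#' @return Tibble: `file_id`, `level`, `bin`, `count`, `bin_width`,
#'   `n_ratios_in_file`; exactly 6 rows per (file, level).
#' @export
count_bins <- function(ratios, scheme = bin_scheme(), files = NULL) {
  w <- bin_widths(scheme)
  lv <- unique(as.character(ratios$level))
  if (!length(lv)) lv <- "all_pulses"
  base <- tidyr::expand_grid(
    file_id = unique(c(as.character(ratios$file_id), files)),
    level = lv,
    bin = bin_levels()
  )
  if (!nrow(base)) {
    return(tibble::tibble(file_id = character(), level = character(),
                          bin = character(), count = integer(),
                          bin_width = numeric(), n_ratios_in_file = integer()))
  }
  tallied <- dplyr::summarise(
    dplyr::group_by(ratios[!is.na(ratios$bin), ],
                    .data$file_id, .data$level, .data$bin),
    count = dplyr::n(), .groups = "drop"
  )
  totals <- dplyr::summarise(
    dplyr::group_by(ratios, .data$file_id, .data$level),
    n_ratios_in_file = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(base, tallied, by = c("file_id", "level", "bin"))
  out <- dplyr::left_join(out, totals, by = c("file_id", "level"))
  out$count <- as.integer(ifelse(is.na(out$count), 0L, out$count))
  out$n_ratios_in_file <- as.integer(ifelse(is.na(out$n_ratios_in_file),
                                            0L, out$n_ratios_in_file))
  out$bin_width <- as.numeric(w[out$bin])
  dplyr::arrange(out, .data$level, .data$file_id,
                 match(.data$bin, bin_levels()))
}

#' Share of double meter among rhythmic-category hits
#'
#' Proportion of on-integer double-meter ratios (1:2 plus 2:1) pooled over
#' files, per analysis level. With `denominator = "on"` the base is all
#' on-integer ratios (1:1 + 1:2 + 2:1); with `"classified"` it is every ratio
#' that fell in any of the six bins.
#'
#' @param bin_counts Output of [count_bins()].
#' @param denominator `"on"` (default) or `"classified"`.
#' @return Tibble per level: `n_double`, `n_denominator`, `share` (`NA` when
#'   the denominator is zero).
#' @export
double_meter_share <- function(bin_counts, denominator = c("on", "classified")) {
  denominator <- match.arg(denominator)
  per_level <- split(bin_counts, bin_counts$level)
  out <- lapply(names(per_level), function(lv) {
    b <- per_level[[lv]]
    tot <- tapply(b$count, b$bin, sum)
    tot[is.na(tot)] <- 0
    dbl <- sum(tot[c("on1:2", "on2:1")], na.rm = TRUE)
    den <- if (denominator == "on") {
      sum(tot[c("on1:1", "on1:2", "on2:1")], na.rm = TRUE)
    } else {
      sum(tot, na.rm = TRUE)
    }
    tibble::tibble(level = lv, n_double = dbl, n_denominator = den,
                   share = if (den > 0) dbl / den else NA_real_)
  })
  dplyr::bind_rows(out)
}

#' Within-call positional density of a rhythmic category
#'
#' Gaussian kernel density, boundary-reflected at 0 and 1 and normalized to
#' integrate to 1 on [0, 1], of the relative call positions of on-integer
#' ratios belonging to one rhythmic category. Shows where along the call a
#' category concentrates (e.g. isochrony early, double meter at the edges).
#'
#' @param ratios A `ratio_table` with `rel_pos` populated.
#' @param category One of `"iso_1_1"`, `"half_1_2"`, `"double_2_1"`.
#' @param bw Kernel bandwidth; default Silverman's rule on the matching
#'   positions.
#' @param n Grid size.
#' @return Tibble `x` (position in [0,1]), `density`.
#' @export
category_position_density <- function(ratios,
                                      category = c("iso_1_1", "half_1_2",
                                                   "double_2_1"),
                                      bw = NULL, n = 512) {
  category <- match.arg(category)
  x <- ratios$rel_pos[ratios$category == category & ratios$zone == "on" &
                        !is.na(ratios$rel_pos)]
  if (length(x) < 2) {
    stop_callrhythm(
      sprintf("fewer than 2 on-integer ratios for category '%s'", category),
      "insufficient_data_error"
    )
  }
  bw <- bw %||% bw.nrd0(x)
  aug <- c(x, -x, 2 - x)  # reflect mass escaping the [0,1] support
  d <- density(aug, bw = bw, n = n, from = 0, to = 1)
  y <- d$y * 3
  area <- sum((y[-1] + y[-n]) / 2 * diff(d$x))
  tibble::tibble(x = d$x, density = y / area)
}
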