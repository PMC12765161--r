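test_that("interval and ratio arithmetic follows the definitions", {
  expect_equal(compute_tk(c(0, 2, 4)), c(2, 2))
  expect_equal(compute_tk(c(0, 1, 3)), c(1, 2))
  expect_equal(compute_rk(c(2, 2)), 0.5)
  expect_equal(compute_rk(c(1, 2)), 1 / 3)
  expect_equal(compute_rk(c(2, 1)), 2 / 3)
  expect_error(compute_tk(c(0, 2, 2)), class = "validation_error")
  expect_warning(expect_length(compute_tk(1), 0), "fewer than 2")
  expect_warning(expect_length(compute_rk(2), 0), "fewer than 2")
})

test_that("ratio complement identity r(a,b) + r(b,a) = 1 holds", {
  set.seed(42)
  for (i in 1:200) {
    ab <- exp(rnorm(2, 0, 2))
    expect_equal(compute_rk(ab) + compute_rk(rev(ab)), 1, tolerance = 1e-12)
  }
})

test_that("series construction matches the level definitions", {
  ev <- make_events("f1", "c1", c("pulse", "pant", "pulse", "pulse"),
                    c(0, 1, 2, 4))
  lvl1 <- build_series(ev, "all_pulses")
  expect_equal(lvl1$onset_s, c(0, 2, 4))
  lvl2 <- build_series(ev, "pulse_pant_series")
  expect_equal(lvl2$onset_s, c(0, 1, 2))  # the alternating run p-t-p
  expect_equal(build_series(ev, "pulses_within_series")$onset_s, c(0, 2))
  expect_equal(build_series(ev, "pants_within_series")$onset_s, 1)
})

test_that("a pant-free table leaves levels (ii)-(iv) empty with a warning", {
  ev <- make_events("f1", "c1", "pulse", c(0, 2, 4, 6))
  expect_equal(nrow(build_series(ev, "all_pulses")), 4)
  for (l in c("pulse_pant_series", "pulses_within_series",
              "pants_within_series")) {
    expect_warning(out <- build_series(ev, l), "no pant events")
    expect_equal(nrow(out), 0)
  }
})

test_that("alternation sections recover the generator's ground truth", {
  corpus <- generate_corpus(synth_config(
    n_calls = 12, pant_insertion_prob = 0.5,
    pant_position_profile = "uniform", seed = 11
  ))
  found <- find_sections(corpus$events)
  truth <- corpus$truth$events
  expect_equal(found$section_id, truth$true_section)
})

test_that("interval/ratio lengths obey count conservation per series", {
  corpus <- generate_corpus(synth_config(n_calls = 10, seed = 21))
  for (l in analysis_levels()) {
    ser <- suppressWarnings(build_series(corpus$events, l))
    iv <- suppressWarnings(rhythm_intervals(corpus$events, l))
    rt <- suppressWarnings(rhythm_ratios(corpus$events, l))
    n_ev <- table(ser$series_id)
    n_tk <- table(factor(iv$series_id, levels = names(n_ev)))
    expect_equal(as.numeric(n_tk[n_ev >= 2]), as.numeric(n_ev[n_ev >= 2]) - 1,
                 info = l)
    n_rk <- table(factor(rt$series_id, levels = names(n_ev)))
    expect_equal(as.numeric(n_rk[n_ev >= 3]), as.numeric(n_ev[n_ev >= 3]) - 2,
                 info = l)
  }
})

test_that("zero-jitter isochrony gives 100% on-integer 1:1 ratios", {
  corpus <- generate_corpus(synth_config(
    n_calls = 5, pulses_per_call = 10, jitter_cv = 0,
    pant_insertion_prob = 0, seed = 1
  ))
  rt <- rhythm_ratios(corpus$events, "all_pulses")
  expect_true(all(rt$r_k == 0.5))
  expect_true(all(rt$category == "iso_1_1" & rt$zone == "on"))
})

test_that("zero-jitter midpoint pants halve level (ii) intervals exactly", {
  corpus <- generate_corpus(synth_config(
    n_calls = 4, pulses_per_call = 8, jitter_cv = 0,
    pant_insertion_prob = 1, pant_phase = 0.5, pant_phase_sd = 0,
    pant_position_profile = "uniform", seed = 2
  ))
  iv2 <- rhythm_intervals(corpus$events, "pulse_pant_series")
  expect_true(all(iv2$t_k == 1.0))  # half the 2 s pulse period
  iv3 <- rhythm_intervals(corpus$events, "pulses_within_series")
  iv4 <- rhythm_intervals(corpus$events, "pants_within_series")
  expect_true(all(iv3$t_k == 2.0))
  expect_true(all(iv4$t_k == 2.0))
})

test_that("bin tallies match a brute-force recount and keep zeros", {
  corpus <- generate_corpus(synth_config(n_calls = 15, seed = 31))
  rt <- rhythm_ratios(corpus$events, "all_pulses")
  bc <- count_bins(rt)
  expect_equal(nrow(bc), length(unique(rt$file_id)) * 6)
  for (i in seq_len(nrow(bc))) {
    scheme <- bin_scheme()
    segs <- scheme[scheme$bin == bc$bin[i], ]
    manual <- 0
    rs <- rt$r_k[rt$file_id == bc$file_id[i]]
    for (j in seq_len(nrow(segs))) {
      manual <- manual + sum(rs >= segs$lo[j] & rs < segs$hi[j])
    }
    expect_equal(bc$count[i], manual)
  }
  expect_true(all(tapply(bc$count, bc$file_id, sum) <=
                    tapply(bc$n_ratios_in_file, bc$file_id, max)))

  empty <- rt[0, ]
  bc0 <- count_bins(empty, files = c("fA", "fB"))
  expect_equal(nrow(bc0), 12)
  expect_true(all(bc0$count == 0))
})

test_that("double-meter share uses the documented arithmetic", {
  mk <- function(counts) {
    tibble::tibble(file_id = "f1", level = "all_pulses", bin = bin_levels(),
                   count = counts, bin_width = bin_widths(),
                   n_ratios_in_file = sum(counts))
  }
  # counts in bin_levels() order: off1:1, on1:1, off1:2, on1:2, off2:1, on2:1
  expect_equal(double_meter_share(mk(c(0, 9, 0, 1, 0, 0)))$share, 0.10)
  expect_equal(double_meter_share(mk(c(0, 2, 0, 1, 0, 0)))$share, 1 / 3)
  expect_true(is.na(double_meter_share(mk(rep(0, 6)))$share))
  cl <- double_meter_share(mk(c(5, 9, 0, 1, 0, 0)), denominator = "classified")
  expect_equal(cl$share, 1 / 15)
})

test_that("positional density recovers point mass, uniformity and bimodality", {
  rt_point <- tibble::tibble(category = "iso_1_1", zone = "on",
                             rel_pos = rep(0.5, 50))
  d <- category_position_density(rt_point, "iso_1_1", bw = 0.01)
  expect_equal(d$x[which.max(d$density)], 0.5, tolerance = 0.01)

  set.seed(3)
  rt_unif <- tibble::tibble(category = "iso_1_1", zone = "on",
                            rel_pos = runif(1e4))
  du <- category_position_density(rt_unif, "iso_1_1")
  expect_lt(max(abs(du$density - 1)), 0.15)
  area <- sum((du$density[-1] + du$density[-nrow(du)]) / 2 * diff(du$x))
  expect_equal(area, 1, tolerance = 1e-6)

  expect_error(
    category_position_density(rt_point, "double_2_1"),
    "double_2_1", class = "insufficient_data_error"
  )

  # pants concentrated early/late with off-midpoint phase -> bimodal 1:2
  corpus <- generate_corpus(synth_config(
    n_calls = 40, pulses_per_call = c(20, 40), jitter_cv = 0.03,
    pant_insertion_prob = 0.45, pant_phase = 1 / 3, pant_phase_sd = 0.01,
    pant_position_profile = "edges", seed = 17
  ))
  rt <- rhythm_ratios(corpus$events, "pulse_pant_series")
  db <- category_position_density(rt, "half_1_2")
  at <- function(x) db$density[which.min(abs(db$x - x))]
  expect_gt(at(0.12), at(0.5))
  expect_gt(at(0.88), at(0.5))
})
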