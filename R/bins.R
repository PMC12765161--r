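#' On/off-integer ratio bin scheme
#'
#' The interval-ratio axis r_k = t_k / (t_k + t_{k+1}) is partitioned into six
#' named bins around the three small-integer rhythmic categories: isochrony
#' 1:1 (r = 0.50), 1:2 (r = 1/3) and 2:1 (r = 2/3). Each category has a
#' narrow "on-integer" window centred on the integer ratio and a flanking
#' "off-integer" window split into a lower and an upper segment. Intervals
#' are half-open, lower-inclusive `[lo, hi)`, so the six bins tile
#' `[0.286, 0.714)` with no overlap; ratios outside that range are left
#' unclassified.
#'
#' @param boundaries Optional named numeric vector overriding the default
#'   breakpoints (rarely needed; the defaults are the conventional published
#'   boundaries).
#' @return A tibble with one row per contiguous segment: `bin` (factor level
#'   name, e.g. `"on1:1"`), `category` (`iso_1_1`, `half_1_2`, `double_2_1`),
#'   `zone` (`on`/`off`), `lo`, `hi`. Off bins contribute two rows each.
#' @seealso [classify_ratio()], [bin_widths()]
#' @export
#' @examples
#' bin_scheme()
#' bin_widths(bin_scheme())
bin_scheme <- function(boundaries = NULL) {
  b <- c(
    lo12_off = 0.286, lo12_on = 0.308, hi12_on = 0.364, hi12_off = 0.400,
    lo11_on = 0.444, hi11_on = 0.555, hi11_off = 0.600,
    lo21_on = 0.636, hi21_on = 0.692, hi21_off = 0.714
  )
  if (!is.null(boundaries)) {
    stopifnot(all(names(boundaries) %in% names(b)))
    b[names(boundaries)] <- boundaries
  }
  tibble::tibble(
    bin = c("off1:2", "on1:2", "off1:2", "off1:1", "on1:1", "off1:1",
            "off2:1", "on2:1", "off2:1"),
    category = c("half_1_2", "half_1_2", "half_1_2",
                 "iso_1_1", "iso_1_1", "iso_1_1",
                 "double_2_1", "double_2_1", "double_2_1"),
    zone = c("off", "on", "off", "off", "on", "off", "off", "on", "off"),
    lo = unname(c(b["lo12_off"], b["lo12_on"], b["hi12_on"],
                  b["hi12_off"], b["lo11_on"], b["hi11_on"],
                  b["hi11_off"], b["lo21_on"], b["hi21_on"])),
    hi = unname(c(b["lo12_on"], b["hi12_on"], b["hi12_off"],
                  b["lo11_on"], b["hi11_on"], b["hi11_off"],
                  b["lo21_on"], b["hi21_on"], b["hi21_off"]))
  )
}

#' Factor levels of the six ratio bins, in model order
#' @return Character vector `off1:1, on1:1, off1:2, on1:2, off2:1, on2:1`.
#' @export
bin_levels <- function() {
  c("off1:1", "on1:1", "off1:2", "on1:2", "off2:1", "on2:1")
}

#' Total width of each ratio bin
#'
#' Off bins are unions of two segments; their width is the sum of segment
#' lengths. Widths enter the count model as an exposure offset.
#'
#' @param scheme A bin scheme, see [bin_scheme()].
#' @return Named numeric vector of widths, one per bin, in [bin_levels()]
#'   order.
#' @export
bin_widths <- function(scheme = bin_scheme()) {
  w <- tapply(scheme$hi - scheme$lo, scheme$bin, sum)
  out <- as.numeric(w[bin_levels()])
  names(out) <- bin_levels()
  out
}

#' Classify interval ratios into rhythmic-category bins
#'
#' @param r Numeric vector of ratios, each strictly between 0 and 1.
#' @param scheme Bin scheme from [bin_scheme()].
#' @return Tibble with columns `r`, `bin`, `category`, `zone`. Ratios outside
#'   the covered range get `bin = NA`, `category = "none"`, `zone = "none"`.
#' @export
#' @examples
#' classify_ratio(c(0.50, 0.58, 0.20))
classify_ratio <- function(r, scheme = bin_scheme()) {
  if (!is.numeric(r)) stop_callrhythm("`r` must be numeric", "domain_error")
  bad <- !is.na(r) & (r <= 0 | r >= 1)
  if (any(bad)) {
    stop_callrhythm(
      sprintf("ratios must lie strictly in (0, 1); offending values: %s",
              paste(format(r[bad]), collapse = ", ")),
      "domain_error"
    )
  }
  idx <- rep(NA_integer_, length(r))
  for (i in seq_len(nrow(scheme))) {
    hit <- !is.na(r) & r >= scheme$lo[i] & r < scheme$hi[i]
    idx[hit] <- i
  }
  bin <- rep(NA_character_, length(r))
  category <- rep("none", length(r))
  zone <- rep("none", length(r))
  hit <- !is.na(idx)
  bin[hit] <- scheme$bin[idx[hit]]
  category[hit] <- scheme$category[idx[hit]]
  zone[hit] <- scheme$zone[idx[hit]]
  category[is.na(r)] <- NA_character_
  zone[is.na(r)] <- NA_character_
  tibble::tibble(r = r, bin = bin, category = category, zone = zone)
}
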