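#' Construct and validate an event table
#'
#' An event table is the pipeline's canonical representation of annotated
#' long-call elements: one row per voiced event with its recording file, call,
#' kind (`pulse` = voiced exhale, `pant` = voiced inhale), onset and duration
#' in seconds. Rows are sorted by `(file_id, call_id, onset_s)`; onsets must
#' be strictly increasing within a call (tied onsets are invalid, not broken
#' arbitrarily). Calls with fewer than two pulses are flagged in the
#' `flagged_calls` attribute and kept.
#'
#' @param x Data frame with columns `file_id`, `call_id`, `kind`, `onset_s`,
#'   `duration_s` and optionally `section_id`.
#' @param provenance Free-text source description stored as an attribute.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(x, provenance = "in-memory") {
  required <- c("file_id", "call_id", "kind", "onset_s", "duration_s")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop_callrhythm(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  x <- tibble::as_tibble(x)
  if (!"section_id" %in% names(x)) x$section_id <- NA_character_
  x <- x[, c("file_id", "call_id", "section_id", "kind", "onset_s", "duration_s")]
  x$file_id <- as.character(x$file_id)
  x$call_id <- as.character(x$call_id)
  x$section_id <- as.character(x$section_id)
  x$kind <- as.character(x$kind)

  bad_kind <- !x$kind %in% c("pulse", "pant")
  if (any(bad_kind)) {
    stop_callrhythm(
      sprintf("unknown kind label(s): %s",
              paste(unique(x$kind[bad_kind]), collapse = ", ")),
      "validation_error"
    )
  }
  if (nrow(x) && (any(!is.finite(x$onset_s)) || any(x$onset_s < 0))) {
    stop_callrhythm("onset_s must be finite and >= 0", "validation_error")
  }
  if (nrow(x) && (any(!is.finite(x$duration_s)) || any(x$duration_s <= 0))) {
    stop_callrhythm("duration_s must be finite and > 0", "validation_error")
  }

  x <- dplyr::arrange(x, .data$file_id, .data$call_id, .data$onset_s)
  if (nrow(x)) {
    key <- paste(x$file_id, x$call_id, sep = "\r")
    same <- key[-1] == key[-nrow(x)]
    nonmono <- c(FALSE, same & diff(x$onset_s) <= 0)
    if (any(nonmono)) {
      rows <- which(nonmono)
      stop_callrhythm(
        sprintf("onsets not strictly increasing within a call at sorted row(s): %s",
                paste(rows, collapse = ", ")),
        "validation_error"
      )
    }
  }

  n_pulse <- dplyr::summarise(
    dplyr::group_by(x, .data$file_id, .data$call_id),
    n_pulse = sum(.data$kind == "pulse"), .groups = "drop"
  )
  flagged <- n_pulse[n_pulse$n_pulse < 2, c("file_id", "call_id")]
  if (nrow(flagged)) {
    warning(sprintf("%d call(s) have fewer than 2 pulses; flagged, not dropped",
                    nrow(flagged)), call. = FALSE)
  }

  structure(x,
            class = c("event_table", class(tibble::tibble())),
            provenance = provenance,
            flagged_calls = flagged)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, %d call(s), %d file(s)\n",
              nrow(x), nrow(unique(x[, c("file_id", "call_id")])),
              length(unique(x$file_id))))
  cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

zenodo_dialects <- c("zenodo_tempo", "zenodo_granger", "zenodo_tk_rk",
                     "zenodo_rk_overall")

#' Read long-call annotations or derived tables
#'
#' Reads an annotation file in one of several dialects and returns either a
#' canonical [event_table()] (event-level dialects) or a derived
#' interval/ratio table (deposited-data dialects that ship precomputed t_k or
#' r_k values rather than raw events), tagged with provenance so downstream
#' stages can start mid-pipeline.
#'
#' Dialects:
#' \describe{
#'   \item{canonical_csv}{CSV with columns `file_id`, `call_id`, `kind`,
#'     `onset_s`, `duration_s` (+ optional `section_id`).}
#'   \item{raven_selection}{Tab-separated Raven Pro selection table with
#'     `Begin Time (s)`, `End Time (s)` and an annotation column mapping to
#'     the event kind. Read-only.}
#'   \item{zenodo_tempo}{Deposited tempo table: one row per t_k with its
#'     series type. Returns an interval table.}
#'   \item{zenodo_granger}{Deposited event-onset table for causality tests.
#'     Returns an [event_table()].}
#'   \item{zenodo_tk_rk}{Deposited pulse/pant-within-series t_k and r_k.
#'     Returns a ratio table.}
#'   \item{zenodo_rk_overall}{Deposited overall (all-pulses) t_k/r_k table.
#'     Returns a ratio table.}
#' }
#'
#' Column names of the deposited datasets are not fixed by the pipeline; they
#' are declared in a small YAML mapping file (see
#' `system.file("extdata", "zenodo_mapping.yaml", package = "callrhythm")`)
#' that maps each dialect's canonical field names to the column headers found
#' in the deposit.
#'
#' @param path Path to the file.
#' @param dialect One of `canonical_csv`, `raven_selection`, `zenodo_tempo`,
#'   `zenodo_granger`, `zenodo_tk_rk`, `zenodo_rk_overall`.
#' @param mapping Optional parsed YAML mapping list (Zenodo dialects only);
#'   defaults to the mapping file shipped with the package.
#' @param annotation_col Raven dialect: name of the column holding the event
#'   kind (default `"Annotation"`).
#' @return An `event_table`, or a tibble of class `interval_table` /
#'   `ratio_table` for derived dialects.
#' @export
read_events <- function(path,
                        dialect = c("canonical_csv", "raven_selection",
                                    "zenodo_tempo", "zenodo_granger",
                                    "zenodo_tk_rk", "zenodo_rk_overall"),
                        mapping = NULL,
                        annotation_col = "Annotation") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_callrhythm(sprintf("file not found: %s", path), "io_error")
  }
  prov <- sprintf("%s [%s]", path, dialect)

  if (dialect == "canonical_csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(event_table(df, provenance = prov))
  }

  if (dialect == "raven_selection") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("Begin Time (s)", "End Time (s)", annotation_col)
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols)) {
      stop_callrhythm(
        sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
        "schema_error"
      )
    }
    kind <- tolower(trimws(as.character(df[[annotation_col]])))
    out <- tibble::tibble(
      file_id = if ("Begin File" %in% names(df)) as.character(df[["Begin File"]])
                else rep(basename(path), nrow(df)),
      call_id = if ("Call" %in% names(df)) as.character(df[["Call"]])
                else rep("call1", nrow(df)),
      kind = kind,
      onset_s = df[["Begin Time (s)"]],
      duration_s = df[["End Time (s)"]] - df[["Begin Time (s)"]]
    )
    return(event_table(out, provenance = prov))
  }

  # Zenodo dialects: rename deposit columns to canonical names per mapping.
  mapping <- mapping %||% default_zenodo_mapping()
  m <- mapping[[dialect]]
  if (is.null(m)) {
    stop_callrhythm(sprintf("mapping has no entry for dialect '%s'", dialect),
                    "schema_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- m$columns
  missing_cols <- setdiff(unlist(cols), names(df))
  if (length(missing_cols)) {
    stop_callrhythm(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  ren <- df[, unlist(cols), drop = FALSE]
  names(ren) <- names(cols)
  ren <- tibble::as_tibble(ren)

  out <- switch(
    dialect,
    zenodo_tempo = {
      ren$tk_type <- as.character(ren$tk_type)
      structure(ren, class = c("interval_table", class(tibble::tibble())),
                provenance = prov)
    },
    zenodo_granger = {
      ren$duration_s <- ren$duration_s %||% 0.1
      event_table(ren, provenance = prov)
    },
    zenodo_tk_rk = ,
    zenodo_rk_overall = {
      structure(ren, class = c("ratio_table", class(tibble::tibble())),
                provenance = prov)
    }
  )
  out
}

default_zenodo_mapping <- function() {
  path <- system.file("extdata", "zenodo_mapping.yaml", package = "callrhythm")
  yaml::read_yaml(path)
}

#' Write an event table as canonical CSV
#'
#' The canonical format round-trips: `read_events(write_events(t), "canonical_csv")`
#' reproduces `t`. Writing is deterministic (byte-stable across repeated
#' writes of the same table).
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  out <- as.data.frame(table)[, c("file_id", "call_id", "section_id",
                                  "kind", "onset_s", "duration_s")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
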