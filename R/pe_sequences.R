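#' Prefix-encoded temporal event sequences
#'
#' A prefix-encoded (PE) sequence records a subject's event history as an
#' alternating list of inter-event durations and state symbols, written
#' `"0.A,t1.B,t2.C,..."`: the first event carries the mandatory `0.` prefix and
#' every later event carries the time elapsed since the previous one. The
#' reserved symbol `"Z"` marks censoring (the last state's outcome is
#' unobserved) and may only appear once, in final position.
#'
#' @param durations Numeric vector of inter-event durations; the first must be
#'   0 and all must be non-negative.
#' @param symbols Character vector of event symbols, same length as
#'   `durations`. Symbols must be non-empty and must not contain `","` or
#'   `"."`.
#' @param patient_id Identifier attached to the sequence.
#' @return A `pe_seq` object: a list with elements `patient_id`, `durations`
#'   and `symbols`.
#' @examples
#' pe_seq(c(0, 5), c("A", "B"), "P1")
#' @export
pe_seq <- function(durations, symbols, patient_id = NA_character_) {
  durations <- as.numeric(durations)
  symbols <- as.character(symbols)
  if (length(durations) != length(symbols)) {
    stop("`durations` and `symbols` must have the same length", call. = FALSE)
  }
  if (length(durations) < 1L) {
    stop("a PE sequence must contain at least one event", call. = FALSE)
  }
  if (anyNA(durations) || any(durations < 0)) {
    stop("durations must be non-negative and non-missing", call. = FALSE)
  }
  if (durations[1L] != 0) {
    stop("the first event must have duration 0 (the '0.' prefix)", call. = FALSE)
  }
  if (anyNA(symbols) || any(!nzchar(symbols)) || any(grepl("[,.]", symbols))) {
    stop("symbols must be non-empty and contain neither ',' nor '.'", call. = FALSE)
  }
  z <- which(symbols == "Z")
  if (length(z) > 1L || (length(z) == 1L && z != length(symbols))) {
    stop("censoring symbol 'Z' may appear only once, as the final event", call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, durations = durations, symbols = symbols),
    class = "pe_seq"
  )
}

#' @export
length.pe_seq <- function(x) length(x$symbols)

#' @export
print.pe_seq <- function(x, ...) {
  cat("<pe_seq> ", if (!is.na(x$patient_id)) paste0(x$patient_id, ": "),
      format_pe(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.pe_seq <- function(x, ...) format_pe(x)

# Canonical duration rendering: up to 6 significant digits, plain decimal
# notation, integers without a decimal point. Needed so that
# parse_pe(format_pe(s)) round-trips bit-exactly.
format_duration <- function(x) {
  format(signif(x, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Serialize a PE sequence to its string form
#'
#' Inverse of [parse_pe()]: durations are rendered with up to 6 significant
#' digits in plain decimal notation so that parsing the output recovers the
#' sequence exactly.
#'
#' @param seq A `pe_seq` object.
#' @return A single string such as `"0.A,5.B"`.
#' @examples
#' format_pe(pe_seq(c(0, 5), c("A", "B")))
#' @export
format_pe <- function(seq) {
  stopifnot(inherits(seq, "pe_seq"))
  paste(paste0(format_duration(seq$durations), ".", seq$symbols), collapse = ",")
}

#' Parse a PE-format string
#'
#' Accepts the grammar `duration "." symbol ("," duration "." symbol)*` where
#' the first duration must be 0. Durations may contain a decimal point, so the
#' split on `"."` takes the *last* dot of each comma-separated token as the
#' duration/symbol separator.
#'
#' @param text A single PE-format string, e.g. `"0.A,5.B"`.
#' @param patient_id Identifier to attach to the parsed sequence.
#' @return A `pe_seq` object.
#' @examples
#' parse_pe("0.A,5.B")
#' parse_pe("0.A,3.B,2.Z")
#' @export
parse_pe <- function(text, patient_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(text, ",", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || !nzchar(text)) {
    stop("empty PE string", call. = FALSE)
  }
  m <- regmatches(tokens, regexec("^([0-9]+(?:\\.[0-9]+)?)\\.([^.,]+)$", tokens))
  bad <- which(vapply(m, length, integer(1L)) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed PE token '%s' at position %d", tokens[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  durations <- vapply(m, function(g) as.numeric(g[2L]), numeric(1L))
  symbols <- vapply(m, function(g) g[3L], character(1L))
  if (durations[1L] != 0) {
    stop("first event must carry the '0.' prefix (position 1)", call. = FALSE)
  }
  z <- which(symbols == "Z")
  if (length(z) > 0L && (length(z) > 1L || z[1L] != length(symbols))) {
    stop(sprintf("censoring symbol 'Z' in non-final position %d", z[1L]), call. = FALSE)
  }
  pe_seq(durations, symbols, patient_id)
}

#' Convert panel-format longitudinal records to PE sequences
#'
#' Panel data has one row per visit: a subject identifier, an event symbol and
#' a time stamp. Within each subject, rows are sorted by time, consecutive
#' visits with the same symbol are collapsed into a single state (the method
#' models state *switches*, not visits), and the inter-event durations become
#' the PE sequence's time prefixes. Two time representations are supported:
#' calendar dates (durations are day differences) and plain numbers (durations
#' are numeric differences, in whatever unit the data uses).
#'
#' @param records A data frame of visit records.
#' @param id_col,event_col,time_col Names of the subject-ID, event-symbol and
#'   time columns. Defaults `"id"`, `"event"`, `"time"`.
#' @param time_mode `"auto"` (default; dates if the time column is `Date` or
#'   parses as dates), `"numeric"` or `"dates"`.
#' @param date_format Optional format string passed to [as.Date()] when times
#'   are character dates; ISO-8601 (`"%Y-%m-%d"`) is tried by default.
#' @param collapse_repeats Collapse consecutive identical symbols within a
#'   subject (default `TRUE`).
#' @param censor If `TRUE`, append the censoring symbol `"Z"` to every subject
#'   whose final state is not already `"Z"`, with duration equal to the time
#'   from the final state's start to the subject's last observed visit.
#' @return A tibble with one row per subject: `patient_id`, `n_events`, `pe`
#'   (the string form) and `seq` (a list column of `pe_seq` objects).
#' @examples
#' panel <- data.frame(
#'   id = c("P1", "P1", "P2"),
#'   event = c("A", "B", "A"),
#'   time = c(0, 5, 7)
#' )
#' panel_to_pe(panel)
#' @export
panel_to_pe <- function(records, id_col = "id", event_col = "event",
                        time_col = "time",
                        time_mode = c("auto", "numeric", "dates"),
                        date_format = NULL, collapse_repeats = TRUE,
                        censor = FALSE) {
  time_mode <- match.arg(time_mode)
  for (col in c(id_col, event_col, time_col)) {
    if (!col %in% names(records)) {
      stop(sprintf("column '%s' not found in `records`", col), call. = FALSE)
    }
  }
  df <- tibble::tibble(
    patient_id = as.character(records[[id_col]]),
    event = as.character(records[[event_col]]),
    time = records[[time_col]]
  )
  if (nrow(df) == 0L) stop("`records` must cover at least one patient", call. = FALSE)

  time <- df$time
  if (time_mode == "auto") {
    time_mode <- if (inherits(time, "Date") ||
                     (is.character(time) && !anyNA(suppressWarnings(
                       as.Date(time, format = date_format %||% "%Y-%m-%d"))))) {
      "dates"
    } else {
      "numeric"
    }
  }
  if (time_mode == "dates") {
    if (!inherits(time, "Date")) {
      time <- as.Date(as.character(time), format = date_format %||% "%Y-%m-%d")
    }
    if (anyNA(time)) stop("unparseable dates in time column", call. = FALSE)
    df$time <- as.numeric(time)   # days since epoch; differences are day counts
  } else {
    df$time <- as.numeric(time)
    if (anyNA(df$time)) {
      stop("time column mixes representations or contains non-numeric values",
           call. = FALSE)
    }
  }

  # Duplicate (patient, time) rows: identical symbols deduplicate silently,
  # conflicting symbols are an error.
  conflicts <- df |>
    dplyr::distinct(.data$patient_id, .data$time, .data$event) |>
    dplyr::count(.data$patient_id, .data$time) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts) > 0L) {
    stop(sprintf("conflicting symbols at tied times for patient(s): %s",
                 paste(unique(conflicts$patient_id), collapse = ", ")),
         call. = FALSE)
  }

  build_one <- function(g) {
    g <- dplyr::arrange(dplyr::distinct(g, .data$time, .data$event,
                                        .keep_all = TRUE), .data$time)
    last_visit <- g$time[nrow(g)]
    if (collapse_repeats) {
      keep <- c(TRUE, g$event[-1L] != g$event[-nrow(g)])
      g <- g[keep, , drop = FALSE]
    }
    durations <- c(0, diff(g$time))
    symbols <- g$event
    if (censor && symbols[length(symbols)] != "Z") {
      durations <- c(durations, last_visit - g$time[nrow(g)])
      symbols <- c(symbols, "Z")
    }
    pe_seq(durations, symbols, g$patient_id[1L])
  }

  seqs <- df |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    lapply(build_one)
  pe_tbl(seqs)
}

#' Assemble a tibble of PE sequences
#'
#' @param seqs A list of `pe_seq` objects.
#' @return A tibble with columns `patient_id`, `n_events`, `pe`, `seq`.
#' @export
pe_tbl <- function(seqs) {
  stopifnot(all(vapply(seqs, inherits, logical(1L), "pe_seq")))
  ids <- vapply(seqs, function(s) as.character(s$patient_id), character(1L))
  tibble::tibble(
    patient_id = ids,
    n_events = vapply(seqs, length, integer(1L)),
    pe = vapply(seqs, format_pe, character(1L)),
    seq = seqs
  )
}

#' Read and write one-sequence-per-line PE files
#'
#' The on-disk format is one line per subject: `patient_id<TAB>pe_string`.
#'
#' @param tbl A tibble as produced by [panel_to_pe()] or [pe_tbl()].
#' @param file Path to read from or write to.
#' @return `read_pe()` returns a sequence tibble; `write_pe()` returns `tbl`
#'   invisibly.
#' @export
write_pe <- function(tbl, file) {
  stopifnot(all(c("patient_id", "pe") %in% names(tbl)))
  writeLines(paste(tbl$patient_id, tbl$pe, sep = "\t"), file)
  invisible(tbl)
}

#' @rdname write_pe
#' @export
read_pe <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1L)) != 2L)) {
    stop("each line must be 'patient_id<TAB>pe_string'", call. = FALSE)
  }
  seqs <- lapply(parts, function(p) parse_pe(p[2L], p[1L]))
  pe_tbl(seqs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
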