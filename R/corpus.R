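#' Construct a song cycle
#'
#' One pass through a singer's theme sequence. The phrase sequence is kept at
#' phrase-type resolution; repetition of a theme is disallowed except as
#' consecutive alternation of its phrase types (e.g. `5a, 5c, 5a, 5c`), the
#' convention used for transcribing song cycles.
#'
#' @param index cycle number within the recording (>= 1).
#' @param phrases character vector of phrase-type labels, in sung order.
#' @param units optional list of character vectors, one per phrase, giving
#'   the unit tokens of each phrase.
#' @param onset_s,offset_s optional numeric vectors of per-phrase start and
#'   end times in seconds from the start of the recording.
#' @return An object of class `song_cycle`.
#' @export
song_cycle <- function(index, phrases, units = NULL,
                       onset_s = NULL, offset_s = NULL) {
  if (length(phrases) == 0L) stop("a song cycle must contain phrases")
  parsed <- parse_label(phrases)  # validates the label grammar
  if (!is.null(units)) {
    stopifnot(is.list(units), length(units) == length(phrases))
    if (!is.null(onset_s)) {
      stopifnot(length(onset_s) == length(phrases),
                length(offset_s) == length(phrases))
      if (any(offset_s <= onset_s)) stop("phrase offsets must exceed onsets")
      if (is.unsorted(onset_s)) stop("phrases must be time-ordered")
    }
  }
  structure(list(index = as.integer(index), phrases = parsed$label,
                 units = units, onset_s = onset_s, offset_s = offset_s),
            class = "song_cycle")
}

#' Construct a singer recording
#'
#' @param singer_id singer identifier (text).
#' @param year recording year.
#' @param site recording site name (e.g. `"Kerama"`, `"Motobu"`).
#' @param date recording date (`Date`, ISO string, or a printed day-first
#'   form such as `"16 February"`, resolved against `year`).
#' @param length_s recording length in seconds (> 0).
#' @param cycles list of [song_cycle()] objects.
#' @param snr_db optional signal-to-noise ratio of song units in dB.
#' @param complete logical; `FALSE` when no complete song cycle was captured,
#'   which excludes the recording from similarity and complexity analyses.
#' @return An object of class `singer_recording`.
#' @export
singer_recording <- function(singer_id, year, site, date, length_s, cycles,
                             snr_db = NA_real_, complete = TRUE) {
  if (length_s <= 0) stop("length_s must be positive")
  stopifnot(length(cycles) >= 1L,
            all(vapply(cycles, inherits, logical(1), "song_cycle")))
  date <- parse_song_date(date, year)
  if (!is.na(date) && as.integer(format(date, "%Y")) != as.integer(year)) {
    stop("recording date does not fall in the stated year")
  }
  structure(list(singer_id = as.character(singer_id), year = as.integer(year),
                 site = as.character(site), date = date,
                 length_s = as.numeric(length_s), snr_db = as.numeric(snr_db),
                 complete = isTRUE(complete), cycles = cycles),
            class = "singer_recording")
}

#' Construct a song corpus
#'
#' @param recordings list of [singer_recording()] objects with unique
#'   `(singer_id, year)` pairs.
#' @param provenance free-text note on the origin of the data.
#' @return An object of class `song_corpus`.
#' @export
song_corpus <- function(recordings, provenance = "") {
  stopifnot(all(vapply(recordings, inherits, logical(1), "singer_recording")))
  key <- vapply(recordings, function(r) paste(r$singer_id, r$year), "")
  if (anyDuplicated(key)) {
    stop("duplicate (singer_id, year) pair: ", key[duplicated(key)][1L])
  }
  structure(list(recordings = recordings, provenance = provenance),
            class = "song_corpus")
}

#' @export
print.song_corpus <- function(x, ...) {
  yrs <- table(vapply(x$recordings, `[[`, integer(1), "year"))
  cat("song_corpus:", length(x$recordings), "recordings (",
      paste(names(yrs), "=", yrs, collapse = ", "), ")\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.song_corpus <- function(x) length(x$recordings)

# day-first printed dates ("16 February") or ISO; NA passes through
parse_song_date <- function(date, year) {
  if (inherits(date, "Date")) return(date)
  if (is.na(date) || !nzchar(date)) return(as.Date(NA))
  d <- suppressWarnings(as.Date(date, format = "%Y-%m-%d"))
  if (!is.na(d)) return(d)
  d <- suppressWarnings(as.Date(paste(date, year), format = "%d %B %Y"))
  if (is.na(d)) stop("cannot parse date: '", date, "'")
  d
}

#' Filter recordings on data-quality rules
#'
#' Applies the two recording-eligibility rules used when assembling a song
#' corpus: a minimum unit signal-to-noise ratio, and a minimum temporal
#' separation between recordings from the same site in the same year (to
#' minimise the chance of sampling the same singer twice; among recordings
#' closer than the minimum separation the earlier one is kept).
#'
#' Recordings without an SNR value fail the SNR rule while it is enabled;
#' pass `min_snr_db = NULL` to disable it (e.g. for corpora that were
#' pre-screened upstream). Either rule can be disabled with `NULL`.
#' The filter is idempotent.
#'
#' @param corpus a [song_corpus()].
#' @param min_snr_db SNR threshold in dB (recordings at or below it are
#'   dropped), or `NULL` to disable.
#' @param min_separation_h minimum separation in hours between same-site,
#'   same-year recordings, or `NULL` to disable.
#' @return The filtered `song_corpus`, with a data frame of dropped
#'   recordings and reasons in `attr(, "dropped")`.
#' @export
filter_recordings <- function(corpus, min_snr_db = 10, min_separation_h = 24) {
  recs <- corpus$recordings
  dropped <- data.frame(singer_id = character(0), year = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  drop_one <- function(r, reason) {
    dropped[nrow(dropped) + 1L, ] <<- list(r$singer_id, r$year, reason)
  }
  if (!is.null(min_snr_db)) {
    keep <- logical(length(recs))
    for (i in seq_along(recs)) {
      ok <- !is.na(recs[[i]]$snr_db) && recs[[i]]$snr_db > min_snr_db
      keep[i] <- ok
      if (!ok) drop_one(recs[[i]], "snr")
    }
    recs <- recs[keep]
  }
  if (!is.null(min_separation_h) && length(recs) > 0L) {
    site <- vapply(recs, `[[`, character(1), "site")
    year <- vapply(recs, `[[`, integer(1), "year")
    date <- as.Date(vapply(recs, function(r) as.character(r$date), ""))
    keep <- rep(TRUE, length(recs))
    for (g in split(seq_along(recs), paste(site, year))) {
      g <- g[order(date[g])]
      last_kept <- date[g[1L]]
      for (i in g[-1L]) {
        if (as.numeric(difftime(date[i], last_kept, units = "hours")) <
            min_separation_h) {
          keep[i] <- FALSE
          drop_one(recs[[i]], "separation")
        } else {
          last_kept <- date[i]
        }
      }
    }
    recs <- recs[keep]
  }
  out <- song_corpus(recs, corpus$provenance)
  attr(out, "dropped") <- dropped
  out
}

#' Segment a unit stream into phrases at the largest inter-unit gaps
#'
#' Phrases are delimited by the largest time intervals between units. The
#' boundary rule is scale-free: a gap opens a new phrase when it exceeds
#' `k` times the median inter-unit gap of the stream.
#'
#' @param events data frame of unit events with columns `token`, `onset_s`,
#'   `offset_s`, time-ordered and non-overlapping.
#' @param k multiplier on the median inter-unit gap (default 3).
#' @return A list of character vectors, the unit-token strings of the
#'   phrases in order; the chosen gap threshold is in `attr(, "threshold_s")`.
#' @examples
#' ev <- data.frame(token = letters[1:5],
#'                  onset_s = c(0, 1, 2, 8, 9), offset_s = c(0.8, 1.8, 2.8, 8.8, 9.8))
#' segment_phrases(ev)
#' @export
segment_phrases <- function(events, k = 3) {
  stopifnot(is.data.frame(events),
            all(c("token", "onset_s", "offset_s") %in% names(events)))
  n <- nrow(events)
  if (n == 0L) stop("no unit events to segment")
  if (any(events$offset_s <= events$onset_s)) {
    stop("unit offsets must exceed onsets")
  }
  if (is.unsorted(events$onset_s)) stop("unit events must be time-ordered")
  if (n == 1L) {
    out <- list(as.character(events$token))
    attr(out, "threshold_s") <- NA_real_
    return(out)
  }
  gaps <- events$onset_s[-1L] - events$offset_s[-n]
  if (any(gaps < 0)) stop("overlapping units at position ",
                          which(gaps < 0)[1L] + 1L)
  threshold <- k * stats::median(gaps)
  cut_after <- which(gaps > threshold)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  out <- mapply(function(s, e) as.character(events$token[s:e]),
                starts, ends, SIMPLIFY = FALSE)
  attr(out, "threshold_s") <- threshold
  out
}

#' Read a Raven Pro selection table
#'
#' Reads the tab-separated selection-table export of Raven Pro, honouring the
#' standard column names `"Begin Time (s)"` and `"End Time (s)"` verbatim.
#' The unit label is taken from `annotation_col`, or from the first column
#' outside the standard Raven set when unspecified.
#'
#' @param path path to a tab-separated selection table.
#' @param annotation_col name of the annotation column holding unit labels.
#' @return A data frame of unit events (`token`, `onset_s`, `offset_s`),
#'   time-ordered.
#' @export
read_raven_selection_table <- function(path, annotation_col = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty selection table: ", path)
  for (col in c("Begin Time (s)", "End Time (s)")) {
    if (!col %in% names(tab)) stop("missing mandatory column '", col, "'")
  }
  if (is.null(annotation_col)) {
    standard <- c("Selection", "View", "Channel", "Begin Time (s)",
                  "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)",
                  "Delta Time (s)", "Delta Freq (Hz)")
    cand <- setdiff(names(tab), standard)
    if (length(cand) == 0L) stop("no annotation column found")
    annotation_col <- cand[1L]
  } else if (!annotation_col %in% names(tab)) {
    stop("missing annotation column '", annotation_col, "'")
  }
  ev <- data.frame(token = as.character(tab[[annotation_col]]),
                   onset_s = as.numeric(tab[["Begin Time (s)"]]),
                   offset_s = as.numeric(tab[["End Time (s)"]]),
                   stringsAsFactors = FALSE)
  ev[order(ev$onset_s), , drop = FALSE]
}

#' Read a song transcription table into a corpus
#'
#' The transcription table is a delimited (comma or tab) UTF-8 file with one
#' row per sung phrase and mandatory columns `singer_id`, `year`, `site`,
#' `date`, `cycle`, `position`, `phrase_type`. Optional columns: `length`
#' (`mm:ss`) or `length_s`, `snr_db`, `complete`, and unit-level detail as
#' `units` (space-separated unit tokens) with per-phrase `onset_s` /
#' `offset_s` seconds.
#'
#' @param path path to the transcription file.
#' @param provenance provenance note attached to the corpus (defaults to the
#'   file name).
#' @return A [song_corpus()].
#' @export
read_transcription <- function(path, provenance = basename(path)) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    stop("empty transcription file: ", path)
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0L) stop("empty transcription file: ", path)
  mandatory <- c("singer_id", "year", "site", "date", "cycle", "position",
                 "phrase_type")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing)) stop("missing mandatory column '", missing[1L], "'")
  has_units <- "units" %in% names(tab)
  recs <- list()
  for (key in unique(paste(tab$singer_id, tab$year))) {
    rt <- tab[paste(tab$singer_id, tab$year) == key, , drop = FALSE]
    cycles <- list()
    for (ci in sort(unique(rt$cycle))) {
      ct <- rt[rt$cycle == ci, , drop = FALSE]
      ct <- ct[order(ct$position), , drop = FALSE]
      units <- NULL; onset <- NULL; offset <- NULL
      if (has_units && !all(is.na(ct$units) | ct$units == "")) {
        units <- strsplit(as.character(ct$units), "[[:space:]]+")
        if (all(c("onset_s", "offset_s") %in% names(ct))) {
          onset <- as.numeric(ct$onset_s)
          offset <- as.numeric(ct$offset_s)
        }
      }
      cycles[[length(cycles) + 1L]] <-
        song_cycle(ci, as.character(ct$phrase_type), units = units,
                   onset_s = onset, offset_s = offset)
    }
    r1 <- rt[1L, ]
    length_s <- if ("length_s" %in% names(rt)) as.numeric(r1$length_s)
                else if ("length" %in% names(rt)) parse_mmss(r1$length)
                else NA_real_
    if (is.na(length_s)) {
      length_s <- sum(vapply(cycles, function(cy) {
        if (is.null(cy$offset_s)) 0 else max(cy$offset_s) - min(cy$onset_s)
      }, numeric(1)))
      if (length_s <= 0) length_s <- 1  # unknown; must still be positive
    }
    recs[[length(recs) + 1L]] <- singer_recording(
      singer_id = r1$singer_id, year = r1$year, site = r1$site,
      date = r1$date, length_s = length_s, cycles = cycles,
      snr_db = if ("snr_db" %in% names(rt)) as.numeric(r1$snr_db) else NA_real_,
      complete = if ("complete" %in% names(rt)) as.logical(r1$complete) else TRUE)
  }
  song_corpus(recs, provenance)
}

parse_mmss <- function(x) {
  parts <- strsplit(as.character(x), ":")[[1L]]
  if (length(parts) != 2L) return(NA_real_)
  60 * as.numeric(parts[1L]) + as.numeric(parts[2L])
}

#' Flatten a corpus to a transcription table
#'
#' Inverse of [read_transcription()]: one row per phrase, unit tokens joined
#' by spaces. `write_transcription()` writes the table as CSV so generated
#' corpora are indistinguishable from field transcriptions on disk.
#'
#' @param x a [song_corpus()].
#' @param row.names,optional,... ignored; present for the S3 generic.
#' @return A data frame in the transcription-table layout.
#' @export
as.data.frame.song_corpus <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- list()
  for (r in x$recordings) {
    for (cy in r$cycles) {
      n <- length(cy$phrases)
      rows[[length(rows) + 1L]] <- data.frame(
        singer_id = r$singer_id, year = r$year, site = r$site,
        date = as.character(r$date), length_s = r$length_s,
        snr_db = r$snr_db, complete = r$complete,
        cycle = cy$index, position = seq_len(n), phrase_type = cy$phrases,
        units = if (is.null(cy$units)) NA_character_
                else vapply(cy$units, paste, "", collapse = " "),
        onset_s = if (is.null(cy$onset_s)) NA_real_ else cy$onset_s,
        offset_s = if (is.null(cy$offset_s)) NA_real_ else cy$offset_s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname as.data.frame.song_corpus
#' @param corpus a [song_corpus()].
#' @param path output file path.
#' @export
write_transcription <- function(corpus, path) {
  utils::write.csv(as.data.frame(corpus), path, row.names = FALSE, na = "")
  invisible(path)
}
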