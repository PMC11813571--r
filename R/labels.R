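#' Parse phrase-type labels
#'
#' A phrase-type label encodes a theme number, an optional variant letter
#' (`a`-`d`) and zero, one or two trailing `e` marks flagging a between-year
#' evolved version of the phrase, e.g. `"2"`, `"5c"`, `"1ee"`, `"5ce"`.
#' Internal whitespace (a typographic artefact of printed transcription
#' tables, e.g. `"8 a"`) is removed before parsing.
#'
#' @param x character vector of raw labels.
#' @return A data frame with one row per label and columns `label` (canonical
#'   text form), `theme` (integer), `variant` (single letter or `NA`) and
#'   `evolved` (integer count of trailing `e` marks, 0-2).
#' @examples
#' parse_label(c("8 a", "1a", "5ce", "1ee", "2"))
#' @export
parse_label <- function(x) {
  if (length(x) == 0L) stop("no labels to parse")
  x <- as.character(x)
  clean <- gsub("[[:space:]]+", "", x)
  if (any(!nzchar(clean))) {
    stop("empty phrase-type label at position ",
         which(!nzchar(clean))[1L])
  }
  m <- regmatches(clean, regexec("^([0-9]+)([a-d]?)(e{0,2})$", clean))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed phrase-type label: '", x[bad][1L], "'")
  }
  theme <- as.integer(vapply(m, `[`, character(1), 2L))
  variant <- vapply(m, `[`, character(1), 3L)
  variant[!nzchar(variant)] <- NA_character_
  evolved <- nchar(vapply(m, `[`, character(1), 4L))
  if (any(theme < 1L)) stop("theme numbers must be positive")
  data.frame(label = clean, theme = theme, variant = variant,
             evolved = as.integer(evolved), stringsAsFactors = FALSE)
}

#' Format parsed phrase-type labels back to canonical text
#'
#' Inverse of [parse_label()]: `format_label(parse_label(x))$ == canonical x`.
#'
#' @param parsed data frame as returned by [parse_label()], or a list with
#'   elements `theme`, `variant`, `evolved`.
#' @return character vector of canonical labels.
#' @export
format_label <- function(parsed) {
  variant <- ifelse(is.na(parsed$variant), "", parsed$variant)
  paste0(parsed$theme, variant,
         strrep("e", parsed$evolved))
}

#' Extract the theme number from phrase-type labels
#'
#' @param x character vector of labels or a data frame from [parse_label()].
#' @return integer vector of theme numbers.
#' @examples
#' theme_of(c("1ee", "2", "9b"))
#' @export
theme_of <- function(x) {
  if (is.data.frame(x)) return(x$theme)
  parse_label(x)$theme
}

#' Collapse a phrase-type sequence to its theme sequence
#'
#' Maps each phrase-type label to its theme and merges consecutive duplicate
#' themes, so alternating phrase types of one theme (e.g. `5a, 5c, 5a, 5c`)
#' collapse to a single visit to that theme. Order is preserved.
#'
#' @param phrases character vector of phrase-type labels (one song cycle).
#' @return integer vector of themes with no immediate repetition.
#' @examples
#' collapse_to_themes(c("9a", "5ce", "1ee", "6e", "8a", "8b", "8c"))
#' @export
collapse_to_themes <- function(phrases) {
  th <- theme_of(phrases)
  if (length(th) == 0L) return(integer(0))
  th[c(TRUE, th[-1L] != th[-length(th)])]
}
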