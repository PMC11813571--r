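#' First-order theme-transition matrix for one year
#'
#' Collapses every song cycle of the year to its theme sequence
#' ([collapse_to_themes()]) and counts adjacent theme pairs. Cycle
#' boundaries are hard breaks: the last theme of a cycle contributes no
#' transition into the next cycle. Proportions are row-normalised, so they
#' give the share of the time each transition occurred from a given theme.
#' Transitions observed exactly once are flagged (the "dotted line"
#' annotation of transition diagrams).
#'
#' @param corpus a [song_corpus()].
#' @param year the year to tabulate (must be present in the corpus).
#' @param complete_only restrict to recordings with a complete cycle
#'   (default `FALSE`: partial cycles still carry transition information).
#' @return An object of class `transition_matrix`: list with `year`,
#'   `themes` (ordered), `counts`, `proportions` (rows with no outgoing
#'   transitions are all-`NA`), `once` (logical matrix), `n_transitions`.
#' @export
transition_counts <- function(corpus, year, complete_only = FALSE) {
  recs <- Filter(function(r) r$year == year, corpus$recordings)
  if (length(recs) == 0L) stop("year ", year, " absent from corpus")
  if (complete_only) recs <- Filter(function(r) r$complete, recs)
  seqs <- unlist(lapply(recs, function(r) {
    lapply(r$cycles, function(cy) collapse_to_themes(cy$phrases))
  }), recursive = FALSE)
  themes <- sort(unique(unlist(seqs)))
  k <- length(themes)
  counts <- matrix(0L, k, k, dimnames = list(from = themes, to = themes))
  for (s in seqs) {
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) {
      fi <- match(s[i], themes); ti <- match(s[i + 1L], themes)
      counts[fi, ti] <- counts[fi, ti] + 1L
    }
  }
  rs <- rowSums(counts)
  proportions <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(year = year, themes = themes, counts = counts,
                 proportions = proportions, once = counts == 1L,
                 n_transitions = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 2, ...) {
  cat("transition_matrix, year", x$year, "-", x$n_transitions,
      "transitions over", length(x$themes), "themes\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Stereotypy of theme transitions
#'
#' Shannon entropy (bits) of each theme's outgoing transition distribution,
#' averaged over themes with outgoing transitions, weighted by their
#' transition counts. Zero means fully deterministic sequencing (maximal
#' stereotypy); larger values mean more variable theme ordering.
#'
#' @param tm a `transition_matrix` from [transition_counts()].
#' @return Mean outgoing entropy in bits.
#' @export
stereotypy <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  rs <- rowSums(tm$counts)
  rows <- which(rs > 0)
  if (length(rows) == 0L) stop("no outgoing transitions")
  h <- vapply(rows, function(i) {
    p <- tm$proportions[i, ]
    p <- p[!is.na(p) & p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  sum(h * rs[rows]) / sum(rs[rows])
}

#' Export a transition matrix as a DOT graph
#'
#' Writes the year's transition diagram in Graphviz DOT format: nodes are
#' themes, edge labels are percentages, transitions observed once are
#' dotted.
#'
#' @param tm a `transition_matrix`.
#' @param path optional output file; when `NULL` the DOT text is returned.
#' @return The DOT text, invisibly when written to a file.
#' @export
transitions_to_dot <- function(tm, path = NULL) {
  lines <- c(sprintf("digraph transitions_%s {", tm$year),
             "  rankdir=LR;")
  k <- length(tm$themes)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      n <- tm$counts[i, j]
      if (n == 0L) next
      style <- if (tm$once[i, j]) ", style=dotted" else ""
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"%.0f%%\"%s];",
        tm$themes[i], tm$themes[j], 100 * tm$proportions[i, j], style))
    }
  }
  lines <- c(lines, "}")
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}
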