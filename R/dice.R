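#' Phrase-type inventory of a singer
#'
#' The set of phrase-type labels a singer used across all song cycles
#' (presence/absence; multiplicity ignored). With `level = "theme"` the
#' inventory is collapsed to theme numbers.
#'
#' @param recording a [singer_recording()].
#' @param level `"phrase_type"` (default) or `"theme"`.
#' @return Character vector of distinct labels, in first-use order.
#' @export
phrase_inventory <- function(recording, level = c("phrase_type", "theme")) {
  level <- match.arg(level)
  labels <- unlist(lapply(recording$cycles, `[[`, "phrases"),
                   use.names = FALSE)
  if (level == "theme") labels <- as.character(theme_of(labels))
  unique(labels)
}

#' Dice's Similarity Index between two inventories
#'
#' `2 |A intersect B| / (|A| + |B|)`: the extent of sharing between two item
#' sets, irrespective of order or multiplicity.
#'
#' @param a,b non-empty sets of labels (character vectors; duplicates are
#'   ignored).
#' @return Similarity in `[0, 1]`.
#' @examples
#' dice_similarity(c("1ee", "6e", "8a"), c("9a", "1ee", "6e"))
#' @export
dice_similarity <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("Dice similarity is undefined for an empty inventory")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Dice similarity matrix over a corpus
#'
#' Builds per-singer inventories with [phrase_inventory()] and computes all
#' pairwise [dice_similarity()] values. Recordings flagged as lacking a
#' complete song cycle are excluded by default.
#'
#' @param corpus a [song_corpus()].
#' @param level inventory granularity, `"phrase_type"` (default; separates
#'   evolved `'e'` versions) or `"theme"`.
#' @param complete_only drop incomplete recordings (default `TRUE`).
#' @return A `similarity_matrix` labelled by singer id.
#' @export
dice_matrix <- function(corpus, level = c("phrase_type", "theme"),
                        complete_only = TRUE) {
  level <- match.arg(level)
  recs <- corpus$recordings
  if (complete_only) recs <- Filter(function(r) r$complete, recs)
  if (length(recs) < 2L) stop("need at least two recordings")
  ids <- vapply(recs, `[[`, character(1), "singer_id")
  if (anyDuplicated(ids)) {
    stop("duplicate singer ids: ", ids[duplicated(ids)][1L])
  }
  invs <- lapply(recs, phrase_inventory, level = level)
  n <- length(invs)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- dice_similarity(invs[[i]], invs[[j]])
    }
  }
  as_similarity_matrix(S)
}
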