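#' Token-level Levenshtein edit distance
#'
#' Minimum number of single-token insertions, deletions or substitutions
#' needed to turn one sequence into the other. Tokens are compared as whole
#' symbols (phrase-type labels or unit labels), so `"5c"` and `"5ce"` are
#' distinct tokens at distance 1 by substitution.
#'
#' @param a,b token sequences (character or integer vectors; may be empty).
#' @return Non-negative integer edit distance.
#' @examples
#' levenshtein_distance(c("1a", "2", "3a", "4a", "5a", "5b"),
#'                      c("1a", "3a", "4a", "5a", "2"))
#' @export
levenshtein_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  m <- length(a); n <- length(b)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    sub_cost <- as.integer(a[i] != b)
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + sub_cost[j])
    }
    prev <- cur
  }
  prev[n + 1L]
}

#' Levenshtein Distance Similarity Index (LSI)
#'
#' Edit distance standardised by the length of the longer sequence and
#' subtracted from one, giving a similarity between 0 (no similarity) and 1
#' (identical sequences).
#'
#' @inheritParams levenshtein_distance
#' @return Similarity in `[0, 1]`.
#' @export
lsi <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) {
    stop("LSI is undefined for two empty sequences")
  }
  1 - levenshtein_distance(a, b) / max(length(a), length(b))
}

#' Pairwise LSI similarity matrix
#'
#' @param sequences named list of token sequences (>= 2, unique names).
#' @return A symmetric `similarity_matrix` (unit diagonal, values in
#'   `[0, 1]`) with labels in input order.
#' @export
lsi_matrix <- function(sequences) {
  stopifnot(length(sequences) >= 2L)
  labels <- names(sequences)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("sequences must be named")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate sequence labels: ", labels[duplicated(labels)][1L])
  }
  n <- length(sequences)
  S <- diag(1, n)
  dimnames(S) <- list(labels, labels)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- lsi(sequences[[i]], sequences[[j]])
    }
  }
  as_similarity_matrix(S)
}

#' Set-median sequence
#'
#' The member of a set of sequences minimising the summed Levenshtein
#' distance to all members (the "most typical or representative" sequence).
#' This is the set median, restricted to members of the set; a generalised
#' median string is deliberately not offered. Ties are broken by input
#' order: `"first"` (default) keeps the earliest minimiser, `"last"` the
#' latest.
#'
#' @param sequences list of token sequences (>= 1).
#' @param ties tie-breaking rule, `"first"` or `"last"`.
#' @return The median sequence; its position in the input is in
#'   `attr(, "index")`.
#' @export
set_median <- function(sequences, ties = c("first", "last")) {
  ties <- match.arg(ties)
  n <- length(sequences)
  if (n == 0L) stop("set median of an empty set is undefined")
  sums <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- levenshtein_distance(sequences[[i]], sequences[[j]])
      sums[i] <- sums[i] + d
      sums[j] <- sums[j] + d
    }
  }
  idx <- if (ties == "first") which.min(sums)
         else max(which(sums == min(sums)))
  out <- sequences[[idx]]
  attr(out, "index") <- idx
  out
}

#' Per-singer median sequences from a corpus
#'
#' Computes, for each (complete) recording, the [set_median()] of its song
#' cycles' sequences — the "median theme sequence" used for between-singer
#' LSI comparison. By default sequences stay at phrase-type resolution
#' (tokens such as `"5ce"`), which preserves the evolved-version marks that
#' separate years; `tokenization = "theme"` collapses each cycle to its
#' theme sequence first.
#'
#' @param corpus a [song_corpus()].
#' @param tokenization `"phrase_type"` (default) or `"theme"`.
#' @param ties tie rule passed to [set_median()].
#' @param complete_only drop recordings flagged incomplete (default `TRUE`).
#' @return Named list of median token sequences, one per singer.
#' @export
median_sequences <- function(corpus, tokenization = c("phrase_type", "theme"),
                             ties = c("first", "last"), complete_only = TRUE) {
  tokenization <- match.arg(tokenization)
  ties <- match.arg(ties)
  recs <- corpus$recordings
  if (complete_only) recs <- Filter(function(r) r$complete, recs)
  out <- lapply(recs, function(r) {
    seqs <- lapply(r$cycles, function(cy) {
      if (tokenization == "theme") as.character(collapse_to_themes(cy$phrases))
      else cy$phrases
    })
    med <- set_median(seqs, ties = ties)
    attr(med, "index") <- NULL
    med
  })
  names(out) <- vapply(recs, `[[`, character(1), "singer_id")
  out
}

as_similarity_matrix <- function(S) {
  validate_similarity_matrix(S)
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Validate a similarity matrix
#'
#' Checks symmetry, unit diagonal and the `[0, 1]` range.
#'
#' @param S numeric matrix with identical row and column labels.
#' @return `S`, invisibly; errors on violation.
#' @export
validate_similarity_matrix <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S))) {
    stop("similarity matrix must carry identical row and column labels")
  }
  if (max(abs(S - t(S))) > 1e-12) stop("similarity matrix must be symmetric")
  if (any(abs(diag(S) - 1) > 1e-12)) stop("diagonal must be 1")
  if (min(S) < -1e-12 || max(S) > 1 + 1e-12) stop("values must lie in [0, 1]")
  invisible(S)
}

#' @export
print.similarity_matrix <- function(x, digits = 3, ...) {
  cat("similarity_matrix:", nrow(x), "objects\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Read and write labelled similarity matrices as CSV
#'
#' The on-disk form is a labelled square CSV, identical for LSI and Dice
#' matrices so the clustering functions consume either.
#'
#' @param S a `similarity_matrix`.
#' @param path file path.
#' @return `read_similarity_matrix()` returns a `similarity_matrix`.
#' @export
write_similarity_matrix <- function(S, path) {
  utils::write.csv(unclass(S), path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_similarity_matrix(as.matrix(tab))
}
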