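# Independent oracles used to check the package implementations.

# Breadth-first edit-script search: expand the frontier of reachable
# alignment states one edit at a time, sliding along free matches, until
# the end state is reached. Independent of the dynamic-programming table.
lev_bfs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  m <- length(a); n <- length(b)
  slide <- function(st) {
    i <- st[[1L]]; j <- st[[2L]]
    while (i < m && j < n && a[i + 1L] == b[j + 1L]) {
      i <- i + 1L; j <- j + 1L
    }
    c(i, j)
  }
  enc <- function(st) st[1L] * (n + 1L) + st[2L]
  frontier <- list(slide(c(0L, 0L)))
  seen <- enc(frontier[[1L]])
  d <- 0L
  repeat {
    if (any(vapply(frontier, function(s) s[1L] == m && s[2L] == n,
                   logical(1)))) {
      return(d)
    }
    nxt <- list()
    for (st in frontier) {
      i <- st[1L]; j <- st[2L]
      cand <- list()
      if (i < m) cand <- c(cand, list(c(i + 1L, j)))          # deletion
      if (j < n) cand <- c(cand, list(c(i, j + 1L)))          # insertion
      if (i < m && j < n) cand <- c(cand, list(c(i + 1L, j + 1L)))  # subst
      for (cc in cand) {
        cc <- slide(cc)
        key <- enc(cc)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt <- c(nxt, list(cc))
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
}

# every token sequence of length 0..maxlen over an alphabet
all_token_seqs <- function(alphabet, maxlen) {
  out <- list(character(0))
  for (len in seq_len(maxlen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      unname(unlist(grid[i, ], use.names = FALSE))
    }))
  }
  out
}

# exhaustive set median via the BFS distance oracle
set_median_oracle <- function(seqs) {
  sums <- vapply(seq_along(seqs), function(i) {
    sum(vapply(seq_along(seqs), function(j) {
      lev_bfs(seqs[[i]], seqs[[j]])
    }, numeric(1)))
  }, numeric(1))
  seqs[[which.min(sums)]]
}

# from-scratch average-linkage agglomeration: cluster distances recomputed
# as means of the original pairwise distances (no Lance-Williams update),
# returning the cophenetic matrix
upgma_oracle_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1L]]]; b <- clusters[[best[2L]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1L]]] <- c(a, b)
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# Bartlett statistic written out from its textbook formula
bartlett_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- tabulate(groups)
  N <- sum(ni)
  vi <- tapply(values, groups, var)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / C
}

# random token sequences for property tests
random_seqs <- function(n, alphabet = c("a", "b", "c"), max_len = 6) {
  lapply(seq_len(n), function(i) {
    sample(alphabet, sample.int(max_len, 1L), replace = TRUE)
  })
}

# small corpus with unit-level detail, built in code
toy_unit_corpus <- function() {
  cyc <- function(idx, phrases, units, t0 = 0) {
    n <- length(phrases)
    onset <- t0 + (seq_len(n) - 1L) * 10
    song_cycle(idx, phrases, units = units,
               onset_s = onset, offset_s = onset + 8)
  }
  r1 <- singer_recording(
    "W1", 2011, "Kerama", "2011-02-16", 600,
    list(cyc(1, c("1a", "2", "3a"),
             list(c("u1", "u2", "u1"), c("u3", "u3"), c("u4"))),
         cyc(2, c("1a", "3a"),
             list(c("u1", "u2"), c("u4", "u4")), t0 = 100)))
  r2 <- singer_recording(
    "W2", 2011, "Motobu", "2011-02-20", 500,
    list(cyc(1, c("2", "3a"),
             list(c("u3", "u5"), c("u4", "u1", "u4")))))
  song_corpus(list(r1, r2), provenance = "toy")
}
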