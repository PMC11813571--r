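#' Convert a similarity matrix to a distance matrix
#'
#' Two conventions are offered. `"complement"` is the elementwise
#' `d = 1 - s` (bounded, zero diagonal). `"profile_correlation"` treats each
#' object's vector of similarities to all objects as its feature profile and
#' returns `1 - Pearson correlation` between profiles — the convention a
#' similarity matrix receives when it is clustered as a data matrix by
#' multiscale-bootstrap cluster software, and the one under which the
#' package reproduces the published Okinawa dendrograms (see the vignette).
#'
#' @param S a `similarity_matrix` (or labelled symmetric matrix).
#' @param method `"complement"` or `"profile_correlation"`.
#' @return Symmetric distance matrix with zero diagonal and the same labels.
#' @export
to_distance <- function(S, method = c("complement", "profile_correlation")) {
  method <- match.arg(method)
  S <- unclass(S)
  D <- switch(method,
    complement = 1 - S,
    profile_correlation = {
      C <- suppressWarnings(stats::cor(S))
      C[is.na(C)] <- 0
      1 - C
    })
  diag(D) <- 0
  D
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Unweighted pair-group agglomeration: at each step the two clusters at
#' minimal average inter-cluster distance are merged, and the merge node's
#' height is that average distance. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest member label), so results do not depend on input order.
#'
#' @param D symmetric distance matrix (or `dist`) with zero diagonal and
#'   unique labels; no `NA` entries.
#' @return An object of class `hclust` (usable with [stats::cophenetic()],
#'   `plot()`, [ape::as.phylo()], ...).
#' @examples
#' D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(D)$height  # 0.2, then (0.6 + 0.8) / 2 = 0.7
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least two objects")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (any(is.na(D))) stop("NA entries in distance matrix")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")

  M <- D                     # current cluster-level distances
  size <- rep(1L, n)
  id <- -seq_len(n)          # hclust coding: negative leaves
  key <- labels              # smallest member label per active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_len(length(act) - 1L)) {
      for (jj in (ii + 1L):length(act)) {
        i <- act[ii]; j <- act[jj]
        d <- M[i, j]
        pk <- sort(c(key[i], key[j]))
        better <- d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 &&
             (pk[1L] < best_key[1L] ||
                (pk[1L] == best_key[1L] && pk[2L] < best_key[2L])))
        if (better) {
          best <- c(i, j); best_d <- d; best_key <- pk
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    # record merge with leaves before internal nodes, as hclust does
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- best_d
    # Lance-Williams update for unweighted average linkage
    upd <- (size[i] * M[i, act] + size[j] * M[j, act]) / (size[i] + size[j])
    M[i, act] <- upd
    M[act, i] <- upd
    M[i, i] <- 0
    size[i] <- size[i] + size[j]
    id[i] <- step
    key[i] <- min(key[i], key[j])
    active[j] <- FALSE
  }

  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) ord <<- c(ord, -node)
    else { walk(merge[node, 1L]); walk(merge[node, 2L]) }
  }
  walk(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Cophenetic correlation coefficient (CCC)
#'
#' Pearson correlation between the lower-triangle entries of the input
#' distance matrix and the cophenetic distances implied by a dendrogram.
#' Values above 0.8 are conventionally taken as a good fit of the tree to
#' the data.
#'
#' @param D the distance matrix the tree was built from.
#' @param tree an `hclust` object over `D`'s labels.
#' @return Correlation in `[-1, 1]`.
#' @export
ccc <- function(D, tree) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("CCC is undefined for fewer than 3 leaves")
  if (!setequal(rownames(D), tree$labels)) {
    stop("tree labels do not match the distance matrix")
  }
  D <- D[tree$labels, tree$labels]
  stats::cor(as.numeric(stats::as.dist(D)),
             as.numeric(stats::cophenetic(tree)))
}

# leaf-label sets of every internal node, indexed by merge row
clade_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- character(0)
    for (k in 1:2) {
      ch <- tree$merge[i, k]
      members <- c(members,
                   if (ch < 0L) tree$labels[-ch] else sets[[ch]])
    }
    sets[[i]] <- sort(members)
  }
  sets
}

#' Fit the multiscale-bootstrap model for one node
#'
#' Given bootstrap proportions `BP(r)` of a clade at several resampling
#' scales `r` (replicate size = `ceiling(r * n)` of `n` features), fits
#' `qnorm(1 - BP(r)) = v * sqrt(r) + c / sqrt(r)` by weighted least squares
#' with binomial-variance weights, where `v` estimates the signed distance
#' of the data from the clade's boundary and `c` its curvature. The
#' approximately unbiased probability is `AU = 1 - pnorm(v - c)`; the plain
#' bootstrap probability is `BP` at `r = 1`. Proportions of exactly 0 or 1
#' receive a continuity correction of `0.5 / B`.
#'
#' @param bp numeric vector of bootstrap proportions, one per scale.
#' @param scales positive resampling scales.
#' @param B number of bootstrap replicates per scale.
#' @return List with `v`, `c`, `au` (percent), `bp` (percent, at the scale
#'   closest to 1). `au` is `NA` when fewer than two usable scales remain.
#' @export
fit_multiscale <- function(bp, scales, B) {
  stopifnot(length(bp) == length(scales), all(scales > 0))
  usable <- is.finite(bp)
  bp_report <- 100 * bp[usable][which.min(abs(scales[usable] - 1))]
  if (sum(usable) < 2L) {
    return(list(v = NA_real_, c = NA_real_, au = NA_real_, bp = bp_report))
  }
  # saturated nodes: the signed-distance model degenerates, so AU is
  # capped at the corresponding extreme rather than fitted
  if (all(bp[usable] == 1)) {
    return(list(v = -Inf, c = 0, au = 100, bp = bp_report))
  }
  if (all(bp[usable] == 0)) {
    return(list(v = Inf, c = 0, au = 0, bp = bp_report))
  }
  p <- pmin(pmax(bp[usable], 0.5 / B), 1 - 0.5 / B)
  r <- scales[usable]
  z <- stats::qnorm(1 - p)
  w <- B * stats::dnorm(z)^2 / (p * (1 - p))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  XtW <- t(X * w)
  beta <- tryCatch(solve(XtW %*% X, XtW %*% z),
                   error = function(e) NULL)
  if (is.null(beta)) {
    return(list(v = NA_real_, c = NA_real_, au = NA_real_, bp = bp_report))
  }
  v <- beta[1L]; cc <- beta[2L]
  list(v = v, c = cc, au = 100 * (1 - stats::pnorm(v - cc)), bp = bp_report)
}

#' Multiscale bootstrap supports for UPGMA clades
#'
#' Resamples the rows of a feature-profile matrix at several scales,
#' reclusters each replicate, records how often every clade of the
#' reference tree reappears, and fits the multiscale model
#' ([fit_multiscale()]) per clade to obtain approximately unbiased (AU) and
#' plain bootstrap (BP) probabilities. AU > 95 is conventionally read as
#' significant support, BP > 70 as strong plain support.
#'
#' For trees built from a similarity matrix the natural profile is the
#' similarity matrix itself (each object's row of similarities is its
#' feature vector), with `dist_method = "correlation"`.
#'
#' @param profile numeric matrix, features in rows, objects in columns
#'   (column names label the objects).
#' @param B bootstrap replicates per scale (default 1000, >= 100).
#' @param scales resampling scales `r` (default `0.5, 0.6, ..., 1.4`).
#' @param dist_method distance between resampled object profiles:
#'   `"correlation"` (`1 - cor`, default) or `"euclidean"`.
#' @param seed optional integer seed for reproducible resampling.
#' @param tree optional reference `hclust` tree whose clades are scored;
#'   defaults to the UPGMA tree of the full profile.
#' @return An object of class `support_fit`: a data frame with one row per
#'   internal node of the reference tree (`node`, `members`, `bp`, `au`,
#'   `v`, `c`), with the reference `hclust` tree in `attr(, "tree")` and the
#'   per-scale proportions in `attr(, "bp_by_scale")`.
#' @export
bootstrap_support <- function(profile, B = 1000,
                              scales = seq(0.5, 1.4, by = 0.1),
                              dist_method = c("correlation", "euclidean"),
                              seed = NULL, tree = NULL) {
  dist_method <- match.arg(dist_method)
  stopifnot(is.matrix(profile), B >= 100, all(scales > 0))
  if (is.null(colnames(profile))) {
    colnames(profile) <- as.character(seq_len(ncol(profile)))
  }
  if (!is.null(seed)) set.seed(seed)
  nf <- nrow(profile)
  prof_dist <- function(P) {
    if (dist_method == "correlation") {
      C <- suppressWarnings(stats::cor(P))
      C[is.na(C)] <- 0
      D <- 1 - C
      diag(D) <- 0
      D
    } else {
      as.matrix(stats::dist(t(P)))
    }
  }
  ref_tree <- if (is.null(tree)) upgma(prof_dist(profile)) else tree
  ref_clades <- clade_sets(ref_tree)
  clade_key <- vapply(ref_clades, paste, "", collapse = "\r")

  counts <- matrix(0L, length(ref_clades), length(scales))
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * nf)
    for (b in seq_len(B)) {
      idx <- sample.int(nf, m, replace = TRUE)
      tr <- upgma(prof_dist(profile[idx, , drop = FALSE]))
      hit <- vapply(clade_sets(tr), paste, "", collapse = "\r")
      counts[, si] <- counts[, si] + (clade_key %in% hit)
    }
  }
  bp_by_scale <- counts / B
  dimnames(bp_by_scale) <- list(NULL, paste0("r=", scales))

  fits <- lapply(seq_along(ref_clades), function(i) {
    fit_multiscale(bp_by_scale[i, ], scales, B)
  })
  out <- data.frame(
    node = seq_along(ref_clades),
    members = vapply(ref_clades, paste, "", collapse = ","),
    bp = vapply(fits, `[[`, numeric(1), "bp"),
    au = vapply(fits, `[[`, numeric(1), "au"),
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    stringsAsFactors = FALSE)
  attr(out, "tree") <- ref_tree
  attr(out, "bp_by_scale") <- bp_by_scale
  class(out) <- c("support_fit", "data.frame")
  out
}

#' Export a dendrogram to Newick text
#'
#' Branch lengths follow the usual ultrametric convention (a leaf branch is
#' half the pairwise merge height); AU/BP supports, when given, are written
#' as internal-node labels of the form `"au/bp"` (rounded percent). The
#' output parses back to an identical topology.
#'
#' @param tree an `hclust` object (e.g. from [upgma()]).
#' @param supports optional `support_fit` from [bootstrap_support()] for the
#'   same tree.
#' @return Newick string (terminated by `";"`).
#' @export
to_newick <- function(tree, supports = NULL) {
  phy <- ape::as.phylo(tree)
  if (!is.null(supports)) {
    want <- lapply(strsplit(supports$members, ","), sort)
    pp <- ape::prop.part(phy)
    tip <- attr(pp, "labels")
    labs <- character(phy$Nnode)
    for (i in seq_len(phy$Nnode)) {
      members <- sort(tip[pp[[i]]])
      hit <- which(vapply(want, identical, logical(1), members))
      if (length(hit) == 1L) {
        labs[i] <- sprintf("%.0f/%.0f", supports$au[hit], supports$bp[hit])
      }
    }
    phy$node.label <- labs
  }
  ape::write.tree(phy)
}

#' Cluster a similarity matrix and assess the fit
#'
#' The standard pipeline from a similarity matrix to a supported
#' dendrogram: convert to distances ([to_distance()]; profile-correlation
#' by default, mirroring the published analysis), cluster with [upgma()],
#' compute the cophenetic correlation ([ccc()]), and optionally attach
#' AU/BP supports ([bootstrap_support()] on the similarity profiles).
#'
#' @param S a `similarity_matrix`.
#' @param distance distance convention, `"profile_correlation"` (default)
#'   or `"complement"`.
#' @param bootstrap logical; compute AU/BP node supports.
#' @param B,scales,seed passed to [bootstrap_support()].
#' @return An object of class `song_clustering`: list with `tree`
#'   (`hclust`), `dist`, `ccc`, `support` (or `NULL`), `distance`.
#' @export
cluster_similarity <- function(S,
                               distance = c("profile_correlation",
                                            "complement"),
                               bootstrap = FALSE, B = 1000,
                               scales = seq(0.5, 1.4, by = 0.1),
                               seed = NULL) {
  distance <- match.arg(distance)
  D <- to_distance(S, method = distance)
  tree <- upgma(D)
  support <- NULL
  if (bootstrap) {
    support <- bootstrap_support(unclass(S), B = B, scales = scales,
                                 dist_method = if (distance == "complement")
                                   "euclidean" else "correlation",
                                 seed = seed, tree = tree)
  }
  structure(list(tree = tree, dist = D, ccc = ccc(D, tree),
                 support = support, distance = distance),
            class = "song_clustering")
}

#' @export
print.song_clustering <- function(x, ...) {
  cat("song_clustering:", length(x$tree$labels), "objects,",
      x$distance, "distance, CCC =", round(x$ccc, 3), "\n")
  if (!is.null(x$support)) {
    cat("AU/BP supports over", ncol(attr(x$support, "bp_by_scale")),
        "scales\n")
  }
  invisible(x)
}
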