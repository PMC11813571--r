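dmat <- function(v, labels) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[lower.tri(D)] <- v
  D + t(D)
}

test_that("similarity-to-distance conversions behave as stated", {
  S <- lsi_matrix(list(A = c("x", "y"), B = c("x", "y"), C = c("p", "q")))
  D <- to_distance(S)
  expect_equal(D["A", "B"], 0)
  expect_equal(D["A", "C"], 1)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  expect_equal(D, t(D))
  Dc <- to_distance(S, "profile_correlation")
  expect_equal(diag(Dc), c(A = 0, B = 0, C = 0))
  expect_equal(Dc, t(Dc))
})

test_that("UPGMA reproduces hand-computed merges and heights", {
  D2 <- dmat(0.2, c("A", "B"))
  t2 <- upgma(D2)
  expect_equal(t2$height, 0.2)
  D3 <- dmat(c(0.2, 0.6, 0.8), c("A", "B", "C"))  # AB, AC, BC
  t3 <- upgma(D3)
  expect_equal(t3$height, c(0.2, 0.7))            # (0.6 + 0.8) / 2
  coph <- as.matrix(stats::cophenetic(t3))
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.7)
})

test_that("UPGMA is exact on ultrametric input", {
  # build an ultrametric by reading cophenetic distances off a known tree
  D <- dmat(c(0.1, 0.5, 0.5, 0.5, 0.5, 0.3), c("A", "B", "C", "D"))
  tr <- upgma(D)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(D), rownames(D)],
               D)
  expect_equal(ccc(D, tr), 1)
})

test_that("UPGMA agrees with hclust and the exhaustive oracle on random matrices", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    D <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
    dimnames(D) <- list(LETTERS[1:n], LETTERS[1:n])
    mine <- upgma(D)
    ref <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(as.matrix(stats::cophenetic(mine)),
                 as.matrix(stats::cophenetic(ref)))
    expect_equal(as.matrix(stats::cophenetic(mine))[rownames(D), rownames(D)],
                 upgma_oracle_cophenetic(D))
  }
})

test_that("UPGMA tie-breaks are deterministic under input reordering", {
  D <- dmat(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), c("B", "A", "C", "D"))
  t1 <- upgma(D)
  perm <- c("D", "C", "A", "B")
  t2 <- upgma(D[perm, perm])
  lab <- sort(rownames(D))
  expect_equal(as.matrix(stats::cophenetic(t1))[lab, lab],
               as.matrix(stats::cophenetic(t2))[lab, lab])
  # all distances tied: first merge joins the lexicographically least pair
  first_pair <- sort(t1$labels[-t1$merge[1, ]])
  expect_equal(first_pair, c("A", "B"))
})

test_that("UPGMA rejects degenerate input", {
  D <- dmat(0.2, c("A", "B"))
  D[1, 2] <- NA; D[2, 1] <- NA
  expect_error(upgma(D), "NA")
  expect_error(upgma(matrix(0, 1, 1)), "two")
})

test_that("cophenetic correlation matches a hand-computed example", {
  D3 <- dmat(c(0.2, 0.6, 0.8), c("A", "B", "C"))
  r <- ccc(D3, upgma(D3))
  expect_equal(r, stats::cor(c(0.2, 0.6, 0.8), c(0.2, 0.7, 0.7)))
  expect_equal(round(r, 3), 0.945)
  expect_error(ccc(dmat(0.2, c("A", "B")), upgma(dmat(0.2, c("A", "B")))),
               "3 leaves")
})

test_that("CCC is exactly one on generated ultrametric matrices", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    base <- as.matrix(stats::dist(matrix(rnorm(n * 2), n)))
    dimnames(base) <- list(letters[1:n], letters[1:n])
    U <- as.matrix(stats::cophenetic(upgma(base)))  # ultrametric by construction
    expect_equal(ccc(U, upgma(U)), 1)
  }
})

test_that("the multiscale fit matches its analytic special cases", {
  scales <- seq(0.5, 1.4, by = 0.1)
  # BP = 1/2 at every scale: v = c = 0, AU = 50
  f <- fit_multiscale(rep(0.5, length(scales)), scales, B = 1000)
  expect_equal(f$v, 0, tolerance = 1e-10)
  expect_equal(f$c, 0, tolerance = 1e-10)
  expect_equal(f$au, 50)
  expect_equal(f$bp, 50)
  # exact model values are recovered, and AU = 1 - pnorm(v - c)
  for (vc in list(c(0.5, 0.3), c(-0.4, 0.2), c(1.1, 0))) {
    bp <- 1 - stats::pnorm(vc[1] * sqrt(scales) + vc[2] / sqrt(scales))
    f <- fit_multiscale(bp, scales, B = 1000)
    expect_equal(f$v, vc[1], tolerance = 1e-6)
    expect_equal(f$c, vc[2], tolerance = 1e-6)
    expect_equal(f$au, 100 * (1 - stats::pnorm(vc[1] - vc[2])),
                 tolerance = 1e-6)
  }
  # with c = 0 the AU equals the normal-theory probability implied by BP(1)
  bp0 <- 1 - stats::pnorm(0.8 * sqrt(scales))
  f0 <- fit_multiscale(bp0, scales, B = 1000)
  expect_equal(f0$au / 100, 1 - stats::pnorm(0.8), tolerance = 1e-6)
  expect_equal(f0$au, f0$bp, tolerance = 1e-4)
  # AU is monotone in v - c
  aus <- vapply(seq(-1, 1, by = 0.25), function(v) {
    bp <- 1 - stats::pnorm(v * sqrt(scales) + 0.2 / sqrt(scales))
    fit_multiscale(bp, scales, B = 1000)$au
  }, numeric(1))
  expect_true(all(diff(aus) < 0))
  # a single usable scale leaves AU undefined rather than guessed
  expect_true(is.na(fit_multiscale(0.4, 1, B = 100)$au))
})

test_that("well-separated blocks receive decisive AU/BP support", {
  set.seed(14)
  blocks <- rep(c(1, -1), each = 4)
  profile <- t(sapply(1:30, function(i) {
    rnorm(1) * blocks + rnorm(8, sd = 0.3)
  }))
  colnames(profile) <- paste0("o", 1:8)
  sup <- bootstrap_support(profile, B = 200, scales = seq(0.6, 1.4, 0.2),
                           seed = 15)
  b1 <- paste(sort(paste0("o", 1:4)), collapse = ",")
  b2 <- paste(sort(paste0("o", 5:8)), collapse = ",")
  for (b in c(b1, b2)) {
    row <- sup[sup$members == b, ]
    expect_equal(nrow(row), 1L)
    expect_gte(row$au, 95)
    expect_gte(row$bp, 70)
  }
  bps <- attr(sup, "bp_by_scale")
  expect_true(all(bps >= 0 & bps <= 1))
})

test_that("Newick export carries halved branch lengths and round-trips", {
  t2 <- upgma(dmat(0.2, c("A", "B")))
  expect_true(to_newick(t2) %in% c("(A:0.1,B:0.1);", "(B:0.1,A:0.1);"))
  D3 <- dmat(c(0.2, 0.6, 0.8), c("A", "B", "C"))
  t3 <- upgma(D3)
  nwk <- to_newick(t3)
  phy <- ape::read.tree(text = nwk)
  expect_true(ape::is.monophyletic(phy, c("A", "B")))
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # supports appear as node labels and topology survives
  set.seed(16)
  profile <- t(sapply(1:20, function(i) {
    rnorm(1) * c(1, 1, -1, -1) + rnorm(4, sd = 0.4)
  }))
  colnames(profile) <- letters[1:4]
  sup <- bootstrap_support(profile, B = 100, scales = c(0.8, 1, 1.2),
                           seed = 17)
  nwk2 <- to_newick(attr(sup, "tree"), supports = sup)
  expect_match(nwk2, "\\)[0-9]+/[0-9]+")
  phy2 <- ape::read.tree(text = nwk2)
  expect_setequal(phy2$tip.label, letters[1:4])
})

test_that("the clustering pipeline reports tree, distance and fit together", {
  S <- dice_matrix(okinawa_song_corpus())
  cl <- cluster_similarity(S)
  expect_s3_class(cl$tree, "hclust")
  expect_equal(cl$ccc, ccc(cl$dist, cl$tree))
  cl2 <- cluster_similarity(S, distance = "complement")
  expect_equal(cl2$dist, to_distance(S, "complement"))
})
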