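tv_frame <- function(n_units, n_unit_types, duration_s, n_themes) {
  transform_complexity(data.frame(n_units = n_units,
                                  n_unit_types = n_unit_types,
                                  duration_s = duration_s,
                                  n_themes = n_themes))
}

test_that("variable transforms are logs and a square", {
  tv <- tv_frame(exp(1), exp(1), exp(1), 2)
  expect_equal(unlist(tv[c("log_units", "log_unit_types", "log_duration",
                           "themes_sq")], use.names = FALSE),
               c(1, 1, 1, 4))
  tv1 <- tv_frame(1, 1, 1, 1)
  expect_equal(unlist(tv1[c("log_units", "log_unit_types", "log_duration",
                            "themes_sq")], use.names = FALSE),
               c(0, 0, 0, 1))
  # monotone in every coordinate
  lo <- tv_frame(10, 3, 60, 2)
  hi <- tv_frame(20, 6, 120, 4)
  for (v in c("log_units", "log_unit_types", "log_duration", "themes_sq")) {
    expect_gt(hi[[v]], lo[[v]])
  }
  expect_error(tv_frame(0, 1, 1, 1), "positive")
  expect_error(tv_frame(2, 3, 1, 1), "exceed")
})

test_that("song variables count units, types, themes and span", {
  vars <- song_variables(toy_unit_corpus())
  expect_equal(nrow(vars), 3L)
  w1c1 <- vars[vars$singer_id == "W1" & vars$cycle == 1, ]
  expect_equal(w1c1$n_units, 6L)         # u1 u2 u1 u3 u3 u4
  expect_equal(w1c1$n_unit_types, 4L)
  expect_equal(w1c1$n_themes, 3L)
  expect_equal(w1c1$duration_s, 28)      # onsets 0,10,20; offsets +8
  # duplicate-free unit strings have as many types as units
  w2 <- vars[vars$singer_id == "W2" & vars$cycle == 1, ]
  expect_equal(w2$n_units, 5L)
  expect_equal(w2$n_unit_types, 4L)      # u4 repeats
  # a corpus without unit detail is refused with guidance
  expect_error(song_variables(okinawa_song_corpus()), "unit-level")
})

test_that("song variables match the generator truth record exactly", {
  gen <- generate_corpus(generator_config(seed = 21))
  vars <- song_variables(gen$corpus)
  tg <- gen$truth$song_targets
  merged <- merge(vars, tg, by = c("singer_id", "year", "cycle"))
  expect_equal(nrow(merged), nrow(vars))
  expect_equal(merged$n_units, merged$target_units)
  expect_equal(merged$n_themes, merged$target_themes)
  expect_equal(merged$duration_s, merged$target_duration_s)
})

test_that("normality and correlation reports flag what they should", {
  set.seed(22)
  n <- 40
  base <- data.frame(n_units = exp(rnorm(n, 5, 0.3)))
  base$n_unit_types <- base$n_units^1.0          # collinear on log scale
  base$duration_s <- exp(-log(base$n_units) + 10) # anti-collinear
  base$n_themes <- pmax(1, rpois(n, 5))
  tv <- transform_complexity(base)
  cr <- correlation_report(tv)
  r_ut <- cr$r[cr$var1 == "log_units" & cr$var2 == "log_unit_types"]
  r_ud <- cr$r[cr$var1 == "log_units" & cr$var2 == "log_duration"]
  expect_equal(r_ut, 1)
  expect_equal(r_ud, -1)
  # independent normals: small correlation, W near 1
  ind <- data.frame(n_units = exp(rnorm(200, 5, 0.2)),
                    n_unit_types = exp(rnorm(200, 3, 0.2)),
                    duration_s = exp(rnorm(200, 6, 0.2)),
                    n_themes = 5)
  ind$n_unit_types <- pmin(ind$n_unit_types, ind$n_units)
  tvi <- transform_complexity(ind)
  cri <- correlation_report(tvi)
  r_ui <- cri$r[cri$var1 == "log_units" & cri$var2 == "log_duration"]
  expect_lt(abs(r_ui), 0.2)
  nr <- normality_report(tvi)
  expect_gt(nr$W[nr$variable == "log_units"], 0.98)
  # constant column reported as NA, not dropped
  expect_true(any(is.na(cri$r[cri$var1 == "themes_sq" |
                                cri$var2 == "themes_sq"])))
})

test_that("PCA scores follow the stated conventions", {
  set.seed(23)
  x <- rnorm(20)
  same <- data.frame(n_units = exp(x), n_unit_types = exp(x),
                     duration_s = exp(x), n_themes = round(exp(x / 2) + 2))
  same$n_themes <- NULL
  # four identical standardised columns: equal loadings, full variance
  tv <- data.frame(log_units = x, log_unit_types = x,
                   log_duration = x, themes_sq = x)
  cs <- complexity_scores(tv)
  expect_equal(unname(cs$loadings), rep(0.5, 4))
  expect_equal(unname(cs$variance_fraction), 1)
  # sign convention: loading on log_units positive even for negated data
  tv2 <- data.frame(log_units = -x, log_unit_types = -x,
                    log_duration = -x + rnorm(20, sd = 0.1),
                    themes_sq = -x + rnorm(20, sd = 0.1))
  cs2 <- complexity_scores(tv2)
  expect_gt(cs2$loadings[["log_units"]], 0)
  # scores are invariant to row reordering (up to the same reordering)
  perm <- sample(20)
  cs3 <- complexity_scores(tv2[perm, ])
  expect_equal(cs3$scores$pc1, cs2$scores$pc1[perm])
  # squared loadings sum to one per component; variance fractions sum to 1
  expect_equal(colSums(cs2$loading_matrix^2), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(sum(cs2$sdev^2) / sum(cs2$sdev^2), 1)
  expect_error(complexity_scores(tv[1:4, ]), "5 songs")
})

test_that("per-singer averages reduce songs to one score per singer-year", {
  sc <- data.frame(singer_id = c("a", "a", "b"), year = 2011,
                   pc1 = c(1.5, -1.5, 2))
  avg <- average_by_singer(sc)
  expect_equal(avg$score[avg$singer_id == "a"], 0)
  expect_equal(avg$score[avg$singer_id == "b"], 2)
  gen <- generate_corpus(generator_config(seed = 24))
  cs <- complexity_scores(transform_complexity(song_variables(gen$corpus)))
  avg2 <- average_by_singer(cs$scores)
  direct <- tapply(cs$scores$pc1, cs$scores$singer_id, mean)
  expect_equal(avg2$score, as.numeric(direct[avg2$singer_id]))
})

test_that("the Bartlett statistic matches its textbook formula", {
  vals <- c(0, 2, 0, 4)
  grp <- c("a", "a", "b", "b")
  b <- bartlett_by_year(vals, grp)
  expect_equal(b$k_squared, bartlett_oracle(vals, grp), tolerance = 1e-10)
  expect_equal(round(b$k_squared, 4), 0.2975)
  expect_equal(b$df, 1)
  # equal variances give a zero statistic
  eq <- bartlett_by_year(c(0, 2, 5, 7, 10, 12), rep(c("a", "b", "c"),
                                                    each = 2))
  expect_equal(eq$k_squared, 0, tolerance = 1e-10)
  expect_error(bartlett_by_year(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "zero")
  expect_error(bartlett_by_year(1:4, rep("a", 4)), "two year")
})

test_that("the year model reduces to the pooled two-sample t for two groups", {
  set.seed(25)
  x <- rnorm(8); y <- rnorm(6, mean = 1)
  fit <- year_regression(c(x, y), rep(c(2011, 2012), c(8, 6)))
  tt <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(fit$coefficients$t[2], unname(tt$statistic),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$p[2], tt$p.value, tolerance = 1e-10)
  expect_equal(fit$df[2], fit$n - 2)
  # identical group means: F (and slope) vanish
  flat <- year_regression(rep(c(1, 2), 4), rep(c(2011, 2012), each = 4))
  expect_equal(flat$f_statistic, 0, tolerance = 1e-10)
  # reference level is the earliest year regardless of input order
  fit2 <- year_regression(c(y, x), rep(c(2012, 2011), c(6, 8)))
  expect_equal(fit2$reference_year, "2011")
  expect_equal(fit2$coefficients$t[2], fit$coefficients$t[2])
  expect_warning(year_regression(c(1, 2, 3), c(2011, 2011, 2012)),
                 "single observation")
})
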