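#' Raw complexity variables per song
#'
#' For every song cycle with unit-level detail, counts the number of units,
#' the number of distinct unit types, the song duration (last unit offset
#' minus first unit onset, in seconds) and the number of distinct themes.
#' These four variables are the inputs of the song-complexity score.
#'
#' @param corpus a [song_corpus()] carrying unit tokens and phrase times.
#' @param complete_only drop recordings flagged incomplete (default `TRUE`).
#' @return Data frame with columns `singer_id`, `year`, `cycle`, `n_units`,
#'   `n_unit_types`, `duration_s`, `n_themes`.
#' @export
song_variables <- function(corpus, complete_only = TRUE) {
  recs <- corpus$recordings
  if (complete_only) recs <- Filter(function(r) r$complete, recs)
  rows <- list()
  for (r in recs) {
    for (cy in r$cycles) {
      if (is.null(cy$units) || is.null(cy$onset_s)) {
        stop("recording ", r$singer_id, " lacks unit-level detail; ",
             "supply unit tokens and phrase times (or a generated corpus)")
      }
      tokens <- unlist(cy$units, use.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        singer_id = r$singer_id, year = r$year, cycle = cy$index,
        n_units = length(tokens),
        n_unit_types = length(unique(tokens)),
        duration_s = max(cy$offset_s) - min(cy$onset_s),
        n_themes = length(unique(theme_of(cy$phrases))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Transform complexity variables towards normality
#'
#' Unit count, unit-type count and duration are natural-log transformed;
#' the left-skewed theme count is square transformed. (The log base only
#' rescales a column and is absorbed when the variables are standardised
#' for the PCA.)
#'
#' @param vars data frame from [song_variables()] (columns `n_units`,
#'   `n_unit_types`, `duration_s`, `n_themes`, all positive).
#' @return The input with columns `log_units`, `log_unit_types`,
#'   `log_duration`, `themes_sq` appended.
#' @export
transform_complexity <- function(vars) {
  need <- c("n_units", "n_unit_types", "duration_s", "n_themes")
  stopifnot(all(need %in% names(vars)))
  if (any(vars[need] <= 0)) stop("complexity variables must be positive")
  if (any(vars$n_unit_types > vars$n_units)) {
    stop("n_unit_types cannot exceed n_units")
  }
  vars$log_units <- log(vars$n_units)
  vars$log_unit_types <- log(vars$n_unit_types)
  vars$log_duration <- log(vars$duration_s)
  vars$themes_sq <- vars$n_themes^2
  vars
}

transformed_cols <- c("log_units", "log_unit_types", "log_duration",
                      "themes_sq")

#' Shapiro-Wilk normality report for the transformed variables
#'
#' @param tv data frame from [transform_complexity()] (n >= 3).
#' @return Data frame with per-variable `W` and `p` (reported, not gating).
#' @export
normality_report <- function(tv) {
  stopifnot(nrow(tv) >= 3L)
  res <- lapply(transformed_cols, function(v) {
    if (stats::sd(tv[[v]]) == 0) {
      return(data.frame(variable = v, W = NA_real_, p = NA_real_))
    }
    s <- stats::shapiro.test(tv[[v]])
    data.frame(variable = v, W = unname(s$statistic), p = s$p.value)
  })
  do.call(rbind, res)
}

#' Pairwise Pearson correlation report for the transformed variables
#'
#' @param tv data frame from [transform_complexity()] (n >= 3).
#' @return Data frame of all variable pairs with `r` and `p`; a pair
#'   involving a constant column is reported with `NA` rather than dropped.
#' @export
correlation_report <- function(tv) {
  stopifnot(nrow(tv) >= 3L)
  pairs <- utils::combn(transformed_cols, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- tv[[pr[1L]]]; y <- tv[[pr[2L]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(var1 = pr[1L], var2 = pr[2L],
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(var1 = pr[1L], var2 = pr[2L],
               r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' PCA song-complexity scores
#'
#' Runs a principal components analysis of the four transformed variables
#' and extracts the first component score of each song as its complexity
#' score. Variables are standardised (correlation-matrix PCA) by default;
#' `standardize = FALSE` uses the covariance matrix. The component sign is
#' oriented so the loading on `log_units` is positive — more units means
#' higher complexity.
#'
#' @param tv data frame from [transform_complexity()] (>= 5 songs).
#' @param standardize use the correlation matrix (default `TRUE`).
#' @return List with `scores` (input id columns plus `pc1`), `loadings`
#'   (4-vector for PC1), `loading_matrix`, `variance_fraction` (share of
#'   variance on PC1), `sdev`.
#' @export
complexity_scores <- function(tv, standardize = TRUE) {
  stopifnot(all(transformed_cols %in% names(tv)))
  if (nrow(tv) < 5L) stop("need at least 5 songs for the PCA")
  X <- as.matrix(tv[transformed_cols])
  if (any(apply(X, 2, stats::sd) == 0) && standardize) {
    stop("constant transformed variable; correlation PCA is undefined")
  }
  pc <- stats::princomp(X, cor = standardize)
  if (pc$sdev[1L] <= .Machine$double.eps) {
    stop("no informative dimension in the complexity variables")
  }
  flip <- if (pc$loadings[1L, 1L] < 0) -1 else 1
  scores <- tv[setdiff(names(tv), transformed_cols)]
  scores$pc1 <- flip * as.numeric(pc$scores[, 1L])
  lm1 <- flip * pc$loadings[, 1L]
  list(scores = scores,
       loadings = lm1,
       loading_matrix = unclass(pc$loadings),
       variance_fraction = pc$sdev[1L]^2 / sum(pc$sdev^2),
       sdev = pc$sdev)
}

#' Average song-complexity scores per singer
#'
#' Arithmetic mean of the per-song scores within each `(singer, year)`, so
#' singers with more transcribed songs are not over-represented.
#'
#' @param scores data frame with columns `singer_id`, `year`, `pc1`.
#' @return Data frame with one `score` per `(singer_id, year)`.
#' @export
average_by_singer <- function(scores) {
  stopifnot(all(c("singer_id", "year", "pc1") %in% names(scores)))
  out <- stats::aggregate(list(score = scores$pc1),
                          by = list(singer_id = scores$singer_id,
                                    year = scores$year),
                          FUN = mean)
  out[order(out$year, out$singer_id), , drop = FALSE]
}

#' Bartlett homogeneity-of-variance test across years
#'
#' Standard Bartlett statistic (with the small-sample correction factor)
#' for equality of score variances across years.
#'
#' @param scores numeric values (e.g. per-singer mean complexity scores).
#' @param years grouping years (>= 2 groups of >= 2 values each).
#' @return List with `k_squared`, `df`, `p_value`.
#' @export
bartlett_by_year <- function(scores, years) {
  years <- factor(years)
  if (nlevels(years) < 2L) stop("need at least two year groups")
  sizes <- table(years)
  if (any(sizes < 2L)) stop("each year group needs at least two values")
  if (any(tapply(scores, years, stats::var) == 0)) {
    stop("zero within-year variance; Bartlett statistic undefined")
  }
  b <- stats::bartlett.test(scores, years)
  list(k_squared = unname(b$statistic), df = unname(b$parameter),
       p_value = b$p.value)
}

#' Linear model of complexity across years
#'
#' Ordinary least squares of per-singer scores on year as a categorical
#' predictor, indicator-coded against the earliest year. Reports each later
#' year's coefficient with its t statistic and p value (the year-vs-baseline
#' contrast), the overall F statistic with its degrees of freedom, and the
#' adjusted R-squared.
#'
#' @param scores numeric per-singer scores.
#' @param years recording years (categorical; >= 2 levels).
#' @return An object of class `year_model`: list with `coefficients` (data
#'   frame: `term`, `estimate`, `se`, `t`, `p`), `adj_r_squared`,
#'   `f_statistic`, `df` (length 2), `p_value`, `reference_year`, `n`,
#'   `singleton_years` (years with a single observation, flagged), `model`.
#' @export
year_regression <- function(scores, years) {
  years <- factor(years, levels = sort(unique(years)))
  if (nlevels(years) < 2L) stop("need at least two years")
  singleton <- names(which(table(years) == 1L))
  if (length(singleton)) {
    warning("year(s) with a single observation: ",
            paste(singleton, collapse = ", "))
  }
  dat <- data.frame(score = scores, year = years)
  fit <- stats::lm(score ~ year, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  coef_df <- data.frame(term = rownames(co), estimate = co[, 1L],
                        se = co[, 2L], t = co[, 3L], p = co[, 4L],
                        row.names = NULL, stringsAsFactors = FALSE)
  fst <- sm$fstatistic
  structure(list(coefficients = coef_df,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(fst[1L]),
                 df = unname(fst[2:3]),
                 p_value = unname(stats::pf(fst[1L], fst[2L], fst[3L],
                                            lower.tail = FALSE)),
                 reference_year = levels(years)[1L],
                 n = length(scores),
                 singleton_years = singleton,
                 model = fit),
            class = "year_model")
}

#' @export
print.year_model <- function(x, ...) {
  cat("Year model of song complexity (reference year ",
      x$reference_year, ", n = ", x$n, ")\n", sep = "")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), t = round(t, 3), p = signif(p, 3)))
  cat(sprintf("Adj R-squared = %.3f, F = %.2f on (%d, %d) df, p = %.3g\n",
              x$adj_r_squared, x$f_statistic, x$df[1L], x$df[2L],
              x$p_value))
  invisible(x)
}
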