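#' Configuration for the synthetic song-corpus generator
#'
#' Bundles the parameters of a multi-year corpus simulation with the
#' statistical structure the analysis pipeline assumes: strong within-year
#' song conformity, between-year theme evolution (labels gaining an `'e'`
#' mark), theme innovation and loss, variable theme ordering, and
#' unit-level counts and durations driven by a per-song complexity factor.
#'
#' The four complexity variables follow an explicit one-factor model on
#' their transformed scales: each song draws a common factor
#' `f ~ N(0, factor_sd^2)` and independent noise `e_i ~ N(0, noise_sd^2)`,
#' and the log unit count, log unit-type count, log duration and log
#' squared theme count are each shifted by `f + e_i` (plus the year
#' effect). With `lambda = factor_sd^2 / (factor_sd^2 + noise_sd^2)`, the
#' four standardised variables are equicorrelated with correlation
#' `lambda`, so the expected share of variance on the first principal
#' component is `(1 + 3 * lambda) / 4` — the closed-form target of the
#' parameter-recovery checks.
#'
#' @param years recording years (consecutive).
#' @param singers_per_year singers simulated per year.
#' @param cycles_per_singer transcribed song cycles per singer.
#' @param n_themes initial theme-inventory size.
#' @param variable_theme simulate one "variable" theme whose two phrase
#'   types alternate within a cycle (an alternating theme-5-like block).
#' @param alt_repeats alternation pairs sung for the variable theme.
#' @param sequence_noise per-position probability of swapping adjacent
#'   themes in a singer's sequence (within-year conformity is high when
#'   this is small).
#' @param dropout baseline per-theme omission probability per song; the
#'   factor model modulates the realised theme count around
#'   `n_themes * (1 - dropout)` (clamped at the year's inventory size).
#'   With `dropout = 0` every song carries the full inventory (the theme
#'   channel of the factor is then inactive).
#' @param evolution_rate per-theme probability of gaining an `'e'` mark
#'   from one year to the next (capped at two marks).
#' @param innovation_rate Poisson mean of new themes appearing per year.
#' @param deletion_prob per-theme probability of being lost per year.
#' @param phrase_repeats geometric parameter for the number of physical
#'   phrase repetitions per theme (mean repeats `1 + (1 - p) / p`).
#' @param base_units,base_unit_types,base_duration_s expected units, unit
#'   types and duration (s) per song at year effect 1.
#' @param unit_duration_meanlog,unit_duration_sdlog log-normal parameters
#'   of unit durations (s).
#' @param unit_gap_meanlog,unit_gap_sdlog log-normal parameters of
#'   within-phrase inter-unit gaps (s).
#' @param factor_sd,noise_sd standard deviations of the per-song common
#'   complexity factor and the per-variable noise (log scale).
#' @param year_effect multiplicative effect on expected counts per year
#'   (recycled to `length(years)`); the default mimics a
#'   decrease-then-increase complexity trajectory.
#' @param seed integer seed; the same configuration always generates the
#'   same corpus.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(years = 2011:2013,
                             singers_per_year = 5,
                             cycles_per_singer = 2,
                             n_themes = 6,
                             variable_theme = TRUE,
                             alt_repeats = 2,
                             sequence_noise = 0.1,
                             dropout = 0.3,
                             evolution_rate = 0.5,
                             innovation_rate = 1,
                             deletion_prob = 0.15,
                             phrase_repeats = 0.5,
                             base_units = 250,
                             base_unit_types = 20,
                             base_duration_s = 400,
                             unit_duration_meanlog = log(0.8),
                             unit_duration_sdlog = 0.3,
                             unit_gap_meanlog = log(0.3),
                             unit_gap_sdlog = 0.3,
                             factor_sd = 0.25,
                             noise_sd = 0.2,
                             year_effect = c(1, 0.7, 1.6),
                             seed = 1) {
  cfg <- as.list(environment())
  probs <- c(sequence_noise, dropout, evolution_rate, deletion_prob,
             phrase_repeats)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_themes < 2L) stop("need at least two themes")
  if (any(year_effect <= 0)) stop("year effects must be positive")
  for (nm in c("singers_per_year", "cycles_per_singer", "n_themes",
               "alt_repeats", "seed")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  cfg$year_effect <- rep_len(year_effect, length(years))
  structure(cfg, class = "generator_config")
}

#' Model-implied PC1 variance fraction of a generator configuration
#'
#' Evaluates the share of variance the first principal component of the
#' four transformed complexity variables is expected to carry under a
#' configuration's factor model, exactly rather than by simulation. The
#' three log-scale channels are jointly normal with correlation
#' `lambda = factor_sd^2 / (factor_sd^2 + noise_sd^2)`; the theme channel
#' passes through the integer rounding and clamping of the realised theme
#' count, whose moments are obtained by one-dimensional Gaussian
#' integration; year effects enter as a mixture over years. The result is
#' the top-eigenvalue share of the implied pooled correlation matrix. In
#' the continuous, flat-year limit this reduces to the equicorrelated
#' closed form `(1 + 3 * lambda) / 4`.
#'
#' @param config a [generator_config()] with `dropout > 0` (at zero
#'   dropout the theme channel is constant and the correlation-scale PCA
#'   is undefined).
#' @return Expected fraction of variance on PC1 (scalar in `[0.25, 1]`).
#' @export
expected_pc1_fraction <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$dropout <= 0) {
    stop("the theme channel is constant when dropout = 0")
  }
  sf2 <- config$factor_sd^2
  s2 <- sf2 + config$noise_sd^2
  s <- sqrt(s2)
  ly <- log(config$year_effect)
  base_th <- max(2, config$n_themes * (1 - config$dropout))
  cap <- config$n_themes
  g <- function(z) pmin(cap, pmax(2, round(base_th * exp(z / 2))))^2

  # per-year moments of the theme channel, z ~ N(ly, s^2)
  zg <- seq(-8, 8, length.out = 4001)
  wg <- stats::dnorm(zg); wg <- wg / sum(wg)
  mu_y <- v_y <- c_y <- numeric(length(ly))
  for (k in seq_along(ly)) {
    z <- ly[k] + s * zg
    y <- g(z)
    mu_y[k] <- sum(wg * y)
    v_y[k] <- sum(wg * y^2) - mu_y[k]^2
    # cov with the common factor: E[f | z] = (sf2 / s2) (z - ly)
    c_y[k] <- (sf2 / s2) * sum(wg * (z - ly[k]) * y)
  }
  pvar <- function(x) mean((x - mean(x))^2)
  pcov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

  var_x <- s2 + pvar(ly)                  # pooled variance, log channels
  cov_xx <- sf2 + pvar(ly)                # pooled covariance between them
  var_t <- mean(v_y) + pvar(mu_y)         # pooled variance, theme channel
  cov_xt <- mean(c_y) + pcov(ly, mu_y)

  rho <- cov_xx / var_x
  rho_t <- cov_xt / sqrt(var_x * var_t)
  R <- matrix(rho, 4, 4)
  R[4, ] <- R[, 4] <- rho_t
  diag(R) <- 1
  eigen(R, symmetric = TRUE, only.values = TRUE)$values[1L] / 4
}

# phrase-type labels of one theme record
theme_labels <- function(th) {
  paste0(th$number, th$variants, strrep("e", th$evolved))
}

# evolved unit alphabet of a theme: one token class changes per 'e' mark
theme_alphabet <- function(th, size) {
  base <- paste0("u", th$number, ".", seq_len(size))
  k <- min(th$evolved, size)
  if (k > 0) base[seq_len(k)] <- paste0(base[seq_len(k)],
                                        strrep("e", th$evolved))
  base
}

#' Generate a synthetic multi-year song corpus
#'
#' Simulates the theme inventory of each year by evolving the previous
#' year's inventory (evolution, innovation, loss), then simulates each
#' singer's song cycles: the canonical theme order perturbed by adjacent
#' swaps and factor-driven theme omission, phrase-type tokens (with an
#' alternating block for the variable theme), and timed unit strings whose
#' counts and span realise the factor-model draws described in
#' [generator_config()]. Deterministic under a fixed `seed`.
#'
#' @param config a [generator_config()].
#' @return List with `corpus` (a [song_corpus()] with unit-level detail)
#'   and `truth` (realised per-year inventories, canonical orders,
#'   per-song factor draws and targets, configured year effects, and the
#'   closed-form expected PC1 variance fraction).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  # -- year inventories ------------------------------------------------
  inv <- lapply(seq_len(cfg$n_themes), function(i) {
    list(number = i, variants = "a", evolved = 0L)
  })
  if (cfg$variable_theme) {
    vt <- min(5L, cfg$n_themes)  # a theme-5-like alternating block
    inv[[vt]]$variants <- c("a", "c")
  }
  next_theme <- cfg$n_themes + 1L
  inventories <- vector("list", length(cfg$years))
  inventories[[1L]] <- inv
  for (yi in seq_along(cfg$years)[-1L]) {
    cur <- inventories[[yi - 1L]]
    keep <- stats::runif(length(cur)) >= cfg$deletion_prob
    if (sum(keep) < 2L) keep[seq_len(2L)] <- TRUE
    cur <- cur[keep]
    cur <- lapply(cur, function(th) {
      if (stats::runif(1) < cfg$evolution_rate) {
        th$evolved <- min(th$evolved + 1L, 2L)
      }
      th
    })
    for (k in seq_len(stats::rpois(1, cfg$innovation_rate))) {
      cur[[length(cur) + 1L]] <- list(number = next_theme, variants = "a",
                                      evolved = 0L)
      next_theme <- next_theme + 1L
    }
    inventories[[yi]] <- cur
  }

  lambda <- cfg$factor_sd^2 / (cfg$factor_sd^2 + cfg$noise_sd^2)
  recordings <- list()
  targets <- list()
  singer_seq <- list()
  singer_no <- 0L

  for (yi in seq_along(cfg$years)) {
    year <- cfg$years[yi]
    inv_y <- inventories[[yi]]
    n_inv <- length(inv_y)
    # anchored to the configured inventory size so the theme channel keeps
    # a year-independent baseline (realised counts still clamp at n_inv)
    base_th <- max(2, cfg$n_themes * (1 - cfg$dropout))
    log_yeff <- log(cfg$year_effect[yi])
    # per-year theme popularity: songs omitting themes all omit the same,
    # least popular, ones (nested theme sets preserve within-year
    # conformity, as observed in real corpora where one variable theme is
    # the commonly skipped one)
    popularity <- sample.int(n_inv)
    for (si in seq_len(cfg$singers_per_year)) {
      singer_no <- singer_no + 1L
      id <- sprintf("S%02d", singer_no)
      singer_seq[[id]] <- vapply(inv_y, `[[`, integer(1), "number")
      cycles <- list()
      t0 <- 0
      for (ci in seq_len(cfg$cycles_per_singer)) {
        f <- stats::rnorm(1, 0, cfg$factor_sd)
        e <- stats::rnorm(4, 0, cfg$noise_sd)
        n_units <- max(8L, as.integer(round(
          cfg$base_units * exp(log_yeff + f + e[1L]))))
        n_types <- max(2L, as.integer(round(
          cfg$base_unit_types * exp(log_yeff + f + e[2L]))))
        duration <- cfg$base_duration_s * exp(log_yeff + f + e[3L])
        n_th <- if (cfg$dropout == 0) n_inv else
          min(n_inv, max(2L, as.integer(round(
            base_th * exp((log_yeff + f + e[4L]) / 2)))))

        use <- sort(order(popularity)[seq_len(n_th)])
        themes <- inv_y[use]
        # adjacent swaps perturb the canonical order
        ord <- seq_len(n_th)
        for (p in seq_len(n_th - 1L)) {
          if (stats::runif(1) < cfg$sequence_noise) {
            ord[c(p, p + 1L)] <- ord[c(p + 1L, p)]
          }
        }
        themes <- themes[ord]

        # phrase-type token sequence (repetitions removed; the variable
        # theme contributes an alternating block)
        tokens <- list()
        for (th in themes) {
          labs <- theme_labels(th)
          tokens[[length(tokens) + 1L]] <-
            if (length(labs) > 1L) rep(labs, cfg$alt_repeats) else labs
        }
        phrases <- unlist(tokens, use.names = FALSE)
        block_of <- rep(seq_along(themes),
                        vapply(tokens, length, integer(1)))

        # allocate unit types and unit counts over themes
        a_t <- pmax(1L, diff(round(seq(0, n_types, length.out = n_th + 1L))))
        w <- 1 + stats::rgeom(n_th, cfg$phrase_repeats)
        theme_units <- pmax(a_t, diff(round(cumsum(c(0, w)) / sum(w)
                                            * n_units)))
        # split each theme's units over its (possibly alternating) tokens
        n_tok <- length(phrases)
        units <- vector("list", n_tok)
        for (b in seq_along(themes)) {
          alphabet <- theme_alphabet(themes[[b]], a_t[b])
          tok_idx <- which(block_of == b)
          per <- pmax(1L, diff(round(seq(0, theme_units[b],
                                         length.out = length(tok_idx) + 1L))))
          for (k in seq_along(tok_idx)) {
            pat <- if (k %% 2 == 0L) rev(alphabet) else alphabet
            units[[tok_idx[k]]] <- rep(pat, length.out = per[k])
          }
        }

        # timed unit stream: small gaps within a phrase, larger between,
        # rescaled so the song spans its target duration
        onset <- numeric(n_tok); offset <- numeric(n_tok)
        t <- 0
        big_gap <- 8 * exp(cfg$unit_gap_meanlog)
        for (k in seq_len(n_tok)) {
          L <- length(units[[k]])
          dur <- stats::rlnorm(L, cfg$unit_duration_meanlog,
                               cfg$unit_duration_sdlog)
          gap <- stats::rlnorm(max(L - 1L, 0L), cfg$unit_gap_meanlog,
                               cfg$unit_gap_sdlog)
          onset[k] <- t
          t <- t + sum(dur) + sum(gap)
          offset[k] <- t
          t <- t + big_gap
        }
        span <- offset[n_tok]
        scale <- duration / span
        onset <- onset * scale + t0
        offset <- offset * scale + t0
        t0 <- offset[n_tok] + 30  # pause between cycles

        cycles[[ci]] <- song_cycle(ci, phrases, units = units,
                                   onset_s = onset, offset_s = offset)
        targets[[length(targets) + 1L]] <- data.frame(
          singer_id = id, year = year, cycle = ci, f = f,
          target_units = n_units, target_unit_types = n_types,
          target_duration_s = duration, target_themes = n_th,
          n_phrases = sum(w), stringsAsFactors = FALSE)
      }
      day <- 10 + (si - 1L) * 7  # same-site recordings a week apart
      recordings[[length(recordings) + 1L]] <- singer_recording(
        singer_id = id, year = year,
        site = if (si %% 2 == 0L) "SiteB" else "SiteA",
        date = as.Date(sprintf("%d-02-01", year)) + day,
        length_s = t0, cycles = cycles, snr_db = 15, complete = TRUE)
    }
  }

  corpus <- song_corpus(recordings,
                        provenance = sprintf("synthetic corpus (seed %d)",
                                             cfg$seed))
  truth <- list(
    inventories = lapply(inventories, function(iv) {
      sort(unlist(lapply(iv, theme_labels)))
    }),
    canonical_orders = lapply(inventories, function(iv) {
      vapply(iv, `[[`, integer(1), "number")
    }),
    singer_sequences = singer_seq,
    song_targets = do.call(rbind, targets),
    year_effect = cfg$year_effect,
    lambda = lambda,
    expected_pc1_fraction = if (cfg$dropout > 0)
      expected_pc1_fraction(cfg) else NA_real_)
  list(corpus = corpus, truth = truth)
}

#' Parameter-recovery study on synthetic corpora
#'
#' Generates a series of corpora from a configuration (varying only the
#' seed) and checks that the analysis pipeline recovers what was built in:
#' year-cluster purity of the LSI dendrogram (cutting the tree into one
#' cluster per year and scoring the majority-year fraction), the signs of
#' the fitted year effects in the complexity regression, and the PC1
#' variance fraction against its closed-form factor-model value.
#'
#' @param config a [generator_config()]; its `seed` seeds the study.
#' @param n_corpora corpora used for purity and the PC1 fraction.
#' @param n_sign_seeds corpora used for the year-effect sign check.
#' @return An object of class `recovery_report`: list with `purity`
#'   (per-corpus and mean), `sign_recovery_rate`, `pc1_fraction` (mean and
#'   per-corpus), `expected_pc1_fraction`, `n_corpora`, `n_sign_seeds`.
#' @export
recovery_suite <- function(config, n_corpora = 20, n_sign_seeds = 100) {
  stopifnot(inherits(config, "generator_config"))
  reseed <- function(k) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * k) %% .Machine$integer.max
    cfg
  }
  years <- config$years

  purity <- numeric(n_corpora)
  frac <- numeric(n_corpora)
  for (k in seq_len(n_corpora)) {
    gen <- generate_corpus(reseed(k))
    med <- median_sequences(gen$corpus)
    cl <- cluster_similarity(lsi_matrix(med))
    grp <- stats::cutree(cl$tree, k = length(years))
    singer_year <- vapply(gen$corpus$recordings, `[[`, integer(1), "year")
    names(singer_year) <- vapply(gen$corpus$recordings, `[[`,
                                 character(1), "singer_id")
    yr <- singer_year[cl$tree$labels]
    purity[k] <- sum(vapply(split(yr, grp), function(g) {
      max(table(g))
    }, numeric(1))) / length(yr)

    tv <- transform_complexity(song_variables(gen$corpus))
    frac[k] <- complexity_scores(tv)$variance_fraction
  }

  true_sign <- sign(log(config$year_effect[-1L]))
  hits <- 0L
  for (k in seq_len(n_sign_seeds)) {
    gen <- generate_corpus(reseed(n_corpora + k))
    tv <- transform_complexity(song_variables(gen$corpus))
    sc <- average_by_singer(complexity_scores(tv)$scores)
    fit <- year_regression(sc$score, sc$year)
    est <- fit$coefficients$estimate[-1L]
    if (all(sign(est) == true_sign)) hits <- hits + 1L
  }

  structure(list(purity = purity, mean_purity = mean(purity),
                 sign_recovery_rate = hits / n_sign_seeds,
                 pc1_fraction = frac, mean_pc1_fraction = mean(frac),
                 expected_pc1_fraction = if (config$dropout > 0)
                   expected_pc1_fraction(config) else NA_real_,
                 n_corpora = n_corpora, n_sign_seeds = n_sign_seeds),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0(
    "recovery_report over %d corpora (+%d for signs):\n",
    "  mean year-cluster purity  %.3f\n",
    "  year-effect sign recovery %.2f\n",
    "  mean PC1 variance share   %.3f (factor model: %.3f)\n"),
    x$n_corpora, x$n_sign_seeds, x$mean_purity, x$sign_recovery_rate,
    x$mean_pc1_fraction, x$expected_pc1_fraction))
  invisible(x)
}
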