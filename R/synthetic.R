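#' Synthetic study configuration
#'
#' Parameters of the synthetic supportive-supervision study: a multi-council
#' roster of dispensaries, health centers and hospitals under four owner
#' categories, assessed yearly 2011--2014 with a nine-section indicator
#' catalog.  Effects are specified as percentage-point gaps in the overall
#' score (the scale on which results are reported) and converted internally
#' to latent logit offsets; see Details.
#'
#' @details Each answer is drawn from a Bernoulli (or graded) response with
#' success probability
#' `plogis(mu + year_t + level_f + owner_f + u_council + delta_{f,QD} +
#'  slope * (w_i - mean(w)) - difficulty_i)`.
#' With `calibrate = TRUE` (default) the baseline and the effect offsets are
#' solved (Gauss-Hermite integration over the latent normal spread) so that
#' the marginal yes-probability gaps match the configured percentage points,
#' keeping probabilities bounded away from 0 and 1.
#'
#' @param n_councils,facilities_per_council roster size (default 8 x 20).
#' @param level_mix,owner_mix category probabilities (sum to 1).
#' @param years assessment years.
#' @param section_sizes named integer vector of indicators per section.
#' @param total_indicators optional target total; section sizes are scaled
#'   proportionally (largest-remainder, every section kept nonempty).
#' @param baseline_pct expected overall score (%) at the reference cell
#'   (2011, health_center, private_not_for_profit).
#' @param year_effects_pp,level_effects_pp,owner_effects_pp named
#'   percentage-point effects relative to the reference categories.
#' @param council_sd,qd_sd,difficulty_sd latent (logit-scale) standard
#'   deviations of the council random intercept, the facility-by-section
#'   deviation, and the per-indicator difficulty.
#' @param weight_compliance_slope logit tilt per unit of indicator weight:
#'   positive values make heavily weighted indicators more likely to be met.
#' @param graded_share_qd4 share of QD4 (medicine availability) indicators
#'   answered on the graded scale.
#' @param graded_levels number of equally spaced graded levels in \[0, 1\]
#'   (default 3: 0, 0.5, 1).
#' @param inapplicable_share probability that an indicator is restricted to
#'   health centers and hospitals (not applicable at dispensaries).
#' @param answers_per_indicator named list, section -> vector of possible
#'   answer counts (sampled uniformly).  Default: single answers except the
#'   observation/exit-interview sections (QD3A--D, QD6: 1--3).
#' @param dropout_rate probability a facility-year is unreachable (deleted).
#' @param calibrate convert percentage effects to logit offsets by marginal
#'   calibration (default) or treat them as raw logit offsets divided by 10.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_councils = 8L,
    facilities_per_council = 20L,
    level_mix = c(dispensary = 0.65, health_center = 0.25, hospital = 0.10),
    owner_mix = c(public = 0.60, private_not_for_profit = 0.20,
                  private_for_profit = 0.15, parastatal = 0.05),
    years = 2011:2014,
    section_sizes = c(QD1 = 41L, QD2 = 17L, QD3A = 17L, QD3B = 19L,
                      QD3C = 10L, QD3D = 12L, QD4 = 16L, QD5 = 21L,
                      QD6 = 6L),
    total_indicators = NULL,
    baseline_pct = 67.3,
    year_effects_pp = c("2012" = 3.1, "2013" = 6.5, "2014" = 8.4),
    level_effects_pp = c(hospital = 1.8, dispensary = -7.7),
    owner_effects_pp = c(private_for_profit = -5.5, public = 1.8,
                         parastatal = -0.9),
    council_sd = 0.3,
    qd_sd = 0.3,
    difficulty_sd = 1.0,
    weight_compliance_slope = 0.05,
    graded_share_qd4 = 0.7,
    graded_levels = 3L,
    inapplicable_share = 0.15,
    answers_per_indicator = NULL,
    dropout_rate = 0,
    calibrate = TRUE) {
  stopifnot(n_councils >= 1L, facilities_per_council >= 1L,
            abs(sum(level_mix) - 1) < 1e-8, abs(sum(owner_mix) - 1) < 1e-8,
            all(names(level_mix) %in% FACILITY_LEVELS),
            all(names(owner_mix) %in% OWNER_CATEGORIES),
            all(section_sizes >= 1L), graded_levels >= 2L,
            dropout_rate >= 0, dropout_rate < 1)
  if (!all(names(section_sizes) %in% QD_SECTIONS))
    stop("section_sizes names must be sections ",
         paste(QD_SECTIONS, collapse = "/"))
  if (!is.null(total_indicators))
    section_sizes <- scale_sections(section_sizes, total_indicators)
  if (is.null(answers_per_indicator)) {
    answers_per_indicator <- lapply(QD_SECTIONS, function(s)
      if (s %in% c("QD3A", "QD3B", "QD3C", "QD3D", "QD6")) 1:3 else 1L)
    names(answers_per_indicator) <- QD_SECTIONS
  }
  cfg <- list(n_councils = as.integer(n_councils),
              facilities_per_council = as.integer(facilities_per_council),
              level_mix = level_mix, owner_mix = owner_mix,
              years = as.integer(years), section_sizes = section_sizes,
              baseline_pct = baseline_pct,
              year_effects_pp = year_effects_pp,
              level_effects_pp = level_effects_pp,
              owner_effects_pp = owner_effects_pp,
              council_sd = council_sd, qd_sd = qd_sd,
              difficulty_sd = difficulty_sd,
              weight_compliance_slope = weight_compliance_slope,
              graded_share_qd4 = graded_share_qd4,
              graded_levels = as.integer(graded_levels),
              inapplicable_share = inapplicable_share,
              answers_per_indicator = answers_per_indicator,
              dropout_rate = dropout_rate,
              calibrate = isTRUE(calibrate))
  class(cfg) <- "synthetic_config"
  cfg
}

# proportional largest-remainder scaling of section sizes to a target total,
# keeping every section nonempty
scale_sections <- function(sizes, total) {
  total <- as.integer(total)
  if (total < length(sizes)) stop("total smaller than the number of sections")
  raw <- sizes / sum(sizes) * total
  base <- setNames(pmax(1L, floor(raw)), names(sizes))
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(base, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      s <- ord[(i - 1L) %% length(sizes) + 1L]
      if (base[s] > 1L) { base[s] <- base[s] - 1L; rem <- rem + 1L }
      i <- i + 1L
    }
  }
  storage.mode(base) <- "integer"
  base
}

# E[plogis(a + z)], z ~ N(0, sd), by Gauss-Hermite quadrature
marginal_plogis <- function(a, sd, nodes = 40L) {
  gh <- pracma::gaussHermite(nodes)
  vapply(a, function(ai)
    sum(gh$w * plogis(ai + sqrt(2) * sd * gh$x)) / sqrt(pi), numeric(1))
}

# total latent spread around a fixed-effect linear predictor
latent_spread <- function(config) {
  var_w <- var(rep(1:5, 2))   # variance of a uniform weight draw on 1..5
  sqrt(config$council_sd^2 + config$qd_sd^2 + config$difficulty_sd^2 +
         config$weight_compliance_slope^2 * var_w)
}

#' Latent (logit-scale) effects implied by a configuration
#'
#' Solves for the baseline and effect offsets on the logit scale such that
#' the marginal yes-probabilities reproduce the configured baseline and
#' percentage-point gaps (integrating over council, section and difficulty
#' heterogeneity).  With `calibrate = FALSE` the percentage effects are used
#' as crude logit offsets (`pp / 10`).
#'
#' @param config a [synthetic_config()].
#' @return list with `mu` and named vectors `year`, `level`, `owner`
#'   (reference categories at 0).
#' @export
latent_effects <- function(config) {
  s <- latent_spread(config)
  p0 <- config$baseline_pct / 100
  if (!config$calibrate) {
    mu <- qlogis(p0)
    solve_gap <- function(pp) pp / 10
  } else {
    mu <- uniroot(function(m) marginal_plogis(m, s) - p0,
                  c(-10, 10), tol = 1e-9)$root
    solve_gap <- function(pp) {
      target <- p0 + pp / 100
      stopifnot(target > 0, target < 1)
      uniroot(function(b) marginal_plogis(mu + b, s) - target,
              c(-15, 15), tol = 1e-9)$root - 0
    }
  }
  yr <- setNames(numeric(length(config$years)), as.character(config$years))
  for (y in names(config$year_effects_pp))
    yr[y] <- solve_gap(config$year_effects_pp[[y]])
  lv <- setNames(numeric(length(FACILITY_LEVELS)), FACILITY_LEVELS)
  for (l in names(config$level_effects_pp))
    lv[l] <- solve_gap(config$level_effects_pp[[l]])
  ow <- setNames(numeric(length(OWNER_CATEGORIES)), OWNER_CATEGORIES)
  for (o in names(config$owner_effects_pp))
    ow[o] <- solve_gap(config$owner_effects_pp[[o]])
  list(mu = mu, year = yr, level = lv, owner = ow, spread = s)
}

#' Generate a synthetic indicator catalog
#'
#' Weights are drawn uniformly from 1..5; a configurable share of indicators
#' is restricted to health centers and hospitals (not applicable at
#' dispensaries); part of QD4 uses the graded medicine-availability scale.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the catalog is a deterministic function of
#'   (config, seed).
#' @return an `indicator_catalog`.
#' @export
generate_catalog <- function(config, seed) {
  set.seed(seed)
  sizes <- config$section_sizes
  section <- rep(names(sizes), sizes)
  n <- length(section)
  id <- sprintf("I%03d", seq_len(n))
  weight <- sample(1:5, n, replace = TRUE)
  itype <- vapply(section, function(s) {
    probs <- switch(substr(s, 1, 3),
                    QD1 = c(0.8, 0.2, 0.0),
                    QD2 = c(0.5, 0.5, 0.0),
                    QD3 = c(0.05, 0.9, 0.05),
                    QD4 = c(0.6, 0.4, 0.0),
                    QD5 = c(0.3, 0.7, 0.0),
                    QD6 = c(0.0, 0.2, 0.8))
    sample(INDICATOR_TYPES, 1L, prob = probs)
  }, character(1))
  restricted <- runif(n) < config$inapplicable_share
  applicable <- ifelse(restricted, "health_center;hospital",
                       paste(FACILITY_LEVELS, collapse = ";"))
  graded <- section == "QD4" & runif(n) < config$graded_share_qd4
  as_catalog(data.frame(
    id = id, section = section, weight = weight, itype = itype,
    applicable_levels = applicable,
    response_kind = ifelse(graded, "graded", "binary"),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic facility roster
#'
#' Facilities are split evenly across councils; level and owner are drawn
#' from the configured mixes.
#'
#' @inheritParams generate_catalog
#' @return a `facility_roster`.
#' @export
generate_roster <- function(config, seed) {
  set.seed(seed)
  n <- config$n_councils * config$facilities_per_council
  council <- rep(sprintf("C%02d", seq_len(config$n_councils)),
                 each = config$facilities_per_council)
  as_roster(data.frame(
    facility = sprintf("F%03d", seq_len(n)),
    level = sample(names(config$level_mix), n, replace = TRUE,
                   prob = config$level_mix),
    owner = sample(names(config$owner_mix), n, replace = TRUE,
                   prob = config$owner_mix),
    council = council, stringsAsFactors = FALSE))
}

#' Simulate assessment responses with known ground truth
#'
#' Draws every recorded answer from the latent additive model described in
#' [synthetic_config()].  Indicators inapplicable at a facility's level emit
#' a single `na` answer; graded indicators draw from the equally spaced
#' graded scale with the same mean as the binary success probability.
#'
#' @param catalog an `indicator_catalog` from [generate_catalog()].
#' @param roster a `facility_roster` from [generate_roster()].
#' @inheritParams generate_catalog
#' @return list with `responses` (an `assessment_responses` table) and
#'   `truth` (class `synthetic_truth`: everything needed to recompute every
#'   response probability exactly; see [response_probability()]).
#' @export
simulate_responses <- function(catalog, roster, config, seed) {
  set.seed(seed)
  eff <- latent_effects(config)
  n_ind <- nrow(catalog)
  difficulty <- setNames(rnorm(n_ind, 0, config$difficulty_sd), catalog$id)
  # decorrelate difficulty from weight within each section, so that
  # weight_compliance_slope is the exact weight-success coupling rather than
  # being confounded by sampling covariance in a finite catalog
  for (s in unique(catalog$section)) {
    idx <- which(catalog$section == s)
    wc <- catalog$weight[idx] - mean(catalog$weight[idx])
    if (sum(wc^2) > 0)
      difficulty[idx] <- difficulty[idx] -
        sum(difficulty[idx] * wc) / sum(wc^2) * wc
  }
  councils <- unique(roster$council)
  u <- setNames(rnorm(length(councils), 0, config$council_sd), councils)
  delta <- matrix(rnorm(nrow(roster) * length(QD_SECTIONS), 0, config$qd_sd),
                  nrow = nrow(roster),
                  dimnames = list(roster$facility, QD_SECTIONS))
  mean_w <- mean(catalog$weight)

  grid <- CJ(facility = roster$facility, year = config$years,
             indicator = catalog$id, sorted = TRUE)
  cat_idx <- match(grid$indicator, catalog$id)
  ros_idx <- match(grid$facility, roster$facility)
  grid[, `:=`(
    section = catalog$section[cat_idx],
    graded = catalog$response_kind[cat_idx] == "graded",
    applicable = mapply_applicable(catalog$applicable_levels[cat_idx],
                                   roster$level[ros_idx]))]
  eta <- eff$mu +
    eff$year[as.character(grid$year)] +
    eff$level[roster$level[ros_idx]] +
    eff$owner[roster$owner[ros_idx]] +
    u[roster$council[ros_idx]] +
    delta[cbind(ros_idx, match(grid$section, QD_SECTIONS))] +
    config$weight_compliance_slope * (catalog$weight[cat_idx] - mean_w) -
    difficulty[cat_idx]
  grid[, p := plogis(eta)]

  # answer counts per assessed row, by section
  counts <- integer(nrow(grid))
  for (s in QD_SECTIONS) {
    rows <- which(grid$section == s)
    choices <- config$answers_per_indicator[[s]]
    counts[rows] <- if (length(choices) == 1L) choices
                    else sample(choices, length(rows), replace = TRUE)
  }
  counts[!grid$applicable] <- 1L   # a single na record

  long <- grid[rep(seq_len(.N), counts)]
  nlev <- config$graded_levels
  rbin <- runif(nrow(long))
  answer <- ifelse(rbin < long$p, "yes", "no")
  gr <- which(long$graded & long$applicable)
  if (length(gr))
    answer[gr] <- format_answer(rbinom(length(gr), nlev - 1L, long$p[gr]) /
                                  (nlev - 1L))
  answer[!long$applicable] <- "na"
  responses <- data.frame(facility = long$facility, year = long$year,
                          indicator = long$indicator, answer = answer,
                          stringsAsFactors = FALSE)

  dropped <- character(0)
  if (config$dropout_rate > 0) {
    fy <- unique(responses[c("facility", "year")])
    out <- runif(nrow(fy)) < config$dropout_rate
    if (any(out)) {
      key <- paste(fy$facility, fy$year)[out]
      dropped <- key
      responses <- responses[!paste(responses$facility, responses$year)
                             %in% key, , drop = FALSE]
    }
  }

  truth <- structure(list(
    config = config, effects = eff, difficulty = difficulty,
    council_intercepts = u, qd_deviation = delta, mean_weight = mean_w,
    dropped = dropped, catalog = catalog, roster = roster),
    class = "synthetic_truth")
  list(responses = as_responses(responses), truth = truth)
}

mapply_applicable <- function(applicable_levels, level) {
  mapply(function(al, lv) lv %in% strsplit(al, ";", fixed = TRUE)[[1]],
         applicable_levels, level, USE.NAMES = FALSE)
}

# graded answers as short decimal strings, stable across platforms
format_answer <- function(x) formatC(x, format = "g", digits = 6)

#' Exact response probability under the generator truth
#'
#' @param truth a `synthetic_truth` from [simulate_responses()].
#' @param facility,year,indicator the response cell.
#' @return Success probability in (0, 1), or `NA` if the indicator is not
#'   applicable at the facility's level.
#' @export
response_probability <- function(truth, facility, year, indicator) {
  ros <- truth$roster; cat <- truth$catalog
  ri <- match(facility, ros$facility); ci <- match(indicator, cat$id)
  if (anyNA(ri) || anyNA(ci)) stop("unknown facility or indicator")
  app <- mapply_applicable(cat$applicable_levels[ci], ros$level[ri])
  eff <- truth$effects
  eta <- eff$mu + eff$year[as.character(year)] +
    eff$level[ros$level[ri]] + eff$owner[ros$owner[ri]] +
    truth$council_intercepts[ros$council[ri]] +
    truth$qd_deviation[cbind(ri, match(cat$section[ci], QD_SECTIONS))] +
    truth$config$weight_compliance_slope * (cat$weight[ci] -
                                              truth$mean_weight) -
    truth$difficulty[ci]
  ifelse(app, plogis(unname(eta)), NA_real_)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: catalog, roster and responses from one master seed
#' (stage seeds are derived deterministically).
#'
#' @inheritParams generate_catalog
#' @return list: `catalog`, `roster`, `responses`, `truth`.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1L) {
  catalog <- generate_catalog(config, seed)
  roster <- generate_roster(config, seed + 1L)
  sim <- simulate_responses(catalog, roster, config, seed + 2L)
  list(catalog = catalog, roster = roster,
       responses = sim$responses, truth = sim$truth)
}

#' Model-implied percentage-scale effects (recovery oracle)
#'
#' Computes the exact expected score of every facility-year under the
#' generator (Gauss-Hermite integration over the council and section
#' deviations, using the realized indicator difficulties and weights) and
#' projects those means onto the main-effects design `~ year + level +
#' owner`.  The result is the true estimand a linear model of the scores is
#' aiming at, on the percentage scale, accounting for logit-scale
#' nonlinearity.
#'
#' @param truth a `synthetic_truth`.
#' @param weighted score with catalog weights (default, matching the
#'   scoring pipeline) or unweighted.
#' @param outcome `"overall"` or one of `"qd1"`..`"qd6"`.
#' @return Named numeric vector of true coefficients (reference categories:
#'   first year, health_center, private_not_for_profit).
#' @export
implied_effects <- function(truth, weighted = TRUE, outcome = "overall") {
  cfg <- truth$config; cat <- truth$catalog; ros <- truth$roster
  eff <- truth$effects
  sdz <- sqrt(cfg$council_sd^2 + cfg$qd_sd^2)
  w <- if (weighted) cat$weight else rep(1, nrow(cat))
  a_i <- cfg$weight_compliance_slope * (cat$weight - truth$mean_weight) -
    truth$difficulty
  qd <- section_to_qd(cat$section)
  disp_ok <- vapply(strsplit(cat$applicable_levels, ";", fixed = TRUE),
                    function(l) "dispensary" %in% l, logical(1))

  cell_mean <- function(yr, lv, ow) {
    keep <- if (lv == "dispensary") disp_ok else rep(TRUE, nrow(cat))
    a <- eff$mu + eff$year[as.character(yr)] + eff$level[lv] +
      eff$owner[ow] + a_i[keep]
    p <- marginal_plogis(a, sdz)
    qk <- qd[keep]; wk <- w[keep]
    qs <- vapply(QD_DIMENSIONS, function(q) {
      j <- qk == q
      if (!any(j)) return(NA_real_)
      100 * sum(wk[j] * p[j]) / sum(wk[j])
    }, numeric(1))
    names(qs) <- tolower(QD_DIMENSIONS)
    c(qs, overall = mean(qs, na.rm = TRUE))
  }

  frame <- expand.grid(facility = ros$facility, year = cfg$years,
                       stringsAsFactors = FALSE)
  frame$level <- ros$level[match(frame$facility, ros$facility)]
  frame$owner <- ros$owner[match(frame$facility, ros$facility)]
  cells <- unique(frame[c("year", "level", "owner")])
  cells$m <- vapply(seq_len(nrow(cells)), function(i)
    cell_mean(cells$year[i], cells$level[i], cells$owner[i])[[outcome]],
    numeric(1))
  frame$m <- cells$m[match(paste(frame$year, frame$level, frame$owner),
                           paste(cells$year, cells$level, cells$owner))]
  frame$year <- factor(frame$year, levels = cfg$years)
  frame$level <- factor(frame$level,
                        levels = c("health_center", "dispensary", "hospital"))
  frame$owner <- factor(frame$owner,
                        levels = c("private_not_for_profit", "public",
                                   "private_for_profit", "parastatal"))
  frame <- droplevels(frame)
  coef(lm(m ~ year + level + owner, data = frame))
}

#' Planted block loading matrix
#'
#' A loading matrix with one factor per section: indicators load `within` on
#' their own section's factor and `noise` elsewhere.  Used to test factor
#' allocation recovery.
#'
#' @param section_sizes named integer vector (sections -> indicator counts).
#' @param within,noise on- and off-block loadings.
#' @return matrix (indicators x sections) with dimnames.
#' @export
planted_loading_matrix <- function(section_sizes, within = 0.8,
                                   noise = 0.05) {
  p <- sum(section_sizes)
  L <- matrix(noise, p, length(section_sizes),
              dimnames = list(sprintf("I%03d", seq_len(p)),
                              names(section_sizes)))
  sec <- rep(names(section_sizes), section_sizes)
  L[cbind(seq_len(p), match(sec, names(section_sizes)))] <- within
  L
}

#' Simulate continuous indicator scores from a loading matrix
#'
#' `X = F L' + E` with independent standard-normal factors and residual
#' variance `1 - rowSums(L^2)` (floored at 0.01).
#'
#' @param loadings matrix (indicators x factors), e.g. from
#'   [planted_loading_matrix()].
#' @param n number of facilities (rows).
#' @param seed integer seed.
#' @return numeric matrix n x indicators with indicator column names.
#' @export
simulate_factor_scores <- function(loadings, n, seed) {
  set.seed(seed)
  k <- ncol(loadings); p <- nrow(loadings)
  Fm <- matrix(rnorm(n * k), n, k)
  res_sd <- sqrt(pmax(0.01, 1 - rowSums(loadings^2)))
  X <- Fm %*% t(loadings) +
    matrix(rnorm(n * p), n, p) %*% diag(res_sd, p)
  colnames(X) <- rownames(loadings)
  X
}
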