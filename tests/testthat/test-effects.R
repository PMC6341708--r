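test_that("mixed model recovers a planted owner effect within its CI", {
  cfg <- synthetic_config()
  ds <- simulate_dataset(cfg, 71)
  cards <- score_facilities(ds$catalog, ds$responses)
  frame <- make_model_frame(cards, ds$roster)
  fit <- fit_mixed(frame, "overall")
  truth <- implied_effects(ds$truth)
  cf <- fit$coefficients
  row <- cf[cf$term == "ownerprivate_for_profit", ]
  ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$se
  expect_gt(truth[["ownerprivate_for_profit"]], ci[1])
  expect_lt(truth[["ownerprivate_for_profit"]], ci[2])
  # the planted magnitude is in the right ballpark of the estimate too
  expect_lt(abs(row$estimate - (-5.5)), 3)
  expect_true(fit$random[["council"]] > 0)
})

test_that("a single council leaves the random effect unidentifiable", {
  cfg <- small_config(n_councils = 1L, facilities_per_council = 20L)
  ds <- simulate_dataset(cfg, 3)
  frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                            ds$roster)
  expect_error(fit_mixed(frame, "overall"), "2 councils")
})

test_that("changing reference categories changes coefficients but not fitted
           values", {
  cfg <- small_config()
  ds <- simulate_dataset(cfg, 73)
  frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                            ds$roster)
  f1 <- fit_mixed(frame, "overall")
  frame2 <- frame
  frame2$level <- relevel(frame2$level, tail(levels(frame2$level), 1))
  frame2$owner <- relevel(frame2$owner, tail(levels(frame2$owner), 1))
  f2 <- fit_mixed(frame2, "overall")
  expect_false(isTRUE(all.equal(f1$coefficients$estimate,
                                f2$coefficients$estimate)))
  expect_equal(unname(fitted(f1$model)), unname(fitted(f2$model)),
               tolerance = 1e-6)
})

test_that("larger council heterogeneity raises the estimated random-intercept
           variance", {
  v <- sapply(c(0.1, 0.8), function(sd) {
    cfg <- small_config(council_sd = sd, n_councils = 8L,
                        facilities_per_council = 10L)
    ds <- simulate_dataset(cfg, 75)
    frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                              ds$roster)
    fit_mixed(frame, "overall")$random[["council"]]
  })
  expect_gt(v[2], v[1])
})

test_that("backward Wald pruning removes unplanted interactions and replays
           deterministically", {
  cfg <- small_config(n_councils = 6L, facilities_per_council = 12L)
  ds <- simulate_dataset(cfg, 77)
  frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                            ds$roster)
  pr <- prune_interactions(frame, "overall")
  expect_false(any(grepl(":", pr$coefficients$term)))
  expect_true(any(vapply(pr$pruning_trace, function(s) isTRUE(s$removed),
                         logical(1))))
  aics <- vapply(pr$pruning_trace, function(s) s$aic, numeric(1))
  expect_true(all(is.finite(aics)))
  pr2 <- prune_interactions(frame, "overall")
  expect_identical(pr$coefficients, pr2$coefficients)
  expect_identical(lapply(pr$pruning_trace, `[`, c("rhs", "term", "removed")),
                   lapply(pr2$pruning_trace, `[`, c("rhs", "term", "removed")))
})

test_that("a strongly planted level-by-year interaction survives pruning", {
  # plant an interaction by simulating two year-slices with different level
  # gaps and stacking them
  cfg_a <- small_config(years = c(2011L, 2012L), n_councils = 8L,
                        facilities_per_council = 15L,
                        level_effects_pp = c(hospital = 0, dispensary = 0))
  cfg_b <- small_config(years = c(2013L, 2014L), n_councils = 8L,
                        facilities_per_council = 15L,
                        level_effects_pp = c(hospital = 0,
                                             dispensary = -20))
  catalog <- generate_catalog(cfg_a, 81)
  roster <- generate_roster(cfg_a, 82)
  ra <- simulate_responses(catalog, roster, cfg_a, 83)$responses
  rb <- simulate_responses(catalog, roster, cfg_b, 84)$responses
  cards <- score_facilities(catalog, as_responses(rbind(ra, rb)))
  frame <- make_model_frame(cards, roster)
  frame$period <- factor(ifelse(frame$year %in% c("2011", "2012"),
                                "early", "late"))
  fit_full <- fit_mixed(frame, "overall", formula = "period * level")
  wt <- facscore:::wald_term_tests(fit_full$model, frame, "period * level",
                                   "overall")
  expect_lt(wt$p[wt$term == "period:level"], 0.05)
})

test_that("cluster-robust fixed-effects check is deterministic and close to
           the mixed model on well-specified data", {
  cfg <- small_config(n_councils = 8L, facilities_per_council = 10L)
  ds <- simulate_dataset(cfg, 91)
  frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                            ds$roster)
  rc1 <- robust_fixed_check(frame, "overall")
  rc2 <- robust_fixed_check(frame, "overall")
  expect_identical(rc1$comparison, rc2$comparison)
  # deltas small relative to the mixed-model SEs
  expect_true(all(abs(rc1$comparison$delta_estimate) <
                    2 * rc1$comparison$se_mixed))
  # under heavy council heterogeneity the cluster-robust SE inflates for
  # between-council quantities (the intercept); within-council-balanced
  # year contrasts may legitimately tighten
  ratios <- sapply(93:95, function(seed) {
    het <- small_config(council_sd = 1.2, n_councils = 8L,
                        facilities_per_council = 10L)
    dsh <- simulate_dataset(het, seed)
    frh <- make_model_frame(score_facilities(dsh$catalog, dsh$responses),
                            dsh$roster)
    rch <- robust_fixed_check(frh, "overall")
    naive <- summary(rch$fixed_model)$coefficients[, "Std. Error"]
    (rch$comparison$se_robust / naive[rch$comparison$term])[
      rch$comparison$term == "(Intercept)"]
  })
  expect_true(all(ratios > 1))
})

test_that("null effects are not over-detected", {
  null_cfg <- small_config(year_effects_pp = numeric(0),
                           level_effects_pp = numeric(0),
                           owner_effects_pp = numeric(0),
                           n_councils = 6L, facilities_per_council = 8L,
                           years = c(2013L, 2014L))
  rej <- 0L; tot <- 0L
  for (r in 1:60) {
    ds <- simulate_dataset(null_cfg, 3000 + r)
    frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                              ds$roster)
    fit <- fit_mixed(frame, "overall")
    p <- fit$coefficients$p[fit$coefficients$term != "(Intercept)"]
    rej <- rej + sum(p < 0.05); tot <- tot + length(p)
  }
  expect_lt(rej / tot, 0.125)  # near-nominal, allowing small-sample slack
})

test_that("the effects table lays out one starred column per outcome", {
  cfg <- small_config()
  ds <- simulate_dataset(cfg, 95)
  frame <- make_model_frame(score_facilities(ds$catalog, ds$responses),
                            ds$roster)
  et <- effects_table(frame, outcomes = c("overall", "qd1"), prune = FALSE)
  expect_named(et$table, c("term", "overall", "qd1"))
  expect_true("(Intercept)" %in% et$table$term)
  expect_match(et$table$overall[et$table$term == "(Intercept)"],
               "^-?[0-9.]+")
})
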