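test_that("fraction_met handles binary, graded, repeated and na answers", {
  expect_equal(fraction_met("yes"), 1)
  expect_equal(fraction_met(c("yes", "no")), 0.5)
  expect_equal(fraction_met(c("yes", "yes", "no")), 2 / 3)
  expect_true(is.na(fraction_met(c("na", "na"))))
  expect_equal(fraction_met(c("0.5", "1")), 0.75)
  expect_equal(fraction_met(c("na", "0.5")), 0.5)
  expect_error(fraction_met(c("yes", "0.5")), "malformed")
  expect_error(fraction_met(character(0)), "nonempty")
  expect_error(fraction_met("perhaps"), "invalid")
})

test_that("qd_score is the weighted share of possible points", {
  cat2 <- as_catalog(data.frame(
    id = c("A", "B"), section = "QD1", weight = c(5L, 1L),
    itype = "structure",
    applicable_levels = "dispensary;health_center;hospital",
    response_kind = "binary", stringsAsFactors = FALSE))
  r <- make_responses("F1", 2014, list(A = "yes", B = "no"))
  expect_equal(qd_score(cat2, r, "F1", 2014, "QD1", weighted = TRUE),
               100 * 5 / 6, tolerance = 1e-12)
  expect_equal(qd_score(cat2, r, "F1", 2014, "QD1", weighted = FALSE), 50)
  r_all <- make_responses("F1", 2014, list(A = "yes", B = "yes"))
  expect_equal(qd_score(cat2, r_all, "F1", 2014, "QD1"), 100)
  r_na <- make_responses("F1", 2014, list(A = "na", B = "na"))
  expect_true(is.na(qd_score(cat2, r_na, "F1", 2014, "QD1")))
})

test_that("facility scores: all-yes gives 100, QDs contribute equally, and an
           extra failed indicator lowers the score", {
  catalog <- tiny_catalog()
  all_yes <- make_responses("F1", 2014, setNames(
    as.list(ifelse(catalog$response_kind == "graded", "1", "yes")),
    catalog$id))
  sc <- score_facility(catalog, all_yes, "F1", 2014)
  expect_equal(sc$overall, 100)
  expect_equal(unlist(sc[paste0("qd", 1:6)], use.names = FALSE),
               rep(100, 6))

  # overall equals the mean of the defined QD scores
  cfg <- small_config()
  ds <- simulate_dataset(cfg, 11)
  cards <- score_facilities(ds$catalog, ds$responses)
  qm <- as.matrix(cards[paste0("qd", 1:6)])
  expect_equal(cards$overall, rowMeans(qm, na.rm = TRUE), tolerance = 1e-12)

  # facility with one extra applicable-but-failed indicator scores lower
  base <- list(T01 = "yes", T02 = "yes")
  with_fail <- c(base, list(T03 = "no"))
  s_base <- oracle_score(catalog, make_responses("A", 2014, base),
                         "A", 2014)
  s_fail <- oracle_score(catalog, make_responses("B", 2014, with_fail),
                         "B", 2014)
  got_base <- score_facility(catalog, make_responses("A", 2014, base),
                             "A", 2014)
  got_fail <- score_facility(catalog, make_responses("B", 2014, with_fail),
                             "B", 2014)
  expect_equal(got_base$overall, s_base$overall)
  expect_equal(got_fail$overall, s_fail$overall)
  expect_lt(got_fail$overall, got_base$overall)
  expect_error(score_facility(catalog, make_responses("A", 2014, base),
                              "Z", 2014), "empty assessment")
})

test_that("QD3 pooling and sub-section averaging differ as designed", {
  catalog <- tiny_catalog()
  # QD3A (w3) met, QD3B (w2) failed, others absent
  r <- make_responses("F1", 2014,
                      list(T03 = "yes", T04 = "no", T01 = "yes"))
  pooled <- score_facility(catalog, r, "F1", 2014, qd3 = "pooled")
  subm <- score_facility(catalog, r, "F1", 2014, qd3 = "submean")
  expect_equal(pooled$qd3, 100 * 3 / 5)
  expect_equal(subm$qd3, mean(c(100, 0)))
})

test_that("ranking is descending with deterministic lexicographic ties", {
  sc <- data.frame(facility = c("B", "A", "C"), score = c(80, 90, 80))
  rk <- rank_facilities(sc)
  expect_equal(rk$facility, c("A", "B", "C"))
  expect_equal(rk$rank, 1:3)
  one <- rank_facilities(data.frame(facility = "X", score = 12))
  expect_equal(one$rank, 1L)
  expect_error(rank_facilities(data.frame(facility = c("A", "B"),
                                          year = c(2013, 2014),
                                          overall = c(1, 2))),
               "multiple years")
})

test_that("rank agreement: identity, reversal and mismatch", {
  a <- data.frame(facility = letters[1:6], rank = 1:6)
  expect_equal(compare_rankings(a, a)$spearman_rho, 1)
  expect_equal(compare_rankings(a, a)$kendall_tau, 1)
  expect_equal(compare_rankings(a, a)$max_displacement, 0)
  rev <- data.frame(facility = letters[1:6], rank = 6:1)
  expect_equal(compare_rankings(a, rev)$spearman_rho, -1)
  expect_error(compare_rankings(a, data.frame(facility = letters[2:7],
                                              rank = 1:6)),
               "different facility sets")
})

test_that("assessment diagnostics count assessed indicators and answers", {
  r <- rbind(make_responses("F1", 2014, list(T01 = "yes", T02 = "no")),
             make_responses("F2", 2014,
                            list(T01 = c("yes", "no", "yes"), T02 = "no")))
  d <- assessment_diagnostics(r)
  expect_equal(d$n_indicators_assessed, c(2L, 2L))
  expect_equal(d$avg_answers_per_indicator, c(1, 2))
  # all-na indicators are not assessed
  r2 <- make_responses("F1", 2014, list(T01 = "yes", T09 = c("na", "na")))
  d2 <- assessment_diagnostics(r2)
  expect_equal(d2$n_indicators_assessed, 1L)
})

test_that("scoring invariants hold on random synthetic facilities", {
  cfg <- small_config()
  ds <- simulate_dataset(cfg, 21)
  resp <- ds$responses
  cards <- score_facilities(ds$catalog, resp)
  fys <- unique(resp[c("facility", "year")])
  set.seed(42)
  pick <- fys[sample(nrow(fys), 40), ]

  # range and oracle equivalence, weighted and unweighted
  for (w in c(TRUE, FALSE)) {
    sw <- score_facilities(ds$catalog, resp, weighted = w)
    qm <- as.matrix(sw[c(paste0("qd", 1:6), "overall")])
    expect_true(all(qm >= 0 - 1e-9 & qm <= 100 + 1e-9, na.rm = TRUE))
    for (i in seq_len(nrow(pick))) {
      o <- oracle_score(ds$catalog, resp, pick$facility[i], pick$year[i],
                        weighted = w)
      row <- sw[sw$facility == pick$facility[i] & sw$year == pick$year[i], ]
      expect_equal(row$overall, o$overall, tolerance = 1e-9)
      expect_equal(unlist(row[paste0("qd", 1:6)], use.names = FALSE),
                   unname(o$qd), tolerance = 1e-9)
    }
  }

  # weight neutrality: constant weights == unweighted
  flat <- ds$catalog; flat$weight <- 3L
  expect_equal(score_facilities(flat, resp, weighted = TRUE)$overall,
               score_facilities(flat, resp, weighted = FALSE)$overall,
               tolerance = 1e-12)

  # permutation invariance
  set.seed(1)
  shuf <- resp[sample(nrow(resp)), ]
  expect_equal(score_facilities(ds$catalog, shuf), cards)
  cat_shuf <- ds$catalog[sample(nrow(ds$catalog)), ]
  expect_equal(score_facilities(as_catalog(cat_shuf), resp)$overall,
               cards$overall)

  # NA neutrality: dropping all-na indicator rows changes nothing
  fr <- suppressWarnings(facscore:::indicator_fractions(resp))
  na_keys <- fr[is.na(fr$fraction), ]
  keep <- !paste(resp$facility, resp$year, resp$indicator) %in%
    paste(na_keys$facility, na_keys$year, na_keys$indicator)
  expect_equal(score_facilities(ds$catalog, resp[keep, ]), cards)

  # monotonicity: flipping single 'no' answers to 'yes' never lowers scores
  set.seed(7)
  nos <- which(resp$answer == "no")
  for (i in sample(nos, 25)) {
    flipped <- resp
    flipped$answer[i] <- "yes"
    s2 <- score_facilities(ds$catalog, flipped)
    expect_true(all(s2$overall - cards$overall >= -1e-12))
    qd_diff <- as.matrix(s2[paste0("qd", 1:6)]) -
      as.matrix(cards[paste0("qd", 1:6)])
    expect_true(all(qd_diff >= -1e-12, na.rm = TRUE))
  }
})
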