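test_that("indicator score matrix holds per-facility fractions with missing
           cells for inapplicable indicators", {
  cat2 <- tiny_catalog()
  r <- rbind(make_responses("F1", 2014,
                            list(T01 = "yes", T02 = c("yes", "no"))),
             make_responses("F2", 2014, list(T01 = "yes", T02 = "na")))
  m <- suppressMessages(indicator_score_matrix(cat2, r, 2014))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["F1", "T01"], 1)
  expect_equal(m["F1", "T02"], 0.5)
  expect_true(is.na(m["F2", "T02"]))
  expect_error(indicator_score_matrix(cat2, r, 1999), "no responses")

  # column means track generator probabilities
  cfg <- small_config(n_councils = 5L, facilities_per_council = 60L,
                      years = 2014L)
  ds <- simulate_dataset(cfg, 61)
  ms <- indicator_score_matrix(ds$catalog, ds$responses, 2014)
  fr <- facscore:::indicator_fractions(ds$responses)
  p <- response_probability(ds$truth, fr$facility, fr$year, fr$indicator)
  pbar <- tapply(p, fr$indicator, mean, na.rm = TRUE)[colnames(ms)]
  emp <- colMeans(ms, na.rm = TRUE)
  n <- colSums(!is.na(ms))
  se <- sqrt(pbar * (1 - pbar) / n)
  expect_true(all(abs(emp - pbar) < 4 * se + 0.02))
})

test_that("principal-axis factoring recovers planted block structure", {
  sizes <- setNames(rep(3L, 9), c("QD1", "QD2", "QD3A", "QD3B", "QD3C",
                                  "QD3D", "QD4", "QD5", "QD6"))
  L <- planted_loading_matrix(sizes, within = 0.8, noise = 0.05)
  X <- simulate_factor_scores(L, n = 300, seed = 5)
  fa <- fit_factors(X, k = 9)
  expect_true(all(abs(fa$loadings) <= 1 + 1e-6))
  alloc <- allocate_indicators(fa)
  sec <- rep(names(sizes), sizes)
  # indicators of the same designed block land on the same factor
  block_factor <- tapply(alloc$factor, sec, function(f)
    as.integer(names(which.max(table(f)))))
  hits <- mean(alloc$factor == block_factor[sec])
  expect_gte(hits, 0.9)

  # rank-1 data: a single factor explains essentially all common variance
  set.seed(6)
  f1 <- rnorm(200)
  X1 <- outer(f1, rep(1, 6)) * 0.9 + matrix(rnorm(200 * 6, 0, 0.3), 200)
  fa1 <- fit_factors(X1, k = 1)
  expect_gt(fa1$prop_var[1], 0.7)
  expect_error(fit_factors(X1, k = 10), "rank")
})

test_that("ml extraction agrees with principal axis on clean structure", {
  sizes <- setNames(rep(4L, 3), c("QD1", "QD2", "QD4"))
  L <- planted_loading_matrix(sizes, within = 0.8, noise = 0.05)
  X <- simulate_factor_scores(L, n = 400, seed = 8)
  a_paf <- allocate_indicators(fit_factors(X, k = 3, method = "paf"))
  a_ml <- allocate_indicators(fit_factors(X, k = 3, method = "ml"))
  # same partition of indicators into factors (labels may permute)
  expect_equal(length(unique(paste(a_paf$factor, a_ml$factor))), 3L)
})

test_that("allocation flags follow the 0.4 / 0.2 thresholds", {
  L <- rbind(strong = c(0.8, 0.1, 0.05),
             weak = c(0.35, 0.2, 0.1),
             crossed = c(0.6, 0.45, 0.1),
             neg = c(-0.7, 0.2, 0.1))
  colnames(L) <- paste0("F", 1:3)
  al <- allocate_indicators(L)
  expect_equal(al$factor, c(1L, 1L, 1L, 1L))
  expect_equal(al$weak, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(al$cross_loaded, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(al$loading[4], -0.7)  # signed loading, absolute allocation
  expect_error(allocate_indicators(matrix(c(NA, 1), 1)), "finite")
})

test_that("factor-section matching recovers permutations and the concordance
           table conserves counts", {
  sizes <- setNames(rep(2L, 9), c("QD1", "QD2", "QD3A", "QD3B", "QD3C",
                                  "QD3D", "QD4", "QD5", "QD6"))
  catalog <- as_catalog(data.frame(
    id = sprintf("I%03d", 1:18), section = rep(names(sizes), sizes),
    weight = 3L, itype = "process",
    applicable_levels = "dispensary;health_center;hospital",
    response_kind = "binary", stringsAsFactors = FALSE))

  perm <- c(3L, 1L, 4L, 2L, 9L, 5L, 8L, 7L, 6L)  # section i -> factor perm[i]
  alloc <- data.frame(indicator = catalog$id,
                      factor = rep(perm, each = 2L),
                      loading = 0.8, weak = FALSE, cross_loaded = FALSE,
                      stringsAsFactors = FALSE)
  mp <- match_factors_to_sections(alloc, catalog)
  expect_equal(unname(mp$section_to_factor), perm)
  expect_equal(mp$agreement, 18L)

  tab <- concordance_table(alloc, mp, catalog)
  tot <- tab[tab$section == "Total", ]
  expect_equal(tot$n_matched, 18L)
  expect_equal(tot$pct_matched, 100)
  expect_equal(tab$n_matched[tab$section != "Total"] +
                 tab$n_unmatched[tab$section != "Total"],
               tab$n_indicators[tab$section != "Total"])
  expect_equal(sum(tab$n_indicators[tab$section != "Total"]),
               tot$n_indicators)

  # perturb one indicator: conservation and percentages with the stated
  # denominators
  alloc2 <- alloc
  alloc2$factor[1] <- perm[2]        # one QD1 indicator strays to QD2's factor
  alloc2$weak[1] <- TRUE
  mp2 <- match_factors_to_sections(alloc2, catalog)
  expect_equal(unname(mp2$section_to_factor), perm)  # matching unchanged
  tab2 <- concordance_table(alloc2, mp2, catalog)
  qd1 <- tab2[tab2$section == "QD1", ]
  expect_equal(qd1$n_unmatched, 1L)
  expect_equal(qd1$pct_matched, 50)
  expect_equal(qd1$pct_unmatched_strong, 0)   # the stray one is weak
  expect_equal(qd1$pct_matched_strong, 100)
  tot2 <- tab2[tab2$section == "Total", ]
  expect_equal(tot2$n_matched + tot2$n_unmatched, 18L)

  expect_error(match_factors_to_sections(
    data.frame(indicator = "ZZZ", factor = 1L, loading = 1, weak = FALSE,
               cross_loaded = FALSE), catalog), "absent")
})
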