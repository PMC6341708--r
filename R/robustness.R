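#' Nested, section-stratified indicator subsets
#'
#' Builds a chain of nested indicator sets of the requested sizes for the
#' subset-robustness analysis.  A seeded global order is drawn in which the
#' first indicators are one random pick per section (so no section empties
#' at the smallest size) followed by the remaining indicators in random
#' order; the subset of size `k` is the first `k` entries, which makes every
#' smaller set a subset of every larger one.
#'
#' @param catalog an `indicator_catalog`.
#' @param sizes ascending subset sizes; the maximum must not exceed the
#'   catalog size and the minimum must cover one indicator per section.
#' @param seed integer seed.
#' @return Named list of character vectors of indicator ids, one per size.
#' @export
nested_subsets <- function(catalog, sizes, seed) {
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly ascending")
  if (max(sizes) > nrow(catalog))
    stop("requested subset size ", max(sizes),
         " exceeds catalog size ", nrow(catalog))
  sections <- unique(catalog$section)
  if (min(sizes) < length(sections))
    stop("smallest size cannot cover all ", length(sections), " sections")
  set.seed(seed)
  heads <- vapply(sections, function(s) {
    ids <- catalog$id[catalog$section == s]
    ids[sample.int(length(ids), 1L)]
  }, character(1))
  heads <- heads[sample.int(length(heads))]
  rest <- setdiff(catalog$id, heads)
  ord <- c(heads, rest[sample.int(length(rest))])
  out <- lapply(sizes, function(k) ord[seq_len(k)])
  names(out) <- as.character(sizes)
  out
}

#' Score and rank differences across indicator subsets
#'
#' For each subset, overall facility scores are recomputed from the same
#' responses (unweighted by default, as in the published robustness check),
#' facilities are re-ranked, and the absolute per-facility differences in
#' score and rank against the reference (largest) set are averaged.
#'
#' @param catalog an `indicator_catalog`.
#' @param responses an `assessment_responses` table restricted to one year.
#' @param subsets list of indicator-id vectors, e.g. [nested_subsets()].
#' @param reference indicator ids of the reference set; defaults to the
#'   largest subset.
#' @param weighted use catalog weights (default `FALSE`).
#' @return data.frame of class `subset_curve`: `subset_size`,
#'   `mean_abs_score_diff`, `mean_abs_rank_diff`; exactly (0, 0) at the
#'   reference size.
#' @export
subset_difference_curve <- function(catalog, responses, subsets,
                                    reference = NULL, weighted = FALSE) {
  r <- as.data.frame(responses)
  if (nrow(r) == 0L) stop("no responses (empty facility set)")
  if (length(unique(r$year)) > 1L)
    stop("responses span multiple years; the curve is per-year")
  if (is.null(reference))
    reference <- subsets[[which.max(lengths(subsets))]]
  if (any(lengths(subsets) > length(reference)))
    stop("reference must be the largest set")
  score_subset <- function(ids) {
    sub_cat <- catalog[catalog$id %in% ids, , drop = FALSE]
    sub_r <- r[r$indicator %in% ids, , drop = FALSE]
    sc <- score_facilities(sub_cat, sub_r, weighted = weighted)
    rk <- rank_facilities(sc)
    data.frame(facility = rk$facility, score = rk$score, rank = rk$rank,
               stringsAsFactors = FALSE)
  }
  ref <- score_subset(reference)
  pts <- lapply(subsets, function(ids) {
    s <- score_subset(ids)
    s <- s[match(ref$facility, s$facility), , drop = FALSE]
    if (anyNA(s$score))
      stop("a facility lost all scored indicators in a subset")
    data.frame(subset_size = length(ids),
               mean_abs_score_diff = mean(abs(s$score - ref$score)),
               mean_abs_rank_diff = mean(abs(s$rank - ref$rank)))
  })
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  class(out) <- c("subset_curve", "data.frame")
  out
}

#' Least-squares trend through curve points
#'
#' @param x,y numeric vectors (e.g. subset sizes and mean absolute
#'   differences).
#' @param kind `"quadratic"` (2nd-order polynomial, needs >= 3 points) or
#'   `"linear"` (needs >= 2 points).
#' @return list: `kind`, `coefficients` (intercept, linear, and quadratic
#'   when applicable), `r_squared`, `fitted`.
#' @export
fit_trend <- function(x, y, kind = c("quadratic", "linear")) {
  kind <- match.arg(kind)
  need <- if (kind == "quadratic") 3L else 2L
  if (length(x) < need)
    stop(kind, " trend needs at least ", need, " points")
  if (length(x) != length(y)) stop("x and y lengths differ")
  d <- data.frame(x = x, y = y)
  fit <- if (kind == "quadratic") lm(y ~ x + I(x^2), data = d)
         else lm(y ~ x, data = d)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(kind = kind, coefficients = coef(fit), r_squared = r2,
       fitted = unname(predict(fit)))
}

#' Weighted versus unweighted scoring (weight ablation)
#'
#' Scores the same responses once with catalog weights and once with all
#' weights equal, and summarises the impact on overall scores and ranks.
#'
#' @param catalog an `indicator_catalog`.
#' @param responses an `assessment_responses` table restricted to one year.
#' @return list of class `weight_ablation`: `mean_overall_weighted`,
#'   `mean_overall_unweighted`, `mean_abs_score_diff`, `mean_abs_rank_diff`,
#'   and the `per_facility` table.
#' @export
weight_ablation <- function(catalog, responses) {
  r <- as.data.frame(responses)
  if (length(unique(r$year)) > 1L)
    stop("responses span multiple years; ablate one year at a time")
  sw <- score_facilities(catalog, r, weighted = TRUE)
  su <- score_facilities(catalog, r, weighted = FALSE)
  rw <- rank_facilities(sw); ru <- rank_facilities(su)
  ru <- ru[match(rw$facility, ru$facility), , drop = FALSE]
  per <- data.frame(facility = rw$facility,
                    score_weighted = rw$score, score_unweighted = ru$score,
                    rank_weighted = rw$rank, rank_unweighted = ru$rank,
                    stringsAsFactors = FALSE)
  out <- list(
    mean_overall_weighted = mean(per$score_weighted),
    mean_overall_unweighted = mean(per$score_unweighted),
    mean_abs_score_diff = mean(abs(per$score_weighted -
                                     per$score_unweighted)),
    mean_abs_rank_diff = mean(abs(per$rank_weighted - per$rank_unweighted)),
    per_facility = per)
  class(out) <- "weight_ablation"
  out
}

#' @export
print.weight_ablation <- function(x, ...) {
  cat("Weight ablation over", nrow(x$per_facility), "facilities\n")
  cat(sprintf("  mean overall score, weighted:   %.1f\n",
              x$mean_overall_weighted))
  cat(sprintf("  mean overall score, unweighted: %.1f\n",
              x$mean_overall_unweighted))
  cat(sprintf("  mean |score difference|: %.2f\n", x$mean_abs_score_diff))
  cat(sprintf("  mean |rank difference|:  %.2f\n", x$mean_abs_rank_diff))
  invisible(x)
}
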