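#' Fraction of an indicator met
#'
#' Converts the recorded answers for one indicator at one facility-year into
#' a fulfilment fraction.  Binary answers earn the share of `yes` among
#' `yes`/`no` answers, so answering an indicator several times with mixed
#' results earns partial credit (and makes a full score harder to obtain).
#' Graded answers (values in \[0, 1\]) are averaged.  An indicator whose
#' answers are all `na` is not applicable and returns `NA` (excluded from
#' scoring).
#'
#' @param answers character (or numeric) vector: `yes`/`no`/`na` tokens or
#'   decimals in \[0, 1\].  Mixing the two kinds in one list is malformed.
#' @return A fraction in \[0, 1\], or `NA_real_` when nothing is applicable.
#' @examples
#' fraction_met(c("yes"))              # 1
#' fraction_met(c("yes", "no"))        # 0.5
#' fraction_met(c("na", "na"))         # NA: excluded
#' fraction_met(c("0.5", "1"))         # graded mean 0.75
#' @export
fraction_met <- function(answers) {
  if (length(answers) == 0L) stop("answers must be nonempty")
  a <- tolower(trimws(as.character(answers)))
  is_tok <- a %in% c("yes", "no", "na")
  num <- suppressWarnings(as.numeric(a[!is_tok]))
  if (anyNA(num) || any(num < 0 | num > 1))
    stop("invalid answer value(s): ",
         paste(unique(a[!is_tok][is.na(num) | num < 0 | num > 1]),
               collapse = ", "))
  has_bin <- any(a %in% c("yes", "no"))
  has_grad <- length(num) > 0L
  if (has_bin && has_grad)
    stop("malformed input: binary and graded answers mixed in one list")
  if (has_grad) return(mean(num))
  n_yes <- sum(a == "yes"); n_no <- sum(a == "no")
  if (n_yes + n_no == 0L) return(NA_real_)
  n_yes / (n_yes + n_no)
}

# vectorised fraction_met over a long response table -> one row per
# (facility, year, indicator); malformed mixed lists are caught here too
indicator_fractions <- function(responses) {
  dt <- as.data.table(as.data.frame(responses))
  a <- tolower(trimws(as.character(dt$answer)))
  num <- suppressWarnings(as.numeric(a))
  bad <- !(a %in% c("yes", "no", "na")) & (is.na(num) | num < 0 | num > 1)
  if (any(bad))
    stop("invalid answer value(s): ", paste(unique(a[bad]), collapse = ", "))
  dt[, `:=`(.yes = a == "yes", .no = a == "no",
            .num = ifelse(a %in% c("yes", "no", "na"), NA_real_, num))]
  agg <- dt[, {
    ny <- sum(.yes); nn <- sum(.no); g <- .num[!is.na(.num)]
    if ((ny + nn) > 0L && length(g) > 0L)
      stop("malformed input: binary and graded answers mixed for indicator ",
           indicator[1L])
    f <- if (length(g)) mean(g)
         else if (ny + nn > 0L) ny / (ny + nn)
         else NA_real_
    list(fraction = f, n_answers = ny + nn + length(g))
  }, by = .(facility, year, indicator)]
  agg[]
}

#' Quality-dimension score
#'
#' Percentage of total possible points obtained over the indicators of one
#' or more sections: `100 * sum(w_i f_i) / sum(w_i)` across indicators with
#' a defined fulfilment fraction, where `w_i` is the catalog weight when
#' `weighted`, else 1.
#'
#' @param catalog an `indicator_catalog`.
#' @param responses an `assessment_responses` table.
#' @param facility,year the facility-year to score.
#' @param sections character vector of sections (e.g. `"QD1"` or
#'   `c("QD3A","QD3B","QD3C","QD3D")`).
#' @param weighted use catalog weights (default) or equal weights.
#' @return Percentage in \[0, 100\]; `NA` when no applicable indicator in the
#'   section set was assessed.
#' @export
qd_score <- function(catalog, responses, facility, year, sections,
                     weighted = TRUE) {
  fac <- facility; yr <- year
  ids <- catalog$id[catalog$section %in% sections]
  r <- as.data.frame(responses)
  r <- r[r$facility == fac & r$year == yr & r$indicator %in% ids, ,
         drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  fr <- indicator_fractions(r)
  fr <- fr[!is.na(fr$fraction), ]
  if (nrow(fr) == 0L) return(NA_real_)
  w <- if (weighted) catalog$weight[match(fr$indicator, catalog$id)]
       else rep(1, nrow(fr))
  100 * sum(w * fr$fraction) / sum(w)
}

#' Score all facility-years
#'
#' Computes the six quality-dimension scores, the overall score (arithmetic
#' mean of the defined QD scores, so each QD contributes equally), and the
#' assessment diagnostics for every facility-year present in `responses`.
#'
#' @inheritParams qd_score
#' @param weighted use catalog weights (default) or equal weights.
#' @param qd3 `"pooled"` (default) computes QD3 as one weighted aggregate
#'   over all QD3A--QD3D indicators; `"submean"` averages the four defined
#'   sub-section scores instead.
#' @return A `data.frame` of class `scorecards` with columns `facility`,
#'   `year`, `qd1`..`qd6`, `overall`, `n_indicators`, `avg_answers`.
#'   Undefined QDs (nothing applicable assessed) are `NA` and drop out of
#'   the overall mean.
#' @export
score_facilities <- function(catalog, responses, weighted = TRUE,
                             qd3 = c("pooled", "submean")) {
  qd3 <- match.arg(qd3)
  catalog <- as_catalog(catalog)
  r <- as.data.frame(responses)
  if (nrow(r) == 0L) stop("empty assessment: no responses")
  unknown <- setdiff(unique(r$indicator), catalog$id)
  if (length(unknown))
    stop("responses reference indicators absent from the catalog: ",
         paste(head(unknown, 5L), collapse = ", "))
  fr <- indicator_fractions(r)
  fr[, `:=`(section = catalog$section[match(indicator, catalog$id)],
            w = if (weighted) catalog$weight[match(indicator, catalog$id)]
                else rep(1L, .N))]
  def <- fr[!is.na(fraction)]

  if (qd3 == "pooled") {
    def[, qd := section_to_qd(section)]
    qds <- def[, .(score = 100 * sum(w * fraction) / sum(w)),
               by = .(facility, year, qd)]
  } else {
    sec <- def[, .(score = 100 * sum(w * fraction) / sum(w)),
               by = .(facility, year, section)]
    sec[, qd := section_to_qd(section)]
    qds <- sec[, .(score = mean(score)), by = .(facility, year, qd)]
  }
  wide <- dcast(qds, facility + year ~ qd, value.var = "score")
  for (q in QD_DIMENSIONS) if (!q %in% names(wide)) wide[, (q) := NA_real_]
  qmat <- as.matrix(wide[, QD_DIMENSIONS, with = FALSE])
  wide[, overall := rowMeans(qmat, na.rm = TRUE)]

  diag <- def[, .(n_indicators = .N, avg_answers = mean(n_answers)),
              by = .(facility, year)]
  out <- merge(wide, diag, by = c("facility", "year"), all.x = TRUE)
  setnames(out, QD_DIMENSIONS, tolower(QD_DIMENSIONS))
  setorder(out, facility, year)
  out <- as.data.frame(out)
  class(out) <- c("scorecards", "data.frame")
  out
}

#' Score a single facility-year
#'
#' @inheritParams score_facilities
#' @param facility,year the facility-year to score.
#' @return One-row `scorecards` data.frame.
#' @export
score_facility <- function(catalog, responses, facility, year,
                           weighted = TRUE, qd3 = c("pooled", "submean")) {
  fac <- facility; yr <- year
  r <- as.data.frame(responses)
  r <- r[r$facility == fac & r$year == yr, , drop = FALSE]
  if (nrow(r) == 0L)
    stop("empty assessment: no responses for ", fac, " in ", yr)
  score_facilities(catalog, r, weighted = weighted, qd3 = qd3)
}

#' Rank facilities by score
#'
#' Descending by score, rank 1 = best; ties broken deterministically by
#' facility id (lexicographic), so ranks are always a permutation of 1..n.
#'
#' @param scorecards a `scorecards` data.frame (or any data.frame with a
#'   `facility` column and a `score` or `overall` column).  All rows must be
#'   from the same year when a `year` column is present.
#' @return A `data.frame` of class `facility_ranking` with columns
#'   `facility`, `score`, `rank`.
#' @export
rank_facilities <- function(scorecards) {
  x <- as.data.frame(scorecards)
  if ("year" %in% names(x) && length(unique(x$year)) > 1L)
    stop("scorecards span multiple years; rank one year at a time")
  sc <- if ("overall" %in% names(x)) x$overall else x$score
  if (is.null(sc)) stop("no 'overall' or 'score' column to rank on")
  if (nrow(x) == 0L) stop("nothing to rank")
  ord <- order(-sc, x$facility)
  out <- data.frame(facility = x$facility[ord], score = sc[ord],
                    rank = seq_len(nrow(x)), stringsAsFactors = FALSE)
  class(out) <- c("facility_ranking", "data.frame")
  out
}

#' Agreement between two facility rankings
#'
#' Compares e.g. a qualitatively assigned ranking with the quantitative
#' checklist-based one: Spearman's rho and Kendall's tau on the ranks, the
#' maximum displacement, and the per-facility displacement table.
#'
#' @param rank_a,rank_b data.frames with `facility` and `rank` columns
#'   (e.g. from [rank_facilities()]); the facility sets must coincide.
#' @return A list of class `rank_agreement`: `spearman_rho`, `kendall_tau`,
#'   `max_displacement`, and `displacement` (per-facility table,
#'   `rank_a - rank_b`).
#' @export
compare_rankings <- function(rank_a, rank_b) {
  a <- as.data.frame(rank_a); b <- as.data.frame(rank_b)
  if (!setequal(a$facility, b$facility))
    stop("rankings cover different facility sets")
  b <- b[match(a$facility, b$facility), , drop = FALSE]
  d <- a$rank - b$rank
  out <- list(
    spearman_rho = cor(a$rank, b$rank, method = "spearman"),
    kendall_tau = cor(a$rank, b$rank, method = "kendall"),
    max_displacement = max(abs(d)),
    displacement = data.frame(facility = a$facility, rank_a = a$rank,
                              rank_b = b$rank, displacement = d,
                              stringsAsFactors = FALSE))
  class(out) <- "rank_agreement"
  out
}

#' @export
print.rank_agreement <- function(x, ...) {
  cat("Rank agreement over", nrow(x$displacement), "facilities\n")
  cat(sprintf("  Spearman rho: %.3f\n", x$spearman_rho))
  cat(sprintf("  Kendall tau:  %.3f\n", x$kendall_tau))
  cat(sprintf("  max |rank_a - rank_b|: %d\n", as.integer(x$max_displacement)))
  invisible(x)
}

#' Assessment diagnostics
#'
#' Number of indicators assessed (at least one applicable answer) and the
#' average number of answers per assessed indicator, per facility-year.
#' A high indicator count or answer multiplicity makes a full score harder
#' to reach, which is why these accompany the quantitative ranks.
#'
#' @param responses an `assessment_responses` table.
#' @param facility,year optional filters.
#' @return data.frame: `facility`, `year`, `n_indicators_assessed`,
#'   `avg_answers_per_indicator`.
#' @export
assessment_diagnostics <- function(responses, facility = NULL, year = NULL) {
  fac <- facility; yr <- year
  r <- as.data.frame(responses)
  if (!is.null(fac)) r <- r[r$facility %in% fac, , drop = FALSE]
  if (!is.null(yr)) r <- r[r$year %in% yr, , drop = FALSE]
  if (nrow(r) == 0L) stop("no responses to diagnose")
  fr <- indicator_fractions(r)
  def <- fr[!is.na(fr$fraction), ]
  out <- def[, .(n_indicators_assessed = .N,
                 avg_answers_per_indicator = mean(n_answers)),
             by = .(facility, year)]
  setorder(out, facility, year)
  as.data.frame(out)
}
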