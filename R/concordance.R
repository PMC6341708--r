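#' Facility-by-indicator score matrix
#'
#' One row per facility, one column per indicator, entries the unweighted
#' fulfilment fraction ([fraction_met()]) for the chosen year.  Not-applicable
#' indicators give missing cells; indicators assessed nowhere are dropped
#' (with a message).
#'
#' @param catalog an `indicator_catalog`.
#' @param responses an `assessment_responses` table.
#' @param year the assessment year to use.
#' @return numeric matrix, facilities x indicators.
#' @export
indicator_score_matrix <- function(catalog, responses, year) {
  yr <- year
  r <- as.data.frame(responses)
  r <- r[r$year == yr, , drop = FALSE]
  if (nrow(r) == 0L) stop("no responses in year ", yr)
  fr <- indicator_fractions(r)
  wide <- dcast(fr, facility ~ indicator, value.var = "fraction")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$facility
  keep_order <- intersect(catalog$id, colnames(m))
  m <- m[, keep_order, drop = FALSE]
  empty <- colSums(!is.na(m)) == 0L
  if (any(empty)) {
    message("dropping ", sum(empty), " indicator(s) assessed nowhere: ",
            paste(head(colnames(m)[empty], 5L), collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  m
}

#' Extract latent factors from an indicator score matrix
#'
#' Principal-axis factoring on the correlation matrix (squared-multiple-
#' correlation start, iterated communalities) with varimax rotation, the
#' workflow behind allocating indicators to the factor of their strongest
#' loading.  Missing cells are imputed by the column mean; constant columns
#' cannot be correlated and are dropped with a message.
#'
#' @param x numeric matrix (observations x indicators), e.g. from
#'   [indicator_score_matrix()].
#' @param k number of factors to extract (default 9, one per section).
#' @param method `"paf"` (principal axis, default) or `"ml"`
#'   (maximum likelihood via [stats::factanal()]).
#' @param rotate `"varimax"` (default) or `"none"`.
#' @param max_iter,tol communality iteration controls for `"paf"`.
#' @return list of class `loading_matrix`: `loadings` (indicators x factors,
#'   factors ordered by explained variance), `communality`, `ss_loadings`,
#'   `prop_var`, `dropped`, `k`, `n`, `method`, `rotation`.
#' @export
fit_factors <- function(x, k = 9L, method = c("paf", "ml"),
                        rotate = c("varimax", "none"),
                        max_iter = 200L, tol = 1e-4) {
  method <- match.arg(method); rotate <- match.arg(rotate)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  # column-mean imputation of missing cells
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  keep <- apply(x, 2L, function(col) sd(col) > 0)
  if (!all(keep))
    message("dropping ", sum(!keep), " constant indicator column(s)")
  dropped <- colnames(x)[!keep]
  x <- x[, keep, drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  R <- cor(x)
  rank_R <- sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1e-8)
  if (k > rank_R)
    stop("k = ", k, " exceeds the rank (", rank_R,
         ") of the correlation matrix")

  if (method == "ml") {
    fa <- factanal(covmat = R, factors = k, rotation = "none", n.obs = n)
    L <- matrix(fa$loadings, p, k)
  } else {
    h2 <- smc_start(R)
    L <- NULL
    for (it in seq_len(max_iter)) {
      Rr <- R; diag(Rr) <- h2
      e <- eigen(Rr, symmetric = TRUE)
      lam <- pmax(e$values[seq_len(k)], 0)
      L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
      h2_new <- pmin(rowSums(L^2), 1)
      if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
      h2 <- h2_new
    }
  }
  if (rotate == "varimax" && k >= 2L)
    L <- varimax(L, normalize = TRUE)$loadings[, , drop = FALSE]
  L <- unclass(L)
  # order factors by explained variance, fix sign so each column sums positive
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2L, sgn, `*`)
  dimnames(L) <- list(colnames(x), sprintf("F%d", seq_len(k)))
  ss <- colSums(L^2)
  out <- list(loadings = L, communality = rowSums(L^2), ss_loadings = ss,
              prop_var = ss / p, dropped = dropped, k = k, n = n,
              method = method, rotation = rotate)
  class(out) <- "loading_matrix"
  out
}

# squared multiple correlations as starting communalities; falls back to the
# largest absolute correlation when R is (near-)singular
smc_start <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0)) {
    smc <- 1 - 1 / diag(inv)
    if (all(is.finite(smc)) && all(smc >= 0) && all(smc <= 1)) return(smc)
  }
  A <- abs(R); diag(A) <- 0
  apply(A, 1L, max)
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf("%s factor solution (%s rotation): %d indicators, %d factors, n = %d\n",
              toupper(x$method), x$rotation, nrow(x$loadings), x$k, x$n))
  cat("proportion of variance:",
      paste(sprintf("%.3f", x$prop_var), collapse = " "), "\n")
  invisible(x)
}

#' Allocate indicators to factors
#'
#' Each indicator goes to the factor of its largest absolute loading.  It is
#' flagged weak when that loading is below the weak threshold (default 0.4)
#' and cross-loaded when any other factor's absolute loading comes within
#' the cross window (default 0.2) of the assigned one.  Exact argmax ties
#' break to the lower factor index (with a message).
#'
#' @param loadings a `loading_matrix` from [fit_factors()] or a plain
#'   indicators x factors matrix.
#' @param weak_threshold,cross_window the two thresholds.
#' @return data.frame of class `factor_allocation`: `indicator`, `factor`
#'   (index), `loading` (signed), `weak`, `cross_loaded`.
#' @export
allocate_indicators <- function(loadings, weak_threshold = 0.4,
                                cross_window = 0.2) {
  L <- if (inherits(loadings, "loading_matrix")) loadings$loadings
       else as.matrix(loadings)
  if (!all(is.finite(L))) stop("loadings must be finite")
  A <- abs(L)
  fac <- integer(nrow(A)); cross <- logical(nrow(A))
  ties <- 0L
  for (i in seq_len(nrow(A))) {
    j <- which.max(A[i, ])
    if (sum(A[i, ] == A[i, j]) > 1L) ties <- ties + 1L
    fac[i] <- j
    cross[i] <- any(A[i, -j] >= A[i, j] - cross_window)
  }
  if (ties) message(ties, " exact argmax tie(s) broken to the lower index")
  out <- data.frame(
    indicator = rownames(L) %||% sprintf("V%d", seq_len(nrow(L))),
    factor = fac, loading = L[cbind(seq_len(nrow(L)), fac)],
    weak = A[cbind(seq_len(nrow(A)), fac)] < weak_threshold,
    cross_loaded = cross, stringsAsFactors = FALSE)
  class(out) <- c("factor_allocation", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimal one-to-one matching of factors to designed sections
#'
#' Builds the section x factor contingency table of allocations and finds
#' the one-to-one assignment maximizing total agreement by exact exhaustive
#' search over permutations.
#'
#' @param allocations a `factor_allocation` from [allocate_indicators()].
#' @param catalog the `indicator_catalog` carrying the designed sections.
#' @return list of class `factor_section_map`: `section_to_factor` (named
#'   integer), `factor_to_section` (named character), `agreement` (matched
#'   indicator count), `contingency`.
#' @export
match_factors_to_sections <- function(allocations, catalog) {
  sec <- catalog$section[match(allocations$indicator, catalog$id)]
  if (anyNA(sec)) stop("allocations contain indicators absent from catalog")
  sections <- QD_SECTIONS[QD_SECTIONS %in% unique(catalog$section)]
  k <- max(allocations$factor)
  if (length(sections) != k)
    stop("need as many factors (", k, ") as sections (",
         length(sections), ") for one-to-one matching")
  C <- matrix(0L, length(sections), k,
              dimnames = list(sections, sprintf("F%d", seq_len(k))))
  tab <- table(factor(sec, levels = sections),
               factor(allocations$factor, levels = seq_len(k)))
  C[] <- as.integer(tab)
  if (sum(C) == 0L) stop("degenerate all-zero contingency table")
  perms <- e1071::permutations(k)
  score <- numeric(nrow(perms))
  for (j in seq_len(k)) score <- score + C[j, perms[, j]]
  best <- perms[which.max(score), ]
  section_to_factor <- setNames(best, sections)
  factor_to_section <- setNames(sections[order(best)],
                                sprintf("F%d", seq_len(k)))
  out <- list(section_to_factor = section_to_factor,
              factor_to_section = factor_to_section,
              agreement = max(score), contingency = C)
  class(out) <- "factor_section_map"
  out
}

#' @export
print.factor_section_map <- function(x, ...) {
  cat("Factor-section matching (agreement:", x$agreement, "indicators)\n")
  print(data.frame(factor = names(x$factor_to_section),
                   section = unname(x$factor_to_section)))
  invisible(x)
}

#' Concordance of factor allocation with the designed sections
#'
#' Per section: how many indicators the factor analysis allocates to that
#' section's matched factor, and how the matched / unmatched indicators
#' break down into cross-loaded and strongly loading (|loading| >= the weak
#' threshold).  Percentages use the per-section count for the match rate,
#' the matched count for the matched breakdown and the unmatched count for
#' the unmatched breakdown.
#'
#' @param allocations a `factor_allocation`.
#' @param mapping a `factor_section_map`.
#' @param catalog the `indicator_catalog`.
#' @return data.frame of class `concordance_table`, one row per section
#'   plus a `Total` row.
#' @export
concordance_table <- function(allocations, mapping, catalog) {
  sec <- catalog$section[match(allocations$indicator, catalog$id)]
  matched <- allocations$factor == mapping$section_to_factor[sec]
  strong <- !allocations$weak
  cross <- allocations$cross_loaded
  per <- lapply(names(mapping$section_to_factor), function(s) {
    in_s <- sec == s
    n <- sum(in_s); m <- sum(in_s & matched); u <- n - m
    data.frame(
      section = s, factor = unname(mapping$section_to_factor[s]),
      n_indicators = n, n_matched = m,
      pct_matched = pct(m, n),
      n_matched_cross = sum(in_s & matched & cross),
      pct_matched_cross = pct(sum(in_s & matched & cross), m),
      n_matched_strong = sum(in_s & matched & strong),
      pct_matched_strong = pct(sum(in_s & matched & strong), m),
      n_unmatched = u,
      n_unmatched_cross = sum(in_s & !matched & cross),
      pct_unmatched_cross = pct(sum(in_s & !matched & cross), u),
      n_unmatched_strong = sum(in_s & !matched & strong),
      pct_unmatched_strong = pct(sum(in_s & !matched & strong), u),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  tot <- out[1, ]
  tot$section <- "Total"; tot$factor <- NA_integer_
  for (cn in grep("^n_", names(out), value = TRUE)) tot[[cn]] <- sum(out[[cn]])
  tot$pct_matched <- pct(tot$n_matched, tot$n_indicators)
  tot$pct_matched_cross <- pct(tot$n_matched_cross, tot$n_matched)
  tot$pct_matched_strong <- pct(tot$n_matched_strong, tot$n_matched)
  tot$pct_unmatched_cross <- pct(tot$n_unmatched_cross, tot$n_unmatched)
  tot$pct_unmatched_strong <- pct(tot$n_unmatched_strong, tot$n_unmatched)
  out <- rbind(out, tot)
  rownames(out) <- NULL
  class(out) <- c("concordance_table", "data.frame")
  out
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
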