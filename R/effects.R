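#' Build the model frame for effect estimation
#'
#' Joins facility-year scorecards to the roster and sets the categorical
#' covariates with fixed reference categories: first assessment year,
#' `health_center`, `private_not_for_profit`.
#'
#' @param scorecards a `scorecards` data.frame from [score_facilities()].
#' @param roster a `facility_roster`.
#' @return data.frame with outcome columns (`overall`, `qd1`..`qd6`) and
#'   factors `year`, `level`, `owner`, plus `council` and `facility`.
#' @export
make_model_frame <- function(scorecards, roster) {
  x <- merge(as.data.frame(scorecards), as.data.frame(roster),
             by = "facility")
  if (nrow(x) == 0L) stop("no scorecard rows match the roster")
  x$year <- factor(x$year, levels = sort(unique(x$year)))
  x$level <- factor(x$level,
                    levels = intersect(c("health_center", "dispensary",
                                         "hospital"), unique(x$level)))
  x$owner <- factor(x$owner,
                    levels = intersect(c("private_not_for_profit", "public",
                                         "private_for_profit", "parastatal"),
                                       unique(x$owner)))
  x$council <- factor(x$council)
  x
}

fixed_rhs <- function(interactions = FALSE) {
  if (interactions) "year * level * owner" else "year + level + owner"
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Mixed linear model for facility scores
#'
#' Fits `outcome ~ year + level + owner + (1 | council)` by REML
#' (coefficients on the percentage scale), with Satterthwaite p-values.
#' AIC is reported from the maximum-likelihood refit so that models with
#' different fixed effects are comparable.
#'
#' @param frame model frame from [make_model_frame()].
#' @param outcome `"overall"` (default) or one of `"qd1"`..`"qd6"`.
#' @param formula optional right-hand side for the fixed part (character),
#'   e.g. `"year * level"`; defaults to the additive main effects.
#' @param facility_intercept also include a facility random intercept
#'   (off by default: the published model uses council only).
#' @param reml fit by REML (default) or ML.
#' @return list of class `effects_result`: `model`, `coefficients` (term,
#'   estimate, se, df, t, p, stars), `random` (variance components), `aic`,
#'   `outcome`, `formula`.
#' @export
fit_mixed <- function(frame, outcome = "overall", formula = NULL,
                      facility_intercept = FALSE, reml = TRUE) {
  if (!outcome %in% names(frame)) stop("unknown outcome: ", outcome)
  if (nlevels(frame$council) < 2L)
    stop("need at least 2 councils to identify the council random effect")
  if (anyNA(frame[[outcome]])) {
    frame <- frame[!is.na(frame[[outcome]]), , drop = FALSE]
    frame <- droplevels(frame)
  }
  rhs <- formula %||% fixed_rhs()
  re <- "(1 | council)"
  if (facility_intercept) re <- paste(re, "+ (1 | facility)")
  f <- as.formula(paste(outcome, "~", rhs, "+", re))
  model <- lmerTest::lmer(f, data = frame, REML = reml)
  smr <- summary(model)$coefficients
  coefs <- data.frame(term = rownames(smr), estimate = smr[, "Estimate"],
                      se = smr[, "Std. Error"], df = smr[, "df"],
                      t = smr[, "t value"], p = smr[, "Pr(>|t|)"],
                      stars = p_stars(smr[, "Pr(>|t|)"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(model))
  random <- setNames(vc$vcov, ifelse(is.na(vc$grp), "residual", vc$grp))
  aic_ml <- AIC(if (reml) lme4::refitML(model) else model)
  out <- list(model = model, coefficients = coefs, random = random,
              aic = aic_ml, outcome = outcome,
              formula = paste(outcome, "~", rhs, "+", re))
  class(out) <- "effects_result"
  out
}

#' @export
print.effects_result <- function(x, ...) {
  cat("Mixed linear model:", x$formula, "\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 2)
  tab$se <- round(tab$se, 2)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "estimate", "se", "p", "stars")], row.names = FALSE)
  cat(sprintf("Random-intercept variance (council): %.2f; residual: %.2f\n",
              x$random[["council"]], x$random[["residual"]]))
  cat(sprintf("AIC (ML): %.1f\n", x$aic))
  if (!is.null(x$pruning_trace)) {
    removed <- vapply(x$pruning_trace, function(s)
      if (isTRUE(s$removed)) s$term else NA_character_, character(1))
    removed <- removed[!is.na(removed)]
    cat("Pruned interaction terms:",
        if (length(removed)) paste(removed, collapse = ", ") else "none",
        "\n")
  }
  invisible(x)
}

# Wald chi-square tests of whole model terms from the fitted fixed part;
# robust to columns dropped for rank deficiency
wald_term_tests <- function(model, frame, rhs, outcome) {
  tt <- terms(as.formula(paste(outcome, "~", rhs)))
  mm <- model.matrix(tt, data = frame)
  asgn <- attr(mm, "assign")
  labels <- attr(tt, "term.labels")
  orders <- attr(tt, "order")
  b <- lme4::fixef(model)
  keep <- colnames(mm) %in% names(b)
  asgn <- asgn[keep]
  V <- as.matrix(vcov(model))
  res <- lapply(seq_along(labels), function(ti) {
    idx <- which(asgn == ti)
    idx <- idx[colnames(mm)[keep][idx] %in% names(b)]
    if (!length(idx))
      return(data.frame(term = labels[ti], order = orders[ti], df = 0L,
                        chisq = NA_real_, p = NA_real_))
    bn <- colnames(mm)[keep][idx]
    bi <- b[bn]
    Vi <- V[bn, bn, drop = FALSE]
    ch <- tryCatch(as.numeric(t(bi) %*% solve(Vi, bi)),
                   error = function(e) NA_real_)
    data.frame(term = labels[ti], order = orders[ti], df = length(bi),
               chisq = ch, p = pchisq(ch, length(bi), lower.tail = FALSE))
  })
  do.call(rbind, res)
}

#' Backward pruning of interaction terms by Wald tests
#'
#' Starts from the full factorial model
#' `outcome ~ year * level * owner + (1 | council)` (third- and second-order
#' interactions) and removes, among the highest-order interaction terms
#' still present, the one with the largest Wald p-value, repeating until
#' every remaining interaction of the current highest order is significant
#' at `alpha` or no interactions remain.  Models are compared on ML fits;
#' the AIC of every visited model is recorded.  If the saturated model is
#' not estimable the largest estimable model starts the search (logged in
#' the trace).
#'
#' @inheritParams fit_mixed
#' @param alpha Wald significance threshold for keeping a term.
#' @return `effects_result` for the final model (REML refit) with an extra
#'   `pruning_trace`: one entry per step (`rhs`, `aic`, `term`, `p`,
#'   `removed`).
#' @export
prune_interactions <- function(frame, outcome = "overall", alpha = 0.05,
                               facility_intercept = FALSE) {
  terms_now <- attr(terms(as.formula(paste("~", fixed_rhs(TRUE)))),
                    "term.labels")
  trace <- list()
  repeat {
    rhs <- paste(terms_now, collapse = " + ")
    fit <- tryCatch(
      fit_mixed(frame, outcome, formula = rhs,
                facility_intercept = facility_intercept, reml = FALSE),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # saturated model not estimable: drop the highest-order terms wholesale
      orders <- vapply(strsplit(terms_now, ":", fixed = TRUE), length, 1L)
      if (max(orders) == 1L) stop("main-effects model not estimable: ",
                                  conditionMessage(fit))
      trace[[length(trace) + 1L]] <- list(
        rhs = rhs, aic = NA_real_, term = NA_character_, p = NA_real_,
        removed = FALSE, note = "not estimable; dropping highest order")
      terms_now <- terms_now[orders < max(orders)]
      next
    }
    wt <- wald_term_tests(fit$model, frame, rhs, outcome)
    ints <- wt[wt$order >= 2L & is.finite(wt$p), , drop = FALSE]
    if (nrow(ints) == 0L) {
      trace[[length(trace) + 1L]] <- list(rhs = rhs, aic = fit$aic,
                                          term = NA_character_,
                                          p = NA_real_, removed = FALSE)
      break
    }
    top <- ints[ints$order == max(ints$order), , drop = FALSE]
    worst <- top[which.max(top$p), ]
    if (worst$p > alpha) {
      trace[[length(trace) + 1L]] <- list(rhs = rhs, aic = fit$aic,
                                          term = worst$term, p = worst$p,
                                          removed = TRUE)
      terms_now <- setdiff(terms_now, worst$term)
    } else {
      trace[[length(trace) + 1L]] <- list(rhs = rhs, aic = fit$aic,
                                          term = worst$term, p = worst$p,
                                          removed = FALSE)
      break
    }
  }
  final_rhs <- paste(terms_now, collapse = " + ")
  out <- fit_mixed(frame, outcome, formula = final_rhs,
                   facility_intercept = facility_intercept, reml = TRUE)
  out$pruning_trace <- trace
  out
}

#' Robust-variance fixed-effects sensitivity check
#'
#' Fits the same fixed effects by ordinary least squares with a
#' council-clustered (CR1) sandwich variance estimator and compares
#' coefficients and standard errors with the council-random-intercept
#' mixed model.
#'
#' @inheritParams fit_mixed
#' @return list of class `robust_check`: `comparison` (term, mixed and
#'   fixed estimates/SEs, deltas), `max_abs_delta`, `mixed`, `fixed_model`.
#' @export
robust_fixed_check <- function(frame, outcome = "overall", formula = NULL) {
  rhs <- formula %||% fixed_rhs()
  mixed <- fit_mixed(frame, outcome, formula = rhs)
  if (anyNA(frame[[outcome]]))
    frame <- droplevels(frame[!is.na(frame[[outcome]]), , drop = FALSE])
  f <- as.formula(paste(outcome, "~", rhs))
  fm <- lm(f, data = frame)
  Vcl <- sandwich::vcovCL(fm, cluster = frame$council)
  ct <- lmtest::coeftest(fm, vcov. = Vcl)
  common <- intersect(mixed$coefficients$term, rownames(ct))
  mc <- mixed$coefficients[match(common, mixed$coefficients$term), ]
  comparison <- data.frame(
    term = common,
    estimate_mixed = mc$estimate, se_mixed = mc$se,
    estimate_fixed = ct[common, "Estimate"],
    se_robust = ct[common, "Std. Error"],
    delta_estimate = ct[common, "Estimate"] - mc$estimate,
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(comparison = comparison,
              max_abs_delta = max(abs(comparison$delta_estimate)),
              mixed = mixed, fixed_model = fm)
  class(out) <- "robust_check"
  out
}

#' @export
print.robust_check <- function(x, ...) {
  cat("Random-intercept vs cluster-robust fixed-effects fit\n")
  tab <- x$comparison
  for (cn in setdiff(names(tab), "term")) tab[[cn]] <- round(tab[[cn]], 2)
  print(tab, row.names = FALSE)
  cat(sprintf("max |coefficient delta|: %.3f\n", x$max_abs_delta))
  invisible(x)
}

#' Effects table across outcomes
#'
#' Fits the (optionally pruned) mixed model for the overall score and each
#' quality dimension and lays the coefficients out as one column per
#' outcome with significance stars.
#'
#' @inheritParams prune_interactions
#' @param outcomes outcome columns to fit.
#' @param prune apply [prune_interactions()] per outcome (default) or fit
#'   the additive model directly.
#' @return list of class `effects_table`: `table` (term x outcome,
#'   formatted "estimate stars"), `fits` (per-outcome `effects_result`).
#' @export
effects_table <- function(frame, outcomes = c("overall", paste0("qd", 1:6)),
                          prune = TRUE, alpha = 0.05) {
  outcomes <- intersect(outcomes, names(frame))
  fits <- lapply(outcomes, function(oc) {
    if (prune) prune_interactions(frame, oc, alpha = alpha)
    else fit_mixed(frame, oc)
  })
  names(fits) <- outcomes
  terms_all <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  tab <- data.frame(term = terms_all, stringsAsFactors = FALSE)
  for (oc in outcomes) {
    cf <- fits[[oc]]$coefficients
    i <- match(terms_all, cf$term)
    tab[[oc]] <- ifelse(is.na(i), "",
                        sprintf("%.1f%s", cf$estimate[i],
                                ifelse(cf$stars[i] == "", "",
                                       paste0(" ", cf$stars[i]))))
  }
  out <- list(table = tab, fits = fits)
  class(out) <- "effects_table"
  out
}

#' @export
print.effects_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
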