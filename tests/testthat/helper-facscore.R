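# shared fixtures: built in code, deterministic

# a hand-written catalog touching every section
tiny_catalog <- function() {
  as_catalog(data.frame(
    id = sprintf("T%02d", 1:9),
    section = c("QD1", "QD2", "QD3A", "QD3B", "QD3C", "QD3D", "QD4",
                "QD5", "QD6"),
    weight = c(5, 1, 3, 2, 4, 1, 2, 5, 3),
    itype = c("structure", "structure", "process", "process", "process",
              "process", "structure", "process", "outcome"),
    applicable_levels = c(rep("dispensary;health_center;hospital", 8),
                          "health_center;hospital"),
    response_kind = c(rep("binary", 6), "graded", "binary", "binary"),
    stringsAsFactors = FALSE))
}

# reduced synthetic study for fast unit tests
small_config <- function(...) {
  args <- list(
    n_councils = 4L, facilities_per_council = 6L,
    section_sizes = c(QD1 = 4L, QD2 = 3L, QD3A = 2L, QD3B = 2L, QD3C = 2L,
                      QD3D = 2L, QD4 = 3L, QD5 = 3L, QD6 = 2L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# independent scoring oracle: per-indicator loops, no shared code path with
# score_facilities beyond fraction_met's definition
oracle_score <- function(catalog, responses, facility, year,
                         weighted = TRUE) {
  r <- responses[responses$facility == facility & responses$year == year, ]
  qds <- c("QD1", "QD2", "QD3", "QD4", "QD5", "QD6")
  qd_of <- function(s) if (grepl("^QD3", s)) "QD3" else s
  qd_scores <- sapply(qds, function(q) {
    ids <- catalog$id[sapply(catalog$section, qd_of) == q]
    num <- 0; den <- 0
    for (id in ids) {
      ans <- r$answer[r$indicator == id]
      if (length(ans) == 0) next
      a <- tolower(trimws(as.character(ans)))
      g <- suppressWarnings(as.numeric(a[!a %in% c("yes", "no", "na")]))
      f <- if (length(g)) mean(g)
           else if (sum(a %in% c("yes", "no")) > 0)
             sum(a == "yes") / sum(a %in% c("yes", "no"))
           else NA_real_
      if (is.na(f)) next
      w <- if (weighted) catalog$weight[catalog$id == id] else 1
      num <- num + w * f; den <- den + w
    }
    if (den == 0) NA_real_ else 100 * num / den
  })
  list(qd = qd_scores, overall = mean(qd_scores, na.rm = TRUE))
}

# responses for one facility-year from literal per-indicator answer lists
make_responses <- function(facility, year, answers) {
  do.call(rbind, lapply(names(answers), function(id)
    data.frame(facility = facility, year = year, indicator = id,
               answer = as.character(answers[[id]]),
               stringsAsFactors = FALSE)))
}
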