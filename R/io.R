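#' Read an indicator catalog
#'
#' The catalog CSV carries one row per checklist indicator with columns
#' `id`, `section` (one of QD1, QD2, QD3A--QD3D, QD4, QD5, QD6), `weight`
#' (integer importance 1--5), `itype` (structure/process/outcome),
#' `applicable_levels` (semicolon-separated subset of
#' dispensary;health_center;hospital) and `response_kind` (binary or graded).
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `indicator_catalog`.
#' @seealso [write_catalog()], [generate_catalog()]
#' @export
read_catalog <- function(path) {
  as_catalog(read.csv(path, stringsAsFactors = FALSE))
}

#' Coerce and validate an indicator catalog
#'
#' @param x data.frame with the catalog columns (see [read_catalog()]).
#' @return Validated `indicator_catalog`.
#' @export
as_catalog <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "section", "weight", "itype", "applicable_levels",
            "response_kind")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$id))
    stop("catalog contains duplicated indicator ids")
  if (!all(x$section %in% QD_SECTIONS))
    stop("unknown section(s): ",
         paste(unique(setdiff(x$section, QD_SECTIONS)), collapse = ", "))
  x$weight <- as.integer(x$weight)
  if (any(is.na(x$weight)) || any(!x$weight %in% 1:5))
    stop("weights must be integers in 1..5")
  if (!all(x$itype %in% INDICATOR_TYPES))
    stop("itype must be one of ", paste(INDICATOR_TYPES, collapse = "/"))
  if (!all(x$response_kind %in% RESPONSE_KINDS))
    stop("response_kind must be one of ",
         paste(RESPONSE_KINDS, collapse = "/"))
  lv <- strsplit(x$applicable_levels, ";", fixed = TRUE)
  bad <- vapply(lv, function(l) length(l) == 0L ||
                  !all(l %in% FACILITY_LEVELS), logical(1))
  if (any(bad))
    stop("applicable_levels must be a nonempty ';'-list of facility levels")
  class(x) <- c("indicator_catalog", "data.frame")
  x
}

#' @rdname read_catalog
#' @param catalog an `indicator_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a facility roster
#'
#' Columns: `facility`, `level` (dispensary/health_center/hospital), `owner`
#' (public/private_not_for_profit/private_for_profit/parastatal), `council`.
#' Every facility belongs to exactly one council.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `facility_roster`.
#' @export
read_roster <- function(path) {
  as_roster(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_roster
#' @param x data.frame with roster columns.
#' @export
as_roster <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("facility", "level", "owner", "council")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("roster is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$facility))
    stop("roster assigns a facility to more than one row")
  if (!all(x$level %in% FACILITY_LEVELS))
    stop("unknown facility level(s)")
  if (!all(x$owner %in% OWNER_CATEGORIES))
    stop("unknown owner category(s)")
  class(x) <- c("facility_roster", "data.frame")
  x
}

#' @rdname read_roster
#' @param roster a `facility_roster`.
#' @export
write_roster <- function(roster, path) {
  write.csv(as.data.frame(roster), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format assessment responses
#'
#' One row per recorded answer: columns `facility`, `year`, `indicator`,
#' `answer`.  An answer is `yes`, `no` or `na` for binary indicators, or a
#' decimal in \[0, 1\] for graded (medicine-availability style) indicators.
#' Repeated answers to the same indicator appear as repeated rows.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `assessment_responses`.
#' @export
read_responses <- function(path) {
  as_responses(read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(answer = "character")))
}

#' @rdname read_responses
#' @param x data.frame with response columns.
#' @export
as_responses <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("facility", "year", "indicator", "answer")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("responses are missing columns: ", paste(miss, collapse = ", "))
  x$year <- as.integer(x$year)
  x$answer <- tolower(trimws(as.character(x$answer)))
  num <- suppressWarnings(as.numeric(x$answer))
  ok <- x$answer %in% c("yes", "no", "na") |
    (!is.na(num) & num >= 0 & num <= 1)
  if (!all(ok))
    stop("invalid answer value(s), e.g. '",
         x$answer[which(!ok)[1]], "' at row ", which(!ok)[1])
  class(x) <- c("assessment_responses", "data.frame")
  x
}

#' @rdname read_responses
#' @param responses an `assessment_responses` table.
#' @export
write_responses <- function(responses, path) {
  write.csv(as.data.frame(responses), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scorecard table
#'
#' Columns: facility, year, qd1..qd6, overall, n_indicators, avg_answers;
#' percentages at full precision (round for display only).
#'
#' @param scorecards output of [score_facilities()].
#' @param path CSV file path.
#' @export
write_scorecards <- function(scorecards, path) {
  write.csv(as.data.frame(scorecards), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
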