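#' Pipeline run configuration
#'
#' One configuration object drives a full reproducible run: simulate (or
#' load) data, score, rank, subset-robustness, weight ablation, factor
#' concordance and mixed-model effects.  Per-stage seeds are derived
#' deterministically from the master seed, so one number reproduces the
#' whole run.
#'
#' @param seed master integer seed.
#' @param out_dir output directory for the report bundle.
#' @param synthetic a [synthetic_config()] (used unless `inputs` is given).
#' @param inputs optional list with `catalog`, `roster`, `responses` CSV
#'   paths to analyse existing data instead of simulating.
#' @param stages character vector of stages to run, in dependency order.
#' @param analysis_year year used for ranking, robustness and concordance
#'   (default: last configured year).
#' @param weighted score with catalog weights (default) in the scoring and
#'   effects stages; the robustness curve is always also run unweighted.
#' @param subset_sizes sizes for [nested_subsets()]; default: eight sizes up
#'   to the catalog size.
#' @param k_factors factors to extract (default 9).
#' @param weak_threshold,cross_window,alpha analysis thresholds.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "facscore_run",
                       synthetic = synthetic_config(), inputs = NULL,
                       stages = c("data", "score", "rank", "robustness",
                                  "concordance", "effects"),
                       analysis_year = NULL, weighted = TRUE,
                       subset_sizes = NULL, k_factors = 9L,
                       weak_threshold = 0.4, cross_window = 0.2,
                       alpha = 0.05) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              synthetic = synthetic, inputs = inputs, stages = stages,
              analysis_year = analysis_year, weighted = weighted,
              subset_sizes = subset_sizes, k_factors = as.integer(k_factors),
              weak_threshold = weak_threshold, cross_window = cross_window,
              alpha = alpha)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips through serialization unchanged (synthetic
#' sub-config included).
#'
#' @param path YAML file path.
#' @return [run_config()] for `read_run_config`; `path` invisibly for
#'   `write_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) {
    sa <- y$synthetic
    for (nm in c("level_mix", "owner_mix", "section_sizes",
                 "year_effects_pp", "level_effects_pp", "owner_effects_pp"))
      if (!is.null(sa[[nm]])) sa[[nm]] <- unlist(sa[[nm]])
    if (!is.null(sa$answers_per_indicator))
      sa$answers_per_indicator <- lapply(sa$answers_per_indicator, as.integer)
    do.call(synthetic_config, sa)
  } else synthetic_config()
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  syn <- unclass(y$synthetic)
  # yaml serialises named atomic vectors as plain sequences; keep the names
  # by writing maps
  for (nm in c("level_mix", "owner_mix", "section_sizes", "year_effects_pp",
               "level_effects_pp", "owner_effects_pp"))
    syn[[nm]] <- as.list(syn[[nm]])
  y$synthetic <- syn
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_seed <- function(config, stage) {
  config$seed * 100L + match(stage, c("data", "score", "rank", "robustness",
                                      "concordance", "effects"))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every tabular
#' artifact as CSV (configs/metadata as JSON) under `out_dir`, and finishes
#' with a manifest listing each output file with its MD5 content hash, the
#' stage seeds and row counts.  A rerun with the same configuration is
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of in-memory stage results, including
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log <- list()
  out <- function(name) file.path(config$out_dir, name)
  note <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
    log[[stage]] <<- msg
  }
  stages <- config$stages

  # -- data ----------------------------------------------------------------
  if ("data" %in% stages) {
    if (!is.null(config$inputs)) {
      res$catalog <- read_catalog(config$inputs$catalog)
      res$roster <- read_roster(config$inputs$roster)
      res$responses <- read_responses(config$inputs$responses)
      note("data", sprintf("loaded %d indicators, %d facilities, %d answers",
                           nrow(res$catalog), nrow(res$roster),
                           nrow(res$responses)))
    } else {
      s <- stage_seed(config, "data")
      ds <- simulate_dataset(config$synthetic, s)
      res[c("catalog", "roster", "responses", "truth")] <- ds
      truth_json <- list(
        mu = ds$truth$effects$mu,
        year_effects = as.list(ds$truth$effects$year),
        level_effects = as.list(ds$truth$effects$level),
        owner_effects = as.list(ds$truth$effects$owner),
        council_intercepts = as.list(ds$truth$council_intercepts),
        difficulty = as.list(ds$truth$difficulty),
        mean_weight = ds$truth$mean_weight,
        dropped = ds$truth$dropped, seed = s)
      jsonlite::write_json(truth_json, out("truth.json"),
                           auto_unbox = TRUE, digits = NA)
      note("data", sprintf(
        "simulated %d indicators, %d facilities, %d answers (seed %d)",
        nrow(res$catalog), nrow(res$roster), nrow(res$responses), s))
    }
    write_catalog(res$catalog, out("catalog.csv"))
    write_roster(res$roster, out("roster.csv"))
    write_responses(res$responses, out("responses.csv"))
  } else stop("missing upstream output: stage 'data' is required")

  yr <- config$analysis_year %||% max(res$responses$year)
  r_yr <- res$responses[res$responses$year == yr, , drop = FALSE]

  # -- score ---------------------------------------------------------------
  if ("score" %in% stages) {
    res$scorecards <- score_facilities(res$catalog, res$responses,
                                       weighted = config$weighted)
    write_scorecards(res$scorecards, out("scorecards.csv"))
    note("score", sprintf("%d facility-year scorecards (weighted = %s)",
                          nrow(res$scorecards), config$weighted))
  }

  # -- rank ----------------------------------------------------------------
  if ("rank" %in% stages) {
    if (is.null(res$scorecards))
      stop("missing upstream output for stage 'rank': run 'score' first")
    sc_yr <- res$scorecards[res$scorecards$year == yr, , drop = FALSE]
    res$ranking <- rank_facilities(sc_yr)
    write.csv(as.data.frame(res$ranking), out("ranking.csv"),
              row.names = FALSE, quote = FALSE)
    note("rank", sprintf("ranked %d facilities for %d", nrow(res$ranking), yr))
  }

  # -- robustness ----------------------------------------------------------
  if ("robustness" %in% stages) {
    sizes <- config$subset_sizes %||%
      unique(pmin(nrow(res$catalog),
                  round(seq(0.125, 1, by = 0.125) * nrow(res$catalog))))
    subs <- nested_subsets(res$catalog, sizes,
                           seed = stage_seed(config, "robustness"))
    res$subset_curve <- subset_difference_curve(res$catalog, r_yr, subs,
                                                weighted = FALSE)
    write.csv(as.data.frame(res$subset_curve), out("subset_curve.csv"),
              row.names = FALSE, quote = FALSE)
    res$trends <- list(
      score = fit_trend(res$subset_curve$subset_size,
                        res$subset_curve$mean_abs_score_diff, "quadratic"),
      rank = fit_trend(res$subset_curve$subset_size,
                       res$subset_curve$mean_abs_rank_diff, "linear"))
    jsonlite::write_json(res$trends, out("trend.json"),
                         auto_unbox = TRUE, digits = NA)
    res$ablation <- weight_ablation(res$catalog, r_yr)
    jsonlite::write_json(res$ablation[c("mean_overall_weighted",
                                        "mean_overall_unweighted",
                                        "mean_abs_score_diff",
                                        "mean_abs_rank_diff")],
                         out("ablation.json"), auto_unbox = TRUE, digits = NA)
    write.csv(res$ablation$per_facility, out("ablation_per_facility.csv"),
              row.names = FALSE, quote = FALSE)
    note("robustness", sprintf("subset curve over %d sizes; ablation |dscore| %.2f",
                               length(subs), res$ablation$mean_abs_score_diff))
  }

  # -- concordance ---------------------------------------------------------
  if ("concordance" %in% stages) {
    m <- indicator_score_matrix(res$catalog, res$responses, yr)
    res$factors <- fit_factors(m, k = config$k_factors)
    res$allocation <- allocate_indicators(
      res$factors, weak_threshold = config$weak_threshold,
      cross_window = config$cross_window)
    res$mapping <- match_factors_to_sections(res$allocation, res$catalog)
    res$concordance <- concordance_table(res$allocation, res$mapping,
                                         res$catalog)
    write.csv(round(res$factors$loadings, 6), out("loadings.csv"),
              quote = FALSE)
    write.csv(as.data.frame(res$concordance), out("concordance.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(factor_to_section = as.list(res$mapping$factor_to_section),
           agreement = res$mapping$agreement),
      out("mapping.json"), auto_unbox = TRUE, digits = NA)
    tot <- res$concordance[res$concordance$section == "Total", ]
    note("concordance", sprintf("%d/%d indicators matched (%.0f%%)",
                                tot$n_matched, tot$n_indicators,
                                tot$pct_matched))
  }

  # -- effects -------------------------------------------------------------
  if ("effects" %in% stages) {
    if (is.null(res$scorecards))
      stop("missing upstream output for stage 'effects': run 'score' first")
    frame <- make_model_frame(res$scorecards, res$roster)
    res$effects <- effects_table(frame, prune = TRUE, alpha = config$alpha)
    write.csv(res$effects$table, out("effects_table.csv"),
              row.names = FALSE, quote = TRUE)
    traces <- lapply(res$effects$fits, function(f) f$pruning_trace)
    jsonlite::write_json(traces, out("pruning_trace.json"),
                         auto_unbox = TRUE, digits = NA)
    res$robust <- robust_fixed_check(frame, "overall")
    write.csv(res$robust$comparison, out("robust_check.csv"),
              row.names = FALSE, quote = FALSE)
    note("effects", sprintf("fitted %d outcomes; robust-check max |delta| %.3f",
                            length(res$effects$fits), res$robust$max_abs_delta))
  }

  # -- manifest ------------------------------------------------------------
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(config$out_dir, files))
  res$manifest <- list(
    package = "facscore",
    version = as.character(utils::packageVersion("facscore")),
    master_seed = config$seed,
    stage_seeds = setNames(
      lapply(config$stages, function(s) stage_seed(config, s)),
      config$stages),
    analysis_year = yr, stages = config$stages, log = log,
    files = setNames(as.list(unname(hashes)), files))
  jsonlite::write_json(res$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Validate catalog / roster / responses consistency
#'
#' Reports unknown indicators, facilities missing from the roster, answers
#' outside the allowed domain, and non-`na` answers recorded for indicators
#' that are not applicable at the facility's level.
#'
#' @param catalog an `indicator_catalog` (or data.frame).
#' @param roster a `facility_roster` (or data.frame).
#' @param responses a raw responses data.frame (validated here rather than
#'   at parse time).
#' @return data.frame of issues: `type`, `row`, `message` (zero rows when
#'   clean).
#' @export
validate_inputs <- function(catalog, roster, responses) {
  r <- as.data.frame(responses)
  issues <- list()
  add <- function(type, row, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, row = row, message = msg, stringsAsFactors = FALSE)

  a <- tolower(trimws(as.character(r$answer)))
  num <- suppressWarnings(as.numeric(a))
  bad <- !(a %in% c("yes", "no", "na")) & (is.na(num) | num < 0 | num > 1)
  for (i in which(bad))
    add("answer_domain", i, paste0("invalid answer '", r$answer[i], "'"))

  unk <- !r$indicator %in% catalog$id
  for (i in which(unk))
    add("unknown_indicator", i,
        paste0("indicator '", r$indicator[i], "' not in catalog"))

  nofac <- !r$facility %in% roster$facility
  for (i in which(nofac))
    add("unknown_facility", i,
        paste0("facility '", r$facility[i], "' not in roster"))

  ok <- !bad & !unk & !nofac
  if (any(ok)) {
    lev <- roster$level[match(r$facility, roster$facility)]
    app <- mapply_applicable(
      catalog$applicable_levels[match(r$indicator, catalog$id)], lev)
    viol <- ok & !app & a != "na"
    for (i in which(viol))
      add("applicability", i,
          paste0("indicator '", r$indicator[i], "' is not applicable at ",
                 lev[i], " level but has answer '", r$answer[i], "'"))
  }
  if (!length(issues))
    return(data.frame(type = character(), row = integer(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
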