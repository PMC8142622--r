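# Pipeline orchestration: validated configuration, the
# preprocess -> link -> calibrate -> classify run, provenance and
# structured logging. Everything a run needs is echoed into a sidecar so
# the run can be reproduced from its own output directory.

.CONFIG_KEYS <- c("left_path", "right_path", "gold_path", "left_dialect",
                  "right_dialect", "linker", "cutoff", "calibrate",
                  "review_n", "review_strategy", "bloom_m", "bloom_k",
                  "schedule", "top_n", "key_field", "output_dir", "seed")

#' Build a validated pipeline configuration
#'
#' All knobs of a linkage run in one validated object. Unknown keys are
#' rejected: a misspelled parameter must fail loudly, not fall back to a
#' default.
#'
#' @param left_path,right_path Registry CSV paths.
#' @param output_dir Output directory (created if absent).
#' @param gold_path Optional gold-standard CSV; when present the cut-off
#'   is calibrated against it.
#' @param left_dialect,right_dialect Date dialects of the inputs.
#' @param linker `"bloom"`, `"index"`, `"deterministic"` or `"two_stage"`.
#' @param cutoff Fixed cut-off used when `calibrate` is `FALSE` (or no
#'   gold standard is available).
#' @param calibrate Calibrate the cut-off from the gold standard?
#' @param review_n,review_strategy Review-sample parameters for
#'   calibration.
#' @param bloom_m,bloom_k Bloom-filter parameters.
#' @param schedule Query-mode schedule for the index linker.
#' @param top_n Candidates retained per probe (index linker).
#' @param key_field Key for the deterministic linker.
#' @param seed Global seed.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(left_path, right_path, output_dir,
                            gold_path = NULL,
                            left_dialect = "DMY", right_dialect = "DMY",
                            linker = c("bloom", "index", "deterministic",
                                       "two_stage"),
                            cutoff = 0.85, calibrate = !is.null(gold_path),
                            review_n = 2000L,
                            review_strategy = "score_stratified",
                            bloom_m = 128L, bloom_k = 3L,
                            schedule = c("exact", "semi_exact", "fuzzy"),
                            top_n = 10L, key_field = "nis", seed = 1L) {
  linker <- match.arg(linker)
  cfg <- list(left_path = left_path, right_path = right_path,
              gold_path = gold_path, left_dialect = left_dialect,
              right_dialect = right_dialect, linker = linker,
              cutoff = cutoff, calibrate = isTRUE(calibrate),
              review_n = as.integer(review_n),
              review_strategy = review_strategy,
              bloom_m = as.integer(bloom_m), bloom_k = as.integer(bloom_k),
              schedule = schedule, top_n = as.integer(top_n),
              key_field = key_field, output_dir = output_dir,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]. Unknown keys are rejected before any
#'   computation.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  .assert(length(unknown) == 0,
          paste("unknown config keys:", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

.log_line <- function(con, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full linkage pipeline
#'
#' Executes preprocess, link, (optionally) calibrate, classify, and
#' writes the run artifacts into `config$output_dir`: `linked_pairs.csv`,
#' `cutoff_report.json` / `.csv` (when calibrated), `preprocessing_report.json`,
#' `provenance.json` (config echo, package version, seed) and `log.jsonl`.
#' Identical configurations produce byte-identical linked-pair outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the linked pairs, the cut-off report (or
#'   `NULL`), output paths, and -- when a gold standard was supplied --
#'   precision/recall/F1 against it.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"),
          "`config` must be a pipeline_config")
  for (p in c(config$left_path, config$right_path, config$gold_path)) {
    .assert(file.exists(p), paste("input not found:", p))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$output_dir, "log.jsonl"), "wt")
  on.exit(close(logcon))

  left_raw <- read_registry(config$left_path)
  right_raw <- read_registry(config$right_path)
  gold <- if (!is.null(config$gold_path)) read_gold(config$gold_path)
  .log_line(logcon, "ingest", left = nrow(left_raw), right = nrow(right_raw))

  left <- clean_registry(left_raw, config$left_dialect)
  right <- clean_registry(right_raw, config$right_dialect)
  dl <- deduplicate(left); dr <- deduplicate(right)
  left <- dl$registry; right <- dr$registry
  prep <- list(left = preprocessing_report(left, dl$removed),
               right = preprocessing_report(right, dr$removed))
  jsonlite::write_json(prep, file.path(config$output_dir,
                                       "preprocessing_report.json"),
                       auto_unbox = TRUE)
  .log_line(logcon, "preprocess", left = nrow(left), right = nrow(right),
            dup_left = dl$removed, dup_right = dr$removed)

  params <- bloom_params(m = config$bloom_m, k = config$bloom_k)
  report <- NULL
  if (config$linker == "bloom") {
    cand <- build_blocks(left, right, default_predicates())
    scored <- score_candidates(left, right, cand, params)
    cutoff <- config$cutoff
    if (config$calibrate && !is.null(gold)) {
      # review sample comes from the linked dataset (best one-to-one
      # pairs), where both classes are well represented
      best_pairs <- links(classify(scored, 0))
      report <- calibrate_cutoff(best_pairs, gold, n = config$review_n,
                                 seed = config$seed,
                                 strategy = config$review_strategy)
      cutoff <- report$selected_cutoff
    }
    classified <- classify(scored, cutoff)
    linked <- links(classified)
  } else if (config$linker == "index") {
    idx <- build_index(right)
    linked_all <- link_by_index(left, idx, schedule = config$schedule,
                                top_n = config$top_n, cutoff = 0)
    cutoff <- config$cutoff
    if (config$calibrate && !is.null(gold)) {
      report <- calibrate_cutoff(linked_all, gold, n = config$review_n,
                                 seed = config$seed,
                                 strategy = config$review_strategy)
      cutoff <- report$selected_cutoff
    }
    linked <- linked_all[score >= cutoff]
  } else if (config$linker == "deterministic") {
    kj <- link_by_key(left, right, config$key_field)
    linked <- data.table::copy(kj$pairs)[, `:=`(score = 1)]
    jsonlite::write_json(split(kj$ambiguous$record_id, kj$ambiguous$key),
                         file.path(config$output_dir, "ambiguity_report.json"))
  } else {
    ts <- link_births_two_stage(left, right, stage1 = stage1_index(),
                                cutoff = config$cutoff)
    linked <- ts$links[, .(left_id = child_id, right_id = target_id,
                           score = mother_score)]
  }
  .log_line(logcon, "link", linker = config$linker, n_links = nrow(linked))

  out_cols <- intersect(c("left_id", "right_id", "score", "score_full_name",
                          "score_mother_name", "score_birth_date",
                          "score_sex", "score_municipality_code",
                          "classification", "mode"), names(linked))
  out <- data.table::as.data.table(linked)[, out_cols, with = FALSE]
  data.table::setorderv(out, intersect(c("score", "left_id", "right_id"),
                                       names(out)),
                        order = c(-1L, 1L, 1L)[seq_len(min(3, length(out_cols)))])
  pairs_path <- file.path(config$output_dir, "linked_pairs.csv")
  data.table::fwrite(out, pairs_path, na = "")
  if (!is.null(report)) {
    write_cutoff_report(report,
                        file.path(config$output_dir, "cutoff_report.json"),
                        file.path(config$output_dir, "cutoff_report.csv"))
  }
  quality <- NULL
  if (!is.null(gold)) {
    key <- paste(out$left_id, out$right_id)
    gkey <- paste(gold$left_id, gold$right_id)
    tp <- sum(key %in% gkey)
    precision <- if (nrow(out)) tp / nrow(out) else NA_real_
    recall <- tp / length(gkey)
    f1 <- if (!is.na(precision) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    quality <- list(true_positives = tp, precision = precision,
                    recall = recall, f1 = f1)
    .log_line(logcon, "evaluate", precision = precision, recall = recall,
              f1 = f1)
  }
  provenance <- list(package = "registrylink",
                     version = as.character(utils::packageVersion("registrylink")),
                     config = unclass(config),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."))
  jsonlite::write_json(provenance,
                       file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(linked = out, report = report, quality = quality,
                 paths = list(pairs = pairs_path,
                              output_dir = config$output_dir)))
}
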