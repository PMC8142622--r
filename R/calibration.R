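# Accuracy assessment and cut-off calibration: sample scored pairs for
# review, compute sensitivity/specificity over a cut-off grid, area under
# the ROC curve, and select the operating cut-off by the Youden index.
# In production the review labels come from clerical review of ~2000
# sampled pairs per linked dataset; in testing they come from the
# synthetic gold standard.

#' Sample scored pairs for review
#'
#' Draws a without-replacement sample of candidate pairs for labeling.
#' `"score_stratified"` splits the score distribution into deciles and
#' draws equally from each (taking a whole decile when it is smaller than
#' its quota), so rare high-score pairs are represented; `"uniform"`
#' samples uniformly. If `n` is at least the population size, the entire
#' population is returned and the `undersized` flag is set.
#'
#' @param scored A `scored_pairs` table (needs a `score` column).
#' @param n Requested sample size (default 2000, the customary clerical
#'   review batch).
#' @param seed Integer seed; fixed seeds reproduce identical samples.
#' @param strategy `"score_stratified"` or `"uniform"`.
#' @return A `review_sample`: the sampled rows with an unfilled `label`
#'   column and attributes `undersized`, `seed`, `strategy`.
#' @export
sample_pairs <- function(scored, n = 2000L, seed = 1L,
                         strategy = c("score_stratified", "uniform")) {
  strategy <- match.arg(strategy)
  sc <- data.table::as.data.table(scored)
  .assert(nrow(sc) > 0, "`scored` must be non-empty")
  .assert(is.numeric(n) && n >= 1, "`n` must be a positive integer")
  n <- as.integer(n)
  undersized <- n >= nrow(sc)
  idx <- if (undersized) {
    seq_len(nrow(sc))
  } else if (strategy == "uniform") {
    .with_seed(seed, sort(sample.int(nrow(sc), n)))
  } else {
    breaks <- unique(stats::quantile(sc$score, probs = 0:10 / 10,
                                     names = FALSE, type = 7))
    bin <- if (length(breaks) < 2) rep(1L, nrow(sc)) else
      .bincode(sc$score, breaks, include.lowest = TRUE)
    quota <- ceiling(n / length(unique(bin)))
    .with_seed(seed, {
      picked <- unlist(lapply(split(seq_len(nrow(sc)), bin), function(ix) {
        if (length(ix) <= quota) ix else sort(sample(ix, quota))
      }), use.names = FALSE)
      if (length(picked) > n) picked <- sort(sample(picked, n))
      sort(picked)
    })
  }
  out <- sc[idx]
  out[, label := NA_character_]
  data.table::setattr(out, "undersized", undersized)
  data.table::setattr(out, "seed", seed)
  data.table::setattr(out, "strategy", strategy)
  data.table::setattr(out, "class", c("review_sample", class(out)))
  out[]
}

#' Label a review sample from a gold standard
#'
#' Pairs present in the gold standard are labeled `match`, all others
#' `non_match` -- the testable stand-in for clerical review.
#'
#' @param sample A [sample_pairs()] result.
#' @param gold Gold-standard pairs (`left_id`, `right_id`).
#' @return The sample with the `label` column filled.
#' @export
label_sample <- function(sample, gold) {
  gold <- data.table::as.data.table(gold)
  s <- data.table::copy(data.table::as.data.table(sample))
  key <- paste(s$left_id, s$right_id, sep = "\r")
  gkey <- paste(gold$left_id, gold$right_id, sep = "\r")
  s[, label := ifelse(key %in% gkey, "match", "non_match")]
  for (a in c("undersized", "seed", "strategy"))
    data.table::setattr(s, a, attr(sample, a, exact = TRUE))
  data.table::setattr(s, "class", c("review_sample", "data.table",
                                    "data.frame"))
  s[]
}

#' Export / import a review sample for manual labeling
#'
#' `export_review_sample()` writes the pairs with an empty `label` column;
#' a reviewer fills `match` / `non_match` and `import_review_labels()`
#' reads them back.
#'
#' @param sample A review sample.
#' @param path CSV path.
#' @return The path (export) or the labeled sample (import).
#' @export
export_review_sample <- function(sample, path) {
  data.table::fwrite(data.table::as.data.table(sample), path, na = "")
  invisible(path)
}

#' @rdname export_review_sample
#' @export
import_review_labels <- function(path) {
  s <- data.table::fread(path, colClasses = "character", na.strings = "")
  .assert(all(c("left_id", "right_id", "score", "label") %in% names(s)),
          "labeled file must have left_id, right_id, score, label")
  s[, score := as.numeric(score)]
  bad <- !is.na(s$label) & !s$label %in% c("match", "non_match")
  .assert(!any(bad), "labels must be 'match' or 'non_match'")
  s[]
}

#' Confusion counts at a cut-off
#'
#' A pair counts as positive when `score >= cutoff`. Sensitivity is
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`; a ratio with a zero
#' denominator is reported as `NA` (missing), never as 0.
#'
#' @param sample A labeled review sample.
#' @param cutoff Threshold.
#' @return A list with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_at <- function(sample, cutoff) {
  s <- data.table::as.data.table(sample)
  .assert(all(!is.na(s$label)), "sample must be fully labeled")
  pos <- s$score >= cutoff
  is_match <- s$label == "match"
  tp <- sum(pos & is_match); fn <- sum(!pos & is_match)
  fp <- sum(pos & !is_match); tn <- sum(!pos & !is_match)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC analysis over a cut-off grid
#'
#' Computes sensitivity, specificity and Youden `J = sens + spec - 1` at
#' each grid cut-off, the ROC curve over the points
#' `(1 - specificity, sensitivity)` augmented with `(0,0)` and `(1,1)`,
#' the area under it by the trapezoidal rule, and the selected operating
#' cut-off (see [select_cutoff()]).
#'
#' @param sample A labeled review sample containing both classes.
#' @param grid Candidate cut-offs (at least 2; default 101 equally spaced
#'   points in `[0, 1]`).
#' @param criterion `"youden"` (maximize J) or `"closest_topleft"`
#'   (minimize distance to the (0, 1) corner).
#' @return An object of class `cutoff_report`: `table` (cutoff,
#'   sensitivity, specificity, youden_j), `auc`, `selected_cutoff`,
#'   `criterion`.
#' @export
roc_report <- function(sample, grid = seq(0, 1, by = 0.01),
                       criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  s <- data.table::as.data.table(sample)
  .assert(length(grid) >= 2, "grid must contain at least 2 cut-offs")
  .assert(all(!is.na(s$label)), "sample must be fully labeled")
  .assert(length(unique(s$label)) == 2,
          "labels must contain both matches and non-matches")
  grid <- sort(unique(grid))
  rows <- lapply(grid, function(ct) {
    cf <- confusion_at(s, ct)
    data.table::data.table(cutoff = ct, sensitivity = cf$sensitivity,
                           specificity = cf$specificity,
                           youden_j = cf$sensitivity + cf$specificity - 1)
  })
  tab <- data.table::rbindlist(rows)
  pts <- data.table::data.table(fpr = c(0, 1 - tab$specificity, 1),
                                tpr = c(0, tab$sensitivity, 1))
  pts <- pts[stats::complete.cases(pts)]
  data.table::setorder(pts, fpr, tpr)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  rep <- structure(list(table = tab, auc = auc, selected_cutoff = NA_real_,
                        criterion = criterion),
                   class = "cutoff_report")
  rep$selected_cutoff <- select_cutoff(rep)
  rep
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat("<cutoff_report>", nrow(x$table), "candidate cut-offs, AUC =",
      round(x$auc, 4), "\n  selected cut-off:", x$selected_cutoff,
      paste0("(", x$criterion, ")"), "\n")
  invisible(x)
}

#' Select the operating cut-off
#'
#' Returns the grid cut-off maximizing the Youden index
#' `J = sensitivity + specificity - 1` (or, under
#' `criterion = "closest_topleft"`, minimizing the Euclidean distance to
#' the ROC corner `(0, 1)`). Cut-offs with missing sensitivity or
#' specificity are excluded; ties are broken by the smallest cut-off. The
#' result is invariant to grid ordering and duplicated grid points.
#'
#' @param report A [roc_report()] object (or its `table`).
#' @return The selected cut-off (a scalar).
#' @export
select_cutoff <- function(report) {
  tab <- if (inherits(report, "cutoff_report")) report$table else
    data.table::as.data.table(report)
  criterion <- if (inherits(report, "cutoff_report")) report$criterion else
    "youden"
  tab <- unique(tab[!is.na(sensitivity) & !is.na(specificity)])
  .assert(nrow(tab) > 0, "no usable cut-off: all have missing measures")
  data.table::setorder(tab, cutoff)
  obj <- if (criterion == "youden") {
    tab$sensitivity + tab$specificity - 1
  } else {
    -sqrt((1 - tab$sensitivity)^2 + (1 - tab$specificity)^2)
  }
  tab$cutoff[which.max(obj)]
}

#' Calibrate a cut-off from scored pairs and a gold standard
#'
#' Convenience wrapper chaining [sample_pairs()], [label_sample()] and
#' [roc_report()]: the testable analogue of sampling ~2000 linked pairs
#' for clerical review and choosing the cut-off that maximizes the
#' accuracy measures.
#'
#' @param scored Scored pairs.
#' @param gold Gold standard.
#' @param n,seed,strategy Passed to [sample_pairs()].
#' @param grid,criterion Passed to [roc_report()].
#' @return A `cutoff_report`.
#' @export
calibrate_cutoff <- function(scored, gold, n = 2000L, seed = 1L,
                             strategy = "score_stratified",
                             grid = seq(0, 1, by = 0.01),
                             criterion = "youden") {
  sample <- sample_pairs(scored, n = n, seed = seed, strategy = strategy)
  labeled <- label_sample(sample, gold)
  if (length(unique(labeled$label)) < 2) {
    # stratified review missed one class entirely; fall back to labeling
    # the full candidate set so the ROC is defined
    labeled <- label_sample(scored, gold)
  }
  roc_report(labeled, grid = grid, criterion = criterion)
}

#' Write a cut-off report to disk
#'
#' JSON (full report) plus a flat CSV of the per-cutoff table.
#'
#' @param report A `cutoff_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_cutoff_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(auc = report$auc,
                              selected_cutoff = report$selected_cutoff,
                              criterion = report$criterion,
                              table = report$table),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) data.table::fwrite(report$table, csv_path)
  invisible(report)
}
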