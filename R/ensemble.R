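# Five-predictor ensemble deleteriousness score (LRT, MutationAssessor,
# PROVEAN, VEST3, CADD) mapped to predicted relative-activity bins.
#
# Default aggregation is the fraction of per-predictor deleterious calls
# among the available calls; every printed ensemble score in the study data
# is a multiple of 0.2 (k / 5), which is what this mode produces. A
# mean-of-normalised-scores mode is retained as an alternative.

PREDICTORS <- c("lrt", "mutation_assessor", "provean", "vest3", "cadd")

#' Ensemble scoring configuration
#'
#' Per-predictor deleterious directions and thresholds ship as a documented
#' default: LRT (p-like score, lower = deleterious, < 0.001), MutationAssessor
#' (higher, >= 1.935), PROVEAN (lower, <= -2.5), VEST3 (higher, >= 0.5),
#' CADD phred (higher, >= 20). The activity-bin map anchors the scores the
#' framework reports (1.0 -> 0%, 0.8 -> 0-10%, 0.6 -> 20-30%) and extends to
#' the rest of `[0, 1]` by piecewise-linear interpolation, clearly an
#' extension beyond the anchored points.
#'
#' @param thresholds named list of `list(cut =, higher_deleterious =)` per
#'   predictor.
#' @param aggregation `"fraction"` (default) or `"mean"` of normalised scores.
#' @param deleterious_score_threshold ensemble score above which a variant is
#'   called deleterious (default 0.5).
#' @param bin_anchors data.frame `score`, `lo`, `hi` anchoring the score to
#'   activity-percent mapping; must cover score 0 and 1.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(
    thresholds = list(
      lrt = list(cut = 0.001, higher_deleterious = FALSE),
      mutation_assessor = list(cut = 1.935, higher_deleterious = TRUE),
      provean = list(cut = -2.5, higher_deleterious = FALSE),
      vest3 = list(cut = 0.5, higher_deleterious = TRUE),
      cadd = list(cut = 20, higher_deleterious = TRUE)),
    aggregation = c("fraction", "mean"),
    deleterious_score_threshold = 0.5,
    bin_anchors = data.frame(
      score = c(0.0, 0.6, 0.8, 1.0),
      lo = c(80, 20, 0, 0),
      hi = c(90, 30, 10, 0))) {
  aggregation <- match.arg(aggregation)
  stopifnot(all(PREDICTORS %in% names(thresholds)),
            min(bin_anchors$score) == 0, max(bin_anchors$score) == 1,
            !is.unsorted(bin_anchors$score))
  structure(list(thresholds = thresholds, aggregation = aggregation,
                 deleterious_score_threshold = deleterious_score_threshold,
                 bin_anchors = bin_anchors),
            class = "ensemble_config")
}

#' Per-predictor deleterious call
#'
#' @param raw raw predictor score (may be `NA`: returns `NA` with a warning,
#'   excluded from aggregation).
#' @param predictor one of `"lrt"`, `"mutation_assessor"`, `"provean"`,
#'   `"vest3"`, `"cadd"`.
#' @param cfg an [ensemble_config()].
#' @return Logical flag (or `NA` for a missing score).
#' @examples
#' call_predictor(-10, "provean")  # deleterious (lower-is-worse predictor)
#' call_predictor(0, "cadd")       # benign
#' @export
call_predictor <- function(raw, predictor, cfg = ensemble_config()) {
  if (!predictor %in% names(cfg$thresholds)) {
    stop("no threshold configured for predictor: ", predictor)
  }
  if (is.na(raw)) {
    warning("missing ", predictor, " score: no call")
    return(NA)
  }
  th <- cfg$thresholds[[predictor]]
  if (th$higher_deleterious) raw >= th$cut else raw <= th$cut
}

map_activity_bin <- function(score, anchors) {
  lo <- stats::approx(anchors$score, anchors$lo, score, rule = 2,
                      ties = "ordered")$y
  hi <- stats::approx(anchors$score, anchors$hi, score, rule = 2,
                      ties = "ordered")$y
  c(lo = lo, hi = hi)
}

#' Ensemble deleteriousness score and predicted activity bin
#'
#' Fraction mode (default): score = deleterious calls / available calls.
#' Mean mode: mean of per-predictor scores normalised to `[0, 1]` in the
#' deleterious direction (threshold maps to 0.5). Deleterious when the score
#' exceeds 0.5; the predicted activity bin comes from the configured anchor
#' map.
#'
#' @param scores named list/vector of raw predictor scores (`lrt`,
#'   `mutation_assessor`, `provean`, `vest3`, `cadd`), `NA` allowed.
#' @param cfg an [ensemble_config()].
#' @param label variant label carried into the result.
#' @return An `ensemble_prediction` list: `label`, `adme_score`,
#'   `deleterious`, `bin_lo`, `bin_hi`, `n_calls`, `calls`.
#' @examples
#' adme_score(list(lrt = 0, mutation_assessor = 5, provean = -9,
#'                 vest3 = 0.9, cadd = 29), label = "A297V")
#' @export
adme_score <- function(scores, cfg = ensemble_config(), label = NA_character_) {
  raw <- vapply(PREDICTORS, function(p) {
    v <- scores[[p]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (all(is.na(raw))) stop("all predictor scores missing for ", label)
  calls <- vapply(PREDICTORS, function(p) {
    if (is.na(raw[[p]])) return(NA)
    suppressWarnings(call_predictor(raw[[p]], p, cfg))
  }, logical(1))
  avail <- !is.na(calls)
  score <- if (cfg$aggregation == "fraction") {
    sum(calls[avail]) / sum(avail)
  } else {
    norm <- vapply(PREDICTORS[avail], function(p) {
      th <- cfg$thresholds[[p]]
      v <- raw[[p]]
      # logistic squash centred on the threshold, oriented so that more
      # deleterious -> closer to 1; scale = |threshold| + 1
      sc <- abs(th$cut) + 1
      z <- (v - th$cut) / sc * if (th$higher_deleterious) 1 else -1
      1 / (1 + exp(-4 * z))
    }, numeric(1))
    mean(norm)
  }
  bin <- map_activity_bin(score, cfg$bin_anchors)
  structure(list(label = label, adme_score = score,
                 deleterious = score > cfg$deleterious_score_threshold,
                 bin_lo = unname(bin["lo"]), bin_hi = unname(bin["hi"]),
                 n_calls = sum(avail), calls = calls),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat("<ensemble_prediction> ", x$label, ": score ", round(x$adme_score, 3),
      if (x$deleterious) " (deleterious)" else " (tolerated)",
      ", predicted activity ", x$bin_lo, "-", x$bin_hi, "%\n", sep = "")
  invisible(x)
}

#' Score a table of variants
#'
#' @param tab data.frame with a `variant` column and raw-score columns
#'   `lrt`, `mutation_assessor`, `provean`, `vest3`, `cadd`.
#' @param cfg an [ensemble_config()].
#' @return data.frame: `variant`, `adme_score`, `deleterious`, `bin_lo`,
#'   `bin_hi`, `n_calls`.
#' @export
score_variants <- function(tab, cfg = ensemble_config()) {
  stopifnot("variant" %in% names(tab))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    p <- adme_score(as.list(tab[i, intersect(PREDICTORS, names(tab))]),
                    cfg = cfg, label = tab$variant[i])
    data.frame(variant = p$label, adme_score = p$adme_score,
               deleterious = p$deleterious, bin_lo = p$bin_lo,
               bin_hi = p$bin_hi, n_calls = p$n_calls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
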