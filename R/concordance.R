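# Relative catalytic activity from assay replicates, and concordance between
# predicted activity bins and measured activities.

#' Relative catalytic activity from assay replicates
#'
#' Each replicate product-formation rate is expressed as a percentage of the
#' mean reference (wild-type) rate; the result is the mean and sample
#' standard deviation (n - 1 denominator) over replicates.
#'
#' @param rates numeric vector of per-replicate rates (>= 2 values).
#' @param reference_rates matched wild-type replicate rates (mean must be
#'   positive).
#' @param label variant label.
#' @return A `relative_activity` list: `label`, `mean_pct`, `sd_pct`,
#'   `n_replicates`.
#' @examples
#' relative_activity(c(10, 20, 30), c(95, 100, 105))  # 20% +/- 10%
#' @export
relative_activity <- function(rates, reference_rates, label = NA_character_) {
  stopifnot(length(rates) >= 2, all(rates >= 0))
  ref_mean <- mean(reference_rates)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("reference mean rate must be positive")
  }
  pct <- 100 * rates / ref_mean
  structure(list(label = label, mean_pct = mean(pct),
                 sd_pct = stats::sd(pct), n_replicates = length(rates)),
            class = "relative_activity")
}

#' Concordance of one prediction with one measurement
#'
#' Default rule `"sd-overlap"`: concordant when the measured interval
#' `[mean - SD, mean + SD]` intersects the predicted bin (closed intervals),
#' with a point prediction of 0% widened to `[0, 10]` - the lowest
#' reportable class of the scoring framework. Alternative rules:
#' `"mean-in-bin"` (measured mean inside the bin) and `"tolerance"` (mean
#' within `tol` percentage points of the bin).
#'
#' @param bin_lo,bin_hi predicted activity bin (percent).
#' @param mean_pct,sd_pct measured relative activity (percent).
#' @param rule concordance rule id.
#' @param tol tolerance (percent points) for the `"tolerance"` rule.
#' @return Logical flag.
#' @export
concordant <- function(bin_lo, bin_hi, mean_pct, sd_pct = 0,
                       rule = c("sd-overlap", "mean-in-bin", "tolerance"),
                       tol = 10) {
  rule <- match.arg(rule)
  if (bin_lo == 0 && bin_hi == 0) bin_hi <- 10
  switch(rule,
         "sd-overlap" = (mean_pct - sd_pct) <= bin_hi &&
                        (mean_pct + sd_pct) >= bin_lo,
         "mean-in-bin" = mean_pct >= bin_lo && mean_pct <= bin_hi,
         "tolerance" = mean_pct >= bin_lo - tol && mean_pct <= bin_hi + tol)
}

#' Concordance summary over a set of variants
#'
#' @param tab data.frame with columns `variant`, `bin_lo`, `bin_hi`,
#'   `mean_pct`, `sd_pct`.
#' @param rule rule id passed to [concordant()].
#' @param tol tolerance for the `"tolerance"` rule.
#' @return A `concordance_result`: per-variant table (with `concordant`
#'   flags and the rule id) plus `n_concordant`, `n_total`, `fraction` and
#'   `percent` (the rendered integer percentage, rounded down as printed in
#'   study summaries: 6/11 -> 54).
#' @export
concordance_summary <- function(tab, rule = "sd-overlap", tol = 10) {
  needed <- c("variant", "bin_lo", "bin_hi", "mean_pct", "sd_pct")
  stopifnot(all(needed %in% names(tab)), nrow(tab) >= 1)
  flags <- vapply(seq_len(nrow(tab)), function(i) {
    concordant(tab$bin_lo[i], tab$bin_hi[i], tab$mean_pct[i], tab$sd_pct[i],
               rule = rule, tol = tol)
  }, logical(1))
  per <- tab[, needed]
  per$concordant <- flags
  per$rule <- rule
  n <- nrow(per)
  k <- sum(flags)
  structure(list(per_variant = per, n_concordant = k, n_total = n,
                 fraction = k / n, percent = floor(100 * k / n), rule = rule),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> rule = ", x$rule, "\n", sep = "")
  cat("  concordant: ", x$n_concordant, " of ", x$n_total, " (",
      x$percent, "%)\n", sep = "")
  invisible(x)
}

#' Packaged study table: predicted bins and measured activities
#'
#' The 11 CYP2C19/CYP2D6 missense variants with their ensemble scores,
#' predicted activity bins and measured relative activities (mean +/- SD
#' percent of the reference enzyme, three independent expressions),
#' transcribed from the study's comparison table so the headline concordance
#' check needs no download.
#'
#' @return data.frame: `variant`, `enzyme`, `adme_score`, `bin_lo`, `bin_hi`,
#'   `call`, `mean_pct`, `sd_pct`.
#' @export
cyp_reference_table <- function() {
  f <- system.file("extdata", "cyp_variant_reference.tsv", package = "cypvar")
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
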