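# Orchestration: prepare -> mutate -> interactions -> channels -> ensemble ->
# concordance in one configured run, with provenance.

#' Validate and normalise a pipeline run configuration
#'
#' A configuration is a plain list (or a YAML/JSON file) with any of the
#' blocks: `scores` (path/data.frame of raw predictor scores), `predictions`
#' (pre-computed predicted bins), `measured` (path/data.frame with
#' `variant`, `mean_pct`, `sd_pct`), `structure` (list: `pdb`,
#' `chains_to_keep`, `het_to_keep`), `ligand` (path), `variants` (labels,
#' e.g. `"A297V"`), `chain`, `channel` (sphere-list path or `"compute"`),
#' `rule`, `seed`, `out_dir`. Structural blocks are optional: with only
#' scores and measurements the run covers ensemble + concordance.
#'
#' @param cfg list or path to a YAML/JSON config file.
#' @return The validated config list.
#' @export
run_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    cfg <- if (grepl("\\.json$", cfg)) jsonlite::read_json(cfg, simplifyVector = TRUE)
           else yaml::read_yaml(cfg)
  }
  stopifnot(is.list(cfg))
  for (f in c("scores", "predictions", "measured", "ligand", "channel")) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1 && v != "compute" && !file.exists(v)) {
      stop("configured file does not exist: ", f, " = ", v)
    }
  }
  if (!is.null(cfg$structure) && is.character(cfg$structure$pdb) &&
      !file.exists(cfg$structure$pdb)) {
    stop("configured file does not exist: structure$pdb = ", cfg$structure$pdb)
  }
  if (!is.null(cfg$variants) && anyDuplicated(cfg$variants)) {
    stop("variant labels must be unique")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$rule)) cfg$rule <- "sd-overlap"
  if (is.null(cfg$chain)) cfg$chain <- "A"
  cfg
}

read_tab <- function(x) {
  if (is.data.frame(x)) return(x)
  sep <- if (grepl("\\.csv$", x)) "," else "\t"
  utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Run the full variant-assessment pipeline
#'
#' Executes the configured stages in order: ensemble scoring, concordance
#' against measurements, structural mutagenesis + interaction reports, and
#' channel proximity classification. A failure in a per-variant structural
#' stage is recorded in that variant's slot and does not abort the others.
#' Re-running an unchanged config reproduces identical report content.
#'
#' @param cfg configuration accepted by [run_config()].
#' @return A `run_report` list: `predictions`, `concordance`,
#'   `interaction_reports`, `interaction_table`, `proximity`, `errors`,
#'   `provenance`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- run_config(cfg)
  report <- list(predictions = NULL, concordance = NULL,
                 interaction_reports = list(), interaction_table = NULL,
                 proximity = NULL, errors = list(),
                 provenance = list(seed = cfg$seed, rule = cfg$rule,
                                   package_version =
                                     as.character(utils::packageVersion("cypvar"))))

  # ensemble stage
  preds <- NULL
  if (!is.null(cfg$scores)) {
    ec <- if (is.null(cfg$ensemble)) ensemble_config() else cfg$ensemble
    preds <- score_variants(read_tab(cfg$scores), cfg = ec)
  } else if (!is.null(cfg$predictions)) {
    preds <- read_tab(cfg$predictions)
  }
  report$predictions <- preds

  # concordance stage
  if (!is.null(preds) && !is.null(cfg$measured)) {
    meas <- read_tab(cfg$measured)
    tab <- merge(preds[, c("variant", "bin_lo", "bin_hi")],
                 meas[, c("variant", "mean_pct", "sd_pct")],
                 by = "variant", sort = FALSE)
    report$concordance <- concordance_summary(tab, rule = cfg$rule)
  }

  # structural stage
  if (!is.null(cfg$structure)) {
    prep <- preparation_config(
      chains_to_keep = if (is.null(cfg$structure$chains_to_keep)) "A"
                       else cfg$structure$chains_to_keep,
      het_to_keep = if (is.null(cfg$structure$het_to_keep)) "HEM"
                    else cfg$structure$het_to_keep)
    s <- read_structure(cfg$structure$pdb)
    s <- suppressWarnings(prepare_structure(s, prep))
    if (!is.null(cfg$ligand)) s <- add_ligand(s, read_ligand(cfg$ligand))
    s <- assign_radii(s)
    lib <- if (is.null(cfg$rotamers)) rotamer_library()
           else rotamer_library(cfg$rotamers)
    params <- if (is.null(cfg$interaction)) interaction_params()
              else cfg$interaction
    for (v in cfg$variants) {
      res <- tryCatch({
        m <- mutation_spec(v, chain = cfg$chain)
        mut <- apply_mutation(s, m, lib, params = params)
        variant_report(s, mut, paste0(m$chain, ":", m$resno), params = params,
                       label = m$label)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        report$errors[[v]] <- conditionMessage(res)
      } else {
        report$interaction_reports[[v]] <- res
      }
    }
    if (length(report$interaction_reports) > 0) {
      report$interaction_table <- interaction_table(report$interaction_reports)
    }

    # channel stage
    if (!is.null(cfg$channel)) {
      chp <- if (is.null(cfg$channel_params)) channel_params()
             else cfg$channel_params
      ch <- tryCatch({
        if (identical(cfg$channel, "compute")) {
          find_channel_simple(s, params = chp)
        } else {
          load_channel(cfg$channel)
        }
      }, error = function(e) e)
      if (inherits(ch, "error")) {
        report$errors[["channel"]] <- conditionMessage(ch)
      } else {
        sites <- if (!is.null(cfg$sites)) cfg$sites else {
          vapply(cfg$variants, function(v)
            paste0(cfg$chain, ":", mutation_spec(v)$resno), character(1))
        }
        report$proximity <- classify_proximity(ch, s, unname(sites),
                                               params = chp)
        report$channel <- ch
      }
    }
    report$provenance$radius_set <- s$metadata$radius_set
    report$provenance$hydrogen_mode <- s$metadata$hydrogen_mode
    report$provenance$rotamer_library <- lib$file
  }

  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

#' Flatten interaction reports to a study-style table
#'
#' One row per variant: interaction counts in wild type and mutant, their
#' difference, and the mutant clash count, plus provenance columns.
#'
#' @param reports list of `variant_report` objects.
#' @return data.frame.
#' @export
interaction_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    data.frame(variant = r$label, n_wt = r$n_interactions_wt,
               n_mut = r$n_interactions_mut, difference = r$difference,
               n_clashes = r$n_clashes_mut,
               radius_set = if (is.null(r$conventions$radius_set)) NA_character_
                            else r$conventions$radius_set,
               hydrogen_mode = r$conventions$hydrogen_mode,
               counting_unit = r$conventions$counting_unit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run report to disk
#'
#' Emits `predictions.tsv`, `concordance.tsv` + `concordance.json`,
#' `interactions.tsv`, `proximity.tsv` and `provenance.json` (each only when
#' its stage ran).
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$predictions)) wt(report$predictions, "predictions.tsv")
  if (!is.null(report$concordance)) {
    wt(report$concordance$per_variant, "concordance.tsv")
    jsonlite::write_json(
      list(n_concordant = report$concordance$n_concordant,
           n_total = report$concordance$n_total,
           fraction = report$concordance$fraction,
           percent = report$concordance$percent,
           rule = report$concordance$rule),
      file.path(dir, "concordance.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$interaction_table)) {
    wt(report$interaction_table, "interactions.tsv")
  }
  if (!is.null(report$proximity)) wt(report$proximity, "proximity.tsv")
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$predictions)) {
    cat("  predictions: ", nrow(x$predictions), " variants\n", sep = "")
  }
  if (!is.null(x$concordance)) {
    cat("  concordance: ", x$concordance$n_concordant, "/",
        x$concordance$n_total, " (", x$concordance$percent, "%)\n", sep = "")
  }
  if (!is.null(x$interaction_table)) {
    cat("  interaction reports: ", nrow(x$interaction_table), "\n", sep = "")
  }
  if (length(x$errors) > 0) {
    cat("  errors: ", paste(names(x$errors), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
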