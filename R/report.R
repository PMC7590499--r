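# Orchestration: one call runs coding (or ingests precomputed outputs),
# individual- and population-level metrics, the Dirichlet harness, and
# writes the report files. The package's function surface is its interface;
# run_pipeline() is the single entry point a script would wrap.

#' Pipeline run configuration
#'
#' Exactly one of `outputs` (precomputed coder outputs) and `probbase`
#' (code the records here) must be supplied. Inputs may be given as objects
#' or file paths.
#'
#' @param records a [va_records()] cohort or a records CSV path.
#' @param outputs a [va_outputs()] table or CSV path, or `NULL`.
#' @param probbase a [probbase()] or probbase CSV path, or `NULL`.
#' @param dictionary a [cause_dictionary()] or CSV path.
#' @param prevalence a [prevalence_setting()].
#' @param rule a [reporting_rule()].
#' @param validation a [validation_config()].
#' @param out_dir directory for report files (created if missing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(records, outputs = NULL, probbase = NULL,
                       dictionary = default_cause_dictionary(),
                       prevalence = prevalence_setting(),
                       rule = reporting_rule(),
                       validation = validation_config(),
                       out_dir = tempfile("vacheck_run_")) {
  if (is.null(outputs) == is.null(probbase)) {
    stop("supply exactly one of 'outputs' (precomputed) or 'probbase' (code here)")
  }
  if (is.character(dictionary)) dictionary <- read_cause_dictionary(dictionary)
  if (is.character(records)) records <- load_records(records, dictionary)
  if (is.character(outputs)) outputs <- load_va_outputs(outputs)
  if (is.character(probbase)) probbase <- read_probbase(probbase)
  stopifnot(inherits(records, "va_records"),
            inherits(validation, "validation_config"))
  structure(list(records = records, outputs = outputs, probbase = probbase,
                 dictionary = dictionary, prevalence = prevalence,
                 rule = rule, validation = validation, out_dir = out_dir),
            class = "run_config")
}

# percentages (1 decimal) forced to sum exactly to 100.0 per column via
# largest-remainder apportionment of tenths
largest_remainder_pct <- function(fractions) {
  tenths <- fractions * 1000
  base <- floor(tenths)
  short <- 1000 - sum(base)
  if (short > 0) {
    give <- utils::head(order(tenths - base, decreasing = TRUE), short)
    base[give] <- base[give] + 1
  }
  base / 10
}

#' Gold-by-predicted flow table
#'
#' One row per (gold cause, predicted top cause) pair with its death count:
#' the data behind an alluvial diagram of cause reassignment. Counts sum to
#' the cohort size and marginalize to the confusion-matrix margins.
#'
#' @param records a [va_records()] cohort (or gold cause vector).
#' @param outputs a [va_outputs()] table (or predicted top-cause vector).
#' @param dictionary a [cause_dictionary()] (orders the rows).
#' @return data.frame with columns `gold`, `predicted`, `count`.
#' @export
export_flows <- function(records, outputs, dictionary = default_cause_dictionary()) {
  gold <- as_gold(records)
  pred <- as_top(outputs)
  if (length(gold) == 0) {
    return(data.frame(gold = character(0), predicted = character(0),
                      count = integer(0)))
  }
  m <- confusion_matrix(gold, pred, dictionary$code)
  flows <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(flows) <- c("gold", "predicted", "count")
  flows <- flows[flows$count > 0, , drop = FALSE]
  rownames(flows) <- NULL
  flows
}

#' Infection-subset individual metrics
#'
#' Re-runs the per-cause confusion analysis on the pooled subset of deaths
#' whose gold-standard broad category is infectious. When both the records
#' (`infection_cause`) and the outputs (`infection_cause1`) carry
#' infection-level annotations, the analysis is at the subtype level over
#' [infection_dictionary()]; otherwise it falls back to broad categories
#' within the subset.
#'
#' @param records a [va_records()] cohort.
#' @param outputs the aligned [va_outputs()] table.
#' @param dictionary broad [cause_dictionary()] used for the fallback.
#' @return data.frame of per-cause counts and metrics (see
#'   [binary_metrics()]), with an attribute `"level"` of `"subtype"` or
#'   `"broad"`.
#' @export
infection_subset_metrics <- function(records, outputs,
                                     dictionary = default_cause_dictionary()) {
  stopifnot(inherits(records, "va_records"))
  sel <- records$data$cda_cause == "infections"
  if (!any(sel)) stop("no deaths with an infectious gold-standard cause")
  out_sub <- outputs[sel, , drop = FALSE]
  has_subtype <- "infection_cause" %in% names(records$data) &&
    !all(is.na(records$data$infection_cause[sel])) &&
    "infection_cause1" %in% names(outputs)
  if (has_subtype) {
    gold <- records$data$infection_cause[sel]
    top <- top_cause(out_sub)
    pred <- ifelse(top == "infections" & !is.na(out_sub$infection_cause1),
                   out_sub$infection_cause1, top)
    causes <- group_causes(infection_dictionary(), "other_adult",
                           substantive = TRUE)
    level <- "subtype"
  } else {
    gold <- records$data$cda_cause[sel]
    pred <- top_cause(out_sub)
    causes <- unique(dictionary$code)
    level <- "broad"
  }
  res <- binary_metrics(confusion_by_cause(gold, pred, causes))
  attr(res, "level") <- level
  res
}

#' Run the full validation pipeline
#'
#' Codes the records (or ingests precomputed outputs), evaluates every study
#' group with [validate_group()], and writes six report files to
#' `config$out_dir`:
#' \itemize{
#' \item `table1_individual.csv` — per group and cause: confusion counts and
#'   sensitivity/specificity/PPV/NPV display percentages (`N/A` literal for
#'   undefined entries);
#' \item `table2_concordance.csv` — per group: median chance-corrected
#'   concordance across draws and observed-data kappa;
#' \item `table3_infections.csv` — infection-subset metrics pooled across
#'   groups (see [infection_subset_metrics()]);
#' \item `table4_population.csv` — per group and cause: likelihood-weighted
#'   coder CSMFs and gold-standard CSMFs (percent columns forced to sum to
#'   100.0 by largest-remainder rounding) plus median CSMF accuracy and its
#'   chance-corrected value;
#' \item `draws.csv` — per group and draw: composition, CCC, CSMF accuracy,
#'   chance-corrected CSMF accuracy;
#' \item `flows.csv` — gold-by-predicted flow counts (see [export_flows()]).
#' }
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the per-group [validate_group()] results
#'   (`groups`), the coder outputs (`outputs`) and the report file paths
#'   (`files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- config$records
  dictionary <- config$dictionary
  if (is.null(config$outputs)) {
    message("coding records with the Bayes engine")
    outputs <- code_cohort(records, config$probbase, config$prevalence,
                           config$rule, dictionary)
  } else {
    message("using precomputed coder outputs; engine skipped")
    outputs <- config$outputs
    if (nrow(outputs) != n_records(records)) {
      stop("precomputed outputs do not match the cohort size")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("table1_individual.csv", "table2_concordance.csv",
                       "table3_infections.csv", "table4_population.csv",
                       "draws.csv", "flows.csv"))
  names(paths) <- c("table1", "table2", "table3", "table4", "draws", "flows")

  groups_present <- intersect(va_groups(), unique(records$data$group))
  t1 <- t2 <- t4 <- dr <- list()
  results <- list()
  for (g in groups_present) {
    sel <- records$data$group == g
    rec_g <- records[sel]
    out_g <- outputs[sel, , drop = FALSE]
    cfg <- config$validation
    v <- validate_group(rec_g, out_g, dictionary, cfg)
    results[[g]] <- v

    pc <- v$per_cause
    t1[[g]] <- data.frame(group = g, cause = pc$cause, n = pc$n,
                          TP = pc$TP, TN = pc$TN, FP = pc$FP, FN = pc$FN,
                          sensitivity = pc$sensitivity_pct,
                          specificity = pc$specificity_pct,
                          ppv = pc$ppv_pct, npv = pc$npv_pct)
    t2[[g]] <- data.frame(group = g, ccc = v$median_ccc, kappa = v$kappa)

    causes <- group_causes(dictionary, g)
    cda <- cda_csmf(rec_g, causes)
    mod <- model_csmf(out_g, causes, cfg$max_causes_used, unknown = "residual")
    t4[[g]] <- data.frame(group = g, cause = causes,
                          model_n = round(mod * n_records(rec_g), 1),
                          model_csmf_pct = largest_remainder_pct(mod),
                          cda_n = as.integer(round(cda * n_records(rec_g))),
                          cda_csmf_pct = largest_remainder_pct(cda),
                          csmfa = v$median_csmfa,
                          cccsmfa = v$median_cccsmfa)
    comp_cols <- setdiff(names(v$draws), c("draw", "ccc", "csmfa", "cccsmfa"))
    composition <- apply(v$draws[comp_cols], 1, function(z)
      paste(comp_cols, sprintf("%.6f", z), sep = ":", collapse = ";"))
    dr[[g]] <- data.frame(group = g, draw = v$draws$draw,
                          composition = composition,
                          ccc = v$draws$ccc, csmfa = v$draws$csmfa,
                          cccsmfa = v$draws$cccsmfa)
  }
  na_literal <- function(d) { d[] <- lapply(d, function(col) {
    if (is.numeric(col)) { col <- as.character(col); col[is.na(col)] <- "N/A" }
    col }); d }
  utils::write.csv(na_literal(do.call(rbind, t1)), paths["table1"], row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, t2), paths["table2"], row.names = FALSE, quote = FALSE)
  t3 <- tryCatch(infection_subset_metrics(records, outputs, dictionary),
                 error = function(e) NULL)
  if (is.null(t3)) {
    t3df <- data.frame(cause = character(0), n = integer(0))
  } else {
    t3df <- data.frame(cause = t3$cause, n = t3$n, TP = t3$TP, TN = t3$TN,
                       FP = t3$FP, FN = t3$FN,
                       sensitivity = t3$sensitivity_pct,
                       specificity = t3$specificity_pct,
                       ppv = t3$ppv_pct, npv = t3$npv_pct)
  }
  utils::write.csv(na_literal(t3df), paths["table3"], row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, t4), paths["table4"], row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, dr), paths["draws"], row.names = FALSE, quote = FALSE)
  utils::write.csv(export_flows(records, outputs, dictionary), paths["flows"],
                   row.names = FALSE, quote = FALSE)
  message("reports written to ", config$out_dir,
          " (seed ", config$validation$seed, ", ",
          config$validation$n_draws, " draws per group)")
  invisible(list(groups = results, outputs = outputs, files = paths))
}
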