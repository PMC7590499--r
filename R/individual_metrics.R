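# Individual-level agreement between the coder and the gold standard:
# per-cause confusion counts built from the top (most probable) cause,
# sensitivity/specificity/PPV/NPV with round-half-to-even percent display,
# Cohen's kappa, and chance-corrected concordance (CCC).

#' Top (most probable) cause of each coded death
#'
#' @param outputs a [va_outputs()] table.
#' @return Character vector: `cause1`, or `"non_conclusive"` for an empty
#'   report.
#' @export
top_cause <- function(outputs) {
  top <- outputs$cause1
  top[is.na(top)] <- nonconclusive_code()
  top
}

as_gold <- function(records) {
  if (inherits(records, "va_records")) records$data$cda_cause else as.character(records)
}

as_top <- function(outputs) {
  if (inherits(outputs, "va_outputs") || is.data.frame(outputs)) top_cause(outputs)
  else as.character(outputs)
}

#' Gold-by-predicted confusion matrix
#'
#' @param records a [va_records()] cohort or a character vector of gold
#'   cause codes.
#' @param outputs a [va_outputs()] table or a character vector of predicted
#'   top causes.
#' @param causes character vector of cause codes spanning the axes
#'   (the residual category included); codes outside the list are kept as
#'   extra levels so totals are preserved.
#' @return Integer matrix, rows = gold cause, columns = predicted top cause.
#' @export
confusion_matrix <- function(records, outputs, causes) {
  gold <- as_gold(records)
  pred <- as_top(outputs)
  if (length(gold) != length(pred)) stop("records and outputs differ in length")
  lev <- union(causes, union(gold, pred))
  m <- table(factor(gold, lev), factor(pred, lev))
  m <- unclass(m)
  names(dimnames(m)) <- c("gold", "predicted")
  m
}

#' Per-cause confusion counts from top-cause assignment
#'
#' For each cause `j`: TP = gold `j` and top `j`; FN = gold `j`, top not `j`;
#' FP = gold not `j`, top `j`; TN = the remainder. Each row sums to the
#' cohort size, and `TP + FN` is the gold-standard count of the cause.
#'
#' @inheritParams confusion_matrix
#' @param causes cause codes to tabulate (typically
#'   `group_causes(dictionary, group)`).
#' @return data.frame with columns `cause`, `n` (gold count), `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_by_cause <- function(records, outputs, causes) {
  gold <- as_gold(records)
  pred <- as_top(outputs)
  if (length(gold) != length(pred)) stop("records and outputs differ in length")
  if (inherits(records, "va_records") &&
      (inherits(outputs, "va_outputs") || is.data.frame(outputs)) &&
      !identical(sub("\\.\\d+$", "", records$data$id), sub("\\.\\d+$", "", outputs$id))) {
    stop("record ids and output ids do not align")
  }
  n <- length(gold)
  res <- lapply(causes, function(j) {
    tp <- sum(gold == j & pred == j)
    fn <- sum(gold == j & pred != j)
    fp <- sum(gold != j & pred == j)
    data.frame(cause = j, n = tp + fn, TP = tp, TN = n - tp - fn - fp,
               FP = fp, FN = fn, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Round an exact percentage half to even
#'
#' Computes `100 * num / den` rounded to the nearest integer with ties going
#' to the even integer (banker's rounding), using integer arithmetic so the
#' tie decision is exact.
#'
#' @param num,den non-negative integer vectors (recycled); `den == 0` yields
#'   `NA` (the metric is not applicable).
#' @return Integer vector of display percentages.
#' @export
#' @examples
#' pct_round_half_even(c(25, 10, 54), c(27, 16, 80))  # 93, 62, 68
pct_round_half_even <- function(num, den) {
  stopifnot(all(num >= 0, na.rm = TRUE), all(den >= 0, na.rm = TRUE))
  n2 <- 200 * as.integer(num)
  d <- as.integer(den)
  out <- rep(NA_integer_, length(n2))
  ok <- !is.na(d) & d > 0
  q <- n2[ok] %/% (2L * d[ok])
  r <- n2[ok] %% (2L * d[ok])  # remainder of 200*num relative to 2*den
  up <- r > d[ok] | (r == d[ok] & q %% 2L == 1L)
  out[ok] <- as.integer(q + up)
  out
}

#' Sensitivity, specificity and predictive values from confusion counts
#'
#' Full-precision percentages are returned alongside integer display columns
#' rounded half to even (`*_pct`); a zero denominator yields `NA`
#' ("not applicable").
#'
#' @param counts data.frame with columns `TP`, `TN`, `FP`, `FN` (e.g. from
#'   [confusion_by_cause()]); extra columns are carried through.
#' @return `counts` with columns `sensitivity`, `specificity`, `ppv`, `npv`
#'   (numeric percent, `NA` when undefined) and `sensitivity_pct`,
#'   `specificity_pct`, `ppv_pct`, `npv_pct` (integer display).
#' @export
binary_metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  with_den <- list(
    sensitivity = list(counts$TP, counts$TP + counts$FN),
    specificity = list(counts$TN, counts$TN + counts$FP),
    ppv         = list(counts$TP, counts$TP + counts$FP),
    npv         = list(counts$TN, counts$TN + counts$FN)
  )
  for (nm in names(with_den)) {
    num <- with_den[[nm]][[1]]
    den <- with_den[[nm]][[2]]
    counts[[nm]] <- pct(num, den)
    counts[[paste0(nm, "_pct")]] <- pct_round_half_even(num, den)
  }
  counts
}

#' Cohen's kappa for a gold-by-predicted cross-tabulation
#'
#' `(p_o - p_e) / (1 - p_e)` with `p_o` the diagonal proportion and `p_e`
#' the expected agreement from the margins.
#'
#' @param x a square count matrix (e.g. from [confusion_matrix()]).
#' @return Kappa in `[-1, 1]`, or `NA` when both axes are concentrated on a
#'   single category (`p_e == 1`).
#' @export
cohen_kappa <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  n <- sum(x)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(x)) / n
  pe <- sum(rowSums(x) * colSums(x)) / n^2
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Chance-corrected concordance for one cause
#'
#' Rescales a cause's sensitivity so that random guessing among `K` causes
#' scores 0 and perfect detection scores 1:
#' `(sensitivity - 1/K) / (1 - 1/K)`.
#'
#' @param sensitivity fraction in `[0, 1]` (not a percent).
#' @param K number of substantive causes competing in the group (`K >= 2`).
#' @return Numeric in `[-1/(K-1), 1]`.
#' @export
ccc_per_cause <- function(sensitivity, K) {
  if (any(K < 2)) stop("chance-corrected concordance needs K >= 2")
  stopifnot(all(sensitivity >= -1e-12 & sensitivity <= 1 + 1e-12, na.rm = TRUE))
  (sensitivity - 1 / K) / (1 - 1 / K)
}

#' Overall chance-corrected concordance of a cohort
#'
#' Unweighted mean of [ccc_per_cause()] over the substantive causes with at
#' least one gold-standard death; `K` is the number of substantive causes in
#' the group's dictionary (not the number observed).
#'
#' @inheritParams confusion_matrix
#' @param substantive_causes character vector of the group's substantive
#'   cause codes.
#' @return Numeric scalar.
#' @export
overall_ccc <- function(records, outputs, substantive_causes) {
  gold <- as_gold(records)
  pred <- as_top(outputs)
  K <- length(substantive_causes)
  if (K < 2) stop("need at least 2 substantive causes")
  counts <- confusion_by_cause(gold, pred, substantive_causes)
  eligible <- counts$n > 0
  if (!any(eligible)) stop("no substantive cause has a gold-standard death")
  sens <- counts$TP[eligible] / counts$n[eligible]
  mean(ccc_per_cause(sens, K))
}

#' First- and second-cause agreement summary
#'
#' Counts deaths whose top cause matches the gold standard; among the
#' remainder, counts those whose second reported cause matches, with the
#' mean likelihood attached to those second causes. A death contributes to
#' at most one of the two counters.
#'
#' @param records a [va_records()] cohort (or character gold vector).
#' @param outputs a [va_outputs()] table.
#' @return A list with `n_first_match`, `n_second_match`,
#'   `mean_second_likelihood` (`NA` when there is no second-cause match).
#' @export
agreement_summary <- function(records, outputs) {
  gold <- as_gold(records)
  stopifnot(length(gold) == nrow(outputs))
  first <- !is.na(outputs$cause1) & outputs$cause1 == gold
  second <- !first & !is.na(outputs$cause2) & outputs$cause2 == gold
  list(n_first_match = sum(first),
       n_second_match = sum(second),
       mean_second_likelihood = if (any(second)) mean(outputs$lik2[second]) else NA_real_)
}
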