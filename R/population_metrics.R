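# Population-level comparison: cause-specific mortality fractions (CSMFs)
# for gold standard and coder (partial-likelihood weighting for the latter),
# CSMF accuracy, and its chance correction against a random-allocation
# baseline.

#' Gold-standard CSMF vector
#'
#' Fraction of deaths attributed to each cause by the gold standard, over the
#' given cause list (the residual category included; the gold standard itself
#' can be non-conclusive).
#'
#' @param records a [va_records()] cohort or character vector of gold cause
#'   codes.
#' @param causes cause codes spanning the vector (typically
#'   `group_causes(dictionary, group)`).
#' @return Named numeric vector over `causes`, summing to 1.
#' @export
cda_csmf <- function(records, causes) {
  gold <- as_gold(records)
  if (length(gold) == 0) stop("empty cohort")
  cnt <- table(factor(gold, causes))
  stats::setNames(as.numeric(cnt) / length(gold), causes)
}

#' Coder CSMF vector with partial-likelihood weighting
#'
#' Every reported cause of every death contributes its likelihood; per-death
#' residual mass (1 minus the likelihoods used) accrues to the residual
#' non-conclusive category. By default only the first two reported causes
#' are used, the likelihood of a third cause joining the residual.
#'
#' @param outputs a [va_outputs()] table.
#' @param causes cause codes spanning the vector, residual category last.
#' @param max_causes_used how many reported causes contribute their
#'   likelihood (default 2; set 3 to use every reported cause).
#' @param unknown what to do with likelihood assigned to a cause outside
#'   `causes`: `"error"` (default) or `"residual"` (the mass joins the
#'   non-conclusive fraction, as unattributable within this cause list).
#' @return Named numeric vector over `causes`, summing to 1.
#' @export
model_csmf <- function(outputs, causes, max_causes_used = 2L,
                       unknown = c("error", "residual")) {
  n <- nrow(outputs)
  if (n == 0) stop("empty cohort")
  unknown <- match.arg(unknown)
  stopifnot(max_causes_used >= 1, nonconclusive_code() %in% causes)
  w <- stats::setNames(numeric(length(causes)), causes)
  used <- 0
  for (k in seq_len(min(3L, max_causes_used))) {
    ck <- outputs[[paste0("cause", k)]]
    lk <- outputs[[paste0("lik", k)]]
    keep <- !is.na(ck) & lk > 0
    off <- keep & !(ck %in% causes)
    if (any(off)) {
      if (unknown == "error") {
        stop("output cause(s) outside the cause list: ",
             paste(unique(ck[off]), collapse = ", "))
      }
      keep <- keep & !off  # mass stays unused and falls into the residual
    }
    if (any(keep)) {
      contrib <- tapply(lk[keep], factor(ck[keep], causes), sum)
      contrib[is.na(contrib)] <- 0
      w <- w + contrib
    }
    used <- used + sum(lk[keep])
  }
  w[nonconclusive_code()] <- w[nonconclusive_code()] + (n - used)
  w / n
}

#' CSMF accuracy
#'
#' `1 - sum(|est - true|) / (2 * (1 - min(true)))`: one minus the total
#' misallocated fraction scaled by its maximum possible value given the true
#' composition. Equals 1 iff the vectors are equal and is bounded below
#' by 0.
#'
#' @param true,est CSMF vectors on the same cause support (same names when
#'   named).
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' csmf_accuracy(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))  # 0.875
csmf_accuracy <- function(true, est) {
  if (length(true) != length(est)) stop("CSMF vectors differ in length")
  if (!is.null(names(true)) && !is.null(names(est)) &&
      !identical(names(true), names(est))) {
    stop("CSMF vectors differ in cause support")
  }
  stopifnot(abs(sum(true) - 1) < 1e-6, abs(sum(est) - 1) < 1e-6)
  denom <- 2 * (1 - min(true))
  if (denom <= 0) {
    stop("degenerate true composition (single cause); exclude this draw")
  }
  max(0, min(1, 1 - sum(abs(est - true)) / denom))
}

#' Chance-corrected CSMF accuracy
#'
#' Rescales CSMF accuracy so that random allocation scores 0:
#' `(csmfa - baseline) / (1 - baseline)`. Negative values mean worse than
#' random allocation.
#'
#' @param csmfa CSMF accuracy in `[0, 1]`.
#' @param baseline random-allocation accuracy in `(0, 1)`; either the
#'   empirical [random_allocation_baseline()] or the analytic large-K
#'   constant [analytic_baseline()].
#' @return Numeric `<= 1`, possibly negative.
#' @export
chance_corrected_csmfa <- function(csmfa, baseline) {
  if (any(baseline >= 1) || any(baseline <= 0)) stop("baseline must lie in (0, 1)")
  (csmfa - baseline) / (1 - baseline)
}

#' Analytic random-allocation CSMF accuracy limit
#'
#' The large-K limit of the median CSMF accuracy of uniformly random
#' allocation against uninformative Dirichlet compositions, `1 - 1/e`. For
#' small cause lists the empirical baseline is noticeably larger (the exact
#' large-n median is 2/3 at K = 2), which is why the empirical baseline is
#' the default throughout the package.
#'
#' @return `1 - exp(-1)` (about 0.6321).
#' @export
analytic_baseline <- function() 1 - exp(-1)

#' Empirical random-allocation CSMF accuracy baseline
#'
#' Median [csmf_accuracy()] over draws in which the true composition is a
#' symmetric Dirichlet sample over `K` causes and the estimate allocates
#' each of `n` deaths to a uniformly random cause.
#'
#' @param K number of causes (`>= 2`); alternatively a [cause_dictionary()]
#'   plus `group`, in which case `K` is the number of substantive causes of
#'   that group.
#' @param n cohort size being allocated.
#' @param n_draws number of Dirichlet draws (default 500).
#' @param alpha symmetric Dirichlet concentration (default 1, uninformative).
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is restored afterwards.
#' @param group study group, used only when `K` is a dictionary.
#' @return Median accuracy, strictly between 0 and 1.
#' @export
random_allocation_baseline <- function(K, n, n_draws = 500L, alpha = 1,
                                       seed = NULL, group = NULL) {
  if (inherits(K, "cause_dictionary")) {
    stopifnot(!is.null(group))
    K <- length(group_causes(K, group, substantive = TRUE))
  }
  stopifnot(K >= 2, n >= 1, n_draws >= 1, alpha > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  truth <- rdirichlet(n_draws, K, alpha)
  est <- t(stats::rmultinom(n_draws, n, rep(1 / K, K))) / n
  acc <- vapply(seq_len(n_draws), function(i) {
    csmf_accuracy(truth[i, ], est[i, ])
  }, numeric(1))
  stats::median(acc)
}
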