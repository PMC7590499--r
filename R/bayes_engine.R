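# InterVA-style Bayesian cause assignment. A probbase supplies a prior over
# substantive causes and P(indicator = yes | cause); the posterior for a
# death multiplies the prior by the conditionals of its "yes" indicators
# (accumulated in the log domain), and a reporting rule truncates the
# posterior to at most three causes plus a residual non-conclusive mass.

#' Construct a probbase
#'
#' @param prior named numeric vector over substantive causes (no residual
#'   category); normalized to sum 1.
#' @param conditional numeric matrix, rows = causes (rownames matching
#'   `names(prior)`), columns = indicators; entry = P(indicator yes | cause).
#'   Values are clamped into `[clamp, 1 - clamp]` so that a sparse table can
#'   never annihilate the whole posterior.
#' @param malaria_causes,hiv_causes cause codes whose priors respond to the
#'   malaria / HIV prevalence levels of a [prevalence_setting()].
#' @param clamp floor/ceiling applied to the conditionals (default `1e-6`).
#' @return An object of class `probbase`.
#' @export
probbase <- function(prior, conditional, malaria_causes = character(),
                     hiv_causes = character(), clamp = 1e-6) {
  stopifnot(is.numeric(prior), !is.null(names(prior)), is.matrix(conditional))
  if (is.null(rownames(conditional)) ||
      !identical(rownames(conditional), names(prior))) {
    stop("conditional rownames must match names(prior)")
  }
  if (any(prior < 0) || sum(prior) <= 0) stop("prior must be non-negative with positive sum")
  if (nonconclusive_code() %in% names(prior)) {
    stop("the probbase covers substantive causes only")
  }
  bad <- setdiff(c(malaria_causes, hiv_causes), names(prior))
  if (length(bad)) stop("prevalence-tagged cause(s) not in probbase: ", paste(bad, collapse = ", "))
  conditional <- pmin(pmax(conditional, clamp), 1 - clamp)
  structure(list(prior = prior / sum(prior),
                 conditional = conditional,
                 malaria_causes = malaria_causes,
                 hiv_causes = hiv_causes,
                 clamp = clamp),
            class = "probbase")
}

#' @export
print.probbase <- function(x, ...) {
  cat("<probbase> ", length(x$prior), " causes x ", ncol(x$conditional),
      " indicators\n", sep = "")
  invisible(x)
}

#' Read / write a probbase CSV
#'
#' First column `cause`, second column `prior`, remaining columns one per
#' indicator (header row carries indicator names).
#'
#' @param path file path.
#' @param malaria_causes,hiv_causes prevalence tags (sidecar configuration,
#'   not stored in the CSV).
#' @inheritParams probbase
#' @return A [probbase()] (reader) or `path` invisibly (writer).
#' @export
read_probbase <- function(path, malaria_causes = character(),
                          hiv_causes = character(), clamp = 1e-6) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(d)[1:2], c("cause", "prior"))) {
    stop("probbase CSV must start with columns 'cause', 'prior'")
  }
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$cause
  prior <- stats::setNames(as.numeric(d$prior), d$cause)
  probbase(prior, m, malaria_causes, hiv_causes, clamp)
}

#' @rdname read_probbase
#' @param pb a [probbase()].
#' @export
write_probbase <- function(pb, path) {
  stopifnot(inherits(pb, "probbase"))
  out <- data.frame(cause = names(pb$prior), prior = unname(pb$prior),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(pb$conditional, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Prevalence setting for malaria and HIV
#'
#' Epidemiological context enters the coder as a prior adjustment: causes
#' tagged as malaria- or HIV-related have their prior weight multiplied by
#' the factor of the configured level, after which the prior is renormalized.
#'
#' @param malaria,hiv prevalence levels, one of `"high"`, `"low"`,
#'   `"very_low"`. The defaults mirror a setting with low malaria
#'   transmission and high HIV prevalence.
#' @param factors named positive multipliers per level.
#' @return An object of class `prevalence_setting`.
#' @export
prevalence_setting <- function(malaria = "low", hiv = "high",
                               factors = c(high = 1, low = 0.1, very_low = 0.01)) {
  malaria <- match.arg(malaria, c("high", "low", "very_low"))
  hiv <- match.arg(hiv, c("high", "low", "very_low"))
  stopifnot(all(c("high", "low", "very_low") %in% names(factors)))
  if (any(factors <= 0)) stop("prevalence factors must be strictly positive")
  structure(list(malaria = malaria, hiv = hiv, factors = factors),
            class = "prevalence_setting")
}

#' Apply a prevalence setting to a probbase
#'
#' @param pb a [probbase()].
#' @param setting a [prevalence_setting()].
#' @return A new [probbase()] with adjusted, renormalized prior.
#' @export
apply_prevalence <- function(pb, setting = prevalence_setting()) {
  stopifnot(inherits(pb, "probbase"), inherits(setting, "prevalence_setting"))
  prior <- pb$prior
  prior[pb$malaria_causes] <- prior[pb$malaria_causes] *
    setting$factors[[setting$malaria]]
  prior[pb$hiv_causes] <- prior[pb$hiv_causes] * setting$factors[[setting$hiv]]
  probbase(prior / sum(prior), pb$conditional, pb$malaria_causes,
           pb$hiv_causes, clamp = pb$clamp)
}

#' Cause reporting rule
#'
#' The coder reports the top posterior cause only if its probability reaches
#' `top_threshold`; further causes (up to `max_causes`) are reported while
#' their posterior is at least `relative_threshold` times the top posterior.
#' Whatever mass is not reported becomes the non-conclusive residual.
#'
#' @param top_threshold minimum posterior for any cause to be reported
#'   (default 0.4).
#' @param relative_threshold fraction of the top posterior a further cause
#'   must reach (default 0.5).
#' @param max_causes maximum number of reported causes (default 3).
#' @return An object of class `reporting_rule`.
#' @export
reporting_rule <- function(top_threshold = 0.4, relative_threshold = 0.5,
                           max_causes = 3L) {
  stopifnot(top_threshold > 0, top_threshold < 1,
            relative_threshold > 0, relative_threshold <= 1,
            max_causes >= 1)
  structure(list(top_threshold = top_threshold,
                 relative_threshold = relative_threshold,
                 max_causes = as.integer(max_causes)),
            class = "reporting_rule")
}

#' Posterior over causes for one death
#'
#' Bayes' rule with cause-conditional independence of indicators: the
#' posterior is proportional to the prior times the product of
#' P(indicator | cause) over indicators answered "yes". "No" and missing
#' answers contribute nothing (so structurally unavailable indicators are
#' well-defined). Accumulation is done in the log domain and normalized with
#' log-sum-exp, so long indicator lists cannot underflow.
#'
#' @param indicators character vector of length `ncol(pb$conditional)` with
#'   entries `"Y"`, `"N"`, `"."`.
#' @param pb a [probbase()].
#' @return Named numeric posterior over the probbase causes, summing to 1.
#' @export
compute_posterior <- function(indicators, pb) {
  stopifnot(inherits(pb, "probbase"))
  if (length(indicators) != ncol(pb$conditional)) {
    stop("record has ", length(indicators), " indicators, probbase expects ",
         ncol(pb$conditional))
  }
  yes <- which(indicators == "Y")
  loglik <- log(pb$prior)
  if (length(yes)) {
    loglik <- loglik + rowSums(log(pb$conditional[, yes, drop = FALSE]))
  }
  m <- max(loglik)
  if (!is.finite(m)) {
    stop("posterior mass vanished; check the prior and use log-domain accumulation")
  }
  w <- exp(loglik - m)
  w / sum(w)
}

#' Truncate a posterior to a reported cause list
#'
#' @param posterior named numeric vector summing to 1 (see
#'   [compute_posterior()]). Ties are broken by position (dictionary order).
#' @param rule a [reporting_rule()].
#' @return A list with `assigned` (data.frame `cause`, `likelihood`, 0-3
#'   rows, non-increasing) and `nonconclusive` (residual mass).
#' @export
report_causes <- function(posterior, rule = reporting_rule()) {
  stopifnot(abs(sum(posterior) - 1) < 1e-6)
  ord <- order(-posterior)  # stable: ties keep dictionary order
  p <- posterior[ord]
  keep <- integer(0)
  if (p[1] >= rule$top_threshold) {
    keep <- 1L
    k <- 2L
    while (k <= min(length(p), rule$max_causes) &&
           p[k] >= rule$relative_threshold * p[1]) {
      keep <- c(keep, k)
      k <- k + 1L
    }
  }
  assigned <- data.frame(cause = names(p)[keep],
                         likelihood = unname(p[keep]),
                         stringsAsFactors = FALSE)
  list(assigned = assigned, nonconclusive = 1 - sum(assigned$likelihood))
}

#' Code a cohort of death records
#'
#' Runs [compute_posterior()] and [report_causes()] for every record, after a
#' single prevalence adjustment of the probbase. A histogram of the number of
#' reported causes per death is reported via [message()].
#'
#' @param records a [va_records()] cohort.
#' @param pb a [probbase()] whose indicator count matches the cohort.
#' @param setting a [prevalence_setting()].
#' @param rule a [reporting_rule()].
#' @param dictionary optional [cause_dictionary()]; when supplied, each
#'   record's posterior is computed over the causes in scope for its study
#'   group (prior renormalized within the scope), the analog of screening
#'   causes by age and sex before coding.
#' @return A [va_outputs()] table, one row per record in input order.
#' @export
code_cohort <- function(records, pb, setting = prevalence_setting(),
                        rule = reporting_rule(), dictionary = NULL) {
  stopifnot(inherits(records, "va_records"))
  pb <- apply_prevalence(pb, setting)
  scoped <- list()
  if (!is.null(dictionary)) {
    for (g in unique(records$data$group)) {
      keep <- intersect(rownames(pb$conditional),
                        group_causes(dictionary, g, substantive = TRUE))
      if (length(keep) < 2) stop("probbase covers fewer than 2 causes of group '", g, "'")
      scoped[[g]] <- probbase(pb$prior[keep] / sum(pb$prior[keep]),
                              pb$conditional[keep, , drop = FALSE],
                              intersect(pb$malaria_causes, keep),
                              intersect(pb$hiv_causes, keep), clamp = pb$clamp)
    }
  }
  n <- n_records(records)
  out <- data.frame(id = records$data$id,
                    cause1 = rep(NA_character_, n), lik1 = rep(0, n),
                    cause2 = rep(NA_character_, n), lik2 = rep(0, n),
                    cause3 = rep(NA_character_, n), lik3 = rep(0, n),
                    nonconclusive = rep(1, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pb_i <- if (length(scoped)) scoped[[records$data$group[i]]] else pb
    rep_i <- report_causes(compute_posterior(records$indicators[i, ], pb_i), rule)
    k <- nrow(rep_i$assigned)
    if (k > 0) {
      out[i, paste0("cause", seq_len(k))] <- rep_i$assigned$cause
      out[i, paste0("lik", seq_len(k))] <- rep_i$assigned$likelihood
    }
    out$nonconclusive[i] <- rep_i$nonconclusive
  }
  res <- va_outputs(out)
  ncauses <- rowSums(!is.na(as.matrix(out[c("cause1", "cause2", "cause3")])))
  h <- table(factor(ncauses, 0:3))
  message("coded ", n, " deaths: ",
          paste0(h, " with ", names(h), " cause(s)", collapse = ", "))
  res
}
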