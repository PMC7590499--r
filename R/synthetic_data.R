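# Synthetic cohorts with the statistical structure the validation assumes:
# five study groups of fixed sizes, one certain gold-standard cause per
# death, three-valued indicator responses with a structural missingness mask,
# and coder outputs of up to three causes with residual non-conclusive mass.
# A direct misclassification simulator bypasses the Bayes engine so the
# metric modules can be tested in isolation.

default_true_csmf <- function() {
  list(
    stillbirth = c(infections = 4, fetal_growth_restriction = 7,
                   intrapartum_hypoxia = 3, intrauterine_hypoxia = 2,
                   congenital_malformations = 0, non_conclusive = 2) / 18,
    neonate = c(infections = 27, congenital_malformations = 4,
                preterm_complications = 5, intrapartum_complications = 3,
                other_diseases = 2, non_conclusive = 0) / 41,
    child = c(infections = 42, congenital_malformations = 2,
              malignant_neoplasms = 7, other_diseases = 3,
              non_conclusive = 0) / 54,
    maternal = c(infections = 39, abortion = 9, eclampsia = 4,
                 obstetric_hemorrhage = 16, other_obstetric_complications = 6,
                 non_obstetric_diseases = 16, non_conclusive = 1) / 91,
    other_adult = c(infections = 80, malignant_neoplasms = 16,
                    other_diseases = 16, non_conclusive = 0) / 112
  )
}

default_infection_fractions <- function() {
  c(disseminated_infections = 51, pneumonia = 36, meningitis = 15,
    tuberculosis = 7, diarrhoea = 2, hiv_aids_related = 57, malaria = 6,
    other_infections = 18) / 192
}

#' Specification of a synthetic validation cohort
#'
#' The defaults emulate a hospital-based autopsy validation series: group
#' sizes 18/41/54/91/112 (stillbirths through other adults), per-group true
#' cause compositions equal to the gold-standard CSMFs of such a series, 245
#' indicators of which 43 are structurally unavailable (24 flagged as
#' secondary questions), a mean first-cause likelihood of 0.90 and a mean
#' second-cause likelihood of 0.38 with a second cause reported for about
#' 10% of deaths.
#'
#' @param group_sizes named integer vector over [va_groups()].
#' @param true_csmf named list: per group, a named simplex vector over that
#'   group's causes (residual category allowed; it stands for deaths whose
#'   gold-standard diagnosis is itself non-conclusive).
#' @param n_indicators number of indicator questions (default 245).
#' @param n_unobservable indicators never observed in any record
#'   (default 43).
#' @param n_secondary how many of the unobservable indicators are secondary
#'   questions (default 24); carried as an attribute, behaviorally inert.
#' @param first_cause_likelihood_mean,second_cause_likelihood_mean means of
#'   the simulated likelihoods (defaults 0.90 and 0.38).
#' @param second_cause_prob probability that a simulated output reports a
#'   second cause (default 33/316).
#' @param likelihood_sd spread of the likelihood noise (default 0.05).
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(group_sizes = c(stillbirth = 18, neonate = 41,
                                            child = 54, maternal = 91,
                                            other_adult = 112),
                            true_csmf = default_true_csmf(),
                            n_indicators = 245L,
                            n_unobservable = 43L,
                            n_secondary = 24L,
                            first_cause_likelihood_mean = 0.90,
                            second_cause_likelihood_mean = 0.38,
                            second_cause_prob = 33 / 316,
                            likelihood_sd = 0.05,
                            seed = 1L) {
  stopifnot(all(names(group_sizes) %in% va_groups()), all(group_sizes >= 0),
            n_unobservable >= 0, n_unobservable <= n_indicators,
            n_secondary <= n_unobservable,
            first_cause_likelihood_mean > 0, first_cause_likelihood_mean <= 1,
            second_cause_likelihood_mean >= 0, second_cause_likelihood_mean <= 1,
            second_cause_prob >= 0, second_cause_prob <= 1)
  for (g in names(true_csmf)) {
    v <- true_csmf[[g]]
    if (abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
      stop("true_csmf for group '", g, "' is not a simplex vector")
    }
  }
  structure(list(group_sizes = group_sizes, true_csmf = true_csmf,
                 n_indicators = as.integer(n_indicators),
                 n_unobservable = as.integer(n_unobservable),
                 n_secondary = as.integer(n_secondary),
                 first_cause_likelihood_mean = first_cause_likelihood_mean,
                 second_cause_likelihood_mean = second_cause_likelihood_mean,
                 second_cause_prob = second_cause_prob,
                 likelihood_sd = likelihood_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Synthetic probbase with per-cause indicator blocks
#'
#' Each substantive cause receives a private block of indicators whose
#' yes-probability is `0.05 + 0.9 * signal`; all other indicators stay at
#' the background rate 0.05. At `signal = 1` the blocks are pathognomonic
#' (0.95 vs 0.05); at `signal = 0` the conditionals are constant across
#' causes and the posterior always equals the prior. The prior is uniform.
#'
#' @param dictionary a [cause_dictionary()]; the probbase covers the union of
#'   substantive causes across all groups. A character vector of cause codes
#'   is also accepted.
#' @param n_indicators number of indicators (must be at least the number of
#'   causes).
#' @param signal signal strength in `[0, 1]`.
#' @param seed integer seed (block layout is deterministic; the seed is kept
#'   for interface stability of generators as pure functions of (spec, seed)).
#' @return A [probbase()].
#' @export
make_probbase <- function(dictionary = default_cause_dictionary(),
                          n_indicators = 245L, signal = 0.8, seed = 1L) {
  stopifnot(signal >= 0, signal <= 1)
  causes <- if (inherits(dictionary, "cause_dictionary")) {
    setdiff(dictionary$code, nonconclusive_code())
  } else as.character(dictionary)
  K <- length(causes)
  if (n_indicators < K) stop("fewer indicators than causes")
  block <- n_indicators %/% K
  cond <- matrix(0.05, nrow = K, ncol = n_indicators,
                 dimnames = list(causes, indicator_names(n_indicators)))
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * block + 1L):(k * block)
    cond[k, cols] <- 0.05 + 0.9 * signal
  }
  probbase(stats::setNames(rep(1 / K, K), causes), cond)
}

#' Simulate a cohort of death records
#'
#' Per group, gold-standard causes are drawn from the group's true
#' composition; indicators are drawn Bernoulli from the true cause's
#' conditional probbase row (background rate only for gold non-conclusive
#' deaths, which carry no cause signal). A single mask of
#' `spec$n_unobservable` indicator positions is set to missing for every
#' record: the missingness emulates fields structurally absent from source
#' documents, not per-death nonresponse. Deaths whose gold cause is
#' infectious also receive an infection-level subtype in column
#' `infection_cause`.
#'
#' @param spec a [simulation_spec()].
#' @param pb a [probbase()] (see [make_probbase()]).
#' @param dictionary a [cause_dictionary()].
#' @return A [va_records()] cohort; the missing-indicator mask is attached
#'   as attribute `"missing_mask"` (with its secondary-question subset as
#'   attribute `"secondary_mask"`).
#' @export
simulate_cohort <- function(spec = simulation_spec(),
                            pb = make_probbase(n_indicators = spec$n_indicators),
                            dictionary = default_cause_dictionary()) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(pb, "probbase"))
  if (ncol(pb$conditional) != spec$n_indicators) {
    stop("probbase indicator count does not match spec$n_indicators")
  }
  set.seed(spec$seed)
  I <- spec$n_indicators
  groups <- names(spec$group_sizes)[spec$group_sizes > 0]
  meta <- list()
  rows <- list()
  counter <- 0L
  for (g in groups) {
    n <- spec$group_sizes[[g]]
    comp <- spec$true_csmf[[g]]
    if (is.null(comp)) stop("no true_csmf for group '", g, "'")
    gold <- sample(names(comp), n, replace = TRUE, prob = comp)
    infect <- ifelse(gold == "infections",
                     sample(names(default_infection_fractions()), n,
                            replace = TRUE, prob = default_infection_fractions()),
                     NA_character_)
    ind <- matrix("N", nrow = n, ncol = I)
    for (i in seq_len(n)) {
      p <- if (gold[i] %in% rownames(pb$conditional)) {
        pb$conditional[gold[i], ]
      } else rep(0.05, I)  # residual gold category: background only
      ind[i, stats::runif(I) < p] <- "Y"
    }
    meta[[g]] <- data.frame(id = sprintf("d%04d", counter + seq_len(n)),
                            group = g, cda_cause = gold,
                            infection_cause = infect,
                            stringsAsFactors = FALSE)
    rows[[g]] <- ind
    counter <- counter + n
  }
  data <- do.call(rbind, meta)
  rownames(data) <- NULL
  indicators <- do.call(rbind, rows)
  mask <- sort(sample.int(I, spec$n_unobservable))
  indicators[, mask] <- "."
  out <- va_records(data, indicators, dictionary)
  attr(out, "missing_mask") <- mask
  attr(out, "secondary_mask") <- mask[seq_len(min(spec$n_secondary, length(mask)))]
  out
}

#' Misclassification kernel interpolating chance and perfection
#'
#' Row-stochastic K x K matrix `s * I + (1 - s) / K`: at `s = 0` the
#' predicted top cause is uniform regardless of the gold cause, at `s = 1`
#' prediction is perfect.
#'
#' @param causes character vector of substantive cause codes.
#' @param s accuracy parameter in `[0, 1]`.
#' @return Matrix with `causes` as row and column names.
#' @export
misclassification_kernel <- function(causes, s) {
  stopifnot(s >= 0, s <= 1, length(causes) >= 2)
  K <- length(causes)
  m <- matrix((1 - s) / K, K, K, dimnames = list(causes, causes))
  diag(m) <- diag(m) + s
  m
}

#' Simulate coder outputs directly from a confusion kernel
#'
#' Bypasses the Bayes engine: each death's top cause is drawn from the
#' kernel row of its gold cause, with a first likelihood around
#' `spec$first_cause_likelihood_mean`; with probability
#' `spec$second_cause_prob` a second (different) cause is added with
#' likelihood around `spec$second_cause_likelihood_mean`; the remainder is
#' non-conclusive mass. Gold non-conclusive deaths receive an empty
#' (non-conclusive) report. When the drawn top cause is infectious and the
#' record carries an infection subtype, a predicted subtype is drawn from a
#' subtype kernel with the same diagonal weight as `kernel` and stored in
#' `infection_cause1`.
#'
#' @param records a [va_records()] cohort.
#' @param kernel row-stochastic matrix over substantive causes (rows = gold,
#'   columns = predicted), e.g. [misclassification_kernel()]. Rows must
#'   cover every substantive gold cause present in `records`.
#' @param spec a [simulation_spec()] (likelihood parameters).
#' @param seed integer seed.
#' @return A [va_outputs()] table aligned with `records`.
#' @export
simulate_va_outputs <- function(records, kernel, spec = simulation_spec(),
                                seed = spec$seed) {
  stopifnot(inherits(records, "va_records"), is.matrix(kernel))
  if (any(abs(rowSums(kernel) - 1) > 1e-9) || any(kernel < 0)) {
    stop("kernel rows must be non-negative and sum to 1")
  }
  gold <- records$data$cda_cause
  nc <- nonconclusive_code()
  missing_rows <- setdiff(setdiff(unique(gold), nc), rownames(kernel))
  if (length(missing_rows)) {
    stop("kernel lacks rows for gold cause(s): ", paste(missing_rows, collapse = ", "))
  }
  set.seed(seed)
  n <- length(gold)
  rtrunc <- function(n, mean) pmin(pmax(stats::rnorm(n, mean, spec$likelihood_sd), 0), 1)
  out <- data.frame(id = records$data$id,
                    cause1 = NA_character_, lik1 = 0,
                    cause2 = NA_character_, lik2 = 0,
                    cause3 = NA_character_, lik3 = 0,
                    nonconclusive = 1, stringsAsFactors = FALSE)
  preds <- colnames(kernel)
  # diagonal weight of the (sub)type kernel mirrors the broad kernel's:
  # for s*I + (1-s)/K the mean diagonal is s + (1-s)/K, inverted here
  Kk <- ncol(kernel)
  s_diag <- max(0, min(1, (Kk * mean(diag(kernel)) - 1) / (Kk - 1)))
  subtype_codes <- names(default_infection_fractions())
  sub_kernel <- misclassification_kernel(subtype_codes, s_diag)
  has_subtype <- "infection_cause" %in% names(records$data)
  out$infection_cause1 <- NA_character_
  for (i in seq_len(n)) {
    if (gold[i] == nc) next
    top <- sample(preds, 1L, prob = kernel[gold[i], ])
    if (top == nc) next
    l1 <- rtrunc(1L, spec$first_cause_likelihood_mean)
    out$cause1[i] <- top
    out$lik1[i] <- l1
    if (stats::runif(1) < spec$second_cause_prob && length(preds) > 1L) {
      second <- sample(setdiff(preds, top), 1L)
      # the second likelihood keeps its target mean; the first yields so the
      # report still sums to at most 1 with non-increasing likelihoods
      l2 <- min(rtrunc(1L, spec$second_cause_likelihood_mean), 0.5)
      if (l2 > 0) {
        out$lik1[i] <- min(l1, 1 - l2)
        out$cause2[i] <- second
        out$lik2[i] <- min(l2, out$lik1[i])
      }
    }
    out$nonconclusive[i] <- 1 - out$lik1[i] - out$lik2[i]
    if (has_subtype && top == "infections" && !is.na(records$data$infection_cause[i])) {
      out$infection_cause1[i] <- sample(subtype_codes, 1L,
                                        prob = sub_kernel[records$data$infection_cause[i], ])
    }
  }
  va_outputs(out)
}

#' Parameter-recovery check of the whole metric pipeline
#'
#' Runs the synthetic pipeline at signal strengths 0, 0.5 and 1 on a
#' five-cause cohort of `n` deaths: gold causes uniform, coder outputs drawn
#' from the misclassification kernel `s * I + (1 - s)/K`, and the Dirichlet
#' validation harness applied to each run. Asserts that median CCC, kappa
#' and median CSMF accuracy increase with the signal; that the zero-signal
#' run sits at chance level (|median CCC| < 0.05, |median chance-corrected
#' CSMF accuracy| < 0.10); and that the full-signal run reaches at least 0.9
#' on CCC, kappa and CSMF accuracy. As a cross-check of the Bayes engine
#' route, a pathognomonic probbase cohort is coded and its top-cause
#' accuracy (expected > 95%) is reported.
#'
#' @param seed integer seed.
#' @param n cohort size per run (default 500).
#' @param n_draws Dirichlet draws per run (default 500).
#' @param assert stop on a violated property (default `TRUE`)?
#' @return A data.frame report, one row per signal strength, with the
#'   engine check attached as attribute `"engine_accuracy"` and any violated
#'   properties as attribute `"violations"`.
#' @export
parameter_recovery_suite <- function(seed = 1L, n = 500L, n_draws = 500L,
                                     assert = TRUE) {
  causes <- paste0("c", 1:5)
  dict <- cause_dictionary(code = c(causes, nonconclusive_code()),
                           label = c(paste("Cause", 1:5), "Non-conclusive"),
                           groups = rep("all", 6))
  spec <- simulation_spec(seed = seed)
  set.seed(seed)
  gold <- sample(causes, n, replace = TRUE)
  data <- data.frame(id = sprintf("s%04d", seq_len(n)), group = "other_adult",
                     cda_cause = gold, stringsAsFactors = FALSE)
  records <- va_records(data, matrix(character(0), nrow = n, ncol = 0), dict)
  rows <- lapply(c(0, 0.5, 1), function(s) {
    outputs <- simulate_va_outputs(records, misclassification_kernel(causes, s),
                                   spec, seed = seed + round(1000 * s))
    v <- validate_group(records, outputs, dict,
                        validation_config(n_draws = n_draws, seed = seed))
    data.frame(signal = s, median_ccc = v$median_ccc, kappa = v$kappa,
               median_csmfa = v$median_csmfa, median_cccsmfa = v$median_cccsmfa)
  })
  report <- do.call(rbind, rows)

  # engine route: pathognomonic probbase recovers the gold cause
  eng_dict <- default_cause_dictionary()
  eng_spec <- simulation_spec(seed = seed + 7L)
  eng_pb <- make_probbase(eng_dict, eng_spec$n_indicators, signal = 1)
  eng_records <- simulate_cohort(eng_spec, eng_pb, eng_dict)
  eng_outputs <- suppressMessages(
    code_cohort(eng_records, eng_pb, prevalence_setting(), reporting_rule()))
  substantive_gold <- eng_records$data$cda_cause != nonconclusive_code()
  eng_acc <- mean(top_cause(eng_outputs)[substantive_gold] ==
                    eng_records$data$cda_cause[substantive_gold])

  violations <- character(0)
  if (!all(diff(report$median_ccc) > 0)) violations <- c(violations, "median CCC not increasing in signal")
  if (!all(diff(report$kappa) > 0)) violations <- c(violations, "kappa not increasing in signal")
  if (!all(diff(report$median_csmfa) > 0)) violations <- c(violations, "median CSMF accuracy not increasing in signal")
  if (abs(report$median_ccc[1]) >= 0.05) violations <- c(violations, "zero-signal median CCC not at chance level")
  if (abs(report$median_cccsmfa[1]) >= 0.10) violations <- c(violations, "zero-signal median chance-corrected CSMF accuracy not at chance level")
  if (report$median_ccc[3] < 0.9) violations <- c(violations, "full-signal median CCC below 0.9")
  if (report$kappa[3] < 0.9) violations <- c(violations, "full-signal kappa below 0.9")
  if (report$median_csmfa[3] < 0.9) violations <- c(violations, "full-signal median CSMF accuracy below 0.9")
  if (eng_acc <= 0.95) violations <- c(violations, "pathognomonic engine accuracy not above 95%")

  attr(report, "engine_accuracy") <- eng_acc
  attr(report, "violations") <- violations
  if (assert && length(violations)) {
    stop("parameter recovery failed:\n  ", paste(violations, collapse = "\n  "))
  }
  report
}
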