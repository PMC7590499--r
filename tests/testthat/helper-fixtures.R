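# Small in-code fixtures shared across test files.

toy_dictionary <- function(K = 5) {
  cause_dictionary(code = c(paste0("c", seq_len(K)), nonconclusive_code()),
                   label = c(paste("Cause", seq_len(K)), "Non-conclusive"),
                   groups = rep("all", K + 1))
}

# cohort without indicator data (metric-module tests don't need indicators)
toy_cohort <- function(gold, group = "child", dict = toy_dictionary()) {
  n <- length(gold)
  va_records(data.frame(id = sprintf("t%04d", seq_len(n)), group = group,
                        cda_cause = gold, stringsAsFactors = FALSE),
             matrix(character(0), nrow = n, ncol = 0), dict)
}

# outputs with a single certain cause per death
identity_outputs <- function(gold, lik = 1) {
  va_outputs(data.frame(id = sprintf("t%04d", seq_along(gold)),
                        cause1 = gold, lik1 = lik,
                        cause2 = NA_character_, lik2 = 0,
                        cause3 = NA_character_, lik3 = 0,
                        nonconclusive = 1 - lik, stringsAsFactors = FALSE))
}

# random valid outputs over a cause list (for round-trip / property tests)
random_outputs <- function(n, causes) {
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    picked <- sample(causes, k)
    liks <- if (k > 0) sort(runif(k, 0, 1 / (k + 1)), decreasing = TRUE) else numeric(0)
    data.frame(id = sprintf("r%04d", i),
               cause1 = if (k >= 1) picked[1] else NA_character_,
               lik1 = if (k >= 1) liks[1] else 0,
               cause2 = if (k >= 2) picked[2] else NA_character_,
               lik2 = if (k >= 2) liks[2] else 0,
               cause3 = if (k >= 3) picked[3] else NA_character_,
               lik3 = if (k >= 3) liks[3] else 0,
               nonconclusive = 1 - sum(liks), stringsAsFactors = FALSE)
  })
  va_outputs(do.call(rbind, rows))
}

# two-cause toy probbase for engine arithmetic checks
toy_probbase <- function(prior = c(a = 0.5, b = 0.5),
                         cond = rbind(a = c(0.8, 0.3), b = c(0.2, 0.3))) {
  colnames(cond) <- vacheck:::indicator_names(ncol(cond))
  probbase(prior, cond)
}
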