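test_that("posterior follows Bayes' rule on hand-worked cases", {
  pb <- toy_probbase()
  # one yes on the discriminating indicator: prior (.5,.5), P = (.8,.2)
  post <- compute_posterior(c("Y", "N"), pb)
  expect_equal(unname(post), c(0.8, 0.2), tolerance = 1e-12)
  # no yes answers: posterior equals prior
  expect_equal(unname(compute_posterior(c("N", "."), pb)), c(0.5, 0.5))
  # constant conditionals across causes: posterior equals prior
  pb0 <- probbase(c(a = 0.3, b = 0.7),
                  rbind(a = c(0.4, 0.6), b = c(0.4, 0.6)))
  expect_equal(unname(compute_posterior(c("Y", "Y"), pb0)), c(0.3, 0.7),
               tolerance = 1e-12)
})

test_that("log-domain accumulation matches the direct product and survives long records", {
  set.seed(11)
  for (rep in 1:100) {
    K <- sample(2:5, 1); I <- sample(3:12, 1)
    prior <- stats::setNames(runif(K, 0.1, 1), paste0("c", 1:K))
    prior <- prior / sum(prior)
    cond <- matrix(runif(K * I, 0.01, 0.99), K,
                   dimnames = list(names(prior), NULL))
    pb <- probbase(prior, cond)
    ind <- sample(c("Y", "N", "."), I, TRUE)
    yes <- which(ind == "Y")
    direct <- prior * apply(pb$conditional[, yes, drop = FALSE], 1, prod)
    direct <- direct / sum(direct)
    expect_equal(compute_posterior(ind, pb), direct, tolerance = 1e-9)
  }
  # 5000 indicators all answered yes would underflow a naive product
  I <- 5000
  cond <- matrix(runif(2 * I, 0.01, 0.05), 2, dimnames = list(c("a", "b"), NULL))
  pb <- probbase(c(a = 0.5, b = 0.5), cond)
  post <- compute_posterior(rep("Y", I), pb)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_true(all(post > 0))
})

test_that("posterior is invariant to indicator column order and always sums to 1", {
  set.seed(13)
  K <- 4; I <- 30
  prior <- stats::setNames(rep(1 / K, K), paste0("c", 1:K))
  cond <- matrix(runif(K * I, 0.05, 0.95), K, dimnames = list(names(prior), NULL))
  pb <- probbase(prior, cond)
  for (rep in 1:20) {
    ind <- sample(c("Y", "N", "."), I, TRUE)
    perm <- sample.int(I)
    pb_perm <- probbase(prior, cond[, perm], clamp = 1e-6)
    expect_equal(compute_posterior(ind, pb), compute_posterior(ind[perm], pb_perm),
                 tolerance = 1e-12)
    expect_equal(sum(compute_posterior(ind, pb)), 1, tolerance = 1e-12)
  }
})

test_that("prevalence adjustment rescales tagged priors and is monotone in the level", {
  prior <- stats::setNames(rep(0.2, 5), paste0("c", 1:5))
  cond <- matrix(0.5, 5, 4, dimnames = list(names(prior), NULL))
  pb <- probbase(prior, cond, malaria_causes = "c1", hiv_causes = "c5")
  # both high: unchanged
  same <- apply_prevalence(pb, prevalence_setting("high", "high"))
  expect_equal(same$prior, pb$prior, tolerance = 1e-12)
  # malaria low: weight 0.2 * 0.1 = 0.02, renormalized over total 0.82
  adj <- apply_prevalence(pb, prevalence_setting("low", "high"))
  expect_equal(unname(adj$prior["c1"]), 0.02 / 0.82, tolerance = 1e-12)
  expect_equal(unname(adj$prior["c2"]), 0.2 / 0.82, tolerance = 1e-12)
  # very_low can never give the malaria cause a larger posterior than low
  set.seed(17)
  cond2 <- matrix(runif(5 * 20, 0.05, 0.95), 5, dimnames = list(names(prior), NULL))
  pb2 <- probbase(prior, cond2, malaria_causes = "c1")
  lo <- apply_prevalence(pb2, prevalence_setting("low", "high"))
  vlo <- apply_prevalence(pb2, prevalence_setting("very_low", "high"))
  for (rep in 1:50) {
    ind <- sample(c("Y", "N"), 20, TRUE)
    expect_lte(compute_posterior(ind, vlo)["c1"], compute_posterior(ind, lo)["c1"] + 1e-12)
  }
})

test_that("reporting rule truncates the posterior as specified", {
  rule <- reporting_rule(top_threshold = 0.4, relative_threshold = 0.5,
                         max_causes = 3)
  p <- stats::setNames(c(0.9, 0.05, 0.03, 0.02), paste0("c", 1:4))
  r <- report_causes(p, rule)
  expect_identical(r$assigned$cause, "c1")
  expect_equal(r$nonconclusive, 0.1, tolerance = 1e-12)
  # below the top threshold: non-conclusive diagnosis
  r2 <- report_causes(stats::setNames(c(0.3, 0.3, 0.2, 0.2), paste0("c", 1:4)), rule)
  expect_identical(nrow(r2$assigned), 0L)
  expect_equal(r2$nonconclusive, 1)
  # relative threshold keeps the 0.3 but drops the 0.1s
  r3 <- report_causes(stats::setNames(c(0.5, 0.3, 0.1, 0.1), paste0("c", 1:4)), rule)
  expect_identical(r3$assigned$cause, c("c1", "c2"))
  expect_equal(r3$assigned$likelihood, c(0.5, 0.3))
  expect_equal(r3$nonconclusive, 0.2, tolerance = 1e-12)
  # ties broken by dictionary order
  r4 <- report_causes(stats::setNames(c(0.45, 0.45, 0.1), paste0("c", 1:3)), rule)
  expect_identical(r4$assigned$cause[1], "c1")
})

test_that("cohort coding preserves order, respects group scope, and recovers pathognomonic causes", {
  dict <- default_cause_dictionary()
  spec <- simulation_spec(seed = 21)
  pb <- make_probbase(dict, spec$n_indicators, signal = 1)
  rec <- simulate_cohort(spec, pb, dict)
  out <- suppressMessages(code_cohort(rec, pb, dictionary = dict))
  expect_identical(out$id, rec$data$id)
  gold <- rec$data$cda_cause
  sub <- gold != nonconclusive_code()
  expect_gt(mean(top_cause(out)[sub] == gold[sub]), 0.95)
  # scoped coding never assigns a cause outside the record's group dictionary
  for (g in unique(rec$data$group)) {
    sel <- rec$data$group == g & !is.na(out$cause1)
    expect_true(all(out$cause1[sel] %in% group_causes(dict, g, TRUE)))
  }
  # permutation equivariance
  perm <- sample.int(n_records(rec))
  out_perm <- suppressMessages(code_cohort(rec[perm], pb, dictionary = dict))
  expect_equal(out_perm$cause1, out$cause1[perm])
  expect_equal(out_perm$lik1, out$lik1[perm])
  # empty cohort
  expect_identical(nrow(suppressMessages(
    code_cohort(rec[integer(0)], pb, dictionary = dict))), 0L)
})

test_that("probbase round-trips through CSV with clamping applied once", {
  pb <- toy_probbase()
  path <- withr::local_tempfile(fileext = ".csv")
  write_probbase(pb, path)
  back <- read_probbase(path)
  expect_equal(back$prior, pb$prior, tolerance = 1e-12)
  expect_equal(back$conditional, pb$conditional, tolerance = 1e-10)
})
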