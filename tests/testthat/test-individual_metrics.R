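test_that("top cause falls back to the residual category for empty reports", {
  out <- va_outputs(data.frame(id = c("a", "b", "c"),
                               cause1 = c("x", NA, "x"), lik1 = c(0.9, 0, 0.5),
                               cause2 = c(NA, NA, "y"), lik2 = c(0, 0, 0.3),
                               cause3 = NA, lik3 = 0,
                               nonconclusive = c(0.1, 1, 0.2)))
  expect_identical(top_cause(out), c("x", nonconclusive_code(), "x"))
})

test_that("per-cause confusion counts tie out against a brute-force recount", {
  set.seed(31)
  causes <- c(paste0("c", 1:4), nonconclusive_code())
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    gold <- sample(causes, n, TRUE)
    pred <- sample(causes, n, TRUE)
    counts <- confusion_by_cause(gold, pred, causes)
    m <- confusion_matrix(gold, pred, causes)
    expect_identical(sum(counts$TP), sum(diag(m)))
    for (j in seq_along(causes)) {
      expect_identical(counts$TP[j] + counts$FN[j], sum(gold == causes[j]))
      expect_identical(counts$TP[j] + counts$TN[j] + counts$FP[j] + counts$FN[j], n)
    }
    expect_identical(sum(counts$TP + counts$FN), n)
  }
  # perfect predictor has no off-diagonal mass
  gold <- sample(causes, 30, TRUE)
  perfect <- confusion_by_cause(gold, gold, causes)
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))
})

test_that("banker's rounding of percentages matches the printed convention", {
  expect_identical(pct_round_half_even(c(25, 2, 25, 2), c(27, 14, 37, 4)),
                   c(93L, 14L, 68L, 50L))
  expect_identical(pct_round_half_even(10, 16), 62L)  # 62.5 -> even
  expect_identical(pct_round_half_even(7, 8), 88L)    # 87.5 -> even
  expect_identical(pct_round_half_even(27, 40), 68L)  # 67.5 -> even
  expect_identical(pct_round_half_even(1, 8), 12L)    # 12.5 -> even
  expect_true(is.na(pct_round_half_even(0, 0)))
})

test_that("binary metrics reproduce printed worked examples and flag undefined entries", {
  m <- binary_metrics(data.frame(TP = 25, TN = 2, FP = 12, FN = 2))
  expect_identical(c(m$sensitivity_pct, m$specificity_pct, m$ppv_pct, m$npv_pct),
                   c(93L, 14L, 68L, 50L))
  m2 <- binary_metrics(data.frame(TP = 0, TN = 14, FP = 0, FN = 4))
  expect_identical(m2$sensitivity_pct, 0L)
  expect_identical(m2$specificity_pct, 100L)
  expect_true(is.na(m2$ppv_pct))
  expect_identical(m2$npv_pct, 78L)
  m3 <- binary_metrics(data.frame(TP = 20, TN = 20, FP = 12, FN = 26))
  expect_identical(m3$specificity_pct, 62L)
  # full precision is retained alongside the display value
  expect_equal(m3$specificity, 100 * 20 / 32)
})

test_that("Cohen's kappa matches hand arithmetic and its degenerate conventions", {
  expect_equal(cohen_kappa(rbind(c(25, 2), c(12, 2))), 52 / 626, tolerance = 1e-12)
  expect_equal(cohen_kappa(diag(c(5, 9, 3))), 1)
  # rows proportional to the column margins: independence, kappa 0
  indep <- outer(c(10, 20, 30), c(1, 2, 3) / 6)
  expect_equal(cohen_kappa(indep), 0, tolerance = 1e-12)
  # all mass on one category on both axes: undefined
  one <- matrix(0, 2, 2); one[1, 1] <- 10
  expect_true(is.na(cohen_kappa(one)))
})

test_that("chance-corrected concordance rescales sensitivity against 1/K", {
  expect_equal(ccc_per_cause(1, 6), 1)
  expect_equal(ccc_per_cause(1 / 6, 6), 0)
  expect_equal(ccc_per_cause(0, 6), -0.2)
  expect_equal(ccc_per_cause(0.5, 4), 1 / 3)
  expect_error(ccc_per_cause(0.5, 1), "K >= 2")
})

test_that("overall CCC is 1 for the identity predictor, 0 in expectation at chance", {
  causes <- paste0("c", 1:5)
  set.seed(37)
  gold <- sample(causes, 200, TRUE, prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  expect_identical(overall_ccc(gold, gold, causes), 1)
  # uniformly random predictor over 10,000 deaths is at chance level
  gold_big <- sample(causes, 10000, TRUE)
  pred_big <- sample(causes, 10000, TRUE)
  expect_lt(abs(overall_ccc(gold_big, pred_big, causes)), 0.02)
  # single eligible cause: reduces to the per-cause formula
  g <- rep("c1", 10)
  p <- c(rep("c1", 5), rep("c2", 5))
  expect_equal(overall_ccc(g, p, paste0("c", 1:4)), (0.5 - 0.25) / 0.75)
})

test_that("agreement summary credits each death to at most one counter", {
  gold <- c("a", "b", "c")
  out <- va_outputs(data.frame(id = 1:3,
                               cause1 = c("a", "x", "x"), lik1 = c(0.9, 0.6, 0.6),
                               cause2 = c("b", "b", NA), lik2 = c(0.05, 0.4, 0),
                               cause3 = NA, lik3 = 0,
                               nonconclusive = c(0.05, 0, 0.4)))
  s <- agreement_summary(gold, out)
  expect_identical(s$n_first_match, 1L)
  expect_identical(s$n_second_match, 1L)
  expect_equal(s$mean_second_likelihood, 0.4)
  # all firsts match: no second-cause credit even when cause2 also matches
  s2 <- agreement_summary(c("a", "b"), va_outputs(data.frame(
    id = 1:2, cause1 = c("a", "b"), lik1 = 0.8, cause2 = c("a", "b"),
    lik2 = 0.1, cause3 = NA, lik3 = 0, nonconclusive = 0.1)))
  expect_identical(s2$n_first_match, 2L)
  expect_identical(s2$n_second_match, 0L)
  expect_true(is.na(s2$mean_second_likelihood))
  # exhaustive: first-match and second-match flags are mutually exclusive
  toys <- expand.grid(c1 = c("a", "b"), c2 = c("a", "b"), gold = c("a", "b"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(toys))) {
    o <- va_outputs(data.frame(id = "t", cause1 = toys$c1[i], lik1 = 0.5,
                               cause2 = toys$c2[i], lik2 = 0.3, cause3 = NA,
                               lik3 = 0, nonconclusive = 0.2))
    s3 <- agreement_summary(toys$gold[i], o)
    expect_lte(s3$n_first_match + s3$n_second_match, 1L)
  }
})
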