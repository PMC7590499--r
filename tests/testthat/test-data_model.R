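test_that("default dictionary has the expected group-specific cause lists", {
  d <- default_cause_dictionary()
  expect_s3_class(d, "cause_dictionary")
  sizes <- vapply(va_groups(), function(g) length(group_causes(d, g)), integer(1))
  expect_identical(unname(sizes), c(6L, 6L, 5L, 7L, 4L))
  for (g in va_groups()) {
    causes <- group_causes(d, g)
    expect_identical(causes[length(causes)], nonconclusive_code())
    expect_false(nonconclusive_code() %in% group_causes(d, g, substantive = TRUE))
  }
})

test_that("dictionary invariants are enforced", {
  expect_error(cause_dictionary(c("a", "a", "non_conclusive"), letters[1:3],
                                rep("all", 3)), "unique")
  expect_error(cause_dictionary(c("a", "b"), c("A", "B"), rep("all", 2)),
               "non_conclusive")
  # non-conclusive is reordered to the end
  d <- cause_dictionary(c("non_conclusive", "a", "b"), c("NC", "A", "B"),
                        rep("all", 3))
  expect_identical(d$code[3], "non_conclusive")
})

test_that("ICD-10 mapping uses longest prefix within group scope and never falls back silently", {
  m <- data.frame(prefix = c("O15", "A4", "A41"),
                  group = c("maternal", "any", "neonate"),
                  category = c("eclampsia", "x", "y"),
                  stringsAsFactors = FALSE)
  expect_identical(map_icd10("O15.0", "maternal", m), "eclampsia")
  expect_identical(map_icd10("A41.9", "neonate", m), "y")   # longest prefix wins
  expect_identical(map_icd10("A41.9", "child", m), "x")     # neonate row out of scope
  expect_error(map_icd10("Z99", "maternal", m), "unmapped")
})

test_that("shipped ICD-10 map is consistent with the default dictionary", {
  m <- read_icd10_map(dictionary = default_cause_dictionary())
  expect_true(all(c("prefix", "group", "category") %in% names(m)))
  expect_identical(map_icd10("O15.0", "maternal", m), "eclampsia")
  expect_identical(map_icd10("P05.9", "stillbirth", m), "fetal_growth_restriction")
})

test_that("records round-trip through CSV and invalid rows are rejected by id", {
  dict <- toy_dictionary(3)
  set.seed(101)
  ind <- matrix(sample(c("Y", "N", "."), 5 * 245, TRUE), nrow = 5)
  rec <- va_records(data.frame(id = paste0("d", 1:5), group = "neonate",
                               cda_cause = c("c1", "c2", "c3", "c1", "c2"),
                               stringsAsFactors = FALSE), ind, dict)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  expect_message(load_records(path, dict), "5 records")
  rec2 <- suppressMessages(load_records(path, dict))
  expect_identical(rec2$data$cda_cause, rec$data$cda_cause)
  expect_identical(rec2$indicators, rec$indicators)
  expect_identical(n_indicators(rec2), 245L)

  bad <- rec$data
  bad$cda_cause[2] <- "not_a_cause"
  expect_error(va_records(bad, ind, dict), "d2")
  bad2 <- rec$data
  bad2$group[3] <- "adultish"
  expect_error(va_records(bad2, ind, dict), "d3")
})

test_that("coder output writer and reader are inverse at 12 significant digits", {
  set.seed(7)
  out <- random_outputs(100, paste0("c", 1:4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_va_outputs(out, path)
  back <- load_va_outputs(path)
  expect_identical(back$cause1, out$cause1)
  expect_identical(back$cause2, out$cause2)
  expect_identical(back$cause3, out$cause3)
  for (col in c("lik1", "lik2", "lik3", "nonconclusive")) {
    expect_equal(signif(back[[col]], 12), signif(out[[col]], 12))
  }
  # single-cause row serializes with empty trailing fields
  one <- va_outputs(data.frame(id = "x", cause1 = "A", lik1 = 0.9,
                               cause2 = NA, lik2 = 0, cause3 = NA, lik3 = 0,
                               nonconclusive = 0.1))
  write_va_outputs(one, path)
  expect_identical(readLines(path)[2], "x,A,0.9,,,,,0.1")
  # empty report row carries all residual mass
  empty <- va_outputs(data.frame(id = "y", cause1 = NA, lik1 = 0,
                                 cause2 = NA, lik2 = 0, cause3 = NA, lik3 = 0,
                                 nonconclusive = 1))
  write_va_outputs(empty, path)
  expect_equal(load_va_outputs(path)$nonconclusive, 1)
})

test_that("output validation rejects broken likelihood structure", {
  base <- data.frame(id = "z", cause1 = "a", lik1 = 0.3, cause2 = "b",
                     lik2 = 0.5, cause3 = NA, lik3 = 0, nonconclusive = 0.2)
  expect_error(va_outputs(base), "non-increasing")
  base$lik2 <- 0.1
  expect_error(va_outputs(base), "sum to 1")
  base$nonconclusive <- 0.6
  expect_s3_class(va_outputs(base), "va_outputs")
})
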