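make_run <- function(seed, out_dir, n_draws = 30) {
  spec <- simulation_spec(seed = seed)
  pb <- make_probbase(signal = 0.8)
  rec <- simulate_cohort(spec, pb)
  run_config(rec, probbase = pb,
             validation = validation_config(n_draws = n_draws, seed = seed),
             out_dir = out_dir)
}

test_that("flow export marginalizes to the confusion matrix and handles edge cases", {
  dict <- toy_dictionary(3)
  gold <- c("c1", "c1", "c2", "c3", "c3")
  pred <- c("c1", "c2", "c2", "c3", "c1")
  flows <- export_flows(gold, pred, dict)
  expect_identical(sum(flows$count), 5L)
  m <- confusion_matrix(gold, pred, dict$code)
  for (i in seq_len(nrow(flows))) {
    expect_identical(flows$count[i], m[flows$gold[i], flows$predicted[i]])
  }
  gold_margin <- tapply(flows$count, flows$gold, sum)
  expect_identical(as.integer(gold_margin[c("c1", "c2", "c3")]), c(2L, 1L, 2L))
  # perfect predictor: diagonal flows only
  perfect <- export_flows(gold, gold, dict)
  expect_true(all(perfect$gold == perfect$predicted))
  # empty cohort
  expect_identical(nrow(export_flows(character(0), character(0), dict)), 0L)
})

test_that("infection-subset metrics work at subtype level and fall back to broad categories", {
  spec <- simulation_spec(seed = 71)
  rec <- simulate_cohort(spec)
  out <- simulate_va_outputs(
    rec, misclassification_kernel(setdiff(default_cause_dictionary()$code,
                                          nonconclusive_code()), 0.7), spec)
  sub <- infection_subset_metrics(rec, out)
  expect_identical(attr(sub, "level"), "subtype")
  expect_identical(sub$cause,
                   group_causes(infection_dictionary(), "other_adult", TRUE))
  n_inf <- sum(rec$data$cda_cause == "infections")
  expect_identical(sum(sub$n), n_inf)
  expect_true(all(sub$TP + sub$TN + sub$FP + sub$FN == n_inf))
  # engine outputs carry no subtype annotation: broad-level fallback
  pb <- make_probbase(signal = 0.8)
  out2 <- suppressMessages(code_cohort(rec, pb, dictionary = default_cause_dictionary()))
  sub2 <- infection_subset_metrics(rec, out2)
  expect_identical(attr(sub2, "level"), "broad")
})

test_that("the pipeline emits the six report files with coherent CSMF columns", {
  dir <- withr::local_tempdir()
  res <- suppressWarnings(suppressMessages(run_pipeline(make_run(73, dir))))
  files <- c("table1_individual.csv", "table2_concordance.csv",
             "table3_infections.csv", "table4_population.csv",
             "draws.csv", "flows.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  t4 <- utils::read.csv(file.path(dir, "table4_population.csv"))
  sums <- aggregate(cbind(model_csmf_pct, cda_csmf_pct) ~ group, t4, sum)
  expect_true(all(sums$model_csmf_pct == 100))
  expect_true(all(sums$cda_csmf_pct == 100))
  t2 <- utils::read.csv(file.path(dir, "table2_concordance.csv"))
  expect_identical(sort(t2$group), sort(va_groups()))
  expect_true(all(c("ccc", "kappa") %in% names(t2)))
  t1 <- utils::read.csv(file.path(dir, "table1_individual.csv"),
                        stringsAsFactors = FALSE)
  expect_true(all(c("TP", "TN", "FP", "FN", "sensitivity", "npv") %in% names(t1)))
  # undefined metrics appear as the N/A literal, not as empty cells
  expect_true(any(t1$ppv == "N/A" | t1$sensitivity == "N/A"))
  flows <- utils::read.csv(file.path(dir, "flows.csv"))
  expect_identical(sum(flows$count), 316L)
})

test_that("identical configuration and seed reproduce the reports byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressWarnings(suppressMessages(run_pipeline(make_run(79, d1, n_draws = 20))))
  suppressWarnings(suppressMessages(run_pipeline(make_run(79, d2, n_draws = 20))))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a run with precomputed outputs skips the engine", {
  spec <- simulation_spec(seed = 81)
  rec <- simulate_cohort(spec)
  out <- simulate_va_outputs(
    rec, misclassification_kernel(setdiff(default_cause_dictionary()$code,
                                          nonconclusive_code()), 0.5), spec)
  dir <- withr::local_tempdir()
  cfg <- run_config(rec, outputs = out,
                    validation = validation_config(n_draws = 15, seed = 81),
                    out_dir = dir)
  expect_message(suppressWarnings(run_pipeline(cfg)), "engine skipped")
  expect_error(run_config(rec), "exactly one")
  expect_error(run_config(rec, outputs = out, probbase = make_probbase()),
               "exactly one")
})
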