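# The recursive capture-recapture protocol: ordering, initialization,
# stepping, full traces in both modes, and the combined estimator.

table5 <- inference_summary_fixture()

test_that("database ordering is primary-first, precision-descending, stable", {
  prec <- setNames(table5$precision, table5$database)
  ord <- order_databases(prec, "ICD10 Codes")
  expect_equal(ord, c("ICD10 Codes", "Cytokine Modulator Prescriptions",
                      "Patient Portal", "EPR IBD Registry",
                      "Endoscopy Records", "Flare Calls", "OPCS4 Codes",
                      "IBD Clinic Appointments", "Calprotectin > 50",
                      "Clinical Letters", "Histopathology Records"))
  # ties keep declared order even when declared the other way round
  expect_equal(order_databases(c(b = 0.9, a = 0.9, p = 0.5), "p"),
               c("p", "b", "a"))
  expect_equal(order_databases(c(x = 0.5), "x"), "x")
  expect_config_error(order_databases(c(a = 0.9), "zzz"))
})

test_that("initialization discounts the primary flagged count by precision", {
  st <- inference_init(8337, 0.96, "primary")
  expect_equal(st$cumulative_tp, 8004)
  expect_equal(st$combined_size, 8337)
  expect_equal(inference_init(120, 1)$cumulative_tp, 120)
  st0 <- inference_init(0, 0.5)
  expect_equal(c(st0$combined_size, st0$cumulative_tp), c(0, 0))
})

test_that("a single step reproduces published row arithmetic", {
  st <- inference_init(8337, 0.96, "icd10")
  st <- inference_step(st, 1.0, "cytokine", flagged = 1762, intersection = 1718)
  row <- st$steps[2, ]
  expect_equal(row$jaccard_with_combined, 0.205)
  expect_equal(row$unique, 44L)
  expect_equal(row$incremental_tp, 44L)
  expect_equal(st$cumulative_tp, 8048)

  st2 <- inference_init(8337, 0.96)
  st2$combined_size <- 8910L; st2$cumulative_tp <- 8554L
  st2 <- inference_step(st2, 0.87, "flare", flagged = 7705, intersection = 4428)
  expect_equal(st2$steps[2, "unique"], 3277L)
  expect_equal(st2$steps[2, "incremental_tp"], 2851L)
  expect_equal(st2$cumulative_tp, 11405L)

  # fully nested database adds nothing
  st3 <- inference_init(100, 0.9, "a")
  st3 <- inference_step(st3, 0.8, "b", flagged = 40, intersection = 40)
  expect_equal(st3$combined_size, 100L)
  expect_equal(st3$steps$incremental_tp[2], 0L)

  expect_error(inference_step(inference_init(10, 1), 0.5, "b",
                              flagged = 5, intersection = 7), "inconsistent")
})

test_that("summary replay of the bundled 11-database table is exact", {
  tr <- run_inference(table5, primary = "ICD10 Codes", mode = "summary_replay")
  expect_equal(tr$cumulative_tp, 18253)
  expect_equal(tr$combined_size, 20831)
  expect_equal(tr$steps$jaccard_with_combined[-1],
               c(0.205, 0.408, 0.501, 0.447, 0.363, 0.046, 0.282, 0.228,
                 0.485, 0.257))
  expect_equal(tr$steps$incremental_tp[-1],
               c(44, 155, 23, 328, 2851, 514, 1199, 482, 4129, 524))
  # monotone accumulation and the upper-bound relation at every step
  expect_true(all(diff(tr$steps$cumulative_tp) >= 0))
  expect_true(all(diff(tr$steps$combined_size) >= 0))
  expect_true(all(tr$steps$cumulative_tp <= tr$steps$combined_size))
  # trace-internal identities
  expect_equal(tr$steps$unique, tr$steps$flagged - tr$steps$intersection)
  expect_equal(tr$steps$cumulative_tp[nrow(tr$steps)],
               tr$steps$incremental_tp[1] + sum(tr$steps$incremental_tp[-1]))
})

test_that("set-based mode matches a brute-force union/intersection oracle", {
  withr::with_seed(42, {
    ids <- sprintf("P%02d", 1:30)
    sets <- list(a = sample(ids, 18), b = sample(ids, 12), c = sample(ids, 20))
  })
  prec <- c(a = 0.9, b = 0.8, c = 0.7)
  tr <- run_inference(sets, prec, primary = "a", mode = "set_based")
  # oracle: explicit running union
  comb <- unique(sets$a)
  expect_equal(tr$steps$intersection[2], length(intersect(sets$b, comb)))
  comb <- union(comb, sets$b)
  expect_equal(tr$steps$intersection[3], length(intersect(sets$c, comb)))
  comb <- union(comb, sets$c)
  expect_equal(tr$combined_size, length(comb))
  expect_equal(tr$combined_size, length(unique(unlist(sets))))
})

test_that("single-database inference is just the base step", {
  tr <- run_inference(list(only = c("x", "y", "z")), c(only = 0.5),
                      primary = "only", mode = "set_based")
  expect_equal(nrow(tr$steps), 1)
  expect_equal(tr$cumulative_tp, 2)  # round(3 * 0.5) half away from zero
  expect_equal(tr$combined_size, 3)
})

test_that("exact per-stratum precision makes the estimate exact", {
  # when every database's precision is exact within its unique stratum the
  # protocol recovers the true flagged-positive count; here precision 1
  # everywhere means cumulative_tp equals the union size
  m <- random_membership(40, 4, p = 0.5, seed = 9)
  prec <- setNames(rep(1, 4), colnames(m))
  tr <- run_inference(m, prec, primary = "db1", mode = "set_based")
  expect_equal(tr$cumulative_tp, tr$combined_size)
})

test_that("combined estimator and missed fraction follow the printed logic", {
  ce <- combine_estimates(8159, c(clinic_letters = 4889))
  expect_equal(ce$total, 13048L)
  expect_named(ce$addends, c("model_confident_tp", "clinic_letters"))
  expect_equal(combine_estimates(17)$total, 17L)
  expect_equal(combine_estimates(0, 0)$total, 0L)
  expect_config_error(combine_estimates(-1))

  expect_equal(missed_fraction(8048, 13048), 38.3)
  expect_equal(missed_fraction(500, 500), 0)
  expect_equal(missed_fraction(5000, 10000), 50)
  expect_config_error(missed_fraction(10, 0))
  expect_config_error(missed_fraction(20, 10))
})
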