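test_that("population generation is seeded, validated, and hits marginals", {
  cfg <- population_config(n_patients = 10000, female_fraction = 0.6027,
                           seed = 1)
  pop1 <- generate_population(cfg)
  pop2 <- generate_population(cfg)
  expect_identical(pop1, pop2)
  expect_lt(abs(mean(pop1$sex == "female") - 0.6027), 0.02)
  expect_lt(abs(mean(pop1$ethnicity == "white") - 0.8504), 0.02)
  expect_lt(abs(mean(pop1$age) - cfg$age_mean) / cfg$age_mean, 0.05)
  expect_true(all(pop1$age >= 18))
  expect_true(all(pop1$imd_decile %in% 1:10))
  expect_true(all(pop1$referral_year >= 2007 & pop1$referral_year <= 2023))

  solo <- generate_population(population_config(n_patients = 1,
                                                disease_prevalence = 1))
  expect_equal(nrow(solo), 1)
  expect_true(solo$disease_status)

  expect_config_error(population_config(n_patients = 0))
  expect_config_error(population_config(disease_prevalence = 1.5))
  expect_config_error(population_config(year_range = c(2023, 2007)))
})

test_that("membership generation honors the database profiles", {
  pop <- generate_population(population_config(n_patients = 3000,
                                               disease_prevalence = 0.3,
                                               seed = 2))
  perfect <- database_profile("perfect", coverage = 1, flag_sensitivity = 1,
                              flag_false_positive_rate = 0)
  empty <- database_profile("empty", coverage = 0, flag_sensitivity = 1,
                            flag_false_positive_rate = 1)
  m <- generate_membership(pop, list(perfect, empty), seed = 3)
  expect_equal(m$perfect, as.integer(pop$disease_status))
  expect_true(all(m$empty == 0))
  expect_config_error(generate_membership(pop, list(perfect, perfect)))
})

test_that("empirical precision converges to the generative target", {
  pop <- generate_population(population_config(n_patients = 20000,
                                               disease_prevalence = 0.75,
                                               seed = 4))
  profs <- default_database_profiles()
  m <- generate_membership(pop, profs, seed = 5)
  truth <- as.integer(pop$disease_status)
  targets <- c("ICD10 Codes" = 0.96, "Flare Calls" = 0.87,
               "Clinical Letters" = 0.79, "Histopathology Records" = 0.73)
  for (db in names(targets)) {
    pred <- m[[db]]
    emp <- sum(pred & truth) / sum(pred)
    expect_lt(abs(emp - targets[[db]]), 0.03, label = db)
  }
  # the recall-style profile parameter is recovered too
  emp_rec <- sum(m[["ICD10 Codes"]] & truth) / sum(truth)
  expect_lt(abs(emp_rec - 0.95 * profs[["ICD10 Codes"]]$coverage), 0.03)
})

test_that("generated documents exercise all template families", {
  pop <- generate_population(population_config(n_patients = 400,
                                               disease_prevalence = 0.4,
                                               seed = 6))
  docs <- generate_documents(pop, seed = 7)
  expect_true(all(docs$doc_type %in% c("letter", "endoscopy",
                                       "histopathology")))
  expect_true(all(docs$patient_id %in% pop$patient_id))
  flagged <- vapply(normalize_terms(docs$text),
                    function(t) flag_document(t)$flagged, logical(1))
  status <- pop$disease_status[match(docs$patient_id, pop$patient_id)]
  # diseased letters almost always carry a term; confounders produce false
  # positives among the non-diseased
  expect_gt(mean(flagged[status & docs$doc_type == "letter"]), 0.9)
  expect_gt(sum(flagged[!status]), 0)
  expect_lt(mean(flagged[!status]), 0.6)
  expect_config_error(generate_documents(pop, templates = list(positive =
    character(), negative = character())))
})

test_that("letter precision falls below endoscopy precision by design", {
  pop <- generate_population(population_config(n_patients = 6000,
                                               disease_prevalence = 0.5,
                                               seed = 8))
  docs <- generate_documents(pop, seed = 9)
  prec <- vapply(c("letter", "endoscopy"), function(dt) {
    fl <- flag_patients(docs, dt, patient_ids = pop$patient_id)
    cc <- confusion_counts(fl$flag, as.integer(pop$disease_status))
    cc$tp / (cc$tp + cc$fp)
  }, numeric(1))
  expect_lt(prec[["letter"]], prec[["endoscopy"]])
})

test_that("gold-standard sampling enforces eligibility, prevalence and split", {
  pop <- generate_population(population_config(n_patients = 20000, seed = 10))
  m <- generate_membership(pop, default_database_profiles(), seed = 11)
  gold <- sample_gold_standard(m, pop, n = 2800, min_databases = 2,
                               split_fraction = 0.3, seed = 12)
  expect_equal(nrow(gold), 2800)
  expect_equal(sum(gold$split == "validation"), 840)
  expect_true(all(gold$n_databases >= 2))
  expect_equal(mean(gold$label), 0.75)
  # labels are the true status (perfect chart review)
  expect_equal(gold$label,
               as.integer(pop$disease_status[match(gold$patient_id,
                                                   pop$patient_id)]))
  # min_databases = 1 makes everyone with any record eligible
  gold1 <- sample_gold_standard(m, pop, n = 100, min_databases = 1, seed = 13)
  expect_true(all(gold1$n_databases >= 1))
  # shortfall error names the deficit
  expect_error(sample_gold_standard(m, pop, n = 2800, min_databases = 11,
                                    seed = 14), "need")
  expect_config_error(sample_gold_standard(m, pop, n = 10, min_databases = 0))
})

test_that("membership and gold standard are reproducible for a fixed seed", {
  pop <- generate_population(population_config(n_patients = 2000, seed = 15))
  m1 <- generate_membership(pop, default_database_profiles(), seed = 16)
  m2 <- generate_membership(pop, default_database_profiles(), seed = 16)
  expect_identical(m1, m2)
  g1 <- sample_gold_standard(m1, pop, n = 200, seed = 17)
  g2 <- sample_gold_standard(m2, pop, n = 200, seed = 17)
  expect_identical(g1, g2)
})
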