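# Shared in-code fixtures for the suite.

# random binary membership matrix with patient ids
random_membership <- function(n_patients, n_db, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_patients * n_db, 1, p), n_patients, n_db,
                dimnames = list(sprintf("P%03d", seq_len(n_patients)),
                                paste0("db", seq_len(n_db))))
  })
  m
}

# brute-force set versions of the membership columns
oracle_sets <- function(m) {
  lapply(setNames(colnames(m), colnames(m)),
         function(cn) rownames(m)[m[, cn] == 1])
}

# random confusion table with at least one evaluated patient
random_confusion <- function(seed, max_cell = 50) {
  withr::with_seed(seed, {
    repeat {
      cc <- list(tp = sample(0:max_cell, 1), fp = sample(0:max_cell, 1),
                 fn = sample(0:max_cell, 1), tn = sample(0:max_cell, 1))
      if (cc$tp + cc$fp + cc$fn + cc$tn > 0) break
    }
  })
  cc$n <- cc$tp + cc$fp + cc$fn + cc$tn
  class(cc) <- "confusion_counts"
  cc
}

# binary labels generated from a known logistic model over binary flags
logistic_instance <- function(n, betas, intercept = -1, seed = 1, p_flag = 0.3) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * length(betas), 1, p_flag), n, length(betas),
                dimnames = list(NULL, paste0("flag", seq_along(betas))))
    eta <- intercept + drop(x %*% betas)
    y <- rbinom(n, 1, plogis(eta))
  })
  list(x = as.data.frame(x), y = y)
}

expect_config_error <- function(expr) {
  expect_error(expr, class = "cohortcapture_config_error")
}
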