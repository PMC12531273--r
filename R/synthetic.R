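# Seeded synthetic multi-database EHR generator. Emulates the study
# conditions the analysis assumes: a large gastroenterology-referral
# population with ~16.5% disease prevalence, 11 partially overlapping
# databases whose flagging accuracy matches published per-database
# precision/recall profiles, template free-text documents with disease
# terms, synonyms and confounder phrases, and a chart-review gold standard
# sampled only from patients present in at least two databases.

#' Population generator configuration
#'
#' @param n_patients population size (default 37,947, the scale of a
#'   15-year single-centre referral population).
#' @param disease_prevalence fraction with the disease in (0,1); default
#'   0.165, the expected disease fraction among specialist referrals.
#' @param seed RNG seed.
#' @param year_range inclusive first/last referral year.
#' @param age_mean,age_sd mean/sd of age (years), truncated at >= 18.
#' @param female_fraction,white_fraction demographic marginals.
#' @param imd_probs probabilities over deprivation deciles 1..10; default a
#'   slight linear tilt giving mean about 5.9.
#' @return list of class `population_config`.
#' @export
population_config <- function(n_patients = 37947,
                              disease_prevalence = 0.165,
                              seed = 1L,
                              year_range = c(2007L, 2023L),
                              age_mean = 51.79, age_sd = 24,
                              female_fraction = 0.6027,
                              white_fraction = 0.8504,
                              imd_probs = NULL) {
  if (n_patients < 1) stop_config("n_patients must be >= 1")
  if (disease_prevalence <= 0 || disease_prevalence > 1) {
    stop_config("disease_prevalence must lie in (0, 1]")
  }
  if (length(year_range) != 2 || year_range[1] > year_range[2]) {
    stop_config("year_range must be an ordered pair")
  }
  for (frac in c(female_fraction, white_fraction)) {
    if (frac < 0 || frac > 1) stop_config("demographic fractions must lie in [0, 1]")
  }
  if (is.null(imd_probs)) {
    k <- 1:10
    imd_probs <- (1 + 0.0497 * (k - 5.5)) / 10
  }
  if (length(imd_probs) != 10 || any(imd_probs < 0)) {
    stop_config("imd_probs must be 10 non-negative weights")
  }
  structure(list(n_patients = as.integer(n_patients),
                 disease_prevalence = disease_prevalence,
                 seed = as.integer(seed), year_range = as.integer(year_range),
                 age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 white_fraction = white_fraction,
                 imd_probs = imd_probs / sum(imd_probs)),
            class = "population_config")
}

#' Generate a synthetic referral population
#'
#' Demographics are sampled independently per field (only marginals are
#' emulated): age from a normal truncated at 18, sex/ethnicity as Bernoulli
#' marginals, deprivation decile from `imd_probs`, referral year uniform on
#' the study window. Deterministic for a fixed seed.
#'
#' @param config a [population_config()].
#' @return data.frame, one row per patient: `patient_id`, `disease_status`
#'   (logical), `age`, `sex`, `ethnicity`, `imd_decile`, `referral_year`.
#' @export
generate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_patients
  # location parameter solved so the >=18-truncated mean equals age_mean
  trunc_mean <- function(mu) {
    a <- (18 - mu) / config$age_sd
    mu + config$age_sd * dnorm(a) / (1 - pnorm(a))
  }
  mu <- uniroot(function(m) trunc_mean(m) - config$age_mean,
                c(config$age_mean - 3 * config$age_sd, config$age_mean),
                tol = 1e-6)$root
  withr::with_seed(config$seed, {
    age <- rnorm(n, mu, config$age_sd)
    while (any(age < 18)) {
      age[age < 18] <- rnorm(sum(age < 18), mu, config$age_sd)
    }
    eth <- ifelse(rbinom(n, 1, config$white_fraction) == 1, "white",
                  sample(c("asian", "african", "other"), n, replace = TRUE))
    data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      disease_status = runif(n) < config$disease_prevalence,
      age = round(age, 1),
      sex = ifelse(rbinom(n, 1, config$female_fraction) == 1, "female", "male"),
      ethnicity = eth,
      imd_decile = sample.int(10, n, replace = TRUE, prob = config$imd_probs),
      referral_year = sample(seq(config$year_range[1], config$year_range[2]),
                             n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Construct a database flagging profile
#'
#' @param name unique database name.
#' @param coverage fraction of the population with any record in the
#'   database.
#' @param flag_sensitivity P(flagged | diseased, covered).
#' @param flag_false_positive_rate P(flagged | not diseased, covered).
#' @param is_registry if TRUE membership implies a flag for diseased
#'   patients (sensitivity forced to 1 among members).
#' @return list of class `database_profile`.
#' @export
database_profile <- function(name, coverage, flag_sensitivity,
                             flag_false_positive_rate, is_registry = FALSE) {
  for (p in c(coverage, flag_sensitivity, flag_false_positive_rate)) {
    if (p < 0 || p > 1) stop_config("profile probabilities must lie in [0, 1]")
  }
  if (is_registry) flag_sensitivity <- 1
  structure(list(name = name, coverage = coverage,
                 flag_sensitivity = flag_sensitivity,
                 flag_false_positive_rate = flag_false_positive_rate,
                 is_registry = is_registry), class = "database_profile")
}

#' Back-solve a profile from published precision/recall
#'
#' Given a database's observed precision and recall against a gold standard
#' of known prevalence, the implied false-positive rate among covered
#' non-diseased patients is
#' `fpr = prev * recall * (1 - precision) / ((1 - prev) * precision)`.
#'
#' @param name database name.
#' @param precision,recall published operating point.
#' @param coverage fraction covered.
#' @param prevalence gold-standard disease prevalence the operating point was
#'   measured at (default 0.75, an enriched chart-review cohort).
#' @param is_registry registry flag.
#' @return a [database_profile()].
#' @export
profile_from_metrics <- function(name, precision, recall, coverage,
                                 prevalence = 0.75, is_registry = FALSE) {
  if (precision <= 0 || precision > 1) stop_config("precision must lie in (0, 1]")
  fpr <- prevalence * recall * (1 - precision) / ((1 - prevalence) * precision)
  database_profile(name, coverage, recall, min(1, fpr), is_registry)
}

#' Default 11-database profile set
#'
#' Profiles calibrated to the published per-database operating points
#' (precision, recall, gold-standard coverage) of a coded + registry +
#' event + free-text database mix, declared in precision order with the
#' diagnostic-codes database first. The true hospital generating mechanisms
#' are unobserved; these profiles reproduce the observed operating points,
#' not the underlying processes.
#'
#' @return named list of [database_profile()] objects.
#' @export
default_database_profiles <- function() {
  spec <- list(
    #                name                 prec  rec  coverage registry
    list("ICD10 Codes",                      0.96, 0.95, 0.9548, FALSE),
    list("Cytokine Modulator Prescriptions", 1.00, 1.00, 0.2357, FALSE),
    list("Patient Portal",                   0.97, 1.00, 0.5095, TRUE),
    list("EPR IBD Registry",                 0.97, 1.00, 0.6798, TRUE),
    list("Endoscopy Records",                0.95, 0.70, 0.8790, FALSE),
    list("Flare Calls",                      0.87, 1.00, 0.6012, FALSE),
    list("OPCS4 Codes",                      0.86, 0.17, 0.3260, FALSE),
    list("IBD Clinic Appointments",          0.80, 0.70, 0.7905, FALSE),
    list("Calprotectin > 50",                0.80, 0.70, 0.6345, FALSE),
    list("Clinical Letters",                 0.79, 0.99, 0.9450, FALSE),
    list("Histopathology Records",           0.73, 0.89, 0.6024, FALSE))
  profs <- lapply(spec, function(s)
    profile_from_metrics(s[[1]], s[[2]], s[[3]], s[[4]], is_registry = s[[5]]))
  setNames(profs, vapply(profs, `[[`, "", "name"))
}

#' Generate the patient-by-database flag matrix
#'
#' For each database, a patient is covered with probability `coverage`;
#' covered diseased patients are flagged with probability `flag_sensitivity`
#' and covered non-diseased patients with probability
#' `flag_false_positive_rate`. Uncovered patients are 0 — absence of a
#' record is encoded as 0, never missing.
#'
#' @param population output of [generate_population()].
#' @param profiles list of [database_profile()]s with unique names.
#' @param seed RNG seed.
#' @return data.frame: `patient_id` plus one binary column per database.
#' @export
generate_membership <- function(population, profiles = default_database_profiles(),
                                seed = 1L) {
  if (length(profiles) == 0) stop_config("profiles must be non-empty")
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_config("duplicate database names: ",
                                      paste(nms[duplicated(nms)], collapse = ", "))
  n <- nrow(population)
  dis <- population$disease_status
  withr::with_seed(seed, {
    cols <- lapply(profiles, function(pf) {
      covered <- runif(n) < pf$coverage
      p_flag <- ifelse(dis, pf$flag_sensitivity, pf$flag_false_positive_rate)
      as.integer(covered & (runif(n) < p_flag))
    })
  })
  out <- data.frame(patient_id = population$patient_id, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[nms[i]]] <- cols[[i]]
  out
}

#' Default document templates
#'
#' Template sentences with a `{term}` slot. `positive` templates carry a
#' disease term, `synonym` templates an abbreviation the normalizer must
#' expand, `confounder` templates a non-IBD colitide that the permissive
#' substring patterns intentionally over-match, and `negative` templates no
#' matchable term at all.
#'
#' @return list with character vectors `positive`, `synonym`, `confounder`,
#'   `negative`.
#' @export
default_templates <- function() {
  list(
    positive = c(
      "Diagnosis: {term}. Continues on maintenance therapy.",
      "Findings consistent with {term}; discussed in MDT.",
      "{term} confirmed on review of imaging and bloods."),
    synonym = c(
      "Known {term}, currently stable on azathioprine.",
      "Follow-up of {term}; no new symptoms reported."),
    confounder = c(
      "Appearances in keeping with {term}; IBD felt unlikely.",
      "Features of {term} on biopsy; no chronicity."),
    negative = c(
      "Normal colonoscopy to caecum. No abnormality seen.",
      "Reflux symptoms improving on PPI therapy.",
      "Unremarkable mucosa throughout; biopsies taken routinely."))
}

#' Default term lists for document generation
#'
#' @return list with `disease` (the normalized terms), `synonyms`
#'   (abbreviations/variants), `confounders` (other colitides).
#' @export
default_term_lists <- function() {
  list(disease = normalized_terms(),
       synonyms = c("UC", "CD", "crohns", "IBDU"),
       confounders = c("ischaemic colitis", "ischemic colitis",
                       "infective colitis", "radiation colitis",
                       "diverticular colitis"))
}

#' Generate synthetic free-text documents
#'
#' Each patient covered by a free-text database receives one document of
#' that type. Diseased patients receive a disease-term (or synonym) document
#' with probability `p_disease_term`, otherwise a negative template.
#' Non-diseased patients receive a confounder document with a per-type
#' probability (concentrated in clinic letters by default, which drags
#' letter precision below endoscopy precision), otherwise a negative
#' template.
#'
#' @param population output of [generate_population()].
#' @param templates template list as in [default_templates()].
#' @param terms term list as in [default_term_lists()].
#' @param seed RNG seed.
#' @param coverage named per-type coverage fractions.
#' @param p_disease_term probability a diseased patient's document names the
#'   disease.
#' @param p_confounder named per-type probability a non-diseased patient's
#'   document contains a confounder colitide.
#' @param p_synonym among disease-term documents, probability the term is an
#'   unnormalized synonym rather than a canonical form.
#' @return data.frame with `patient_id`, `doc_type`, `text`.
#' @export
generate_documents <- function(population,
                               templates = default_templates(),
                               terms = default_term_lists(),
                               seed = 1L,
                               coverage = c(letter = 0.945, endoscopy = 0.879,
                                            histopathology = 0.6024),
                               p_disease_term = c(letter = 0.99,
                                                  endoscopy = 0.70,
                                                  histopathology = 0.89),
                               p_confounder = c(letter = 0.55,
                                                endoscopy = 0.10,
                                                histopathology = 0.45),
                               p_synonym = 0.3) {
  if (!length(templates$positive) || !length(templates$negative)) {
    stop_config("templates must include positive and negative variants")
  }
  fill <- function(tpl, term) gsub("{term}", term, tpl, fixed = TRUE)
  withr::with_seed(seed, {
    rows <- lapply(names(coverage), function(dt) {
      covered <- population[runif(nrow(population)) < coverage[[dt]], ]
      if (nrow(covered) == 0) return(NULL)
      txt <- vapply(seq_len(nrow(covered)), function(i) {
        if (covered$disease_status[i]) {
          if (runif(1) < p_disease_term[[dt]]) {
            if (runif(1) < p_synonym && length(templates$synonym)) {
              fill(sample(templates$synonym, 1), sample(terms$synonyms, 1))
            } else {
              fill(sample(templates$positive, 1), sample(terms$disease, 1))
            }
          } else sample(templates$negative, 1)
        } else {
          if (runif(1) < p_confounder[[dt]] && length(templates$confounder)) {
            fill(sample(templates$confounder, 1), sample(terms$confounders, 1))
          } else sample(templates$negative, 1)
        }
      }, character(1))
      data.frame(patient_id = covered$patient_id, doc_type = dt, text = txt,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Sample a chart-review gold standard
#'
#' Emulates a strongly supervised validation cohort: eligibility is
#' restricted to patients present in at least `min_databases` databases (the
#' multi-database sampling bias that later produces edge-node
#' underprediction), sampling is stratified by true disease status to hit a
#' target prevalence, labels are copied from the true status (perfect chart
#' review), and a seeded split marks a validation fraction.
#'
#' @param membership patient-by-database table from [generate_membership()].
#' @param population matching population table (source of true status).
#' @param n gold-standard size (default 2800).
#' @param min_databases minimum row sum for eligibility (default 2).
#' @param split_fraction validation fraction (default 0.3).
#' @param target_prevalence disease fraction in the sample (default 0.75).
#' @param seed RNG seed.
#' @return data.frame with `patient_id`, `label` (0/1), `split`
#'   ("training"/"validation"), `n_databases`.
#' @export
sample_gold_standard <- function(membership, population, n = 2800,
                                 min_databases = 2, split_fraction = 0.3,
                                 target_prevalence = 0.75, seed = 1L) {
  if (min_databases < 1) stop_config("min_databases must be >= 1")
  m <- as_membership_matrix(membership)
  deg <- rowSums(m)
  eligible <- rownames(m)[deg >= min_databases]
  status <- setNames(population$disease_status, population$patient_id)
  pos_pool <- eligible[status[eligible]]
  neg_pool <- eligible[!status[eligible]]
  n_pos <- round_half_away(n * target_prevalence)
  n_neg <- n - n_pos
  if (length(pos_pool) < n_pos || length(neg_pool) < n_neg) {
    stop(sprintf(paste0("cannot sample gold standard: need %d diseased and %d ",
                        "non-diseased eligible patients (>=%d databases), have %d and %d"),
                 n_pos, n_neg, min_databases, length(pos_pool), length(neg_pool)))
  }
  withr::with_seed(seed, {
    ids <- c(sample(pos_pool, n_pos), sample(neg_pool, n_neg))
    ids <- sample(ids)  # shuffle before the split
    n_val <- round_half_away(n * split_fraction)
    split <- rep("training", n)
    split[sample.int(n, n_val)] <- "validation"
  })
  data.frame(patient_id = ids,
             label = as.integer(status[ids]),
             split = split,
             n_databases = as.integer(deg[match(ids, rownames(m))]),
             stringsAsFactors = FALSE)
}
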