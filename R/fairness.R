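# Stratified discrimination audit: AUROC within demographic subgroups with
# DeLong confidence intervals, and the maximal pairwise gap per attribute.
# The audit measures bias; it does not attempt to correct it.

#' Decadal age bands
#'
#' @param age numeric ages in years.
#' @param width band width in years (default 10, giving 20-29, 30-39, ...).
#' @return factor of band labels.
#' @export
age_band <- function(age, width = 10) {
  lo <- floor(age / width) * width
  factor(sprintf("%d-%d", lo, lo + width - 1))
}

#' Deprivation quintile from IMD decile
#'
#' Collapses deciles 1..10 to quintiles 1..5 (1 = most deprived).
#'
#' @param imd_decile integer deciles 1..10.
#' @return factor of quintiles.
#' @export
imd_band <- function(imd_decile) {
  factor(ceiling(imd_decile / 2), levels = 1:5)
}

#' Stratified AUROC across demographic groups
#'
#' Computes the AUROC within each level of each grouping attribute, with
#' DeLong 95% intervals, flags (never silently drops) groups below the
#' minimum size or with a single outcome class, and reports the maximal
#' pairwise AUROC gap per attribute among evaluable groups.
#'
#' @param probabilities model probabilities for the audited patients.
#' @param labels binary outcomes.
#' @param group_assignments data.frame of one or more attribute columns
#'   (e.g. sex, ethnicity, [age_band()], [imd_band()]), rows aligned to
#'   `probabilities`.
#' @param min_group_size groups smaller than this are flagged as
#'   underpowered (default 30).
#' @return list of class `fairness_report`: `groups` (data.frame with
#'   `attribute`, `group`, `n`, `auc`, `lower`, `upper`, `flag`), `gaps`
#'   (data.frame `attribute`, `max_gap`), `pooled_auc`.
#' @export
stratified_auc <- function(probabilities, labels, group_assignments,
                           min_group_size = 30) {
  ga <- as.data.frame(group_assignments)
  y <- as.integer(labels)
  if (nrow(ga) != length(y)) stop_config("group assignments not aligned to labels")
  if (any(is.na(ga))) stop_config("groups must cover all evaluated patients")
  rows <- list(); gaps <- list()
  for (attr_name in names(ga)) {
    g <- as.factor(ga[[attr_name]])
    aucs <- c()
    for (lev in levels(g)) {
      idx <- which(g == lev)
      n <- length(idx)
      flag <- character()
      if (n < min_group_size) flag <- c(flag, "underpowered")
      if (length(unique(y[idx])) < 2) {
        flag <- c(flag, "single_class")
        a <- lo <- hi <- NA_real_
      } else {
        r <- pROC::roc(response = y[idx], predictor = probabilities[idx],
                       levels = c(0, 1), direction = "<", quiet = TRUE)
        ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
        a <- ci[2]; lo <- ci[1]; hi <- ci[3]
        if (!length(flag)) aucs <- c(aucs, a)
      }
      rows[[length(rows) + 1]] <- data.frame(
        attribute = attr_name, group = lev, n = n, auc = a,
        lower = lo, upper = hi,
        flag = if (length(flag)) paste(flag, collapse = ";") else "",
        stringsAsFactors = FALSE)
    }
    gaps[[attr_name]] <- data.frame(
      attribute = attr_name,
      max_gap = if (length(aucs) >= 2) max(aucs) - min(aucs) else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(groups = do.call(rbind, rows),
                 gaps = do.call(rbind, gaps),
                 pooled_auc = if (length(unique(y)) == 2)
                   auc_value(y, probabilities) else NA_real_,
                 min_group_size = min_group_size),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("Fairness audit (pooled AUROC %.3f, min group size %d)\n",
              x$pooled_auc, x$min_group_size))
  print(x$groups, row.names = FALSE, digits = 3)
  cat("max pairwise AUROC gap per attribute:\n")
  print(x$gaps, row.names = FALSE, digits = 3)
  invisible(x)
}
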