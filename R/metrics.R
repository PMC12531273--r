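# Per-database diagnostic accuracy against a chart-reviewed gold standard:
# confusion counts, the six standard screening metrics, percentile-bootstrap
# intervals, and precision-based ranking.

#' Confusion counts for binary flags against binary truth
#'
#' @param pred binary (0/1 or logical) predicted flags.
#' @param truth binary gold-standard labels, same length and order.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("prediction and truth vectors are not aligned: lengths ",
         length(pred), " vs ", length(truth))
  }
  if (any(!pred %in% c(0, 1)) || any(!truth %in% c(0, 1))) {
    stop_config("pred and truth must be binary 0/1")
  }
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1),
                 tn = sum(pred == 0 & truth == 0),
                 n = length(pred)), class = "confusion_counts")
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Accuracy (TP+TN)/N, precision TP/(TP+FP), NPV TN/(TN+FN), recall
#' TP/(TP+FN), specificity TN/(TN+FP), and the unweighted harmonic-mean F1.
#' Ratios with a zero denominator are reported as 0 and the affected metric
#' names are flagged in a `degenerate` attribute plus a warning, matching the
#' convention of printing 0.0 for degenerate cells.
#'
#' @param counts a `confusion_counts` object (or a list with tp/fp/fn/tn).
#' @return named numeric vector of the six metrics with attribute
#'   `degenerate` (character vector of zero-denominator metrics).
#' @examples
#' classification_metrics(confusion_counts(c(1,1,0), c(1,0,0)))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  if (n == 0) stop("cannot evaluate metrics on an empty set")
  degenerate <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  out <- c(accuracy = (tp + tn) / n,
           precision = precision,
           npv = safe(tn, tn + fn, "npv"),
           recall = recall,
           specificity = safe(tn, tn + fp, "specificity"),
           f1 = f1)
  if (length(degenerate)) {
    warning("zero-denominator metrics reported as 0: ",
            paste(unique(degenerate), collapse = ", "))
  }
  attr(out, "degenerate") <- unique(degenerate)
  out
}

#' Bootstrap confidence intervals for diagnostic metrics
#'
#' Percentile intervals (2.5/97.5) over patient-level resamples with
#' replacement; deterministic for a fixed seed.
#'
#' @param pred,truth aligned binary vectors.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return a data.frame of class `metric_set`, one row per metric with
#'   `estimate`, `lower`, `upper`; coverage counts in attributes.
#' @export
bootstrap_metrics <- function(pred, truth, n_reps = 1000, seed = 1,
                              conf = 0.95) {
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  pred <- as.integer(pred); truth <- as.integer(truth)
  point <- suppressWarnings(classification_metrics(confusion_counts(pred, truth)))
  if (length(unique(truth)) == 1) {
    warning("gold-standard labels are all one class; some metrics are degenerate")
  }
  n <- length(pred)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(classification_metrics(confusion_counts(pred[idx], truth[idx])))
    }, numeric(6))
  })
  alpha <- (1 - conf) / 2
  lower <- apply(reps, 1, quantile, probs = alpha, names = FALSE)
  upper <- apply(reps, 1, quantile, probs = 1 - alpha, names = FALSE)
  out <- data.frame(metric = names(point), estimate = as.numeric(point),
                    lower = lower, upper = upper, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- attr(point, "degenerate")
  attr(out, "n_reps") <- n_reps
  class(out) <- c("metric_set", "data.frame")
  out
}

#' Evaluate every database column against the gold standard
#'
#' One row per database: coverage of the gold standard (count and fraction of
#' gold-standard patients present/flagged in the database) and the six
#' metrics with bootstrap intervals.
#'
#' @param membership binary patient-by-database table; rows aligned to, or
#'   matched by `patient_id` against, the gold standard.
#' @param gold data.frame with `patient_id` and binary `label`.
#' @param n_reps,seed bootstrap settings.
#' @return data.frame, one row per database, columns `database`, `coverage_n`,
#'   `coverage_frac`, then `<metric>`, `<metric>_lower`, `<metric>_upper`.
#' @export
database_metrics <- function(membership, gold, n_reps = 1000, seed = 1) {
  m <- as_membership_matrix(membership)
  ids <- rownames(m)
  if (is.null(ids)) stop_config("membership needs patient ids")
  hit <- match(as.character(gold$patient_id), ids)
  if (anyNA(hit)) stop_config("gold-standard patients missing from membership table")
  sub <- m[hit, , drop = FALSE]
  truth <- as.integer(gold$label)
  rows <- lapply(colnames(sub), function(db) {
    pred <- sub[, db]
    ms <- suppressWarnings(bootstrap_metrics(pred, truth, n_reps = n_reps,
                                             seed = seed))
    vals <- setNames(ms$estimate, ms$metric)
    lo <- setNames(ms$lower, paste0(ms$metric, "_lower"))
    hi <- setNames(ms$upper, paste0(ms$metric, "_upper"))
    cbind(data.frame(database = db, coverage_n = sum(pred),
                     coverage_frac = mean(pred), stringsAsFactors = FALSE),
          as.data.frame(as.list(c(vals, lo, hi))))
  })
  do.call(rbind, rows)
}

#' Rank databases by precision
#'
#' Positive predictive value is the primary ranking measure for deciding the
#' integration order of the inference protocol. Descending by point estimate;
#' ties keep input order.
#'
#' @param metrics data.frame with `database` and `precision` columns (e.g.
#'   from [database_metrics()]), or a named numeric vector of precisions.
#' @return character vector of database names, best first.
#' @export
rank_by_precision <- function(metrics) {
  if (is.numeric(metrics) && !is.null(names(metrics))) {
    prec <- metrics
  } else {
    if (nrow(metrics) < 1) stop_config("need at least one database")
    prec <- setNames(metrics$precision, metrics$database)
  }
  names(prec)[order(-prec, seq_along(prec))]
}
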