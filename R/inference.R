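# Recursive Jaccard capture-recapture estimation of total cohort size.
#
# The protocol: start from the primary database, discount its flagged count
# by its precision to seed the running true-positive total; then take each
# remaining database in descending order of precision, measure its overlap
# with the running "combined" union, count the patients it uniquely adds,
# and discount those by that database's own precision. The running union
# gives an upper bound on cohort size; the cumulative discounted total is
# the estimate. The method assumes each database's precision applies equally
# to its intersection and its unique remainder, which makes the final figure
# an upper estimate.

#' Order databases for the inference protocol
#'
#' Primary database first, then all others by descending precision; ties
#' keep the declared input order (stable sort).
#'
#' @param precisions named numeric vector of per-database precision (PPV).
#' @param primary name of the primary (seed) database.
#' @return character vector of database names in integration order.
#' @examples
#' order_databases(c(icd10 = 0.96, letters = 0.79, cytokine = 1.0), "icd10")
#' @export
order_databases <- function(precisions, primary) {
  if (is.null(names(precisions)) || any(!nzchar(names(precisions)))) {
    stop_config("precisions must be a fully named vector")
  }
  if (!primary %in% names(precisions)) {
    stop_config("unknown primary database '", primary, "'")
  }
  rest <- precisions[names(precisions) != primary]
  ord <- names(rest)[order(-rest, seq_along(rest))]
  c(primary, ord)
}

#' Initialize the inference state from the primary database
#'
#' The full flagged set of the primary database seeds the running combined
#' union; its precision-discounted count (rounded half away from zero) seeds
#' the cumulative true-positive estimate.
#'
#' @param flagged number of patients flagged by the primary database.
#' @param precision primary database precision in \[0, 1\].
#' @param name database name recorded in the trace.
#' @return list of class `inference_state` with `combined_size`,
#'   `cumulative_tp`, `integrated`, and the base step row.
#' @export
inference_init <- function(flagged, precision, name = "primary") {
  if (flagged < 0) stop_config("flagged count must be non-negative")
  if (precision < 0 || precision > 1) stop_config("precision must lie in [0, 1]")
  tp <- as.integer(round_half_away(flagged * precision))
  base <- data.frame(
    database = name, flagged = as.integer(flagged),
    jaccard_with_combined = NA_real_,
    intersection = 0L, unique = as.integer(flagged),
    precision = precision, incremental_tp = tp, cumulative_tp = tp,
    combined_size = as.integer(flagged), stringsAsFactors = FALSE)
  structure(list(combined_size = as.integer(flagged), cumulative_tp = tp,
                 integrated = name, combined_set = NULL, steps = base),
            class = "inference_state")
}

#' Integrate one database into the running estimate
#'
#' In `set_based` mode pass the database's flagged patient-id set; the
#' intersection with the running combined set is computed exactly. In
#' `summary_replay` mode pass the flagged and intersection counts directly
#' (e.g. from a published summary table). Either way: the Jaccard index with
#' the combined set is reported to 3 d.p.; `unique = flagged - intersection`
#' patients are added to the union; `round(unique * precision)` (half away
#' from zero) is added to the cumulative true-positive estimate.
#'
#' @param state an `inference_state`.
#' @param precision this database's precision.
#' @param name database name.
#' @param flagged_set patient-id vector (set_based mode).
#' @param flagged,intersection counts (summary_replay mode).
#' @return updated `inference_state`; the new step row is appended to
#'   `state$steps`.
#' @export
inference_step <- function(state, precision, name,
                           flagged_set = NULL, flagged = NULL,
                           intersection = NULL) {
  stopifnot(inherits(state, "inference_state"))
  if (precision < 0 || precision > 1) stop_config("precision must lie in [0, 1]")
  if (!is.null(flagged_set)) {
    flagged_set <- unique(as.character(flagged_set))
    flagged <- length(flagged_set)
    if (is.null(state$combined_set)) {
      stop_config("state was initialized without a combined set; use run_inference(..., mode = 'set_based')")
    }
    intersection <- length(intersect(flagged_set, state$combined_set))
  }
  if (is.null(flagged) || is.null(intersection)) {
    stop_config("supply either flagged_set or both flagged and intersection counts")
  }
  if (intersection > min(flagged, state$combined_size)) {
    stop(sprintf("inconsistent counts for '%s': intersection %d exceeds min(flagged %d, combined %d)",
                 name, intersection, flagged, state$combined_size))
  }
  un <- flagged - intersection
  jac <- if (state$combined_size + flagged - intersection > 0) {
    round_half_up(intersection / (state$combined_size + flagged - intersection), 3)
  } else NA_real_
  inc <- as.integer(round_half_away(un * precision))
  state$combined_size <- state$combined_size + as.integer(un)
  state$cumulative_tp <- state$cumulative_tp + inc
  state$integrated <- c(state$integrated, name)
  if (!is.null(flagged_set)) {
    state$combined_set <- union(state$combined_set, flagged_set)
  }
  state$steps <- rbind(state$steps, data.frame(
    database = name, flagged = as.integer(flagged),
    jaccard_with_combined = jac,
    intersection = as.integer(intersection), unique = as.integer(un),
    precision = precision, incremental_tp = inc,
    cumulative_tp = state$cumulative_tp,
    combined_size = state$combined_size, stringsAsFactors = FALSE))
  state
}

#' Run the full recursive Jaccard inference protocol
#'
#' Orders the databases (primary first, then descending precision), seeds the
#' state from the primary database and integrates the remainder one step at a
#' time.
#'
#' @param x in `set_based` mode, a binary membership matrix/data.frame (see
#'   [jaccard_matrix()]) or a named list of flagged patient-id sets; in
#'   `summary_replay` mode, a data.frame with columns `database`, `flagged`,
#'   `intersection` (intersection ignored/NA for the primary row) as printed
#'   in a published inference table.
#' @param precisions named numeric vector of per-database precision; in
#'   summary_replay mode a `precision` column of `x` may be used instead.
#' @param primary primary database name.
#' @param mode `"set_based"` or `"summary_replay"`.
#' @return an `inference_trace`: the per-step table plus final
#'   `combined_size` (union upper bound) and `cumulative_tp` (the estimate).
#' @examples
#' tab <- read.csv(system.file("extdata", "inference_summary_11db.csv",
#'                             package = "cohortcapture"))
#' run_inference(tab, primary = "ICD10 Codes", mode = "summary_replay")
#' @export
run_inference <- function(x, precisions = NULL, primary,
                          mode = c("set_based", "summary_replay")) {
  mode <- match.arg(mode)
  if (mode == "summary_replay") {
    tab <- as.data.frame(x)
    need <- c("database", "flagged", "intersection")
    if (!all(need %in% names(tab))) {
      stop_config("summary table needs columns: ", paste(need, collapse = ", "))
    }
    if (is.null(precisions)) {
      if (!"precision" %in% names(tab)) {
        stop_config("supply precisions or a precision column")
      }
      precisions <- setNames(tab$precision, tab$database)
    }
    if (anyDuplicated(tab$database)) stop_config("duplicate database names")
    ord <- order_databases(precisions, primary)
    rows <- tab[match(ord, tab$database), ]
    st <- inference_init(rows$flagged[1], precisions[[primary]], name = primary)
    for (i in seq_len(nrow(rows))[-1]) {
      st <- inference_step(st, precisions[[rows$database[i]]],
                           name = rows$database[i],
                           flagged = rows$flagged[i],
                           intersection = rows$intersection[i])
    }
  } else {
    sets <- if (is.list(x) && !is.data.frame(x)) x else membership_sets(x)
    if (anyDuplicated(names(sets))) stop_config("duplicate database names")
    if (is.null(precisions)) stop_config("set_based mode requires precisions")
    ord <- order_databases(precisions[names(sets)], primary)
    prim_set <- unique(as.character(sets[[primary]]))
    st <- inference_init(length(prim_set), precisions[[primary]], name = primary)
    st$combined_set <- prim_set
    for (nm in ord[-1]) {
      st <- inference_step(st, precisions[[nm]], name = nm,
                           flagged_set = sets[[nm]])
    }
  }
  structure(list(steps = st$steps, combined_size = st$combined_size,
                 cumulative_tp = st$cumulative_tp, order = st$integrated,
                 mode = mode),
            class = "inference_trace")
}

#' @export
print.inference_trace <- function(x, ...) {
  cat(sprintf("Recursive Jaccard cohort-size inference (%s mode)\n", x$mode))
  print(x$steps, row.names = FALSE, digits = 4)
  cat(sprintf("Final union (upper bound): %s patients\n",
              format(x$combined_size, big.mark = ",")))
  cat(sprintf("Estimated true-positive cohort: %s patients\n",
              format(x$cumulative_tp, big.mark = ",")))
  invisible(x)
}

#' Combine a model-based estimate with unaccounted-for database totals
#'
#' Adds the true positives a classifier confidently identifies to the
#' unaccounted-for (model-missed) true positives contributed by named
#' databases, recording the provenance of each addend.
#'
#' @param model_confident_tp true positives identified by the model.
#' @param unaccounted_unique_tps named or unnamed numeric vector/list of
#'   additional true-positive counts not captured by the model.
#' @return list of class `combined_estimate` with `total` and `addends`.
#' @examples
#' combine_estimates(8159, c(clinic_letters = 4889))$total  # 13048
#' @export
combine_estimates <- function(model_confident_tp, unaccounted_unique_tps = numeric()) {
  extra <- unlist(unaccounted_unique_tps)
  if (length(extra) == 0) extra <- numeric()
  if (model_confident_tp < 0 || any(extra < 0)) {
    stop_config("all addends must be non-negative")
  }
  addends <- c(setNames(model_confident_tp, "model_confident_tp"), extra)
  structure(list(total = as.integer(sum(addends)), addends = addends),
            class = "combined_estimate")
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat("Combined cohort estimate:", format(x$total, big.mark = ","), "\n")
  for (i in seq_along(x$addends)) {
    cat(sprintf("  %s: %s\n", names(x$addends)[i] %||% "addend",
                format(x$addends[i], big.mark = ",")))
  }
  invisible(x)
}

#' Fraction of the cohort missed by a baseline estimate
#'
#' `100 * (full - baseline) / full`, as a percentage rounded half up to one
#' decimal place.
#'
#' @param baseline_estimate the smaller (e.g. codes + medication) estimate.
#' @param full_estimate the full combined estimate; must be positive and at
#'   least the baseline.
#' @return percentage (1 d.p.).
#' @examples
#' missed_fraction(8048, 13048)  # 38.3
#' @export
missed_fraction <- function(baseline_estimate, full_estimate) {
  if (full_estimate <= 0) stop_config("full estimate must be positive")
  if (baseline_estimate < 0 || baseline_estimate > full_estimate) {
    stop_config("need 0 <= baseline <= full estimate")
  }
  round_half_up(100 * (full_estimate - baseline_estimate) / full_estimate, 1)
}

#' Bundled published inference summary table
#'
#' Convenience loader for the packaged summary of a published 11-database
#' recursive inference run (flagged counts, intersections with the running
#' combined set, and per-database precisions), usable with
#' `run_inference(mode = "summary_replay")`.
#'
#' @return data.frame with columns `database`, `flagged`, `intersection`,
#'   `precision`.
#' @export
inference_summary_fixture <- function() {
  read.csv(system.file("extdata", "inference_summary_11db.csv",
                       package = "cohortcapture"),
           stringsAsFactors = FALSE)
}
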