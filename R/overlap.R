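# Set-overlap machinery: Jaccard similarity, the intersection-from-Jaccard
# identity, pairwise similarity matrices and UpSet-style cardinality counts.

#' Jaccard similarity between two sets
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|}, the size of the intersection
#' divided by the size of the union.
#'
#' @param a,b vectors of element identifiers (duplicates ignored).
#' @return a fraction in \[0, 1\].
#' @examples
#' jaccard(1:3, 2:4)  # 2/4 = 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    stop("jaccard undefined: both sets are empty")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Recover an intersection size from a Jaccard index
#'
#' Inverts the Jaccard definition: given \eqn{|A|}, \eqn{|B|} and
#' \eqn{J = |A \cap B| / |A \cup B|}, the intersection is
#' \eqn{J (|A| + |B|) / (1 + J)}, rounded half away from zero. Exact when
#' `j` is passed unrounded; a 3-d.p. `j` can be off by one patient.
#'
#' @param size_a,size_b set sizes (non-negative).
#' @param j Jaccard index in \[0, 1\].
#' @return integer intersection size.
#' @examples
#' intersection_from_jaccard(8337, 1762, 0.205)  # 1718
#' @export
intersection_from_jaccard <- function(size_a, size_b, j) {
  if (size_a < 0 || size_b < 0) stop_config("set sizes must be non-negative")
  if (j < 0 || j > 1) stop_config("jaccard index must lie in [0, 1]")
  as.integer(round_half_away(j * (size_a + size_b) / (1 + j)))
}

#' Pairwise Jaccard matrix over database membership columns
#'
#' Computes the symmetric database-by-database Jaccard similarity matrix from
#' a binary patient-by-database membership/flag matrix, either over all
#' member patients or restricted to flag-positive patients.
#'
#' @param membership a data.frame or matrix with a `patient_id` column (or
#'   rownames) and one binary column per database.
#' @param subset `"all_patients"` or `"flagged_only"` tag recorded on the
#'   result (columns are already 0/1 flags; the tag documents which flag
#'   definition the caller supplied).
#' @return a matrix of class `jaccard_matrix` with `subset` attribute;
#'   diagonal 1 for non-empty columns. An empty pair of columns yields 0 with
#'   a warning.
#' @export
jaccard_matrix <- function(membership, subset = c("all_patients", "flagged_only")) {
  subset <- match.arg(subset)
  m <- as_membership_matrix(membership)
  if (ncol(m) < 2) stop_config("need at least two database columns")
  k <- ncol(m)
  # cross-products give all pairwise intersection counts at once
  mm <- crossprod(m)
  sizes <- diag(mm)
  if (any(sizes == 0)) {
    warning("empty flagged set(s), Jaccard reported as 0: ",
            paste(colnames(m)[sizes == 0], collapse = ", "))
  }
  out <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (jx in seq_len(k)) {
      un <- sizes[i] + sizes[jx] - mm[i, jx]
      out[i, jx] <- if (un == 0) 0 else mm[i, jx] / un
    }
  }
  diag(out)[sizes > 0] <- 1
  structure(out, subset = subset, class = c("jaccard_matrix", "matrix", "array"))
}

#' Label Jaccard values as high / moderate / low
#'
#' Conventional thresholds for database-comparison work: above 0.75 is high,
#' below 0.35 low, the rest moderate.
#'
#' @param j numeric vector or `jaccard_matrix`.
#' @param high,low category boundaries.
#' @return character vector/matrix of labels.
#' @export
jaccard_category <- function(j, high = 0.75, low = 0.35) {
  out <- ifelse(j > high, "high", ifelse(j < low, "low", "moderate"))
  if (is.matrix(j)) dim(out) <- dim(j)
  out
}

#' Cardinality summary of a membership matrix
#'
#' Counts patients by the number of databases they appear in (exact degree
#' and at-least degree) and by distinct database combination, the counts an
#' UpSet plot displays.
#'
#' @param membership binary patient-by-database table (see [jaccard_matrix()]).
#' @return list of class `cardinality_summary`: `degree` (data.frame with
#'   `k`, `exactly_k`, `at_least_k`), `combinations` (data.frame of non-empty
#'   combination patterns with counts, largest first), `n_patients`.
#' @export
cardinality_summary <- function(membership) {
  m <- as_membership_matrix(membership)
  deg <- rowSums(m)
  kmax <- ncol(m)
  exactly <- vapply(0:kmax, function(k) sum(deg == k), numeric(1))
  at_least <- rev(cumsum(rev(exactly)))
  combo <- apply(m, 1, paste, collapse = "")
  tab <- sort(table(combo), decreasing = TRUE)
  combos <- data.frame(pattern = names(tab), n = as.integer(tab),
                       degree = vapply(strsplit(names(tab), ""), function(p)
                         sum(p == "1"), numeric(1)),
                       stringsAsFactors = FALSE)
  structure(list(
    degree = data.frame(k = 0:kmax, exactly_k = as.integer(exactly),
                        at_least_k = as.integer(at_least)),
    combinations = combos,
    databases = colnames(m),
    n_patients = nrow(m)), class = "cardinality_summary")
}

#' @export
print.cardinality_summary <- function(x, ...) {
  cat(sprintf("Cardinality over %d patients x %d databases\n",
              x$n_patients, length(x$databases)))
  print(x$degree, row.names = FALSE)
  invisible(x)
}

# Coerce a membership data.frame (optionally with patient_id column) or
# matrix to a binary numeric matrix with patient ids as rownames.
as_membership_matrix <- function(membership) {
  if (is.matrix(membership)) {
    m <- membership
  } else {
    df <- as.data.frame(membership)
    id_col <- intersect(c("patient_id", "id"), names(df))
    if (length(id_col)) {
      ids <- as.character(df[[id_col[1]]])
      df <- df[setdiff(names(df), id_col)]
      m <- as.matrix(df)
      rownames(m) <- ids
    } else {
      m <- as.matrix(df)
    }
  }
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("db", seq_len(ncol(m)))
  }
  storage.mode(m) <- "numeric"
  if (any(is.na(m))) m[is.na(m)] <- 0  # missing-as-0 convention
  if (any(!m %in% c(0, 1))) stop_config("membership values must be binary 0/1")
  m
}

# Flag-positive patient-id sets per database column.
membership_sets <- function(membership) {
  m <- as_membership_matrix(membership)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  lapply(setNames(colnames(m), colnames(m)), function(cn) ids[m[, cn] == 1])
}
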