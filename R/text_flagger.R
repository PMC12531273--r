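# Free-text concept flagging: synonym normalization followed by a
# deliberately permissive five-pattern substring search. The patterns are
# prefix-free stems ('olitis', 'rohn', 'octitis', 'flammatory bowel
# disease', 'ibd'), so every colitide matches 'olitis' -- the over-matching
# is a documented property of the screening design, traded for near-perfect
# recall.

ibd_patterns <- c(olitis = "olitis",
                  rohn = "rohn",
                  octitis = "octitis",
                  flammatory_bowel_disease = "flammatory bowel disease",
                  ibd = "ibd")

#' The five normalized disease terms
#'
#' Canonical surface forms that synonym normalization maps onto.
#' @return character vector of length five.
#' @export
normalized_terms <- function() {
  c("Ulcerative Colitis", "Crohn's Disease", "IBD",
    "Inflammatory Bowel Disease", "Proctitis")
}

#' Bundled synonym dictionary
#'
#' A small thesaurus mapping common abbreviations and variant spellings onto
#' the five normalized terms. Licensed meta-thesauri (e.g. UMLS MRCONSO)
#' cannot be redistributed; a user-supplied thesaurus can be loaded with
#' [read_synonym_map()] and used anywhere this default is accepted. The
#' normalized terms map to themselves so normalization is idempotent.
#'
#' @return named character vector: names are surface forms (matched
#'   case-insensitively on word boundaries), values are normalized terms.
#' @export
default_synonym_map <- function() {
  map <- c(
    "uc" = "Ulcerative Colitis",
    "ulcerative colitis" = "Ulcerative Colitis",
    "cd" = "Crohn's Disease",
    "crohns disease" = "Crohn's Disease",
    "crohn's disease" = "Crohn's Disease",
    "crohns" = "Crohn's Disease",
    "crohn's" = "Crohn's Disease",
    "crohn disease" = "Crohn's Disease",
    "ibd-u" = "IBD",
    "ibdu" = "IBD",
    "ibd unclassified" = "IBD",
    "ibd" = "IBD",
    "inflammatory bowel disease" = "Inflammatory Bowel Disease",
    "proctitis" = "Proctitis")
  ok <- map %in% normalized_terms()
  stopifnot(all(ok))
  map
}

#' Load a user-supplied synonym thesaurus
#'
#' Reads a two-column CSV (`surface`, `normalized`); every normalized term
#' must be one of [normalized_terms()].
#'
#' @param path CSV file path.
#' @return named character vector usable with [normalize_terms()].
#' @export
read_synonym_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("surface", "normalized") %in% names(df))) {
    stop_config("thesaurus file needs 'surface' and 'normalized' columns")
  }
  bad <- setdiff(unique(df$normalized), normalized_terms())
  if (length(bad)) {
    stop_config("normalized terms must be restricted to the canonical list; found: ",
                paste(bad, collapse = ", "))
  }
  setNames(df$normalized, tolower(df$surface))
}

#' Normalize disease synonyms in free text
#'
#' Replaces every mapped surface form (matched case-insensitively on word
#' boundaries, longest form first) with its normalized term; unmapped text is
#' left unchanged. Idempotent because the normalized terms are themselves
#' mapped to themselves and matched first.
#'
#' @param text character vector of documents.
#' @param map synonym map (default [default_synonym_map()]).
#' @return character vector, same length as `text`.
#' @examples
#' normalize_terms("known UC, stable", c("uc" = "Ulcerative Colitis"))
#' @export
normalize_terms <- function(text, map = default_synonym_map()) {
  if (length(map) == 0) return(text)
  names(map) <- tolower(names(map))
  # include identity entries for the replacement values so a second pass
  # matches the full normalized form before any embedded synonym
  idmap <- setNames(unique(map), tolower(unique(map)))
  map <- c(map, idmap[setdiff(names(idmap), names(map))])
  forms <- names(map)[order(-nchar(names(map)))]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", forms)
  pattern <- paste0("(?i)\\b(", paste0(esc, collapse = "|"), ")\\b")
  vapply(text, function(t) {
    if (is.na(t) || !nzchar(t)) return(t %||% "")
    m <- gregexpr(pattern, t, perl = TRUE)[[1]]
    if (m[1] == -1) return(t)
    regmatches(t, list(m)) <- list(unname(map[tolower(regmatches(t, list(m))[[1]])]))
    t
  }, character(1), USE.NAMES = FALSE)
}

#' Flag a document as suggestive of the disease
#'
#' Lowercases the text and tests the five case-insensitive substring
#' patterns. The document is flagged iff at least one pattern matches.
#'
#' @param text a single document string.
#' @param require_ibd_boundary if TRUE the short 'ibd' stem must occur on
#'   word boundaries (so e.g. "antibody" never trips it); default FALSE,
#'   matching the plain-substring screening design.
#' @return list of class `flag_result`: `flagged`, `matched_patterns`
#'   (names of matching patterns), `matched_spans` (data.frame of pattern,
#'   `start`, `end`; 0-based, half-open).
#' @examples
#' flag_document("Pan-colitis seen at 30 cm.")$matched_patterns
#' @export
flag_document <- function(text, require_ibd_boundary = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  low <- tolower(text)
  spans <- list()
  for (nm in names(ibd_patterns)) {
    pat <- ibd_patterns[[nm]]
    m <- if (nm == "ibd" && require_ibd_boundary) {
      gregexpr("\\bibd\\b", low, perl = TRUE)[[1]]
    } else {
      gregexpr(pat, low, fixed = TRUE)[[1]]
    }
    if (m[1] != -1) {
      spans[[nm]] <- data.frame(pattern = nm, start = as.integer(m) - 1L,
                                end = as.integer(m) - 1L + attr(m, "match.length"),
                                stringsAsFactors = FALSE)
    }
  }
  matched <- names(spans)
  structure(list(flagged = length(matched) > 0,
                 matched_patterns = matched,
                 matched_spans = if (length(spans)) do.call(rbind, spans)
                                 else data.frame(pattern = character(),
                                                 start = integer(),
                                                 end = integer())),
            class = "flag_result")
}

#' Aggregate document flags to patient level
#'
#' A patient is flagged for a document type iff at least one of their
#' documents of that type is flagged; patients with no documents of that type
#' get 0 (missing-as-0 convention).
#'
#' Documents are synonym-normalized before matching (the
#' normalize-then-match design), so abbreviations like "UC" are caught.
#'
#' @param documents data.frame with `patient_id`, `doc_type`, `text` (as
#'   produced by [generate_documents()] or [read_documents_jsonl()]).
#' @param doc_type one of `"letter"`, `"endoscopy"`, `"histopathology"`.
#' @param patient_ids optional universe of patients for the output (defaults
#'   to the patients present in `documents`).
#' @param synonym_map thesaurus applied by [normalize_terms()] before
#'   matching; NULL skips normalization.
#' @param ... passed to [flag_document()].
#' @return data.frame with `patient_id` and binary `flag`.
#' @export
flag_patients <- function(documents, doc_type, patient_ids = NULL,
                          synonym_map = default_synonym_map(), ...) {
  allowed <- c("letter", "endoscopy", "histopathology")
  if (!doc_type %in% allowed) {
    stop_config("unknown doc_type '", doc_type, "'; expected one of: ",
                paste(allowed, collapse = ", "))
  }
  docs <- documents[documents$doc_type == doc_type, , drop = FALSE]
  txt <- if (is.null(synonym_map)) docs$text else
    normalize_terms(docs$text, synonym_map)
  doc_flag <- vapply(txt, function(t) flag_document(t, ...)$flagged,
                     logical(1), USE.NAMES = FALSE)
  flagged_ids <- unique(as.character(docs$patient_id[doc_flag]))
  ids <- patient_ids %||% unique(as.character(documents$patient_id))
  data.frame(patient_id = ids,
             flag = as.integer(ids %in% flagged_ids),
             stringsAsFactors = FALSE)
}

#' Read documents from a JSON-lines file
#'
#' One JSON object per line with fields `patient_id`, `doc_type`, `text`.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_documents_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, jsonlite::fromJSON)
  data.frame(patient_id = vapply(rows, `[[`, "", "patient_id"),
             doc_type = vapply(rows, `[[`, "", "doc_type"),
             text = vapply(rows, `[[`, "", "text"),
             stringsAsFactors = FALSE)
}

#' Write documents to a JSON-lines file
#'
#' @param documents data.frame with `patient_id`, `doc_type`, `text`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_documents_jsonl <- function(documents, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(documents))) {
    writeLines(jsonlite::toJSON(list(patient_id = documents$patient_id[i],
                                     doc_type = documents$doc_type[i],
                                     text = documents$text[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
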