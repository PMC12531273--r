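# Shared numeric conventions and small helpers.

#' Round half away from zero
#'
#' Integer rounding used for all patient counts (incremental true positives,
#' intersection back-calculation). Unlike [base::round()], which rounds half
#' to even, halves move away from zero, matching how the printed tables were
#' produced.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Round half up to a fixed number of decimals
#'
#' Decimal rounding used when printing Jaccard indices (3 d.p.) and
#' percentages (1 d.p.).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

stop_config <- function(...) {
  stop(structure(class = c("cohortcapture_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# area under the ROC curve via pROC, with fixed direction so that higher
# scores mean the positive class
auc_value <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

# short content hash (FNV-1a over the serialized object) used to stamp
# pipeline reports with the configuration that produced them
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # 31-bit polynomial rolling hash kept in double precision
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
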