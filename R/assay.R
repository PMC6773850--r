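# Small defined assay formulas: specific killing, alanine/serine peptide
# scans, background subtraction and fold-change normalization.

#' Percent antigen-specific killing
#'
#' 100 - (ratio_with / ratio_without) * 100, where each ratio is the
#' relevant/irrelevant target-cell ratio measured with and without effector
#' T cells.  Values below zero are possible (e.g. outgrowth of relevant
#' targets) and are returned as-is with a `negative` flag.
#'
#' @param ratio_with relevant/irrelevant ratio in the presence of T cells
#'   (>= 0).
#' @param ratio_without relevant/irrelevant ratio with no T cells (> 0).
#' @return list with `percent` and `negative`.
#' @export
specific_killing <- function(ratio_with, ratio_without) {
  if (!is.finite(ratio_without) || ratio_without <= 0) {
    abort("ratio_without must be a positive number")
  }
  if (!is.finite(ratio_with) || ratio_with < 0) {
    abort("ratio_with must be non-negative")
  }
  pct <- 100 - (ratio_with / ratio_without) * 100
  list(percent = pct, negative = pct < 0)
}

#' Alanine/serine scan of a peptide
#'
#' One variant per position: the native residue is replaced with alanine,
#' except where the native residue already is alanine, which is replaced
#' with serine.  Output order follows position order.
#'
#' @param peptide amino-acid string of length 8-11.
#' @return character vector of variants, one per position.
#' @export
alanine_scan <- function(peptide) {
  n <- nchar(peptide)
  if (n < 8L || n > 11L) abort("peptide length %d outside the supported 8-11", n)
  if (!valid_aa(peptide)) abort("peptide '%s' contains non-amino-acid characters", peptide)
  chars <- strsplit(peptide, "")[[1]]
  vapply(seq_len(n), function(i) {
    v <- chars
    v[i] <- if (chars[i] == "A") "S" else "A"
    paste(v, collapse = "")
  }, character(1))
}

#' Background-subtracted response
#'
#' Cognate-stimulation response minus irrelevant-peptide response, floored
#' at zero by default (figure-legend convention); the unfloored value is
#' always retained.
#'
#' @param cognate response to the cognate peptide.
#' @param irrelevant response to the irrelevant peptide.
#' @param floor floor the net value at zero (default TRUE).
#' @return list with `net` (floored if requested) and `raw`.
#' @export
net_response <- function(cognate, irrelevant, floor = TRUE) {
  raw <- cognate - irrelevant
  list(net = if (floor) max(0, raw) else raw, raw = raw)
}

#' Fold change relative to a reference
#'
#' @param value measured value.
#' @param reference reference value (> 0).
#' @return value / reference.
#' @export
fold_change <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    abort("reference must be positive")
  }
  value / reference
}
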