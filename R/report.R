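# Enrichment report IO: one TSV row per (chain, position, amino acid)
# tested, stable sort, round-trippable.

REPORT_COLUMNS <- c("chain", "position", "amino_acid", "a", "b", "c", "d",
                    "odds_ratio", "per_donor_p", "cmh_statistic", "p",
                    "p_adjusted", "direction", "tested", "family_size",
                    "category")

#' Write an enrichment report
#'
#' @param results an `enrichment_result` table from [run_enrichment()].
#' @param path output TSV path.
#' @param annotation optional structural annotation (chain, position,
#'   category) merged into a `category` column.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(results, path, annotation = NULL) {
  dt <- data.table::as.data.table(results)
  for (col in setdiff(REPORT_COLUMNS, c(names(dt), "category"))) {
    dt[, (col) := NA]
  }
  if (!"category" %in% names(dt)) {
    if (!is.null(annotation)) {
      ann <- data.table::as.data.table(annotation)[, .(chain, position, category)]
      dt <- merge(dt, ann, by = c("chain", "position"), all.x = TRUE)
    } else {
      dt[, category := NA_integer_]
    }
  }
  dt <- dt[, REPORT_COLUMNS, with = FALSE]
  data.table::setorder(dt, chain, position, amino_acid)
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read an enrichment report
#'
#' @param path report TSV path.
#' @return data.table of class `enrichment_result`.
#' @export
read_enrichment_report <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = "per_donor_p"))
  missing <- setdiff(setdiff(REPORT_COLUMNS, "category"), names(dt))
  if (length(missing)) {
    abort("report lacks column(s): %s", paste(missing, collapse = ", "))
  }
  data.table::setorder(dt, chain, position, amino_acid)
  data.table::setattr(dt, "class", c("enrichment_result", class(dt)))
  dt[]
}
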