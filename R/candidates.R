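# Candidate framework residues: the curated 14-residue table and the
# statistical selection that intersects enrichment results with the
# packaged structural-category annotation.
#
# Structural categories: 1 solvent exposed, 2 hydrophobic core,
# 3 Valpha-Vbeta interface, 4 V-C interface.  The categories come from 3D
# modeling in the original study; here they ship as a static, user-
# replaceable annotation table.

#' Load the curated candidate-residue table
#'
#' The packaged 14-residue set with dominant and weak residue identities
#' and structural category per position.  Twelve of the entries are the
#' residues named in the published functional analyses (alpha 5, 19, 20,
#' 24, 39, 50, 55, 86, 96; beta 9, 10, 43); the remaining two (beta 18 and
#' beta 88) are synthetic placeholders for figure-only entries, which is
#' why the file carries a `_synthetic` suffix.
#'
#' @param path optional path to a replacement table with the same columns
#'   (chain, position, dominant_aa, weak_aa, category, evidence).
#' @return data.table of class `candidate_set` with 14 rows (packaged
#'   table) spanning all four structural categories.
#' @export
load_curated_candidates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "candidate_residues_synthetic.tsv",
                        package = "tcrforge", mustWork = TRUE)
  }
  if (!file.exists(path)) abort("candidate table not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chain", "position", "dominant_aa", "weak_aa", "category",
            "evidence")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    abort("candidate table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(!dt$category %in% 1:4)) abort("categories must lie in 1-4")
  if (any(dt$dominant_aa == dt$weak_aa)) {
    abort("dominant and weak identities must differ at every candidate position")
  }
  if (anyDuplicated(dt, by = c("chain", "position"))) {
    abort("duplicate (chain, position) entries in the candidate table")
  }
  data.table::setorder(dt, chain, position)
  data.table::setattr(dt, "class", c("candidate_set", class(dt)))
  dt[]
}

#' Load the packaged structural-category annotation
#'
#' Per (chain, IMGT position) category codes derived from the curated
#' candidate table; user-replaceable.
#'
#' @param path optional replacement TSV (chain, position, category).
#' @return data.table with columns chain, position, category.
#' @export
load_structural_annotation <- function(path = NULL) {
  if (is.null(path)) {
    tab <- load_curated_candidates()
    return(tab[, .(chain, position, category)])
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("chain", "position", "category") %in% names(dt))) {
    abort("annotation needs columns chain, position, category")
  }
  dt[, .(chain, position, category)]
}

#' Select candidate residues from enrichment results
#'
#' Keeps framework (position, amino acid) pairs that are significant at
#' `alpha_level` (adjusted p in ngs mode, raw p in sanger mode),
#' dominant-enriched, and annotated with a structural category in
#' `categories`.  The weak-arm identity reported for each candidate is the
#' modal weak-arm residue at that position.  Ties order by smaller p, then
#' larger |log odds ratio|, then lower position.
#'
#' @param results an `enrichment_result` table.
#' @param alpha_level significance threshold in (0, 1]; 0 yields no
#'   candidates.
#' @param categories structural categories to admit (subset of 1:4).
#' @param annotation annotation table, default the packaged one.
#' @return data.table of class `candidate_set` (possibly empty) with
#'   columns chain, position, dominant_aa, weak_aa, category, evidence, p.
#' @export
select_candidates <- function(results, alpha_level = 0.05, categories = 1:4,
                              annotation = load_structural_annotation()) {
  dt <- data.table::as.data.table(results)
  ann <- data.table::as.data.table(annotation)
  if (!nrow(ann)) {
    warn("no annotated positions; returning an empty candidate list")
    return(empty_candidates())
  }
  use_p <- if (all(is.na(dt$family_size %||% NA))) dt$p else dt$p_adjusted
  dt[, p_sel := use_p]
  hits <- dt[tested & !is.na(p_sel) & p_sel < alpha_level &
               direction == "dominant-enriched"]
  hits <- merge(hits, ann[category %in% categories],
                by = c("chain", "position"))
  if (!nrow(hits)) return(empty_candidates())

  # Modal weak-arm residue at each selected position.
  weak_mode <- dt[, .SD[which.max(c)], by = .(chain, position)][
    , .(chain, position, weak_aa = amino_acid)]
  hits <- merge(hits, weak_mode, by = c("chain", "position"))
  hits[weak_aa == amino_acid, weak_aa := NA_character_]
  out <- hits[, .(chain, position, dominant_aa = amino_acid, weak_aa,
                  category, evidence = "enrichment", p = p_sel,
                  odds_ratio)]
  out[, effect_rank := -abs(log(odds_ratio))]
  data.table::setorder(out, p, effect_rank, position)
  out[, c("odds_ratio", "effect_rank") := NULL]
  data.table::setattr(out, "class", c("candidate_set", class(out)))
  out[]
}

empty_candidates <- function() {
  out <- data.table::data.table(
    chain = character(0), position = integer(0),
    dominant_aa = character(0), weak_aa = character(0),
    category = integer(0), evidence = character(0), p = numeric(0))
  data.table::setattr(out, "class", c("candidate_set", class(out)))
  out[]
}

#' Write a candidate table
#' @param candidates a `candidate_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  data.table::fwrite(data.table::as.data.table(candidates), path,
                     sep = "\t", na = "NA")
  invisible(path)
}
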