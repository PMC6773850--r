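# Template-based IMGT numbering of TCR V domains.
#
# Clonotypes arrive with a V-gene call, so numbering is a germline lookup
# plus a CDR3 splice rather than an ab initio alignment: V-segment residues
# sit at their gapped coordinates (1-104) and the CDR3 fills 105-117 from
# both ends toward the middle (the standard IMGT center-out rule).

#' Number a TCR V domain
#'
#' Places the germline V-segment residues at their IMGT coordinates and
#' splices the CDR3 amino-acid string into positions 105-117 center-out:
#' for a CDR3 of length L, ceiling(L/2) residues run up from 105 and
#' floor(L/2) run down from 117, leaving central gaps for short loops.
#' CDR3s longer than 13 need IMGT insertion codes (111.1 style) and are
#' rejected.
#'
#' @param gene a `germline_gene`.
#' @param cdr3_aa CDR3 amino-acid string (length 5-13, exclusive of the
#'   2nd-CYS 104 and J-anchor 118).
#' @param fw_variants optional named character vector of framework residue
#'   overrides, names = IMGT positions (e.g. `c("96" = "L")`).
#' @return an object of class `numbered_domain` with fields `chain`,
#'   `residues` (named character vector, names = occupied IMGT positions),
#'   `regions`, `source_gene` and `anchor_ok`.
#' @export
number_v_domain <- function(gene, cdr3_aa, fw_variants = NULL) {
  if (!inherits(gene, "germline_gene")) abort("`gene` must be a germline_gene")
  L <- nchar(cdr3_aa)
  if (L < 5L || L > 25L) abort("CDR3 length %d outside the supported 5-25", L)
  if (L > 13L) {
    abort("CDR3 of length %d requires IMGT insertion codes, which are not supported", L)
  }
  if (!valid_aa(cdr3_aa)) abort("CDR3 '%s' contains non-amino-acid characters", cdr3_aa)

  res <- gene_residues(gene)
  pos <- which(!is.na(res))
  residues <- setNames(res[pos], pos)

  cdr3_chars <- strsplit(cdr3_aa, "")[[1]]
  n_up <- ceiling(L / 2)
  n_down <- L - n_up
  cdr3_pos <- c(seq(105L, length.out = n_up),
                if (n_down > 0) seq(117L, by = -1L, length.out = n_down))
  cdr3_res <- c(cdr3_chars[seq_len(n_up)],
                if (n_down > 0) rev(cdr3_chars[(n_up + 1):L]))
  residues <- c(residues, setNames(cdr3_res, cdr3_pos))
  residues <- residues[order(as.integer(names(residues)))]

  if (!is.null(fw_variants) && length(fw_variants)) {
    vp <- names(fw_variants)
    missing <- setdiff(vp, names(residues))
    if (length(missing)) {
      abort("framework variant at unoccupied position(s): %s",
            paste(missing, collapse = ", "))
    }
    if (any(!is_framework_position(as.integer(vp)))) {
      abort("framework variants may only touch FR1-FR3 positions")
    }
    residues[vp] <- unname(fw_variants)
  }

  anchor_ok <- all(vapply(names(IMGT_ANCHORS), function(p) {
    r <- residues[p]
    !is.na(r) && unname(r) == IMGT_ANCHORS[[p]]
  }, logical(1)))
  if (!anchor_ok) {
    warn("domain from %s: conserved anchor residue(s) missing (C23/W41/C104)",
         gene$name)
  }

  structure(list(
    chain = gene$chain,
    residues = residues,
    regions = setNames(imgt_region(as.integer(names(residues))), names(residues)),
    source_gene = gene$name,
    anchor_ok = anchor_ok
  ), class = "numbered_domain")
}

#' @export
print.numbered_domain <- function(x, ...) {
  cat(sprintf("<numbered_domain> %s chain from %s, %d occupied positions\n",
              x$chain, x$source_gene, length(x$residues)))
  invisible(x)
}

#' Residue at an IMGT position
#'
#' @param domain a `numbered_domain`.
#' @param position IMGT position (1-128).
#' @return single amino-acid letter, or `NA_character_` for a gap position.
#' @export
residue_at <- function(domain, position) {
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1 || position > IMGT_MAX_POSITION) {
    abort("position must be a single integer in 1-%d", IMGT_MAX_POSITION)
  }
  r <- domain$residues[as.character(as.integer(position))]
  if (is.na(r)) NA_character_ else unname(r)
}

#' Build the framework position mask for a chain
#'
#' The union of occupied FR1-FR3 positions across the genes of the chain,
#' sorted ascending.  FR4 (J-encoded) and all CDR positions are excluded.
#' Under the packaged reference convention each chain yields 77 positions.
#'
#' @param germline_set a `germline_set`.
#' @param chain "alpha" or "beta".
#' @return object of class `framework_mask`: an integer vector of IMGT
#'   positions with attribute `chain`.
#' @export
build_framework_mask <- function(germline_set, chain = c("alpha", "beta")) {
  chain <- match.arg(chain)
  genes <- genes_of_chain(germline_set, chain)
  if (!length(genes)) abort("no %s-chain genes in the germline set", chain)
  occ <- sort(unique(unlist(lapply(genes, occupied_positions))))
  mask <- occ[is_framework_position(occ)]
  structure(as.integer(mask), chain = chain, class = "framework_mask")
}

#' @export
print.framework_mask <- function(x, ...) {
  cat(sprintf("<framework_mask> %s chain, %d positions\n",
              attr(x, "chain"), length(x)))
  invisible(x)
}

#' Export a framework mask as a two-column table
#'
#' @param mask a `framework_mask`.
#' @param path output TSV path (columns: chain, imgt_position).
#' @return `path`, invisibly.
#' @export
write_framework_mask <- function(mask, path) {
  dt <- data.table::data.table(chain = attr(mask, "chain"),
                               imgt_position = as.integer(mask))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
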