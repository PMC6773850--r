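# Clonotype tables and the repertoire library container.
#
# The table dialect is a documented superset of Decombinator-style output:
# UTF-8 TSV, "#"-prefixed comment lines ignored, required columns
# donor_id / phenotype / chain / v_gene / j_gene / cdr3_aa, optional
# abundance (default 1) and fw_variants (comma-separated "pos:AA" framework
# residue overrides relative to the germline of v_gene).  Unknown columns
# are preserved as opaque annotations.

CLONOTYPE_REQUIRED <- c("donor_id", "phenotype", "chain", "v_gene",
                        "j_gene", "cdr3_aa")
CLONOTYPE_KNOWN <- c(CLONOTYPE_REQUIRED, "abundance", "fw_variants")
PHENOTYPES <- c("dominant", "weak")
CHAINS <- c("alpha", "beta")

#' Construct a repertoire library from a clonotype table
#'
#' Validates field values, strips allele suffixes from V-gene names, merges
#' duplicated clonotype rows (same donor, phenotype, chain, V gene, J gene
#' and CDR3) by summing abundances, and wraps the result.
#'
#' @param clonotypes data.frame with the columns listed above.
#' @return an object of class `repertoire_library`.
#' @export
repertoire_library <- function(clonotypes) {
  dt <- data.table::as.data.table(clonotypes)
  missing <- setdiff(CLONOTYPE_REQUIRED, names(dt))
  if (length(missing)) {
    abort("clonotype table lacks required column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (!"abundance" %in% names(dt)) dt[, abundance := 1L]
  if (!"fw_variants" %in% names(dt)) dt[, fw_variants := ""]
  dt[is.na(fw_variants), fw_variants := ""]

  if (nrow(dt)) {
    check_rows(dt)
    dt[, v_gene := strip_allele(v_gene)]
    key <- c("donor_id", "phenotype", "chain", "v_gene", "j_gene",
             "cdr3_aa", "fw_variants")
    if (anyDuplicated(dt, by = key)) {
      n_before <- nrow(dt)
      extra <- setdiff(names(dt), c(key, "abundance"))
      dt <- dt[, c(list(abundance = sum(abundance)),
                   lapply(.SD, data.table::first)),
               by = key, .SDcols = extra]
      warn("%d duplicated clonotype row(s) merged by summing abundance",
           n_before - nrow(dt))
    }
  }
  data.table::setcolorder(
    dt, c(intersect(CLONOTYPE_KNOWN, names(dt)),
          setdiff(names(dt), CLONOTYPE_KNOWN)))
  data.table::setorder(dt, donor_id, phenotype, chain, v_gene, j_gene, cdr3_aa)
  structure(list(
    clonotypes = dt[],
    donors = sort(unique(dt$donor_id)),
    empty = nrow(dt) == 0L
  ), class = "repertoire_library")
}

check_rows <- function(dt) {
  bad <- which(!dt$phenotype %in% PHENOTYPES)
  if (length(bad)) {
    abort("row %d: phenotype '%s' is not one of dominant/weak",
          bad[1], dt$phenotype[bad[1]])
  }
  bad <- which(!dt$chain %in% CHAINS)
  if (length(bad)) {
    abort("row %d: chain '%s' is not one of alpha/beta", bad[1], dt$chain[bad[1]])
  }
  bad <- which(!grepl(V_GENE_PATTERN, dt$v_gene))
  if (length(bad)) {
    abort("row %d: v_gene '%s' does not match IMGT nomenclature",
          bad[1], dt$v_gene[bad[1]])
  }
  bad <- which(!vapply(dt$cdr3_aa, valid_aa, logical(1)))
  if (length(bad)) {
    abort("row %d: cdr3_aa '%s' contains non-amino-acid characters",
          bad[1], dt$cdr3_aa[bad[1]])
  }
  if (any(!is.finite(dt$abundance) | dt$abundance <= 0)) {
    abort("abundance must be a positive count")
  }
  mismatch <- which((dt$chain == "alpha") != startsWith(dt$v_gene, "TRAV"))
  if (length(mismatch)) {
    abort("row %d: chain '%s' inconsistent with v_gene '%s'",
          mismatch[1], dt$chain[mismatch[1]], dt$v_gene[mismatch[1]])
  }
  invisible(TRUE)
}

#' @export
print.repertoire_library <- function(x, ...) {
  dt <- x$clonotypes
  cat(sprintf(
    "<repertoire_library> %d clonotypes, %d donor(s)%s\n",
    nrow(dt), length(x$donors), if (x$empty) " [empty]" else ""))
  if (nrow(dt)) {
    tab <- dt[, .N, by = .(phenotype, chain)]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-8s %-5s %d\n", tab$phenotype[i], tab$chain[i], tab$N[i]))
    }
  }
  invisible(x)
}

#' Read a clonotype TSV into a repertoire library
#'
#' @param path path to a tab-separated clonotype table with a header row.
#' @return a `repertoire_library`; an empty (header-only) file yields an
#'   empty library with `$empty = TRUE`.
#' @export
read_clonotype_table <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "cdr3_aa"))
  # fread drops "#" comment lines only when asked per-line; filter defensively
  if (nrow(dt) && is.character(dt[[1]])) {
    dt <- dt[!startsWith(dt[[1]], "#")]
  }
  repertoire_library(dt)
}

#' Write a repertoire library as a clonotype TSV
#'
#' @param library a `repertoire_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(library, path) {
  data.table::fwrite(library$clonotypes, path, sep = "\t")
  invisible(path)
}

# Parse a fw_variants annotation ("96:L,100:S") into a named character
# vector (names = positions).  Empty string -> NULL.
parse_fw_variants <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L)) abort("malformed fw_variants entry '%s'", x)
  setNames(vapply(kv, `[`, character(1), 2L),
           vapply(kv, `[`, character(1), 1L))
}

format_fw_variants <- function(v) {
  if (is.null(v) || !length(v)) return("")
  paste(sprintf("%s:%s", names(v), unname(v)), collapse = ",")
}
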