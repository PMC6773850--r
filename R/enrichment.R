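# Positional amino-acid enrichment between dominant and weak libraries.
#
# For every framework position and amino acid A, a 2x2 table counts A
# versus not-A clonotypes in the dominant versus weak arm.  Per-donor
# tables get a two-sided Fisher exact test (point-probability ordering on
# the hypergeometric distribution); donors are combined with the
# Cochran-Mantel-Haenszel score test (no continuity correction) and the
# family is controlled with Bonferroni.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The p-value is the sum of hypergeometric point probabilities not larger
#' than that of the observed table (classical "as or more extreme"
#' ordering), with a small relative tolerance on the comparison to avoid
#' floating-point artifacts.  A table with a zero margin is degenerate and
#' returns p = 1.
#'
#' @param a,b,c,d cell counts: a = (A, dominant), b = (not-A, dominant),
#'   c = (A, weak), d = (not-A, weak).
#' @param rel_tol relative tolerance for the point-probability comparison.
#' @return list with elements `p` and `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, rel_tol = 1e-12) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    return(list(p = 1, degenerate = TRUE))
  }
  ks <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- probs[ks == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
  list(p = p, degenerate = FALSE)
}

#' Odds ratio of a 2x2 table
#'
#' (a*d)/(b*c), with the Haldane-Anscombe +0.5 continuity correction applied
#' to every cell only when some cell is zero.
#'
#' @inheritParams fisher_exact_2x2
#' @return positive finite odds ratio.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Cochran-Mantel-Haenszel test across donor strata
#'
#' Score test for a common association across stratified 2x2 tables:
#' statistic = (sum_k (a_k - E_k))^2 / sum_k Var_k with the hypergeometric
#' mean and variance per stratum and no continuity correction; p from the
#' chi-square distribution with 1 df.  With a single stratum the statistic
#' equals the Mantel-Haenszel (score) chi-square of that table.  Strata with
#' a zero margin carry no information and are skipped; if every stratum is
#' degenerate the result is p = 1 with `degenerate = TRUE`.
#'
#' @param tables data.frame (or list of such rows) with columns a, b, c, d;
#'   one row per stratum.
#' @return list with `statistic`, `p`, `degenerate`.
#' @export
cmh_test <- function(tables) {
  tab <- data.table::as.data.table(tables)
  if (!nrow(tab)) abort("at least one stratum is required")
  a <- as.double(tab$a); b <- as.double(tab$b)
  c <- as.double(tab$c); d <- as.double(tab$d)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  ok <- pmin(r1, r2, c1, c2) > 0 & n > 1
  if (!any(ok)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  }
  e <- (r1 * c1 / n)[ok]
  v <- (r1 * r2 * c1 * c2 / (n^2 * (n - 1)))[ok]
  stat <- sum(a[ok] - e)^2 / sum(v)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Bonferroni adjustment for a stated family size
#'
#' @param p numeric vector of raw p-values.
#' @param family_size number of tests in the family (>= length(p)).
#' @return adjusted p-values, min(1, family_size * p), order-preserving.
#' @export
bonferroni <- function(p, family_size) {
  if (family_size < length(p)) {
    abort("family_size (%d) smaller than the number of p-values (%d)",
          family_size, length(p))
  }
  pmin(1, p * family_size)
}

#' Tally amino-acid counts per donor, position and phenotype
#'
#' Numbers every clonotype against its germline V segment (framework
#' variant overrides applied), then counts each distinct clonotype once per
#' (donor, chain, masked position, amino acid, phenotype).  Gap positions
#' contribute nothing.  Abundance weighting is off by default because the
#' study counts distinct clonotypes.
#'
#' @param library a `repertoire_library`.
#' @param germline_set a `germline_set` resolving every v_gene.
#' @param masks optional named list of `framework_mask` per chain.
#' @param abundance_weight if TRUE weight clonotypes by their abundance.
#' @return data.table with columns donor_id, chain, position, amino_acid,
#'   n_dominant, n_weak.
#' @export
tally_position_aa <- function(library, germline_set, masks = NULL,
                              abundance_weight = FALSE) {
  dt <- library$clonotypes
  if (!nrow(dt)) abort("cannot tally an empty library")
  unresolved <- setdiff(unique(dt$v_gene), names(germline_set))
  if (length(unresolved)) {
    abort("v_gene(s) not in the germline set: %s",
          paste(unresolved, collapse = ", "))
  }
  if (is.null(masks)) {
    masks <- lapply(setNames(CHAINS, CHAINS), function(ch) {
      if (ch %in% dt$chain) build_framework_mask(germline_set, ch) else integer(0)
    })
  }

  # Residue lookup per gene restricted to the chain mask.
  gene_tab <- data.table::rbindlist(lapply(unique(dt$v_gene), function(g) {
    gene <- germline_set[[g]]
    mask <- as.integer(masks[[gene$chain]])
    res <- gene_residues(gene)[mask]
    keep <- !is.na(res)
    data.table::data.table(v_gene = g, chain = gene$chain,
                           position = mask[keep], amino_acid = res[keep])
  }))

  # Clonotypes collapse to (donor, phenotype, chain, gene, variant) groups;
  # the residue profile is identical within a group.
  grp <- dt[, .(w = if (abundance_weight) sum(abundance) else .N),
            by = .(donor_id, phenotype, chain, v_gene, fw_variants)]
  expanded <- merge(grp, gene_tab, by = c("chain", "v_gene"),
                    allow.cartesian = TRUE)
  has_var <- which(nzchar(expanded$fw_variants))
  if (length(has_var)) {
    uv <- unique(expanded$fw_variants[has_var])
    for (vstr in uv) {
      v <- parse_fw_variants(vstr)
      sel <- expanded$fw_variants == vstr &
        expanded$position %in% as.integer(names(v))
      if (any(sel)) {
        expanded$amino_acid[sel] <-
          unname(v[as.character(expanded$position[sel])])
      }
    }
  }
  counts <- expanded[, .(n = sum(w)),
                     by = .(donor_id, phenotype, chain, position, amino_acid)]
  out <- data.table::dcast(counts, donor_id + chain + position + amino_acid ~
                             phenotype, value.var = "n", fill = 0)
  for (col in PHENOTYPES) if (!col %in% names(out)) out[, (col) := 0]
  data.table::setnames(out, c("dominant", "weak"), c("n_dominant", "n_weak"))
  data.table::setorder(out, donor_id, chain, position, amino_acid)
  out[]
}

#' Run the positional-enrichment analysis
#'
#' Mode "sanger" pools donors into one 2x2 table per (chain, position,
#' amino acid) and applies Fisher's exact test without multiplicity
#' correction.  Mode "ngs" computes per-donor Fisher tests, the CMH test
#' across donors and a Bonferroni adjustment of the CMH p over the tested
#' family, counted per chain.  Pairs whose pooled amino-acid count is below
#' `min_count` are reported but flagged untested and excluded from the
#' family.
#'
#' @param library a `repertoire_library` containing both phenotypes.
#' @param germline_set a `germline_set`.
#' @param mode "sanger" or "ngs".
#' @param min_count minimum pooled count of the amino acid for testing.
#' @param abundance_weight passed to [tally_position_aa()].
#' @return data.table of class `enrichment_result`, sorted by chain,
#'   position, amino acid; columns include pooled counts a/b/c/d, the
#'   pooled odds ratio, per-donor p-values (packed "donor=p" string), the
#'   test p-value, `p_adjusted`, `direction`, `tested` and `family_size`.
#' @export
run_enrichment <- function(library, germline_set,
                           mode = c("ngs", "sanger"),
                           min_count = 5L, abundance_weight = FALSE) {
  mode <- match.arg(mode)
  dt <- library$clonotypes
  if (!nrow(dt)) abort("cannot analyse an empty library")
  if (length(unique(dt$phenotype)) < 2L) {
    abort("the library must contain both dominant and weak clonotypes")
  }
  tallies <- tally_position_aa(library, germline_set,
                               abundance_weight = abundance_weight)
  # Occupied-position totals per donor and phenotype give the not-A cells.
  totals <- tallies[, .(tot_dom = sum(n_dominant), tot_weak = sum(n_weak)),
                    by = .(donor_id, chain, position)]
  per <- merge(tallies, totals, by = c("donor_id", "chain", "position"))
  per[, `:=`(a = n_dominant, b = tot_dom - n_dominant,
             c = n_weak, d = tot_weak - n_weak)]

  pooled <- per[, .(a = sum(a), b = sum(b), c = sum(c), d = sum(d)),
                by = .(chain, position, amino_acid)]
  pooled[, tested := (a + c) >= min_count & (b + d) > 0 &
           (a + b) > 0 & (c + d) > 0]
  pooled[, odds_ratio := mapply(odds_ratio_2x2, a, b, c, d)]
  pooled[, direction := data.table::fcase(
    !tested, "none",
    odds_ratio > 1, "dominant-enriched",
    odds_ratio < 1, "weak-enriched",
    default = "none")]

  if (mode == "sanger") {
    fr <- mapply(function(a, b, c, d) fisher_exact_2x2(a, b, c, d)$p,
                 pooled$a, pooled$b, pooled$c, pooled$d)
    pooled[, `:=`(p = fr, per_donor_p = NA_character_,
                  cmh_statistic = NA_real_, p_adjusted = fr,
                  family_size = NA_integer_)]
  } else {
    key <- c("chain", "position", "amino_acid")
    donor_p <- per[, .(per_donor_p = paste(
      sprintf("%s=%.6g", donor_id,
              mapply(function(a, b, c, d) fisher_exact_2x2(a, b, c, d)$p,
                     a, b, c, d)), collapse = ",")), by = key]
    cmh <- per[, {
      r <- cmh_test(.SD[, .(a, b, c, d)])
      .(cmh_statistic = r$statistic, p = r$p)
    }, by = key]
    pooled <- Reduce(function(x, y) merge(x, y, by = key),
                     list(pooled, donor_p, cmh))
    pooled[, family_size := sum(tested), by = chain]
    pooled[, p_adjusted := NA_real_]
    pooled[tested == TRUE, p_adjusted := bonferroni(p, .N), by = chain]
  }
  data.table::setorder(pooled, chain, position, amino_acid)
  data.table::setattr(pooled, "class",
                      c("enrichment_result", class(pooled)))
  data.table::setattr(pooled, "mode", mode)
  pooled[]
}

#' Compare V-gene usage between phenotypes
#'
#' Computes clonotype-weighted per-donor gene frequencies within each chain
#' and phenotype and tests each gene with a two-sided unpaired Student
#' (equal-variance) t-test on the per-donor frequencies; Welch by flag.
#' With fewer than 2 donors the frequencies are returned and the test is
#' skipped.
#'
#' @param library a `repertoire_library`.
#' @param var_equal use the pooled-variance Student test (default TRUE).
#' @return data.table with one row per (chain, gene): mean frequencies,
#'   `t_statistic`, `p`, `tested`.
#' @export
compare_v_usage <- function(library, var_equal = TRUE) {
  dt <- library$clonotypes
  if (!nrow(dt)) abort("cannot analyse an empty library")
  donors <- sort(unique(dt$donor_id))
  grid <- data.table::CJ(donor_id = donors, phenotype = PHENOTYPES,
                         v_gene = unique(dt$v_gene))
  grid <- merge(grid, unique(dt[, .(v_gene, chain)]), by = "v_gene")
  counts <- dt[, .(n = .N), by = .(donor_id, phenotype, chain, v_gene)]
  freq <- merge(grid, counts,
                by = c("donor_id", "phenotype", "chain", "v_gene"),
                all.x = TRUE)
  freq[is.na(n), n := 0L]
  freq[, total := sum(n), by = .(donor_id, phenotype, chain)]
  freq[, f := ifelse(total > 0, n / total, 0)]

  can_test <- length(donors) >= 2L
  out <- freq[, {
    fd <- f[phenotype == "dominant"]
    fw <- f[phenotype == "weak"]
    present <- any(n > 0)
    if (can_test && present && (stats::sd(fd) > 0 || stats::sd(fw) > 0)) {
      tt <- t.test(fd, fw, var.equal = var_equal)
      .(freq_dominant = mean(fd), freq_weak = mean(fw),
        t_statistic = unname(tt$statistic), p = tt$p.value, tested = TRUE)
    } else {
      .(freq_dominant = mean(fd), freq_weak = mean(fw),
        t_statistic = NA_real_, p = NA_real_, tested = FALSE)
    }
  }, by = .(chain, v_gene)]
  data.table::setorder(out, chain, v_gene)
  out[]
}
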