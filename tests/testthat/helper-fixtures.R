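# Shared fixtures: load the packaged germline once, and build small
# hand-made objects used across test files.

pkg_germline <- load_packaged_germline()

# A minimal fabricated gene: fully occupied FR1-FR3 (no gaps anywhere in
# 1-104) with valid anchors.
gapless_gene <- function(name = "TRAV99") {
  chars <- rep("G", 104)
  chars[23] <- "C"; chars[41] <- "W"; chars[104] <- "C"
  germline_gene(name, paste(chars, collapse = ""))
}

# A tiny four-row clonotype table (2 donors x 2 phenotypes).
toy_clonotype_table <- function() {
  data.frame(
    donor_id = c("d1", "d1", "d2", "d2"),
    phenotype = c("dominant", "weak", "dominant", "weak"),
    chain = c("alpha", "alpha", "beta", "beta"),
    v_gene = c("TRAV38-2", "TRAV13-2", "TRBV7-8", "TRBV7-3"),
    j_gene = c("TRAJ4", "TRAJ9", "TRBJ1-1", "TRBJ2-1"),
    cdr3_aa = c("AVSDLEPNSSASK", "AENRDDKIIF", "ASSLRGNTGELF", "ASSLAGGYNEQF"),
    stringsAsFactors = FALSE)
}

# Independent two-sided Fisher oracle: enumerate all tables with the fixed
# margins via lchoose (no dhyper), point-probability ordering.
fisher_oracle <- function(a, b, c, d, rel_tol = 1e-9) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(r1 + r2, c1)
  probs <- exp(lp)
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Closed-form single-table Mantel-Haenszel (score) chi-square.
mh_chisq_1 <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  v <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  (a - e)^2 / v
}
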