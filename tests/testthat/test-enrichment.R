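# Exact tests, stratified combination, multiplicity control and tallies.

test_that("Fisher p matches enumeration oracle on reference tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  # fully-polarized table: twice the point mass of the extreme table
  r <- fisher_exact_2x2(10, 0, 0, 10)
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$p, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 7, 7, 3)$p, fisher_oracle(3, 7, 7, 3),
               tolerance = 1e-12)
})

test_that("Fisher p agrees with the enumeration oracle and fisher.test on random tables", {
  set.seed(77)
  for (i in 1:200) {
    t <- as.list(sample(0:25, 4, replace = TRUE))
    names(t) <- c("a", "b", "c", "d")
    if (min(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d) == 0) next
    p <- fisher_exact_2x2(t$a, t$b, t$c, t$d)$p
    expect_equal(p, fisher_oracle(t$a, t$b, t$c, t$d), tolerance = 1e-10)
    # independent established implementation as a second route
    p_ref <- stats::fisher.test(matrix(unlist(t), 2, byrow = TRUE))$p.value
    expect_equal(p, p_ref, tolerance = 1e-7)
  }
})

test_that("zero-margin tables are degenerate with p = 1", {
  r <- fisher_exact_2x2(0, 0, 3, 4)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
})

test_that("odds ratio follows the Haldane-Anscombe rule only at zero cells", {
  expect_equal(odds_ratio_2x2(5, 5, 5, 5), 1)
  expect_equal(odds_ratio_2x2(80, 20, 20, 80), 16)
  or <- odds_ratio_2x2(10, 0, 0, 10)
  expect_true(is.finite(or) && or > 1)
  expect_equal(or, (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("CMH reduces to the closed-form MH chi-square for one stratum", {
  one <- data.frame(a = 80, b = 20, c = 20, d = 80)
  r <- cmh_test(one)
  expect_equal(r$statistic, mh_chisq_1(80, 20, 20, 80), tolerance = 1e-12)
  expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
  # random single-stratum tables against the closed form
  set.seed(55)
  for (i in 1:20) {
    t <- sample(1:60, 4, replace = TRUE)
    expect_equal(cmh_test(data.frame(a = t[1], b = t[2], c = t[3], d = t[4]))$statistic,
                 mh_chisq_1(t[1], t[2], t[3], t[4]), tolerance = 1e-10)
  }
})

test_that("CMH on reference strata matches mantelhaen and the exact permutation oracle", {
  strata <- data.frame(a = c(8, 7), b = c(2, 3), c = c(2, 3), d = c(8, 7))
  r <- cmh_test(strata)
  arr <- array(c(8, 2, 2, 8, 7, 3, 3, 7), dim = c(2, 2, 2))
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  # exact permutation null: product of per-stratum hypergeometrics
  a1 <- 0:10; a2 <- 0:10
  pr <- outer(dhyper(a1, 10, 10, 10), dhyper(a2, 10, 10, 10))
  grid <- expand.grid(a1 = a1, a2 = a2)
  v <- 2 * (10 * 10 * 10 * 10) / (20^2 * 19)
  stat <- (grid$a1 + grid$a2 - 10)^2 / v
  p_exact <- sum(pr[cbind(grid$a1 + 1, grid$a2 + 1)][stat >= r$statistic * (1 - 1e-9)])
  expect_equal(p_exact, 0.004381683, tolerance = 1e-6)
  # the asymptotic p tracks the exact permutation p at small-table resolution
  expect_lt(abs(r$p - p_exact), 0.005)
})

test_that("CMH is invariant to stratum relabeling and degenerate strata flag", {
  strata <- data.frame(a = c(8, 7), b = c(2, 3), c = c(2, 3), d = c(8, 7))
  expect_equal(cmh_test(strata)$statistic,
               cmh_test(strata[2:1, ])$statistic, tolerance = 1e-12)
  null2 <- data.frame(a = c(5, 5), b = c(5, 5), c = c(5, 5), d = c(5, 5))
  r0 <- cmh_test(null2)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  deg <- data.frame(a = c(0, 0), b = c(0, 0), c = c(3, 2), d = c(4, 1))
  expect_true(cmh_test(deg)$degenerate)
})

test_that("Bonferroni multiplies by the family size, capped and order-preserving", {
  expect_equal(bonferroni(0.04, 1), 0.04)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(c(0.01, 0.002), 5), c(0.05, 0.01))
  p <- c(0.001, 0.02, 0.4)
  expect_equal(bonferroni(p, 50), stats::p.adjust(p, "bonferroni", n = 50))
  expect_error(bonferroni(c(0.1, 0.2), 1), "family_size")
})

test_that("tallies count each distinct clonotype once and respect gaps", {
  tab <- data.frame(
    donor_id = "d1", phenotype = "dominant", chain = "alpha",
    v_gene = "TRAV38-2", j_gene = c("TRAJ4", "TRAJ9"),
    cdr3_aa = c("AVSDLEPNSSASK", "AVRDLEPNSSASK"), stringsAsFactors = FALSE)
  tal <- tally_position_aa(repertoire_library(tab), pkg_germline)
  expect_true(all(tal$n_dominant == 2L))
  expect_true(all(tal$n_weak == 0L))
  # exactly one amino acid per masked position for a single-gene library
  expect_equal(nrow(tal), 77L)
  # gap positions contribute nothing
  expect_false(73 %in% tal$position)
})

test_that("tallies match a direct scan on a planted 80/20 library", {
  make_rows <- function(phen, n_L) {
    data.frame(
      donor_id = "d1", phenotype = phen, chain = "alpha",
      v_gene = "TRAV13-2", j_gene = "TRAJ4",
      cdr3_aa = replicate(100, paste(sample(c("A", "G", "S", "T", "V"), 10,
                                            replace = TRUE), collapse = "")),
      fw_variants = c(rep("96:L", n_L), rep("", 100 - n_L)),
      stringsAsFactors = FALSE)
  }
  set.seed(42)
  lib <- repertoire_library(rbind(make_rows("dominant", 80),
                                  make_rows("weak", 20)))
  tal <- tally_position_aa(lib, pkg_germline)
  p96 <- tal[position == 96]
  expect_equal(p96[amino_acid == "L", .(n_dominant, n_weak)],
               data.table::data.table(n_dominant = 80L, n_weak = 20L))
  expect_equal(p96[amino_acid == "P", .(n_dominant, n_weak)],
               data.table::data.table(n_dominant = 20L, n_weak = 80L))
  res <- run_enrichment(lib, pkg_germline, mode = "sanger")
  row <- res[chain == "alpha" & position == 96 & amino_acid == "L"]
  expect_equal(row$odds_ratio, 16)
  expect_equal(row$p, fisher_oracle(80, 20, 20, 80), tolerance = 1e-10)
})

test_that("unresolvable genes abort the tally", {
  tab <- toy_clonotype_table()
  tab$v_gene[1] <- "TRAV77"
  expect_error(tally_position_aa(repertoire_library(tab), pkg_germline),
               "TRAV77")
})

test_that("swapping phenotype labels flips direction and preserves p", {
  lib <- generate_library(synthetic_config(n_per_phenotype = 120, seed = 8))
  res <- run_enrichment(lib, pkg_germline, mode = "ngs")
  swapped <- lib
  swapped$clonotypes <- data.table::copy(lib$clonotypes)
  swapped$clonotypes[, phenotype := ifelse(phenotype == "dominant",
                                           "weak", "dominant")]
  res2 <- run_enrichment(swapped, pkg_germline, mode = "ngs")
  m <- merge(res, res2, by = c("chain", "position", "amino_acid"))
  expect_equal(m$p.x, m$p.y, tolerance = 1e-12)
  flip <- c("dominant-enriched" = "weak-enriched",
            "weak-enriched" = "dominant-enriched", "none" = "none")
  expect_identical(unname(flip[m$direction.x]), m$direction.y)
})

test_that("results are invariant to clonotype row order", {
  lib <- generate_library(synthetic_config(n_per_phenotype = 80, seed = 13))
  res <- run_enrichment(lib, pkg_germline, mode = "ngs")
  shuffled <- lib
  shuffled$clonotypes <- lib$clonotypes[sample(.N)]
  res2 <- run_enrichment(shuffled, pkg_germline, mode = "ngs")
  expect_equal(res, res2)
})

test_that("single-clonotype-per-arm libraries yield no discoveries", {
  tab <- toy_clonotype_table()[1:2, ]
  lib <- repertoire_library(tab)
  res <- run_enrichment(lib, pkg_germline, mode = "ngs", min_count = 1)
  expect_false(any(res$p_adjusted < 0.05, na.rm = TRUE))
})

test_that("single-phenotype libraries are rejected", {
  tab <- toy_clonotype_table()
  tab$phenotype <- "dominant"
  expect_error(run_enrichment(repertoire_library(tab), pkg_germline),
               "both dominant and weak")
})

test_that("V-usage comparison matches the closed-form two-sample t", {
  # three donors, constructed so per-donor frequencies are exactly the
  # textbook vectors (0.3, 0.31, 0.29) vs (0.1, 0.11, 0.09) for TRAV38-2
  set.seed(21)
  rows <- list()
  fd <- c(30, 31, 29); fw <- c(10, 11, 9)
  for (d in 1:3) {
    add <- function(phen, gene, n) {
      data.frame(donor_id = sprintf("d%d", d), phenotype = phen,
                 chain = "alpha", v_gene = gene, j_gene = "TRAJ4",
                 cdr3_aa = replicate(n, paste(sample(AA <- c("A","G","S","T","V","L","P","E","K","R"),
                                                     9, TRUE), collapse = "")),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- add("dominant", "TRAV38-2", fd[d])
    rows[[length(rows) + 1]] <- add("dominant", "TRAV13-2", 100 - fd[d])
    rows[[length(rows) + 1]] <- add("weak", "TRAV38-2", fw[d])
    rows[[length(rows) + 1]] <- add("weak", "TRAV13-2", 100 - fw[d])
  }
  lib <- repertoire_library(do.call(rbind, rows))
  usage <- compare_v_usage(lib)
  row <- usage[v_gene == "TRAV38-2"]
  # closed-form pooled-variance t for the two frequency triples
  x <- fd / 100; y <- fw / 100
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  t_ref <- (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  p_ref <- 2 * stats::pt(-abs(t_ref), df = 4)
  expect_equal(row$t_statistic, t_ref, tolerance = 1e-10)
  expect_equal(row$p, p_ref, tolerance = 1e-10)
  expect_true(row$tested)
})

test_that("identical usage gives t = 0 and absent genes are skipped", {
  tab <- rbind(toy_clonotype_table(), toy_clonotype_table())
  tab$donor_id <- rep(c("d1", "d2"), each = 4)
  tab$cdr3_aa[5:8] <- c("AVAAAAAAK", "AEAAAAAAF", "ASAAAAAAF", "ASAAAAAGF")
  lib <- repertoire_library(tab)
  usage <- compare_v_usage(lib)
  # every gene is exclusively dominant or weak here -> zero variance in one
  # arm with equal frequencies across donors; still tested (sd>0 in a arm)
  expect_true(all(usage$freq_dominant >= 0 & usage$freq_dominant <= 1))
  # single-donor library: frequencies returned, test skipped
  one <- repertoire_library(toy_clonotype_table()[1:2, ])
  u1 <- compare_v_usage(one)
  expect_true(all(!u1$tested))
  expect_true(all(is.na(u1$p)))
})
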