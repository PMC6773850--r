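# Substitution plans: LRY triple, 14-residue conversions, atomic
# application, CDR integrity, biochemical equivalence expansion.

residues_of <- function(tcr) {
  list(a = tcr$alpha$residues, b = tcr$beta$residues)
}

hamming <- function(t1, t2) {
  sum(unlist(residues_of(t1)) != unlist(residues_of(t2)))
}

cdr_residues <- function(tcr) {
  lapply(list(tcr$alpha, tcr$beta), function(dom) {
    dom$residues[dom$regions %in% c("CDR1", "CDR2", "CDR3")]
  })
}

test_that("LRY plan proposes exactly the missing target residues", {
  weak1 <- example_tcr("weak1")
  plan <- build_lry_plan(weak1)
  expect_equal(nrow(plan), 3L)
  expect_equal(attr(plan, "label"), "LRY")
  key <- plan[, paste(chain, position, from_aa, to_aa)]
  expect_setequal(key, c("alpha 96 P L", "beta 9 S R", "beta 10 N Y"))
  # a receptor already carrying the triple yields an empty plan
  modified <- apply_plan(weak1, plan)
  expect_equal(nrow(build_lry_plan(modified)), 0L)
  # partial carriage: only the missing edits are proposed
  dom <- example_tcr("dominant")
  expect_equal(nrow(build_lry_plan(dom)), 0L)
  partial <- apply_plan(weak1, substitution_plan(
    data.frame(chain = "alpha", position = 96L, from_aa = "P", to_aa = "L"),
    "single"))
  p2 <- build_lry_plan(partial)
  expect_equal(nrow(p2), 2L)
  expect_setequal(p2$position, c(9L, 10L))
})

test_that("gapped required positions abort the LRY designer by name", {
  g <- pkg_germline[["TRAV13-2"]]
  chars <- strsplit(g$gapped_seq, "")[[1]]
  chars[96] <- "."
  gapped <- germline_gene("TRAV13-2", paste(chars, collapse = ""))
  tcr <- tcr_pair("gapped",
                  number_v_domain(gapped, "AENRDDKIIF"),
                  number_v_domain(pkg_germline[["TRBV7-3"]], "ASSLAGGYNEQF"))
  expect_error(build_lry_plan(tcr), "a96")
})

test_that("14-residue conversion is a round trip on the weak 1 receptor", {
  weak1 <- example_tcr("weak1")
  up <- build_conversion_plan(weak1, direction = "to_dominant")
  expect_equal(nrow(up), 14L)
  expect_true("alpha 96 P L" %in% up[, paste(chain, position, from_aa, to_aa)])
  converted <- apply_plan(weak1, up)
  expect_equal(hamming(weak1, converted), 14L)
  down <- build_conversion_plan(converted, direction = "to_weak")
  expect_equal(nrow(down), 14L)
  restored <- apply_plan(converted, down)
  expect_identical(residues_of(restored), residues_of(weak1))
  # dominant receptor converted to weak includes the named reversals
  dplan <- build_conversion_plan(example_tcr("dominant"), direction = "to_weak")
  key <- dplan[, paste(chain, position, to_aa)]
  expect_true(all(c("alpha 39 F", "alpha 55 D", "beta 43 R") %in% key))
})

test_that("positions matching neither identity are skipped with a warning", {
  weak1 <- example_tcr("weak1")
  odd <- apply_plan(weak1, substitution_plan(
    data.frame(chain = "alpha", position = 96L, from_aa = "P", to_aa = "G"),
    "odd"))
  expect_warning(plan <- build_conversion_plan(odd, direction = "to_dominant"),
                 "neither identity")
  expect_equal(nrow(plan), 13L)
  expect_false(96L %in% plan[chain == "alpha", position])
})

test_that("plan application is atomic and changes exactly the planned positions", {
  weak1 <- example_tcr("weak1")
  expect_identical(residues_of(apply_plan(weak1, substitution_plan(
    data.frame(chain = character(0), position = integer(0),
               from_aa = character(0), to_aa = character(0)), "empty"))),
    residues_of(weak1))
  plan <- build_lry_plan(weak1)
  out <- apply_plan(weak1, plan)
  expect_equal(hamming(weak1, out), 3L)
  expect_identical(residue_at(out$alpha, 96), "L")
  expect_identical(residue_at(out$beta, 9), "R")
  expect_identical(residue_at(out$beta, 10), "Y")
  expect_identical(cdr_residues(out), cdr_residues(weak1))
  # stale from_aa: error, no partial application
  stale <- substitution_plan(
    data.frame(chain = c("alpha", "beta"), position = c(96L, 9L),
               from_aa = c("P", "Q"), to_aa = c("L", "R")), "stale")
  expect_error(apply_plan(weak1, stale), "b9 expects Q")
  expect_identical(residue_at(weak1$alpha, 96), "P")
})

test_that("plans refuse CDR positions and duplicate or null edits", {
  expect_error(substitution_plan(
    data.frame(chain = "alpha", position = 107L, from_aa = "A", to_aa = "G")),
    "framework")
  expect_error(substitution_plan(
    data.frame(chain = "alpha", position = c(5L, 5L),
               from_aa = c("A", "A"), to_aa = c("G", "T"))),
    "unique positions")
  expect_error(substitution_plan(
    data.frame(chain = "alpha", position = 5L, from_aa = "A", to_aa = "A")),
    "must differ")
})

test_that("equivalence expansion follows biochemical classes with a cap", {
  weak1 <- example_tcr("weak1")
  lry <- build_lry_plan(weak1)
  vars <- equivalence_variants(lry)
  # hydrophobic(5) x basic(3) x aromatic(4), none colliding with from_aa
  expect_length(vars, 60L)
  a96 <- unique(vapply(vars, function(p) p[chain == "alpha", to_aa], character(1)))
  expect_setequal(a96, c("L", "I", "V", "M", "F"))
  # every variant applies cleanly and preserves CDRs
  for (p in vars[seq(1, 60, by = 12)]) {
    out <- apply_plan(weak1, p)
    expect_identical(cdr_residues(out), cdr_residues(weak1))
  }
  # class sizes (5,4,4) give 80 variants: targets L, Y, S from fresh residues
  plan3 <- substitution_plan(
    data.frame(chain = c("alpha", "alpha", "beta"),
               position = c(5L, 6L, 5L),
               from_aa = c("G", "G", "G"),
               to_aa = c("L", "Y", "S")), "triple")
  expect_length(equivalence_variants(plan3), 80L)
  expect_error(equivalence_variants(plan3, limit = 10L), "80")
  # singleton class collapses to the plan itself
  single <- substitution_plan(
    data.frame(chain = "alpha", position = 5L, from_aa = "D", to_aa = "E"),
    "acid")
  vs <- equivalence_variants(single)
  expect_length(vs, 1L)
  expect_equal(vs[[1]]$to_aa, "E")
})

test_that("LRY idempotence: plan after application is empty", {
  for (nm in c("weak1", "weak2", "weak3")) {
    tcr <- example_tcr(nm)
    out <- apply_plan(tcr, build_lry_plan(tcr))
    expect_equal(nrow(build_lry_plan(out)), 0L)
    expect_identical(cdr_residues(out), cdr_residues(tcr))
  }
})

test_that("TCR FASTA export carries both chains, gapped and ungapped", {
  weak1 <- example_tcr("weak1")
  pg <- tempfile(fileext = ".fasta")
  write_tcr_fasta(weak1, pg, gapped = TRUE)
  gseqs <- as.character(Biostrings::readBStringSet(pg))
  expect_length(gseqs, 2L)
  expect_true(any(grepl("TRAV13-2", names(gseqs))))
  expect_equal(unique(nchar(gseqs)), 117L)
  pu <- tempfile(fileext = ".fasta")
  write_tcr_fasta(weak1, pu, gapped = FALSE)
  useqs <- as.character(Biostrings::readBStringSet(pu))
  expect_identical(unname(useqs), unname(gsub(".", "", gseqs, fixed = TRUE)))
})
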