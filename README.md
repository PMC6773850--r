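# tcrforge

Discovery and engineering of expression-determining framework residues in
human alpha/beta T cell receptors (TCRs).

TCRs transferred into engineered T cells vary widely in surface
expression, and low-expressing ("weak") receptors impair therapeutic
function.  The determinants are framework residues of the variable
domains — scaffold positions outside the antigen-binding CDR loops — so
they can be engineered without changing specificity.  `tcrforge` is for
computational immunologists and TCR engineers: it implements the
discovery pipeline that finds such residues from sorted dominant/weak
clonotype libraries, and the design tools that apply them, including the
stabilizing triple **L96α + R9β + Y10β** ("LRY") at the variable–constant
interfaces and the full 14-residue dominant/weak conversion set.

## What it computes

For every IMGT framework position and amino acid *A*, clonotype counts of
*A* versus not-*A* in the dominant versus weak library form a 2×2 table
per donor:

* per-donor two-sided **Fisher exact tests** with point-probability
  ("as-or-more-extreme") ordering on the hypergeometric distribution;
* the **Cochran–Mantel–Haenszel** score test across donors,
  χ² = (Σₖ (aₖ − Eₖ))² / Σₖ Vₖ with hypergeometric mean/variance per
  stratum and no continuity correction;
* **Bonferroni** adjustment over the tested family, counted per chain;
* pooled odds ratios (Haldane–Anscombe +0.5 only at zero cells) for
  direction, and unpaired t-tests on per-donor V-gene usage frequencies.

Around the statistics sit: a seeded synthetic sorted-repertoire
generator with planted residue-level effects (known ground truth for
every stage), template-based IMGT unique numbering (V segment at gapped
coordinates 1–104, CDR3 spliced 105–117 center-out, 77 framework
positions per chain under the packaged convention),
structural-category candidate selection, atomic substitution plans with
CDR-integrity guarantees, biochemical-equivalence expansion of designs,
and the small assay formulas (percent specific killing, alanine/serine
peptide scans, background subtraction, fold change).

The packaged germline, candidate and category tables are **synthetic
stand-ins** (files suffixed `_synthetic`): faithful at the functionally
characterized residues and anchors, fabricated elsewhere.  Supply real
IMGT-gapped references via `read_gapped_fasta()` for real data.

## Worked example

```r
library(tcrforge)

lib <- generate_library(synthetic_config(seed = 1))
lib
#> <repertoire_library> 884 clonotypes, 3 donor(s)
#>   dominant alpha 222
#>   dominant beta  220
#>   weak     alpha 222
#>   weak     beta  220

res  <- run_enrichment(lib, load_packaged_germline(), mode = "ngs")
cand <- select_candidates(res, alpha_level = 0.05)
head(as.data.frame(cand), 3)
#>   chain position dominant_aa weak_aa category   evidence        p
#> 1 alpha       96           L       P        4 enrichment 1.80e-14
#> 2  beta        9           R       S        4 enrichment 1.84e-03
#> 3  beta       18           I       V        2 enrichment 6.85e-03

weak1 <- example_tcr("weak1")          # TRAV13-2 / TRBV7-3
build_lry_plan(weak1)
#> <substitution_plan> 'LRY', 3 edit(s)
#>   a96 P -> L
#>   b9 S -> R
#>   b10 N -> Y
residue_at(apply_plan(weak1, build_lry_plan(weak1))$alpha, 96)
#> [1] "L"
```

The default synthetic library (3 donors, 442 distinct clonotypes per
phenotype, published V-usage skew, one planted effect: leucine at alpha
position 96 with odds ratio 5) is analysed in NGS mode; the planted
residue comes out as the top candidate with its correct dominant/weak
identities and structural category (4 = V–C interface), followed by
residues carried along by the configured V-gene usage skew.  The LRY
designer proposes exactly the three published edits on the weak 1
receptor, whose framework carries none of the target residues.

A thin command-line front end ships in `inst/scripts/forge.R`
(subcommands `simulate`, `enrich`, `candidates`, `design`, `peptides`,
`run`).

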