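---
title: "Discovering and engineering expression-determining TCR framework residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and engineering expression-determining TCR framework residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrforge)
```

## The problem

Human alpha/beta T cell receptors (TCRs) with identical constant domains
differ widely in how well they reach the cell surface, and this surface
density limits the function of TCR-gene-engineered T cells.  The variable
(V) domains are responsible: some receptors behave as *dominant* — they
keep being expressed when forced to compete with a strongly expressed
introduced TCR — while others are *weak* and disappear from the surface.
The residues that separate the two classes sit in the framework regions,
the scaffold of the V domain outside the antigen-binding CDR loops, so
they can be engineered without touching antigen specificity.

`tcrforge` implements the computational side of this programme as a
reusable pipeline:

1. sample (or load) sorted dominant/weak clonotype libraries per donor;
2. place every clonotype's V domain on the IMGT unique numbering so
   positions are comparable across genes;
3. test every framework position and amino acid for enrichment between
   the two libraries;
4. intersect significant hits with a structural-category annotation to
   nominate candidate residues;
5. build and apply substitution plans — the three-residue stabilizing
   triple (L96 on the alpha chain, R9/Y10 on the beta chain), full
   14-residue conversions between the dominant and weak identities, or
   custom sets — with guarantees that CDR loops are never modified.

## Coordinates and the framework mask

All public coordinates are 1-based IMGT positions.  The fixed region
boundaries are FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104,
CDR3 105–117 and FR4 118–128; the V segment ends at the second conserved
cysteine (position 104), and the conserved anchors C23, W41 and C104 are
validated on every numbered domain (violations warn rather than abort,
since real rearrangements occasionally lose an anchor).

Numbering is template-based: clonotypes arrive with a V-gene call, so the
V segment is a germline lookup at its gapped coordinates and the CDR3 is
spliced into 105–117 from both ends toward the middle (center-out rule;
for length $L \le 13$, $\lceil L/2 \rceil$ residues ascend from 105 and
the rest descend from 117).  CDR3s longer than 13 would need IMGT
insertion codes (111.1-style); they are rejected rather than approximated
because CDR3 is excluded from framework statistics anyway.

The framework mask of a chain is the union of occupied FR1–FR3 positions
across the germline set.  FR4 is J-encoded and excluded; with the
packaged reference convention each chain exposes **77** framework
positions.  The count of 77 fixes the gap pattern only up to choice; the
packaged convention trims CDR1 to six and CDR2 to five germline residues
and leaves FR3 scheme positions 73, 81, 82, 84 and 85 unoccupied.  The
mask is data, not code: replacing the germline FASTA replaces the mask.

The packaged germline set is synthetic (the file is suffixed
`_synthetic`): residue identities at the functionally characterized
positions — e.g. P96 in TRAV13-2 versus L96 in TRAV38-2, S9/N10 in
TRBV7-3 versus R9/Y10 in TRBV7-8, F39/L39, D55/R55, R43/Q43 — and the
anchors are faithful, while all remaining positions are fabricated.  Any
analysis of real repertoires should substitute a real IMGT-gapped
germline FASTA via `read_gapped_fasta()`.

## The statistical model

At every masked position and for every amino acid $A$, counts of $A$
versus not-$A$ clonotypes form a 2×2 table per donor:

$$\begin{array}{c|cc} & \text{dominant} & \text{weak}\\\hline A & a & c\\ \lnot A & b & d \end{array}$$

Counting is clonotype-weighted by default (each distinct clonotype counts
once, regardless of read abundance), matching a design in which the
discovery unit is the distinct rearrangement; abundance weighting is a
flag.

* **Sanger mode** pools donors into a single table per (position, amino
  acid) and applies the two-sided Fisher exact test with no multiplicity
  correction, mirroring a small-library exploratory analysis.
* **NGS mode** keeps donors as strata: per-donor Fisher tests are
  reported, the donors are combined with the Cochran–Mantel–Haenszel
  (CMH) score test, and the CMH p-values are Bonferroni-adjusted.

The Fisher p-value is defined by point-probability ordering — the sum of
hypergeometric point masses not exceeding that of the observed table —
with a $10^{-12}$ relative tolerance on the comparison so that ties at
the observed mass are included regardless of floating-point noise.  The
CMH statistic is $\left(\sum_k (a_k - E_k)\right)^2 / \sum_k V_k$ with
hypergeometric mean and variance per stratum and **no continuity
correction**; this keeps the single-stratum case exactly equal to the
Mantel–Haenszel score chi-square, and at NGS-scale counts the correction
is immaterial.  The CMH reference distribution is asymptotic
($\chi^2_1$); its p-values track an exact permutation (product
hypergeometric) null only up to the discreteness of small tables, which
is why the test suite compares against permutation oracles with an
absolute tolerance rather than to machine precision.

The Bonferroni family is the set of (position, amino acid) pairs actually
tested, counted per chain.  Pairs with a pooled amino-acid count below 5
(configurable) are reported but flagged untested: exact tests on
vanishing counts are uninformative and would only inflate the family.
The family size used is recorded in every result row.

Direction is read from the pooled odds ratio $(ad)/(bc)$, computed with
the Haldane–Anscombe +0.5 correction only when a cell is zero.  The
symmetry of the whole analysis — swapping the phenotype labels flips
every direction and changes no p-value — is asserted as a property test.

V-gene usage is compared separately: per-donor within-chain gene
frequencies, two-sided unpaired Student (equal-variance) t-test between
phenotypes, Welch by flag.  With a single donor the test is skipped and
only frequencies are reported.

## The synthetic repertoire generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: 3 donors, 442 distinct clonotypes per phenotype (884
total, split across donors as evenly as possible — the per-donor counts
are not specified by the study, so an even split is the documented
default), CDR3 lengths uniform on 8–13, V genes drawn from the packaged
18-gene pool with the published usage skew (TRAV38-2, TRBV7-8 and
TRBV5-1 up-weighted 2–3× in the dominant arm; TRAV13-2, TRBV9, TRBV7-9
and TRBV2 in the weak arm), and one planted residue effect: leucine at
alpha position 96 with a dominant:weak carriage odds ratio of 5 on a
weak-arm baseline of 0.2.  The baseline of 0.2 represents a common
framework polymorphism — frequent enough to be testable at Sanger scale,
rare enough not to dominate the position.

Planted effects are residue-level, not gene-level: each clonotype carries
the planted amino acid with probability $p_w$ (weak arm) or
$p_d = \mathrm{OR} \cdot p_w/(1-p_w) \,/\, (1 + \mathrm{OR} \cdot
p_w/(1-p_w))$ (dominant arm), so the marginal log-odds difference equals
$\log \mathrm{OR}$ exactly in expectation.  Non-carriers whose germline
residue already equals the planted amino acid display a configured
alternative residue instead; without this rule, genes natively carrying
the planted residue would dilute the realized effect.  Deviations from
the germline are recorded in the `fw_variants` column of the clonotype
table ("96:L"), so the emitted TSV is self-contained and the planted
truth is recoverable by direct counting.

Clonotype distinctness — the study counts *distinct* clonotypes — is
enforced globally on (chain, V gene, J gene, CDR3) by resampling CDR3s on
collision.  A single seed drives everything; identical configurations
and seeds give byte-identical serialized libraries.

What the generator does **not** emulate: nucleotide-level V(D)J
recombination statistics, sequencing error, UMI structure, CDR3 length/
composition biases, allelic linkage between framework positions, and
donor-specific effect heterogeneity (planted odds ratios are shared
across donors, which is exactly the CMH common-effect assumption).
Passing tests therefore demonstrate the correctness and calibration of
the statistical machinery under the stated sampling model, not
performance on real repertoires.

## Candidate selection and substitution design

Candidates are dominant-enriched framework hits below the significance
threshold that carry a structural-category annotation: 1 solvent
exposed, 2 hydrophobic core, 3 V&alpha;–V&beta; interface, 4 V–C
interface.  The annotation ships as a static, user-replaceable table
(categories originally derive from 3D modeling, which is out of scope
here).  Ties order by smaller p, then larger |log odds ratio|, then
lower position.  The curated 14-residue table bundles the full published
candidate set; two of its rows (beta 18 and beta 88) are synthetic
placeholders for entries only shown in a figure, and are marked as such
in the `evidence` column.

Substitution plans record (chain, position, from, to) and apply
atomically: a stale `from` residue aborts the whole plan.  CDR residues
are invariant under every plan the package produces — plans are
framework-only by construction and the property is asserted on every
test receptor.  Conversion plans are involutive on matched positions:
converting weak→dominant and back restores the original sequence
exactly.  Equivalence expansion replaces each planned target with its
biochemical class (hydrophobic {L, I, V, M, F}, aromatic {F, Y, W, H},
basic {R, K, H}, acidic {D, E}, polar {S, T, N, Q}, small {A, G, C, P});
the classes are a standard Taylor-style grouping and user-editable, and
the Cartesian expansion is capped (default 1000 plans).

## Numerical and design choices

* Degenerate 2×2 tables (a zero margin) are defined to have p = 1 with a
  flag rather than erroring, so sparse positions never abort a scan.
* Counts are coerced to double before forming products of four margins
  (integer overflow begins near cell counts of ~200 otherwise).
* Ordering of all outputs is fixed (chain, position, amino acid) so
  serialized reports are byte-stable and reruns are checksum-identical.
* Allele suffixes ("*01") are stripped on input: the analysis is
  gene-level, matching gene-level usage reporting.
* The out-of-range CDR3 policy (reject > 13) and the FR4 exclusion are
  deliberate scope boundaries, not approximations.

## Problem sizes used by the test suite

The suite exercises the generator at up to 5000 clonotypes per arm for
effect-size fidelity and recovery (100 seeds each), 100 replicate null
libraries of 500 per arm for family-wise error calibration, and an
exhaustive Fisher-versus-enumeration sweep over all 2×2 tables with row
margins up to 30.  These sizes were chosen as the smallest at which the
binomial assertions (≥ 95/100 recoveries, ≤ 8/100 null discoveries) are
stable across seeds.

## Limitations

* Template-based numbering cannot process clonotypes without a V-gene
  call, and there is no HMM/profile fallback.
* The CMH p-value is asymptotic; at very small per-donor counts the
  Bonferroni-adjusted discoveries are conservative rather than exact.
* The packaged germline, category and candidate tables are synthetic
  stand-ins at all positions not explicitly characterized in the
  published work; analyses of real data must supply real references.
* No stability (ΔΔG) prediction, no codon-level design, and no ranking
  of edit importance is attempted: the design modules book-keep
  substitutions, they do not predict their effect sizes.

## A worked example

```{r example, eval = FALSE}
library(tcrforge)

lib <- generate_library(synthetic_config(seed = 1))
res <- run_enrichment(lib, load_packaged_germline(), mode = "ngs")
cand <- select_candidates(res, alpha_level = 0.05)
head(cand)

weak1 <- example_tcr("weak1")
plan <- build_lry_plan(weak1)
plan
stabilized <- apply_plan(weak1, plan)
residue_at(stabilized$alpha, 96)  # "L"
```
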