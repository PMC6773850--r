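Package: tcrforge
Title: Discovery and Engineering of Expression-Determining TCR Framework Residues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for finding T cell receptor (TCR) variable-domain
    framework residues that separate dominantly from weakly expressed
    receptors, and for designing framework substitutions on arbitrary
    alpha/beta TCR sequences.  Includes a synthetic sorted-repertoire
    generator with planted positional effects, template-based IMGT unique
    numbering of V domains, per-position amino-acid enrichment statistics
    (exact Fisher tests per donor, Cochran-Mantel-Haenszel stratification
    across donors, Bonferroni control), structural-category candidate
    selection, substitution-plan construction (including the stabilizing
    L96-alpha/R9-beta/Y10-beta triple and full 14-residue conversions) with
    biochemical-equivalence expansion, and the small assay formulas used to
    post-process functional read-outs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
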