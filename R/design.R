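# Framework substitution design: LRY triple, full 14-residue conversions,
# custom plans, and biochemical-equivalence expansion.
#
# Plans are audit-friendly: every edit records the residue it expects to
# replace (from_aa) and application is atomic -- a stale from_aa aborts the
# whole plan, mirroring site-directed mutagenesis bookkeeping.

#' Pair two numbered V domains into a TCR
#'
#' @param name label for the receptor.
#' @param alpha,beta `numbered_domain` objects of the matching chains.
#' @return object of class `tcr_pair`.
#' @export
tcr_pair <- function(name, alpha, beta) {
  if (!inherits(alpha, "numbered_domain") || alpha$chain != "alpha") {
    abort("`alpha` must be a numbered alpha-chain domain")
  }
  if (!inherits(beta, "numbered_domain") || beta$chain != "beta") {
    abort("`beta` must be a numbered beta-chain domain")
  }
  structure(list(name = name, alpha = alpha, beta = beta),
            class = "tcr_pair")
}

#' @export
print.tcr_pair <- function(x, ...) {
  cat(sprintf("<tcr_pair> %s: %s / %s\n", x$name,
              x$alpha$source_gene, x$beta$source_gene))
  invisible(x)
}

#' Packaged example TCRs
#'
#' Builds the study's reference receptors from the packaged germline set:
#' "dominant" (TRAV38-2/TRBV7-8), "weak1" (TRAV13-2/TRBV7-3), "weak2"
#' (TRAV23/TRBV7-9) and "weak3" (TRAV29/TRBV2), with fixed illustrative
#' CDR3s.
#'
#' @param which one of "dominant", "weak1", "weak2", "weak3".
#' @param germline a `germline_set` containing the required genes.
#' @return a `tcr_pair`.
#' @export
example_tcr <- function(which = c("weak1", "dominant", "weak2", "weak3"),
                        germline = load_packaged_germline()) {
  which <- match.arg(which)
  spec <- list(
    dominant = list(a = "TRAV38-2", b = "TRBV7-8",
                    ca = "AVSDLEPNSSASKIIF", cb = "ASSLRGNTGELF"),
    weak1 = list(a = "TRAV13-2", b = "TRBV7-3",
                 ca = "AENRDDKIIF", cb = "ASSLAGGYNEQF"),
    weak2 = list(a = "TRAV23", b = "TRBV7-9",
                 ca = "AASIGPLGDF", cb = "ASSPRDSSYEQY"),
    weak3 = list(a = "TRAV29", b = "TRBV2",
                 ca = "AASGGSYIPTF", cb = "ASSEAPSTDTQY")
  )[[which]]
  # CDR3 strings here are trimmed to the supported <= 13 residue span.
  ca <- substr(spec$ca, 1, 13); cb <- substr(spec$cb, 1, 13)
  tcr_pair(which,
           number_v_domain(germline[[spec$a]], ca),
           number_v_domain(germline[[spec$b]], cb))
}

#' Construct a substitution plan
#'
#' @param edits data.frame with columns chain, position, from_aa, to_aa.
#' @param label plan label (e.g. "LRY").
#' @return object of class `substitution_plan`.
#' @export
substitution_plan <- function(edits, label = "custom") {
  dt <- data.table::as.data.table(edits)
  need <- c("chain", "position", "from_aa", "to_aa")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    abort("plan lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(dt)) {
    if (anyDuplicated(dt, by = c("chain", "position"))) {
      abort("plan edits must target unique positions per chain")
    }
    if (any(dt$from_aa == dt$to_aa)) {
      abort("from_aa and to_aa must differ in every edit")
    }
    if (any(!is_framework_position(dt$position))) {
      abort("plan edits must stay within framework (FR1-FR3) positions")
    }
  }
  dt <- dt[, need, with = FALSE]
  data.table::setattr(dt, "label", label)
  data.table::setattr(dt, "class", c("substitution_plan", class(dt)))
  dt[]
}

#' @export
print.substitution_plan <- function(x, ...) {
  cat(sprintf("<substitution_plan> '%s', %d edit(s)\n",
              attr(x, "label"), nrow(x)))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s%d %s -> %s\n", substr(x$chain[i], 1, 1),
                  x$position[i], x$from_aa[i], x$to_aa[i]))
    }
  }
  invisible(x)
}

# The stabilizing triple: leucine 96 alpha plus arginine 9 / tyrosine 10
# beta, which reinforce the V-C interfaces.
LRY_TARGETS <- data.frame(chain = c("alpha", "beta", "beta"),
                          position = c(96L, 9L, 10L),
                          to_aa = c("L", "R", "Y"),
                          stringsAsFactors = FALSE)

#' Build the LRY stabilization plan for a TCR
#'
#' Proposes L96 on the alpha chain and R9/Y10 on the beta chain wherever
#' the current residue differs from the target; a TCR already carrying the
#' triple yields an empty plan.
#'
#' @param tcr a `tcr_pair`.
#' @return a `substitution_plan` labelled "LRY".
#' @export
build_lry_plan <- function(tcr) {
  edits <- list()
  for (i in seq_len(nrow(LRY_TARGETS))) {
    ch <- LRY_TARGETS$chain[i]; pos <- LRY_TARGETS$position[i]
    cur <- residue_at(tcr[[ch]], pos)
    if (is.na(cur)) {
      abort("required position %s%d is unoccupied in %s",
            substr(ch, 1, 1), pos, tcr$name)
    }
    if (cur != LRY_TARGETS$to_aa[i]) {
      edits[[length(edits) + 1L]] <- data.frame(
        chain = ch, position = pos, from_aa = cur,
        to_aa = LRY_TARGETS$to_aa[i], stringsAsFactors = FALSE)
    }
  }
  substitution_plan(
    if (length(edits)) do.call(rbind, edits) else
      data.frame(chain = character(0), position = integer(0),
                 from_aa = character(0), to_aa = character(0)),
    label = "LRY")
}

#' Build a full conversion plan from a candidate table
#'
#' For `direction = "to_dominant"`, every candidate position whose current
#' residue equals the weak identity is edited to the dominant identity
#' (and vice versa).  Positions matching neither identity are skipped with
#' a warning; positions already at the target are skipped silently.
#'
#' @param tcr a `tcr_pair`.
#' @param candidates a candidate table (default the packaged 14-residue
#'   set).
#' @param direction "to_dominant" or "to_weak".
#' @return a `substitution_plan`.
#' @export
build_conversion_plan <- function(tcr, candidates = load_curated_candidates(),
                                  direction = c("to_dominant", "to_weak")) {
  direction <- match.arg(direction)
  cand <- data.table::as.data.table(candidates)
  edits <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chain[i]; pos <- cand$position[i]
    from_id <- if (direction == "to_dominant") cand$weak_aa[i] else cand$dominant_aa[i]
    to_id <- if (direction == "to_dominant") cand$dominant_aa[i] else cand$weak_aa[i]
    cur <- residue_at(tcr[[ch]], pos)
    if (is.na(cur)) next
    if (cur == to_id) next
    if (cur != from_id) {
      warn("%s: residue %s at %s%d matches neither identity (%s/%s); skipped",
           tcr$name, cur, substr(ch, 1, 1), pos,
           cand$dominant_aa[i], cand$weak_aa[i])
      next
    }
    edits[[length(edits) + 1L]] <- data.frame(
      chain = ch, position = pos, from_aa = cur, to_aa = to_id,
      stringsAsFactors = FALSE)
  }
  substitution_plan(
    if (length(edits)) do.call(rbind, edits) else
      data.frame(chain = character(0), position = integer(0),
                 from_aa = character(0), to_aa = character(0)),
    label = if (direction == "to_dominant") "weak->dom" else "dom->weak")
}

#' Apply a substitution plan to a TCR
#'
#' Atomic: every edit's from_aa must match the current residue or the call
#' aborts with the offending position and the TCR is left untouched.  CDR
#' residues are never altered (plans are framework-only by construction).
#'
#' @param tcr a `tcr_pair`.
#' @param plan a `substitution_plan`.
#' @return a new `tcr_pair` differing from `tcr` at exactly the planned
#'   positions, with the edit log in attribute `edit_log`.
#' @export
apply_plan <- function(tcr, plan) {
  for (i in seq_len(nrow(plan))) {
    cur <- residue_at(tcr[[plan$chain[i]]], plan$position[i])
    if (is.na(cur) || cur != plan$from_aa[i]) {
      abort("edit %s%d expects %s but the receptor carries %s; plan not applied",
            substr(plan$chain[i], 1, 1), plan$position[i],
            plan$from_aa[i], if (is.na(cur)) "a gap" else cur)
    }
  }
  out <- tcr
  for (i in seq_len(nrow(plan))) {
    ch <- plan$chain[i]
    out[[ch]]$residues[[as.character(plan$position[i])]] <- plan$to_aa[i]
  }
  out$name <- sprintf("%s[%s]", tcr$name, attr(plan, "label"))
  attr(out, "edit_log") <- data.table::as.data.table(plan)
  out
}

#' Standard biochemical residue classes
#'
#' A Taylor-style classification used for equivalence expansion; residues
#' may belong to several classes, and `primary_biochemical_class()` picks
#' the class used for a given target residue.
#'
#' @return named list of character vectors.
#' @export
biochemical_classes <- function() {
  list(
    hydrophobic = c("L", "I", "V", "M", "F"),
    aromatic    = c("F", "Y", "W", "H"),
    basic       = c("R", "K", "H"),
    acidic      = c("D", "E"),
    polar       = c("S", "T", "N", "Q"),
    small       = c("A", "G", "C", "P")
  )
}

#' Primary biochemical class of a residue
#' @param aa single amino-acid letter.
#' @return class name (see [biochemical_classes()]).
#' @export
primary_biochemical_class <- function(aa) {
  map <- c(L = "hydrophobic", I = "hydrophobic", V = "hydrophobic",
           M = "hydrophobic", F = "aromatic", Y = "aromatic",
           W = "aromatic", H = "basic", R = "basic", K = "basic",
           D = "acidic", E = "acidic", S = "polar", T = "polar",
           N = "polar", Q = "polar", A = "small", G = "small",
           C = "small", P = "small")
  cls <- map[aa]
  if (is.na(cls)) abort("unknown amino acid '%s'", aa)
  unname(cls)
}

#' Expand a plan into biochemically equivalent variants
#'
#' For each edit, alternative target residues are drawn from the
#' biochemical class of the planned target (hydrophobic for L96 alpha,
#' basic for R9 beta, aromatic for Y10 beta, ...), excluding the residue
#' being replaced.  The Cartesian expansion across edits is capped.
#'
#' @param plan a `substitution_plan`.
#' @param classes class table (default [biochemical_classes()]).
#' @param limit maximum number of variant plans.
#' @return list of `substitution_plan` objects (includes the original
#'   targets as one combination).
#' @export
equivalence_variants <- function(plan, classes = biochemical_classes(),
                                 limit = 1000L) {
  if (!nrow(plan)) return(list(plan))
  options_per_edit <- lapply(seq_len(nrow(plan)), function(i) {
    cls <- classes[[primary_biochemical_class(plan$to_aa[i])]]
    setdiff(cls, plan$from_aa[i])
  })
  n_var <- prod(lengths(options_per_edit))
  if (n_var > limit) {
    abort("equivalence expansion yields %d plans, above the limit of %d",
          n_var, limit)
  }
  combos <- do.call(expand.grid,
                    c(options_per_edit, stringsAsFactors = FALSE))
  lapply(seq_len(nrow(combos)), function(k) {
    dt <- data.table::as.data.table(plan)
    dt[, to_aa := unlist(combos[k, ])]
    substitution_plan(dt, label = sprintf("%s~%d", attr(plan, "label"), k))
  })
}

#' Export a TCR pair as FASTA
#'
#' Writes both chains, gapped (IMGT coordinates, positions 1-117) and
#' ungapped; headers carry the receptor name and chain.
#'
#' @param tcr a `tcr_pair`.
#' @param path output FASTA path.
#' @param gapped emit IMGT-gapped (TRUE) or ungapped sequences.
#' @return `path`, invisibly.
#' @export
write_tcr_fasta <- function(tcr, path, gapped = TRUE) {
  seq_of <- function(domain) {
    if (gapped) {
      chars <- rep(GAP_CHAR, 117L)
      idx <- as.integer(names(domain$residues))
      chars[idx] <- unname(domain$residues)
      paste(chars, collapse = "")
    } else {
      paste(unname(domain$residues), collapse = "")
    }
  }
  x <- Biostrings::BStringSet(c(seq_of(tcr$alpha), seq_of(tcr$beta)))
  names(x) <- sprintf("%s|%s|%s", tcr$name, c("alpha", "beta"),
                      c(tcr$alpha$source_gene, tcr$beta$source_gene))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
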