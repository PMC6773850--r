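# Synthetic paired dominant/weak repertoire libraries with planted,
# residue-level positional enrichment.
#
# The generator emulates the sorted-library design: per donor, two arms of
# distinct clonotypes ("dominant" and "weak" surface-expression phenotypes),
# V-gene usage skew between arms, and configurable per-position amino-acid
# effects planted at framework positions.  A planted effect
# (chain, position, aa, odds_ratio) makes the carriage odds of `aa` at that
# position odds_ratio-fold higher in the dominant arm than in the weak arm,
# so the marginal log-odds difference equals log(odds_ratio) in expectation.

#' Configure a synthetic repertoire
#'
#' Defaults emulate the study's Sanger-scale library: 3 donors, 442
#' clonotypes per phenotype (884 total), the packaged 18-gene pool with the
#' published usage skew (TRAV38-2/TRBV7-8/TRBV5-1 enriched in the dominant
#' arm; TRAV13-2/TRBV9/TRBV7-9/TRBV2 in the weak arm), and one planted
#' effect: leucine at alpha position 96 with dominant:weak odds ratio 5.
#'
#' @param n_donors number of donors (strata for the CMH test).
#' @param n_per_phenotype total distinct clonotypes per phenotype, split as
#'   evenly as possible across donors.
#' @param germline a `germline_set` providing the gene pool.
#' @param v_gene_pool optional character vector restricting the pool.
#' @param v_usage_weights list with elements `dominant` and `weak`, each a
#'   named non-negative weight vector over pool genes (unnamed genes get
#'   weight 1).
#' @param planted_effects data.frame with columns chain, position,
#'   amino_acid, odds_ratio and optionally baseline (weak-arm carriage
#'   probability, default 0.2) and alt_aa (residue shown by non-carriers
#'   whose germline already matches amino_acid).
#' @param cdr3_length_range integer length-2 vector, CDR3 lengths sampled
#'   uniformly from this interval (within 5-13).
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_donors = 3L,
                             n_per_phenotype = 442L,
                             germline = load_packaged_germline(),
                             v_gene_pool = NULL,
                             v_usage_weights = default_usage_weights(),
                             planted_effects = default_planted_effects(),
                             cdr3_length_range = c(8L, 13L),
                             seed = 1L) {
  if (n_donors < 1L) abort("n_donors must be >= 1")
  if (n_per_phenotype < 1L) abort("at least one clonotype per phenotype is required")
  pool <- v_gene_pool %||% names(germline)
  missing <- setdiff(pool, names(germline))
  if (length(missing)) {
    abort("pool gene(s) absent from the germline set: %s",
          paste(missing, collapse = ", "))
  }
  if (cdr3_length_range[1] < 5L || cdr3_length_range[2] > 13L ||
      cdr3_length_range[1] > cdr3_length_range[2]) {
    abort("cdr3_length_range must lie within 5-13")
  }
  pe <- normalize_planted_effects(planted_effects, germline)
  structure(list(
    n_donors = as.integer(n_donors),
    n_per_phenotype = as.integer(n_per_phenotype),
    germline = germline,
    v_gene_pool = pool,
    v_usage_weights = v_usage_weights,
    planted_effects = pe,
    cdr3_length_range = as.integer(cdr3_length_range),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Null-library configuration
#'
#' Same scale as the default configuration but with no planted effects and
#' identical V-usage weights in both arms, so no position is truly enriched.
#'
#' @param n_donors,n_per_phenotype,seed as in [synthetic_config()].
#' @param germline a `germline_set`.
#' @return a `synthetic_config`.
#' @export
null_config <- function(n_donors = 3L, n_per_phenotype = 442L, seed = 1L,
                        germline = load_packaged_germline()) {
  synthetic_config(
    n_donors = n_donors, n_per_phenotype = n_per_phenotype,
    germline = germline,
    v_usage_weights = list(dominant = numeric(0), weak = numeric(0)),
    planted_effects = no_planted_effects(),
    seed = seed)
}

#' Published V-usage skew used by the default configuration
#' @return list with named weight vectors `dominant` and `weak`.
#' @export
default_usage_weights <- function() {
  list(
    dominant = c("TRAV38-2" = 3, "TRBV7-8" = 3, "TRBV5-1" = 2),
    weak     = c("TRAV13-2" = 3, "TRBV9" = 2, "TRBV7-9" = 2, "TRBV2" = 2)
  )
}

#' Default planted effect (hydrophobic enrichment at alpha 96)
#' @return data.frame of planted effects.
#' @export
default_planted_effects <- function() {
  data.frame(chain = "alpha", position = 96L, amino_acid = "L",
             odds_ratio = 5, baseline = 0.2, alt_aa = "P",
             stringsAsFactors = FALSE)
}

#' Empty planted-effect table
#' @return zero-row data.frame with the planted-effect columns.
#' @export
no_planted_effects <- function() {
  data.frame(chain = character(0), position = integer(0),
             amino_acid = character(0), odds_ratio = numeric(0),
             baseline = numeric(0), alt_aa = character(0),
             stringsAsFactors = FALSE)
}

normalize_planted_effects <- function(pe, germline) {
  pe <- data.table::as.data.table(pe)
  if (!nrow(pe)) return(no_planted_effects())
  need <- c("chain", "position", "amino_acid", "odds_ratio")
  missing <- setdiff(need, names(pe))
  if (length(missing)) {
    abort("planted_effects lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (!"baseline" %in% names(pe)) pe[, baseline := 0.2]
  if (!"alt_aa" %in% names(pe)) pe[, alt_aa := NA_character_]
  if (any(pe$odds_ratio <= 0)) abort("planted odds ratios must be > 0")
  if (any(pe$baseline <= 0 | pe$baseline >= 1)) {
    abort("planted baseline carriage must lie in (0, 1)")
  }
  for (i in seq_len(nrow(pe))) {
    mask <- build_framework_mask(germline, pe$chain[i])
    if (!pe$position[i] %in% mask) {
      abort("planted position %d (%s chain) is outside the framework mask",
            pe$position[i], pe$chain[i])
    }
    if (is.na(pe$alt_aa[i])) {
      cur <- curated_identity(pe$chain[i], pe$position[i])
      alt <- if (!is.na(cur) && cur != pe$amino_acid[i]) cur
             else if (pe$amino_acid[i] != "S") "S" else "A"
      pe[i, alt_aa := alt]
    }
    if (pe$alt_aa[i] == pe$amino_acid[i]) {
      abort("planted alt_aa must differ from the planted amino acid")
    }
  }
  as.data.frame(pe)
}

# Weak-arm residue identity from the curated candidate table, if annotated.
curated_identity <- function(chain, position) {
  tab <- tryCatch(load_curated_candidates(), error = function(e) NULL)
  if (is.null(tab)) return(NA_character_)
  hit <- tab[tab$chain == chain & tab$position == position, ]
  if (nrow(hit)) hit$weak_aa[1] else NA_character_
}

# Split n as evenly as possible across k donors (first donors get the
# remainder), documented default for the unstated per-donor counts.
donor_split <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Generate a synthetic repertoire library
#'
#' @param config a `synthetic_config`.
#' @return a `repertoire_library` whose clonotypes are globally distinct by
#'   (chain, v_gene, j_gene, cdr3_aa); the generating seed is recorded in
#'   attribute `seed`.
#' @export
generate_library <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config()")
  }
  germline <- config$germline
  pool_chain <- set_chains(germline)[config$v_gene_pool]
  pools <- split(config$v_gene_pool, pool_chain)
  if (is.null(pools$alpha) || is.null(pools$beta)) {
    abort("the gene pool must cover both chains")
  }

  with_seed(config$seed, {
    rows <- list()
    for (phen in PHENOTYPES) {
      counts <- donor_split(config$n_per_phenotype, config$n_donors)
      for (d in seq_len(config$n_donors)) {
        n <- counts[d]
        if (n == 0L) next
        chain <- rep(CHAINS, length.out = n)
        v <- character(n)
        for (ch in CHAINS) {
          idx <- which(chain == ch)
          w <- usage_weights_for(config, phen, pools[[ch]])
          v[idx] <- sample(pools[[ch]], length(idx), replace = TRUE, prob = w)
        }
        j <- ifelse(chain == "alpha",
                    sample(TRAJ_NAMES, n, replace = TRUE),
                    sample(TRBJ_NAMES, n, replace = TRUE))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          donor_id = sprintf("donor%d", d), phenotype = phen,
          chain = chain, v_gene = v, j_gene = j)
      }
    }
    dt <- data.table::rbindlist(rows)
    dt[, cdr3_aa := random_cdr3(.N, config$cdr3_length_range)]
    dt <- ensure_distinct_cdr3(dt, config$cdr3_length_range)
    dt[, abundance := 1L]
    dt[, fw_variants := plant_variants(dt, config)]
    lib <- repertoire_library(dt)
    attr(lib, "seed") <- config$seed
    lib
  })
}

usage_weights_for <- function(config, phenotype, pool) {
  w <- rep(1, length(pool))
  names(w) <- pool
  extra <- config$v_usage_weights[[phenotype]]
  hit <- intersect(names(extra), pool)
  w[hit] <- extra[hit]
  if (any(w < 0) || !any(w > 0)) {
    abort("usage weights must be non-negative with at least one positive entry")
  }
  w
}

random_cdr3 <- function(n, len_range) {
  if (n == 0L) return(character(0))
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  letters <- sample(AA20, sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_len(n), function(i) {
    paste(letters[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

# Resample CDR3s on collision so clonotypes are globally distinct by
# (chain, v_gene, j_gene, cdr3_aa); the discovery unit is the distinct clonotype.
ensure_distinct_cdr3 <- function(dt, len_range) {
  key <- c("chain", "v_gene", "j_gene", "cdr3_aa")
  for (iter in 1:100) {
    dup <- duplicated(dt, by = key)
    if (!any(dup)) return(dt)
    dt[dup, cdr3_aa := random_cdr3(sum(dup), len_range)]
  }
  abort("could not resolve clonotype collisions after 100 resampling rounds")
}

# Sample planted framework variants per clonotype; returns the fw_variants
# annotation column.  Carriage probability is `baseline` in the weak arm and
# the odds-ratio-tilted value in the dominant arm; non-carriers whose
# germline residue already equals the planted amino acid show alt_aa, so the
# marginal carriage equals the configured probabilities exactly.
plant_variants <- function(dt, config) {
  out <- rep("", nrow(dt))
  pe <- config$planted_effects
  if (!nrow(pe)) return(out)
  variants <- vector("list", nrow(dt))
  for (i in seq_len(nrow(pe))) {
    ch <- pe$chain[i]; pos <- as.character(pe$position[i])
    aa <- pe$amino_acid[i]; alt <- pe$alt_aa[i]
    p_weak <- pe$baseline[i]
    odds_dom <- pe$odds_ratio[i] * p_weak / (1 - p_weak)
    p_dom <- odds_dom / (1 + odds_dom)
    idx <- which(dt$chain == ch)
    if (!length(idx)) next
    p <- ifelse(dt$phenotype[idx] == "dominant", p_dom, p_weak)
    carrier <- stats::runif(length(idx)) < p
    germ_res <- vapply(dt$v_gene[idx], function(g) {
      gene_residues(config$germline[[g]])[as.integer(pos)]
    }, character(1))
    shown <- ifelse(carrier, aa, ifelse(germ_res == aa, alt, germ_res))
    differs <- shown != germ_res
    for (k in which(differs)) {
      j <- idx[k]
      variants[[j]] <- c(variants[[j]], setNames(shown[k], pos))
    }
  }
  for (j in seq_along(variants)) {
    if (!is.null(variants[[j]])) out[j] <- format_fw_variants(variants[[j]])
  }
  out
}
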