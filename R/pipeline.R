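# End-to-end orchestration: simulate -> enrich -> select -> design, with a
# JSON manifest recording configuration, seeds, per-stage counts and file
# checksums so a rerun with the same configuration reproduces identical
# outputs.

#' Configure a pipeline run
#'
#' @param out_dir output directory (created if absent).
#' @param synthetic a `synthetic_config` for the simulate stage, or NULL to
#'   read clonotypes from `clonotype_path`.
#' @param clonotype_path existing clonotype TSV (when `synthetic` is NULL).
#' @param germline a `germline_set`.
#' @param mode enrichment mode, "ngs" or "sanger".
#' @param alpha_level candidate-selection significance threshold in (0, 1].
#' @param categories structural categories admitted for candidates.
#' @param design_tcr name of the packaged example TCR to design against
#'   (see [example_tcr()]), or NULL to skip the design stage.
#' @param seed master seed; overrides the synthetic config's seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synthetic = synthetic_config(),
                       clonotype_path = NULL,
                       germline = load_packaged_germline(),
                       mode = c("ngs", "sanger"),
                       alpha_level = 0.05,
                       categories = 1:4,
                       design_tcr = "weak1",
                       seed = 1L) {
  mode <- match.arg(mode)
  if (alpha_level <= 0 || alpha_level > 1) {
    abort("alpha_level must lie in (0, 1]")
  }
  if (is.null(synthetic)) {
    if (is.null(clonotype_path) || !file.exists(clonotype_path)) {
      abort("clonotype_path must name an existing file when synthetic is NULL")
    }
  } else {
    synthetic$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 clonotype_path = clonotype_path, germline = germline,
                 mode = mode, alpha_level = alpha_level,
                 categories = categories, design_tcr = design_tcr,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full discovery-and-design pipeline
#'
#' Stages: (1) simulate a synthetic library or load a clonotype table;
#' (2) positional-enrichment analysis; (3) candidate selection against the
#' structural annotation; (4) substitution design (LRY plan applied to the
#' configured example TCR).  All outputs are TSV/FASTA under `out_dir`,
#' plus `manifest.json`.
#'
#' @param config a `run_config`.
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must come from run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  counts <- list()

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  library <- stage("simulate", {
    if (!is.null(config$synthetic)) {
      lib <- generate_library(config$synthetic)
      paths$clonotypes <- file.path(config$out_dir, "clonotypes.tsv")
      write_clonotype_table(lib, paths$clonotypes)
      lib
    } else {
      read_clonotype_table(config$clonotype_path)
    }
  })
  counts$clonotypes <- nrow(library$clonotypes)
  counts$donors <- length(library$donors)

  results <- stage("enrich", {
    res <- run_enrichment(library, config$germline, mode = config$mode)
    paths$report <- file.path(config$out_dir, "enrichment_report.tsv")
    write_enrichment_report(res, paths$report,
                            annotation = load_structural_annotation())
    res
  })
  counts$pairs_tested <- sum(results$tested)
  counts$pairs_significant <- if (config$mode == "ngs") {
    sum(results$p_adjusted < config$alpha_level, na.rm = TRUE)
  } else {
    sum(results$p[results$tested] < config$alpha_level, na.rm = TRUE)
  }

  candidates <- stage("candidates", {
    cand <- select_candidates(results, alpha_level = config$alpha_level,
                              categories = config$categories)
    paths$candidates <- file.path(config$out_dir, "candidates.tsv")
    write_candidate_table(cand, paths$candidates)
    cand
  })
  counts$candidates <- nrow(candidates)

  if (!is.null(config$design_tcr)) {
    stage("design", {
      tcr <- example_tcr(config$design_tcr, germline = config$germline)
      plan <- build_lry_plan(tcr)
      modified <- apply_plan(tcr, plan)
      paths$design_plan <- file.path(config$out_dir, "design_plan.tsv")
      data.table::fwrite(data.table::as.data.table(plan),
                         paths$design_plan, sep = "\t")
      paths$design_fasta <- file.path(config$out_dir, "design_modified.fasta")
      write_tcr_fasta(modified, paths$design_fasta)
      counts$design_edits <- nrow(plan)
    })
  }

  manifest <- list(
    package = "tcrforge",
    version = as.character(packageVersion("tcrforge")),
    seed = config$seed,
    mode = config$mode,
    alpha_level = config$alpha_level,
    counts = counts,
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
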