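# Orchestration: run the screen-analysis stages end to end from a config
# list, with a machine-readable run manifest and stage logging.

#' Assemble a screen pipeline configuration
#'
#' @param library A `peptide_library` or path to a library TSV.
#' @param input A `count_table` or path to a count TSV (unselected input).
#' @param selected List of `count_table`s or paths (selection replicates).
#' @param domain_label SH2 domain label for the outputs.
#' @param pseudocount Pseudocount used for frequencies; default 1.
#' @param cutoff Either `list(mode = "fixed", value = <x>)` or
#'   `list(mode = "calibrated", max_control_fraction = <f>)`.
#' @param logo_pseudocount Pseudocount for the logo matrix; default 1.
#' @param logo_positions Logo window relative to pTyr; default `-5:5`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(library, input, selected, domain_label,
                            pseudocount = 1,
                            cutoff = list(mode = "fixed", value = 3.2),
                            logo_pseudocount = 1, logo_positions = -5:5,
                            out_dir = "results", seed = 1L) {
  if (!cutoff$mode %in% c("fixed", "calibrated")) {
    stop("cutoff$mode must be 'fixed' or 'calibrated'")
  }
  if (cutoff$mode == "fixed" && is.null(cutoff$value)) {
    stop("fixed cutoff mode needs cutoff$value")
  }
  if (cutoff$mode == "calibrated" && is.null(cutoff$max_control_fraction)) {
    stop("calibrated cutoff mode needs cutoff$max_control_fraction")
  }
  structure(
    list(library = library, input = input, selected = selected,
         domain_label = domain_label, pseudocount = pseudocount,
         cutoff = cutoff, logo_pseudocount = logo_pseudocount,
         logo_positions = logo_positions, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

.log_stage <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

#' Run the screen-analysis pipeline end to end
#'
#' Executes counts -> frequencies -> enrichment -> cutoff -> hits -> logo,
#' writes every table under `cfg$out_dir`, and records a JSON manifest with
#' the tool version, parameters, input checksums, and per-stage row counts.
#' Rerunning with identical inputs and seed reproduces identical outputs.
#'
#' @param cfg A `pipeline_config`.
#' @param quiet Suppress per-stage log lines on standard error.
#' @return The output directory, invisibly; the manifest is
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_screen_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "sh2profiler",
    version = as.character(utils::packageVersion("sh2profiler")),
    seed = cfg$seed,
    parameters = list(pseudocount = cfg$pseudocount, cutoff = cfg$cutoff,
                      logo_pseudocount = cfg$logo_pseudocount,
                      logo_positions = cfg$logo_positions),
    inputs = list(), stages = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lib <- run_stage("library", {
    if (inherits(cfg$library, "peptide_library")) cfg$library else {
      if (!file.exists(cfg$library)) {
        stop("library file not found: ", cfg$library)
      }
      manifest$inputs$library <<- list(
        path = cfg$library, md5 = unname(tools::md5sum(cfg$library)))
      read_peptide_library(cfg$library)
    }
  })
  .log_stage(quiet, "[library] %s: %d entries", lib$name, nrow(lib$entries))
  manifest$stages$library <- list(n_entries = nrow(lib$entries))

  load_counts <- function(x, what) {
    if (inherits(x, "count_table")) return(x)
    if (!file.exists(x)) stop("missing ", what, " count file: ", x)
    manifest$inputs[[what]] <<- list(path = x, md5 = unname(tools::md5sum(x)))
    read_count_table(x, lib)
  }
  input_ct <- run_stage("counts", load_counts(cfg$input, "input"))
  sel_cts <- run_stage("counts", {
    sel <- cfg$selected
    if (!is.list(sel)) sel <- list(sel)
    lapply(seq_along(sel), function(i)
      load_counts(sel[[i]], paste0("selected_rep", i)))
  })
  .log_stage(quiet, "[counts] input %d reads, %d selected replicate(s)",
             input_ct$total_reads, length(sel_cts))
  manifest$stages$counts <- list(input_reads = input_ct$total_reads,
                                 n_replicates = length(sel_cts))

  et <- run_stage("enrichment", {
    fin <- frequencies(input_ct, cfg$pseudocount)
    reps <- lapply(seq_along(sel_cts), function(i) {
      fsel <- frequencies(sel_cts[[i]], cfg$pseudocount)
      enrichment_scores(fin, fsel, domain_label = cfg$domain_label,
                        replicate = paste0("rep", i))
    })
    combine_enrichment(reps, lib = lib, multi_tyr_filter = TRUE)
  })
  write_table(et, file.path(cfg$out_dir, "enrichment.tsv"))
  .log_stage(quiet, "[enrichment] %d peptides x %d replicates",
             nrow(et$scores), ncol(et$scores))
  manifest$stages$enrichment <- list(n_peptides = nrow(et$scores),
                                     n_replicates = ncol(et$scores))

  cutoff <- run_stage("cutoff", {
    if (cfg$cutoff$mode == "fixed") cfg$cutoff$value else
      calibrate_cutoff(et, lib, cfg$cutoff$max_control_fraction)
  })
  hits <- run_stage("hits", call_hits(et, lib, cutoff))
  write_table(hits, file.path(cfg$out_dir, "hits.tsv"))
  .log_stage(quiet, "[hits] cutoff %.4g -> %d hits (control FPR %.3g)",
             cutoff, length(hits$hit_ids), hits$control_fpr_at_cutoff)
  manifest$stages$hits <- list(cutoff = cutoff, n_hits = length(hits$hit_ids),
                               control_fpr = hits$control_fpr_at_cutoff)

  if (length(hits$hit_ids) > 0L) {
    logo <- run_stage("logo",
                      logo_matrix(hits, lib,
                                  pseudocount = cfg$logo_pseudocount,
                                  positions = cfg$logo_positions))
    write_table(logo, file.path(cfg$out_dir, "logo.tsv"))
    .log_stage(quiet, "[logo] %d positions from %d enriched peptides",
               nrow(logo$values), logo$n_enriched)
    manifest$stages$logo <- list(n_positions = nrow(logo$values),
                                 n_enriched = logo$n_enriched)
  } else {
    .log_stage(quiet, "[logo] skipped: empty hit set")
    manifest$stages$logo <- list(skipped = "empty hit set")
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
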