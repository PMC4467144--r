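# Default planted truth for a synthetic end-to-end run: the study's target
# cardinalities (5+6 ETV1-specific, 9+15 ETV4-specific, 8+16 shared, 2
# inverse-overlap), the phenotype regime (81/17/27), and a cohort with the
# seven-gene stage panel, three Gleason-associated genes and two
# subtype-associated genes, against a null background.
default_pipeline_truth <- function(n_genes = 2000) {
  planted_truth(n_genes, roles = c(
    ETV1_target_up = 5, ETV1_target_down = 6,
    ETV4_target_up = 9, ETV4_target_down = 15,
    shared_up = 8, shared_down = 16, inverse = 2,
    invasion_or_aig_assoc = 81, aig_assoc = 17, invasion_assoc = 27,
    stage_low_in_pT3 = 7, gleason_assoc = 3, pea3_up = 2))
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes the analysis stages in order — simulate (or load), association
#' profile, target sets, phenotype sets, cohort associations, panel cut-off
#' scan — writing each stage's report under `out_dir` plus a JSON manifest
#' with the configuration, seed and per-file checksums. A rerun with the same
#' configuration and seed reproduces byte-identical outputs. On stage
#' failure the run aborts naming the failing stage; outputs written so far
#' are retained next to an `INCOMPLETE` marker file.
#'
#' @param out_dir output directory (created if needed).
#' @param config run configuration (see [default_config()]); its `seed`
#'   drives all randomness.
#' @param inputs `"synthetic"` (default), or a named list with paths
#'   `cellline_exprs`, `cohort_exprs`, `cohort_annotations` plus a `models`
#'   list, to run on real data.
#' @param truth planted truth used when `inputs = "synthetic"`.
#' @param panel_genes panel gene ids for the cut-off scan; defaults to the
#'   planted `stage_low_in_pT3` genes for synthetic runs (must be given for
#'   real inputs).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = default_config(),
                         inputs = "synthetic",
                         truth = default_pipeline_truth(),
                         panel_genes = NULL) {
  cfg <- validate_config(config, quiet = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  outputs <- character()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  emit <- function(rel, writer) {
    path <- file.path(out_dir, rel)
    writer(path)
    outputs <<- c(outputs, rel)
    path
  }

  if (identical(inputs, "synthetic")) {
    stage("simulate", {
      expt <- gen_cellline_experiment(truth, seed = cfg$seed)
      cohort <- gen_tumor_cohort(truth, seed = cfg$seed + 1L)
      emit("cellline_expression.tsv",
           function(p) write_expression_matrix(expt$exprs, p))
      emit("cohort_expression.tsv",
           function(p) write_expression_matrix(cohort$exprs, p))
      emit("cohort_annotations.tsv",
           function(p) write_annotations(cohort$annotations, p))
    })
  } else {
    stage("load", {
      for (f in c("cellline_exprs", "cohort_exprs", "cohort_annotations"))
        if (is.character(inputs[[f]]) && !file.exists(inputs[[f]]))
          stop("missing input file: ", inputs[[f]])
      expt <- list(exprs = read_expression_matrix(inputs$cellline_exprs),
                   models = inputs$models)
      cohort <- tumor_cohort(read_expression_matrix(inputs$cohort_exprs),
                             read_annotations(inputs$cohort_annotations))
    })
  }
  if (is.null(panel_genes)) {
    if (!identical(inputs, "synthetic"))
      stop("panel_genes must be given for non-synthetic inputs")
    panel_genes <- planted_genes(truth, "stage_low_in_pT3")
  }

  stage("association_profile", {
    profile <- build_association_profile(expt$models, expt$exprs,
                                         average = cfg$fc_average)
    emit("association_profile.tsv",
         function(p) write_association_profile(profile, p))
  })

  stage("target_sets", {
    target_report <- build_target_report(
      profile, specific_fc = cfg$specific_fc, shared_fc = cfg$shared_fc,
      shared_min_models = cfg$shared_min_models)
    emit("target_sets.tsv",
         function(p) write_gene_set_report(target_report, p))
  })

  stage("phenotype_sets", {
    phenotype_report <- build_phenotype_report(profile, cfg)
    emit("phenotype_sets.tsv",
         function(p) write_gene_set_report(phenotype_report, p))
  })

  stage("cohort_associations", {
    assoc_genes <- sort(unique(c(
      unique(c(target_report$sets$gene, phenotype_report$sets$gene)),
      panel_genes)))
    assoc_genes <- intersect(assoc_genes, rownames(cohort$exprs))
    assoc <- do.call(rbind, lapply(
      c("pT2_vs_pT3", "gleason_low_vs_high"),
      function(gr) cohort_associations(cohort, assoc_genes, gr)))
    emit("cohort_associations.tsv", function(p)
      write.table(assoc, p, sep = "\t", quote = FALSE, row.names = FALSE))
    indep <- do.call(rbind, lapply(
      c("pT2_vs_pT3", "gleason_low_vs_high"), function(gr) {
        ci <- covariate_independence(cohort, gr)
        cbind(grouping = gr, ci$covariates, independent = ci$independent)
      }))
    emit("covariate_independence.tsv", function(p)
      write.table(indep, p, sep = "\t", quote = FALSE, row.names = FALSE))
  })

  stage("panel_scan", {
    scan <- cutoff_scan(cohort, panel_genes,
                        grid = data.frame(q = cfg$panel_percentiles,
                                          k = cfg$panel_k))
    emit("panel_scan.tsv", function(p) write_panel_evaluation(scan$table, p))
  })

  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    inputs = if (identical(inputs, "synthetic")) "synthetic" else "files",
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.remove(marker)
  invisible(manifest)
}
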