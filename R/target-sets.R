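# Threshold comparators. The target rules are quoted as "no less than
# 1.5-fold" (>=); the phenotype rules as "fold-change higher than 1.2/1.5"
# (strict >). Both are honored literally and kept switchable per rule.
fc_meets <- function(fc, threshold, cmp = c(">=", ">")) {
  cmp <- match.arg(cmp)
  ok <- if (cmp == ">=") abs(fc) >= threshold else abs(fc) > threshold
  !is.na(fc) & ok
}

# The two silencing models per ETS used by the specific-target rule.
specific_models_for <- function(ets) {
  switch(ets,
         ETV1 = c(MODEL_SHETV1_LNCAP, MODEL_SHETV1_MDA),
         ETV4 = c(MODEL_SHETV4_MDA, MODEL_SHETV4_PC3),
         stop("unknown ETS: ", ets))
}

#' ETS-specific candidate target genes
#'
#' Genes up- or down-regulated by at least `threshold`-fold, in association
#' direction, in both silencing models of one ETS (LNCaP and MDA-PCa-2b for
#' ETV1; PC3 and MDA-PCa-2b for ETV4). Undefined profile entries (clone
#' disagreement) disqualify a gene.
#'
#' @param profile association profile matrix (genes x models), association
#'   direction (positive = rises with ETS expression).
#' @param ets `"ETV1"` or `"ETV4"`.
#' @param models_for_ets the two silencing-model column names to use; defaults
#'   to the study design for `ets`.
#' @param threshold linear fold-change cut, default 1.5.
#' @param cmp comparator, default `">="` ("no less than").
#' @return list with character vectors `up` and `down`.
#' @export
specific_targets <- function(profile, ets = c("ETV1", "ETV4"),
                             models_for_ets = specific_models_for(ets),
                             threshold = 1.5, cmp = ">=") {
  ets <- match.arg(ets)
  if (length(models_for_ets) != 2)
    stop("the specific-target rule uses exactly the two silencing models of ",
         ets, "; got ", length(models_for_ets))
  missing <- setdiff(models_for_ets, colnames(profile))
  if (length(missing))
    stop("model(s) absent from profile: ", paste(missing, collapse = ", "))
  p <- profile[, models_for_ets, drop = FALSE]
  up   <- rowSums(fc_meets(p, threshold, cmp) & !is.na(p) & p > 0) == 2
  down <- rowSums(fc_meets(p, threshold, cmp) & !is.na(p) & p < 0) == 2
  list(up = rownames(profile)[up], down = rownames(profile)[down])
}

#' ETS-shared candidate target genes
#'
#' Genes up- or down-regulated by at least `threshold`-fold, in association
#' direction, in at least `min_models` of the four silencing models. A gene
#' meeting both the up and the down rule (possible only for
#' `min_models <= 2`) is reported in neither set and announced via a message.
#'
#' @param profile association profile matrix.
#' @param silencing_models the four silencing-model column names.
#' @param threshold linear fold-change cut, default 1.5.
#' @param min_models minimum qualifying models, default 3.
#' @param cmp comparator, default `">="`.
#' @return list with character vectors `up` and `down`.
#' @export
shared_targets <- function(profile,
                           silencing_models = study_model_names(silencing_only = TRUE),
                           threshold = 1.5, min_models = 3, cmp = ">=") {
  if (length(silencing_models) != 4)
    stop("the shared-target rule uses exactly four silencing models")
  if (min_models > length(silencing_models))
    stop("min_models exceeds the number of models")
  missing <- setdiff(silencing_models, colnames(profile))
  if (length(missing))
    stop("model(s) absent from profile: ", paste(missing, collapse = ", "))
  p <- profile[, silencing_models, drop = FALSE]
  hit <- fc_meets(p, threshold, cmp)
  up   <- rowSums(hit & !is.na(p) & p > 0) >= min_models
  down <- rowSums(hit & !is.na(p) & p < 0) >= min_models
  both <- up & down
  if (any(both)) {
    message("gene(s) qualifying as both shared-up and shared-down dropped: ",
            paste(rownames(profile)[both], collapse = ", "))
    up[both] <- down[both] <- FALSE
  }
  list(up = rownames(profile)[up], down = rownames(profile)[down])
}

#' Assemble the ETS target-gene report
#'
#' Runs the ETV1-specific, ETV4-specific and shared rules over the silencing
#' models of an association profile and assembles the Venn bookkeeping.
#' The rules are computed independently; a gene present in both specific
#' lists with opposite directions is flagged `"inverse"` (the TLL1/PYGO1
#' behaviour) and retained in both. For the headline (Venn-region) sets, a
#' gene that meets the shared rule is classed as shared and removed from the
#' specific lists, so the inclusion-exclusion identity
#' `union = |ETV1| + |ETV4| + |shared| - |inverse|` holds exactly; the raw
#' rule outputs are retained under `raw`. The targeted ETS genes themselves
#' are excluded from all candidate sets, and the overexpression model is not
#' used for target filtering.
#'
#' @param profile association profile over (at least) the four silencing
#'   models.
#' @param specific_fc,shared_fc fold-change cuts, default 1.5.
#' @param shared_min_models default 3.
#' @param cmp comparator for both rules, default `">="`.
#' @param exclude_genes gene ids never reported as their own targets,
#'   default `c("ETV1", "ETV4")`.
#' @return object of class `"gene_set_report"`: data.frame `sets` (gene,
#'   direction, provenance), `raw` rule outputs, `inverse` gene ids,
#'   `summary` cardinalities, and the profile rows of reported genes.
#' @export
build_target_report <- function(profile, specific_fc = 1.5, shared_fc = 1.5,
                                shared_min_models = 3, cmp = ">=",
                                exclude_genes = c("ETV1", "ETV4")) {
  keep <- setdiff(rownames(profile), exclude_genes)
  prof <- profile[keep, , drop = FALSE]
  etv1 <- specific_targets(prof, "ETV1", threshold = specific_fc, cmp = cmp)
  etv4 <- specific_targets(prof, "ETV4", threshold = specific_fc, cmp = cmp)
  shared <- shared_targets(prof, threshold = shared_fc,
                           min_models = shared_min_models, cmp = cmp)
  raw <- list(ETV1_specific = etv1, ETV4_specific = etv4, shared = shared)
  shared_all <- c(shared$up, shared$down)
  venn <- list(
    ETV1_specific = lapply(etv1, setdiff, shared_all),
    ETV4_specific = lapply(etv4, setdiff, shared_all),
    shared = shared
  )
  inverse <- sort(union(
    intersect(venn$ETV1_specific$up, venn$ETV4_specific$down),
    intersect(venn$ETV1_specific$down, venn$ETV4_specific$up)))
  same_dir_overlap <- sort(union(
    intersect(venn$ETV1_specific$up, venn$ETV4_specific$up),
    intersect(venn$ETV1_specific$down, venn$ETV4_specific$down)))
  sets <- do.call(rbind, lapply(names(venn), function(prov) {
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      g <- venn[[prov]][[dir]]
      if (!length(g)) return(NULL)
      data.frame(gene = g, direction = dir, provenance = prov,
                 stringsAsFactors = FALSE)
    }))
  }))
  report <- new_gene_set_report(sets, prof, kind = "target")
  report$raw <- raw
  report$inverse <- inverse
  report$same_direction_overlap <- same_dir_overlap
  report$summary <- c(
    ETV1_specific = length(venn$ETV1_specific$up) + length(venn$ETV1_specific$down),
    ETV4_specific = length(venn$ETV4_specific$up) + length(venn$ETV4_specific$down),
    shared = length(shared$up) + length(shared$down),
    inverse_overlap = length(inverse),
    union = length(unique(report$sets$gene))
  )
  report
}

# Shared constructor for target and phenotype reports.
new_gene_set_report <- function(sets, profile, kind) {
  if (is.null(sets))
    sets <- data.frame(gene = character(), direction = character(),
                       provenance = character(), stringsAsFactors = FALSE)
  sets <- sets[order(sets$provenance, sets$direction, sets$gene), , drop = FALSE]
  rownames(sets) <- NULL
  dup <- duplicated(sets[, c("gene", "provenance")])
  if (any(dup))
    stop("a gene may appear in only one direction per provenance: ",
         paste(unique(sets$gene[dup]), collapse = ", "))
  genes <- unique(sets$gene)
  structure(list(sets = sets,
                 profile = profile[genes, , drop = FALSE],
                 kind = kind),
            class = "gene_set_report")
}

#' @export
print.gene_set_report <- function(x, ...) {
  cat(sprintf("gene set report (%s): %d genes in %d set entries\n",
              x$kind, length(unique(x$sets$gene)), nrow(x$sets)))
  print(x$summary)
  invisible(x)
}
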