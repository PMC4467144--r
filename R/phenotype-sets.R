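# Shared include/exclude predicate on the association-direction axis.
# A gene qualifies when it has the same differential direction with
# |FC| > include_fc (strict, "higher than") in all include models, and is NOT
# excluded; exclusion fires when the gene shows the SAME direction with
# |FC| > exclude_fc in all exclude models ("in both" for two exclude models).
# Undefined (NA) entries disqualify on the include side and do not fire on
# the exclude side (a clone-disagreeing gene is not consistently
# differentially expressed there).
include_exclude_sets <- function(profile, include_models, exclude_models,
                                 include_fc, exclude_fc) {
  missing <- setdiff(c(include_models, exclude_models), colnames(profile))
  if (length(missing))
    stop("model(s) absent from profile: ", paste(missing, collapse = ", "))
  inc <- profile[, include_models, drop = FALSE]
  exc <- profile[, exclude_models, drop = FALSE]
  n_inc <- length(include_models)
  res <- lapply(c(up = 1, down = -1), function(s) {
    ok <- rowSums(fc_meets(inc, include_fc, ">") & !is.na(inc) & s * inc > 0) == n_inc
    excluded <- rowSums(fc_meets(exc, exclude_fc, ">") & !is.na(exc) & s * exc > 0) ==
      length(exclude_models)
    rownames(profile)[ok & !excluded]
  })
  res
}

#' Invasion- and/or AIG-associated genes
#'
#' Genes showing the same differential expression profile (|FC| > 1.2,
#' association direction) in the three models with impact on both invasion
#' and anchorage-independent growth (shETV4-PC3, shETV1-LNCaP, PNT2-ETV1),
#' excluding genes differentially expressed in the same direction
#' (|FC| > 1.2) in the model with no impact on either phenotype
#' (shETV1-MDA-PCa-2b).
#'
#' @param profile association profile over the five study models.
#' @param include_models,exclude_model model column names (study defaults).
#' @param include_fc,exclude_fc strict fold-change cuts, both default 1.2.
#' @return list with character vectors `up` and `down`.
#' @export
invasion_or_aig_genes <- function(profile,
                                  include_models = c(MODEL_SHETV4_PC3,
                                                     MODEL_SHETV1_LNCAP,
                                                     MODEL_PNT2_ETV1),
                                  exclude_model = MODEL_SHETV1_MDA,
                                  include_fc = 1.2, exclude_fc = 1.2) {
  include_exclude_sets(profile, include_models, exclude_model,
                       include_fc, exclude_fc)
}

#' AIG-associated genes
#'
#' Genes differentially expressed (|FC| > 1.5, association direction) in the
#' shETV4 populations of both MDA-PCa-2b and PC3, excluding genes with the
#' same differential direction (|FC| > 1.2) in the shETV1 populations of
#' MDA-PCa-2b.
#'
#' @inheritParams invasion_or_aig_genes
#' @param include_fc default 1.5.
#' @param exclude_fc default 1.2.
#' @return list with character vectors `up` and `down`.
#' @export
aig_genes <- function(profile,
                      include_models = c(MODEL_SHETV4_MDA, MODEL_SHETV4_PC3),
                      exclude_model = MODEL_SHETV1_MDA,
                      include_fc = 1.5, exclude_fc = 1.2) {
  include_exclude_sets(profile, include_models, exclude_model,
                       include_fc, exclude_fc)
}

#' Invasion-associated genes
#'
#' Genes differentially expressed (|FC| > 1.5, association direction) in both
#' shETV1-LNCaP and PNT2-ETV1, excluding genes with the same differential
#' direction (|FC| > 1.2) in BOTH the shETV4 and shETV1 populations of
#' MDA-PCa-2b (exclusion requires both models to fire).
#'
#' @inheritParams invasion_or_aig_genes
#' @param exclude_models two model column names (study default: the two
#'   MDA-PCa-2b silencing models).
#' @param include_fc default 1.5.
#' @param exclude_fc default 1.2.
#' @return list with character vectors `up` and `down`.
#' @export
invasion_genes <- function(profile,
                           include_models = c(MODEL_SHETV1_LNCAP,
                                              MODEL_PNT2_ETV1),
                           exclude_models = c(MODEL_SHETV4_MDA,
                                              MODEL_SHETV1_MDA),
                           include_fc = 1.5, exclude_fc = 1.2) {
  include_exclude_sets(profile, include_models, exclude_models,
                       include_fc, exclude_fc)
}

#' Assemble the phenotype-associated gene report
#'
#' Runs the invasion-and/or-AIG, AIG and invasion rules over the five-model
#' association profile. The three rules are computed independently (their
#' containment relations are not enforced); overlaps between the sets are
#' reported in the summary.
#'
#' @param profile association profile over the five study models.
#' @param config run configuration supplying the per-rule cuts
#'   (see [default_config()]).
#' @return object of class `"gene_set_report"` with provenances
#'   `invasion_or_aig`, `aig`, `invasion`.
#' @export
build_phenotype_report <- function(profile, config = default_config()) {
  cfg <- validate_config(config, quiet = TRUE)
  rules <- list(
    invasion_or_aig = invasion_or_aig_genes(profile,
                                            include_fc = cfg$inv_aig_include_fc,
                                            exclude_fc = cfg$inv_aig_exclude_fc),
    aig = aig_genes(profile, include_fc = cfg$aig_include_fc,
                    exclude_fc = cfg$aig_exclude_fc),
    invasion = invasion_genes(profile, include_fc = cfg$invasion_include_fc,
                              exclude_fc = cfg$invasion_exclude_fc)
  )
  sets <- do.call(rbind, lapply(names(rules), function(prov) {
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      g <- rules[[prov]][[dir]]
      if (!length(g)) return(NULL)
      data.frame(gene = g, direction = dir, provenance = prov,
                 stringsAsFactors = FALSE)
    }))
  }))
  report <- new_gene_set_report(sets, profile, kind = "phenotype")
  flat <- lapply(rules, function(r) c(r$up, r$down))
  report$summary <- c(
    invasion_or_aig = length(flat$invasion_or_aig),
    aig = length(flat$aig),
    invasion = length(flat$invasion),
    aig_in_union = length(intersect(flat$aig, flat$invasion_or_aig)),
    invasion_in_union = length(intersect(flat$invasion, flat$invasion_or_aig)),
    aig_invasion_overlap = length(intersect(flat$aig, flat$invasion)),
    union = length(unique(unlist(flat)))
  )
  report
}
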