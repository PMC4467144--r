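#' Construct a tumour cohort
#'
#' Bundles an expression matrix with a per-sample annotation table whose rows
#' match the matrix columns exactly (same ids, same order).
#'
#' @param exprs expression matrix (log2), genes x samples.
#' @param annotations data.frame passing [validate_annotations()], one row
#'   per matrix column.
#' @return object of class `"tumor_cohort"`.
#' @export
tumor_cohort <- function(exprs, annotations) {
  validate_expression_matrix(exprs)
  validate_annotations(annotations)
  if (!identical(annotations$sample_id, colnames(exprs)))
    stop("annotation rows must match expression sample ids (same order)")
  structure(list(exprs = exprs, annotations = annotations),
            class = "tumor_cohort")
}

#' @export
print.tumor_cohort <- function(x, ...) {
  tab <- table(x$annotations$tissue)
  cat(sprintf("tumor cohort: %d genes x %d samples (%s)\n",
              nrow(x$exprs), ncol(x$exprs),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. In `"auto"` mode the
#' exact distribution is used when `min(nA, nB) <= 8` and the data are
#' tie-free; otherwise the normal approximation with tie correction (and
#' continuity correction) is used. The U statistic reported is the number of
#' (a, b) pairs with a > b, so `U_A + U_B = nA * nB`.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`. `"exact"` with ties falls
#'   back to the approximation (the exact distribution assumes no ties).
#' @return list `U`, `p`, `n_a`, `n_b`, `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- switch(mode,
                  auto = min(length(group_a), length(group_b)) <= 8 && !ties,
                  exact = !ties,
                  approx = FALSE)
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = min(1, ht$p.value),
       n_a = length(group_a), n_b = length(group_b), exact = exact)
}

significance_tier <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

cohort_gene_values <- function(cohort, gene, idx) {
  if (!gene %in% rownames(cohort$exprs))
    stop("gene '", gene, "' absent from cohort expression")
  cohort$exprs[gene, idx]
}

# Mann-Whitney association record between two annotated sample groups.
association_record <- function(cohort, gene, idx_a, idx_b, label_a, label_b,
                               contrast) {
  if (sum(idx_a) < 2 || sum(idx_b) < 2)
    stop(sprintf("contrast '%s' needs >= 2 samples per group (got %d vs %d)",
                 contrast, sum(idx_a), sum(idx_b)))
  a <- cohort_gene_values(cohort, gene, idx_a)
  b <- cohort_gene_values(cohort, gene, idx_b)
  mw <- mann_whitney(a, b)
  dmed <- median(a) - median(b)
  data.frame(gene = gene, contrast = contrast,
             group_a = label_a, group_b = label_b,
             n_a = mw$n_a, n_b = mw$n_b,
             direction = if (dmed > 0) "up" else if (dmed < 0) "down" else "none",
             U = mw$U, p = mw$p,
             significant = mw$p < 0.05,
             tier = significance_tier(mw$p),
             stringsAsFactors = FALSE)
}

#' ETS-subtype association of a gene's expression
#'
#' Mann-Whitney comparison of one gene's expression between two annotated
#' cohort groups: PEA3-positive versus ETS-negative carcinomas, PEA3-positive
#' versus ERG-positive carcinomas, or all carcinomas versus normal prostate
#' tissue. Direction is the sign of the median difference (first group minus
#' second); significance tiers at p < 0.05 / 0.01 / 0.001.
#'
#' @param cohort a [tumor_cohort()].
#' @param gene gene id.
#' @param contrast `"PEA3_vs_ETSneg"`, `"PEA3_vs_ERG"` or `"PCa_vs_NPT"`.
#' @return one-row data.frame association record.
#' @export
subtype_association <- function(cohort, gene,
                                contrast = c("PEA3_vs_ETSneg", "PEA3_vs_ERG",
                                             "PCa_vs_NPT")) {
  contrast <- match.arg(contrast)
  an <- cohort$annotations
  pca <- an$tissue == "PCa"
  grp <- switch(contrast,
    PEA3_vs_ETSneg = list(a = pca & !is.na(an$subtype) & an$subtype == "PEA3",
                          b = pca & !is.na(an$subtype) & an$subtype == "ETS_negative",
                          la = "PEA3", lb = "ETS_negative"),
    PEA3_vs_ERG    = list(a = pca & !is.na(an$subtype) & an$subtype == "PEA3",
                          b = pca & !is.na(an$subtype) & an$subtype == "ERG",
                          la = "PEA3", lb = "ERG"),
    PCa_vs_NPT     = list(a = pca, b = an$tissue == "NPT",
                          la = "PCa", lb = "NPT"))
  association_record(cohort, gene, grp$a, grp$b, grp$la, grp$lb, contrast)
}

#' Clinico-pathological association of a gene's expression
#'
#' Mann-Whitney comparison between Gleason groups (low = GS <= 7(3+4) versus
#' high = GS >= 7(4+3)) or pathological stages (organ-confined pT2 versus
#' locally invasive pT3), carcinomas only; samples with a missing grouping
#' value are dropped from the comparison. The record flags the gene as
#' increased or decreased in the higher-risk group when p < 0.05.
#'
#' @param cohort a [tumor_cohort()].
#' @param gene gene id.
#' @param grouping `"gleason_low_vs_high"` or `"pT2_vs_pT3"`.
#' @return one-row data.frame with a `flag` column, e.g. `"decreased in pT3"`.
#' @export
clinico_path_association <- function(cohort, gene,
                                     grouping = c("pT2_vs_pT3",
                                                  "gleason_low_vs_high")) {
  grouping <- match.arg(grouping)
  an <- cohort$annotations
  pca <- an$tissue == "PCa"
  if (grouping == "pT2_vs_pT3") {
    if (all(is.na(an$stage[pca]))) stop("stage is NA for all carcinomas")
    idx_hi <- pca & !is.na(an$stage) & an$stage == "pT3"
    idx_lo <- pca & !is.na(an$stage) & an$stage == "pT2"
    hi_label <- "pT3"
  } else {
    if (all(is.na(an$gleason_group[pca])))
      stop("gleason_group is NA for all carcinomas")
    idx_hi <- pca & !is.na(an$gleason_group) & an$gleason_group == "high"
    idx_lo <- pca & !is.na(an$gleason_group) & an$gleason_group == "low"
    hi_label <- "high Gleason"
  }
  rec <- association_record(cohort, gene, idx_hi, idx_lo, hi_label,
                            if (grouping == "pT2_vs_pT3") "pT2" else "low Gleason",
                            grouping)
  rec$flag <- if (!rec$significant) "" else
    paste(if (rec$direction == "up") "increased" else "decreased",
          "in", hi_label)
  rec
}

#' Covariate independence report for a cohort grouping
#'
#' Mann-Whitney comparison of age and PSA at diagnosis between the two
#' classes of a clinico-pathological grouping. Independence is declared when
#' every assessable covariate has p >= 0.05. This accompanies gene
#' association records and never gates them; it is an operational reading of
#' "independent of age and PSA", not a stratified or regression adjustment.
#'
#' @param cohort a [tumor_cohort()].
#' @param grouping as in [clinico_path_association()].
#' @return list with data.frame `covariates` (covariate, n_a, n_b, p,
#'   assessable) and logical `independent`.
#' @export
covariate_independence <- function(cohort,
                                   grouping = c("pT2_vs_pT3",
                                                "gleason_low_vs_high")) {
  grouping <- match.arg(grouping)
  an <- cohort$annotations
  pca <- an$tissue == "PCa"
  col <- if (grouping == "pT2_vs_pT3") "stage" else "gleason_group"
  lv <- if (grouping == "pT2_vs_pT3") c("pT3", "pT2") else c("high", "low")
  idx_a <- pca & !is.na(an[[col]]) & an[[col]] == lv[1]
  idx_b <- pca & !is.na(an[[col]]) & an[[col]] == lv[2]
  rows <- lapply(c("age_years", "psa_ng_ml"), function(cov) {
    va <- an[[cov]][idx_a]; vb <- an[[cov]][idx_b]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    assessable <- length(va) >= 2 && length(vb) >= 2
    p <- if (assessable) mann_whitney(va, vb)$p else NA_real_
    data.frame(covariate = cov, n_a = length(va), n_b = length(vb),
               p = p, assessable = assessable, stringsAsFactors = FALSE)
  })
  covariates <- do.call(rbind, rows)
  assessed <- covariates$p[covariates$assessable]
  list(covariates = covariates,
       independent = length(assessed) > 0 && all(assessed >= 0.05))
}

#' Association records for many genes
#'
#' Convenience wrapper applying [subtype_association()] or
#' [clinico_path_association()] over a gene vector. No multiple-testing
#' correction is applied (raw p-values are compared with 0.05); a
#' Benjamini-Hochberg adjusted column can be added with `adjust = TRUE`.
#'
#' @param cohort a [tumor_cohort()].
#' @param genes character vector of gene ids.
#' @param contrast a subtype contrast or clinico-pathological grouping name.
#' @param adjust logical; append `p_adj` (Benjamini-Hochberg).
#' @return data.frame, one row per gene.
#' @export
cohort_associations <- function(cohort, genes, contrast, adjust = FALSE) {
  fun <- if (contrast %in% c("pT2_vs_pT3", "gleason_low_vs_high"))
    clinico_path_association else subtype_association
  out <- do.call(rbind, lapply(genes, function(g) fun(cohort, g, contrast)))
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
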