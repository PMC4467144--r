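# Planted-truth role vocabulary. Cell-line roles place association-direction
# effects in the models where the gene's ETS association applies; cohort
# roles place group-mean shifts in the tumour cohort. "inverse" mimics the
# TLL1/PYGO1 behaviour: up-regulated with ETV1, down-regulated with ETV4.
TRUTH_ROLES <- c(
  "null",
  "ETV1_target_up", "ETV1_target_down",
  "ETV4_target_up", "ETV4_target_down",
  "shared_up", "shared_down", "inverse",
  "invasion_or_aig_assoc", "aig_assoc", "invasion_assoc",
  "stage_low_in_pT3", "stage_high_in_pT3", "gleason_assoc", "pea3_up"
)

# Association-direction sign of each role in each of the five models.
role_model_signs <- function(role) {
  m <- study_model_names()
  s <- stats::setNames(numeric(5), m)
  switch(role,
    ETV1_target_up   = { s[c(MODEL_SHETV1_LNCAP, MODEL_SHETV1_MDA, MODEL_PNT2_ETV1)] <- 1 },
    ETV1_target_down = { s[c(MODEL_SHETV1_LNCAP, MODEL_SHETV1_MDA, MODEL_PNT2_ETV1)] <- -1 },
    ETV4_target_up   = { s[c(MODEL_SHETV4_MDA, MODEL_SHETV4_PC3)] <- 1 },
    ETV4_target_down = { s[c(MODEL_SHETV4_MDA, MODEL_SHETV4_PC3)] <- -1 },
    shared_up        = { s[m] <- 1 },
    shared_down      = { s[m] <- -1 },
    inverse          = { s[c(MODEL_SHETV1_LNCAP, MODEL_SHETV1_MDA, MODEL_PNT2_ETV1)] <- 1
                         s[c(MODEL_SHETV4_MDA, MODEL_SHETV4_PC3)] <- -1 },
    invasion_or_aig_assoc = { s[c(MODEL_SHETV4_PC3, MODEL_SHETV1_LNCAP, MODEL_PNT2_ETV1)] <- 1 },
    aig_assoc        = { s[c(MODEL_SHETV4_MDA, MODEL_SHETV4_PC3)] <- 1 },
    invasion_assoc   = { s[c(MODEL_SHETV1_LNCAP, MODEL_PNT2_ETV1)] <- 1 },
    NULL)
  s
}

#' Define planted ground truth for the synthetic generators
#'
#' Assigns a role to every gene: planted cell-line target/phenotype genes,
#' planted cohort-associated genes, or `"null"` (pure noise). Roles partition
#' the genes; role-bearing genes come first (grouped by role, in the order
#' given), null genes fill the remainder.
#'
#' @param n_genes total number of genes (>= sum of planted counts).
#' @param roles named integer vector of planted gene counts per role, e.g.
#'   `c(shared_up = 8, shared_down = 16)`. May be empty.
#' @param lfc planted effect size in |log2 fold-change| units (default 1.0,
#'   i.e. 2-fold on the linear scale).
#' @param weak_lfc planted |log2FC| for the `invasion_or_aig_assoc` role
#'   (default `log2(1.35)`). The broad invasion-and/or-AIG rule exists to
#'   catch weak but concordant changes, so its planted effect sits inside
#'   the (1.2, 1.5] linear band: above the 1.2 inclusion cut, below the 1.5
#'   cut of the stricter single-phenotype rules.
#' @param noise_sd per-gene, per-sample Gaussian noise sd in log2 units
#'   (default 0.1).
#' @return object of class `"planted_truth"`: data.frame `genes` (gene_id,
#'   role) plus `lfc`, `weak_lfc` and `noise_sd`.
#' @export
planted_truth <- function(n_genes, roles = integer(), lfc = 1.0,
                          weak_lfc = log2(1.35), noise_sd = 0.1) {
  if (length(roles)) {
    bad <- setdiff(names(roles), TRUTH_ROLES)
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
    if (any(roles < 0)) stop("role counts must be non-negative")
  }
  n_planted <- sum(roles)
  if (n_genes < n_planted)
    stop("n_genes (", n_genes, ") smaller than planted gene count (",
         n_planted, ")")
  if (lfc < 0 || weak_lfc < 0) stop("planted |log2FC| must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  role_vec <- c(rep(names(roles), times = roles),
                rep("null", n_genes - n_planted))
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      role = role_vec, stringsAsFactors = FALSE)
  structure(list(genes = genes, lfc = lfc, weak_lfc = weak_lfc,
                 noise_sd = noise_sd),
            class = "planted_truth")
}

# Planted |log2FC| per gene, by role.
role_lfc <- function(truth, roles) {
  ifelse(roles == "invasion_or_aig_assoc", truth$weak_lfc, truth$lfc)
}

#' Gene ids carrying a planted role
#'
#' @param truth a [planted_truth()].
#' @param role one of the defined role labels.
#' @return character vector of gene ids.
#' @export
planted_genes <- function(truth, role) {
  if (!role %in% TRUTH_ROLES) stop("unknown role: ", role)
  truth$genes$gene_id[truth$genes$role == role]
}

# Build the five study models with generated sample ids.
build_study_models <- function(n_reps = 1) {
  sid <- function(model, pop, n_reps) {
    base <- paste0(model, ".", pop)
    if (n_reps == 1) base else paste0(base, ".r", seq_len(n_reps))
  }
  mk <- function(name, ets, kind, n_manip) {
    cell_line_model(
      name, ets, kind,
      control = population("control", sid(name, "ctrl", n_reps), "control"),
      manipulated = lapply(seq_len(n_manip), function(i)
        population(paste0("manip", i), sid(name, paste0("m", i), n_reps),
                   "manipulated")))
  }
  list(mk(MODEL_SHETV1_LNCAP, "ETV1", "silencing", 2),
       mk(MODEL_SHETV1_MDA,   "ETV1", "silencing", 2),
       mk(MODEL_SHETV4_MDA,   "ETV4", "silencing", 2),
       mk(MODEL_SHETV4_PC3,   "ETV4", "silencing", 2),
       mk(MODEL_PNT2_ETV1,    "ETV1", "overexpression", 2))
}

#' Simulate the five-model cell-line experiment
#'
#' Generates a log2 expression matrix for the study design: four silencing
#' models with two manipulated populations each, plus the PNT2 ETV1
#' overexpression model with two independent overexpressing populations, each
#' model with its own control. Planted genes shift by the truth's |log2FC| in
#' the association direction of their role in every model where their ETS
#' association applies; on the observed (manipulated-vs-control) axis the
#' shift sign is inverted in silencing models. Null genes are i.i.d. Gaussian
#' noise around their per-gene baseline. Deterministic given `seed`.
#'
#' @param truth a [planted_truth()].
#' @param seed integer seed (required; reproducibility contract).
#' @param n_reps replicate array columns per population (study design: 1).
#' @return list `exprs` (matrix), `models` (list of [cell_line_model()]),
#'   `truth`.
#' @export
gen_cellline_experiment <- function(truth, seed, n_reps = 1) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (!inherits(truth, "planted_truth")) stop("'truth' must be a planted_truth")
  models <- build_study_models(n_reps)
  gene_ids <- truth$genes$gene_id
  withr::with_seed(as.integer(seed), {
    baseline <- rnorm(length(gene_ids), mean = 8, sd = 1)
    cols <- list()
    for (m in models) {
      kind_mult <- if (m$kind == "silencing") -1 else 1
      signs <- vapply(truth$genes$role,
                      function(r) role_model_signs(r)[m$name], numeric(1))
      shift <- signs * role_lfc(truth, truth$genes$role) * kind_mult
      for (s in m$control$sample_ids)
        cols[[s]] <- baseline + rnorm(length(gene_ids), 0, truth$noise_sd)
      for (p in m$manipulated)
        for (s in p$sample_ids)
          cols[[s]] <- baseline + shift +
            rnorm(length(gene_ids), 0, truth$noise_sd)
    }
    exprs <- do.call(cbind, cols)
  })
  dimnames(exprs) <- list(gene_ids, names(cols))
  list(exprs = exprs, models = models, truth = truth)
}

#' Simulate the ETS-subtyped tumour cohort
#'
#' Generates 9 normal prostate tissues (NPT) plus 50 carcinomas with subtype
#' counts 14 PEA3 (12 ETV1, 1 ETV4, 1 ETV5 rearranged), 22 ERG and 14
#' ETS-negative, following the study's cohort composition. Stage and Gleason
#' labels are drawn with configurable prevalence (default 24 pT3 / 26 pT2 and
#' 25 high / 25 low Gleason among carcinomas); age and PSA are independent of
#' stage by construction unless a shift is requested. Cohort roles of the
#' planted truth shift group means: `stage_low_in_pT3` down by the planted
#' log2FC in pT3 carcinomas, `stage_high_in_pT3` up, `gleason_assoc` down in
#' high-Gleason carcinomas, `pea3_up` up in PEA3 carcinomas.
#'
#' @param truth a [planted_truth()].
#' @param seed integer seed (required).
#' @param n_npt normal tissue count (default 9).
#' @param subtype_counts named counts for PEA3/ERG/ETS_negative; must sum to
#'   `n_pca`.
#' @param n_pca carcinoma count (default 50).
#' @param pea3_gene_counts named counts of the rearranged PEA3 gene among
#'   PEA3 tumours; must sum to the PEA3 count.
#' @param n_pt3 pT3 carcinomas (default 24).
#' @param n_gleason_high high-Gleason carcinomas (default 25).
#' @param age_shift_pt3,psa_shift_pt3 additive shifts applied to age (years)
#'   and PSA (ng/ml) of pT3 tumours; default 0 (covariates independent of
#'   stage).
#' @return a [tumor_cohort()] with the truth attached as attribute `"truth"`.
#' @export
gen_tumor_cohort <- function(truth, seed, n_npt = 9,
                             subtype_counts = c(PEA3 = 14, ERG = 22,
                                                ETS_negative = 14),
                             n_pca = 50,
                             pea3_gene_counts = c(ETV1 = 12, ETV4 = 1,
                                                  ETV5 = 1),
                             n_pt3 = 24, n_gleason_high = 25,
                             age_shift_pt3 = 0, psa_shift_pt3 = 0) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (!inherits(truth, "planted_truth")) stop("'truth' must be a planted_truth")
  if (sum(subtype_counts) != n_pca)
    stop("subtype counts sum to ", sum(subtype_counts), ", expected n_pca = ",
         n_pca)
  if (sum(pea3_gene_counts) != subtype_counts[["PEA3"]])
    stop("pea3_gene_counts must sum to the PEA3 subtype count")
  if (n_pt3 > n_pca || n_gleason_high > n_pca)
    stop("n_pt3 and n_gleason_high cannot exceed n_pca")
  gene_ids <- truth$genes$gene_id
  sample_ids <- c(sprintf("NPT%02d", seq_len(n_npt)),
                  sprintf("PCa%02d", seq_len(n_pca)))
  is_pca <- c(rep(FALSE, n_npt), rep(TRUE, n_pca))
  withr::with_seed(as.integer(seed), {
    subtype <- sample(rep(names(subtype_counts), times = subtype_counts))
    pea3_gene <- rep(NA_character_, n_pca)
    pea3_gene[subtype == "PEA3"] <-
      sample(rep(names(pea3_gene_counts), times = pea3_gene_counts))
    stage <- sample(c(rep("pT3", n_pt3), rep("pT2", n_pca - n_pt3)))
    gleason <- sample(c(rep("high", n_gleason_high),
                        rep("low", n_pca - n_gleason_high)))
    age <- round(rnorm(n_npt + n_pca, mean = 63, sd = 7))
    psa <- round(rlnorm(n_npt + n_pca, meanlog = log(8), sdlog = 0.4), 1)
    if (age_shift_pt3 != 0 || psa_shift_pt3 != 0) {
      pt3_idx <- which(is_pca)[stage == "pT3"]
      age[pt3_idx] <- age[pt3_idx] + age_shift_pt3
      psa[pt3_idx] <- psa[pt3_idx] + psa_shift_pt3
    }
    baseline <- rnorm(length(gene_ids), mean = 8, sd = 1)
    exprs <- baseline +
      base::matrix(rnorm(length(gene_ids) * length(sample_ids), 0,
                         truth$noise_sd),
                   nrow = length(gene_ids))
    shift_group <- function(role, sample_idx, sign) {
      g <- which(truth$genes$role == role)
      if (length(g) && length(sample_idx))
        exprs[g, sample_idx] <<- exprs[g, sample_idx] + sign * truth$lfc
    }
    pca_idx <- which(is_pca)
    shift_group("stage_low_in_pT3",  pca_idx[stage == "pT3"], -1)
    shift_group("stage_high_in_pT3", pca_idx[stage == "pT3"], +1)
    shift_group("gleason_assoc",     pca_idx[gleason == "high"], -1)
    shift_group("pea3_up",           pca_idx[subtype == "PEA3"], +1)
  })
  dimnames(exprs) <- list(gene_ids, sample_ids)
  anno <- data.frame(
    sample_id = sample_ids,
    tissue = ifelse(is_pca, "PCa", "NPT"),
    subtype = c(rep(NA_character_, n_npt), subtype),
    pea3_gene = c(rep(NA_character_, n_npt), pea3_gene),
    gleason_group = c(rep(NA_character_, n_npt), gleason),
    stage = c(rep(NA_character_, n_npt), stage),
    age_years = age,
    psa_ng_ml = psa,
    stringsAsFactors = FALSE)
  cohort <- tumor_cohort(exprs, anno)
  attr(cohort, "truth") <- truth
  cohort
}
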