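test_that("Mann-Whitney exact p matches enumeration on the forced example", {
  res <- mann_whitney(1:3, 4:6)
  expect_identical(unname(res$U), 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_true(res$exact)
  expect_equal(res$p, oracle_mw_exact_p(1:3, 4:6))
  # identical multisets are maximally non-significant
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("U statistics of the two orderings sum to nA*nB", {
  withr::local_seed(99)
  for (i in 1:20) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    ua <- mann_whitney(a, b)$U
    ub <- mann_whitney(b, a)$U
    expect_equal(unname(ua + ub), length(a) * length(b))
    expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  }
})

test_that("exact and approximate p agree closely for moderate samples", {
  withr::local_seed(123)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20, 0.3)
    pe <- mann_whitney(a, b, mode = "exact")$p
    pa <- mann_whitney(a, b, mode = "approx")$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

make_cohort <- function(seed = 1, roles = c(stage_low_in_pT3 = 2,
                                            pea3_up = 2, gleason_assoc = 1),
                        noise_sd = 0.3, ...) {
  gen_tumor_cohort(planted_truth(20, roles = roles, noise_sd = noise_sd),
                   seed = seed, ...)
}

test_that("subtype associations detect planted PEA3 genes and reject tiny groups", {
  hits <- vapply(1:60, function(s) {
    coh <- make_cohort(seed = 600 + s)
    g <- planted_genes(attr(coh, "truth"), "pea3_up")[1]
    rec <- subtype_association(coh, g, "PEA3_vs_ETSneg")
    rec$p < 0.05 && rec$direction == "up"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  coh <- make_cohort()
  rec <- subtype_association(coh, rownames(coh$exprs)[1], "PCa_vs_NPT")
  expect_identical(c(rec$n_a, rec$n_b), c(50L, 9L))
  # a contrast with fewer than two samples per side is refused
  an <- coh$annotations
  an$subtype[which(!is.na(an$subtype) & an$subtype == "PEA3")[-1]] <- "ERG"
  coh2 <- tumor_cohort(coh$exprs, an)
  expect_error(subtype_association(coh2, rownames(coh$exprs)[1],
                                   "PEA3_vs_ETSneg"), ">= 2 samples")
})

test_that("clinico-pathological records flag direction in the high-risk group", {
  coh <- make_cohort(seed = 77, noise_sd = 0.2)
  tr <- attr(coh, "truth")
  rec <- clinico_path_association(coh, planted_genes(tr, "stage_low_in_pT3")[1],
                                  "pT2_vs_pT3")
  expect_identical(rec$flag, "decreased in pT3")
  grec <- clinico_path_association(coh, planted_genes(tr, "gleason_assoc")[1],
                                   "gleason_low_vs_high")
  expect_identical(grec$flag, "decreased in high Gleason")
  # a null gene is typically unflagged
  null_g <- planted_genes(tr, "null")[1]
  nrec <- clinico_path_association(coh, null_g, "pT2_vs_pT3")
  expect_true(nrec$flag %in% c("", "increased in pT3", "decreased in pT3"))
  # all-NA grouping errors
  an <- coh$annotations
  an$stage[] <- NA
  expect_error(clinico_path_association(tumor_cohort(coh$exprs, an),
                                        null_g, "pT2_vs_pT3"), "NA")
})

test_that("covariate independence is declared, rejected and marked unassessable", {
  indep <- vapply(1:40, function(s)
    covariate_independence(make_cohort(seed = 700 + s), "pT2_vs_pT3")$independent,
    logical(1))
  expect_gte(mean(indep), 0.85)  # alpha 0.05 on two covariates
  shifted <- gen_tumor_cohort(planted_truth(10), seed = 3,
                              age_shift_pt3 = 10)
  expect_false(covariate_independence(shifted, "pT2_vs_pT3")$independent)
  coh <- make_cohort(seed = 11)
  an <- coh$annotations
  an$psa_ng_ml[] <- NA
  ci <- covariate_independence(tumor_cohort(coh$exprs, an), "pT2_vs_pT3")
  expect_false(ci$covariates$assessable[ci$covariates$covariate == "psa_ng_ml"])
  expect_true(is.na(ci$covariates$p[ci$covariates$covariate == "psa_ng_ml"]))
})

test_that("multi-gene association tables support optional BH adjustment", {
  coh <- make_cohort(seed = 21)
  genes <- rownames(coh$exprs)[1:5]
  tab <- cohort_associations(coh, genes, "pT2_vs_pT3", adjust = TRUE)
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$p_adj >= tab$p))
})
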