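profile_from <- function(rows) {
  # rows: named list gene -> numeric(5) over the five study models
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), study_model_names())
  m
}

test_that("specific rule requires the cut in both models of the ETS", {
  prof <- profile_from(list(
    hit_up   = c(2.0, 1.5, NA, NA, NA),    # >= 1.5 boundary counts
    split    = c(2.0, -2.0, NA, NA, NA),
    below    = c(2.0, 1.4, NA, NA, NA),
    hit_down = c(-1.5, -3.0, NA, NA, NA),
    undef    = c(NA, 2.0, NA, NA, NA)))
  res <- specific_targets(prof, "ETV1")
  expect_identical(res$up, "hit_up")
  expect_identical(res$down, "hit_down")
  expect_error(specific_targets(prof, "ETV1", models_for_ets = "one"),
               "exactly the two")
  # order of the two models is irrelevant
  rev_models <- rev(pea3targets:::specific_models_for("ETV1"))
  expect_identical(specific_targets(prof, "ETV1", models_for_ets = rev_models),
                   res)
})

test_that("shared rule is a 3-of-4 predicate over the silencing models", {
  prof <- profile_from(list(
    three_up = c(1.6, 1.7, 2.0, -1.1, NA),
    two_only = c(1.6, 1.7, NA, 1.2, NA),
    all_down = c(-1.5, -1.6, -1.9, -2.4, NA)))
  res <- shared_targets(prof)
  expect_identical(res$up, "three_up")
  expect_identical(res$down, "all_down")
  expect_error(shared_targets(prof, silencing_models = colnames(prof)[1:3]),
               "four silencing models")
  expect_error(shared_targets(prof, min_models = 5), "exceeds")
})

test_that("raising the threshold never enlarges any target set", {
  withr::local_seed(7001)
  for (i in 1:20) {
    prof <- random_profile(40)
    lo <- shared_targets(prof, threshold = 1.3)
    hi <- shared_targets(prof, threshold = 1.8)
    expect_true(all(hi$up %in% lo$up) && all(hi$down %in% lo$down))
    slo <- specific_targets(prof, "ETV4", threshold = 1.3)
    shi <- specific_targets(prof, "ETV4", threshold = 1.8)
    expect_true(all(shi$up %in% slo$up) && all(shi$down %in% slo$down))
  }
})

test_that("target rules equal brute-force predicate enumeration", {
  withr::local_seed(31415)
  for (i in 1:25) {
    prof <- random_profile(sample(10:200, 1))
    for (ets in c("ETV1", "ETV4")) {
      models <- pea3targets:::specific_models_for(ets)
      expect_identical(specific_targets(prof, ets),
                       oracle_specific(prof, models, 1.5))
    }
    expect_identical(shared_targets(prof),
                     oracle_shared(prof, study_model_names(TRUE), 1.5, 3))
  }
})

test_that("target report bookkeeping obeys inclusion-exclusion", {
  withr::local_seed(88)
  truth <- planted_truth(400, roles = c(
    ETV1_target_up = 5, ETV1_target_down = 6,
    ETV4_target_up = 9, ETV4_target_down = 15,
    shared_up = 8, shared_down = 16, inverse = 2))
  expt <- gen_cellline_experiment(truth, seed = 17)
  prof <- build_association_profile(expt$models, expt$exprs)
  rep <- build_target_report(prof)
  s <- rep$summary
  expect_identical(unname(s["union"]),
                   unname(s["ETV1_specific"] + s["ETV4_specific"] +
                            s["shared"] - s["inverse_overlap"]))
  expect_identical(unname(s["union"]), length(unique(rep$sets$gene)))
  # inverse genes are up with ETV1 and down with ETV4
  inv <- rep$inverse
  expect_identical(sort(inv), sort(planted_genes(truth, "inverse")))
  e1 <- rep$sets[rep$sets$provenance == "ETV1_specific", ]
  e4 <- rep$sets[rep$sets$provenance == "ETV4_specific", ]
  expect_true(all(e1$direction[e1$gene %in% inv] == "up"))
  expect_true(all(e4$direction[e4$gene %in% inv] == "down"))
  # a gene appears in at most one direction per provenance
  expect_false(any(duplicated(rep$sets[, c("gene", "provenance")])))
})

test_that("targeted ETS genes are excluded and empty profiles give empty reports", {
  prof <- profile_from(list(
    ETV1 = c(-5, -6, NA, NA, 8),       # the silenced ETS itself
    gene = c(2, 2, 2, 2, 2)))
  rep <- build_target_report(prof)
  expect_false("ETV1" %in% rep$sets$gene)
  empty <- build_target_report(profile_from(list(dull = c(1, 1, 1, 1, 1))))
  expect_identical(nrow(empty$sets), 0L)
  expect_identical(unname(empty$summary["union"]), 0L)
})
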