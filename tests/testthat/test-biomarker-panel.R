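test_that("percentile thresholds use (n-1)q linear interpolation", {
  expect_equal(percentile_threshold(1:8, 25), 2.75)
  expect_equal(percentile_threshold(1:8, 50), 4.5)
  expect_identical(percentile_threshold(rep(3, 5), 25), 3)
  expect_error(percentile_threshold(1, 25), ">= 2")
  expect_error(percentile_threshold(1:8, 0), "strictly in")
  # nearest-rank variant differs where interpolation lands between values
  expect_equal(percentile_threshold(1:8, 25, method = "nearest"), 2)
})

test_that("flag matrices flag strictly below the threshold and nest by q", {
  truth <- planted_truth(10)
  coh <- gen_tumor_cohort(truth, seed = 2)
  # inject a known gene: evaluable tumours get values 1..50
  idx <- pea3targets:::evaluable_index(coh)
  coh$exprs["g00001", idx] <- seq_len(sum(idx))
  f25 <- flag_matrix(coh, panel_rule("g00001", 25, 1))
  f50 <- flag_matrix(coh, panel_rule("g00001", 50, 1))
  # thresholds 13.25 and 25.5 -> 13 and 25 tumours strictly below
  expect_identical(sum(f25), 13L)
  expect_identical(sum(f50), 25L)
  expect_true(all(rownames(f25)[f25] %in% rownames(f50)[f50]))
  # ties: all-equal values flag nothing
  coh$exprs["g00002", ] <- 5
  expect_identical(sum(flag_matrix(coh, panel_rule("g00002", 25, 1))), 0L)
  expect_error(flag_matrix(coh, panel_rule("nope", 25, 1)), "nope")
})

test_that("k-of-n classification is antitone in k", {
  flags <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), nrow = 3,
                  dimnames = list(c("t1", "t2", "t3"), c("gA", "gB")))
  expect_setequal(classify(flags, 1), c("t1", "t2"))
  expect_identical(classify(flags, 2), "t1")
  expect_true(all(classify(flags, 2) %in% classify(flags, 1)))
  expect_error(panel_rule(c("a", "b"), 25, 3), "k must satisfy")
})

test_that("2x2 evaluation matches the closed-form chi-square", {
  truth <- setNames(rep(c("pT3", "pT2"), each = 10), sprintf("t%02d", 1:20))
  predicted <- c(sprintf("t%02d", 1:8), sprintf("t%02d", 11:12))
  ev <- evaluate_panel(predicted, truth)
  expect_identical(ev$counts, c(TP = 8L, FP = 2L, FN = 2L, TN = 8L))
  expect_equal(ev$chi2, 7.2, tolerance = 1e-12)
  expect_equal(ev$p, pchisq(7.2, df = 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(ev$p, 0.00729, tolerance = 1e-4)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$specificity, 0.8)
  expect_equal(ev$ppv, 0.8)
  expect_equal(ev$npv, 0.8)
  # degenerate: nothing predicted positive
  ev0 <- evaluate_panel(character(), truth)
  expect_identical(ev0$sensitivity, 0)
  expect_true(is.na(ev0$ppv))
  expect_equal(ev0$npv, 10 / 20)
  expect_true(is.na(ev0$p))
  expect_error(evaluate_panel("t1", setNames(character(), character())),
               "empty")
})

test_that("chi-square agrees with expected-count recomputation on random tables", {
  withr::local_seed(555)
  for (i in 1:25) {
    cts <- sample(1:30, 4, replace = TRUE)
    truth <- setNames(rep(c("pT3", "pT2"), c(cts[1] + cts[3], cts[2] + cts[4])),
                      sprintf("s%03d", seq_len(sum(cts))))
    pos_ids <- names(truth)[c(seq_len(cts[1]),
                              cts[1] + cts[3] + seq_len(cts[2]))]
    ev <- evaluate_panel(pos_ids, truth)
    tbl <- matrix(c(ev$counts["TP"], ev$counts["FN"],
                    ev$counts["FP"], ev$counts["TN"]), 2)
    expect_equal(ev$chi2, oracle_chi2_expected(tbl), tolerance = 1e-10)
    expect_equal(ev$chi2,
                 oracle_chi2(ev$counts["TP"], ev$counts["FP"],
                             ev$counts["FN"], ev$counts["TN"]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # swapping both rows and both columns leaves p unchanged
    swapped <- evaluate_panel(setdiff(names(truth), pos_ids),
                              setNames(ifelse(truth == "pT3", "pT2", "pT3"),
                                       names(truth)))
    expect_equal(swapped$p, ev$p, tolerance = 1e-12)
    # rounding-free internal counts: metrics recover TP exactly
    expect_equal(ev$sensitivity * (ev$counts["TP"] + ev$counts["FN"]),
                 ev$counts["TP"], tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("cut-off scans rank by p and deduplicate the grid", {
  truth <- planted_truth(12, roles = c(stage_low_in_pT3 = 7), lfc = 1.5,
                         noise_sd = 0.4)
  coh <- gen_tumor_cohort(truth, seed = 31)
  panel <- planted_genes(truth, "stage_low_in_pT3")
  scan <- cutoff_scan(coh, panel)
  expect_identical(nrow(scan$table), 3L)
  expect_true(!is.unsorted(scan$table$p))
  expect_warning(
    dup <- cutoff_scan(coh, panel, grid = data.frame(q = c(25, 25), k = c(2, 2))),
    "duplicate")
  expect_identical(nrow(dup$table), 1L)
  expect_error(cutoff_scan(coh, panel, grid = data.frame(q = numeric(),
                                                         k = numeric())),
               "empty")
})
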