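test_that("expression matrix round trip preserves ids, order and values", {
  m <- matrix(rnorm(6, 8, 1), nrow = 3,
              dimnames = list(c("TP53", "ATF3", "GSTM4"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  m2 <- read_expression_matrix(path)
  expect_identical(dimnames(m2), dimnames(m))
  expect_equal(m2, m, tolerance = 1e-10)
  # loading twice yields equal objects
  expect_identical(m2, read_expression_matrix(path))
})

test_that("malformed expression files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1.0\t2.0", "g1\t3.0\t4.0"), path)
  expect_error(read_expression_matrix(path), "duplicate gene id.*g1")
  writeLines(c("gene_id\ts1\ts2", "g1\t1.0\tx", "g2\t3.0\t4.0"), path)
  expect_error(read_expression_matrix(path), "row 1.*'g1'.*column 's2'")
  expect_error(read_expression_matrix(tempfile()), "no such file")
  bad <- matrix(c(1, NA), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(validate_expression_matrix(bad), "non-finite")
})

test_that("annotation dialect is strict and handles literal NA", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "sample_id\ttissue\tsubtype\tpea3_gene\tgleason_group\tstage\tage_years\tpsa_ng_ml"
  writeLines(c(hdr,
               "S1\tPCa\tPEA3\tETV1\thigh\tpT3\t64\t8.2",
               "N1\tNPT\tNA\tNA\tNA\tNA\t58\t1.1"), path)
  anno <- read_annotations(path)
  expect_identical(anno$stage, c("pT3", NA))
  expect_identical(anno$pea3_gene[1], "ETV1")
  expect_true(is.na(anno$subtype[2]))
  expect_type(anno$psa_ng_ml, "double")

  writeLines(c(hdr, "S1\tPCa\tPEA3\tETV1\thigh\tT3\t64\t8.2"), path)
  expect_error(read_annotations(path), "invalid stage value 'T3'.*pT2, pT3")
  writeLines(c(hdr, "S1\tPCa\tPEA3\tETV1\thigh\tpT4x\t64\t8.2"), path)
  expect_error(read_annotations(path), "allowed")
  # NPT rows may not carry carcinoma annotations
  writeLines(c(hdr, "N1\tNPT\tNA\tNA\tNA\tpT2\t58\t1.1"), path)
  expect_error(read_annotations(path), "NPT")
})

test_that("annotation write/read round trip is the identity", {
  anno <- data.frame(sample_id = c("N1", "S1"), tissue = c("NPT", "PCa"),
                     subtype = c(NA, "ERG"), pea3_gene = c(NA, NA),
                     gleason_group = c(NA, "low"), stage = c(NA, "pT2"),
                     age_years = c(55, 67), psa_ng_ml = c(1.2, 11.5),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(anno, path)
  expect_equal(read_annotations(path), anno)
})

test_that("gene set report files are deterministic and round trip", {
  prof <- matrix(c(2, -2, 1.6, -1.7), nrow = 2,
                 dimnames = list(c("gB", "gA"), c("m1", "m2")))
  sets <- data.frame(gene = c("gB", "gA"), direction = c("up", "down"),
                     provenance = "shared", stringsAsFactors = FALSE)
  rep <- pea3targets:::new_gene_set_report(sets, prof, "target")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_set_report(rep, path)
  back <- read_gene_set_report(path)
  expect_identical(back$gene, c("gA", "gB"))  # direction, then lexicographic
  expect_identical(back, back[order(back$provenance, back$direction, back$gene), ])
  expect_setequal(paste(back$gene, back$direction), c("gA down", "gB up"))

  empty <- pea3targets:::new_gene_set_report(NULL, prof, "target")
  write_gene_set_report(empty, path)
  expect_identical(nrow(read_gene_set_report(path)), 0L)
  expect_gt(length(readLines(path)), 0)  # header survives
})

test_that("config validation fills defaults and aggregates contradictions", {
  cfg <- validate_config(NULL)
  expect_s3_class(cfg, "run_config")
  expect_identical(cfg$specific_fc, 1.5)
  expect_identical(cfg$panel_percentiles, c(10, 25, 50))
  expect_identical(cfg$panel_k, c(1L, 2L, 4L))
  expect_error(validate_config(list(panel_percentiles = c(0, 25, 50))),
               "strictly between 0 and 100")
  expect_error(validate_config(list(specific_fc = 0.8, alpha = 2)),
               "specific_fc.*\n.*alpha")
  expect_warning(validate_config(list(inv_aig_include_fc = 1.0)),
                 "non-default setting")
  expect_error(validate_config(list(bogus = 1)), "unknown config field")
})
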