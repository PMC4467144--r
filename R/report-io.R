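#' Write a gene-set report as a tab-delimited gene list
#'
#' One row per (gene, provenance) entry with direction and the per-model
#' association FCs, ordered deterministically by provenance, then direction,
#' then gene id. An empty report yields a header-only file.
#'
#' @param report a `"gene_set_report"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_set_report <- function(report, path) {
  if (!inherits(report, "gene_set_report")) stop("not a gene_set_report")
  sets <- report$sets
  fc_cols <- colnames(report$profile)
  fc <- as.data.frame(unclass(report$profile)[sets$gene, , drop = FALSE])
  names(fc) <- paste0("fc.", fc_cols)
  out <- cbind(sets, fc)
  out <- out[order(out$provenance, out$direction, out$gene), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a written gene-set report's set membership
#'
#' Reads back the gene/direction/provenance columns of a file written by
#' [write_gene_set_report()].
#'
#' @param path file path.
#' @return data.frame `gene`, `direction`, `provenance`.
#' @export
read_gene_set_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "direction", "provenance")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("report lacks column(s): ", paste(missing, collapse = ", "))
  df[, need, drop = FALSE]
}

#' Write a panel evaluation (or cut-off scan table) as TSV
#'
#' @param x a `"panel_evaluation"` or the `table` of [cutoff_scan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_evaluation <- function(x, path) {
  if (inherits(x, "panel_evaluation")) {
    x <- data.frame(q = x$rule$q, k = x$rule$k,
                    TP = x$counts["TP"], FP = x$counts["FP"],
                    FN = x$counts["FN"], TN = x$counts["TN"],
                    chi2 = x$chi2, p = x$p, ppv = x$ppv, npv = x$npv,
                    sensitivity = x$sensitivity, specificity = x$specificity)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
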