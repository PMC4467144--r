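#' Comparative-Ct relative quantification
#'
#' Relative expression of a target transcript by the comparative Ct method:
#' `2^-(Ct_target - mean(Ct_references))`. Multiple reference genes (the study
#' uses 18S and GUSB) are combined by the arithmetic mean of their Ct values,
#' equivalent to the geometric mean of their linear quantities.
#'
#' @param ct_target Ct (cycles) of the target gene.
#' @param ct_refs numeric vector of reference-gene Ct values (>=1).
#' @return linear relative expression (dimensionless).
#' @export
comparative_ct <- function(ct_target, ct_refs) {
  if (length(ct_refs) < 1) stop("at least one reference Ct is required")
  if (!all(is.finite(c(ct_target, ct_refs)))) stop("Ct values must be finite")
  2^-(ct_target - mean(ct_refs))
}

#' Median-center a series of linear expression values
#'
#' Each value is divided by the median of the series (for an even count, the
#' mean of the two central values), so the centered series has median exactly
#' 1. Used to place cell-line ETS expression on the scale of a tumour series.
#'
#' @param x named numeric vector of positive linear expression values.
#' @return numeric vector of the same length and names, median 1.
#' @export
median_center <- function(x) {
  if (length(x) < 1) stop("need >=1 value")
  if (any(!is.finite(x) | x <= 0)) stop("all values must be finite and > 0")
  x / median(x)
}

#' Relative expression of a population versus its control
#'
#' Calibrates a (reference-normalized) expression value against the matching
#' control population, e.g. shETS versus shNeg; a knockdown of 70-80 percent
#' corresponds to ratios 0.2-0.3.
#'
#' @param expr linear expression of the population of interest.
#' @param control_expr linear expression of the control population (> 0).
#' @return ratio `expr / control_expr`.
#' @export
relative_expression_vs_control <- function(expr, control_expr) {
  if (any(!is.finite(control_expr) | control_expr <= 0))
    stop("control expression must be finite and > 0")
  expr / control_expr
}

#' Rank samples by series-centered ETS expression and flag outliers
#'
#' @param centered named numeric vector of median-centered expression values.
#' @param flag_threshold fold-change over the series median at or above which
#'   a sample is flagged as an expression outlier. The threshold is a
#'   configurable analysis choice, not a fixed property of the method.
#' @return data.frame `sample`, `centered_expression`, `flagged`, sorted by
#'   descending centered expression.
#' @export
outlier_report <- function(centered, flag_threshold) {
  if (is.null(names(centered))) stop("'centered' must be a named vector")
  ord <- order(centered, decreasing = TRUE)
  data.frame(sample = names(centered)[ord],
             centered_expression = unname(centered[ord]),
             flagged = unname(centered[ord] >= flag_threshold),
             stringsAsFactors = FALSE)
}

#' Read a long-format Ct table
#'
#' Tab-delimited columns `sample_id`, `target`, `ct`, `ref_gene`, `ref_ct`:
#' one row per (sample, target, reference gene).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ct <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "ct", "ref_gene", "ref_ct")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(ct$ct) || !is.numeric(ct$ref_ct))
    stop("'ct' and 'ref_ct' must be numeric")
  ct
}

#' Comparative-Ct quantification of a whole Ct table
#'
#' Applies [comparative_ct()] per (sample, target), averaging the reference
#' Ct values across that record's reference genes.
#'
#' @param ct data.frame as returned by [read_ct_table()].
#' @return data.frame `sample_id`, `target`, `relative_expression`.
#' @export
quantify_ct_table <- function(ct) {
  key <- interaction(ct$sample_id, ct$target, drop = TRUE)
  out <- do.call(rbind, lapply(split(ct, key), function(d) {
    data.frame(sample_id = d$sample_id[1], target = d$target[1],
               relative_expression = comparative_ct(d$ct[1], d$ref_ct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$target, out$sample_id), , drop = FALSE]
}
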