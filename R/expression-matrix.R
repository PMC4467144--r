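#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of log2 normalized expression with
#' unique gene ids as rownames and unique sample ids as colnames, every cell
#' finite.
#'
#' @param x numeric matrix.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene ids as rownames and sample ids as colnames")
  dup_g <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

#' Read a gene x sample expression matrix
#'
#' Tab-delimited with a header row; first column holds gene ids, remaining
#' columns numeric log2 expression. Row and column order is preserved.
#'
#' @param path file path.
#' @return numeric matrix, genes as rownames, samples as colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("expected a gene id column plus >=1 sample column")
  gene_ids <- df[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric cell '%s' at row %d (gene '%s'), column '%s'",
                 vals[bad[1], bad[2]], bad[1], gene_ids[bad[1]],
                 colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write a gene x sample expression matrix
#'
#' Inverse of [read_expression_matrix()]; values are formatted with enough
#' significant digits (15) that a write/read round trip is the identity to
#' well beyond 6 significant digits.
#'
#' @param x expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
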