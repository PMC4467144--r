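#' Signed linear fold-change from log2 expression values
#'
#' Signed-ratio convention: a 2-fold decrease is written -2.0 rather than 0.5,
#' so `|value| >= 1` always and `value == 1` iff the two conditions are equal.
#' With `d = log2_a - log2_b`, returns `+2^d` when `d >= 0` and `-2^-d`
#' otherwise. Vectorized.
#'
#' @param log2_a,log2_b log2 expression of the two conditions (a = numerator).
#' @return signed linear fold-change(s).
#' @export
signed_fold_change <- function(log2_a, log2_b) {
  if (!all(is.finite(log2_a), is.finite(log2_b)))
    stop("log2 expression values must be finite")
  d <- log2_a - log2_b
  ifelse(d >= 0, 2^d, -(2^-d))
}

# Sign of a signed FC for clone-agreement purposes: exactly +1.0 (no change)
# carries no direction, encoded 0, and agrees only with another +1.0.
fc_sign <- function(fc) ifelse(fc == 1, 0, sign(fc))

#' Per-model clone-consensus fold-change
#'
#' For every manipulated population of a model, the signed FC versus the
#' control is computed on population-mean log2 expression (replicate columns
#' averaged). If all manipulated populations share the same differential
#' direction, the signed values are averaged (arithmetic by default); on sign
#' disagreement the consensus is undefined (`NA`). A single-population model
#' returns that population's FC.
#'
#' @param gene gene id (must be a row of `exprs`).
#' @param model a [cell_line_model()].
#' @param exprs expression matrix (log2), genes x samples.
#' @param average `"arithmetic"` (mean of signed linear FCs) or `"geometric"`
#'   (mean of log2 differences, re-expressed as a signed FC).
#' @return signed FC, or `NA` on clone disagreement.
#' @export
consensus_model_fc <- function(gene, model, exprs,
                               average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (!gene %in% rownames(exprs))
    stop("gene '", gene, "' absent from expression matrix")
  missing <- setdiff(model_sample_ids(model), colnames(exprs))
  if (length(missing))
    stop("model '", model$name, "': sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  ctrl <- mean(exprs[gene, model$control$sample_ids])
  l2 <- vapply(model$manipulated,
               function(p) mean(exprs[gene, p$sample_ids]), numeric(1))
  fcs <- signed_fold_change(l2, ctrl)
  s <- fc_sign(fcs)
  if (length(unique(s)) > 1) return(NA_real_)
  if (average == "arithmetic" || length(fcs) == 1) mean(fcs)
  else signed_fold_change(mean(l2), ctrl)
}

#' Orient a fold-change along the ETS-association axis
#'
#' Expresses a manipulated-vs-control FC relative to ETS expression so
#' silencing and overexpression models are comparable: overexpression leaves
#' the FC unchanged; silencing flips the sign (a gene down upon knockdown is
#' positively associated with the ETS). A no-change FC of +1.0 maps to +1.0.
#'
#' @param model_kind `"silencing"` or `"overexpression"`.
#' @param fc signed FC (vectorized; NA passes through).
#' @return association-direction signed FC.
#' @export
association_fc <- function(model_kind = c("silencing", "overexpression"), fc) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "overexpression") return(fc)
  ifelse(is.na(fc) | fc == 1, fc, -fc)
}

#' Build the gene x model association profile
#'
#' For each gene and each model, the clone-consensus FC oriented along the
#' ETS-association axis ([association_fc()]); undefined consensus entries
#' (clone disagreement) are preserved as `NA`, never coerced to 1.
#'
#' @param models list of [cell_line_model()]s with distinct names.
#' @param exprs expression matrix (log2).
#' @param average consensus averaging rule, see [consensus_model_fc()].
#' @return numeric matrix genes x models of class `"assoc_profile"`, with
#'   model kinds stored in `attr(, "kind")`.
#' @export
build_association_profile <- function(models, exprs,
                                      average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  validate_expression_matrix(exprs)
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("model names must be distinct")
  prof <- matrix(NA_real_, nrow = nrow(exprs), ncol = length(models),
                 dimnames = list(rownames(exprs), nm))
  for (j in seq_along(models)) {
    m <- models[[j]]
    ctrl <- colMeans2(exprs, m$control$sample_ids)
    l2 <- vapply(m$manipulated, function(p) colMeans2(exprs, p$sample_ids),
                 numeric(nrow(exprs)))
    l2 <- base::matrix(l2, nrow = nrow(exprs))
    fcs <- signed_fold_change(as.vector(l2), ctrl)  # recycles ctrl per clone
    fcs <- base::matrix(fcs, nrow = nrow(exprs))
    s <- fc_sign(fcs)
    agree <- apply(s, 1L, function(z) length(unique(z)) == 1L)
    cons <- if (average == "arithmetic" || ncol(fcs) == 1) rowMeans(fcs)
            else signed_fold_change(rowMeans(l2), ctrl)
    cons[!agree] <- NA_real_
    prof[, j] <- association_fc(m$kind, cons)
  }
  structure(prof, kind = stats::setNames(vapply(models, `[[`, character(1), "kind"), nm),
            class = c("assoc_profile", class(prof)))
}

# Row means of a subset of columns, kept as a vector even for one column.
colMeans2 <- function(exprs, cols) {
  rowMeans(exprs[, cols, drop = FALSE])
}

#' Export an association profile as a tab-delimited table
#'
#' Undefined entries are rendered `NA`.
#'
#' @param profile matrix from [build_association_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_profile <- function(profile, path) {
  df <- data.frame(gene_id = rownames(profile),
                   format(unclass(profile), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
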