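#' Construct a panel rule
#'
#' A percentile-cut k-of-n low-expression panel: a tumour is called positive
#' (predicted locally invasive) when at least `k` panel genes fall strictly
#' below their per-gene `q`-th percentile across the evaluable tumours.
#'
#' @param genes non-empty character vector of panel gene ids (study default
#'   panel: CCPG1, CDK11A, CHRNB4, PMCH, SERF1A, SLC22A3, TMPRSS11E).
#' @param q percentile in (0, 100).
#' @param k minimum flagged genes, `1 <= k <= length(genes)`.
#' @return object of class `"panel_rule"`.
#' @export
panel_rule <- function(genes, q, k) {
  if (!length(genes)) stop("panel must be non-empty")
  if (anyDuplicated(genes)) stop("panel genes must be distinct")
  if (q <= 0 || q >= 100) stop("percentile q must lie strictly in (0, 100)")
  if (k < 1 || k > length(genes))
    stop("k must satisfy 1 <= k <= panel size (", length(genes), ")")
  structure(list(genes = genes, q = q, k = as.integer(k)),
            class = "panel_rule")
}

#' Percentile threshold by linear interpolation
#'
#' The q-th percentile of the sorted values at position `(n - 1) * q / 100`,
#' interpolating linearly between neighbours (the type-7 quantile). A
#' nearest-rank variant is available.
#'
#' @param values numeric vector of >= 2 expression values.
#' @param q percentile in (0, 100).
#' @param method `"linear"` (default) or `"nearest"` rank.
#' @return threshold value.
#' @export
percentile_threshold <- function(values, q, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) < 2) stop("need >= 2 values")
  if (q <= 0 || q >= 100) stop("percentile q must lie strictly in (0, 100)")
  quantile(values, q / 100, type = if (method == "linear") 7 else 1,
           names = FALSE)
}

# Evaluable tumours: staged carcinomas (pT2 or pT3).
evaluable_index <- function(cohort) {
  an <- cohort$annotations
  an$tissue == "PCa" & !is.na(an$stage) & an$stage %in% c("pT2", "pT3")
}

#' Low-expression flag matrix for a panel rule
#'
#' For each panel gene, the q-th percentile threshold is computed over the
#' evaluable tumours themselves (staged carcinomas) and a tumour is flagged
#' when its expression is strictly below that threshold; under ties the
#' "bottom q percent" therefore never exceeds q percent of the samples.
#'
#' @param cohort a [tumor_cohort()].
#' @param rule a [panel_rule()].
#' @param method percentile method, see [percentile_threshold()].
#' @return logical matrix, evaluable tumours x panel genes.
#' @export
flag_matrix <- function(cohort, rule, method = "linear") {
  missing <- setdiff(rule$genes, rownames(cohort$exprs))
  if (length(missing))
    stop("panel gene(s) absent from cohort: ", paste(missing, collapse = ", "))
  idx <- evaluable_index(cohort)
  if (sum(idx) < 2) stop("need >= 2 evaluable (staged) tumours")
  sub <- cohort$exprs[rule$genes, idx, drop = FALSE]
  # apply over genes returns tumours x genes (results become columns)
  flags <- apply(sub, 1L, function(v)
    v < percentile_threshold(v, rule$q, method))
  base::matrix(flags, ncol = length(rule$genes),
               dimnames = list(colnames(sub), rule$genes))
}

#' k-of-n panel classification
#'
#' @param flags logical tumour x gene flag matrix.
#' @param k minimum flagged genes for a positive call.
#' @return character vector of predicted-positive tumour ids.
#' @export
classify <- function(flags, k) {
  if (k < 1) stop("k must be >= 1")
  rownames(flags)[rowSums(flags) >= k]
}

#' Evaluate panel predictions against pathological stage
#'
#' 2x2 diagnostic evaluation with pT3 (locally invasive) as the positive
#' class: TP/FP/FN/TN counts, sensitivity, specificity, PPV and NPV, and the
#' Pearson chi-square test (1 df, no continuity correction, two-sided).
#' Metrics with a zero denominator are `NA`, as is the chi-square p when a
#' table margin is empty.
#'
#' @param predicted character vector of predicted-positive tumour ids.
#' @param truth named character vector of stage labels (`"pT2"`/`"pT3"`) for
#'   every evaluable tumour.
#' @param rule optional [panel_rule()] recorded in the result.
#' @return object of class `"panel_evaluation"`.
#' @export
evaluate_panel <- function(predicted, truth, rule = NULL) {
  if (!length(truth)) stop("empty truth labels")
  if (is.null(names(truth))) stop("'truth' must be named by tumour id")
  if (!all(truth %in% c("pT2", "pT3")))
    stop("truth labels must be 'pT2' or 'pT3'")
  unknown <- setdiff(predicted, names(truth))
  if (length(unknown))
    stop("predicted tumour(s) not in truth: ", paste(unknown, collapse = ", "))
  pos <- names(truth)[truth == "pT3"]
  neg <- names(truth)[truth == "pT2"]
  tp <- length(intersect(predicted, pos))
  fp <- length(intersect(predicted, neg))
  fn <- length(setdiff(pos, predicted))
  tn <- length(setdiff(neg, predicted))
  tbl <- matrix(c(tp, fn, fp, tn), nrow = 2,
                dimnames = list(predicted = c("pos", "neg"),
                                truth = c("pT3", "pT2")))
  degenerate <- any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)
  if (degenerate) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ht <- suppressWarnings(chisq.test(tbl, correct = FALSE))
    chi2 <- unname(ht$statistic); p <- ht$p.value
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(rule = rule, counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 n_evaluable = tp + fp + fn + tn,
                 chi2 = chi2, p = p,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn)),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  if (!is.null(x$rule))
    cat(sprintf("panel rule: bottom %g%% of >= %d of %d genes\n",
                x$rule$q, x$rule$k, length(x$rule$genes)))
  cat(sprintf("counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$counts["TP"], x$counts["FP"], x$counts["FN"], x$counts["TN"],
              x$n_evaluable))
  cat(sprintf("chi2=%.4g p=%.3g sens=%.3f spec=%.3f PPV=%.3f NPV=%.3f\n",
              x$chi2, x$p, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Apply a panel rule to a cohort
#'
#' Convenience composition of [flag_matrix()], [classify()] and
#' [evaluate_panel()].
#'
#' @param cohort a [tumor_cohort()].
#' @param rule a [panel_rule()].
#' @param method percentile method.
#' @return a `"panel_evaluation"`.
#' @export
apply_panel_rule <- function(cohort, rule, method = "linear") {
  flags <- flag_matrix(cohort, rule, method)
  predicted <- classify(flags, rule$k)
  idx <- evaluable_index(cohort)
  truth <- stats::setNames(cohort$annotations$stage[idx],
                           cohort$annotations$sample_id[idx])
  evaluate_panel(predicted, truth, rule)
}

#' Scan percentile/k cut-off combinations
#'
#' Evaluates one panel rule per `(q, k)` pair (duplicates are dropped with a
#' warning) and ranks the results by ascending chi-square p-value. The study
#' grid is `(10, 1)`, `(25, 2)`, `(50, 4)`.
#'
#' @param cohort a [tumor_cohort()].
#' @param genes panel gene ids.
#' @param grid data.frame with columns `q` and `k`; defaults to the study
#'   grid.
#' @param method percentile method.
#' @return list with `table` (one row per rule, ranked by p) and
#'   `evaluations` (the `"panel_evaluation"` objects, same order).
#' @export
cutoff_scan <- function(cohort, genes,
                        grid = data.frame(q = c(10, 25, 50), k = c(1, 2, 4)),
                        method = "linear") {
  if (!nrow(grid)) stop("cut-off grid is empty")
  dup <- duplicated(grid[, c("q", "k")])
  if (any(dup)) {
    warning("duplicate (q, k) pair(s) in grid dropped")
    grid <- grid[!dup, , drop = FALSE]
  }
  evs <- lapply(seq_len(nrow(grid)), function(i)
    apply_panel_rule(cohort, panel_rule(genes, grid$q[i], grid$k[i]), method))
  tab <- do.call(rbind, lapply(evs, function(e)
    data.frame(q = e$rule$q, k = e$rule$k,
               TP = e$counts["TP"], FP = e$counts["FP"],
               FN = e$counts["FN"], TN = e$counts["TN"],
               chi2 = e$chi2, p = e$p,
               ppv = e$ppv, npv = e$npv,
               sensitivity = e$sensitivity, specificity = e$specificity,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  ord <- order(tab$p)
  list(table = tab[ord, , drop = FALSE], evaluations = evs[ord])
}
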