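#' Growth index from MTT absorbances
#'
#' Net growth relative to the time-zero (post-adherence) measure:
#' `(Tn - T0) / T0`, computed on well-averaged absorbances.
#'
#' @param avg_tn average absorbance at time point n.
#' @param avg_t0 average absorbance at time zero (> 0).
#' @return dimensionless growth index (negative = net loss).
#' @export
growth_index <- function(avg_tn, avg_t0) {
  if (any(avg_t0 <= 0)) stop("time-zero absorbance must be > 0")
  (avg_tn - avg_t0) / avg_t0
}

#' Normalize an assay summary to its control
#'
#' Relative outcome of a manipulated population versus its matching control,
#' e.g. 30 colonies versus 100 control colonies gives 0.30 (a 70 percent
#' decrease).
#'
#' @param value summary value of the population of interest.
#' @param control_value summary value of the control (non-zero).
#' @return ratio `value / control_value`.
#' @export
relative_to_control <- function(value, control_value) {
  if (any(control_value == 0)) stop("control value must be non-zero")
  value / control_value
}

#' Two-sample Student's t test on assay ratios
#'
#' Classical equal-variance two-sample t test (Welch's unequal-variance form
#' behind `welch = TRUE`), two-sided. The test units are the
#' relative-to-control ratios of independent experiments, not individual
#' replicate wells. Degenerate zero-variance inputs follow the convention
#' p = 1 for equal means and p = 0 for unequal means.
#'
#' @param group_a,group_b numeric vectors of >= 2 ratios each.
#' @param welch logical; use the Welch correction instead of pooled variance.
#' @return list `t`, `p` (two-sided), `df`, and `stars` (`"**"` p < 0.01,
#'   `"*"` p < 0.05, `""` otherwise).
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values")
  if (!all(is.finite(c(group_a, group_b)))) stop("values must be finite")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    equal <- mean(group_a) == mean(group_b)
    res <- list(t = if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b)),
                p = if (equal) 1 else 0,
                df = length(group_a) + length(group_b) - 2)
  } else {
    ht <- t.test(group_a, group_b, var.equal = !welch)
    res <- list(t = unname(ht$statistic), p = ht$p.value,
                df = unname(ht$parameter))
  }
  res$stars <- if (res$p < 0.01) "**" else if (res$p < 0.05) "*" else ""
  res
}
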