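# Independent brute-force oracles and fixture builders. These re-derive the
# filtering predicates and test statistics by direct enumeration, separately
# from the package implementation.

# Random association profile: signed FCs with |v| >= 1, a sprinkling of NA
# (clone-disagreement) entries, over the five study models.
random_profile <- function(n_genes, na_frac = 0.1) {
  models <- study_model_names()
  v <- sample(c(-1, 1), n_genes * length(models), replace = TRUE) *
    exp(runif(n_genes * length(models), 0, log(3)))
  v[runif(length(v)) < na_frac] <- NA_real_
  matrix(v, nrow = n_genes,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)), models))
}

# Direct evaluation of the two-model specific-target predicate.
oracle_specific <- function(profile, models, thr) {
  up <- character(); down <- character()
  for (g in rownames(profile)) {
    v <- profile[g, models]
    if (any(is.na(v))) next
    if (all(v >= thr)) up <- c(up, g)
    if (all(v <= -thr)) down <- c(down, g)
  }
  list(up = up, down = down)
}

# Direct evaluation of the m-of-n shared-target predicate.
oracle_shared <- function(profile, models, thr, min_models) {
  up <- character(); down <- character()
  for (g in rownames(profile)) {
    v <- profile[g, models]
    n_up <- sum(!is.na(v) & v >= thr)
    n_dn <- sum(!is.na(v) & v <= -thr)
    if (n_up >= min_models && n_dn >= min_models) next  # pathological: neither
    if (n_up >= min_models) up <- c(up, g)
    if (n_dn >= min_models) down <- c(down, g)
  }
  list(up = up, down = down)
}

# Direct evaluation of an include/exclude phenotype predicate (strict >).
oracle_include_exclude <- function(profile, inc_models, exc_models,
                                   inc_fc, exc_fc) {
  up <- character(); down <- character()
  for (g in rownames(profile)) {
    vi <- profile[g, inc_models]
    ve <- profile[g, exc_models]
    for (s in c(1, -1)) {
      ok <- !any(is.na(vi)) && all(s * vi > 0 & abs(vi) > inc_fc)
      excl <- length(ve) > 0 &&
        all(!is.na(ve) & s * ve > 0 & abs(ve) > exc_fc)
      if (ok && !excl) {
        if (s > 0) up <- c(up, g) else down <- c(down, g)
      }
    }
  }
  list(up = up, down = down)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_mw_exact_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  all_r <- seq_len(n_a + n_b)
  u_all <- apply(combos, 2, function(idx)
    sum(all_r[idx]) - n_a * (n_a + 1) / 2)
  mu <- n_a * n_b / 2
  # two-sided: double the smaller tail (capped at 1), the standard convention
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Closed-form Pearson chi-square for a 2x2 table.
oracle_chi2 <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  n * (tp * tn - fp * fn)^2 /
    ((tp + fp) * (fn + tn) * (tp + fn) * (fp + tn))
}

# Pearson chi-square via expected counts, any 2x2 table.
oracle_chi2_expected <- function(tbl) {
  e <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  sum((tbl - e)^2 / e)
}

# Pooled-variance two-sample t by hand.
oracle_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
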