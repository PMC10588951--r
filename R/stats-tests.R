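#' 2x2 genotype-by-dichotomy count table
#'
#' Rows are two genotypes, columns the tubules with fewer than vs at least
#' `threshold` apoptotic nuclei.
#'
#' @param row_a,row_b integer vectors `c(below, at_or_above)` for the two
#'   genotypes.
#' @param genotypes optional row labels.
#' @return 2x2 integer matrix of class `count_table_2x2`.
#' @export
count_table_2x2 <- function(row_a, row_b, genotypes = c("A", "B")) {
  tab <- rbind(row_a, row_b)
  if (!all(tab >= 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  dimnames(tab) <- list(genotype = genotypes,
                        tubules = c("lt_threshold", "ge_threshold"))
  class(tab) <- c("count_table_2x2", class(tab))
  tab
}

#' @export
print.count_table_2x2 <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Dichotomize per-tubule apoptosis counts at a threshold
#'
#' Splits tubules into those with fewer than `threshold` labelled nuclei
#' and those with `threshold` or more (the threshold is inclusive on the
#' high side: a count of exactly 5 falls in the "five or more" class).
#'
#' @param counts non-negative integer vector of per-tubule counts.
#' @param threshold dichotomy threshold (default 5).
#' @return named integer vector `c(below, at_or_above)`.
#' @export
dichotomize_tunel <- function(counts, threshold = 5L) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  c(below = sum(counts < threshold), at_or_above = sum(counts >= threshold))
}

new_test_result <- function(statistic, p_value, test, n, sided,
                            method = NULL, flags = character(0)) {
  structure(list(statistic = statistic, p_value = p_value, test = test,
                 n = n, sided = sided, method = method, flags = flags),
            class = "sc_test_result")
}

#' @export
print.sc_test_result <- function(x, ...) {
  cat(sprintf("%s (%s%s): statistic = %g, p = %g, n = %s\n",
              x$test, x$sided,
              if (!is.null(x$method)) paste0(", ", x$method) else "",
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples, as used for intensity
#' quantifications. The U statistic counts pairs where x exceeds y (ties
#' half). For small tie-free samples (`n_x + n_y <= 12`) the p-value is
#' exact; otherwise the normal approximation with tie correction and
#' continuity correction is used. The method is recorded.
#'
#' @param x,y numeric samples (non-empty).
#' @param sided `"two.sided"` (default), `"less"` or `"greater"`.
#' @return an `sc_test_result`.
#' @export
mann_whitney_u <- function(x, y, sided = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && (length(x) + length(y)) <= 12L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = sided, exact = exact, correct = TRUE))
  new_test_result(statistic = unname(wt$statistic), p_value = wt$p.value,
                  test = "Mann-Whitney U", n = c(length(x), length(y)),
                  sided = sided,
                  method = if (exact) "exact" else
                    "normal approximation (tie-corrected)")
}

#' Exact Mann-Whitney p-value by enumeration (validation oracle)
#'
#' Brute-force enumeration over all `choose(n_x + n_y, n_x)` group
#' assignments of the pooled sample; requires tie-free data. Two-sided
#' p doubles the smaller tail (capped at 1), matching the exact
#' convention of the test proper. Used to cross-check [mann_whitney_u()].
#'
#' @param x,y tie-free numeric samples.
#' @param sided sidedness.
#' @return exact p-value.
#' @export
mann_whitney_enum_p <- function(x, y, sided = "two.sided") {
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  if (anyDuplicated(c(x, y)) > 0L) stop("enumeration oracle requires tie-free data")
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_stat(x, y)
  idx <- combn(length(pooled), nx)
  u_all <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  switch(sided,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact test of association for a dichotomized count table (e.g. tubules
#' with fewer than vs at least five apoptotic nuclei per genotype).
#' Two-sided p sums hypergeometric probabilities of tables no more likely
#' than the observed one (the minimum-likelihood convention).
#'
#' @param table a [count_table_2x2()] or bare 2x2 matrix.
#' @param sided `"two.sided"` (default), `"less"` or `"greater"`.
#' @return an `sc_test_result`; the statistic is the table's odds ratio
#'   (conditional MLE).
#' @export
fisher_exact_2x2 <- function(table, sided = "two.sided") {
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  tab <- unclass(table)
  if (!is.matrix(tab) || !all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("table entries must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("both margins must be positive for testing")
  }
  ft <- fisher.test(tab, alternative = sided)
  new_test_result(statistic = unname(ft$estimate), p_value = ft$p.value,
                  test = "Fisher's exact", n = rowSums(tab), sided = sided,
                  method = "hypergeometric (minimum likelihood)")
}

#' Fisher two-sided p by direct hypergeometric summation (oracle)
#'
#' Independent of [fisher_exact_2x2()]: enumerates all tables with the
#' observed margins and sums the probabilities of those no more likely
#' than the observed table (with the conventional relative tolerance for
#' ties).
#'
#' @param table 2x2 matrix.
#' @return two-sided p-value.
#' @export
fisher_enum_p <- function(table) {
  tab <- unclass(table)
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Unpaired t test
#'
#' Comparison of two group means (e.g. testis weights). Welch's unequal
#' variance form is the default; the pooled-variance form is available.
#' If both groups are constant with equal means, p = 1 is returned with a
#' flag.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param equal_variance use the pooled-variance (classic) form.
#' @param sided sidedness (default two-sided).
#' @return an `sc_test_result`.
#' @export
t_test_unpaired <- function(x, y, equal_variance = FALSE,
                            sided = "two.sided") {
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  res <- tryCatch(
    t.test(x, y, var.equal = equal_variance, alternative = sided),
    error = function(e) NULL)
  if (is.null(res)) {
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      return(new_test_result(0, 1, "unpaired t", c(length(x), length(y)),
                             sided,
                             method = if (equal_variance) "pooled" else "Welch",
                             flags = "zero variance in both groups"))
    }
    stop("t test failed on degenerate input")
  }
  new_test_result(unname(res$statistic), res$p.value, "unpaired t",
                  c(length(x), length(y)), sided,
                  method = if (equal_variance) "pooled" else "Welch")
}
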