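# Relative risk from a 2x2 table (Katz log-RR interval) and rank tests.

#' Relative risk with Katz confidence interval from a 2x2 table
#'
#' Rows are exposure groups, columns are (event, no event). RR is the risk in
#' row 1 relative to row 2; the 95% CI uses the Katz log-RR normal method.
#' The p-value comes from Pearson's chi-square test (without continuity
#' correction), switching to Fisher's exact test when any expected cell count
#' is below 5.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @return List of class `"rr_result"`: `rr`, `ci_low`, `ci_high`, `p_value`,
#'   `method`, `table`. `rr` is `NA` (flagged via `undefined = TRUE`) when both
#'   rows have zero events.
#' @examples
#' rr_from_table(matrix(c(20, 10, 80, 90), nrow = 2))  # RR = 2
#' @export
rr_from_table <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  if (n1 == 0 || n2 == 0) stop("zero row total")
  a <- tab[1, 1]; c2 <- tab[2, 1]
  undefined <- (a + c2) == 0
  rr <- if (undefined) NA_real_ else (a / n1) / (c2 / n2)
  if (!undefined && a > 0 && c2 > 0) {
    se <- sqrt(1 / a - 1 / n1 + 1 / c2 - 1 / n2)
    ci <- exp(log(rr) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    method <- "chisq"
  }
  out <- list(rr = rr, ci_low = ci[1], ci_high = ci[2], p_value = p,
              method = method, table = tab, undefined = undefined)
  class(out) <- "rr_result"
  out
}

#' @export
print.rr_result <- function(x, ...) {
  cat("RR =", format(x$rr, digits = 4),
      sprintf("[%s, %s], p = %s (%s)\n",
              format(x$ci_low, digits = 4), format(x$ci_high, digits = 4),
              format(x$p_value, digits = 4), x$method))
  invisible(x)
}

#' Wilcoxon rank test (signed-rank or rank-sum)
#'
#' `paired = TRUE` runs the Wilcoxon signed-rank test (exact null for n <= 25
#' without ties, otherwise normal approximation with continuity correction);
#' `paired = FALSE` runs the Mann-Whitney rank-sum test with tie-corrected
#' normal approximation. Between-arm comparisons in the pipeline are unpaired;
#' within-patient comparisons across timepoints are paired.
#'
#' @param values_a,values_b Numeric samples (equal length when paired).
#' @param paired Logical.
#' @return List of class `"bct_test"`: `statistic`, `df`, `p_value`, `method`.
#' @export
rank_test <- function(values_a, values_b, paired = FALSE) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) == 0L || length(values_b) == 0L) stop("empty input")
  if (paired) {
    if (length(values_a) != length(values_b)) stop("paired samples must have equal length")
    d <- values_a - values_b
    if (all(d == 0)) stop("all paired differences are zero")
    wt <- stats::wilcox.test(values_a, values_b, paired = TRUE,
                             exact = length(d[d != 0]) <= 25L && !any(duplicated(abs(d[d != 0]))),
                             correct = TRUE)
    method <- "wilcoxon signed-rank"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = FALSE,
                         exact = FALSE, correct = TRUE))
    method <- "mann-whitney rank-sum"
  }
  out <- list(statistic = unname(wt$statistic), df = NA_integer_,
              p_value = wt$p.value, method = method)
  class(out) <- "bct_test"
  out
}
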