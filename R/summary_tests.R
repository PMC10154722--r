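#' Pooled-variance two-sample t test from summary statistics
#'
#' Computes the independent-samples Student t test (pooled variance,
#' two-tailed) directly from group means, standard deviations and sizes, as
#' used when only published summary tables are available. Degrees of freedom
#' are `n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param label optional comparison label carried into the result.
#' @return A one-row data frame of class `preclinq_test` with columns
#'   `label`, `kind` ("t"), `statistic`, `df`, `p`, `p_adj` (equal to `p`
#'   here), `effect` (Cohen's d via [t_to_d()]) and `effect_type`.
#' @examples
#' ## glutamine, mutant vs control summary from a published table
#' pooled_t_from_summary(2.29, 0.23, 12, 2.84, 0.34, 12)
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  label = "group1 vs group2") {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("degenerate variance: both group SDs are zero")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  new_test_result(label = label, kind = "t", statistic = tstat,
                  df1 = df, df2 = NA_real_, p = p, p_adj = p,
                  effect = t_to_d(tstat, df), effect_type = "cohens_d")
}

## internal constructor for the common result row shape
new_test_result <- function(label, kind, statistic, df1, df2, p, p_adj,
                            effect, effect_type) {
  stopifnot(p >= 0, p <= 1, p_adj + 1e-12 >= p)
  out <- data.frame(label = label, kind = kind, statistic = statistic,
                    df1 = df1, df2 = df2, p = p, p_adj = min(1, p_adj),
                    effect = effect, effect_type = effect_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("preclinq_test", class(out))
  out
}
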