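#' Convert a t statistic to Cohen's d
#'
#' Between-group standardized effect size computed from the test statistic,
#' using the convention
#' \deqn{d = 2t / \sqrt{df}.}
#' The sign of `t` is preserved. For a plain two-sample comparison with equal
#' group sizes and `df = n1 + n2 - 2` this approaches the usual
#' mean-difference/pooled-SD definition; for post-hoc comparisons that pool
#' residual variance across regions (larger `df`), the two conventions
#' deliberately differ and this package reports the test-statistic-based one
#' throughout.
#'
#' @param t t statistic.
#' @param df degrees of freedom of the test (> 0).
#' @return Cohen's d (numeric, same length as `t`).
#' @examples
#' t_to_d(4.60, 22)   # 1.96
#' t_to_d(2.54, 40)   # 0.80
#' @export
t_to_d <- function(t, df) {
  stopifnot(is.numeric(t), is.numeric(df), all(df > 0))
  2 * t / sqrt(df)
}

#' Convert an F statistic to partial eta squared
#'
#' \deqn{\eta^2_p = F \cdot df_1 / (F \cdot df_1 + df_2)}
#' i.e. the proportion of effect-plus-error variance attributable to the
#' effect, recovered from the test statistic and its degrees of freedom.
#' Values lie in `[0, 1)`.
#'
#' @param f F statistic (>= 0).
#' @param df1 numerator degrees of freedom (> 0).
#' @param df2 denominator degrees of freedom (> 0).
#' @return Partial eta squared (numeric).
#' @examples
#' f_to_eta2(11.91, 1, 20)  # 0.37
#' f_to_eta2(0.68, 4, 66)   # 0.04
#' @export
f_to_eta2 <- function(f, df1, df2) {
  stopifnot(is.numeric(f), all(f >= 0), all(df1 > 0), all(df2 > 0))
  f * df1 / (f * df1 + df2)
}
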