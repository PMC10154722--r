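#' CRLB quality-control filter for metabolite concentrations
#'
#' Removes metabolite concentration estimates whose Cramer-Rao lower bound
#' (expressed as %SD) marks them as not accurately detectable. The boundary
#' is inclusive: an entry with `crlb >= threshold` is discarded.
#'
#' @param table metabolite table with columns `subject`, `genotype`,
#'   `metabolite`, `concentration`, `crlb` (%SD).
#' @param threshold rejection threshold in %SD (default 20).
#' @return List with `table` (retained rows) and `rejected` (removed rows,
#'   the rejection log; zero rows when nothing is discarded).
#' @export
apply_crlb_filter <- function(table, threshold = 20) {
  check_metabolite_table(table)  # validate only; rows pass through untouched
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  drop <- table$crlb >= threshold
  out <- list(table = table[!drop, , drop = FALSE],
              rejected = table[drop, , drop = FALSE])
  if (nrow(out$table) == 0)
    warning("CRLB filter removed every row")
  out
}

#' Pooled z-scores of metabolite concentrations
#'
#' Standardizes each concentration against the pooled (both genotypes
#' combined) per-metabolite mean and sample SD (n - 1 denominator), the form
#' used to display different metabolites on a common scale.
#'
#' @param table metabolite table (see [apply_crlb_filter()]).
#' @return The table with an added `z` column.
#' @export
compute_zscores <- function(table) {
  table <- check_metabolite_table(table)
  n_by <- table(table$metabolite)
  if (any(n_by < 2)) stop("need >= 2 observations per metabolite")
  mu <- stats::ave(table$concentration, table$metabolite, FUN = mean)
  sd_ <- stats::ave(table$concentration, table$metabolite, FUN = stats::sd)
  if (any(sd_ == 0)) {
    bad <- unique(table$metabolite[sd_ == 0])
    stop("zero pooled SD for metabolite(s): ", paste(bad, collapse = ", "))
  }
  table$z <- (table$concentration - mu) / sd_
  table
}

#' Bonferroni-corrected genotype comparisons per metabolite
#'
#' For each metabolite, compares the two genotype groups with a
#' pooled-variance (Student) two-sample t test, two-tailed, and applies a
#' Bonferroni correction `p_adj = min(1, m * p)`. The correction multiplier
#' `m` defaults to the number of metabolites tested but is exposed because
#' the appropriate family size is a design choice, not a property of the
#' table. Cohen's d is attached via [t_to_d()].
#'
#' Direction: group 2 minus group 1 in the factor-level order of `genotype`.
#'
#' @param table metabolite table (typically after [apply_crlb_filter()]).
#' @param n_comparisons Bonferroni multiplier `m`; default = number of
#'   metabolites in the table.
#' @return `preclinq_test` data frame, one row per metabolite.
#' @export
metabolite_group_tests <- function(table, n_comparisons = NULL) {
  table <- check_metabolite_table(table)
  g_lev <- levels(table$genotype)
  if (length(g_lev) != 2) stop("need exactly 2 genotype levels")
  mets <- levels(table$metabolite)
  m <- if (is.null(n_comparisons)) length(mets) else n_comparisons
  stopifnot(m >= 1)
  rows <- lapply(mets, function(met) {
    sub <- table[table$metabolite == met, , drop = FALSE]
    x2 <- sub$concentration[sub$genotype == g_lev[2]]
    x1 <- sub$concentration[sub$genotype == g_lev[1]]
    if (length(x1) < 2 || length(x2) < 2)
      stop("metabolite '", met, "': < 2 subjects in a genotype group")
    df <- length(x1) + length(x2) - 2
    sp2 <- ((length(x1) - 1) * stats::var(x1) +
              (length(x2) - 1) * stats::var(x2)) / df
    if (sp2 == 0) {
      tstat <- 0
      p <- 1
    } else {
      tstat <- (mean(x2) - mean(x1)) /
        sqrt(sp2 * (1 / length(x1) + 1 / length(x2)))
      p <- 2 * stats::pt(-abs(tstat), df)
    }
    new_test_result(label = paste0(met, ": ", g_lev[2], " vs ", g_lev[1]),
                    kind = "t", statistic = tstat, df1 = df, df2 = NA_real_,
                    p = p, p_adj = min(1, m * p),
                    effect = t_to_d(tstat, df), effect_type = "cohens_d")
  })
  do.call(rbind, rows)
}

check_metabolite_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("subject", "genotype", "metabolite", "concentration", "crlb")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("metabolite table lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(is.numeric(table$concentration), is.numeric(table$crlb))
  if (any(table$concentration < 0)) stop("negative concentration")
  if (any(table$crlb < 0)) stop("negative CRLB")
  table$genotype <- droplevels(factor(table$genotype))
  table$metabolite <- droplevels(factor(table$metabolite))
  if (anyDuplicated(table[, c("subject", "metabolite")]))
    stop("(subject, metabolite) pairs must be unique")
  table
}
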