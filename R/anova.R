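#' Genotype x ROI split-plot (mixed) ANOVA
#'
#' Tests a between-subject genotype factor, a within-subject ROI factor and
#' their interaction on a long-format regional table. With complete data
#' (every subject measured in every ROI) the classical split-plot
#' sums-of-squares decomposition is used: genotype is tested against the
#' between-subject (subject-within-genotype) mean square, ROI and
#' genotype x ROI against the within-subject residual mean square. Unequal
#' genotype group sizes are allowed; the factors remain orthogonal because
#' every subject contributes every ROI. When individual subject x ROI cells
#' are missing, a REML linear mixed model with a random subject intercept
#' (`lme4`/`lmerTest`, type-3 F tests with Satterthwaite degrees of freedom)
#' supplies the F statistics instead.
#'
#' Partial eta squared is attached to each effect via [f_to_eta2()].
#'
#' @param table data frame with columns `subject`, `genotype`, `roi`,
#'   `value`. Whole subjects absent from the table are simply not analyzed;
#'   `NA` values or absent subject x ROI rows trigger the mixed-model path.
#' @return Data frame of class `preclinq_anova` with one row per effect
#'   (`genotype`, `roi`, `genotype:roi`) and columns `effect`, `F`, `df1`,
#'   `df2`, `p`, `eta2p`; attribute `method` is `"ss"` (closed form) or
#'   `"reml"`.
#' @seealso [bonferroni_posthoc()] for interaction follow-up.
#' @export
mixed_anova <- function(table) {
  table <- check_regional_table(table)
  if (nlevels(table$roi) < 2)
    stop("need >= 2 ROIs for a genotype x ROI model")
  n_per_geno <- tapply(table$subject, table$genotype,
                       function(s) length(unique(s)))
  if (any(is.na(n_per_geno)) || length(n_per_geno) < 2 || any(n_per_geno < 2))
    stop("each genotype needs >= 2 subjects")

  complete <- !anyNA(table$value) &&
    all(table(table$subject, table$roi) == 1)
  if (complete) {
    res <- split_plot_ss(table)
    method <- "ss"
  } else {
    res <- reml_anova(table)
    method <- "reml"
  }
  res$eta2p <- f_to_eta2(res$F, res$df1, res$df2)
  attr(res, "method") <- method
  class(res) <- c("preclinq_anova", class(res))
  res
}

## closed-form split-plot decomposition; complete data, unequal group n allowed
split_plot_ss <- function(table) {
  y <- table$value
  geno <- table$genotype
  roi <- table$roi
  subj <- table$subject
  r <- nlevels(roi)
  g <- nlevels(geno)
  subj_means <- tapply(y, subj, mean)
  subj_geno <- tapply(as.character(geno), subj, function(x) x[1])
  n_s <- length(subj_means)
  grand <- mean(y)

  ss_between <- r * sum((subj_means - grand)^2)
  geno_means <- tapply(y, geno, mean)
  n_i <- tapply(subj, geno, function(s) length(unique(s)))
  ss_geno <- r * sum(n_i * (geno_means - grand)^2)
  ss_subj <- ss_between - ss_geno

  roi_means <- tapply(y, roi, mean)
  ss_roi <- n_s * sum((roi_means - grand)^2)

  cell_means <- tapply(y, list(geno, roi), mean)
  ss_cells <- sum(outer(n_i, rep(1, r)) * (cell_means - grand)^2)
  ss_int <- ss_cells - ss_geno - ss_roi

  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_between - ss_roi - ss_int

  df_geno <- g - 1
  df_subj <- n_s - g
  df_roi <- r - 1
  df_int <- (g - 1) * (r - 1)
  df_err <- (n_s - g) * (r - 1)

  f_geno <- (ss_geno / df_geno) / (ss_subj / df_subj)
  f_roi <- (ss_roi / df_roi) / (ss_err / df_err)
  f_int <- (ss_int / df_int) / (ss_err / df_err)

  data.frame(
    effect = c("genotype", "roi", "genotype:roi"),
    F = c(f_geno, f_roi, f_int),
    df1 = c(df_geno, df_roi, df_int),
    df2 = c(df_subj, df_err, df_err),
    p = stats::pf(c(f_geno, f_roi, f_int),
                  c(df_geno, df_roi, df_int),
                  c(df_subj, df_err, df_err), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

reml_anova <- function(table) {
  table <- table[!is.na(table$value), , drop = FALSE]
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- lmerTest::lmer(value ~ genotype * roi + (1 | subject), data = table)
  an <- stats::anova(fit, type = 3)
  idx <- match(c("genotype", "roi", "genotype:roi"), rownames(an))
  data.frame(
    effect = c("genotype", "roi", "genotype:roi"),
    F = an$`F value`[idx],
    df1 = an$NumDF[idx],
    df2 = an$DenDF[idx],
    p = an$`Pr(>F)`[idx],
    stringsAsFactors = FALSE
  )
}

#' Bonferroni-adjusted per-ROI genotype post-hoc tests
#'
#' Follow-up of a significant genotype x ROI interaction: within each ROI the
#' two genotypes are compared with a t test whose variance is the pooled
#' residual variance of the full cell-means (genotype x ROI) model, with
#' `df = N_obs - n_genotypes * n_ROIs`. P values are Bonferroni-adjusted by
#' the number of ROIs tested and Cohen's d is attached via [t_to_d()] at the
#' same pooled df. With `method = "welch"` an ordinary per-ROI Welch t test
#' is used instead (no variance pooling across ROIs).
#'
#' The comparison direction is group 2 minus group 1 in the factor-level
#' order of `genotype` (so with levels control, mutant a positive statistic
#' means mutant > control).
#'
#' @param table regional long table (`subject`, `genotype`, `roi`, `value`).
#' @param rois ROIs to test (default all in the table).
#' @param method `"pooled"` (default) or `"welch"`.
#' @return `preclinq_test` data frame, one row per ROI.
#' @export
bonferroni_posthoc <- function(table, rois = NULL,
                               method = c("pooled", "welch")) {
  method <- match.arg(method)
  table <- check_regional_table(table)
  table <- table[!is.na(table$value), , drop = FALSE]
  if (is.null(rois)) rois <- levels(table$roi)
  m <- length(rois)
  g_lev <- levels(table$genotype)
  if (length(g_lev) != 2) stop("post-hoc tests need exactly 2 genotypes")

  if (method == "pooled") {
    cell <- interaction(table$genotype, table$roi, drop = TRUE)
    resid2 <- (table$value - stats::ave(table$value, cell))^2
    df <- nrow(table) - nlevels(table$genotype) * nlevels(table$roi)
    if (df <= 0) stop("not enough observations for the cell-means model")
    s2 <- sum(resid2) / df
  }

  rows <- lapply(rois, function(rn) {
    sub <- table[table$roi == rn, , drop = FALSE]
    n1 <- sum(sub$genotype == g_lev[1])
    n2 <- sum(sub$genotype == g_lev[2])
    if (n1 == 0 || n2 == 0) {
      warning("ROI '", rn, "' has an empty genotype cell; skipped")
      return(NULL)
    }
    delta <- mean(sub$value[sub$genotype == g_lev[2]]) -
      mean(sub$value[sub$genotype == g_lev[1]])
    if (method == "pooled") {
      if (s2 <= 0) {
        ## perfectly fitting cell-means model: only the sign is defined
        tstat <- if (delta == 0) 0 else sign(delta) * Inf
      } else {
        tstat <- delta / sqrt(s2 * (1 / n1 + 1 / n2))
      }
      df_t <- df
    } else {
      ht <- stats::t.test(sub$value[sub$genotype == g_lev[2]],
                          sub$value[sub$genotype == g_lev[1]],
                          var.equal = FALSE)
      tstat <- unname(ht$statistic)
      df_t <- unname(ht$parameter)
    }
    p <- 2 * stats::pt(-abs(tstat), df_t)
    new_test_result(label = paste0(rn, ": ", g_lev[2], " vs ", g_lev[1]),
                    kind = "t", statistic = tstat, df1 = df_t, df2 = NA_real_,
                    p = p, p_adj = min(1, m * p),
                    effect = t_to_d(tstat, df_t), effect_type = "cohens_d")
  })
  do.call(rbind, rows)
}

#' Covariate-adjusted genotype test (ANCOVA)
#'
#' Fits `value ~ covariates + genotype` by least squares on a subject-level
#' table and reports the F test for genotype adjusted for the covariates
#' (full vs covariates-only model comparison), with partial eta squared
#' attached. Used for supplementary checks that a genotype effect survives
#' adjustment for e.g. sex or a per-subject fit-quality measure.
#'
#' @param table data frame with one row per subject: columns `genotype`,
#'   `value`, plus the covariate columns.
#' @param covariates character vector of covariate column names.
#' @return `preclinq_test` row (`kind = "F"`, effect = partial eta squared).
#' @export
ancova_adjust <- function(table, covariates) {
  stopifnot(is.data.frame(table), all(c("genotype", "value") %in% names(table)),
            length(covariates) >= 1, all(covariates %in% names(table)))
  table <- stats::na.omit(table[, c("value", "genotype", covariates)])
  table$genotype <- droplevels(factor(table$genotype))
  if (nlevels(table$genotype) != 2) stop("need exactly 2 genotype levels")
  for (cv in covariates) {
    v <- table[[cv]]
    if (is.character(v)) table[[cv]] <- factor(v)
    if (length(unique(v)) < 2)
      stop("covariate '", cv, "' does not vary within the sample")
  }
  f_red <- stats::reformulate(covariates, response = "value")
  f_full <- stats::reformulate(c(covariates, "genotype"), response = "value")
  fit_full <- stats::lm(f_full, data = table)
  if (anyNA(stats::coef(fit_full)))
    stop("collinear covariate: genotype-adjusted model is rank deficient")
  if (summary(fit_full)$sigma < 1e-10 * max(stats::sd(table$value), 1e-10))
    stop("collinear covariate: model fits the outcome exactly, ",
         "no residual variance for the genotype test")
  fit_red <- stats::lm(f_red, data = table)
  cmp <- stats::anova(fit_red, fit_full)
  Fst <- cmp$F[2]
  df1 <- cmp$Df[2]
  df2 <- cmp$Res.Df[2]
  new_test_result(label = paste0("genotype | ",
                                 paste(covariates, collapse = " + ")),
                  kind = "F", statistic = Fst, df1 = df1, df2 = df2,
                  p = cmp$`Pr(>F)`[2], p_adj = cmp$`Pr(>F)`[2],
                  effect = f_to_eta2(Fst, df1, df2),
                  effect_type = "partial_eta2")
}

## validate/coerce a long regional table
check_regional_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("subject", "genotype", "roi", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("regional table lacks column(s): ", paste(miss, collapse = ", "))
  table$subject <- factor(table$subject)
  table$genotype <- droplevels(factor(table$genotype))
  table$roi <- droplevels(factor(table$roi))
  stopifnot(is.numeric(table$value))
  ## a subject must belong to exactly one genotype
  k <- tapply(as.character(table$genotype), table$subject,
              function(x) length(unique(x)))
  if (any(k != 1)) stop("subjects must each have a single genotype")
  table
}
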