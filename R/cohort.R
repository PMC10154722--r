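#' Cohort specification for the synthetic-data generator
#'
#' Describes the cohort every synthetic modality is generated for: group
#' sizes, sex composition, the per-ROI perfusion effect sizes, the
#' per-modality missing-data pattern, and the master seed. Defaults emulate
#' a two-genotype mouse cohort of 12 mutants (9 female, 3 male) and 12
#' wild-type controls (5 female, 7 male), with whole subjects missing per
#' modality: 2 controls for perfusion; 3 controls + 1 mutant for the SV2A
#' ligand; 1 control + 2 mutants for the GABA-A alpha5 ligand; 2 controls +
#' 3 mutants for the benzodiazepine-site ligand; none for spectroscopy.
#'
#' `roi_effects` are expressed in the effect-size metric the analysis
#' reports (Cohen's d computed as `2t/sqrt(df)` from the pooled-residual
#' post-hoc test); the perfusion generator converts them to raw mean shifts
#' via the estimator's sampling expectation, see
#' [delta_for_reported_d()].
#'
#' @param n_per_genotype named count vector `c(control = , mutant = )`,
#'   each >= 2.
#' @param sex_female named vector: number of female subjects per genotype.
#' @param roi_effects named numeric vector, ROI name -> reported-d genotype
#'   difference (mutant minus control) in normalized CBF ratio.
#' @param missing named list, modality -> named count vector of subjects to
#'   drop per genotype. Subjects are dropped deterministically from the end
#'   of each genotype's roster, mirroring a fixed per-modality loss pattern.
#' @param seed master integer seed; each modality derives its own fixed
#'   offset stream from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_genotype = c(control = 12, mutant = 12),
                        sex_female = c(control = 5, mutant = 9),
                        roi_effects = c(vHip = 0.8),
                        missing = list(
                          cbf = c(control = 2, mutant = 0),
                          mrs = c(control = 0, mutant = 0),
                          ucbj = c(control = 3, mutant = 1),
                          ro15 = c(control = 1, mutant = 2),
                          flumazenil = c(control = 2, mutant = 3)),
                        seed = 1L) {
  stopifnot(all(c("control", "mutant") %in% names(n_per_genotype)),
            all(n_per_genotype >= 2),
            all(is.finite(roi_effects)),
            all(c("control", "mutant") %in% names(sex_female)),
            all(sex_female >= 0),
            all(sex_female <= n_per_genotype[names(sex_female)]),
            is.numeric(seed), length(seed) == 1)
  for (mod in names(missing)) {
    mm <- missing[[mod]]
    stopifnot(all(names(mm) %in% names(n_per_genotype)))
    if (any(mm >= n_per_genotype[names(mm)]))
      stop("missing counts must be smaller than the group size (", mod, ")")
  }
  structure(list(n_per_genotype = n_per_genotype, sex_female = sex_female,
                 roi_effects = roi_effects, missing = missing,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Subject roster implied by a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return Data frame `subject`, `genotype`, `sex` (female subjects listed
#'   first within each genotype).
#' @export
cohort_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- lapply(c("control", "mutant"), function(g) {
    n <- spec$n_per_genotype[[g]]
    nf <- spec$sex_female[[g]]
    data.frame(
      subject = sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n)),
      genotype = g,
      sex = c(rep("F", nf), rep("M", n - nf)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$genotype <- factor(out$genotype, levels = c("control", "mutant"))
  out
}

#' Apply a modality's missing-data pattern to the roster
#'
#' Drops the configured number of subjects per genotype, deterministically
#' from the end of each genotype's roster.
#'
#' @param subjects roster from [cohort_subjects()].
#' @param spec a [cohort_spec()].
#' @param modality name of an entry of `spec$missing` (unlisted modalities
#'   lose no subjects).
#' @return Reduced roster data frame.
#' @export
apply_missing <- function(subjects, spec, modality) {
  mm <- spec$missing[[modality]]
  if (is.null(mm)) return(subjects)
  keep <- unlist(lapply(split(seq_len(nrow(subjects)), subjects$genotype),
                        function(i) {
                          g <- as.character(subjects$genotype[i[1]])
                          k <- if (g %in% names(mm)) mm[[g]] else 0
                          utils::head(i, length(i) - k)
                        }))
  subjects[sort(keep), , drop = FALSE]
}

#' Raw standardized shift that yields a target reported d
#'
#' The analysis reports Cohen's d as `2t/sqrt(df)` from a pooled-residual
#' post-hoc t test. For a generator that wants the *expected reported* d to
#' equal a target, the raw standardized mean difference delta (in units of
#' the within-ROI SD) must satisfy
#' `E[d_hat] = 2 a(df) ncp / sqrt(df)` with `ncp = delta /
#' sqrt(1/n1 + 1/n2)` and `a(df) = sqrt(df/2) Gamma((df-1)/2) / Gamma(df/2)`
#' (the mean inflation of a noncentral t). This function inverts that
#' relation.
#'
#' @param d target reported Cohen's d.
#' @param n1,n2 genotype group sizes entering the comparison (after any
#'   missing-data drops).
#' @param df degrees of freedom of the post-hoc t (for the pooled
#'   cell-means convention, `(n1 + n2) * r - 2 r` with `r` ROIs).
#' @return Standardized mean shift delta.
#' @export
delta_for_reported_d <- function(d, n1, n2, df) {
  stopifnot(df > 1, n1 >= 2, n2 >= 2)
  a <- sqrt(df / 2) * exp(lgamma((df - 1) / 2) - lgamma(df / 2))
  d * sqrt(df) * sqrt(1 / n1 + 1 / n2) / (2 * a)
}

#' Noncentrality that yields a target mean partial eta squared
#'
#' Numerically solves `E[F df1 / (F df1 + df2)] = eta2` over the noncentral
#' F(df1, df2, ncp) distribution, so a generator can place a genotype main
#' effect whose *expected estimated* partial eta squared matches a target.
#' Targets at or below the null expectation (the mean estimate under
#' ncp = 0 is positive) are rejected.
#'
#' @param eta2 target mean partial eta squared, in (0, 1).
#' @param df1,df2 degrees of freedom of the F test.
#' @return Noncentrality parameter.
#' @export
ncp_for_eta2 <- function(eta2, df1, df2) {
  stopifnot(eta2 > 0, eta2 < 1, df1 > 0, df2 > 2)
  mean_eta2 <- function(ncp) {
    stats::integrate(function(x) stats::df(x, df1, df2, ncp) *
                       (x * df1 / (x * df1 + df2)),
                     0, Inf, rel.tol = 1e-9)$value
  }
  null_mean <- mean_eta2(0)
  if (eta2 <= null_mean)
    stop("target eta2 (", eta2, ") is not above the null expectation (",
         signif(null_mean, 3), "); use a zero effect instead")
  stats::uniroot(function(ncp) mean_eta2(ncp) - eta2,
                 lower = 0, upper = 500, tol = 1e-8)$root
}
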