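#' Configuration of a synthetic autoradiography film experiment
#'
#' Generating model for one radioligand: a saturating film-response curve
#' `OD = b + A (1 - exp(-k * activity))` shared by the tritium standards and
#' the tissue sections, per-ROI true specific binding (micro-Ci/mg), a
#' between-subject binding SD and a subject-by-ROI residual SD, three
#' consecutive sections per subject and ROI, and (optionally) a nonspecific
#' condition. A genotype main effect is placed as a uniform binding
#' reduction in mutants whose magnitude is solved from a target mean partial
#' eta squared via [ncp_for_eta2()] at the post-missingness group sizes.
#'
#' Ligand presets: `"ucbj"` (5 hippocampal ROIs including dentate gyrus,
#' minimal nonspecific binding, genotype effect eta2 = 0.29), `"ro15"` and
#' `"flumazenil"` (4 ROIs, no nonspecific binding, no genotype effect).
#'
#' @param ligand preset name, or `"custom"` to take every field from the
#'   arguments.
#' @param rois named numeric vector of control-group true binding means per
#'   ROI (micro-Ci/mg).
#' @param eta2_genotype target mean partial eta squared of the genotype
#'   main effect (`NULL` or 0 for no effect; mutants lower).
#' @param nonspecific true nonspecific binding level (micro-Ci/mg), or
#'   `NULL` when the ligand has none.
#' @param subject_sd,roi_sd between-subject and subject-by-ROI residual SDs
#'   of true binding.
#' @param n_sections sections per subject and ROI.
#' @param section_sd SD of per-section activity around the subject-ROI
#'   truth.
#' @param curve list `b`, `A`, `k` of film-response parameters (must be
#'   monotone increasing: `A, k > 0`).
#' @param standards activities of the tritium standards (>= 6 levels).
#' @param n_films number of films the cohort is spread over (one standards
#'   slide, hence one fitted curve, per film).
#' @param standards_od_sd,sections_od_sd additive OD noise SDs.
#' @return List of class `autorad_config`.
#' @export
autorad_config <- function(ligand = c("ucbj", "ro15", "flumazenil", "custom"),
                           rois = NULL, eta2_genotype = NULL,
                           nonspecific = NULL,
                           subject_sd = 0.5, roi_sd = 0.3,
                           n_sections = 3, section_sd = 0.05,
                           curve = list(b = 0.05, A = 1.8, k = 0.25),
                           standards = c(0.25, 0.5, 1, 2, 3.5, 5, 7, 10),
                           n_films = 2,
                           standards_od_sd = 0.01, sections_od_sd = 0.005) {
  ligand <- match.arg(ligand)
  presets <- list(
    ucbj = list(rois = c(dHipCA1 = 3.2, mHipCA3 = 3.5, mHipCA12 = 3.4,
                         vHipCA3 = 3.0, dHipDG = 3.8),
                eta2 = 0.29, nonspecific = 0.15),
    ro15 = list(rois = c(dHipCA1 = 2.6, mHipCA3 = 2.2, mHipCA12 = 2.5,
                         vHipCA3 = 2.0),
                eta2 = NULL, nonspecific = NULL),
    flumazenil = list(rois = c(dHipCA1 = 3.0, mHipCA3 = 2.6,
                               mHipCA12 = 2.9, vHipCA3 = 2.3),
                      eta2 = NULL, nonspecific = NULL))
  if (ligand != "custom") {
    p <- presets[[ligand]]
    if (is.null(rois)) rois <- p$rois
    if (is.null(eta2_genotype)) eta2_genotype <- p$eta2
    if (is.null(nonspecific)) nonspecific <- p$nonspecific
  }
  stopifnot(!is.null(rois), !is.null(names(rois)), all(rois > 0),
            length(standards) >= 6, all(standards > 0),
            subject_sd >= 0, roi_sd >= 0, section_sd >= 0, n_sections >= 1,
            n_films >= 1)
  if (!(curve$A > 0 && curve$k > 0))
    stop("film-response curve must be monotone increasing (A, k > 0)")
  structure(list(ligand = ligand, rois = rois,
                 eta2_genotype = eta2_genotype, nonspecific = nonspecific,
                 subject_sd = subject_sd, roi_sd = roi_sd,
                 n_sections = n_sections, section_sd = section_sd,
                 curve = curve, standards = standards, n_films = n_films,
                 standards_od_sd = standards_od_sd,
                 sections_od_sd = sections_od_sd),
            class = "autorad_config")
}

film_response <- function(curve, activity) {
  curve$b + curve$A * (1 - exp(-curve$k * activity))
}

#' Simulate a film autoradiography experiment for a cohort
#'
#' Generates, per film, the tritium standards table (known activities plus
#' their noisy ODs through the generating film-response curve) and the ROI
#' section OD table (three consecutive sections per subject and ROI, total
#' and — if configured — nonspecific condition), for the subjects retained
#' by the ligand's missing-data pattern. Subjects are assigned to films in
#' roster order. Optionally one standard on the first film is replaced by a
#' gross outlier to exercise the robust calibration.
#'
#' @param spec a [cohort_spec()].
#' @param config an [autorad_config()]; its `ligand` name selects the
#'   missing-data entry of the cohort spec.
#' @param outlier_standard if `TRUE`, the third standard of film 1 gets its
#'   OD replaced by a gross outlier (+1 OD).
#' @return List with `standards` (`film`, `activity`, `od`), `sections`
#'   (`film`, `subject`, `genotype`, `sex`, `roi`, `section`, `condition`,
#'   `od`) and `truth` (per-subject-ROI true specific binding, the
#'   generating curve, the applied genotype shift `delta`, roster).
#' @export
simulate_autorad_film <- function(spec, config = autorad_config("ucbj"),
                                  outlier_standard = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "autorad_config"))
  lig_index <- match(config$ligand, c("ucbj", "ro15", "flumazenil", "custom"))
  set.seed(spec$seed + 303L + 1000L * lig_index)
  subjects <- apply_missing(cohort_subjects(spec), spec, config$ligand)
  n <- nrow(subjects)
  r <- length(config$rois)
  n_g <- table(droplevels(subjects$genotype))

  delta <- 0
  if (!is.null(config$eta2_genotype) && config$eta2_genotype > 0) {
    df2 <- n - 2
    ncp <- ncp_for_eta2(config$eta2_genotype, 1, df2)
    var_submean <- config$subject_sd^2 + config$roi_sd^2 / r
    n_tilde <- prod(n_g) / sum(n_g)
    delta <- sqrt(ncp * var_submean / n_tilde)
  }

  subj_eff <- stats::rnorm(n, 0, config$subject_sd)
  truth_rows <- lapply(seq_len(n), function(i) {
    g <- as.character(subjects$genotype[i])
    mu <- config$rois - if (g == "mutant") delta else 0
    data.frame(subject = subjects$subject[i], genotype = g,
               sex = subjects$sex[i], roi = names(config$rois),
               binding = pmax(unname(mu) + subj_eff[i] +
                                stats::rnorm(r, 0, config$roi_sd), 0.01),
               stringsAsFactors = FALSE)
  })
  truth_binding <- do.call(rbind, c(truth_rows, make.row.names = FALSE))

  ## subjects assigned to films in roster order
  film_of <- stats::setNames(rep_len(paste0("film",
                                            seq_len(config$n_films)), n),
                             subjects$subject)

  standards <- do.call(rbind, lapply(unique(film_of), function(f) {
    od <- film_response(config$curve, config$standards) +
      stats::rnorm(length(config$standards), 0, config$standards_od_sd)
    data.frame(film = f, activity = config$standards, od = od,
               stringsAsFactors = FALSE)
  }))
  if (outlier_standard)
    standards$od[standards$film == unique(film_of)[1]][3] <-
      standards$od[standards$film == unique(film_of)[1]][3] + 1

  conditions <- c("total", if (!is.null(config$nonspecific)) "nonspecific")
  sec_rows <- lapply(seq_len(nrow(truth_binding)), function(i) {
    row <- truth_binding[i, ]
    out <- lapply(conditions, function(cond) {
      base <- if (cond == "total")
        row$binding + (config$nonspecific %||% 0) else config$nonspecific
      act <- pmax(base + stats::rnorm(config$n_sections, 0,
                                      config$section_sd), 0)
      od <- film_response(config$curve, act) +
        stats::rnorm(config$n_sections, 0, config$sections_od_sd)
      data.frame(film = film_of[[row$subject]], subject = row$subject,
                 genotype = row$genotype, sex = row$sex, roi = row$roi,
                 section = seq_len(config$n_sections), condition = cond,
                 od = od, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  sections <- do.call(rbind, c(sec_rows, make.row.names = FALSE))

  list(standards = standards, sections = sections,
       truth = list(subjects = subjects, binding = truth_binding,
                    curve = config$curve, delta = delta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
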