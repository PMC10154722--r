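#' Configuration of the synthetic perfusion modality
#'
#' Geometry, physiology and noise settings for the simulated pCASL data.
#' The image is a small desk-scale volume carrying a three-compartment atlas
#' (dorsal hippocampus `dHip`, ventral hippocampus `vHip`, rest-of-brain
#' `rest`) inside a rectangular brain mask; the analysis only needs labelled
#' masks, not realistic anatomy. Regional physiology is expressed as
#' CBF/whole-brain ratios (`rel_means`, between-subject SD `roi_sd`), with a
#' per-subject global CBF scale (`global_mean`/`global_sd`, ml/100 g/min);
#' the rest compartment absorbs whatever value makes each subject's
#' mask-mean ratio exactly 1, so normalized quantification recovers the
#' drawn ratios directly.
#'
#' @param dim volume dimensions (voxels).
#' @param rel_means named vector of true CBF/whole-brain ratio means for the
#'   named hippocampal ROIs (control group).
#' @param roi_sd between-subject SD of the ROI ratio values (shared across
#'   ROIs and genotypes, so the pooled post-hoc variance is well defined).
#' @param global_mean,global_sd per-subject whole-brain CBF distribution,
#'   ml/100 g/min.
#' @param t1 tissue T1 inside the brain, s.
#' @param si_control baseline control signal intensity (arbitrary units).
#' @param ie_mean,ie_sd per-subject true inversion efficiency distribution
#'   (truncated to `[0, 1]`).
#' @param n_pairs number of label/control pairs.
#' @param voxel_noise_sd additive Gaussian noise SD per voxel per repeat on
#'   the magnitude signal; 0 gives noiseless data.
#' @param ie_noise_sd per-component SD of circular complex Gaussian noise on
#'   the IE scan.
#' @return List of class `perfusion_config`.
#' @export
perfusion_config <- function(dim = c(32, 32, 10),
                             rel_means = c(dHip = 1.25, vHip = 1.05),
                             roi_sd = 0.10,
                             global_mean = 61, global_sd = 16,
                             t1 = 1.8, si_control = 100,
                             ie_mean = 0.85, ie_sd = 0.03,
                             n_pairs = 40,
                             voxel_noise_sd = 1,
                             ie_noise_sd = 0.5) {
  stopifnot(length(dim) == 3, all(dim[1:2] >= 16), dim[3] >= 6,
            roi_sd > 0, global_mean > 0,
            t1 > 0, si_control > 0, ie_mean >= 0, ie_mean <= 1,
            n_pairs >= 1, voxel_noise_sd >= 0, ie_noise_sd >= 0,
            length(rel_means) >= 2, !is.null(names(rel_means)))
  structure(as.list(environment()), class = "perfusion_config")
}

## deterministic 3-region atlas: two hippocampal boxes inside a brain box
make_atlas <- function(config) {
  d <- config$dim
  atlas <- array(0L, d)
  cx <- seq(5, d[1] - 4); cy <- seq(5, d[2] - 4); cz <- seq(2, d[3] - 1)
  atlas[cx, cy, cz] <- 3L  # rest of brain
  bx <- function(c0, w) seq(c0, c0 + w - 1)
  atlas[bx(8, 6), bx(8, 6), bx(3, 3)] <- 1L   # dHip
  atlas[bx(d[1] - 13, 6), bx(d[2] - 13, 6), bx(3, 3)] <- 2L  # vHip
  roi_labels <- c(dHip = 1L, vHip = 2L, rest = 3L)
  list(atlas = atlas, roi_labels = roi_labels, brain_mask = atlas > 0L)
}

#' Ground-truth regional physiology for a cohort
#'
#' Draws, per subject, the true regional CBF ratios, global CBF and
#' inversion efficiency that the image generator embeds and the
#' quantification chain recovers. Mutant ROI means are shifted by the raw
#' delta implied by `spec$roi_effects` (reported-d metric, converted with
#' [delta_for_reported_d()] at the post-missingness group sizes and the
#' pooled post-hoc df). This table-level layer is what Monte-Carlo studies
#' of the downstream statistics sample from.
#'
#' @param spec a [cohort_spec()].
#' @param config a [perfusion_config()].
#' @return List: `subjects` (full roster), `regional` (long data frame
#'   `subject`, `genotype`, `sex`, `roi`, `rel` true ratio, `cbf` true
#'   absolute CBF), `global` and `ie` per subject, and `delta` (the raw
#'   shift applied per affected ROI).
#' @export
simulate_cbf_truth <- function(spec, config = perfusion_config()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "perfusion_config"))
  unknown <- setdiff(names(spec$roi_effects), names(config$rel_means))
  if (length(unknown))
    stop("roi_effects name unknown ROI(s): ", paste(unknown, collapse = ", "))
  subjects <- cohort_subjects(spec)
  kept <- apply_missing(subjects, spec, "cbf")
  n_eff <- table(kept$genotype)
  r <- length(config$rel_means)
  df_post <- sum(n_eff) * r - 2 * r
  delta <- vapply(names(config$rel_means), function(rn) {
    d <- if (rn %in% names(spec$roi_effects)) spec$roi_effects[[rn]] else 0
    if (d == 0) 0 else
      delta_for_reported_d(d, n_eff[["control"]], n_eff[["mutant"]],
                           df_post) * config$roi_sd
  }, numeric(1))

  n <- nrow(subjects)
  global <- stats::rnorm(n, config$global_mean, config$global_sd)
  global <- pmax(global, config$global_mean * 0.2)  # physical floor
  ie <- pmin(pmax(stats::rnorm(n, config$ie_mean, config$ie_sd), 0), 1)
  rel <- sapply(names(config$rel_means), function(rn) {
    mu <- config$rel_means[[rn]] +
      ifelse(subjects$genotype == "mutant", delta[[rn]], 0)
    stats::rnorm(n, mu, config$roi_sd)
  })
  regional <- data.frame(
    subject = rep(subjects$subject, times = ncol(rel)),
    genotype = rep(subjects$genotype, times = ncol(rel)),
    sex = rep(subjects$sex, times = ncol(rel)),
    roi = rep(colnames(rel), each = n),
    rel = as.vector(rel),
    cbf = as.vector(rel) * rep(global, times = ncol(rel)),
    stringsAsFactors = FALSE)
  list(subjects = subjects, regional = regional,
       global = stats::setNames(global, subjects$subject),
       ie = stats::setNames(ie, subjects$subject),
       delta = delta)
}

#' Table-level synthetic regional CBF cohort
#'
#' Convenience wrapper: draws ground truth with [simulate_cbf_truth()]
#' (seeded from the cohort spec) and returns the normalized-ratio long table
#' for the subjects retained by the perfusion missing-data pattern — the exact
#' quantity the imaging chain recovers, without generating images.
#'
#' @param spec a [cohort_spec()].
#' @param config a [perfusion_config()].
#' @return Data frame `subject`, `genotype`, `sex`, `roi`, `value`.
#' @export
simulate_regional_cbf_table <- function(spec, config = perfusion_config()) {
  set.seed(spec$seed + 101L)
  truth <- simulate_cbf_truth(spec, config)
  kept <- apply_missing(truth$subjects, spec, "cbf")
  reg <- truth$regional[truth$regional$subject %in% kept$subject, , drop = FALSE]
  data.frame(subject = reg$subject, genotype = reg$genotype, sex = reg$sex,
             roi = reg$roi, value = reg$rel, stringsAsFactors = FALSE)
}

#' Simulate a complex inversion-efficiency scan
#'
#' Generates the complex control and label images of a carotid flow scan in
#' which, inside the carotid mask, the label signal is
#' `(1 - 2 * true_ie) * M_control` before noise, so [compute_ie()] recovers
#' `true_ie`. Noise is circular complex Gaussian, independent per component.
#'
#' @param true_ie true inversion efficiency in `[0, 1]`.
#' @param noise_sd per-component complex noise SD (0 = noiseless).
#' @param seed optional integer seed (omit when already inside a seeded
#'   stream).
#' @param dim 2D image dimensions.
#' @param magnitude,phase control-signal magnitude and global phase (rad).
#' @return List `control`, `label` (complex matrices), `carotid_mask`
#'   (logical matrix; two small bilateral carotid ROIs).
#' @export
simulate_ie_scan <- function(true_ie, noise_sd = 0, seed = NULL,
                             dim = c(16, 16), magnitude = 100, phase = 0.3) {
  if (!is.finite(true_ie) || true_ie < 0 || true_ie > 1)
    stop("true_ie must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(FALSE, dim[1], dim[2])
  mid <- floor(dim[1] / 2)
  mask[(mid - 1):mid, 4:5] <- TRUE
  mask[(mid - 1):mid, (dim[2] - 4):(dim[2] - 3)] <- TRUE
  ctrl <- matrix(complex(modulus = magnitude, argument = phase),
                 dim[1], dim[2])
  lbl <- ctrl
  lbl[mask] <- (1 - 2 * true_ie) * ctrl[mask]
  if (noise_sd > 0) {
    n <- prod(dim)
    ctrl <- ctrl + complex(real = stats::rnorm(n, 0, noise_sd),
                           imaginary = stats::rnorm(n, 0, noise_sd))
    lbl <- lbl + complex(real = stats::rnorm(n, 0, noise_sd),
                         imaginary = stats::rnorm(n, 0, noise_sd))
  }
  list(control = ctrl, label = lbl, carotid_mask = mask)
}

#' Simulate a cohort of pCASL perfusion datasets
#'
#' For every subject retained by the perfusion missing-data pattern, builds
#' the full image-level dataset: 40 label/control volumes whose mean
#' control-label difference equals the value implied by inverting the CBF
#' quantification model at the subject's true regional CBF, true inversion
#' efficiency and voxel T1; a complex IE scan; a T1 map; the 3-region atlas
#' and brain mask. Additive Gaussian noise is applied per voxel per repeat
#' on the magnitude images (`voxel_noise_sd = 0` gives data the chain
#' recovers exactly).
#'
#' @param spec a [cohort_spec()].
#' @param config a [perfusion_config()].
#' @param params an [acquisition_params()] object (also stored in the
#'   ground truth).
#' @return List with `datasets` (named list of `perfusion_dataset` objects)
#'   and `truth` (from [simulate_cbf_truth()], plus `params`).
#' @export
simulate_perfusion_dataset <- function(spec, config = perfusion_config(),
                                       params = acquisition_params()) {
  set.seed(spec$seed + 101L)
  truth <- simulate_cbf_truth(spec, config)
  kept <- apply_missing(truth$subjects, spec, "cbf")
  geom <- make_atlas(config)
  d <- config$dim
  t1 <- array(0, d)
  t1[geom$brain_mask] <- config$t1
  m0 <- config$si_control / (1 - exp(-params$tr / config$t1))
  ## ml/100g/min -> signal difference, inverse of the quantification model
  dsi_per_cbf <- 2 * params$t1_blood * m0 *
    (1 - exp(-params$tau / params$t1_blood)) /
    (6000 * params$lambda_bp * exp(params$pld / params$t1_blood))

  datasets <- lapply(seq_len(nrow(kept)), function(i) {
    sid <- kept$subject[i]
    rel_map <- array(0, d)
    reg <- truth$regional[truth$regional$subject == sid, , drop = FALSE]
    rel_named <- stats::setNames(reg$rel, reg$roi)
    ## rest compartment absorbs the remainder so the mask mean is exactly 1
    nm <- sum(geom$brain_mask)
    n_roi <- vapply(names(config$rel_means),
                    function(rn) sum(geom$atlas == geom$roi_labels[[rn]]),
                    numeric(1))
    n_rest <- nm - sum(n_roi)
    rest_rel <- (nm - sum(n_roi * rel_named[names(config$rel_means)])) / n_rest
    for (rn in names(config$rel_means))
      rel_map[geom$atlas == geom$roi_labels[[rn]]] <- rel_named[[rn]]
    rel_map[geom$atlas == geom$roi_labels[["rest"]]] <- rest_rel

    cbf_map <- rel_map * truth$global[[sid]]
    ie_true <- truth$ie[[sid]]
    dsi <- cbf_map * dsi_per_cbf * ie_true
    ctrl_base <- array(config$si_control, d)
    ctrl_base[!geom$brain_mask] <- config$si_control * 0.05
    lbl_base <- ctrl_base - dsi
    np <- config$n_pairs
    control <- array(rep(ctrl_base, np), c(d, np))
    label <- array(rep(lbl_base, np), c(d, np))
    if (config$voxel_noise_sd > 0) {
      control <- control + stats::rnorm(length(control), 0,
                                        config$voxel_noise_sd)
      label <- label + stats::rnorm(length(label), 0, config$voxel_noise_sd)
    }
    ie_scan <- simulate_ie_scan(ie_true, noise_sd = config$ie_noise_sd)
    structure(list(subject = sid, genotype = as.character(kept$genotype[i]),
                   sex = kept$sex[i],
                   control = control, label = label,
                   ie_control = ie_scan$control, ie_label = ie_scan$label,
                   carotid_mask = ie_scan$carotid_mask,
                   t1 = t1, atlas = geom$atlas,
                   roi_labels = geom$roi_labels,
                   brain_mask = geom$brain_mask),
              class = "perfusion_dataset")
  })
  names(datasets) <- kept$subject
  truth$params <- params
  list(datasets = datasets, truth = truth)
}
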