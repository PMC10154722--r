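#' pCASL acquisition parameters
#'
#' Container for the constants entering the CBF quantification model, with
#' the defaults used for mouse brain pCASL at 9.4 T: blood-brain partition
#' coefficient lambda = 0.9 ml/g, arterial blood T1 = 2.4 s, labeling
#' duration tau = 3 s, post-label delay 0.3 s, repetition time 4 s.
#'
#' @param lambda_bp blood-brain partition coefficient, ml/g.
#' @param t1_blood longitudinal relaxation time of arterial blood, s.
#' @param tau labeling duration, s.
#' @param pld post-label delay, s.
#' @param tr repetition time of the perfusion readout, s.
#' @return Object of class `acquisition_params` (named list).
#' @export
acquisition_params <- function(lambda_bp = 0.9, t1_blood = 2.4, tau = 3,
                               pld = 0.3, tr = 4) {
  vals <- c(lambda_bp = lambda_bp, t1_blood = t1_blood, tau = tau,
            pld = pld, tr = tr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition parameters must be strictly positive")
  if (pld >= tr) stop("post-label delay must be shorter than TR")
  structure(as.list(vals), class = "acquisition_params")
}

#' Inversion efficiency from a complex carotid flow scan
#'
#' Estimates the labeling inversion efficiency from the complex control and
#' label images of the IE scan as the voxelwise
#' \deqn{IE = |M_{control} - M_{label}| / (2 |M_{control}|)}
#' averaged over the carotid mask (both carotid ROIs jointly). Voxels with
#' zero control magnitude are excluded with a warning. The estimate is
#' invariant to a global complex phase rotation of both images.
#'
#' @param ie_control,ie_label complex arrays (same shape) from the control
#'   and label acquisitions of the IE scan.
#' @param carotid_mask logical array selecting carotid voxels.
#' @return Mean inversion efficiency (scalar, in `[0, 1]` for physical
#'   inputs).
#' @export
compute_ie <- function(ie_control, ie_label, carotid_mask) {
  stopifnot(length(ie_control) == length(ie_label),
            length(carotid_mask) == length(ie_control),
            is.logical(carotid_mask))
  if (!any(carotid_mask)) stop("empty carotid mask")
  mc <- ie_control[carotid_mask]
  ml <- ie_label[carotid_mask]
  mag <- Mod(mc)
  zero <- mag == 0
  if (any(zero)) {
    warning(sum(zero), " zero-magnitude control voxel(s) excluded from IE")
    mc <- mc[!zero]; ml <- ml[!zero]; mag <- mag[!zero]
    if (!length(mc)) stop("no usable carotid voxels")
  }
  mean(Mod(mc - ml) / (2 * mag))
}

#' Voxelwise CBF quantification from time-averaged pCASL signals
#'
#' Single-compartment pCASL quantification:
#' \deqn{CBF = \frac{6000 \lambda (SI_{control} - SI_{label})
#'   e^{PLD/T1_{blood}}}
#'   {2 \cdot IE \cdot T1_{blood} \cdot M_0 (1 - e^{-\tau/T1_{blood}})},
#'   \qquad M_0 = \frac{SI_{control}}{1 - e^{-TR/T1}},}
#' in ml/100 g/min, where the control image corrected for T1 saturation at
#' the sequence TR serves as the equilibrium magnetization. CBF is 0
#' wherever the label equals the control. Voxels with control signal below
#' `eps` or non-positive T1 are set to 0 and counted (attribute
#' `n_excluded`).
#'
#' @param control_mean,label_mean time-averaged control/label signal arrays.
#' @param t1_map voxelwise tissue T1, s.
#' @param ie inversion efficiency in `(0, 1]` (see [compute_ie()]).
#' @param params an [acquisition_params()] object.
#' @param eps smallest usable control signal (division guard).
#' @return CBF array (ml/100 g/min) with attribute `n_excluded`.
#' @export
quantify_cbf <- function(control_mean, label_mean, t1_map, ie,
                         params = acquisition_params(), eps = 1e-8) {
  stopifnot(inherits(params, "acquisition_params"),
            length(control_mean) == length(label_mean),
            length(t1_map) == length(control_mean),
            is.numeric(ie), length(ie) == 1)
  if (!is.finite(ie) || ie <= 0 || ie > 1)
    stop("inversion efficiency must be in (0, 1]")
  bad <- !(control_mean > eps) | !(t1_map > 0)
  m0 <- control_mean / (1 - exp(-params$tr / t1_map))
  cbf <- 6000 * params$lambda_bp * (control_mean - label_mean) *
    exp(params$pld / params$t1_blood) /
    (2 * ie * params$t1_blood * m0 * (1 - exp(-params$tau / params$t1_blood)))
  cbf[bad] <- 0
  cbf[control_mean == label_mean] <- 0
  dim(cbf) <- dim(control_mean)
  attr(cbf, "n_excluded") <- sum(bad)
  cbf
}

#' Normalize a CBF map by its whole-brain mean
#'
#' Returns `cbf / mean(cbf[brain_mask])`, so the mask mean of the output is
#' exactly 1 and regional values become unitless CBF/whole-brain-CBF ratios.
#'
#' @param cbf CBF array.
#' @param brain_mask logical array.
#' @return Normalized map (same shape).
#' @export
normalize_cbf <- function(cbf, brain_mask) {
  stopifnot(length(brain_mask) == length(cbf), is.logical(brain_mask),
            any(brain_mask))
  wb <- mean(cbf[brain_mask])
  if (!is.finite(wb) || wb <= 0)
    stop("non-positive whole-brain mean CBF; cannot normalize")
  out <- cbf / wb
  attr(out, "n_excluded") <- NULL
  out
}

#' Regional means over labelled atlas ROIs
#'
#' @param map numeric array (e.g. a normalized CBF map).
#' @param atlas integer label array on the same grid.
#' @param roi_labels named integer vector mapping ROI name -> atlas label.
#' @return Named numeric vector of ROI means.
#' @export
regional_means <- function(map, atlas, roi_labels) {
  stopifnot(length(map) == length(atlas), length(roi_labels) >= 1,
            !is.null(names(roi_labels)))
  out <- vapply(names(roi_labels), function(rn) {
    sel <- atlas == roi_labels[[rn]]
    if (!any(sel)) stop("ROI '", rn, "' has no voxels in the atlas")
    mean(map[sel])
  }, numeric(1))
  out
}

#' Quantify one subject's perfusion dataset end to end
#'
#' Time-averages the 40 label/control pairs, estimates the inversion
#' efficiency from the complex IE scan, quantifies voxelwise CBF, normalizes
#' by the whole-brain mean and extracts regional ratio values.
#'
#' @param ds a `perfusion_dataset` (see [simulate_perfusion_dataset()]): list
#'   with 4D `control`/`label` arrays, `ie_control`/`ie_label`/`carotid_mask`,
#'   `t1`, `atlas`, `roi_labels`, `brain_mask`.
#' @param params an [acquisition_params()] object.
#' @param rois names of ROIs to report (default: all in `roi_labels`).
#' @return List with `ie`, `cbf` (raw map), `norm` (normalized map),
#'   `regional` (named ROI ratio means), `whole_brain_cbf`.
#' @export
quantify_subject <- function(ds, params = acquisition_params(), rois = NULL) {
  stopifnot(is.list(ds))
  nd <- length(dim(ds$control))
  stopifnot(nd == 4)
  control_mean <- apply(ds$control, 1:3, mean)
  label_mean <- apply(ds$label, 1:3, mean)
  ie <- compute_ie(ds$ie_control, ds$ie_label, ds$carotid_mask)
  cbf <- quantify_cbf(control_mean, label_mean, ds$t1, ie, params)
  norm <- normalize_cbf(cbf, ds$brain_mask)
  labs <- ds$roi_labels
  if (!is.null(rois)) {
    missing_rois <- setdiff(rois, names(labs))
    if (length(missing_rois))
      stop("unknown ROI(s): ", paste(missing_rois, collapse = ", "))
    labs <- labs[rois]
  }
  list(ie = ie, cbf = cbf, norm = norm,
       regional = regional_means(norm, ds$atlas, labs),
       whole_brain_cbf = mean(cbf[ds$brain_mask]))
}

#' Regional CBF-ratio table for a cohort of perfusion datasets
#'
#' Runs [quantify_subject()] on each dataset and stacks the regional ratios
#' into the long table consumed by [mixed_anova()] / [bonferroni_posthoc()].
#'
#' @param datasets list of `perfusion_dataset` objects (each carrying
#'   `subject` and `genotype` fields).
#' @param params an [acquisition_params()] object.
#' @param rois ROI names to extract (default: all except any ROI named
#'   `"rest"`, the non-hippocampal remainder compartment).
#' @return Data frame `subject`, `genotype`, `roi`, `value`.
#' @export
regional_cbf_table <- function(datasets, params = acquisition_params(),
                               rois = NULL) {
  rows <- lapply(datasets, function(ds) {
    rr <- if (is.null(rois)) setdiff(names(ds$roi_labels), "rest") else rois
    q <- quantify_subject(ds, params, rois = rr)
    data.frame(subject = ds$subject, genotype = ds$genotype,
               roi = names(q$regional), value = unname(q$regional),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
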