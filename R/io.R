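#' Write a perfusion dataset to a directory of NIfTI volumes
#'
#' Stores the 4D label/control stacks, the T1 map, atlas, brain mask,
#' carotid mask and the complex IE scan (as real/imaginary volume pairs),
#' plus a small JSON sidecar with subject metadata and ROI labels.
#'
#' @param ds a `perfusion_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_perfusion_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "perfusion_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) RNifti::writeNifti(x, file.path(dir, paste0(nm, ".nii.gz")))
  wr(ds$control, "perfusion_control")
  wr(ds$label, "perfusion_label")
  wr(ds$t1, "t1")
  wr(ds$atlas + 0L, "atlas")
  wr(ds$brain_mask * 1L, "brain_mask")
  wr(ds$carotid_mask * 1L, "carotid_mask")
  wr(Re(ds$ie_control), "ie_control_real"); wr(Im(ds$ie_control), "ie_control_imag")
  wr(Re(ds$ie_label), "ie_label_real"); wr(Im(ds$ie_label), "ie_label_imag")
  meta <- list(subject = ds$subject, genotype = ds$genotype, sex = ds$sex,
               roi_labels = as.list(ds$roi_labels))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a perfusion dataset written by [write_perfusion_dataset()]
#'
#' @param dir dataset directory.
#' @return A `perfusion_dataset` list.
#' @export
read_perfusion_dataset <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    if (!file.exists(f)) stop("missing input file: ", f)
    as.array(RNifti::readNifti(f))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  cplx <- function(nm) {
    re <- rd(paste0(nm, "_real")); im <- rd(paste0(nm, "_imag"))
    z <- complex(real = re, imaginary = im); dim(z) <- dim(re); z
  }
  structure(list(
    subject = meta$subject, genotype = meta$genotype, sex = meta$sex,
    control = rd("perfusion_control"), label = rd("perfusion_label"),
    ie_control = cplx("ie_control"), ie_label = cplx("ie_label"),
    carotid_mask = rd("carotid_mask") > 0,
    t1 = rd("t1"), atlas = array(as.integer(rd("atlas")), dim(rd("atlas"))),
    roi_labels = unlist(meta$roi_labels),
    brain_mask = rd("brain_mask") > 0), class = "perfusion_dataset")
}

#' Write a full synthetic cohort to disk
#'
#' Per-subject NIfTI perfusion directories, CSV tables for the metabolite
#' and autoradiography modalities, and a JSON ground-truth sidecar.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory.
#' @param perfusion,mrs,autorad modality configs (`NULL` skips a modality);
#'   `autorad` is a list of [autorad_config()] objects.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(spec, dir, perfusion = perfusion_config(),
                         mrs = mrs_config(),
                         autorad = list(autorad_config("ucbj"))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list(seed = spec$seed)
  if (!is.null(perfusion)) {
    sim <- simulate_perfusion_dataset(spec, perfusion)
    for (sid in names(sim$datasets))
      write_perfusion_dataset(sim$datasets[[sid]],
                              file.path(dir, "perfusion", sid))
    truth$cbf <- sim$truth[c("regional", "global", "ie", "delta")]
  }
  if (!is.null(mrs)) {
    sim <- simulate_metabolite_table(spec, mrs)
    utils::write.csv(sim$table, file.path(dir, "metabolites.csv"),
                     row.names = FALSE)
    truth$mrs <- sim$truth[c("means", "sds")]
  }
  for (cfg in autorad) {
    sim <- simulate_autorad_film(spec, cfg)
    utils::write.csv(sim$standards,
                     file.path(dir, paste0(cfg$ligand, "_standards.csv")),
                     row.names = FALSE)
    utils::write.csv(sim$sections,
                     file.path(dir, paste0(cfg$ligand, "_sections.csv")),
                     row.names = FALSE)
    truth[[cfg$ligand]] <- list(binding = sim$truth$binding,
                                delta = sim$truth$delta)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
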