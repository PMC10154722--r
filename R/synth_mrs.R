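#' Configuration of the synthetic metabolite modality
#'
#' Generating distributions for the per-subject metabolite concentration
#' table. Defaults are the study conditions of a 9.4 T mouse hippocampal
#' PRESS acquisition: genotype-specific normal concentrations (mM) for
#' glutamate, glutamine and GABA, with the glutamine elevation in mutants;
#' Glx is generated as the per-subject sum Glu + Gln. CRLB (%SD)
#' fit-uncertainty values are drawn from genotype-specific normals (the
#' glutamine CRLB differs by genotype — a higher concentration fits with
#' lower relative uncertainty), with an optional contamination mass above
#' the 20% rejection threshold.
#'
#' @param means,sds named lists (`control`, `mutant`) of named numeric
#'   vectors over `Glu`, `Gln`, `GABA` — concentration means/SDs in mM.
#' @param crlb_means,crlb_sds same shape, CRLB %SD distributions per
#'   metabolite including `Glx`.
#' @param crlb_above_frac probability that an entry's CRLB is replaced by a
#'   draw from Uniform(20, 40), i.e. configurable mass above the cut.
#' @return List of class `mrs_config`.
#' @export
mrs_config <- function(
    means = list(control = c(Glu = 6.77, Gln = 2.29, GABA = 2.08),
                 mutant  = c(Glu = 6.68, Gln = 2.84, GABA = 2.02)),
    sds = list(control = c(Glu = 0.51, Gln = 0.23, GABA = 0.49),
               mutant  = c(Glu = 0.80, Gln = 0.34, GABA = 0.30)),
    crlb_means = list(control = c(Glu = 3, Gln = 14, GABA = 9, Glx = 3),
                      mutant  = c(Glu = 3, Gln = 10, GABA = 9, Glx = 3)),
    crlb_sds = list(control = c(Glu = 0.8, Gln = 2.5, GABA = 2, Glx = 0.8),
                    mutant  = c(Glu = 0.8, Gln = 2.0, GABA = 2, Glx = 0.8)),
    crlb_above_frac = 0) {
  for (g in c("control", "mutant")) {
    stopifnot(all(c("Glu", "Gln", "GABA") %in% names(means[[g]])),
              all(names(means[[g]]) %in% names(sds[[g]])))
    if (any(means[[g]] < 0) || any(sds[[g]] < 0))
      stop("negative metabolite mean or SD")
    if (any(crlb_means[[g]] < 0) || any(crlb_sds[[g]] < 0))
      stop("negative CRLB mean or SD")
  }
  stopifnot(crlb_above_frac >= 0, crlb_above_frac <= 1)
  structure(list(means = means, sds = sds, crlb_means = crlb_means,
                 crlb_sds = crlb_sds, crlb_above_frac = crlb_above_frac),
            class = "mrs_config")
}

#' Simulate a per-subject metabolite concentration table
#'
#' Draws each subject's Glu, Gln and GABA concentration from the
#' genotype-specific normals of the config (truncated at 0), sets
#' Glx = Glu + Gln per subject, and attaches CRLB %SD values. The returned
#' ground truth records the generating means so recovery can be checked.
#'
#' @param spec a [cohort_spec()].
#' @param config an [mrs_config()].
#' @return List with `table` (long metabolite table: `subject`, `genotype`,
#'   `sex`, `metabolite`, `concentration`, `crlb`) and `truth` (generating
#'   means/SDs and the roster used).
#' @export
simulate_metabolite_table <- function(spec, config = mrs_config()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "mrs_config"))
  set.seed(spec$seed + 202L)
  subjects <- apply_missing(cohort_subjects(spec), spec, "mrs")
  mets_base <- names(config$means$control)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    g <- as.character(subjects$genotype[i])
    conc <- stats::rnorm(length(mets_base), config$means[[g]][mets_base],
                         config$sds[[g]][mets_base])
    conc <- pmax(conc, 0)
    names(conc) <- mets_base
    conc <- c(conc, Glx = unname(conc[["Glu"]] + conc[["Gln"]]))
    crlb <- stats::rnorm(length(conc),
                         config$crlb_means[[g]][names(conc)],
                         config$crlb_sds[[g]][names(conc)])
    crlb <- pmax(crlb, 0.2)
    if (config$crlb_above_frac > 0) {
      hit <- stats::runif(length(crlb)) < config$crlb_above_frac
      crlb[hit] <- stats::runif(sum(hit), 20, 40)
    }
    data.frame(subject = subjects$subject[i], genotype = g,
               sex = subjects$sex[i], metabolite = names(conc),
               concentration = unname(conc), crlb = unname(crlb),
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, c(rows, make.row.names = FALSE))
  table$genotype <- factor(table$genotype, levels = levels(subjects$genotype))
  met_levels <- intersect(c("Glu", "Gln", "Glx", "GABA"),
                          unique(table$metabolite))
  table$metabolite <- factor(table$metabolite, levels = met_levels)
  list(table = table,
       truth = list(subjects = subjects, means = config$means,
                    sds = config$sds))
}
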