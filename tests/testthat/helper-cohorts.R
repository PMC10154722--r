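# shared fixture builders; everything is generated in code at test time

tiny_spec <- function(seed = 1, n = 3) {
  cohort_spec(n_per_genotype = c(control = n, mutant = n),
              sex_female = c(control = 1, mutant = 2),
              missing = list(), seed = seed)
}

noiseless_perfusion <- function() {
  perfusion_config(dim = c(16, 16, 8), n_pairs = 4,
                   voxel_noise_sd = 0, ie_noise_sd = 0)
}

noiseless_autorad <- function(ligand = "ucbj") {
  autorad_config(ligand, standards_od_sd = 0, sections_od_sd = 0,
                 section_sd = 0)
}

# metabolite config with no genotype difference (type-I simulations)
null_mrs_config <- function() {
  ctl_m <- c(Glu = 6.77, Gln = 2.29, GABA = 2.08)
  ctl_s <- c(Glu = 0.51, Gln = 0.23, GABA = 0.49)
  mrs_config(means = list(control = ctl_m, mutant = ctl_m),
             sds = list(control = ctl_s, mutant = ctl_s))
}

# long regional table built directly (no generator involved)
make_regional <- function(n1, n2, r, seed = 1, sd = 1,
                          shift = rep(0, r)) {
  set.seed(seed)
  subj <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  geno <- rep(c("control", "mutant"), c(n1, n2))
  tab <- expand.grid(subject = subj, roi = paste0("R", seq_len(r)),
                     stringsAsFactors = FALSE)
  tab$genotype <- geno[match(tab$subject, subj)]
  tab$value <- stats::rnorm(nrow(tab), sd = sd) +
    ifelse(tab$genotype == "mutant",
           shift[match(tab$roi, paste0("R", seq_len(r)))], 0)
  tab
}
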