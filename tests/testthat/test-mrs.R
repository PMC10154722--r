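mk_met <- function(conc, crlb, met = "Gln") {
  n <- length(conc)
  data.frame(subject = sprintf("s%02d", seq_len(n)),
             genotype = rep(c("control", "mutant"), length.out = n),
             metabolite = met, concentration = conc, crlb = crlb,
             stringsAsFactors = FALSE)
}

test_that("CRLB filter boundary is inclusive at the threshold", {
  tab <- mk_met(c(2, 2.1, 2.2, 2.3), c(19.9, 20.0, 20.1, 5))
  out <- apply_crlb_filter(tab)
  expect_equal(out$table$crlb, c(19.9, 5))      # 20.0 discarded
  expect_equal(nrow(out$rejected), 2)
  ## all below threshold -> untouched, empty log
  clean <- mk_met(c(2, 2.1, 2.2, 2.3), c(3, 5, 7, 9))
  out2 <- apply_crlb_filter(clean)
  expect_identical(out2$table, clean)
  expect_equal(nrow(out2$rejected), 0)
})

test_that("CRLB filter is idempotent", {
  set.seed(8)
  tab <- mk_met(runif(12, 1, 3), runif(12, 0, 40))
  once <- apply_crlb_filter(tab)$table
  twice <- apply_crlb_filter(once)$table
  expect_identical(once, twice)
})

test_that("pooled z-scores standardize each metabolite", {
  tab <- mk_met(c(1, 3), c(5, 5))
  z <- compute_zscores(tab)
  expect_equal(z$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(3)
  tab2 <- rbind(mk_met(rnorm(8, 2, 0.3), 5, "Gln"),
                mk_met(rnorm(8, 7, 0.5), 5, "Glu"))
  z2 <- compute_zscores(tab2)
  expect_lt(max(abs(tapply(z2$z, z2$metabolite, mean))), 1e-12)
  expect_equal(as.numeric(tapply(z2$z, z2$metabolite, sd)), c(1, 1))
  expect_error(compute_zscores(mk_met(rep(2, 4), 5)), "zero pooled SD")
})

test_that("group tests match a direct pooled-t computation", {
  set.seed(11)
  tab <- rbind(mk_met(rnorm(10, 2.3, 0.3), 5, "Gln"),
               mk_met(rnorm(10, 6.8, 0.6), 5, "Glu"))
  res <- metabolite_group_tests(tab, n_comparisons = 4)
  for (met in c("Glu", "Gln")) {
    sub <- tab[tab$metabolite == met, ]
    x1 <- sub$concentration[sub$genotype == "control"]
    x2 <- sub$concentration[sub$genotype == "mutant"]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                 (length(x1) + length(x2) - 2))
    t_direct <- (mean(x2) - mean(x1)) /
      (sp * sqrt(1 / length(x1) + 1 / length(x2)))
    row <- res[grepl(met, res$label), ]
    expect_equal(row$statistic, t_direct, tolerance = 1e-12)
    expect_gte(row$p_adj, row$p)        # Bonferroni is monotone
    expect_lte(row$p_adj, 1)            # and capped
    expect_equal(row$p_adj, min(1, 4 * row$p))
  }
})

test_that("identical groups give t = 0 and adjusted p = 1", {
  tab <- mk_met(rep(c(2, 3), 6), 5)
  res <- metabolite_group_tests(tab, 4)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_adj, 1)
})

test_that("generated metabolite tables have the designed structure", {
  spec <- cohort_spec(seed = 21)
  sim <- simulate_metabolite_table(spec)
  tab <- sim$table
  expect_equal(length(unique(tab$subject)), 24)
  ## Glx is the per-subject sum of Glu and Gln
  wide <- reshape(tab[, c("subject", "metabolite", "concentration")],
                  idvar = "subject", timevar = "metabolite",
                  direction = "wide")
  expect_equal(wide$concentration.Glx,
               wide$concentration.Glu + wide$concentration.Gln)
  ## default CRLB mass is entirely below the 20% cut
  expect_true(all(tab$crlb < 20))
  ## configurable mass above the cut produces rejections
  cfg <- mrs_config(crlb_above_frac = 0.5)
  sim2 <- simulate_metabolite_table(cohort_spec(seed = 21), cfg)
  out <- apply_crlb_filter(sim2$table)
  expect_gt(nrow(out$rejected), 0)
  expect_true(all(out$rejected$crlb >= 20))
  ## seeded determinism
  sim3 <- simulate_metabolite_table(cohort_spec(seed = 21))
  expect_identical(sim$table, sim3$table)
  ## negative generating parameters are rejected
  expect_error(mrs_config(means = list(control = c(Glu = -1, Gln = 2,
                                                   GABA = 2),
                                       mutant = c(Glu = 6, Gln = 2,
                                                  GABA = 2))),
               "negative")
})
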