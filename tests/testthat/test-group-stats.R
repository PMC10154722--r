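test_that("split-plot F values equal the aov decomposition", {
  for (des in list(c(5, 5, 2), c(4, 6, 3), c(12, 12, 2))) {
    tab <- make_regional(des[1], des[2], des[3], seed = des[1] * 100 + des[3])
    mine <- mixed_anova(tab)
    expect_identical(attr(mine, "method"), "ss")
    fit <- summary(stats::aov(value ~ genotype * roi + Error(subject),
                              data = transform(tab,
                                               subject = factor(subject),
                                               genotype = factor(genotype),
                                               roi = factor(roi))))
    f_oracle <- c(fit[["Error: subject"]][[1]]["genotype", "F value"],
                  fit[["Error: Within"]][[1]][c("roi", "genotype:roi"),
                                              "F value"])
    expect_equal(mine$F, unname(f_oracle), tolerance = 1e-8)
    expect_equal(mine$eta2p, f_to_eta2(mine$F, mine$df1, mine$df2))
  }
})

test_that("mirrored genotype groups give exactly zero genotype effects", {
  ## mutant data are an exact copy of the control data, so the genotype
  ## and interaction sums of squares vanish identically
  set.seed(1)
  half <- make_regional(4, 0, 3, seed = 1)
  half <- half[half$genotype == "control", ]
  mirror <- half
  mirror$genotype <- "mutant"
  mirror$subject <- sub("^a", "b", mirror$subject)
  tab <- rbind(half, mirror)
  res <- mixed_anova(tab)
  expect_equal(res$F[res$effect == "genotype"], 0, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "genotype:roi"], 0, tolerance = 1e-10)
  expect_gte(res$F[res$effect == "roi"], 0)
})

test_that("missing cells switch to the REML mixed model", {
  tab <- make_regional(6, 6, 3, seed = 2, shift = c(1, 0, 0))
  tab <- tab[-c(3, 20), ]                # knock out two subject x ROI cells
  res <- mixed_anova(tab)
  expect_identical(attr(res, "method"), "reml")
  expect_true(all(is.finite(res$F)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$df2 > 0))
})

test_that("post-hoc df follows the pooled cell-means convention", {
  ## 22 subjects x 2 ROIs complete -> df = 44 - 4 = 40
  tab <- make_regional(10, 12, 2, seed = 3, shift = c(0.5, 0))
  ph <- bonferroni_posthoc(tab)
  expect_equal(ph$df1, c(40, 40))
  expect_equal(ph$effect, t_to_d(ph$statistic, 40))
  expect_equal(ph$p_adj, pmin(1, 2 * ph$p))
})

test_that("post-hoc t matches a hand-worked two-ROI example", {
  ## 2 subjects per genotype, 2 ROIs, numbers chosen for exact arithmetic
  tab <- data.frame(
    subject = rep(c("c1", "c2", "m1", "m2"), each = 2),
    genotype = rep(c("control", "control", "mutant", "mutant"), each = 2),
    roi = rep(c("A", "B"), 4),
    value = c(1, 5, 3, 7, 4, 6, 8, 10))
  ## cell means: A/control 2, B/control 6, A/mutant 6, B/mutant 8
  ## residuals: +-1 in control cells, +-2 in mutant cells
  ## SSE = 4*1 + 4*4 = 20, df = 8 - 4 = 4, s2 = 5
  ## ROI A: t = (6 - 2) / sqrt(5 * (1/2 + 1/2)) = 4 / sqrt(5)
  ph <- bonferroni_posthoc(tab)
  rowA <- ph[grepl("^A", ph$label), ]
  expect_equal(rowA$statistic, 4 / sqrt(5), tolerance = 1e-12)
  expect_equal(rowA$df1, 4)
  ## identical groups in every ROI -> t = 0, adjusted p = 1
  tab0 <- tab
  tab0$value <- rep(c(1, 5), 4)
  ph0 <- bonferroni_posthoc(tab0)
  expect_equal(ph0$statistic, c(0, 0))
  expect_equal(ph0$p_adj, c(1, 1))
})

test_that("welch post-hoc variant does not pool across ROIs", {
  tab <- make_regional(8, 8, 2, seed = 6, shift = c(1, 0))
  phw <- bonferroni_posthoc(tab, method = "welch")
  sub <- tab[tab$roi == "R1", ]
  ht <- t.test(value ~ genotype, data = sub)
  expect_equal(abs(phw$statistic[grepl("R1", phw$label)]),
               abs(unname(ht$statistic)), tolerance = 1e-10)
})

test_that("an empty genotype cell is skipped with a warning", {
  tab <- make_regional(3, 3, 2, seed = 7)
  tab <- tab[!(tab$roi == "R2" & tab$genotype == "mutant"), ]
  expect_warning(ph <- bonferroni_posthoc(tab), "empty genotype cell")
  expect_equal(nrow(ph), 1)
})

test_that("ANCOVA adjusts for covariates and catches collinearity", {
  set.seed(9)
  n <- 400
  tab <- data.frame(genotype = rep(c("control", "mutant"), each = n / 2),
                    value = rnorm(n) + rep(c(0, 0.5), each = n / 2),
                    sex = sample(c("F", "M"), n, replace = TRUE))
  adj <- ancova_adjust(tab, "sex")
  un <- summary(stats::lm(value ~ genotype, data = tab))$fstatistic[["value"]]
  expect_equal(adj$statistic, un, tolerance = 0.15)  # uncorrelated covariate
  expect_equal(adj$df2, n - 3)
  tab$dup <- tab$value
  expect_error(suppressWarnings(ancova_adjust(tab, "dup")), "collinear")
  tab$const <- 1
  expect_error(ancova_adjust(tab, "const"), "vary")
})

test_that("a generated glutamine effect survives sex and CRLB adjustment", {
  set.seed(31)
  hits <- replicate(30, {
    spec <- cohort_spec(seed = sample.int(1e6, 1))
    tab <- simulate_metabolite_table(spec)$table
    gln <- tab[tab$metabolite == "Gln", ]
    gln$value <- gln$concentration
    ancova_adjust(gln, c("sex", "crlb"))$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})
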