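sat_od <- function(a, b = 0.05, A = 1.8, k = 0.25) b + A * (1 - exp(-k * a))

test_that("noiseless straight-line standards take the linear fallback", {
  act <- c(0.5, 1, 2, 4, 8)
  cv <- fit_standard_curve(act, 0.12 * act)
  expect_equal(cv$family, "linear")
  expect_equal(unname(cv$coef[["m"]]), 0.12, tolerance = 1e-10)
  expect_equal(unname(cv$coef[["b"]]), 0, tolerance = 1e-10)
  expect_equal(interpolate_activity(cv, 0.12 * 3.3), 3.3, tolerance = 1e-8)
})

test_that("noiseless saturating standards recover the curve parameters", {
  act <- c(0.25, 0.5, 1, 2, 3.5, 5, 7, 10)
  cv <- fit_standard_curve(act, sat_od(act))
  expect_equal(cv$family, "saturating")
  expect_equal(unname(cv$coef[c("b", "A", "k")]), c(0.05, 1.8, 0.25),
               tolerance = 1e-6)
})

test_that("a gross outlier standard is downweighted to irrelevance", {
  act <- c(0.25, 0.5, 1, 2, 3.5, 5, 7, 10)
  od_clean <- sat_od(act)
  clean <- fit_standard_curve(act, od_clean)
  od_bad <- od_clean
  od_bad[3] <- od_bad[3] + 1          # gross film artefact
  robust <- fit_standard_curve(act, od_bad)
  expect_lt(robust$weights[3], 0.01)
  probe <- sat_od(seq(0.3, 9, length.out = 25))
  expect_lt(max(abs(interpolate_activity(robust, probe) -
                      interpolate_activity(clean, probe)) /
                  interpolate_activity(clean, probe)), 0.05)
})

test_that("curve fitting rejects bad calibration input", {
  expect_error(fit_standard_curve(c(1, 2, 3), c(0.1, 0.2, 0.3)), ">= 4")
  expect_error(fit_standard_curve(c(1, 1, 2, 2), c(0.1, 0.1, 0.2, 0.2)),
               "distinct")
  expect_error(fit_standard_curve(c(1, 2, 4, 8), c(0.8, 0.6, 0.4, 0.2)),
               "monotone")
})

test_that("inverse interpolation is the exact inverse and stays monotone", {
  act <- c(0.25, 0.5, 1, 2, 3.5, 5, 7, 10)
  cv <- fit_standard_curve(act, sat_od(act))
  expect_equal(interpolate_activity(cv, predict_od(cv, 0.5)), 0.5,
               tolerance = 1e-6)
  expect_equal(interpolate_activity(cv, cv$coef[["b"]]), 0)
  ods <- sort(runif(10, 0.2, 1.5))
  expect_true(all(diff(interpolate_activity(cv, ods)) > 0))
  expect_error(interpolate_activity(cv, 2.0), "saturation")
  expect_warning(a0 <- interpolate_activity(cv, 0.01), "clamped")
  expect_equal(a0, 0)
  expect_error(interpolate_activity(cv, 0.01, below = "error"), "baseline")
})

test_that("specific binding subtracts nonspecific and flags negatives", {
  expect_equal(as.numeric(compute_specific_binding(4.0)), 4.0)
  expect_equal(as.numeric(compute_specific_binding(5.0, 1.0)), 4.0)
  expect_warning(sb <- compute_specific_binding(1.0, 2.0), "negative")
  expect_equal(as.numeric(sb), -1.0)
  expect_true(attr(sb, "flag_negative"))
})

test_that("section aggregation averages after conversion and keeps holes", {
  sec <- data.frame(subject = rep(c("s1", "s2"), each = 3),
                    genotype = "control", roi = "CA1",
                    section = rep(1:3, 2), condition = "total",
                    activity = c(2, 2, 2, 1, 2, 3))
  out <- aggregate_sections(sec)
  expect_equal(out$value, c(2, 2))
  ## order of sections is irrelevant
  out2 <- aggregate_sections(sec[sample(nrow(sec)), ])
  expect_equal(out2[order(out2$subject), "value"], c(2, 2))
  ## a missing subject x ROI cell propagates as NA
  sec2 <- rbind(sec, data.frame(subject = "s1", genotype = "control",
                                roi = "DG", section = 1:3,
                                condition = "total", activity = 4))
  out3 <- aggregate_sections(sec2)
  expect_true(is.na(out3$value[out3$subject == "s2" & out3$roi == "DG"]))
  expect_equal(out3$value[out3$subject == "s1" & out3$roi == "DG"], 4)
})

test_that("the noiseless film chain recovers true binding", {
  spec <- tiny_spec(seed = 9)
  sim <- simulate_autorad_film(spec, noiseless_autorad("ucbj"))
  q <- quantify_binding(sim$standards, sim$sections)
  m <- merge(q$binding, sim$truth$binding, by = c("subject", "roi"))
  expect_lt(max(abs(m$value - m$binding) / m$binding), 1e-6)
  ## ligands without a nonspecific condition quantify total as specific
  sim2 <- simulate_autorad_film(spec, noiseless_autorad("ro15"))
  expect_false("nonspecific" %in% sim2$sections$condition)
  q2 <- quantify_binding(sim2$standards, sim2$sections)
  m2 <- merge(q2$binding, sim2$truth$binding, by = c("subject", "roi"))
  expect_lt(max(abs(m2$value - m2$binding) / m2$binding), 1e-6)
})

test_that("film simulation is seeded and validates its configuration", {
  a <- simulate_autorad_film(tiny_spec(seed = 4), autorad_config("ucbj"))
  b <- simulate_autorad_film(tiny_spec(seed = 4), autorad_config("ucbj"))
  expect_identical(a$standards, b$standards)
  expect_identical(a$sections, b$sections)
  expect_error(autorad_config("custom", rois = c(CA1 = 2),
                              curve = list(b = 0, A = -1, k = 0.2)),
               "monotone")
  ## the outlier contamination flag corrupts exactly one standard
  o <- simulate_autorad_film(tiny_spec(seed = 4), autorad_config("ucbj"),
                             outlier_standard = TRUE)
  expect_equal(sum(abs(o$standards$od - a$standards$od) > 0.5), 1)
})
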