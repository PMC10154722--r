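test_that("inversion efficiency covers the limiting and worked cases", {
  mask <- matrix(TRUE, 2, 2)
  mc <- matrix(complex(real = 3, imaginary = 1), 2, 2)
  expect_equal(compute_ie(mc, -mc, mask), 1)      # perfect inversion
  expect_equal(compute_ie(mc, mc, mask), 0)       # no labeling
  expect_equal(compute_ie(matrix(1 + 0i, 2, 2),
                          matrix(-0.7 + 0i, 2, 2), mask), 0.85)
  expect_error(compute_ie(mc, mc, matrix(FALSE, 2, 2)), "empty")
  mc0 <- mc; mc0[1] <- 0 + 0i
  expect_warning(ie <- compute_ie(mc0, mc0, mask), "zero-magnitude")
  expect_equal(ie, 0)
})

test_that("IE is invariant to a global complex phase rotation", {
  set.seed(2)
  for (i in 1:5) {
    mc <- matrix(complex(real = rnorm(16, 5), imaginary = rnorm(16)), 4, 4)
    ml <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
    mask <- matrix(rep(c(TRUE, FALSE), 8), 4, 4)
    rot <- exp(1i * runif(1, 0, 2 * pi))
    expect_equal(compute_ie(mc * rot, ml * rot, mask),
                 compute_ie(mc, ml, mask), tolerance = 1e-12)
  }
})

test_that("CBF quantification matches the hand-evaluated scalar case", {
  ## independent hand evaluation of the single-compartment model:
  ## lambda=0.9, SIc=100, SIl=98, PLD=0.3, T1b=2.4, IE=0.85, TR=4,
  ## T1=1.8, tau=3  ->  37.48392 ml/100 g/min
  cbf <- quantify_cbf(array(100, 1), array(98, 1), array(1.8, 1),
                      ie = 0.85, params = acquisition_params())
  expect_equal(as.numeric(cbf), 37.48392, tolerance = 1e-6)
})

test_that("CBF is zero without perfusion signal and scale invariant", {
  d <- c(4, 4, 2)
  ctrl <- array(runif(prod(d), 90, 110), d)
  t1 <- array(1.8, d)
  expect_true(all(quantify_cbf(ctrl, ctrl, t1, 0.85) == 0))
  lbl <- ctrl * 0.97
  k <- 3.7
  expect_equal(as.numeric(quantify_cbf(k * ctrl, k * lbl, t1, 0.85)),
               as.numeric(quantify_cbf(ctrl, lbl, t1, 0.85)),
               tolerance = 1e-12)
  expect_error(quantify_cbf(ctrl, lbl, t1, 0), "inversion efficiency")
  expect_error(quantify_cbf(ctrl, lbl, t1, 1.2), "inversion efficiency")
})

test_that("low-signal and non-positive-T1 voxels are excluded and counted", {
  ctrl <- array(c(100, 1e-12, 100, 100), c(4, 1, 1))
  lbl <- ctrl * 0.97
  t1 <- array(c(1.8, 1.8, -1, 1.8), c(4, 1, 1))
  cbf <- quantify_cbf(ctrl, lbl, t1, 0.85)
  expect_equal(attr(cbf, "n_excluded"), 2)
  expect_equal(as.numeric(cbf)[c(2, 3)], c(0, 0))
  expect_gt(as.numeric(cbf)[1], 0)
})

test_that("whole-brain normalization fixes the mask mean at 1", {
  mask <- array(TRUE, c(4, 4, 2))
  expect_true(all(normalize_cbf(array(55, c(4, 4, 2)), mask) == 1))
  two <- array(rep(c(80, 40), each = 16), c(4, 4, 2))
  norm <- normalize_cbf(two, mask)
  expect_equal(sort(unique(as.numeric(norm))), c(2 / 3, 4 / 3))
  set.seed(1)
  rnd <- array(runif(32, 10, 90), c(4, 4, 2))
  expect_equal(mean(normalize_cbf(rnd, mask)[mask]), 1, tolerance = 1e-12)
  expect_error(normalize_cbf(array(-1, c(4, 4, 2)), mask), "non-positive")
})

test_that("regional means respect the atlas labelling", {
  atlas <- array(0L, c(4, 4, 1))
  atlas[1:2, , ] <- 1L
  atlas[3, 1, 1] <- 2L
  map <- array(0, c(4, 4, 1))
  map[1:2, , ] <- 1.2
  map[3, 1, 1] <- 7
  labs <- c(roiA = 1L, roiB = 2L)
  expect_equal(regional_means(map, atlas, labs),
               c(roiA = 1.2, roiB = 7))
  ## checkerboard averages to the midpoint
  map[1:2, , ] <- rep(c(0, 2), 4)
  expect_equal(regional_means(map, atlas, labs[1]), c(roiA = 1))
  expect_error(regional_means(map, atlas, c(gone = 9L)), "gone")
})
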