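mkvol2 <- function(vals) {
  new("CTVolume", values = vals, spacing = 0.107, units = "attenuation",
      provenance = "test")
}

test_that("CNR follows its closed form and affine invariance", {
  d <- c(10, 10, 20)
  v <- array(0, dim = d)
  v[, , 1:10] <- rep(c(1, 3), length.out = 1000)    # mean 2, var ~1
  v[, , 11:20] <- rep(c(-1, 1), length.out = 1000)  # mean 0, var ~1
  vol <- mkvol2(v)
  a <- roiBox(c(1, 1, 1), c(10, 10, 10))
  b <- roiBox(c(1, 1, 11), c(10, 10, 20))
  expect_equal(cnr(vol, a, b), 2, tolerance = 2e-3)
  # positive affine gray maps leave CNR unchanged
  vol2 <- mkvol2(3.7 * v + 11)
  expect_equal(cnr(vol2, a, b), cnr(vol, a, b), tolerance = 1e-12)
  # contrast scales CNR linearly at fixed noise (shift one mean)
  v3 <- v; v3[, , 1:10] <- v3[, , 1:10] + 4
  expect_equal(cnr(mkvol2(v3), a, b), 3 * cnr(vol, a, b), tolerance = 5e-3)
  expect_error(cnr(mkvol2(array(1, d)), a, b), "variance")
  expect_error(cnr(vol, roiBox(c(1, 1, 1), c(2, 2, 2)), b), "27")
})

test_that("gCNR matches its defining cases", {
  set.seed(1)
  d <- c(10, 10, 200)
  v <- array(rnorm(prod(d)), dim = d)
  vol <- mkvol2(v)
  a <- roiBox(c(1, 1, 1), c(10, 10, 100))
  b <- roiBox(c(1, 1, 101), c(10, 10, 200))
  # same distribution: overlap ~ 1
  expect_lt(gcnr(vol, a, a), 2 / 256 + 0.02)
  # disjoint supports: exactly 1
  v2 <- v; v2[, , 101:200] <- v2[, , 101:200] + 100
  expect_identical(gcnr(mkvol2(v2), a, b), 1)
  expect_gte(gcnr(vol, a, b), 0)
  expect_lte(gcnr(vol, a, b), 1)
})

test_that("gCNR of Gaussians at 2 sigma separation is the closed-form overlap", {
  set.seed(42)
  d <- c(10, 10, 200)
  v <- array(0, dim = d)
  v[, , 1:100] <- rnorm(1e4)
  v[, , 101:200] <- rnorm(1e4, mean = 2)
  vol <- mkvol2(v)
  a <- roiBox(c(1, 1, 1), c(10, 10, 100))
  b <- roiBox(c(1, 1, 101), c(10, 10, 200))
  # 1 - 2 Phi(-1) = 0.6827
  expect_equal(gcnr(vol, a, b), 1 - 2 * pnorm(-1), tolerance = 0.02 / 0.68)
})

test_that("gCNR is invariant under strictly monotone gray transforms", {
  set.seed(5)
  d <- c(8, 8, 60)
  v <- array(rnorm(prod(d), 5, 1), dim = d)
  v[, , 31:60] <- v[, , 31:60] + 1.5
  a <- roiBox(c(1, 1, 1), c(8, 8, 30))
  b <- roiBox(c(1, 1, 31), c(8, 8, 60))
  g0 <- gcnr(mkvol2(v), a, b)
  expect_equal(gcnr(mkvol2(exp(v / 3)), a, b), g0, tolerance = 0.03)
  expect_equal(gcnr(mkvol2(v^3), a, b), g0, tolerance = 0.03)
})

test_that("noise propagation matches its formula and a Monte-Carlo oracle", {
  basis <- computeBasis(c("adipose", "bone_cortical", "micropaque_1to5"))
  cv <- monoCoefficients(basis, 37.5)
  np <- noisePropagation(basis, 0.03, 0.02, 37.5)
  expect_equal(np$sigma,
               sqrt(cv[["cLE"]]^2 * 0.03^2 + cv[["cHE"]]^2 * 0.02^2),
               tolerance = 1e-12)
  # Monte-Carlo: decompose pure-noise volumes and measure the mono std
  set.seed(8)
  d <- c(50, 50, 40)                     # 1e5 voxels
  muLE <- mkvol2(array(0.4 + rnorm(prod(d), 0, 0.03), dim = d))
  muHE <- mkvol2(array(0.25 + rnorm(prod(d), 0, 0.02), dim = d))
  mono <- synthesizeMono(materialDecompose(muLE, muHE, basis), 37.5)
  expect_equal(sd(mono@values), np$sigma, tolerance = 0.05)
})

test_that("the default basis amplifies mono noise by less than 3", {
  basis <- computeBasis(c("adipose", "bone_cortical", "micropaque_1to5"))
  np <- noisePropagation(basis, 0.02, 0.02, 37.5)
  expect_gt(np$amplification, 1)
  expect_lt(np$amplification, 3)
})

test_that("contrast enhancement factor behaves at its fixed points", {
  expect_identical(contrastEnhancementFactor("adipose", "adipose"), 0)
  # monochromatic reference at the target energy: exactly 1
  expect_equal(contrastEnhancementFactor("micropaque_1to5", "adipose",
                                         he = monochromaticSpectrum(37.5),
                                         E = 37.5), 1, tolerance = 1e-12)
})

test_that("the contrast agent gains about a factor 3 at the barium edge", {
  cef <- contrastEnhancementFactor("micropaque_1to5", "adipose")
  expect_gt(cef, 3 * 0.8)
  expect_lt(cef, 3 * 1.2)
})

test_that("the split-exposure noise budget equals 3/sqrt(2)", {
  expect_equal(doubleExposurePenalty(), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(doubleExposurePenalty(), 1), 2.1)
})

test_that("spectral-pair optimization ranks deterministically", {
  one <- optimizeSpectralPair(kvps = c(45, 70),
                              filters = list(al05 = list(list("aluminum", 0.5))))
  expect_equal(nrow(one), 1)
  expect_equal(one$rank, 1)
  small <- optimizeSpectralPair(kvps = c(45, 60, 70))
  doubled <- optimizeSpectralPair(kvps = c(45, 60, 70), totalBudget = 2e6)
  expect_equal(doubled$objective, sqrt(2) * small$objective,
               tolerance = 1e-9)
  expect_identical(doubled[, c("le_kvp", "le_filter", "he_kvp", "he_filter")],
                   small[, c("le_kvp", "le_filter", "he_kvp", "he_filter")])
  expect_error(optimizeSpectralPair(kvps = c(30, 90)), "40-80")
})

test_that("the published pair is competitive under the exposure model", {
  full <- optimizeSpectralPair()
  paper <- full[full$le_kvp == 45 & full$le_filter == "al05" &
                  full$he_kvp == 70 & full$he_filter == "cu035", ]
  expect_equal(nrow(paper), 1)
  # its mono-noise amplification is below the factor-3 contrast gain
  expect_lt(paper$amplification, 3)
  # it sits in the upper part of the full 322-pair grid
  expect_lt(paper$rank / nrow(full), 0.30)
  # among the 45 -> 70 kVp pairs, copper HE prefiltration minimizes the
  # noise propagated into the mono image
  sub <- full[full$le_kvp == 45 & full$he_kvp == 70, ]
  sub <- sub[order(sub$amplification), ]
  expect_identical(sub$he_filter[1:2], c("cu035", "cu035"))
})

test_that("SNR is mean over standard deviation", {
  set.seed(2)
  v <- array(rnorm(4000, 10, 2), dim = c(10, 10, 40))
  vol <- mkvol2(v)
  roi <- roiBox(c(1, 1, 1), c(10, 10, 40))
  expect_equal(snr(vol, roi), mean(v) / sd(v), tolerance = 1e-12)
})
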