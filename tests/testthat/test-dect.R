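mkvol <- function(vals, spacing = 0.107) {
  new("CTVolume", values = vals, spacing = spacing, units = "attenuation",
      provenance = "test")
}

test_that("a delta-spectrum basis equals pointwise linear attenuations", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  b <- computeBasis(mats, le = monochromaticSpectrum(30),
                    he = monochromaticSpectrum(50))
  manual <- rbind(vapply(mats, effectiveLinearAttenuation, numeric(1), 30),
                  vapply(mats, effectiveLinearAttenuation, numeric(1), 50))
  expect_equal(unname(b@A), unname(manual), tolerance = 1e-12)
  expect_identical(b@source, "spectral-model")
})

test_that("degenerate material trios are rejected with the offending pair", {
  expect_error(computeBasis(c("water", "water", "bone_cortical")),
               "distinct")
  # two spectrally indistinguishable columns: same material twice under
  # different names via a copied object
  w <- bundledMaterial("water")
  w2 <- xrayMaterial("water copy", w@density, w@energy, w@massAtten,
                     w@edges, w@composition)
  expect_error(computeBasis(list(w, w2, bundledMaterial("bone_cortical"))),
               "ill-conditioned|singular")
})

test_that("noiseless decomposition recovers simplex mixtures to 1e-10", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  M <- rbind(basis@A, c(1, 1, 1))
  set.seed(7)
  n <- 1000
  V <- matrix(stats::rexp(3 * n), ncol = 3)
  V <- V / rowSums(V)
  b <- V %*% t(M)                       # rows: (muLE, muHE, 1)
  d <- c(10, 10, 10)
  muLE <- mkvol(array(b[, 1], dim = d))
  muHE <- mkvol(array(b[, 2], dim = d))
  maps <- materialDecompose(muLE, muHE, basis)
  Vhat <- matrix(maps@V, ncol = 3)
  expect_lt(max(abs(Vhat - V)), 1e-10)
  # closure holds exactly by construction
  expect_lt(max(abs(rowSums(Vhat) - 1)), 1e-12)
})

test_that("a pure-material voxel decomposes to a unit fraction", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  d <- c(4, 4, 1)
  muLE <- mkvol(array(basis@A[1, 2], dim = d))
  muHE <- mkvol(array(basis@A[2, 2], dim = d))
  maps <- materialDecompose(muLE, muHE, basis)
  expect_equal(as.numeric(maps@V[1, 1, 1, ]), c(0, 1, 0), tolerance = 1e-10)
})

test_that("noisy raw maps keep exact closure while leaving [0,1]", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  set.seed(3)
  d <- c(20, 20, 5)
  muLE <- mkvol(array(basis@A[1, 1] + rnorm(prod(d), 0, 0.05), dim = d))
  muHE <- mkvol(array(basis@A[2, 1] + rnorm(prod(d), 0, 0.05), dim = d))
  maps <- materialDecompose(muLE, muHE, basis, clipPolicy = "raw")
  tot <- maps@V[, , , 1] + maps@V[, , , 2] + maps@V[, , , 3]
  expect_lt(max(abs(tot - 1)), 1e-12)
  expect_gt(sum(outOfRangeFraction(maps)), 0)
  # renormalized view is clipped to the simplex
  Vc <- concValues(maps, policy = "renormalize")
  expect_gte(min(Vc), 0); expect_lte(max(Vc), 1)
  tot2 <- Vc[, , , 1] + Vc[, , , 2] + Vc[, , , 3]
  expect_lt(max(abs(tot2 - 1)), 1e-6)
})

test_that("ROI calibration reproduces the spectral basis on noiseless data", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  d <- c(18, 6, 3)
  mkpair <- function(row) {
    v <- array(0, dim = d)
    v[1:6, , ] <- basis@A[row, 1]
    v[7:12, , ] <- basis@A[row, 2]
    v[13:18, , ] <- basis@A[row, 3]
    mkvol(v)
  }
  muLE <- mkpair(1); muHE <- mkpair(2)
  rois <- list(roiBox(c(1, 1, 1), c(6, 6, 3)),
               roiBox(c(7, 1, 1), c(12, 6, 3)),
               roiBox(c(13, 1, 1), c(18, 6, 3)))
  cal <- calibrateBasis(muLE, muHE, rois, mats)
  expect_equal(cal@A, basis@A, tolerance = 1e-9)
  expect_identical(cal@source, "roi-calibrated")
  # overlapping or tiny ROIs are rejected
  badrois <- list(roiBox(c(1, 1, 1), c(7, 6, 3)),
                  roiBox(c(7, 1, 1), c(12, 6, 3)),
                  roiBox(c(13, 1, 1), c(18, 6, 3)))
  expect_error(calibrateBasis(muLE, muHE, badrois, mats), "overlap")
  tiny <- list(roiBox(c(1, 1, 1), c(2, 2, 2)),
               roiBox(c(7, 1, 1), c(12, 6, 3)),
               roiBox(c(13, 1, 1), c(18, 6, 3)))
  expect_error(calibrateBasis(muLE, muHE, tiny, mats), "27")
})

test_that("mono synthesis of pure soft tissue is uniform at its table value", {
  mats <- c("soft_tissue", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  d <- c(5, 5, 2)
  V <- array(0, dim = c(d, 3)); V[, , , 1] <- 1
  maps <- new("ConcentrationMaps", V = V, materials = basis@materials,
              spacing = 0.107, clipPolicy = "raw")
  mono <- synthesizeMono(maps, 40)
  expect_equal(unique(as.numeric(mono@values)),
               massAttenuation("soft_tissue", 40) * 1.06,
               tolerance = 1e-12)
})

test_that("decompose-then-synthesize at the LE energy reproduces the input", {
  # delta-spectrum pipeline: algebraic round trip
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats, le = monochromaticSpectrum(30),
                        he = monochromaticSpectrum(50))
  M <- rbind(basis@A, c(1, 1, 1))
  set.seed(11)
  d <- c(8, 8, 2)
  V <- matrix(stats::rexp(3 * prod(d)), ncol = 3); V <- V / rowSums(V)
  b <- V %*% t(M)
  muLE <- mkvol(array(b[, 1], dim = d)); muHE <- mkvol(array(b[, 2], dim = d))
  maps <- materialDecompose(muLE, muHE, basis)
  rec <- synthesizeMono(maps, 30)
  expect_equal(rec@values, muLE@values, tolerance = 1e-9)
})

test_that("the mono image is affine in the input volumes", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  cv <- monoCoefficients(basis, 37.5)
  # finite differencing the pipeline recovers the same coefficients
  d <- c(2, 2, 1)
  base <- function(le, he) {
    maps <- materialDecompose(mkvol(array(le, d)), mkvol(array(he, d)),
                              basis)
    synthesizeMono(maps, 37.5)@values[1]
  }
  f0 <- base(0.4, 0.3)
  expect_equal(base(0.4 + 1e-4, 0.3) - f0, cv[["cLE"]] * 1e-4,
               tolerance = 1e-6)
  expect_equal(base(0.4, 0.3 + 1e-4) - f0, cv[["cHE"]] * 1e-4,
               tolerance = 1e-6)
  expect_equal(f0, cv[["cLE"]] * 0.4 + cv[["cHE"]] * 0.3 + cv[["c0"]],
               tolerance = 1e-10)
})

test_that("physical mixtures stay on the simplex before clipping", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  M <- rbind(basis@A, c(1, 1, 1))
  set.seed(23)
  for (i in 1:50) {
    V <- stats::rexp(3); V <- V / sum(V)
    b <- as.numeric(M %*% V)
    maps <- materialDecompose(mkvol(array(b[1], c(1, 1, 1))),
                              mkvol(array(b[2], c(1, 1, 1))), basis)
    expect_true(all(maps@V >= -1e-9 & maps@V <= 1 + 1e-9))
  }
})

test_that("K-edge contrast in synthesized mono images jumps at 37.5 keV", {
  mats <- c("soft_tissue", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  d <- c(2, 1, 1)
  # voxel 1: pure contrast agent, voxel 2: pure soft tissue
  V <- array(0, dim = c(d, 3)); V[1, 1, 1, 3] <- 1; V[2, 1, 1, 1] <- 1
  maps <- new("ConcentrationMaps", V = V, materials = basis@materials,
              spacing = 0.107, clipPolicy = "raw")
  contr <- function(E) {
    m <- synthesizeMono(maps, E)@values
    m[1] - m[2]
  }
  expect_gt(contr(37.5) / contr(37.3), 3)
})

test_that("misaligned or mislabeled inputs are rejected", {
  mats <- c("adipose", "bone_cortical", "micropaque_1to5")
  basis <- computeBasis(mats)
  a <- mkvol(array(0.3, c(4, 4, 2)))
  b <- mkvol(array(0.3, c(4, 4, 3)))
  expect_error(materialDecompose(a, b, basis), "shape")
  g <- new("CTVolume", values = array(3000, c(4, 4, 2)), spacing = 0.107,
           units = "gray16", provenance = "")
  expect_error(materialDecompose(a, g, basis), "gray16ToAttenuation")
  expect_error(synthesizeMono(materialDecompose(a, mkvol(array(0.3, c(4, 4, 2))),
                                                basis), E = 500), "range")
})
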