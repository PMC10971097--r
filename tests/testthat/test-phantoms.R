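test_that("empty primitive list yields a pure background phantom", {
  spec <- phantomSpec(c(16, 16, 4), 0.107, background = "water")
  ph <- buildPhantom(spec)
  expect_true(all(ph$labels@values == 1))
  spec0 <- phantomSpec(c(16, 16, 4), 0.107, background = "air")
  expect_true(all(buildPhantom(spec0)$labels@values == 0))
})

test_that("unknown material names are rejected", {
  spec <- phantomSpec(c(8, 8, 2), 0.107, background = "kryptonite")
  expect_error(buildPhantom(spec), "unknown material")
})

test_that("voxel spacing outside the scanner range is rejected", {
  expect_error(phantomSpec(c(8, 8, 2), 0.5), "0.035-0.210")
  expect_error(phantomSpec(c(8, 8, 2), 0.01), "0.035-0.210")
})

test_that("full-size contrast-tube phantom matches analytic volumes within 2%", {
  spec <- eppendorfPhantom(spacing = 0.107)   # 50 mm lard, 10 mm tube, 5 mm bone
  ph <- buildPhantom(spec, supersample = 2)
  h <- 0.107
  height <- spec@dim[3] * h
  vox <- h^3
  # occupancy-weighted voxel counts (the discretization-consistent count;
  # plain center sampling quantizes the 46.7-voxel bone box by up to ~3%)
  occ <- function(m) sum(ph$fractions[, , , match(m, ph$materials)])
  expect_equal(occ("bone_cortical"), 125 / vox, tolerance = 0.02)
  expect_equal(occ("micropaque_1to5"), (pi * 25 * height - 125) / vox,
               tolerance = 0.02)
  expect_equal(occ("adipose"), pi * (625 - 25) * height / vox,
               tolerance = 0.02)
  # center-sampled labels agree with the analytic volumes a little more
  # loosely (box-edge quantization)
  nBone <- sum(ph$labels@values == match("bone_cortical", ph$materials))
  expect_equal(nBone, 125 / vox, tolerance = 0.04)
})

test_that("phantom construction is deterministic under a fixed seed", {
  a <- buildPhantom(vesselTreePhantom(seed = 5, depth = 3))
  b <- buildPhantom(vesselTreePhantom(seed = 5, depth = 3))
  expect_identical(a$labels@values, b$labels@values)
  c <- buildPhantom(vesselTreePhantom(seed = 6, depth = 3))
  expect_false(identical(a$labels@values, c$labels@values))
})

test_that("vessel trees follow the Murray taper and diameter floor", {
  segs <- generateVesselTree(seed = 1, depth = 0)
  expect_equal(nrow(segs), 1)
  segs <- generateVesselTree(seed = 1, depth = 4, rootDiameter = 1.5,
                             minDiameter = 0.1)
  # symmetric children: child diameter = parent * 2^(-1/3)
  for (i in which(!is.na(segs$parent))) {
    expect_equal(segs$diameter[i],
                 segs$diameter[segs$id == segs$parent[i]] * 2^(-1 / 3),
                 tolerance = 1e-12)
  }
  # requested floor is respected
  segs2 <- generateVesselTree(seed = 1, depth = 10, rootDiameter = 1.0,
                              minDiameter = 0.3)
  expect_gte(min(segs2$diameter), 0.3)
  expect_error(generateVesselTree(taper = 1.0), "taper")
})

test_that("attenuation rendering maps materials to effective values", {
  spec <- phantomSpec(c(12, 12, 3), 0.107, background = "water")
  ph <- buildPhantom(spec)
  vol <- renderAttenuation(ph, 60)
  expect_true(all(abs(vol@values - effectiveLinearAttenuation("water", 60))
                  < 1e-12))
  # noiseless render is idempotent
  expect_identical(renderAttenuation(ph, 60)@values, vol@values)
  # noisy render has the stated spread
  noisy <- renderAttenuation(ph, 60, noiseSd = 0.05, seed = 3)
  expect_equal(sd(noisy@values), 0.05, tolerance = 0.15)
  # partial-volume fractions mix attenuations linearly
  spec2 <- phantomSpec(c(24, 24, 2), 0.1, background = "water",
    primitives = list(list(type = "cylinder", material = "bone_cortical",
                           center = c(1.2, 1.2), radius = 0.6)))
  ph2 <- buildPhantom(spec2, supersample = 2)
  v2 <- renderAttenuation(ph2, 60)
  manual <- ph2$fractions[, , , 1] * effectiveLinearAttenuation("water", 60) +
    ph2$fractions[, , , 2] * effectiveLinearAttenuation("bone_cortical", 60)
  expect_equal(v2@values, array(manual, dim = dim(v2@values)),
               tolerance = 1e-12)
})

test_that("ground-truth masks are emitted for every material", {
  ph <- buildPhantom(vesselTreePhantom(seed = 1, depth = 2), supersample = 2)
  for (m in ph$materials) {
    mm <- materialMask(ph, m)
    occ <- materialMask(ph, m, occupancy = TRUE)
    expect_true(all(occ[mm]))            # occupancy contains the majority mask
  }
  expect_error(materialMask(ph, "copper"), "not present")
})
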