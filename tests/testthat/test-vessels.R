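grayvol <- function(vals, spacing = 0.107) {
  new("CTVolume", values = vals, spacing = spacing, units = "gray16",
      provenance = "test")
}

test_that("threshold segmentation covers its trivial cases and unit checks", {
  v <- grayvol(array(seq(0, 65535, length.out = 1000), c(10, 10, 10)))
  expect_true(all(thresholdSegment(v, 0)@values == 1))
  expect_true(all(thresholdSegment(v, 65536)@values == 0))
  att <- new("CTVolume", values = array(0.5, c(4, 4, 2)), spacing = 0.107,
             units = "attenuation", provenance = "")
  expect_error(thresholdSegment(att, 10000), "gray")
  expect_error(thresholdSegment(v, 0.5), "gray")
})

test_that("gray16 conversion is the stated linear map", {
  att <- new("CTVolume", values = array(c(0.5, 1.0, 3.2767), c(3, 1, 1)),
             spacing = 0.107, units = "attenuation", provenance = "")
  g <- attenuationToGray16(att)
  expect_identical(as.numeric(g@values), c(5000, 10000, 32767))
  back <- gray16ToAttenuation(g)
  expect_equal(back@values, att@values, tolerance = 1e-12)
})

test_that("region growing floods a constant image from one seed", {
  v <- grayvol(array(100, c(12, 12, 6)))
  m <- seededRegionGrowing(v, c(6, 6, 3))
  expect_true(all(m@values == 1))
})

test_that("region growing stays within its blob", {
  v <- array(100, c(30, 12, 6))
  v[16:30, , ] <- 5000                   # far beyond any local tolerance
  m <- seededRegionGrowing(grayvol(v), c(5, 5, 3), k = 2.5, r = 3)
  expect_true(all(m@values[1:15, , ] == 1))
  expect_true(all(m@values[16:30, , ] == 0))
  expect_error(seededRegionGrowing(grayvol(v), c(50, 5, 3)), "outside")
  expect_error(seededRegionGrowing(grayvol(v), c(5, 5, 3), k = -1),
               "positive")
})

test_that("region growing recovers a noisy gradient bone block", {
  # synthetic bone with a slow gradient and noise in a dark background
  set.seed(4)
  d <- c(40, 40, 20)
  v <- array(rnorm(prod(d), 2000, 150), dim = d)
  gt <- array(FALSE, d); gt[10:30, 10:30, 5:15] <- TRUE
  grad <- array(rep(seq(0, 1500, length.out = 40), each = 1), dim = d)
  v[gt] <- 8000 + grad[gt] + rnorm(sum(gt), 0, 150)
  m <- seededRegionGrowing(grayvol(v), c(20, 20, 10), k = 3, r = 3)
  expect_gt(diceCoefficient(m@values > 0, gt), 0.95)
})

test_that("the four-step pipeline degrades gracefully without bone", {
  set.seed(9)
  d <- c(24, 24, 8)
  v <- array(3000, d)
  v[8:16, 8:16, ] <- 30000
  masks <- vesselPipeline(grayvol(v), boneSeeds = NULL)
  step3 <- thresholdSegment(grayvol(v), 6700)
  expect_identical(masks$vessels@values, step3@values)
  expect_true(all(masks$bone@values == 0))
})

test_that("simulated piglet phantom is segmented faithfully", {
  vs <- vesselSim()
  gtOcc <- materialMask(vs$ph, "micropaque_1to5", occupancy = TRUE)
  gtBone <- materialMask(vs$ph, "bone_trabecular")
  expect_gt(diceCoefficient(vs$masks$vessels, gtOcc), 0.90)
  expect_gt(diceCoefficient(vs$masks$bone, gtBone), 0.95)
  # bone does not leak into the vessel mask
  boneOcc <- materialMask(vs$ph, "bone_trabecular", occupancy = TRUE)
  leak <- sum(vs$masks$vessels@values > 0 & boneOcc) / sum(boneOcc)
  expect_lt(leak, 0.02)
})

test_that("pipeline masks are mutually consistent", {
  vs <- vesselSim()
  thick <- vs$masks$thick@values > 0
  vessels <- vs$masks$vessels@values > 0
  bone <- vs$masks$bone@values > 0
  expect_true(all(vessels[thick]))       # thick vessels within all-vessels
  expect_false(any(bone & vessels))      # bone and vessels disjoint
})

test_that("segmentation is deterministic", {
  vs <- vesselSim()
  again <- vesselPipeline(vs$gray, vs$boneSeeds)
  expect_identical(again$vessels@values, vs$masks$vessels@values)
  expect_identical(again$bone@values, vs$masks$bone@values)
})

test_that("map segmentation agrees with the threshold pipeline", {
  vs <- vesselSim()
  mm <- mapSegmentation(vs$maps, component = 3, threshold = 0.18)
  expect_gt(diceCoefficient(mm, vs$masks$vessels), 0.85)
  # noiseless pure-material maps give exact masks
  V <- array(0, dim = c(4, 4, 2, 3)); V[1:2, , , 3] <- 1; V[3:4, , , 1] <- 1
  maps <- new("ConcentrationMaps", V = V, materials = vs$basis@materials,
              spacing = 0.107, clipPolicy = "renormalize")
  m <- mapSegmentation(maps, 3, 0.18)
  expect_identical(m@values[, , ] > 0, V[, , , 3] > 0)
  expect_error(mapSegmentation(maps, 4), "component")
})

test_that("local thickness recovers canonical shapes", {
  # digital sphere of diameter 21 voxels
  d <- c(31, 31, 31)
  g <- expand.grid(i = 1:31, j = 1:31, k = 1:31)
  sph <- array((g$i - 16)^2 + (g$j - 16)^2 + (g$k - 16)^2 <= 10.5^2, dim = d)
  lt <- localThickness(sph, spacing = 1)
  expect_equal(max(lt@values), 21, tolerance = 1 / 21)
  # through-volume cylinder, 2 mm diameter at 0.1 mm spacing
  d2 <- c(41, 41, 30)
  g2 <- expand.grid(i = 1:41, j = 1:41)
  circ <- (g2$i - 21)^2 + (g2$j - 21)^2 <= 10^2
  cyl <- array(rep(circ, 30), dim = d2)
  lt2 <- localThickness(cyl, spacing = 0.1)
  centerline <- lt2@values[21, 21, 5:25]
  expect_true(all(abs(centerline - 2.0) <= 0.1))
  # never exceeds twice the distance-transform maximum
  dt <- distanceTransform(cyl, spacing = 0.1)
  expect_lte(max(lt2@values), 2 * max(dt@values) + 1e-9)
  expect_error(localThickness(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("local thickness is monotone under dilation", {
  set.seed(12)
  d <- c(24, 24, 24)
  blob <- array(FALSE, d)
  blob[8:16, 8:16, 8:16] <- TRUE
  blob[12:20, 12:14, 10:12] <- TRUE
  lt1 <- localThickness(blob, spacing = 1)
  dil <- array(sqrt(dectangio:::cpp_edt_sq(!blob, as.integer(d))) <= 1.8,
               dim = d)
  lt2 <- localThickness(dil, spacing = 1)
  expect_true(all(lt2@values[blob] >= lt1@values[blob] - 1e-9))
})

test_that("per-vessel diameter summaries track the ground truth", {
  vs <- vesselSim()
  lt <- localThickness(vs$masks$vessels)
  vsum <- vesselSummary(lt, vs$spec@segments)
  # mean measured diameter within about one voxel of truth per segment
  expect_true(all(abs(vsum$mean_diameter - vsum$true_diameter) <
                    2 * 0.107))
  cov <- centerlineCoverage(vs$masks$vessels, vs$spec@segments)
  expect_gt(min(cov$coverage), 0.9)
})
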