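# Shared simulated scans, computed once per test session.
#
# The "tube" simulation is the desk-scale contrast-tube phantom (24 mm
# lard cylinder, 8 mm tube of 1:5 Micropaque, 3 mm cortical bone block,
# 107 um voxels, 24 slices) scanned at the frozen "phantom-2h" preset.
# The "vessel" simulation is the piglet surrogate: a depth-4 vessel tree
# (root 1.5 mm, Murray taper) plus a trabecular bone block in soft
# tissue, scanned at "piglet-1h".

.simCache <- new.env(parent = emptyenv())

erodedMask <- function(mask, margin) {
  d <- dim(mask)
  array(sqrt(dectangio:::cpp_edt_sq(as.logical(mask), as.integer(d))) >
          margin, dim = d)
}

tubeSim <- function() {
  if (!is.null(.simCache$tube)) return(.simCache$tube)
  spec <- eppendorfPhantom(spacing = 0.107, containerDiameter = 24,
                           tubeDiameter = 8, boneSize = 3, nz = 24)
  ph <- buildPhantom(spec)
  le <- defaultSpectrum("LE"); he <- defaultSpectrum("HE")
  pre <- scanPreset("phantom-2h")
  scans <- simulateDectScan(ph, le, he, pre$nAngles, pre$n0le, pre$n0he,
                            seed = 42)
  dimxy <- dim(ph$labels@values)[1:2]
  muLE <- fbpReconstruct(scans$le, dim = dimxy)
  muHE <- fbpReconstruct(scans$he, dim = dimxy)
  basis <- computeBasis(c("adipose", "bone_cortical", "micropaque_1to5"),
                        le, he)
  maps <- materialDecompose(muLE, muHE, basis)
  mono <- synthesizeMono(maps)
  rois <- list(
    lard = roiFromMask(erodedMask(materialMask(ph, "adipose"), 6)),
    contrast = roiFromMask(erodedMask(materialMask(ph, "micropaque_1to5"),
                                      4)),
    bone = roiFromMask(erodedMask(materialMask(ph, "bone_cortical"), 3)),
    lardBox = roiBox(c(40, 40, 5), c(71, 71, 20)))
  .simCache$tube <- list(ph = ph, muLE = muLE, muHE = muHE, basis = basis,
                         maps = maps, mono = mono, rois = rois)
  .simCache$tube
}

vesselSim <- function() {
  if (!is.null(.simCache$vessel)) return(.simCache$vessel)
  spec <- vesselTreePhantom(seed = 2, spacing = 0.107, depth = 4,
                            rootDiameter = 1.5, minDiameter = 0.4,
                            lengthFactor = 4.5)
  ph <- buildPhantom(spec, supersample = 2)
  le <- defaultSpectrum("LE"); he <- defaultSpectrum("HE")
  pre <- scanPreset("piglet-1h")
  scans <- simulateDectScan(ph, le, he, pre$nAngles, pre$n0le, pre$n0he,
                            seed = 3)
  dimxy <- dim(ph$labels@values)[1:2]
  muLE <- fbpReconstruct(scans$le, dim = dimxy)
  muHE <- fbpReconstruct(scans$he, dim = dimxy)
  basis <- computeBasis(c("soft_tissue", "bone_trabecular",
                          "micropaque_1to5"), le, he)
  maps <- materialDecompose(muLE, muHE, basis)
  mono <- synthesizeMono(maps)
  gray <- attenuationToGray16(mono)
  bm <- materialMask(ph, "bone_trabecular")
  seeds <- matrix(round(colMeans(which(bm, arr.ind = TRUE))), nrow = 1)
  masks <- vesselPipeline(gray, seeds)
  .simCache$vessel <- list(spec = spec, ph = ph, muLE = muLE, muHE = muHE,
                           basis = basis, maps = maps, mono = mono,
                           gray = gray, masks = masks, boneSeeds = seeds)
  .simCache$vessel
}

# small antialiased water disk, noiseless monochromatic scan
diskSim <- function() {
  if (!is.null(.simCache$disk)) return(.simCache$disk)
  spec <- phantomSpec(c(128, 128, 1), 0.1, background = "air",
    primitives = list(list(type = "cylinder", material = "water",
                           center = c(6.4, 6.4), radius = 4)))
  ph <- buildPhantom(spec, supersample = 4)
  sino <- simulateScan(ph, monochromaticSpectrum(60), nAngles = 60,
                       n0 = Inf)
  .simCache$disk <- list(ph = ph, sino = sino, r = 4, h = 0.1,
                         mu = massAttenuation("water", 60))
  .simCache$disk
}
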