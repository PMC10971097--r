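## Vessel segmentation workflow: thresholding, seeded region growing
## with a local dynamic tolerance, bone subtraction, concentration-map
## segmentation, and mask utilities.

#' Threshold segmentation
#'
#' Mask of voxels at or above a threshold.  The threshold must match the
#' volume's units: a 16-bit gray threshold on an attenuation volume (or
#' vice versa) is rejected.
#'
#' @param volume a \code{CTVolume} (gray16, attenuation, or fraction).
#' @param threshold threshold in the volume's units.
#' @return a \code{CTVolume} with mask units.
#' @export
thresholdSegment <- function(volume, threshold) {
  stopifnot(is(volume, "CTVolume"))
  if (volume@units == "attenuation" && threshold > 200)
    stop("threshold ", threshold, " looks like a 16-bit gray value but ",
         "the volume is in 1/cm; convert with attenuationToGray16()")
  if (volume@units == "gray16" && threshold < 10 && threshold > 0)
    stop("threshold ", threshold, " looks like an attenuation/fraction ",
         "value but the volume is 16-bit gray")
  if (volume@units == "fraction" && (threshold < 0 || threshold > 1))
    stop("fraction volumes take thresholds in [0, 1]")
  new("CTVolume", values = (volume@values >= threshold) + 0,
      spacing = volume@spacing, units = "mask",
      provenance = sprintf("threshold >= %.6g", threshold))
}

#' Convert an attenuation volume to 16-bit gray values
#'
#' Default calibration: gray = mu[1/cm] * 1e4, so gray 10,000 equals
#' 1 /cm (the scanner's native calibration is configurable).
#'
#' @param volume a \code{CTVolume} in 1/cm.
#' @param scale gray levels per 1/cm (default 1e4).
#' @return a \code{CTVolume} with gray16 units.
#' @export
attenuationToGray16 <- function(volume, scale = 1e4) {
  stopifnot(volume@units == "attenuation")
  v <- pmin(pmax(round(volume@values * scale), 0), 65535)
  new("CTVolume", values = v, spacing = volume@spacing, units = "gray16",
      provenance = paste0(volume@provenance,
                          sprintf(" | gray16 x%.4g", scale)))
}

#' Convert a 16-bit gray volume to attenuation
#'
#' @param volume a \code{CTVolume} with gray16 units.
#' @param scale gray levels per 1/cm (default 1e4).
#' @return a \code{CTVolume} in 1/cm.
#' @export
gray16ToAttenuation <- function(volume, scale = 1e4) {
  stopifnot(volume@units == "gray16")
  new("CTVolume", values = volume@values / scale,
      spacing = volume@spacing, units = "attenuation",
      provenance = paste0(volume@provenance,
                          sprintf(" | 1/cm /%.4g", scale)))
}

#' Seeded region growing with local dynamic tolerance
#'
#' Breadth-first growth from seed voxels under 26-connectivity.  A
#' frontier voxel with gray value g joins the region when
#' \code{|g - m_loc| <= k s_loc}, where m_loc and s_loc are the mean and
#' standard deviation of the already-accepted voxels within a cube of
#' radius r around the candidate.  While too few accepted neighbours
#' exist to estimate a spread (or the local spread is zero), the
#' standard deviation of the seed neighbourhood is used.  The visit
#' order is deterministic (FIFO, neighbours in fixed index order), so
#' identical inputs give identical masks.
#'
#' @param volume a \code{CTVolume}.
#' @param seeds integer matrix of voxel indices (rows of i, j, k) or a
#'   length-3 vector.
#' @param k tolerance multiplier (> 0), default 2.5.
#' @param r neighbourhood radius in voxels, default 3.
#' @return a \code{CTVolume} with mask units.
#' @export
seededRegionGrowing <- function(volume, seeds, k = 2.5, r = 3) {
  stopifnot(is(volume, "CTVolume"))
  if (k <= 0) stop("k must be positive")
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  seeds <- round(seeds)
  d <- dim(volume@values)
  if (!nrow(seeds)) stop("no seeds given")
  if (any(seeds < 1) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seeds outside the volume")
  # seed-neighbourhood spread as the starting tolerance scale
  nb <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
    cbind(pmin(pmax(seeds[i, 1] + g$di, 1), d[1]),
          pmin(pmax(seeds[i, 2] + g$dj, 1), d[2]),
          pmin(pmax(seeds[i, 3] + g$dk, 1), d[3]))
  }))
  sInit <- sd(volume@values[nb])
  if (!is.finite(sInit) || sInit == 0) sInit <- 1e-12
  acc <- cpp_region_grow(as.numeric(volume@values), as.integer(d),
                         as.matrix(seeds), k, as.integer(r), sInit)
  new("CTVolume", values = array(acc + 0, dim = d),
      spacing = volume@spacing, units = "mask",
      provenance = sprintf("region growing k=%.3g r=%d", k, r))
}

#' Four-step vessel segmentation
#'
#' The semi-automated recipe applied to the (16-bit gray) virtual
#' monochromatic image: (1) threshold at the thick-vessel level,
#' including only vessels brighter than bone; (2) seeded region growing
#' with local dynamic tolerance to segment the bone; (3) threshold at
#' the thin-vessel level, capturing thin vessels and bone; (4) subtract
#' the bone region.  The returned all-vessel mask is
#' \code{(step1 | step3) & !bone}, which keeps the masks consistent
#' (thick is a subset of all-vessels away from bone; bone and
#' all-vessels are disjoint).  The subtracted bone region is dilated by
#' \code{boneMargin} voxels so that the bone's partial-volume halo
#' (which sits above the thin threshold) does not survive as spurious
#' vessel voxels.
#'
#' @param volume the mono image as a gray16 \code{CTVolume}.
#' @param boneSeeds seed voxels inside the bone (matrix of i, j, k), or
#'   \code{NULL} when the volume contains no bone (the bone mask is then
#'   empty and the all-vessel mask equals the thin-threshold mask).
#' @param thick thick-vessel gray threshold (default 10000).
#' @param thin thin-vessel gray threshold (default 6700); must be below
#'   \code{thick}.
#' @param k,r region-growing parameters.
#' @param boneMargin dilation (voxels, 26-connected) of the bone region
#'   before subtraction.
#' @return list of mask \code{CTVolume}s: \code{thick}, \code{bone},
#'   \code{vessels}.
#' @export
vesselPipeline <- function(volume, boneSeeds, thick = 10000, thin = 6700,
                           k = 2.5, r = 3, boneMargin = 1) {
  if (!(thick > thin)) stop("thick threshold must exceed thin threshold")
  step1 <- thresholdSegment(volume, thick)
  bone <- if (is.null(boneSeeds)) {
    new("CTVolume", values = array(0, dim = dim(volume@values)),
        spacing = volume@spacing, units = "mask",
        provenance = "empty bone mask (no seeds)")
  } else seededRegionGrowing(volume, boneSeeds, k = k, r = r)
  step3 <- thresholdSegment(volume, thin)
  sub <- bone@values > 0
  if (boneMargin > 0 && any(sub)) {
    d <- dim(sub)
    sub <- array(sqrt(cpp_edt_sq(!sub, as.integer(d))) <=
                   boneMargin * sqrt(3) + 1e-9, dim = d)
  }
  vess <- (step1@values > 0 | step3@values > 0) & !sub
  vessels <- new("CTVolume", values = vess + 0, spacing = volume@spacing,
                 units = "mask", provenance = "vessel pipeline")
  # thick vessels proper: bright voxels outside the bone region
  thickm <- new("CTVolume",
                values = (step1@values > 0 & !sub) + 0,
                spacing = volume@spacing, units = "mask",
                provenance = "thick vessels")
  list(thick = thickm, bone = bone, vessels = vessels)
}

#' Concentration-map segmentation
#'
#' Threshold one component of the (renormalized) volume-fraction maps:
#' the direct initial segmentation the decomposition provides (default
#' threshold: 18% volume fraction).
#'
#' @param maps a \code{ConcentrationMaps}.
#' @param component material index 1-3.
#' @param threshold volume-fraction threshold in [0, 1].
#' @return a \code{CTVolume} with mask units.
#' @export
mapSegmentation <- function(maps, component = 3, threshold = 0.18) {
  if (!component %in% 1:3) stop("component must be 1, 2 or 3")
  v <- concValues(maps, component, policy = "renormalize")
  new("CTVolume", values = (v >= threshold) + 0, spacing = maps@spacing,
      units = "mask",
      provenance = sprintf("map segmentation V%d >= %.3g",
                           component, threshold))
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b masks (\code{CTVolume} or logical arrays).
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is(a, "CTVolume")) a@values > 0 else a > 0
  bv <- if (is(b, "CTVolume")) b@values > 0 else b > 0
  s <- sum(av) + sum(bv)
  if (s == 0) return(1)
  2 * sum(av & bv) / s
}

#' Fraction of centerline voxels covered by a mask
#'
#' Per-segment detection measure for vessel phantoms with ground truth:
#' the fraction of each segment's centerline voxels contained in the
#' mask.
#'
#' @param mask a mask \code{CTVolume}.
#' @param segments ground-truth segment data.frame.
#' @return data.frame with id, diameter, n (centerline voxels) and
#'   coverage.
#' @export
centerlineCoverage <- function(mask, segments) {
  d <- dim(mask@values)
  cl <- centerlineVoxels(segments, d, mask@spacing)
  mv <- mask@values > 0
  hit <- mv[cbind(cl$i, cl$j, cl$k)]
  agg <- stats::aggregate(hit, by = list(id = cl$id), FUN = mean)
  n <- stats::aggregate(hit, by = list(id = cl$id), FUN = length)
  data.frame(id = agg$id,
             diameter = segments$diameter[match(agg$id, segments$id)],
             n = n$x, coverage = agg$x)
}

#' Resolution-limit detectability study
#'
#' Simulates a dual-energy scan of a sub-millimeter straight-vessel
#' phantom, synthesizes the virtual mono image, and measures per-diameter
#' centerline coverage of the thin-threshold segmentation in (a) the
#' mono image and (b) a double-exposure HE image acquired with the same
#' total exposure as the LE+HE pair.  A vessel counts as detected when
#' at least half of its centerline voxels are segmented.
#'
#' @param diameters vessel diameters in mm.
#' @param spacing voxel size in mm.
#' @param preset scan preset name.
#' @param seed RNG seed.
#' @param thin thin-vessel gray threshold (default 6700 at the default
#'   gray scale).
#' @param grayScale gray levels per 1/cm.
#' @param nAngles projection angles.
#' @return data.frame with diameter, centerline coverage in the mono and
#'   double-exposure HE images, and detection flags.
#' @export
resolutionStudy <- function(diameters = c(0.15, 0.2, 0.3, 0.5, 1.0),
                            spacing = 0.107, preset = "phantom-2h",
                            seed = 1L, thin = 6700, grayScale = 1e4,
                            nAngles = 180) {
  spec <- resolutionPhantom(diameters = diameters, spacing = spacing)
  ph <- buildPhantom(spec, supersample = 2)
  le <- defaultSpectrum("LE"); he <- defaultSpectrum("HE")
  pre <- scanPreset(preset)
  P <- .projectPhantom(ph, nAngles)
  sle <- simulateScan(ph, le, nAngles, pre$n0le, seed = seed,
                      projections = P)
  she <- simulateScan(ph, he, nAngles, pre$n0he, seed = seed + 1L,
                      projections = P)
  she2 <- simulateScan(ph, he, nAngles, 2 * pre$n0he, seed = seed + 2L,
                       projections = P)
  dimxy <- dim(ph$labels@values)[1:2]
  muLE <- fbpReconstruct(sle, dim = dimxy)
  muHE <- fbpReconstruct(she, dim = dimxy)
  muHE2 <- fbpReconstruct(she2, dim = dimxy)
  basis <- computeBasis(c("adipose", "bone_cortical", "micropaque_1to5"),
                        le, he)
  maps <- materialDecompose(muLE, muHE, basis)
  mono <- synthesizeMono(maps)
  cm <- centerlineCoverage(
    thresholdSegment(attenuationToGray16(mono, grayScale), thin),
    spec@segments)
  ch <- centerlineCoverage(
    thresholdSegment(attenuationToGray16(muHE2, grayScale), thin),
    spec@segments)
  data.frame(diameter = cm$diameter,
             coverage_mono = cm$coverage,
             coverage_he_double = ch$coverage,
             detected_mono = cm$coverage >= 0.5,
             detected_he_double = ch$coverage >= 0.5)
}
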