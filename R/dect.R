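## Image-domain three-material decomposition and virtual monoenergetic
## synthesis: the core dual-energy math.
##
## Per voxel the model is
##   mu_LE = sum_i a_i^LE V_i,   mu_HE = sum_i a_i^HE V_i,   sum_i V_i = 1
## with a_i^S the effective linear attenuation of basis material i under
## spectrum S; the exact 3 x 3 solve yields the volume-fraction maps V_i,
## from which mu(E) = sum_i (mu/rho)_i(E) rho_i V_i synthesizes an image
## at any monochromatic energy.

.basisSystem <- function(basis) {
  rbind(basis@A, c(1, 1, 1))
}

#' Compute a decomposition basis from spectra
#'
#' Effective linear attenuation of each basis material under the LE and
#' HE spectra.
#'
#' @param materials list (or character vector) of exactly three distinct
#'   basis materials.
#' @param le,he the two spectra.
#' @param maxCondition condition-number threshold above which the system
#'   is rejected as ill-conditioned.
#' @return a \code{\linkS4class{DecompositionBasis}}.
#' @export
computeBasis <- function(materials, le = defaultSpectrum("LE"),
                         he = defaultSpectrum("HE"), maxCondition = 1e4) {
  materials <- lapply(materials, bundledMaterial)
  if (length(materials) != 3) stop("exactly three basis materials required")
  nms <- vapply(materials, materialName, "")
  if (anyDuplicated(nms))
    stop("basis materials must be distinct (duplicated: ",
         nms[duplicated(nms)][1], ")")
  A <- rbind(vapply(materials, effectiveLinearAttenuation, numeric(1),
                    spectrum = le),
             vapply(materials, effectiveLinearAttenuation, numeric(1),
                    spectrum = he))
  .newBasis(materials, A, "spectral-model", maxCondition)
}

.newBasis <- function(materials, A, source, maxCondition = 1e4) {
  M <- rbind(A, c(1, 1, 1))
  cn <- kappa(M, exact = TRUE)
  if (!is.finite(cn) || cn > maxCondition) {
    nms <- vapply(materials, materialName, "")
    # most collinear column pair in (muLE, muHE) direction space
    dirs <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    ang <- abs(crossprod(dirs))
    diag(ang) <- 0
    worst <- which(ang == max(ang), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("decomposition system is singular or ",
                        "ill-conditioned (condition number %.3g); ",
                        "offending pair: %s / %s"),
                 cn, nms[worst[1]], nms[worst[2]]))
  }
  new("DecompositionBasis", materials = materials, A = A, source = source,
      conditionNumber = cn)
}

#' Calibrate a basis from regions of interest
#'
#' Practical image-domain route for real scans where the spectra are
#' imperfectly known: the basis entries are the ROI means of the
#' reconstructed LE and HE volumes over one region of pure material each.
#'
#' @param muLE,muHE co-registered attenuation volumes (1/cm).
#' @param rois list of three ROIs (see \code{\link{roiBox}} /
#'   \code{\link{roiSphere}}), one per basis material, pairwise disjoint,
#'   each at least 27 voxels.
#' @param materials list of the three corresponding materials.
#' @return a \code{\linkS4class{DecompositionBasis}} with source
#'   \code{"roi-calibrated"}.
#' @export
calibrateBasis <- function(muLE, muHE, rois, materials) {
  .checkAligned(muLE, muHE)
  materials <- lapply(materials, bundledMaterial)
  if (length(rois) != 3 || length(materials) != 3)
    stop("three ROIs and three materials required")
  idx <- lapply(rois, roiIndices, volume = muLE)
  for (i in 1:3) {
    if (length(idx[[i]]) < 27)
      stop("ROI ", i, " has fewer than 27 voxels")
  }
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(idx[[i]], idx[[j]])))
      stop("ROIs ", i, " and ", j, " overlap")
  }
  A <- rbind(vapply(idx, function(k) mean(muLE@values[k]), numeric(1)),
             vapply(idx, function(k) mean(muHE@values[k]), numeric(1)))
  .newBasis(materials, A, "roi-calibrated")
}

.checkAligned <- function(muLE, muHE) {
  stopifnot(is(muLE, "CTVolume"), is(muHE, "CTVolume"))
  if (!identical(dim(muLE@values), dim(muHE@values)))
    stop("LE and HE volumes differ in shape")
  if (abs(muLE@spacing - muHE@spacing) > 1e-9)
    stop("LE and HE volumes differ in spacing")
  if (muLE@units != "attenuation" || muHE@units != "attenuation")
    stop("decomposition requires attenuation volumes (1/cm); convert ",
         "gray16 input with gray16ToAttenuation()")
}

#' Three-material decomposition of a dual-energy volume pair
#'
#' Solves the per-voxel 3 x 3 system exactly (the basis matrix is
#' factored once).  Under the \code{"raw"} policy the returned fractions
#' sum to one exactly by construction and may leave [0, 1] under noise;
#' \code{"renormalize"} clips to [0, 1] and rescales the sum to one on
#' access.
#'
#' @param muLE,muHE co-registered attenuation volumes (1/cm), assumed
#'   voxel-aligned (sequential scans of an immobilized specimen; no
#'   registration is performed, a shape/spacing assertion guards this).
#' @param basis a \code{DecompositionBasis}.
#' @param clipPolicy \code{"raw"} (default) or \code{"renormalize"}.
#' @return a \code{\linkS4class{ConcentrationMaps}}.
#' @export
materialDecompose <- function(muLE, muHE, basis,
                              clipPolicy = c("raw", "renormalize")) {
  clipPolicy <- match.arg(clipPolicy)
  .checkAligned(muLE, muHE)
  Minv <- solve(.basisSystem(basis))
  d <- dim(muLE@values)
  V <- array(0, dim = c(d, 3))
  for (i in 1:3) {
    V[, , , i] <- Minv[i, 1] * muLE@values + Minv[i, 2] * muHE@values +
      Minv[i, 3]
  }
  new("ConcentrationMaps", V = V, materials = basis@materials,
      spacing = muLE@spacing, clipPolicy = clipPolicy)
}

#' Volume-fraction values of a concentration map
#'
#' @param maps a \code{ConcentrationMaps}.
#' @param component material index 1-3, or \code{NULL} for the full 4D
#'   array.
#' @param policy clip policy override; default the object's own.
#' @return numeric array.
#' @export
concValues <- function(maps, component = NULL, policy = NULL) {
  if (is.null(policy)) policy <- maps@clipPolicy
  V <- maps@V
  if (policy == "renormalize") {
    V <- pmin(pmax(V, 0), 1)
    tot <- V[, , , 1] + V[, , , 2] + V[, , , 3]
    tot[tot <= 0] <- 1                   # fully clipped voxels stay zero
    for (i in 1:3) V[, , , i] <- V[, , , i] / tot
  }
  if (is.null(component)) V
  else array(V[, , , component], dim = dim(V)[1:3])
}

#' Fraction of voxels outside the physical range
#'
#' Count (per component) of raw volume fractions outside [0, 1]; a
#' noise/model-mismatch diagnostic.
#'
#' @param maps a \code{ConcentrationMaps}.
#' @return named numeric vector of out-of-range fractions.
#' @export
outOfRangeFraction <- function(maps) {
  out <- vapply(1:3, function(i) {
    v <- maps@V[, , , i]
    mean(v < 0 | v > 1)
  }, numeric(1))
  names(out) <- vapply(maps@materials, materialName, "")
  out
}

#' Synthesize a virtual monochromatic image
#'
#' Per voxel, \code{mu(E) = sum_i (mu/rho)_i(E) rho_i V_i} from the raw
#' (unclipped) volume fractions, preserving the affine relation between
#' the mono image and the LE/HE input pair (and hence its noise
#' statistics).  The default energy, 37.5 keV, sits just above the
#' barium K edge (37.4 keV).
#'
#' @param maps a \code{ConcentrationMaps}.
#' @param E monochromatic energy in keV.
#' @return a \code{CTVolume} in 1/cm.
#' @export
synthesizeMono <- function(maps, E = 37.5) {
  mu <- vapply(maps@materials, function(m)
    massAttenuation(m, E) * m@density, numeric(1))
  vals <- array(mu[1] * maps@V[, , , 1] + mu[2] * maps@V[, , , 2] +
                  mu[3] * maps@V[, , , 3], dim = dim(maps@V)[1:3])
  new("CTVolume", values = vals, spacing = maps@spacing,
      units = "attenuation",
      provenance = sprintf("virtual mono %.4g keV", E))
}

#' Affine coefficients of the mono synthesis
#'
#' The decomposition-plus-synthesis pipeline is affine per voxel:
#' \code{mu(E) = cLE mu_LE + cHE mu_HE + c0}.  These coefficients drive
#' the analytic noise propagation.
#'
#' @param basis a \code{DecompositionBasis}.
#' @param E monochromatic energy in keV.
#' @return named numeric vector \code{c(cLE, cHE, c0)}.
#' @export
monoCoefficients <- function(basis, E = 37.5) {
  mu <- vapply(basis@materials, function(m)
    massAttenuation(m, E) * m@density, numeric(1))
  cv <- as.numeric(mu %*% solve(.basisSystem(basis)))
  c(cLE = cv[1], cHE = cv[2], c0 = cv[3])
}
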