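#' @useDynLib dectangio, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats fft mvfft rnorm runif approx var sd qnorm pnorm
#' @importFrom utils read.table write.csv head tail
NULL

#' XrayMaterial: a named substance with energy-resolved attenuation data
#'
#' Holds a material's density, elemental (or component) composition, and a
#' tabulated mass attenuation curve on an ascending energy grid.
#' Absorption edges are represented by duplicated grid energies carrying
#' the below-edge and above-edge values; at an edge energy the above-edge
#' branch applies.
#'
#' @slot name character, human-readable material name.
#' @slot density numeric, g/cm^3.
#' @slot composition data.frame with columns \code{component} and
#'   \code{fraction} (mass fractions summing to one).
#' @slot energy numeric, keV grid (ascending, duplicated at edges).
#' @slot massAtten numeric, cm^2/g at each grid energy.
#' @slot edges numeric, edge energies (keV) present in the grid.
#'
#' @export
setClass("XrayMaterial",
  representation(name = "character", density = "numeric",
                 composition = "data.frame", energy = "numeric",
                 massAtten = "numeric", edges = "numeric"))

setValidity("XrayMaterial", function(object) {
  msg <- character()
  if (length(object@density) != 1 || object@density <= 0)
    msg <- c(msg, "density must be a single positive number")
  if (length(object@energy) != length(object@massAtten))
    msg <- c(msg, "energy and massAtten lengths differ")
  if (any(object@massAtten <= 0))
    msg <- c(msg, "all mass attenuation values must be positive")
  d <- diff(object@energy)
  if (any(d < 0))
    msg <- c(msg, "energy grid must be ascending")
  dup <- which(d == 0)
  if (length(dup)) {
    if (!all(object@energy[dup] %in% object@edges))
      msg <- c(msg, "duplicated energies must be declared edges")
    if (any(object@massAtten[dup + 1] <= object@massAtten[dup]))
      msg <- c(msg, "above-edge value must exceed below-edge value")
  }
  if (nrow(object@composition) > 0) {
    fr <- object@composition$fraction
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
      msg <- c(msg, "mass fractions must be >= 0 and sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' XraySpectrum: filtered polychromatic tube emission
#'
#' Relative photon fluence per energy bin for a tube spectrum after
#' filtration, together with the detector weighting convention used when
#' forming effective attenuation coefficients.
#'
#' @slot kvp numeric, tube voltage (kV).
#' @slot energy numeric, keV bin centers.
#' @slot fluence numeric, relative photon fluence per bin (sums to one).
#' @slot filters data.frame with columns \code{material} and \code{mm}.
#' @slot weighting \code{"energy-integrating"} or \code{"photon-counting"}.
#' @slot output numeric, relative tube output (unnormalized fluence
#'   integral, arbitrary units) used by exposure models.
#'
#' @export
setClass("XraySpectrum",
  representation(kvp = "numeric", energy = "numeric", fluence = "numeric",
                 filters = "data.frame", weighting = "character",
                 output = "numeric"))

setValidity("XraySpectrum", function(object) {
  msg <- character()
  if (any(object@fluence < 0)) msg <- c(msg, "fluence must be >= 0")
  if (!any(object@fluence > 0)) msg <- c(msg, "at least one bin must be > 0")
  if (any(object@energy > object@kvp + 1e-9 & object@fluence > 0))
    msg <- c(msg, "fluence must vanish above kvp")
  if (!object@weighting %in% c("energy-integrating", "photon-counting"))
    msg <- c(msg, "unknown weighting")
  if (length(msg)) msg else TRUE
})

#' CTVolume: a 3D scalar grid with isotropic voxel spacing
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric, isotropic voxel size in mm.
#' @slot units one of \code{"attenuation"} (1/cm), \code{"gray16"},
#'   \code{"label"}, \code{"fraction"}, \code{"mask"}, \code{"mm"}.
#' @slot provenance character, free-text processing history.
#'
#' @export
setClass("CTVolume",
  representation(values = "array", spacing = "numeric", units = "character",
                 provenance = "character"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number (isotropic)")
  if (!object@units %in% c("attenuation", "gray16", "label", "fraction",
                           "mask", "mm"))
    msg <- c(msg, "unknown units")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (object@units == "gray16" &&
      (min(object@values) < 0 || max(object@values) > 65535))
    msg <- c(msg, "gray16 values must lie in [0, 65535]")
  if (length(msg)) msg else TRUE
})

#' CTSinogram: parallel-beam projection data
#'
#' @slot data 3D array: detector bin x angle x slice, line integrals
#'   (dimensionless) after log normalization.
#' @slot angles numeric, projection angles in degrees, within [0, 180).
#' @slot pitch numeric, detector bin pitch in mm (equals voxel spacing).
#' @slot spacing numeric, slice spacing in mm.
#' @slot flagged integer, number of rays clipped at the one-count floor.
#'
#' @export
setClass("CTSinogram",
  representation(data = "array", angles = "numeric", pitch = "numeric",
                 spacing = "numeric", flagged = "integer"))

setValidity("CTSinogram", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3) msg <- c(msg, "data must be 3D")
  if (any(object@angles < 0 | object@angles >= 180))
    msg <- c(msg, "angles must lie in [0, 180) degrees")
  if (dim(object@data)[2] != length(object@angles))
    msg <- c(msg, "angle dimension mismatch")
  if (length(msg)) msg else TRUE
})

#' DecompositionBasis: effective attenuation of three basis materials
#'
#' The 2 x 3 matrix A holds the effective linear attenuation (1/cm) of
#' each basis material under the low-energy (row 1) and high-energy
#' (row 2) spectra.  Together with the volume-fraction closure constraint
#' this defines the 3 x 3 per-voxel decomposition system.
#'
#' @slot materials list of three \code{XrayMaterial} objects.
#' @slot A 2 x 3 numeric matrix of effective linear attenuations (1/cm).
#' @slot source \code{"spectral-model"} or \code{"roi-calibrated"}.
#' @slot conditionNumber numeric, condition number of the 3 x 3 system.
#'
#' @export
setClass("DecompositionBasis",
  representation(materials = "list", A = "matrix", source = "character",
                 conditionNumber = "numeric"))

setValidity("DecompositionBasis", function(object) {
  msg <- character()
  if (length(object@materials) != 3)
    msg <- c(msg, "exactly three basis materials required")
  if (!all(dim(object@A) == c(2, 3)))
    msg <- c(msg, "A must be 2 x 3")
  if (any(object@A <= 0))
    msg <- c(msg, "all effective attenuations must be positive")
  if (!object@source %in% c("spectral-model", "roi-calibrated"))
    msg <- c(msg, "unknown source")
  if (length(msg)) msg else TRUE
})

#' ConcentrationMaps: per-voxel volume fractions of three basis materials
#'
#' The raw (unclipped) solution of the three-material system is always
#' stored; the clip policy governs what \code{\link{concValues}} returns.
#' In raw form the fractions sum to one exactly by construction but may
#' leave [0, 1] in the presence of noise.
#'
#' @slot V 4D numeric array (x, y, z, material), raw volume fractions.
#' @slot materials list of three \code{XrayMaterial} objects.
#' @slot spacing numeric, mm.
#' @slot clipPolicy \code{"raw"} or \code{"renormalize"}.
#'
#' @export
setClass("ConcentrationMaps",
  representation(V = "array", materials = "list", spacing = "numeric",
                 clipPolicy = "character"))

setValidity("ConcentrationMaps", function(object) {
  msg <- character()
  if (length(dim(object@V)) != 4 || dim(object@V)[4] != 3)
    msg <- c(msg, "V must be x,y,z,3")
  if (!object@clipPolicy %in% c("raw", "renormalize"))
    msg <- c(msg, "unknown clip policy")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: a digital phantom specification
#'
#' Ordered geometric primitives on a voxel grid; later primitives
#' overwrite earlier ones.  Vessel-tree phantoms additionally carry the
#' ground-truth centerline segments.
#'
#' @slot dim integer vector (nx, ny, nz).
#' @slot spacing numeric, isotropic voxel size in mm (0.035-0.210, the
#'   scanner's voxel size range).
#' @slot background character, background material name.
#' @slot primitives list of primitive descriptors.
#' @slot seed integer seed used to generate stochastic geometry.
#' @slot segments data.frame of ground-truth vessel segments (may be empty).
#'
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric",
                 background = "character", primitives = "list",
                 seed = "integer", segments = "data.frame"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3 || any(object@dim < 1))
    msg <- c(msg, "dim must be three positive integers")
  if (object@spacing < 0.035 - 1e-9 || object@spacing > 0.210 + 1e-9)
    msg <- c(msg, "spacing must lie in the scanner range 0.035-0.210 mm")
  if (length(msg)) msg else TRUE
})
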