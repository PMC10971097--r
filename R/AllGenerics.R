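#' @rdname XrayMaterial-class
#' @param object,x an object.
#' @export
setGeneric("materialName", function(x) standardGeneric("materialName"))

#' @rdname XrayMaterial-class
#' @export
setGeneric("density", function(x) standardGeneric("density"))

#' @rdname XrayMaterial-class
#' @export
setGeneric("energyGrid", function(x) standardGeneric("energyGrid"))

#' @rdname XrayMaterial-class
#' @export
setGeneric("edgeEnergies", function(x) standardGeneric("edgeEnergies"))

#' @rdname CTVolume-class
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname CTVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname CTVolume-class
#' @export
setGeneric("voxelUnits", function(x) standardGeneric("voxelUnits"))

setMethod("materialName", "XrayMaterial", function(x) x@name)
setMethod("density", "XrayMaterial", function(x) x@density)
setMethod("energyGrid", "XrayMaterial", function(x) x@energy)
setMethod("edgeEnergies", "XrayMaterial", function(x) x@edges)
setMethod("voxelData", "CTVolume", function(x) x@values)
setMethod("spacing", "CTVolume", function(x) x@spacing)
setMethod("spacing", "ConcentrationMaps", function(x) x@spacing)
setMethod("spacing", "PhantomSpec", function(x) x@spacing)
setMethod("voxelUnits", "CTVolume", function(x) x@units)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@values))

#' @export
setMethod("dim", "ConcentrationMaps", function(x) dim(x@V)[1:3])

setMethod("show", "XrayMaterial", function(object) {
  cat(sprintf("XrayMaterial: %s\n  density: %.4g g/cm^3\n", object@name,
              object@density))
  cat(sprintf("  grid: %d points, %.3g-%.4g keV\n", length(object@energy),
              min(object@energy), max(object@energy)))
  if (length(object@edges))
    cat("  edges (keV):", paste(sprintf("%.3f", object@edges),
                                collapse = " "), "\n")
  if (nrow(object@composition))
    cat("  composition:",
        paste(sprintf("%s %.4g", object@composition$component,
                      object@composition$fraction), collapse = ", "), "\n")
})

setMethod("show", "XraySpectrum", function(object) {
  filt <- if (nrow(object@filters))
    paste(sprintf("%s %.3g mm", object@filters$material,
                  object@filters$mm), collapse = " + ")
  else "none"
  cat(sprintf("XraySpectrum: %.4g kVp, filters: %s\n", object@kvp, filt))
  cat(sprintf("  mean energy %.2f keV, %d bins, weighting: %s\n",
              meanEnergy(object), length(object@energy), object@weighting))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels @ %.4g mm [%s]\n",
              d[1], d[2], d[3], object@spacing, object@units))
  cat(sprintf("  range: %.4g .. %.4g\n", min(object@values),
              max(object@values)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "CTSinogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTSinogram: %d bins x %d angles x %d slices @ %.4g mm\n",
              d[1], d[2], d[3], object@pitch))
  if (object@flagged > 0)
    cat(sprintf("  %d rays clipped at the one-count floor\n",
                object@flagged))
})

setMethod("show", "DecompositionBasis", function(object) {
  cat(sprintf("DecompositionBasis (%s), condition number %.3g\n",
              object@source, object@conditionNumber))
  A <- object@A
  dimnames(A) <- list(c("LE", "HE"),
                      vapply(object@materials, materialName, ""))
  print(round(A, 4))
})

setMethod("show", "ConcentrationMaps", function(object) {
  d <- dim(object@V)
  cat(sprintf("ConcentrationMaps: %d x %d x %d voxels, policy '%s'\n",
              d[1], d[2], d[3], object@clipPolicy))
  cat("  materials:", paste(vapply(object@materials, materialName, ""),
                            collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d voxels @ %.4g mm, background %s\n",
              object@dim[1], object@dim[2], object@dim[3], object@spacing,
              object@background))
  cat(sprintf("  %d primitives, %d ground-truth segments, seed %d\n",
              length(object@primitives), nrow(object@segments),
              object@seed))
})
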