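## Material definitions and energy-resolved attenuation lookup.
##
## The bundled tables (inst/extdata/materials) were generated offline by
## tools/make_attenuation_tables.R from a parameterized photon
## cross-section model calibrated to standard tabulations; they cover
## 1-150 keV at <= 0.5 keV spacing with duplicated grid points at
## absorption edges.

.dect_env <- new.env(parent = emptyenv())

#' Construct an XrayMaterial
#'
#' @param name material name.
#' @param density mass density in g/cm^3.
#' @param energy ascending keV grid; absorption edges appear as duplicated
#'   energies (below-edge value first).
#' @param massAtten mass attenuation coefficients, cm^2/g.
#' @param edges numeric vector of edge energies present in the grid.
#' @param composition data.frame with columns \code{component},
#'   \code{fraction}.
#' @return an \code{\linkS4class{XrayMaterial}}.
#' @export
xrayMaterial <- function(name, density, energy, massAtten,
                         edges = numeric(),
                         composition = data.frame(component = character(),
                                                  fraction = numeric())) {
  new("XrayMaterial", name = name, density = density, energy = energy,
      massAtten = massAtten, edges = edges, composition = composition)
}

#' List the bundled materials
#'
#' @return character vector of material identifiers accepted by
#'   \code{\link{bundledMaterial}}.
#' @export
listMaterials <- function() {
  files <- list.files(system.file("extdata", "materials",
                                  package = "dectangio"),
                      pattern = "\\.txt$")
  sort(sub("\\.txt$", "", files))
}

#' Load a bundled material
#'
#' Materials are cached after first load.  Identifiers: see
#' \code{\link{listMaterials}} (e.g. \code{"water"}, \code{"adipose"},
#' \code{"bone_cortical"}, \code{"barium_sulfate"},
#' \code{"micropaque_1to5"}).
#'
#' @param name material identifier (file name without extension).
#' @return an \code{\linkS4class{XrayMaterial}}.
#' @export
bundledMaterial <- function(name) {
  if (is(name, "XrayMaterial")) return(name)
  key <- paste0("material_", name)
  if (!is.null(.dect_env[[key]])) return(.dect_env[[key]])
  path <- system.file("extdata", "materials", paste0(name, ".txt"),
                      package = "dectangio")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown material '", name, "'; see listMaterials()")
  m <- readMaterialTable(path)
  .dect_env[[key]] <- m
  m
}

#' Read a material table from a plain-text file
#'
#' File format: comment header (\code{# name:}, \code{# density:},
#' \code{# composition:}, \code{# edges:}) followed by two columns
#' (keV, cm^2/g).
#'
#' @param path file path.
#' @return an \code{\linkS4class{XrayMaterial}}.
#' @export
readMaterialTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(field) {
    h <- grep(paste0("^# ", field, ":"), hdr, value = TRUE)
    if (!length(h)) stop("missing header field '", field, "' in ", path)
    trimws(sub(paste0("^# ", field, ":"), "", h[1]))
  }
  dat <- read.table(text = lines[!grepl("^#", lines)])
  edges <- get("edges")
  edges <- if (edges == "none") numeric()
           else as.numeric(strsplit(edges, "\\s+")[[1]])
  comp_s <- get("composition")
  comp <- do.call(rbind, lapply(strsplit(comp_s, ",\\s*")[[1]], function(p) {
    kv <- strsplit(trimws(p), "\\s+")[[1]]
    data.frame(component = kv[1], fraction = as.numeric(kv[2]))
  }))
  # normalize away header rounding so the stored fractions sum to one
  comp$fraction <- comp$fraction / sum(comp$fraction)
  xrayMaterial(get("name"), as.numeric(get("density")),
               dat[[1]], dat[[2]], edges = edges, composition = comp)
}

#' Write a material table
#'
#' Inverse of \code{\link{readMaterialTable}}; a written table reread
#' yields bit-identical grids.
#'
#' @param material an \code{XrayMaterial}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMaterialTable <- function(material, path) {
  stopifnot(is(material, "XrayMaterial"))
  comp <- paste(sprintf("%s %.10g", material@composition$component,
                        material@composition$fraction), collapse = ", ")
  edges <- if (length(material@edges))
    paste(sprintf("%.4f", material@edges), collapse = " ") else "none"
  writeLines(c(sprintf("# name: %s", material@name),
               sprintf("# density: %.10g", material@density),
               sprintf("# composition: %s", comp),
               sprintf("# edges: %s", edges),
               "# columns: energy_keV mass_attenuation_cm2_g",
               sprintf("%.4f %.6e", material@energy, material@massAtten)),
             path)
  invisible(path)
}

#' Mass attenuation coefficient at given energies
#'
#' Log-log linear interpolation between bracketing grid points.  At an
#' absorption-edge energy the below-edge branch applies for energies
#' strictly below the edge and the above-edge branch at or above it.
#'
#' @param material an \code{XrayMaterial} or bundled material name.
#' @param E energies in keV (vectorized).
#' @return mass attenuation coefficients, cm^2/g.
#' @export
massAttenuation <- function(material, E) {
  m <- bundledMaterial(material)
  Eg <- m@energy; v <- m@massAtten
  if (any(E < Eg[1] | E > Eg[length(Eg)]))
    stop(sprintf("energy out of range for material '%s' (%.4g-%.4g keV)",
                 m@name, Eg[1], Eg[length(Eg)]))
  # index of the last grid point <= E; duplicated edge energies resolve to
  # the above-edge branch
  i1 <- findInterval(E, Eg)             # rightmost tie for duplicates
  exact <- Eg[i1] == E
  out <- numeric(length(E))
  out[exact] <- v[i1[exact]]
  if (any(!exact)) {
    i <- i1[!exact]
    e <- E[!exact]
    out[!exact] <- exp(log(v[i]) + (log(v[i + 1]) - log(v[i])) *
                         (log(e) - log(Eg[i])) / (log(Eg[i + 1]) - log(Eg[i])))
  }
  out
}

#' Mass attenuation of a mixture
#'
#' Mass-fraction-weighted sum of component mass attenuations (standard
#' mixture rule).
#'
#' @param components list of \code{XrayMaterial} objects or names.
#' @param fractions mass fractions; must sum to one (tolerance 1e-6).
#' @param E energies in keV.
#' @return mass attenuation coefficients, cm^2/g.
#' @export
mixtureMassAttenuation <- function(components, fractions, E) {
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", sum(fractions), ")")
  if (length(components) != length(fractions))
    stop("components and fractions must have equal length")
  out <- 0
  for (i in seq_along(components))
    out <- out + fractions[i] * massAttenuation(components[[i]], E)
  out
}

#' K-edge of a material
#'
#' Returns the K absorption edge (keV) of the material's highest-Z
#' constituent if it lies within the tabulated range, otherwise
#' \code{NULL}.  This is the highest edge energy in the table: L and M
#' edges of a constituent always lie below its own K edge, and in the
#' bundled materials every lighter constituent's K edge lies below the
#' heaviest constituent's.
#'
#' @param material an \code{XrayMaterial} or bundled material name.
#' @return edge energy in keV, or \code{NULL} if no edge is tabulated.
#' @export
kedge <- function(material) {
  m <- bundledMaterial(material)
  if (!length(m@edges)) return(NULL)
  max(m@edges)
}
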