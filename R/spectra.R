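## Filtered polychromatic tube spectra and spectrum-weighted effective
## attenuation coefficients.

#' Generate a filtered tube spectrum
#'
#' Unfiltered bremsstrahlung follows the simplified Kramers rule (photon
#' fluence proportional to kvp - E) on a uniform energy grid, with
#' optional tungsten characteristic K lines whose intensity scales as
#' \code{(kvp/69.525 - 1)^1.65} above the tungsten K binding energy
#' (negligible below ~72 kVp, hence effectively absent for the bundled
#' 45/70 kVp settings).  Each filter attenuates by
#' \code{exp(-(mu/rho) rho t)}; the result is normalized to unit total
#' fluence.  The pre-normalization fluence integral is retained as the
#' relative tube output for exposure models.
#'
#' @param kvp tube voltage in kV (20-100).
#' @param filters list of \code{list(material, mm)} pairs (or a
#'   two-column data.frame); thicknesses in mm.
#' @param step energy grid step in keV (default 0.5).
#' @param weighting detector weighting convention used for effective
#'   coefficients: \code{"energy-integrating"} (default, CsI/CMOS flat
#'   panel) or \code{"photon-counting"}.
#' @param tungstenLines logical; include W characteristic lines when the
#'   tube voltage exceeds the K binding energy.
#' @return an \code{\linkS4class{XraySpectrum}}.
#' @export
generateSpectrum <- function(kvp, filters = list(), step = 0.5,
                             weighting = c("energy-integrating",
                                           "photon-counting"),
                             tungstenLines = TRUE) {
  weighting <- match.arg(weighting)
  if (kvp < 20 || kvp > 100)
    stop("kvp outside the supported range 20-100")
  filters <- .normalizeFilters(filters)
  if (any(filters$mm < 0)) stop("filter thickness must be >= 0")
  E <- seq(max(step, 1), kvp, by = step)
  fl <- pmax(kvp - E, 0)
  wk <- 69.525                             # W K binding energy, keV
  if (tungstenLines && kvp > wk) {
    frac <- 0.6 * (kvp / wk - 1)^1.65      # line share of total fluence
    lines <- c(57.982, 59.318, 67.244)     # Kalpha2, Kalpha1, Kbeta1
    rel <- c(0.28, 0.50, 0.22)
    for (i in seq_along(lines)) {
      j <- which.min(abs(E - lines[i]))
      fl[j] <- fl[j] + frac * rel[i] * sum(fl)
    }
  }
  for (i in seq_len(nrow(filters))) {
    m <- bundledMaterial(filters$material[i])
    fl <- fl * exp(-massAttenuation(m, E) * m@density * filters$mm[i] / 10)
  }
  out <- sum(fl) * step
  new("XraySpectrum", kvp = kvp, energy = E, fluence = fl / sum(fl),
      filters = filters, weighting = weighting, output = out)
}

.normalizeFilters <- function(filters) {
  if (is.data.frame(filters)) {
    if (!nrow(filters))
      return(data.frame(material = character(), mm = numeric()))
    return(data.frame(material = as.character(filters[[1]]),
                      mm = as.numeric(filters[[2]])))
  }
  if (!length(filters))
    return(data.frame(material = character(), mm = numeric()))
  data.frame(
    material = vapply(filters, function(f) as.character(f[[1]]), ""),
    mm = vapply(filters, function(f) as.numeric(f[[2]]), 0))
}

#' Mean energy of a spectrum
#'
#' Fluence-weighted mean photon energy in keV.
#'
#' @param spectrum an \code{XraySpectrum}.
#' @return keV.
#' @export
meanEnergy <- function(spectrum) {
  sum(spectrum@energy * spectrum@fluence)
}

#' Detector weights of a spectrum
#'
#' Fluence per bin multiplied by energy for energy-integrating detection,
#' plain fluence for photon counting.
#'
#' @param spectrum an \code{XraySpectrum}.
#' @return numeric vector of weights (not normalized).
#' @export
spectrumWeights <- function(spectrum) {
  if (spectrum@weighting == "energy-integrating")
    spectrum@fluence * spectrum@energy
  else spectrum@fluence
}

#' Harden a spectrum through an absorber
#'
#' Returns the spectrum after passing through a slab of material,
#' renormalized to unit fluence; the relative output is reduced by the
#' transmitted fluence fraction.
#'
#' @param spectrum an \code{XraySpectrum}.
#' @param material absorber material (name or object).
#' @param mm slab thickness in mm.
#' @return an \code{XraySpectrum}.
#' @export
hardenSpectrum <- function(spectrum, material, mm) {
  m <- bundledMaterial(material)
  fl <- spectrum@fluence *
    exp(-massAttenuation(m, spectrum@energy) * m@density * mm / 10)
  new("XraySpectrum", kvp = spectrum@kvp, energy = spectrum@energy,
      fluence = fl / sum(fl),
      filters = rbind(spectrum@filters,
                      data.frame(material = m@name, mm = mm)),
      weighting = spectrum@weighting,
      output = spectrum@output * sum(fl) / sum(spectrum@fluence))
}

#' Effective mass attenuation under a spectrum
#'
#' Weighted average \code{sum(w * mu/rho) / sum(w)} with weights from the
#' spectrum's detector weighting convention.  If \code{spectrum} is a
#' plain number it is treated as a monochromatic energy and the pointwise
#' table value is returned.
#'
#' @param material an \code{XrayMaterial} or name.
#' @param spectrum an \code{XraySpectrum}, or a single energy in keV.
#' @return cm^2/g.
#' @export
effectiveMassAttenuation <- function(material, spectrum) {
  if (is.numeric(spectrum)) return(massAttenuation(material, spectrum))
  stopifnot(is(spectrum, "XraySpectrum"))
  w <- spectrumWeights(spectrum)
  keep <- w > 0
  if (!any(keep)) stop("empty spectrum")
  sum(w[keep] * massAttenuation(material, spectrum@energy[keep])) /
    sum(w[keep])
}

#' Effective linear attenuation under a spectrum or at an energy
#'
#' Density times (effective) mass attenuation.
#'
#' @inheritParams effectiveMassAttenuation
#' @return 1/cm.
#' @export
effectiveLinearAttenuation <- function(material, spectrum) {
  m <- bundledMaterial(material)
  m@density * effectiveMassAttenuation(m, spectrum)
}

#' Write a spectrum to disk
#'
#' Two-column text (keV, relative fluence) plus a JSON sidecar
#' (\code{<path>.json}) holding kvp, filters and weighting.
#'
#' @param spectrum an \code{XraySpectrum}.
#' @param path output path for the two-column table.
#' @return the path, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  writeLines(sprintf("%.4f %.8e", spectrum@energy, spectrum@fluence), path)
  meta <- list(kvp = spectrum@kvp,
               filters = spectrum@filters,
               weighting = spectrum@weighting,
               output = spectrum@output)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spectrum written by \code{\link{writeSpectrum}}
#'
#' @param path path to the two-column table.
#' @return an \code{XraySpectrum}.
#' @export
readSpectrum <- function(path) {
  dat <- read.table(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  filters <- if (length(meta$filters))
    as.data.frame(meta$filters)
  else data.frame(material = character(), mm = numeric())
  new("XraySpectrum", kvp = as.numeric(meta$kvp), energy = dat[[1]],
      fluence = dat[[2]] / sum(dat[[2]]), filters = filters,
      weighting = meta$weighting, output = as.numeric(meta$output))
}

#' The bundled low- and high-energy scan settings
#'
#' The low-energy spectrum is 45 kVp with a 0.5 mm aluminum prefilter;
#' the high-energy spectrum is 70 kVp with 0.35 mm copper.
#'
#' @param which \code{"LE"} or \code{"HE"}.
#' @param step grid step in keV.
#' @return an \code{XraySpectrum}.
#' @export
defaultSpectrum <- function(which = c("LE", "HE"), step = 0.5) {
  which <- match.arg(which)
  key <- paste0("spectrum_", which, "_", step)
  if (!is.null(.dect_env[[key]])) return(.dect_env[[key]])
  sp <- if (which == "LE")
    generateSpectrum(45, list(list("aluminum", 0.5)), step = step)
  else
    generateSpectrum(70, list(list("copper", 0.35)), step = step)
  .dect_env[[key]] <- sp
  sp
}

#' Monochromatic (delta) spectrum
#'
#' A single-bin spectrum at the given energy; effective coefficients
#' under it equal the pointwise table values exactly.
#'
#' @param E photon energy in keV.
#' @param weighting detector weighting convention (irrelevant for a
#'   single bin).
#' @return an \code{XraySpectrum}.
#' @export
monochromaticSpectrum <- function(E, weighting = "energy-integrating") {
  new("XraySpectrum", kvp = E, energy = E, fluence = 1,
      filters = data.frame(material = character(), mm = numeric()),
      weighting = weighting, output = 1)
}
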