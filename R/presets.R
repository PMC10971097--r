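## Frozen scan presets: exposure surrogates for the simulator.
##
## Absolute exposure of the physical scanner is unknowable from the
## outside, so each preset fixes the expected blank detector counts per
## ray (n0) for the LE and HE scans.  The "phantom-2h" preset was
## calibrated once against the contrast-tube phantom so that the LE and
## HE contrast-to-noise ratios land in the ballpark of the published
## phantom measurements (same ordering and gCNR regime), then frozen.
## The LE/HE split reflects the lower tube output and heavier object
## attenuation at 45 kVp for equal scan time.  "short-15min" is the
## same protocol at one eighth of the exposure (15 min versus 2 h);
## "piglet-1h" is the vessel-imaging protocol (smaller specimen, one
## hour per spectrum).

.scanPresets <- list(
  "phantom-2h" = list(n0le = 2.0e5, n0he = 8.0e5, nAngles = 180),
  "short-15min" = list(n0le = 2.5e4, n0he = 1.0e5, nAngles = 180),
  "piglet-1h" = list(n0le = 2.0e5, n0he = 8.0e5, nAngles = 180)
)

#' Named scan presets
#'
#' @param name one of \code{"phantom-2h"}, \code{"short-15min"},
#'   \code{"piglet-1h"}.
#' @return list with \code{n0le}, \code{n0he}, \code{nAngles}.
#' @export
scanPreset <- function(name = "phantom-2h") {
  p <- .scanPresets[[name]]
  if (is.null(p)) stop("unknown scan preset '", name, "'; available: ",
                       paste(names(.scanPresets), collapse = ", "))
  c(p, list(name = name))
}
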