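## Image-quality metrics (CNR, gCNR, SNR) and analytic noise propagation
## into the virtual monochromatic image.

#' Contrast-to-noise ratio between two regions
#'
#' \code{|mean_A - mean_B| / sqrt((var_A + var_B) / 2)} (pooled-std
#' convention, symmetric in the two regions).
#'
#' @param volume a \code{CTVolume}.
#' @param roiA,roiB ROI descriptors, each at least 27 voxels.
#' @return the CNR (dimensionless).
#' @export
cnr <- function(volume, roiA, roiB) {
  a <- roiValues(volume, roiA)
  b <- roiValues(volume, roiB)
  if (length(a) < 27 || length(b) < 27)
    stop("both ROIs must contain at least 27 voxels")
  pooled <- sqrt((var(a) + var(b)) / 2)
  if (pooled == 0)
    stop("zero pooled variance (degenerate constant image)")
  abs(mean(a) - mean(b)) / pooled
}

#' Signal-to-noise ratio in a region
#'
#' @param volume a \code{CTVolume}.
#' @param roi ROI descriptor.
#' @return \code{mean / sd} of the ROI values.
#' @export
snr <- function(volume, roi) {
  v <- roiValues(volume, roi)
  mean(v) / sd(v)
}

#' Generalized contrast-to-noise ratio (histogram-overlap gCNR)
#'
#' \code{1 - sum_k min(p_A(k), p_B(k))} over a shared histogram of
#' equal-width bins spanning the pooled value range: one minus the
#' overlap of the two ROI value distributions.  Bounded in [0, 1] and
#' invariant under any strictly monotone gray-level transform (up to
#' binning).
#'
#' @param volume a \code{CTVolume}.
#' @param roiA,roiB ROI descriptors (>= 100 voxels recommended).
#' @param bins number of histogram bins (default 256).
#' @return gCNR in [0, 1].
#' @export
gcnr <- function(volume, roiA, roiB, bins = 256) {
  a <- roiValues(volume, roiA)
  b <- roiValues(volume, roiB)
  if (!length(a) || !length(b)) stop("empty ROI")
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(0)        # identical constants overlap fully
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  pa <- tabulate(findInterval(a, br, rightmost.closed = TRUE), bins) /
    length(a)
  pb <- tabulate(findInterval(b, br, rightmost.closed = TRUE), bins) /
    length(b)
  1 - sum(pmin(pa, pb))
}

#' Analytic noise propagation into the mono image
#'
#' From the affine synthesis \code{mu(E) = cLE mu_LE + cHE mu_HE + c0}
#' and independent LE/HE noise (sequential scans), the mono-image noise
#' is \code{sqrt(cLE^2 sLE^2 + cHE^2 sHE^2)}.
#'
#' @param basis a \code{DecompositionBasis}.
#' @param sigmaLE,sigmaHE noise standard deviations of the input volumes.
#' @param E mono energy in keV.
#' @return list with \code{sigma} (the mono noise), \code{cLE},
#'   \code{cHE}, and \code{amplification} (sigma relative to sigmaHE).
#' @export
noisePropagation <- function(basis, sigmaLE, sigmaHE, E = 37.5) {
  cv <- monoCoefficients(basis, E)
  s <- sqrt(cv[["cLE"]]^2 * sigmaLE^2 + cv[["cHE"]]^2 * sigmaHE^2)
  list(sigma = s, cLE = cv[["cLE"]], cHE = cv[["cHE"]],
       amplification = s / sigmaHE)
}

#' Contrast enhancement factor of the mono image over the HE image
#'
#' Ratio of the monochromatic attenuation difference between two
#' materials at energy E to their effective attenuation difference under
#' the HE spectrum, computed from the bundled tables:
#' \code{[mu_A(E) - mu_B(E)] / [mu_A^HE - mu_B^HE]}.
#'
#' @param materialA,materialB the two materials (typically contrast
#'   agent and soft tissue/lard).
#' @param he the HE spectrum.
#' @param E mono energy in keV (default 37.5, just above the barium
#'   K edge).
#' @return the enhancement factor (dimensionless).
#' @export
contrastEnhancementFactor <- function(materialA, materialB,
                                      he = defaultSpectrum("HE"),
                                      E = 37.5) {
  num <- effectiveLinearAttenuation(materialA, E) -
    effectiveLinearAttenuation(materialB, E)
  den <- effectiveLinearAttenuation(materialA, he) -
    effectiveLinearAttenuation(materialB, he)
  if (abs(num) < 1e-12 && abs(den) < 1e-12) return(0)  # identical materials
  if (abs(den) < 1e-12)
    stop("HE contrast is (near) zero; enhancement factor undefined")
  num / den
}

#' Noise-budget penalty of splitting exposure across scans
#'
#' Pure counting (Poisson) noise argument: splitting a fixed total
#' exposure over \code{nScans} sequential scans raises each image's
#' noise by \code{sqrt(nScans)}, so a mono image that tolerates a noise
#' increase of \code{amplification} relative to a single full-exposure
#' scan retains an advantage up to \code{amplification / sqrt(nScans)}.
#' With the default arguments this is \code{3 / sqrt(2) ~= 2.1}.
#'
#' @param amplification tolerable noise amplification (default 3,
#'   matching the factor-3 contrast enhancement).
#' @param nScans number of scans sharing the exposure (default 2).
#' @return the net admissible noise factor.
#' @export
doubleExposurePenalty <- function(amplification = 3, nScans = 2) {
  amplification / sqrt(nScans)
}
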