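## Polychromatic parallel-beam projection simulation and slice-wise
## filtered back-projection.
##
## Physics: per energy bin E, expected detected counts for a ray are
## N0 phi(E) exp(-integral mu(E) dl); the recorded detector signal is the
## weighted sum over bins (weight E for the energy-integrating CsI/CMOS
## convention).  Counting noise is applied as a Gaussian with the exact
## compound-Poisson mean and variance (sum w lambda, sum w^2 lambda), an
## excellent approximation at the photon budgets of interest; rays whose
## signal would fall below one detected count are clipped there and
## counted as flagged.

.projectPhantom <- function(phantom, nAngles) {
  lab <- phantom$labels@values
  d <- dim(lab)
  nmat <- max(1L, length(phantom$materials))   # empty phantom: zero paths
  nbins <- ceiling(sqrt(d[1]^2 + d[2]^2)) + 4
  angles <- (seq_len(nAngles) - 1) * pi / nAngles
  fr <- phantom$fractions
  # collapse identical axial slices (the tube phantom is largely
  # z-invariant) so their path integrals are computed once
  if (is.null(fr)) {
    slices <- lapply(seq_len(d[3]), function(z) lab[, , z])
    uniq <- which(!duplicated(slices))
    map <- match(slices, slices[uniq])
  } else {
    uniq <- seq_len(d[3])
    map <- uniq
  }
  L <- vector("list", length(uniq))
  for (u in seq_along(uniq)) {
    z <- uniq[u]
    if (is.null(fr)) {
      L[[u]] <- cpp_project_paths(as.integer(lab[, , z]), d[1], d[2],
                                  nmat, angles, nbins)
    } else {
      L[[u]] <- cpp_project_fracs(as.numeric(fr[, , z, ]), d[1], d[2],
                                  nmat, angles, nbins)
    }
    dim(L[[u]]) <- c(nbins * nAngles, nmat)
  }
  list(L = L, map = map, nbins = nbins, nAngles = nAngles,
       angles = angles, dim = d)
}

.attenMatrix <- function(materials, energy) {
  # nmat x nE linear attenuation (1/cm)
  t(vapply(materials, function(m) {
    mm <- bundledMaterial(m)
    massAttenuation(mm, energy) * mm@density
  }, numeric(length(energy))))
}

#' Simulate a polychromatic projection scan
#'
#' Slice-wise parallel-beam scan of a built phantom under a tube
#' spectrum, returning log-normalized line integrals with counting
#' noise.  Path lengths use a pixel-driven projector with 2 x 2
#' subpixel sampling; detector bin pitch equals the voxel size.
#'
#' @param phantom result of \code{\link{buildPhantom}}.
#' @param spectrum an \code{XraySpectrum}.
#' @param nAngles number of projection angles over [0, 180).
#' @param n0 expected blank photon count per ray (set \code{Inf} for a
#'   noiseless scan).
#' @param seed RNG seed for the counting noise.
#' @param projections optional precomputed geometry from a previous scan
#'   of the same phantom (shared between the LE and HE scans).
#' @return a \code{\linkS4class{CTSinogram}}.
#' @export
simulateScan <- function(phantom, spectrum, nAngles = 180, n0 = 1e5,
                         seed = 1L, projections = NULL) {
  if (!is.infinite(n0) && n0 <= 0) stop("n0 must be positive")
  P <- if (is.null(projections)) .projectPhantom(phantom, nAngles)
       else projections
  E <- spectrum@energy
  phi <- spectrum@fluence
  keep <- phi > 0
  E <- E[keep]; phi <- phi[keep]
  w <- if (spectrum@weighting == "energy-integrating") E else rep(1, length(E))
  mu <- if (length(phantom$materials))
    .attenMatrix(phantom$materials, E)          # nmat x nE
  else matrix(0, 1, length(E))
  vox_cm <- phantom$labels@spacing / 10
  nz <- P$dim[3]
  nray <- P$nbins * P$nAngles
  sino <- array(0, dim = c(P$nbins, P$nAngles, nz))
  flagged <- 0L
  s0 <- sum(w * phi)                            # blank signal per unit n0
  floor_sig <- min(w)                           # one count at the softest bin
  set.seed(seed)
  # per unique slice: noiseless transmitted spectrum terms
  cacheA <- vector("list", length(P$L))
  for (z in seq_len(nz)) {
    u <- P$map[z]
    if (is.null(cacheA[[u]])) {
      tr <- exp(-(P$L[[u]] * vox_cm) %*% mu)    # nray x nE transmission
      m1 <- as.numeric(tr %*% (w * phi))        # signal mean / n0
      m2 <- as.numeric(tr %*% (w * w * phi))    # signal variance / n0
      cacheA[[u]] <- cbind(m1, m2)
    }
    m <- cacheA[[u]]
    if (is.infinite(n0)) {
      sig <- m[, 1] / s0
    } else {
      sig <- (n0 * m[, 1] + sqrt(n0 * m[, 2]) * rnorm(nray)) / (n0 * s0)
      lo <- sig < floor_sig / (n0 * s0)
      if (any(lo)) {
        flagged <- flagged + sum(lo)
        sig[lo] <- floor_sig / (n0 * s0)
      }
    }
    sino[, , z] <- -log(sig)
  }
  new("CTSinogram", data = sino, angles = P$angles * 180 / pi,
      pitch = phantom$labels@spacing, spacing = phantom$labels@spacing,
      flagged = flagged)
}

#' Simulate a co-registered dual-energy scan pair
#'
#' Runs \code{\link{simulateScan}} for the LE and HE spectra over the
#' same projection geometry (computed once).  The two scans are
#' sequential: their counting noise is independent.
#'
#' @param phantom result of \code{\link{buildPhantom}}.
#' @param le,he the two spectra.
#' @param nAngles projection angles.
#' @param n0le,n0he blank counts per ray for each scan.
#' @param seed base RNG seed (LE uses \code{seed}, HE \code{seed + 1}).
#' @return list with elements \code{le} and \code{he}.
#' @export
simulateDectScan <- function(phantom, le = defaultSpectrum("LE"),
                             he = defaultSpectrum("HE"), nAngles = 180,
                             n0le = 1e5, n0he = 1e5, seed = 1L) {
  P <- .projectPhantom(phantom, nAngles)
  list(le = simulateScan(phantom, le, nAngles, n0le, seed, projections = P),
       he = simulateScan(phantom, he, nAngles, n0he, seed + 1L,
                         projections = P))
}

.rampKernel <- function(nbins, pitch_cm) {
  # discrete Ram-Lak kernel (Kak & Slaney), length 2*nbins - 1
  n <- -(nbins - 1):(nbins - 1)
  h <- numeric(length(n))
  h[n == 0] <- 1 / (4 * pitch_cm^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * pitch_cm)^2
  h
}

#' Filtered back-projection reconstruction
#'
#' Slice-wise ramp-filtered (Ram-Lak) parallel-beam reconstruction of a
#' sinogram onto the original voxel grid; output in 1/cm.
#'
#' @param sinogram a \code{\linkS4class{CTSinogram}}.
#' @param dim target slice size (nx, ny); defaults to the largest square
#'   grid the detector covers.
#' @return a \code{CTVolume} in 1/cm.
#' @export
fbpReconstruct <- function(sinogram, dim = NULL) {
  d <- base::dim(sinogram@data)
  nbins <- d[1]; na <- d[2]; nz <- d[3]
  if (na < 2) stop("need at least 2 angles")
  if (is.null(dim)) {
    n <- floor((nbins - 4) / sqrt(2))
    dim <- c(n, n)
  }
  pitch_cm <- sinogram@pitch / 10
  h <- .rampKernel(nbins, pitch_cm)
  nfft <- 2^ceiling(log2(length(h) + nbins))
  H <- fft(c(h, rep(0, nfft - length(h))))
  angles <- sinogram@angles * pi / 180
  vals <- array(0, dim = c(dim[1], dim[2], nz))
  for (z in seq_len(nz)) {
    p <- sinogram@data[, , z]
    pp <- rbind(p, matrix(0, nfft - nbins, na))
    q <- Re(mvfft(mvfft(pp) * H, inverse = TRUE)) / nfft
    q <- q[nbins:(2 * nbins - 1), , drop = FALSE] * pitch_cm
    bp <- cpp_backproject(as.numeric(q), nbins, angles, dim[1], dim[2])
    vals[, , z] <- 2 * bp            # cpp applies pi/(2 na); FBP needs pi/na
  }
  new("CTVolume", values = vals, spacing = sinogram@pitch,
      units = "attenuation",
      provenance = sprintf("FBP, %d angles", na))
}
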