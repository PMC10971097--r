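## Digital phantom construction: geometric primitives on a voxel grid,
## the contrast-tube ("Eppendorf") preset, and attenuation rendering.
##
## Voxel convention: world position of voxel center (i, j, k) (1-based)
## is ((i - 0.5) s, (j - 0.5) s, (k - 0.5) s) for spacing s; primitives
## are specified in world mm.  Later primitives overwrite earlier ones;
## voxels are labeled by center-of-voxel sampling (optionally
## supersampled for partial-volume fractions).

#' Construct a PhantomSpec
#'
#' @param dim grid size (nx, ny, nz) in voxels.
#' @param spacing isotropic voxel size in mm (scanner range 0.035-0.210).
#' @param background background material name (\code{"air"} for none).
#' @param primitives ordered list of primitives; each is a list with
#'   \code{type} (\code{"cylinder"}, \code{"sphere"}, \code{"box"},
#'   \code{"tube"}, \code{"cone"}), \code{material}, and geometry fields
#'   in mm (see \code{\link{buildPhantom}}).
#' @param seed integer seed stored in the PhantomSpec.
#' @param segments optional data.frame of ground-truth vessel segments.
#' @return a \code{\linkS4class{PhantomSpec}}.
#' @export
phantomSpec <- function(dim, spacing, background = "air",
                        primitives = list(), seed = 0L,
                        segments = NULL) {
  if (is.null(segments))
    segments <- data.frame(id = integer(), parent = integer(),
                           depth = integer(), x0 = numeric(), y0 = numeric(),
                           z0 = numeric(), x1 = numeric(), y1 = numeric(),
                           z1 = numeric(), diameter = numeric())
  new("PhantomSpec", dim = as.integer(dim), spacing = spacing,
      background = background, primitives = primitives,
      seed = as.integer(seed), segments = segments)
}

.primitiveMask <- function(prim, X, Y, Z) {
  # X, Y, Z: coordinate vectors/arrays of voxel centers (mm)
  switch(prim$type,
    cylinder = {
      r2 <- (X - prim$center[1])^2 + (Y - prim$center[2])^2
      m <- r2 <= prim$radius^2
      if (!is.null(prim$zlim))
        m <- m & Z >= prim$zlim[1] & Z <= prim$zlim[2]
      m
    },
    sphere = {
      (X - prim$center[1])^2 + (Y - prim$center[2])^2 +
        (Z - prim$center[3])^2 <= prim$radius^2
    },
    box = {
      X >= prim$lo[1] & X <= prim$hi[1] &
      Y >= prim$lo[2] & Y <= prim$hi[2] &
      Z >= prim$lo[3] & Z <= prim$hi[3]
    },
    tube = ,
    cone = {
      p0 <- prim$p0; p1 <- prim$p1
      d <- p1 - p0
      L2 <- sum(d^2)
      t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / L2
      tc <- pmin(pmax(t, 0), 1)
      dx <- X - (p0[1] + tc * d[1])
      dy <- Y - (p0[2] + tc * d[2])
      dz <- Z - (p0[3] + tc * d[3])
      r <- if (prim$type == "cone")
        prim$r0 + tc * (prim$r1 - prim$r0)
      else prim$radius
      dx * dx + dy * dy + dz * dz <= r * r
    },
    stop("unknown primitive type '", prim$type, "'"))
}

#' Rasterize a phantom specification
#'
#' Voxels are labeled by the last primitive covering the voxel center.
#' With \code{supersample > 1} each voxel is sampled on a supersample^3
#' subgrid and per-material occupancy fractions are returned alongside
#' the (majority-vote) labels, which is how partial-volume effects for
#' sub-voxel vessels are modeled.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param supersample integer subsampling factor per axis (default 1:
#'   plain center sampling).
#' @return a list with elements \code{labels} (a \code{CTVolume} of
#'   material indices, 0 = air), \code{materials} (character vector
#'   mapping label index to material name), \code{fractions} (4D array of
#'   per-material occupancy, or \code{NULL}), and \code{spec}.
#' @export
buildPhantom <- function(spec, supersample = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  mats <- unique(c(if (spec@background != "air") spec@background,
                   vapply(spec@primitives, `[[`, "", "material")))
  for (m in mats) bundledMaterial(m)       # fail early on unknown names
  nx <- spec@dim[1]; ny <- spec@dim[2]; nz <- spec@dim[3]
  s <- spec@spacing
  labelOf <- function(name) if (name == "air") 0L else match(name, mats)
  sampleLabels <- function(ox, oy, oz) {
    # offsets in voxel units relative to the voxel center
    xs <- (seq_len(nx) - 0.5 + ox) * s
    ys <- (seq_len(ny) - 0.5 + oy) * s
    zs <- (seq_len(nz) - 0.5 + oz) * s
    lab <- array(labelOf(spec@background), dim = c(nx, ny, nz))
    X <- array(xs, c(nx, ny, nz))
    Y <- array(rep(ys, each = nx), c(nx, ny, nz))
    Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
    for (p in spec@primitives) {
      m <- .primitiveMask(p, X, Y, Z)
      lab[m] <- labelOf(p$material)
    }
    lab
  }
  ss <- as.integer(supersample)
  if (ss <= 1) {
    lab <- sampleLabels(0, 0, 0)
    fractions <- NULL
  } else {
    off <- (seq_len(ss) - (ss + 1) / 2) / ss
    counts <- array(0, dim = c(nx, ny, nz, length(mats)))
    for (oz in off) for (oy in off) for (ox in off) {
      l <- sampleLabels(ox, oy, oz)
      for (k in seq_along(mats))
        counts[, , , k] <- counts[, , , k] + c(l == k)
    }
    fractions <- counts / ss^3
    lab <- array(0L, dim = c(nx, ny, nz))
    best <- array(0, dim = c(nx, ny, nz))
    for (k in seq_along(mats)) {
      f <- array(fractions[, , , k], dim = c(nx, ny, nz))
      upd <- f > best & f > 0.5           # majority label
      lab[upd] <- k
      best[upd] <- f[upd]
    }
  }
  vol <- new("CTVolume", values = lab + 0.0, spacing = s, units = "label",
             provenance = sprintf("phantom seed %d", spec@seed))
  list(labels = vol, materials = mats, fractions = fractions, spec = spec)
}

#' Ground-truth mask of one material in a built phantom
#'
#' By default the mask contains voxels whose (majority) label is the
#' material; with \code{occupancy = TRUE} and a supersampled phantom it
#' contains every voxel with nonzero occupancy of the material, which is
#' the appropriate reference for structures near the voxel size.
#'
#' @param phantom result of \code{\link{buildPhantom}}.
#' @param material material name.
#' @param occupancy logical; use any-occupancy instead of majority label.
#' @return logical 3D array.
#' @export
materialMask <- function(phantom, material, occupancy = FALSE) {
  k <- match(material, phantom$materials)
  if (is.na(k)) stop("material '", material, "' not present in phantom")
  if (occupancy && !is.null(phantom$fractions))
    return(array(phantom$fractions[, , , k] > 0,
                 dim = dim(phantom$labels@values)))
  phantom$labels@values == k
}

#' The contrast-tube validation phantom
#'
#' A lard-filled cylindrical container with an immersed tube of diluted
#' barium sulfate contrast agent containing a small block of bone:
#' the three-material test object used to validate the dual-energy
#' workflow.  Defaults reproduce the full-size object (50 mm lard
#' cylinder, 10 mm contrast tube, 5 mm bone block at 107 um voxels);
#' scaled-down variants are used for simulated scans.
#'
#' @param spacing voxel size in mm.
#' @param containerDiameter lard cylinder diameter in mm.
#' @param tubeDiameter contrast tube diameter in mm.
#' @param boneSize bone block edge length in mm.
#' @param nz number of axial slices.
#' @param tubeMaterial contrast material (default 1:5 diluted Micropaque).
#' @param boneMaterial bone material.
#' @return a \code{\linkS4class{PhantomSpec}}.
#' @export
eppendorfPhantom <- function(spacing = 0.107, containerDiameter = 50,
                             tubeDiameter = 10, boneSize = 5, nz = 48,
                             tubeMaterial = "micropaque_1to5",
                             boneMaterial = "bone_cortical") {
  n <- ceiling(containerDiameter / spacing) + 8
  cx <- n * spacing / 2
  zmid <- nz * spacing / 2
  tubeOff <- containerDiameter / 8
  prims <- list(
    list(type = "cylinder", material = "adipose", center = c(cx, cx),
         radius = containerDiameter / 2),
    list(type = "cylinder", material = tubeMaterial,
         center = c(cx, cx + tubeOff), radius = tubeDiameter / 2),
    list(type = "box", material = boneMaterial,
         lo = c(cx - boneSize / 2, cx + tubeOff - boneSize / 2,
                zmid - boneSize / 2),
         hi = c(cx + boneSize / 2, cx + tubeOff + boneSize / 2,
                zmid + boneSize / 2)))
  phantomSpec(c(n, n, nz), spacing, background = "air",
              primitives = prims, seed = 0L)
}

#' Render a phantom as an attenuation volume
#'
#' Per-voxel effective linear attenuation of the voxel's material under
#' the given spectrum (or monochromatic energy).  This is the fast
#' analytic imaging mode: optional additive Gaussian noise of stated
#' standard deviation, no projection physics.  When the phantom carries
#' partial-volume fractions the attenuations are volume-fraction mixed.
#'
#' @param phantom result of \code{\link{buildPhantom}}.
#' @param spectrum an \code{XraySpectrum} or a monochromatic energy (keV).
#' @param noiseSd standard deviation of additive Gaussian noise (1/cm).
#' @param seed RNG seed used when \code{noiseSd > 0}.
#' @return a \code{CTVolume} in 1/cm.
#' @export
renderAttenuation <- function(phantom, spectrum, noiseSd = 0, seed = 1L) {
  mu <- vapply(phantom$materials, effectiveLinearAttenuation,
               numeric(1), spectrum = spectrum)
  if (!is.null(phantom$fractions)) {
    vals <- array(0, dim = dim(phantom$labels@values))
    for (k in seq_along(phantom$materials))
      vals <- vals + array(phantom$fractions[, , , k], dim = dim(vals)) *
        mu[k]
  } else {
    lut <- c(0, mu)                        # label 0 = air
    vals <- array(lut[phantom$labels@values + 1L],
                  dim = dim(phantom$labels@values))
  }
  if (noiseSd > 0) {
    set.seed(seed)
    vals <- vals + array(rnorm(length(vals), sd = noiseSd), dim = dim(vals))
  }
  tag <- if (is.numeric(spectrum)) sprintf("%.4g keV", spectrum)
         else sprintf("%.4g kVp", spectrum@kvp)
  new("CTVolume", values = vals, spacing = phantom$labels@spacing,
      units = "attenuation",
      provenance = sprintf("analytic render, %s", tag))
}
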