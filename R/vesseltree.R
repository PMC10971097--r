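## Synthetic branching vessel trees with ground-truth centerlines and
## diameters, plus phantom presets built on them.

#' Generate a bifurcating vessel tree
#'
#' Recursive symmetric bifurcation: each segment of diameter d has length
#' \code{lengthFactor * d}; its two children follow a Murray-type taper
#' (default \code{d_child = d * 2^(-1/3)}, so that
#' \code{d_parent^3 = sum(d_child^3)}).  Child directions deviate from
#' the parent by \code{branchAngle} degrees in a plane whose azimuth
#' advances deterministically (seeded jitter).  Branching stops at
#' \code{depth} or when a child diameter would fall below
#' \code{minDiameter}, so every generated segment has diameter at least
#' \code{minDiameter}.
#'
#' @param seed integer RNG seed (identical seed, identical tree).
#' @param depth maximum number of bifurcation levels (0 = root only).
#' @param rootDiameter root diameter in mm.
#' @param minDiameter smallest admissible diameter in mm.
#' @param rootStart numeric length-3, root start point (mm).
#' @param rootDir numeric length-3 direction (normalized internally).
#' @param lengthFactor segment length as a multiple of its diameter.
#' @param branchAngle half-opening angle between children, degrees.
#' @param taper child/parent diameter ratio; must be < 1.
#' @param jitter angular jitter amplitude in degrees.
#' @return a data.frame of segments with columns id, parent, depth,
#'   x0..z1 (endpoints, mm) and diameter (mm).
#' @export
generateVesselTree <- function(seed = 1L, depth = 4L, rootDiameter = 1.5,
                               minDiameter = 0.2,
                               rootStart = c(0, 0, 0),
                               rootDir = c(1, 0, 0),
                               lengthFactor = 6, branchAngle = 35,
                               taper = 2^(-1 / 3), jitter = 8) {
  if (taper >= 1)
    stop("taper must be < 1 (non-terminating tree)")
  if (minDiameter <= 0 || rootDiameter < minDiameter)
    stop("need 0 < minDiameter <= rootDiameter")
  set.seed(seed)
  segs <- list()
  nid <- 0L
  norm3 <- function(v) v / sqrt(sum(v^2))
  perp <- function(d) {
    # a unit vector perpendicular to d
    a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    norm3(a - sum(a * d) * d)
  }
  rot <- function(d, axis, ang) {
    # Rodrigues rotation of d about unit axis
    d * cos(ang) + .cross(axis, d) * sin(ang) +
      axis * sum(axis * d) * (1 - cos(ang))
  }
  grow <- function(p0, dir, d, lev, parent) {
    nid <<- nid + 1L
    id <- nid
    L <- lengthFactor * d
    p1 <- p0 + L * dir
    segs[[id]] <<- data.frame(id = id, parent = parent, depth = lev,
                              x0 = p0[1], y0 = p0[2], z0 = p0[3],
                              x1 = p1[1], y1 = p1[2], z1 = p1[3],
                              diameter = d)
    dc <- d * taper
    if (lev >= depth || dc < minDiameter) return(invisible())
    u <- perp(dir)
    az <- runif(1, 0, 2 * pi)
    u <- rot(u, dir, az)
    ba <- (branchAngle + runif(2, -jitter, jitter)) * pi / 180
    for (sgn in c(1, -1)) {
      a <- if (sgn > 0) ba[1] else ba[2]
      child <- norm3(rot(dir, u, sgn * a))
      grow(p1, child, dc, lev + 1L, id)
    }
  }
  grow(rootStart, norm3(rootDir), rootDiameter, 0L, NA_integer_)
  do.call(rbind, segs)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.segmentsToPrimitives <- function(segments, material) {
  lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    list(type = "tube", material = material,
         p0 = c(s$x0, s$y0, s$z0), p1 = c(s$x1, s$y1, s$z1),
         radius = s$diameter / 2)
  })
}

#' Vessel-tree phantom with optional bone block
#'
#' A branching contrast-filled vessel tree in a soft-tissue background,
#' with an optional trabecular-bone block placed clear of the tree: the
#' synthetic stand-in for the contrast-infused piglet anatomy used to
#' exercise the segmentation workflow.
#'
#' @param seed tree seed.
#' @param spacing voxel size in mm.
#' @param dim grid size; default sized to hold the tree.
#' @param depth,rootDiameter,minDiameter,lengthFactor,branchAngle see
#'   \code{\link{generateVesselTree}}.
#' @param background background material.
#' @param vesselMaterial contrast material.
#' @param bone logical, include the bone block.
#' @param boneMaterial bone material (juvenile trabecular surrogate).
#' @return a \code{\linkS4class{PhantomSpec}} carrying the ground-truth
#'   segments.
#' @export
vesselTreePhantom <- function(seed = 1L, spacing = 0.107,
                              dim = NULL, depth = 4L,
                              rootDiameter = 1.2, minDiameter = 0.35,
                              lengthFactor = 5, branchAngle = 32,
                              background = "soft_tissue",
                              vesselMaterial = "micropaque_1to5",
                              bone = TRUE,
                              boneMaterial = "bone_trabecular") {
  # grow along +x starting near the -x face, centered in y/z
  if (is.null(dim)) {
    ext <- lengthFactor * rootDiameter * sum(2^(-(0:depth) / 3)) * 1.15
    n <- ceiling(ext / spacing) + 8
    nzv <- max(32, ceiling(0.45 * n))
    dim <- c(n, n, nzv)
  }
  cx <- dim[1] * spacing / 2
  cy <- dim[2] * spacing / 2
  cz <- dim[3] * spacing / 2
  segs <- generateVesselTree(seed = seed, depth = depth,
                             rootDiameter = rootDiameter,
                             minDiameter = minDiameter,
                             rootStart = c(rootDiameter, cy * 0.75, cz),
                             rootDir = c(1, 0.05, 0),
                             lengthFactor = lengthFactor,
                             branchAngle = branchAngle)
  # keep the tree inside the grid and flatten z excursions
  zr <- range(c(segs$z0, segs$z1))
  zscale <- min(1, (dim[3] * spacing * 0.6) / max(diff(zr), 1e-6))
  segs$z0 <- cz + (segs$z0 - mean(zr)) * zscale
  segs$z1 <- cz + (segs$z1 - mean(zr)) * zscale
  prims <- .segmentsToPrimitives(segs, vesselMaterial)
  if (bone) {
    bs <- max(2.5, rootDiameter * 2)
    lo <- c(cx - bs / 2, spacing * 4, cz - bs / 2)
    prims <- c(prims,
               list(list(type = "box", material = boneMaterial,
                         lo = lo, hi = lo + bs)))
  }
  phantomSpec(dim, spacing, background = background, primitives = prims,
              seed = seed, segments = segs)
}

#' Resolution phantom: straight sub-millimeter vessels
#'
#' Parallel contrast-filled tubes of the given diameters in a lard
#' background, tilted a few degrees off the slice normal to avoid
#' grid-aligned sampling, used for the detectability study near the
#' sampling limit.
#'
#' @param diameters vessel diameters in mm.
#' @param spacing voxel size in mm.
#' @param nz number of slices.
#' @param tiltDeg tilt of the tubes relative to the z axis, degrees.
#' @param vesselMaterial contrast material.
#' @return a \code{\linkS4class{PhantomSpec}} with ground-truth segments.
#' @export
resolutionPhantom <- function(diameters = c(0.15, 0.2, 0.3, 0.5, 1.0),
                              spacing = 0.107, nz = 32, tiltDeg = 7,
                              vesselMaterial = "micropaque_1to5") {
  nd <- length(diameters)
  width <- (nd + 1) * 2.2
  n <- ceiling(width / spacing) + 8
  zlen <- nz * spacing
  cy <- n * spacing / 2
  tilt <- tan(tiltDeg * pi / 180) * zlen
  segs <- do.call(rbind, lapply(seq_len(nd), function(i) {
    x <- i * 2.2
    data.frame(id = i, parent = NA_integer_, depth = 0L,
               x0 = x, y0 = cy - tilt / 2, z0 = 0,
               x1 = x, y1 = cy + tilt / 2, z1 = zlen,
               diameter = diameters[i])
  }))
  prims <- c(list(list(type = "cylinder", material = "adipose",
                       center = c(n * spacing / 2, cy),
                       radius = n * spacing / 2 - 2 * spacing)),
             .segmentsToPrimitives(segs, vesselMaterial))
  phantomSpec(c(n, n, nz), spacing, background = "air",
              primitives = prims, seed = 0L, segments = segs)
}

#' Sample ground-truth centerline voxels of vessel segments
#'
#' @param segments segment data.frame (see
#'   \code{\link{generateVesselTree}}).
#' @param dim volume dimensions.
#' @param spacing voxel size in mm.
#' @param stepFraction sampling step along the centerline, as a fraction
#'   of the voxel size.
#' @return data.frame with segment id and voxel indices (i, j, k).
#' @export
centerlineVoxels <- function(segments, dim, spacing, stepFraction = 0.5) {
  out <- lapply(seq_len(nrow(segments)), function(r) {
    s <- segments[r, ]
    p0 <- c(s$x0, s$y0, s$z0); p1 <- c(s$x1, s$y1, s$z1)
    L <- sqrt(sum((p1 - p0)^2))
    nstep <- max(2, ceiling(L / (spacing * stepFraction)))
    t <- seq(0, 1, length.out = nstep)
    ijk <- unique(cbind(
      pmin(pmax(ceiling((p0[1] + t * (p1[1] - p0[1])) / spacing), 1), dim[1]),
      pmin(pmax(ceiling((p0[2] + t * (p1[2] - p0[2])) / spacing), 1), dim[2]),
      pmin(pmax(ceiling((p0[3] + t * (p1[3] - p0[3])) / spacing), 1), dim[3])))
    data.frame(id = s$id, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3])
  })
  do.call(rbind, out)
}
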