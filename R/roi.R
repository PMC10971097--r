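## Lightweight region-of-interest descriptors (box or sphere in voxel
## coordinates, or an explicit mask).

#' Box region of interest
#'
#' @param lo,hi inclusive voxel index corners (length-3 integer vectors).
#' @param label optional text label.
#' @return an ROI descriptor.
#' @export
roiBox <- function(lo, hi, label = "") {
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi >= lo))
  structure(list(type = "box", lo = as.integer(lo), hi = as.integer(hi),
                 label = label), class = "dectROI")
}

#' Spherical region of interest
#'
#' @param center voxel coordinates of the center (may be fractional).
#' @param radius radius in voxels.
#' @param label optional text label.
#' @return an ROI descriptor.
#' @export
roiSphere <- function(center, radius, label = "") {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = radius, label = label), class = "dectROI")
}

#' Mask-defined region of interest
#'
#' @param mask logical 3D array (or \code{CTVolume} with mask units).
#' @param label optional text label.
#' @return an ROI descriptor.
#' @export
roiFromMask <- function(mask, label = "") {
  if (is(mask, "CTVolume")) mask <- mask@values != 0
  structure(list(type = "mask", mask = mask, label = label),
            class = "dectROI")
}

#' Linear voxel indices of an ROI within a volume
#'
#' @param roi an ROI descriptor.
#' @param volume the \code{CTVolume} (or 3D array) the ROI refers to.
#' @return integer vector of linear indices.
#' @export
roiIndices <- function(roi, volume) {
  d <- if (is(volume, "CTVolume")) dim(volume@values) else dim(volume)
  switch(roi$type,
    box = {
      if (any(roi$lo < 1) || any(roi$hi > d))
        stop("ROI exceeds volume bounds")
      ii <- roi$lo[1]:roi$hi[1]; jj <- roi$lo[2]:roi$hi[2]
      kk <- roi$lo[3]:roi$hi[3]
      as.integer(outer(outer(ii, (jj - 1) * d[1], "+"),
                       (kk - 1) * d[1] * d[2], "+"))
    },
    sphere = {
      ii <- max(1, floor(roi$center[1] - roi$radius)):
            min(d[1], ceiling(roi$center[1] + roi$radius))
      jj <- max(1, floor(roi$center[2] - roi$radius)):
            min(d[2], ceiling(roi$center[2] + roi$radius))
      kk <- max(1, floor(roi$center[3] - roi$radius)):
            min(d[3], ceiling(roi$center[3] + roi$radius))
      g <- expand.grid(i = ii, j = jj, k = kk)
      keep <- (g$i - roi$center[1])^2 + (g$j - roi$center[2])^2 +
        (g$k - roi$center[3])^2 <= roi$radius^2
      g <- g[keep, ]
      as.integer(g$i + (g$j - 1) * d[1] + (g$k - 1) * d[1] * d[2])
    },
    mask = {
      if (!identical(dim(roi$mask), d)) stop("ROI mask shape mismatch")
      which(roi$mask)
    },
    stop("unknown ROI type"))
}

#' Values of a volume within an ROI
#'
#' @param volume a \code{CTVolume}.
#' @param roi an ROI descriptor.
#' @return numeric vector.
#' @export
roiValues <- function(volume, roi) {
  volume@values[roiIndices(roi, volume)]
}
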