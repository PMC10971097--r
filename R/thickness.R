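## Local thickness by the maximum inscribed sphere method
## (Hildebrand-Ruegsegger): per foreground voxel, the diameter of the
## largest sphere that contains the voxel and fits inside the structure.

#' Euclidean distance transform of a mask
#'
#' Exact distance (in mm) from each foreground voxel to the nearest
#' background voxel center, by the separable lower-envelope algorithm.
#'
#' @param mask a mask \code{CTVolume} or logical array.
#' @param spacing voxel size in mm (taken from the volume if available).
#' @return a \code{CTVolume} in mm.
#' @export
distanceTransform <- function(mask, spacing = NULL) {
  if (is(mask, "CTVolume")) {
    if (is.null(spacing)) spacing <- mask@spacing
    mask <- mask@values > 0
  }
  if (is.null(spacing)) spacing <- 1
  d <- dim(mask)
  dt <- sqrt(cpp_edt_sq(as.logical(mask), as.integer(d))) * spacing
  new("CTVolume", values = array(dt, dim = d), spacing = spacing,
      units = "mm", provenance = "distance transform")
}

#' Local thickness map (maximum inscribed sphere)
#'
#' For every foreground voxel, the diameter of the largest inscribed
#' sphere containing it: computed from the distance transform followed
#' by sphere-coverage maximization.  Distances to background voxel
#' centers overestimate the inscribed radius by about half a voxel, so
#' the standard half-voxel correction is applied before painting; map
#' values are floored at one voxel spacing inside the mask.
#'
#' @param mask a mask \code{CTVolume} or logical array.
#' @param spacing voxel size in mm (taken from the volume if available).
#' @return a \code{CTVolume} in mm, nonzero only inside the mask.
#' @export
localThickness <- function(mask, spacing = NULL) {
  if (is(mask, "CTVolume")) {
    if (is.null(spacing)) spacing <- mask@spacing
    mask <- mask@values > 0
  }
  if (is.null(spacing)) spacing <- 1
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  r_vox <- sqrt(cpp_edt_sq(as.logical(mask), as.integer(d))) - 0.5
  r_vox[r_vox < 0.5 & as.logical(mask)] <- 0.5
  r_vox[!mask] <- 0
  lt <- cpp_local_thickness(as.numeric(r_vox), as.logical(mask),
                            as.integer(d))
  lt <- pmax(array(lt, dim = d), mask * 1) * spacing
  new("CTVolume", values = lt, spacing = spacing, units = "mm",
      provenance = "local thickness (maximum inscribed sphere)")
}

#' Per-segment diameter summary of a vessel phantom
#'
#' Evaluates the local-thickness map along each ground-truth centerline
#' segment: the quantitative per-vessel report (id, true and measured
#' mean/max diameter, length).
#'
#' @param thicknessMap a \code{CTVolume} from \code{\link{localThickness}}.
#' @param segments ground-truth segment data.frame.
#' @return data.frame, one row per segment.
#' @export
vesselSummary <- function(thicknessMap, segments) {
  d <- dim(thicknessMap@values)
  cl <- centerlineVoxels(segments, d, thicknessMap@spacing)
  vals <- thicknessMap@values[cbind(cl$i, cl$j, cl$k)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(cl)), cl$id),
    function(ii) {
      v <- vals[ii]
      v <- v[v > 0]
      id <- cl$id[ii[1]]
      s <- segments[segments$id == id, ]
      data.frame(id = id, true_diameter = s$diameter,
                 length = sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 +
                                 (s$z1 - s$z0)^2),
                 mean_diameter = if (length(v)) mean(v) else NA_real_,
                 max_diameter = if (length(v)) max(v) else NA_real_)
    }))
  rownames(out) <- NULL
  out
}
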