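## Volume I/O: MHD/RAW (canonical), TIFF stacks, NIfTI.  Isotropic
## spacing only; 16-bit gray versus 1/cm inferred from the stored
## element type or supplied explicitly.

.mhdTypeMap <- c(MET_FLOAT = "float", MET_DOUBLE = "double",
                 MET_USHORT = "ushort", MET_UCHAR = "uchar")

#' Write a volume to disk
#'
#' Formats by extension: \code{.mhd} (MetaImage header + .raw, the
#' canonical format), \code{.tif}/\code{.tiff} (multi-page 32-bit float
#' TIFF stack), \code{.nii}/\code{.nii.gz} (NIfTI).  gray16 volumes are
#' stored as unsigned 16-bit where the format allows, masks as 8-bit.
#'
#' @param volume a \code{CTVolume}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  d <- dim(volume@values)
  if (ext == "mhd") {
    rawpath <- sub("\\.mhd$", ".raw", path)
    type <- switch(volume@units, gray16 = "MET_USHORT",
                   mask = "MET_UCHAR", label = "MET_USHORT", "MET_DOUBLE")
    writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
                 "BinaryDataByteOrderMSB = False",
                 sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
                 sprintf("ElementSpacing = %.6g %.6g %.6g",
                         volume@spacing, volume@spacing, volume@spacing),
                 sprintf("ElementType = %s", type),
                 sprintf("Units = %s", volume@units),
                 sprintf("ElementDataFile = %s", basename(rawpath))), path)
    con <- file(rawpath, "wb")
    on.exit(close(con))
    if (type == "MET_DOUBLE")
      writeBin(as.numeric(volume@values), con, size = 8)
    else if (type == "MET_UCHAR")
      writeBin(as.integer(volume@values), con, size = 1)
    else
      writeBin(as.integer(volume@values), con, size = 2)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(d[3]), function(z)
      volume@values[, , z] / (if (volume@units == "gray16") 65535 else 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(volume@values)
    RNifti::pixdim(img) <- rep(volume@spacing, 3)
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' Read a volume from disk
#'
#' @param path input path (.mhd, .tif/.tiff, .nii/.nii.gz).
#' @param spacing voxel size in mm; required when the file carries none,
#'   overrides it otherwise.  Anisotropic files are rejected.
#' @param units value units (\code{"attenuation"}, \code{"gray16"}, ...);
#'   inferred from the file where possible.
#' @return a \code{CTVolume}.
#' @export
readVolume <- function(path, spacing = NULL, units = NULL) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "mhd") {
    hdr <- readLines(path)
    getf <- function(key) {
      h <- grep(paste0("^", key, " *="), hdr, value = TRUE)
      if (!length(h)) return(NULL)
      trimws(sub("^[^=]*=", "", h[1]))
    }
    d <- as.integer(strsplit(getf("DimSize"), "\\s+")[[1]])
    sp <- as.numeric(strsplit(getf("ElementSpacing"), "\\s+")[[1]])
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic spacing in header; only isotropic volumes are ",
           "supported")
    type <- getf("ElementType")
    funits <- getf("Units")
    rawpath <- file.path(dirname(path), getf("ElementDataFile"))
    con <- file(rawpath, "rb")
    on.exit(close(con))
    n <- prod(d)
    vals <- switch(type,
      MET_FLOAT = readBin(con, numeric(), n, size = 4),
      MET_DOUBLE = readBin(con, numeric(), n, size = 8),
      MET_USHORT = readBin(con, integer(), n, size = 2, signed = FALSE),
      MET_UCHAR = readBin(con, integer(), n, size = 1, signed = FALSE),
      stop("unsupported ElementType ", type))
    if (is.null(units))
      units <- if (!is.null(funits)) funits
               else if (type == "MET_USHORT") "gray16" else "attenuation"
    if (is.null(spacing)) spacing <- sp[1]
    new("CTVolume", values = array(as.numeric(vals), dim = d),
        spacing = spacing, units = units,
        provenance = paste("read", basename(path)))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.null(spacing))
      stop("TIFF stacks carry no voxel size; supply spacing explicitly ",
           "(e.g. --spacing)")
    vals <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
    for (z in seq_along(pages)) vals[, , z] <- pages[[z]]
    if (is.null(units)) units <- "attenuation"
    if (units == "gray16") vals <- vals * 65535
    new("CTVolume", values = vals, spacing = spacing, units = units,
        provenance = paste("read", basename(path)))
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-9 * max(pd))
      stop("anisotropic spacing in header; only isotropic volumes are ",
           "supported")
    if (is.null(spacing)) spacing <- pd[1]
    if (is.null(spacing) || !is.finite(spacing) || spacing <= 0)
      stop("no usable spacing in NIfTI header; supply spacing explicitly")
    if (is.null(units)) units <- "attenuation"
    new("CTVolume", values = array(as.numeric(img), dim = dim(img)),
        spacing = spacing, units = units,
        provenance = paste("read", basename(path)))
  } else stop("unsupported volume format: .", ext)
}
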