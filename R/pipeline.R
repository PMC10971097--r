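## End-to-end pipeline: phantom -> LE/HE simulated scans -> FBP ->
## decomposition -> virtual mono image -> metrics -> segmentation ->
## local thickness, with a provenance record that fully reproduces the
## run.

#' Default pipeline configuration
#'
#' @return a nested list with all tunable parameters at their defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    phantom = list(preset = "eppendorf", spacing = 0.107,
                   containerDiameter = 24, tubeDiameter = 8,
                   boneSize = 3, nz = 24, depth = 4,
                   rootDiameter = 1.2, minDiameter = 0.35),
    scan = list(preset = "phantom-2h"),
    basisMaterials = c("adipose", "bone_cortical", "micropaque_1to5"),
    decomposition = list(basis = "spectral", clip = "raw",
                         monoKeV = 37.5),
    metrics = list(bins = 256, erodeVoxels = 3),
    segmentation = list(thick = 10000, thin = 6700, k = 2.5, r = 3,
                        mapThreshold = 0.18, grayScale = 1e4)
  )
}

#' Read and validate a pipeline configuration
#'
#' Unknown top-level keys are rejected; missing keys take defaults.
#'
#' @param path JSON file, or a list to validate in place.
#' @return the completed configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else path
  def <- defaultPipelineConfig()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in names(def)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
    else if (is.list(def[[k]])) {
      for (k2 in names(def[[k]]))
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- def[[k]][[k2]]
    }
  }
  cfg
}

#' Stable hash of a configuration
#'
#' Polynomial rolling hash (base 257 modulo the Mersenne prime 2^31-1)
#' over the configuration's canonical JSON; used in provenance records.
#'
#' @param config a configuration list.
#' @return hex string.
#' @export
configHash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

.erodedMaskROI <- function(mask, margin, label = "") {
  d <- dim(mask)
  dt <- sqrt(cpp_edt_sq(as.logical(mask), as.integer(d)))
  roiFromMask(array(dt > margin, dim = d), label = label)
}

.phantomFromConfig <- function(cfg) {
  p <- cfg$phantom
  spec <- switch(p$preset,
    eppendorf = eppendorfPhantom(spacing = p$spacing,
                                 containerDiameter = p$containerDiameter,
                                 tubeDiameter = p$tubeDiameter,
                                 boneSize = p$boneSize, nz = p$nz),
    "vessel-tree" = vesselTreePhantom(seed = cfg$seed, spacing = p$spacing,
                                      depth = p$depth,
                                      rootDiameter = p$rootDiameter,
                                      minDiameter = p$minDiameter),
    resolution = resolutionPhantom(spacing = p$spacing),
    stop("unknown phantom preset '", p$preset, "'"))
  buildPhantom(spec, supersample = if (p$preset == "eppendorf") 1L else 2L)
}

#' Run the full dual-energy pipeline
#'
#' Executes every stage on a simulated phantom and writes all artifacts
#' (volumes as MHD/RAW, metrics and provenance as JSON, masks, local
#' thickness map) into \code{outdir}.  Deterministic under a fixed
#' configuration seed.
#'
#' @param config configuration list or JSON path (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param outdir output directory (created if needed).
#' @param verbose print one line per stage.
#' @return invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outdir = tempfile("dectrun"), verbose = TRUE) {
  cfg <- readPipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  phantom <- stage("phantom", .phantomFromConfig(cfg))
  say("phantom", "%s %s voxels @ %.3g mm", cfg$phantom$preset,
      paste(dim(phantom$labels@values), collapse = "x"),
      phantom$labels@spacing)

  le <- defaultSpectrum("LE"); he <- defaultSpectrum("HE")
  preset <- scanPreset(cfg$scan$preset)
  scans <- stage("scan",
    simulateDectScan(phantom, le, he, nAngles = preset$nAngles,
                     n0le = preset$n0le, n0he = preset$n0he,
                     seed = cfg$seed))
  say("scan", "preset %s, %d angles, n0 LE %.3g / HE %.3g",
      preset$name, preset$nAngles, preset$n0le, preset$n0he)

  dimxy <- dim(phantom$labels@values)[1:2]
  muLE <- stage("fbp", fbpReconstruct(scans$le, dim = dimxy))
  muHE <- stage("fbp", fbpReconstruct(scans$he, dim = dimxy))
  say("fbp", "reconstructed %s", paste(dim(muLE@values), collapse = "x"))

  mats <- cfg$basisMaterials
  margin <- cfg$metrics$erodeVoxels
  rois <- lapply(mats, function(m)
    .erodedMaskROI(materialMask(phantom, m), margin, label = m))
  names(rois) <- mats
  basis <- stage("basis", {
    if (cfg$decomposition$basis == "roi")
      calibrateBasis(muLE, muHE, rois, mats)
    else computeBasis(mats, le, he)
  })
  say("basis", "%s, condition number %.3g", basis@source,
      basis@conditionNumber)

  maps <- stage("decompose",
    materialDecompose(muLE, muHE, basis,
                      clipPolicy = cfg$decomposition$clip))
  mono <- stage("mono", synthesizeMono(maps, E = cfg$decomposition$monoKeV))
  say("mono", "synthesized at %.4g keV", cfg$decomposition$monoKeV)

  # metrics: contrast agent vs tissue and vs bone under LE, HE, mono
  contrastName <- mats[3]; tissueName <- mats[1]; boneName <- mats[2]
  vols <- list(LE = muLE, HE = muHE, mono = mono)
  metrics <- list()
  for (v in names(vols)) {
    for (other in c(tissueName, boneName)) {
      pair <- sprintf("%s-vs-%s", contrastName, other)
      a <- roiValues(vols[[v]], rois[[contrastName]])
      b <- roiValues(vols[[v]], rois[[other]])
      metrics[[pair]][[v]] <- list(
        CNR = cnr(vols[[v]], rois[[contrastName]], rois[[other]]),
        gCNR = gcnr(vols[[v]], rois[[contrastName]], rois[[other]],
                    bins = cfg$metrics$bins),
        mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
        n_voxels = c(length(a), length(b)))
    }
  }
  say("metrics", "computed for %d pairs x 3 volumes", 2L)

  seg <- cfg$segmentation
  gray <- attenuationToGray16(mono, scale = seg$grayScale)
  results <- list(phantom = phantom, muLE = muLE, muHE = muHE,
                  basis = basis, maps = maps, mono = mono,
                  metrics = metrics)
  if (any(phantom$materials == boneName) &&
      sum(materialMask(phantom, boneName)) > 0) {
    bm <- materialMask(phantom, boneName)
    ctr <- round(colMeans(which(bm, arr.ind = TRUE)))
    masks <- stage("segment",
      vesselPipeline(gray, matrix(ctr, nrow = 1), thick = seg$thick,
                     thin = seg$thin, k = seg$k, r = seg$r))
    mapMask <- stage("segment",
      mapSegmentation(maps, component = 3, threshold = seg$mapThreshold))
    thick <- stage("thickness", {
      if (sum(masks$vessels@values) > 0) localThickness(masks$vessels)
      else NULL
    })
    say("segment", "vessel mask %d voxels, bone mask %d voxels",
        sum(masks$vessels@values), sum(masks$bone@values))
    results$masks <- masks
    results$mapMask <- mapMask
    results$thickness <- thick
    writeVolume(masks$vessels, file.path(outdir, "vessels.mhd"))
    writeVolume(masks$bone, file.path(outdir, "bone.mhd"))
    writeVolume(mapMask, file.path(outdir, "map_mask.mhd"))
    if (!is.null(thick))
      writeVolume(thick, file.path(outdir, "thickness.mhd"))
  }

  writeVolume(muLE, file.path(outdir, "mu_le.mhd"))
  writeVolume(muHE, file.path(outdir, "mu_he.mhd"))
  writeVolume(mono, file.path(outdir, "mono.mhd"))
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(config = cfg, hash = configHash(cfg),
         package = as.character(utils::packageVersion("dectangio")),
         basis = list(A = basis@A, source = basis@source,
                      conditionNumber = basis@conditionNumber)),
    file.path(outdir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "artifacts in %s", outdir)
  invisible(results)
}
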