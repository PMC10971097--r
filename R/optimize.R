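## Spectral-pair optimization: rank candidate LE/HE acquisition settings
## by the predicted contrast-to-noise ratio of the virtual monochromatic
## image at the target energy.

#' Rank candidate LE/HE spectral pairs
#'
#' For every ordered pair of candidate settings with LE kVp strictly
#' below HE kVp, the objective is the predicted mono-image CNR for the
#' contrast-versus-tissue pair at energy E: the monochromatic contrast
#' divided by the analytically propagated mono noise.  Per-image noise
#' follows a stated photon-budget model: the total exposure time is
#' split equally between the two scans, the relative detected fluence of
#' a candidate is its relative tube output (Kramers area after
#' filtration) times the weighted transmission through a water-equivalent
#' background slab, and sigma is proportional to
#' \code{1 / sqrt(detected fluence)}.  Ties are broken by lower noise
#' amplification.
#'
#' @param kvps candidate tube voltages (kV), constrained to the 40-80 kV
#'   tube range.
#' @param filters list of candidate filter settings; each element is a
#'   list of \code{list(material, mm)} filters (use \code{list()} for
#'   none).  Default: the scanner's three filter options.
#' @param contrast,tissue,bone the three basis materials (the objective
#'   pair is contrast vs tissue).
#' @param E mono energy in keV.
#' @param backgroundMaterial,backgroundMM water-equivalent object slab
#'   used in the exposure model.
#' @param totalBudget relative total photon budget (scales all sigmas;
#'   ranking-invariant).
#' @return data.frame of candidates sorted by decreasing objective, with
#'   the spectral settings, objective value and noise amplification.
#' @export
optimizeSpectralPair <- function(kvps = seq(40, 80, by = 5),
                                 filters = list(
                                   none = list(),
                                   al05 = list(list("aluminum", 0.5)),
                                   cu035 = list(list("copper", 0.35))),
                                 contrast = "micropaque_1to5",
                                 tissue = "soft_tissue",
                                 bone = "bone_cortical",
                                 E = 37.5,
                                 backgroundMaterial = "water",
                                 backgroundMM = 20,
                                 totalBudget = 1e6) {
  if (any(kvps < 40 | kvps > 80))
    stop("candidate kvp outside the 40-80 kV tube range")
  if (!length(kvps) || !length(filters)) stop("empty candidate grid")
  fnames <- names(filters)
  if (is.null(fnames)) fnames <- paste0("f", seq_along(filters))
  cand <- expand.grid(kvp = kvps, filter = fnames,
                      stringsAsFactors = FALSE)
  specs <- vector("list", nrow(cand))
  sig <- numeric(nrow(cand))
  bg <- bundledMaterial(backgroundMaterial)
  for (i in seq_len(nrow(cand))) {
    sp <- generateSpectrum(cand$kvp[i], filters[[cand$filter[i]]])
    specs[[i]] <- sp
    tr <- exp(-massAttenuation(bg, sp@energy) * bg@density *
                backgroundMM / 10)
    detected <- sp@output * sum(sp@fluence * tr)
    sig[i] <- 1 / sqrt(0.5 * totalBudget * detected)
  }
  muA <- effectiveLinearAttenuation(contrast, E)
  muB <- effectiveLinearAttenuation(tissue, E)
  mats <- lapply(c(tissue, bone, contrast), bundledMaterial)
  rows <- list()
  for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(cand))) {
    if (cand$kvp[i] >= cand$kvp[j]) next     # LE kvp strictly below HE
    basis <- tryCatch(
      computeBasis(mats, le = specs[[i]], he = specs[[j]]),
      error = function(e) NULL)
    if (is.null(basis)) next
    np <- noisePropagation(basis, sig[i], sig[j], E = E)
    rows[[length(rows) + 1]] <- data.frame(
      le_kvp = cand$kvp[i], le_filter = cand$filter[i],
      he_kvp = cand$kvp[j], he_filter = cand$filter[j],
      objective = abs(muA - muB) / np$sigma,
      amplification = np$amplification)
  }
  if (!length(rows)) stop("no admissible candidate pair")
  out <- do.call(rbind, rows)
  out <- out[order(-out$objective, out$amplification), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
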