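# dectangio

Dual-energy micro-CT angiography toolkit: three-material decomposition,
virtual monoenergetic imaging at the barium K-edge, and vessel
quantification, with a full polychromatic scan simulator.

## The problem

Post-mortem CT angiography of small specimens fills the vasculature
with a BaSO₄ suspension (Micropaque 1:5, ~0.2 g/mL) and scans at
35–210 µm voxels. A single polychromatic scan cannot cleanly separate
contrast-filled vessels from bone. Dual-energy CT can: one scan with a
low-energy spectrum (45 kVp + 0.5 mm Al) weighted below the barium
K-edge (37.4 keV) and one with a high-energy spectrum
(70 kVp + 0.35 mm Cu) weighted above it.

Each voxel is modeled as a mixture of three basis materials
(soft tissue, bone, contrast agent) with volume fractions `V_i`:

    mu_LE = sum_i a_i^LE V_i
    mu_HE = sum_i a_i^HE V_i
    V_1 + V_2 + V_3 = 1

where `a_i^S` is the effective linear attenuation of material `i` under
spectrum `S`. The exact per-voxel 3×3 solve yields concentration maps,
from which a virtual monochromatic image at any energy `E` follows as
`mu(E) = sum_i (mu/rho)_i(E) rho_i V_i` — by default at 37.5 keV, just
above the K-edge, where the contrast agent's attenuation jumps by a
factor > 4 and the contrast over soft tissue is enhanced roughly
threefold relative to the HE image.

The package covers the whole chain: bundled X-ray attenuation tables
(1–150 keV, edge-resolved), filtered Kramers tube spectra, digital
phantoms (contrast tube, branching vessel trees, sub-millimeter
resolution targets) with ground truth, polychromatic projection
simulation and filtered back-projection, the decomposition and mono
synthesis, CNR/gCNR image-quality metrics with analytic noise
propagation, spectral-pair optimization, the four-step vessel
segmentation recipe (thresholds, seeded region growing with local
dynamic tolerance, bone subtraction, concentration-map segmentation),
and maximum-inscribed-sphere local diameter maps.

## Worked example

Simulate the three-material validation phantom (lard cylinder, tube of
diluted contrast agent, bone block) at the long-exposure preset,
decompose, and synthesize the 37.5 keV mono image:

```r
library(dectangio)

spec <- eppendorfPhantom(spacing = 0.107, containerDiameter = 24,
                         tubeDiameter = 8, boneSize = 3, nz = 24)
ph   <- buildPhantom(spec)
pre  <- scanPreset("phantom-2h")
scans <- simulateDectScan(ph, nAngles = pre$nAngles,
                          n0le = pre$n0le, n0he = pre$n0he, seed = 42)
muLE <- fbpReconstruct(scans$le, dim = dim(ph$labels@values)[1:2])
muHE <- fbpReconstruct(scans$he, dim = dim(ph$labels@values)[1:2])

basis <- computeBasis(c("adipose", "bone_cortical", "micropaque_1to5"))
maps  <- materialDecompose(muLE, muHE, basis)
mono  <- synthesizeMono(maps, E = 37.5)

cef <- contrastEnhancementFactor("micropaque_1to5", "adipose")
roi <- roiBox(c(40, 40, 5), c(71, 71, 20))          # uniform lard block
ratio <- sd(roiValues(mono, roi)) / sd(roiValues(muHE, roi))
cat(sprintf("contrast enhancement factor: %.3f\n", cef))
cat(sprintf("mono/HE noise ratio: %.3f (analytic %.3f)\n", ratio,
            noisePropagation(basis, sd(roiValues(muLE, roi)),
                             sd(roiValues(muHE, roi)))$amplification))
```

```
contrast enhancement factor: 2.455
mono/HE noise ratio: 2.650 (analytic 2.775)
```

The enhancement factor says the mono image carries ~2.5× the
contrast-agent-vs-lard contrast of the HE image (reported as "around
3.0" for the physical system; the difference is spectrum-model
tolerance), while its noise grows by less than 3× — the margin that
makes the dual-energy detour worthwhile. The measured noise ratio
sits ~4% below the analytic affine propagation because correlated
beam-hardening structure partially cancels in the synthesis.

Downstream, `vesselPipeline()` applies the four-step segmentation to
the 16-bit mono image (thresholds 10,000 / 6,700 at the default
gray = μ·10⁴ calibration, bone via seeded region growing),
`mapSegmentation()` thresholds the contrast concentration map at 18%,
and `localThickness()` maps local vessel diameters;
`runPipeline()` chains every stage and writes volumes, masks, metrics
and a provenance record to a directory. A thin command-line front end
lives at `inst/cli/dect-angio.R`.

See the vignette (`vignettes/dual-energy-microct-angiography.Rmd`) for
the models, parameter defaults, and the design decisions behind the
simulator and presets.

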