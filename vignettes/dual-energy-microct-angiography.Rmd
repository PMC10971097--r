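---
title: "Dual-energy micro-CT angiography: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy micro-CT angiography: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Post-mortem micro-CT angiography fills the vasculature of a small
specimen (here, piglet-scale bodies) with a barium sulfate suspension
(Micropaque diluted 1:5, nominally 0.2 g/mL BaSO~4~) and images it at
voxel sizes of 35-210 µm.  A single polychromatic scan confounds the
contrast agent with bone.  Dual-energy CT (DECT) separates them: two
sequential scans with a low-energy (LE) spectrum weighted below the
barium K edge (37.4 keV) and a high-energy (HE) spectrum weighted above
it allow a per-voxel three-material decomposition and the synthesis of a
virtual monochromatic image just above the edge, where the contrast
agent's photoelectric cross-section is maximal.

`dectangio` implements this workflow end to end, together with a
polychromatic scan simulator so that every stage can be exercised and
validated without any scanner data.

# The decomposition model

Each reconstructed voxel is modeled as a volume-fraction mixture of
three basis materials (soft tissue or lard, bone, contrast agent):

$$\mu_{LE} = \sum_{i=1}^{3} a_i^{LE} V_i,\qquad
  \mu_{HE} = \sum_{i=1}^{3} a_i^{HE} V_i,\qquad
  \sum_{i=1}^{3} V_i = 1,$$

where $a_i^S = (\mu/\rho)_i^S\,\rho_i$ is the effective linear
attenuation of basis material $i$ under spectrum $S$.  The 3×3 system is
solved exactly per voxel (`materialDecompose`); no regularization is
applied.  From the fraction maps a virtual monochromatic image at any
energy follows as

$$\mu(E) = \sum_i (\mu/\rho)_i(E)\,\rho_i\,V_i ,$$

with the default $E = 37.5$ keV, just above the barium K edge.  The
composite map decompose-then-synthesize is **affine** in
$(\mu_{LE}, \mu_{HE})$; `monoCoefficients` exposes the coefficients
$(c_{LE}, c_{HE}, c_0)$, which drive the analytic noise propagation
$\sigma_{mono} = \sqrt{c_{LE}^2 \sigma_{LE}^2 + c_{HE}^2 \sigma_{HE}^2}$
(`noisePropagation`; the two scans are sequential, so their counting
noise is independent).

Two clip policies are offered for the fraction maps: `"raw"` (default
for synthesis; fractions sum to one exactly by construction but may
leave [0, 1] under noise, preserving the affine noise statistics) and
`"renormalize"` (clipped to the simplex; used for visualization and
map-based segmentation).

# Attenuation data

The bundled per-material tables (`inst/extdata/materials/`, one
plain-text file per material, 1-150 keV at ≤ 0.5 keV steps with
duplicated grid energies at absorption edges) were generated once by
`tools/make_attenuation_tables.R` from a parameterized photon
cross-section model calibrated against standard tabulations: tabulated
anchors with log-log interpolation for the light and mid-Z elements, and
for I, Cs, Ba, W a piecewise power-law photoelectric term anchored at
the iodine K edge (6.553 → 35.82 cm²/g at 33.169 keV) plus a
Klein-Nishina incoherent term with a simple binding correction and an
approximate coherent term.  Intended accuracy is a few percent over
15-80 keV — the band every bundled default uses; below ~8 keV the curves
locate edges correctly but are only qualitative, which is immaterial
because all bundled spectra are filtered.  Interpolation is log-log
(standard for photon cross sections); at an edge energy the above-edge
branch applies.

The 1:5 Micropaque dilution is modeled as 0.2 g/mL BaSO~4~ suspended in
water (density 1.156 g/cm³, BaSO~4~ mass fraction 0.173), from the
nominal 1 g/mL product concentration; excipients are not modeled.  The
"trabecular bone" material is a **synthetic juvenile surrogate** (55%
cortical-bone material, 45% soft tissue by mass, density 1.5 g/cm³)
representing the partially mineralized temporal bone of a piglet; it is
used by the vessel-tree phantom so that bone falls between the two
published segmentation thresholds, as it does in the real data.

# Spectrum model

`generateSpectrum` uses the simplified Kramers rule (photon fluence
proportional to kvp − E) with optional tungsten K lines whose intensity
scales as $(kvp/69.525-1)^{1.65}$ — numerically negligible at 70 kVp,
so both bundled settings are effectively line-free — followed by
Beer-Lambert filtration.  The bundled settings are the study protocol:
LE = 45 kVp + 0.5 mm Al, HE = 70 kVp + 0.35 mm Cu.  Detector weighting
defaults to energy-integrating (CsI/CMOS flat panel); photon-counting
weighting is available.  The grid step defaults to 0.5 keV, which
resolves the 37.4 keV edge.

All spectrum-dependent quantities inherit this declared model.  The
analytic contrast enhancement factor of the mono image over the HE
image for contrast-vs-lard computes to ≈ 2.46 here, against "around
3.0" reported from the real system; the difference is within the
spectrum-model tolerance (the real tube emission, inherent filtration
and detector response are unpublished).

# The scan simulator

Scans are slice-wise parallel-beam (the vendor's cone-beam FDK is out
of scope; parallel geometry preserves the beam-hardening and noise
phenomenology).  The projector is pixel-driven with an **exact
trapezoidal footprint** (distance-driven): the projection of each
square pixel is integrated analytically over every detector bin, so
projections are exact for the pixelized phantom at every angle.
Detected signal per ray is
$S = \sum_E w_E\, n_E$, $n_E \sim \text{Poisson}(N_0\,\phi_E e^{-\int\mu_E dl})$
with $w_E = E$ for energy-integrating detection; the simulator draws
$S$ from a Gaussian with the exact compound-Poisson mean and variance
(an excellent approximation at all bundled budgets) and floors starved
rays at one detected count (counted and reported as `flagged`).
Reconstruction is Ram-Lak filtered back-projection per slice.

Phantoms are specified as ordered geometric primitives; later
primitives overwrite earlier ones; voxels are center-sampled, with
optional supersampled occupancy fractions (used for all sub-voxel
vessel studies: attenuation is then volume-fraction mixed, the honest
partial-volume model).  Ground truth (per-material majority and
occupancy masks, vessel centerlines and diameters) is emitted with
every phantom.

# Exposure presets and what the simulation does and does not reproduce

Absolute exposure of the physical scanner is unknowable, so scan
presets fix the expected blank counts per detector ray, calibrated once
and frozen:

* `"phantom-2h"`: $N_0^{LE} = 2\times10^5$, $N_0^{HE} = 8\times10^5$,
  180 angles — the long-protocol surrogate, paired with the desk-scale
  contrast-tube phantom (24 mm lard cylinder, 8 mm tube of 1:5
  Micropaque, 3 mm cortical bone block, 24 slices at 107 µm).
* `"short-15min"`: one eighth of that exposure.
* `"piglet-1h"`: the vessel-imaging protocol used with the vessel-tree
  phantom.

A structural point the simulation reproduces — and which explains the
published observations: with *independent counting noise alone* the
mono image can never beat the HE image on contrast-vs-fat CNR, because
the synthesis amplifies noise by $|c_{HE}| \approx 2.8$ while enhancing
that contrast by ≈ 2.5.  The real advantage comes from **correlated
structured noise**: beam-hardening cupping and streaks appear in both
input images and partially cancel in the affine synthesis, while
Poisson noise adds in quadrature.  Consequently the mono ≥ HE ≥ LE
ordering emerges at long exposures (structure-dominated) and flips at
short ones (Poisson-dominated) — exactly the reported 2 h versus 15 min
behaviour, and the `"phantom-2h"` calibration point sits in the regime
where the ordering holds while the lard-region noise still follows the
analytic affine propagation to within 5%.

What passing these tests does **not** show about real data: absolute
CNR magnitudes.  The simulator has no scatter, detector electronics
noise, ring artifacts, focal-spot blur or motion, so its CNRs at
matched geometry are an order of magnitude above the published
phantom values; the reproducible content is the ordering, the gCNR
saturation regime, the noise-amplification bound and the energy
dependence (the 30-50 keV sweep of mono CNR peaks exactly at 37.5 keV,
discontinuously above the K edge).

# Segmentation

The four-step recipe operates on the 16-bit mono image (gray =
μ[1/cm] × 10⁴ by default, so the published thresholds 10,000 / 6,700
correspond to 1.0 / 0.67 cm⁻¹; the scale is a configuration knob since
the scanner's native calibration is unpublished): threshold at the
thick-vessel level; seeded region growing for bone; threshold at the
thin-vessel level; bone subtraction.  "Local dynamic tolerance" is not
defined in the source material; the adopted rule accepts a frontier
voxel when its value lies within $k\,s_{loc}$ (default $k = 2.5$) of
the mean of already-accepted voxels within radius $r = 3$, with the
seed-neighbourhood spread as the starting scale — the rule is isolated
in `seededRegionGrowing` so alternatives can be swapped.  Growth and
connectivity are 26-connected and the visit order is fixed, so masks
are deterministic.

Two deliberate refinements, both visible in the function signatures:
the subtracted bone region is dilated by one voxel (the bone's
partial-volume halo exceeds the thin threshold and would otherwise
survive as false vessels), and Dice-based validation of sub-voxel
structures uses the *occupancy* ground truth (any voxel containing
vessel), since the published thresholds sit deep in the partial-volume
shell by design.

Local vessel diameters use the maximum-inscribed-sphere definition
(Hildebrand-Rüegsegger): exact Euclidean distance transform, a
half-voxel correction of distances-to-background-centers, then
sphere-coverage maximization in decreasing radius order.  On digital
cylinders and spheres this recovers diameters to within a voxel; on the
simulated vessel tree, mean per-segment diameters land within ~5% of
ground truth.

# Spectral-pair optimization

`optimizeSpectralPair` scores every admissible LE/HE candidate pair
(40-80 kVp, the scanner's three filter options) by predicted mono-image
CNR: monochromatic contrast at the target energy divided by the
analytically propagated noise, with per-candidate σ from a declared
photon-budget model (equal exposure split, relative tube output after
filtration, transmission through a water-equivalent slab,
$\sigma \propto 1/\sqrt{\text{detected fluence}}$); ties break toward
lower noise amplification.  The model is a declared reconstruction —
the original optimization procedure is not available — and a pure
Poisson objective has no penalty for beam hardening, so unfiltered
high-kVp pairs score best on raw flux; the published pair ranks in the
upper quarter of the grid, carries a noise amplification below the
factor-3 contrast gain, and copper HE prefiltration dominates among
pairs at the published tube voltages.  Those are the properties the
package asserts.

# Numerical choices and degenerate inputs

* Basis systems with condition number above 10⁴ are rejected, naming
  the most collinear material pair.
* Renormalized fraction maps clip to [0, 1]; fully clipped voxels stay
  zero rather than being renormalized from nothing.
* Log-normalized rays are floored at one detected count (flagged), so
  starved projections stay finite.
* ROI calibration requires three pairwise-disjoint ROIs of ≥ 27 voxels.
* Volumes are isotropic by contract; anisotropic headers are rejected
  at I/O, and gray16 ↔ 1/cm conversions are explicit.
* All randomness flows through explicit integer seeds; identical seeds
  give bit-identical phantoms, sinograms and masks.

# Problem sizes

The bundled studies run at sizes chosen for desk-scale reproducibility:
the contrast-tube scans at 232 × 232 × 24 voxels (107 µm), the
vessel-tree study at 249 × 249 × 113, the resolution study at
132 × 132 × 32, each with 180 projection angles.  The full-size 50 mm
phantom remains available through `eppendorfPhantom()` defaults.

# Known limitations

* The spectrum model is the simplified Kramers form; effective-spectrum
  quantities carry its ~±20% model uncertainty.
* No scatter, detector blur/electronics noise, cone-beam geometry, or
  motion; absolute CNRs are therefore optimistic (see above).
* The three-material model assumes the specimen contains nothing else;
  real specimens violate this mildly (air pockets, marrow), which
  appears as out-of-range raw fractions (`outOfRangeFraction`).
* Attenuation tables are a calibrated parameterization, not a certified
  database; below 8 keV they are qualitative.
* The heaviest-constituent K edge is reported by `kedge` as the highest
  tabulated edge, which is correct for all bundled materials but would
  need care for exotic mixtures of two high-Z elements.
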