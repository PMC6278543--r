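---
title: "Spheroid morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spheroid morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromorph)
```

`spheromorph` measures multicellular tumor spheroids (MCTS) in
brightfield/H&E micrographs: one spheroid per image, three descriptors —
size, roundness, solidity — and, across imaging days, a percent-variation
growth statistic. This vignette documents the model underlying each
stage, the parameters that matter, the numerical conventions, and the
limits of what the synthetic test bed can show.

## Stain model and unmixing

Brightfield staining is multiplicative: each stain attenuates transmitted
light exponentially in its local concentration (Beer–Lambert), so in
optical density, OD = −log₁₀(I/I₀), co-localized stains are *additive*.
Per pixel we form

$$\mathrm{od}_c = -\log_{10}\!\frac{I_c + 1}{i_0 + 1}, \qquad c \in \{R,G,B\},\; i_0 = 255,$$

and solve the linear system $\mathrm{od} = \mathbf{c}\,M$ for the stain
concentrations $\mathbf{c}$, where the rows of $M$ are unit-norm OD
vectors for hematoxylin, eosin, and a residual completing the basis (the
normalized cross product of the first two). The defaults are the standard
published H&E calibration — hematoxylin (0.644, 0.717, 0.267), eosin
(0.093, 0.954, 0.283) — overridable in the config file, since stain
vectors vary across scanners and staining batches. Negative
concentrations (quantization/noise leakage) are clipped to zero *after*
unmixing, so the unmixing itself stays linear.

Numerical conventions, fixed for reproducibility:

* the +1 offset keeps OD finite at zero intensity and maps $I = i_0$
  exactly to zero OD; the maximum representable OD is
  $\log_{10} 256 \approx 2.408$;
* 16-bit inputs are down-converted with `floor(x/257 + 0.5)` before any
  processing, because the thresholding stage operates on 256-bin
  histograms — feeding it 16-bit data would silently change the
  statistic;
* a stain plane is re-encoded to 8 bits as
  `round(255 * 10^(-c))` (transmission convention: 255 = no stain), which
  is the polarity the dark-object threshold expects.

Round-trip accuracy is bounded by 8-bit quantization: a half intensity
step at transmission level $I$ corresponds to
$\tfrac{1}{2}\log_{10}(e)/(I+1)$ OD. Recovered concentrations are within
0.01 OD of truth for each single stain up to ≈ 1.3–1.5 and for moderate
mixtures; when the combined load pushes one channel's OD above ≈ 1.4
(transmission under ~10/255), a single half-step already exceeds 0.01 OD
and the recovery error grows to ~0.03. Tissue at the default fixture
concentrations (hematoxylin 0.6, eosin 0.3) sits far from that regime.

Which plane drives segmentation is genuinely ambiguous in the source
protocol ("the green channel" can denote the eosin plane of the unmixing
or the raw RGB green plane). The default is the **eosin plane** — eosin
dominates cytoplasmic mass, giving the strongest object/background
separation after unmixing — and `deconvolution_channel: rgb_green`
selects the literal green plane instead; both run through the identical
downstream pipeline.

## Histogram-minimum threshold

The *minimum* auto-threshold assumes a bimodal intensity histogram
(object vs. near-white background). The 256-bin histogram is repeatedly
smoothed with a 3-point moving average — edge bins averaged with their
single neighbor and an implicit zero — until it has *exactly two* strict
local maxima; the threshold is the bin of the minimum between the peaks,
taking the lowest bin on ties. Details fixed here (3-point window,
zero-padded edges, strict maxima, iteration cap 10,000, low tie-break)
pin down a variant the method's name alone does not determine.

Two consequences worth knowing:

* a histogram that never becomes bimodal (blank or constant field) is
  rejected; `measure_spheroid()` converts that rejection into
  `threshold_failed` + `no_object` QC flags rather than an error, so
  batch runs continue;
* when the two modes are separated by a run of exactly-zero bins, the
  valley is a plateau and the low tie-break places the threshold at the
  plateau's *left edge* (just above the brightest object pixel), not at
  its midpoint. Either choice segments the same objects; the tie rule
  only needs to be fixed, and low was chosen.

Binarization polarity defaults to `dark_object` (intensity ≤ t), matching
stain-dense spheroids on a bright background.

## Masks, particle filter, object selection

Hole filling converts background components not connected to the image
border into foreground ("include holes"). Foreground components use
8-connectivity by default and holes use 4-connectivity of the background
— the standard dual pairing that avoids topological paradoxes (a
1-px-wide diagonal boundary both enclosing and not enclosing a hole).
Both the filled and the unfilled labelings then drop all particles
*strictly* smaller than `min_particle_area_px` (default 62,000 px,
retained in pixel units because the source protocol's camera calibration
is not recoverable; an object of exactly 62,000 px survives, per the
literal reading of "smaller than"). The largest surviving filled object
is the spheroid; `multiple_objects:k`, `no_object` and `border_touching`
are recorded as flags, not errors — large spheroids can legitimately
clip the field of view. The unfilled mask is restricted to the selected
object's footprint so both masks describe the same spheroid.

## Shape descriptors

* **Size** is the filled-mask pixel count, converted to µm² only when a
  pixel size is supplied (`area_um2` is `NA`, never a silent 1 µm/px
  assumption).
* **Roundness** is $4A/(\pi\,\mathrm{major}^2)$ of the moment-equivalent
  ellipse. Axes come from the second central moments (with the +1/12
  per-pixel variance, which keeps single pixels and 1-px lines
  non-degenerate), rescaled by a common factor so the ellipse area equals
  the mask area. Under that normalization roundness reduces exactly to
  minor/major: 1 for a circle, 0.5 for a 2:1 ellipse, → 0 for a line.
  One subtlety: roundness is an *elongation* measure, not a boundary
  irregularity measure — a k-fold symmetric lobed outline with k ≥ 3 has
  an isotropic second-moment tensor and scores 1 despite its lobes. The
  monotone "more lobing, less roundness" behavior holds for elongated
  (k = 2) shapes, for which the closed form
  $\sqrt{\frac{1-2a+3a^2-1.5a^3+0.375a^4}{1+2a+3a^2+1.5a^3+0.375a^4}}$
  (lobe amplitude $a$) is used as test ground truth. Real lobed spheroids
  are asymmetric, which is why they score low in practice.
* **Solidity** is area(unfilled)/area(filled) ∈ (0, 1]. The source
  protocol's sentence literally divides filled by unfilled (≥ 1) while
  also stating that completely solid objects "culminate" at 1; the
  bounded orientation was adopted so that 1 is the maximum, with
  `solidity_reciprocal: true` available for literal replication.
  Roundness is computed on the filled mask (consistent with the
  single-object definition); for hole-free objects the two masks are
  identical, so the choice only matters for holey aggregates, where the
  filled outline is the biologically meaningful envelope.

Both roundness and solidity are scale-invariant (drift < 0.01 between 1×
and 2× renderings of the same shape), so they are comparable across
magnifications; size is not, which is what the µm² calibration is for.

## Growth statistic and aggregation

Treatment response is percent size variation versus the baseline day
(default 5, the day treatment starts): $100\,(S_d - S_5)/S_5$, computed
per well and unit-invariant. Replicates aggregate as mean ± sample SD
(n − 1 denominator — the reporting convention says "± SD" without
specifying, and sample SD is the defensible choice for n = 3–9
replicates) with a completeness warning below n = 3. No control
subtraction is applied: vehicle (DMSO) wells are carried as their own
condition, matching the variation-vs-baseline definition. The
dose–response table is a pure pivot — missing design cells stay `NA`,
nothing is interpolated. The sparse-staining classifier is strict:
positive fractions < 0.10 are sparse, 0.10 itself is not.

## Synthetic data: what it emulates, what it does not

The generator exists so that every stage has computable ground truth.

* `disk` (radius 180 px), `lobed` (radius 170 px, 6 lobes, amplitude
  0.25) and `aggregate` (radius 240 px, 5 overlapping sub-spheroids of
  half the radius, 20% interior holes) emulate the compact, the
  boundary-lobed and the loose multi-lobed phenotypes. At a nominal
  1 µm/px, diameters (360–480 µm) sit inside the 200–500 µm physiologic
  window; the aggregate geometry is sized so that both its filled and
  its 80%-unfilled mask clear the 62,000 px particle cutoff — a property
  the assay's real spheroids must have, since each image yields a single
  surviving object.
* Holes are punched as disjoint interior disks kept 2 px clear of the
  boundary and of each other, so the unfilled object stays connected;
  the *realized* (rasterized) hole fraction is recorded as truth, and an
  infeasible hole load is an error, not a silent shortfall.
* Rendering inverts the OD transform exactly
  (`round((i0+1)·10^(−od) − 1)`), adds Gaussian sensor noise (default
  sd 5, near-white background 250 so noise stays symmetric under
  clipping), and is deterministic per seed; all randomness flows through
  one explicit seed per artifact with the global RNG state restored.
* The growth model
  $S(d) = S_5\,e^{(r - e\,\mathrm{dose}/(1+\mathrm{dose}))(d-5)}(1+\varepsilon)$
  is a deliberately simple stand-in (the assay fits no growth model); it
  provides seeded series whose percent variation has a closed form, and
  its saturating dose term reproduces the qualitative high-dose
  regression pattern. Its parameters are labeled synthetic throughout.

What passing on synthetic data does **not** show: real micrographs have
uneven illumination, debris, out-of-focus halos, stain variability
between batches, and spheroids touching well walls. The pipeline's QC
flags surface some of these (multiple objects, border contact, failed
threshold), but descriptor accuracy on real data depends on stain
calibration and focus quality that the generator idealizes away.

## Problem sizes and determinism

The test suite verifies the threshold against an exhaustive valley-search
oracle on 1,000 seeded random bimodal histograms, and end-to-end
ground-truth recovery (area within 2%, solidity within 0.03, roundness
within 0.02, mask Jaccard ≥ 0.98 at noise sd 10) on a 20-fixture seeded
suite spanning all three presets — sizes chosen to exercise every code
path at sub-minute runtimes. `measure_spheroid()` is fully
deterministic: identical input bytes and configuration give identical
output rows.

## Known limitations

* One spheroid per image by design: no watershed splitting of touching
  spheroids, no multi-object output.
* Only the minimum auto-threshold is provided; images whose histograms
  are not bimodal (very faint spheroids, heavy debris) fail loudly
  rather than degrade silently.
* Stain vectors are fixed per run (no Macenko-style estimation); badly
  calibrated vectors bias the eosin plane and hence the segmentation.
* The 62,000 px default cutoff is meaningful only at acquisition scales
  comparable to the source protocol's; recalibrate it (config
  `min_particle_area_px`) for other optics.
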