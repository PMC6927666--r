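---
title: "Quantifying SMAD-complex localization and endothelial stiffening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SMAD-complex localization and endothelial stiffening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

plamech bundles two quantitative pipelines used to characterize
BMPR2-deficient endothelial phenotypes: high-content quantification of
proximity ligation assay (PLA) micrographs, which partitions SMAD-complex
puncta into nuclear and cytosolic pools, and AFM force-spectroscopy
analysis, which turns force-distance curves into Young's moduli and
quantitative-imaging (QI) stiffness/height maps. Both pipelines ship with
seeded synthetic-data generators whose ground truth makes every stage
verifiable at desk scale. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish about real data.

## The PLA quantification model

A PLA image pair consists of a nuclear-stain (DAPI) channel and a punctum
channel in which each diffraction-limited spot reports one proximity event
between two proteins (here, SMAD complexes). The pipeline answers one
question per field of view: how many puncta lie inside nuclei versus in
the cytosol?

**Nucleus branch.** The DAPI channel is smoothed with a Gaussian
(`nucleus_sigma = 2` px), binarized with the Huang fuzzy-entropy
auto-threshold, split into individual nuclei by a binary
(distance-transform) watershed, and measured with a connected-particle
pass that discards objects below `nucleus_min_area_px` (default 200 px, a
debris guard; at typical high-magnification sampling real nuclei are
several hundred px).

**Punctum branch.** The PLA channel is flattened by rolling-ball
background subtraction (`ball_radius = 50` px), high-pass enhanced by
subtracting its own sigma-2 Gaussian blur (clipped at zero; only this
subtraction order enhances puncta), binarized with the isodata
("default") auto-threshold, cleaned with a radius-2 binary median filter,
and measured by particle analysis with the punctum size filters.

**Partition.** A punctum is nuclear when its centroid pixel falls on a
positive nucleus label; every other punctum is cytosolic. The
centroid-containment rule makes `n_nuclear + n_cytosolic = n_total` a hard
invariant. The nucleus mask can be grown or shrunk (`nucleus_grow_px`)
before classification; the default applies no adjustment.

### Parameter notes and deliberate deviations

* **Isodata dialect.** The "default" auto-threshold is implemented in the
  desktop-tool dialect: a 256-bin histogram spanning the intensity range
  whose two extreme bins are zeroed before the intermeans iteration. The
  trimming matters after background subtraction, where clipped pixels pile
  up at zero; without it, that mass drags the threshold into the noise
  floor. When trimming empties the histogram (a two-valued image), the
  mid-range value is returned.
* **Punctum connectivity.** Nuclei are labelled with 8-connectivity (the
  common desktop-tool default for large objects). Puncta default to
  4-connectivity (`spot_connectivity`): after the disc-median majority
  filter, genuine diffraction-limited puncta are compact, edge-connected
  blobs, whereas diagonal-only pixel pairs are characteristic of noise
  residuals. With 8-connectivity those residuals survive as 2-px
  "puncta" and push the cytosolic count error at punctum-SNR 5 to ~7%;
  4-connectivity removes them without touching true puncta, and the
  noise-free partition stays exact.
* **Median-filter kernel.** The radius-2 disc uses offsets with
  `d^2 <= r^2` (13 px). The desktop tool's rank filters use `d^2 <= r^2+1`
  (21 px), but a 21-px majority erases diffraction-limited puncta whose
  thresholded footprint is ~13 px, so the geometric disc is used.
* **Border puncta.** Spot detection drops border-touching particles by
  default (`spot_exclude_border`): the filtering chain replicates edge
  pixels, so the one-pixel frame can carry subtraction artifacts, and
  border puncta are only partially observed.
* **Spread-area threshold.** The spreading-area measurement (membrane
  channel, blur, threshold, fill holes, measure) uses the plain intermeans
  threshold rather than Huang. The intermeans fixed point estimates the
  midpoint of the background and cell plateau intensities — the
  area-preserving 50% level of a symmetrically blurred boundary — while
  the fuzzy-entropy threshold settles near the dominant background mode
  and systematically dilates cells. On noise-free discs the measured areas
  agree with $\pi r^2$ to ~0.2%.
* **Coordinates.** Pixel coordinates are 1-based `(row, col)` throughout,
  the R convention; areas are reported in px and in um^2 when a pixel size
  is supplied.

## The force-spectroscopy model

A force-distance record pairs piezo displacement $z$ (nm, increasing
toward the sample) with cantilever deflection (photodiode volts). The
processing chain is: deflection-sensitivity calibration on a rigid
substrate (inverse contact slope, contact region auto-selected as the
upper half of the deflection range); baseline correction (line fit over
the non-contact fraction, with a curvature check that rejects windows that
are not actually contact-free); contact-point detection; conversion to
force and indentation; and an elasticity fit.

Forces follow $F = k \, s \, V$ (nN with $k$ in N/m, $s$ in nm/V), and
indentation is piezo travel past contact minus cantilever bending,
$\delta = (z - z_c) - d$. Two contact models are supported, in the
(nN, nm, Pa) unit system:

* sphere (Hertz, colloidal probe): $F = \tfrac{4}{3}\,
  \frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$, fitted linearly as $F^{2/3}$
  versus $\delta$ through the origin over $\delta \in (0, 50]$ nm — the
  window that keeps the model in its small-deformation validity range
  (well below 10% of the 11,500 nm probe radius);
* cone (Sneddon, sharp tip): $F = \tfrac{2}{\pi} \tan\alpha\,
  \frac{E}{1-\nu^2}\,\delta^2$, fitted as $F$ versus $\delta^2$ through
  the origin, by default over the full indentation reached at the applied
  load (no depth bound is standard for QI batch fitting).

Both linearized fits pass through the origin because the contact laws
have no intercept; a free-intercept variant exists as a robustness
diagnostic only.

### Contact-point rule

The vendor software's rule is not published, so the package defines its
own, exposed in configuration: walking toward the sample, contact is
provisionally the last sample before the deflection exceeds 3 baseline
noise SDs and stays above for 10 consecutive samples (a floor of
$10^{-6}$ of the deflection range keeps the rule meaningful on noiseless
synthetic data); the estimate is then refined by back-extrapolating the
linearized contact law to zero force — $F^{1/\gamma}$ is exactly linear
in tip-sample separation $s = z - d$ with root $s_c$, with $\gamma$ =
3/2 (sphere) or 2 (cone). The refinement regression is variance-weighted
($w \propto d^{2-2/\gamma}$), since additive force noise inflates the
transformed variance near contact. On noiseless curves the contact is
recovered to machine precision; at 2% multiplicative force noise the
median error across seeds is ~2 sample spacings (4-5 nm at 2 nm
sampling).

### Other numerical choices

* **Segment convention.** CFS fits the approach segment (live-cell
  convention); QI analyzes the retract segment. Both are configurable.
* **Non-indentable guard.** A curve whose maximum in-window indentation
  stays below `min_indent` (1 nm) is rejected as non-indentable rather
  than fitted to numerical residue — this is what turns rigid-substrate
  pixels of a QI map into missing values instead of absurd moduli.
* **Missing pixels.** QI pixels whose fit fails are `NA`, never zero, so
  map statistics are unbiased; the contact height is still recorded
  whenever contact detection succeeds (a rigid flat sample yields a full
  height map and an empty modulus map).
* **Heights.** Sample height is reported as the drop from the deepest
  recovered contact point (`height_nm = max(contact_z) - contact_z`),
  so taller features have larger heights; path-averaged differences are
  returned in um.

## The synthetic generators

`make_pla_scene` draws non-overlapping axis-aligned ellipse nuclei
(semi-axes 12-18 px), blurs them with sigma 3 px to emulate optics, and
places Gaussian puncta (sigma 1.5 px, peak 100 a.u. over a 20 a.u. planar
background with mild gradients) — nuclear puncta at least 3 px inside an
ellipse, cytosolic puncta at least 5 px outside all ellipses, all puncta
at least 8 px apart. The default scene (256 x 256 px, 12 nuclei, 15
nuclear + 25 cytosolic puncta) is the reference condition for recovery
tests; noise is additive Gaussian by default (`noise_sd = 20` gives
punctum-SNR 5), with a Poisson option. Placement is rejection-sampled and
fails loudly after 10,000 attempts.

`make_force_curve` builds a linear non-contact baseline and a contact
branch that solves $\delta + F(\delta)/k = z - z_c$ per sample (Newton
iteration from above, converged to 1e-9 nm; the contact laws are convex,
so the iteration is monotone), truncates at the maximum load, and emits
volts via the deflection sensitivity. Defaults mirror the colloidal-probe
acquisition: R = 11,500 nm, nu = 0.5, k = 0.03 N/m, 1 nN load, 2 nm
sampling, contact at 2,000 nm. Force noise is additive (SD proportional
to the maximum force) or multiplicative (per-sample SD proportional to
|F|). `make_qi_grid` derives one seed per pixel by integer mixing of
(seed, row, col), so pixels are independent and the grid reproducible.

What the generators deliberately do not model: photorealistic PSFs and
camera gain, punctum clustering and varying brightness, cell-to-cell
autofluorescence, viscoelastic or bottom-effect force responses, drift
and hysteresis. Passing the recovery tests therefore shows the
algorithms are implemented correctly and are robust to pixel noise at
the stated SNR — not that they are robust to every pathology of real
micrographs or live-cell rheology.

## Validation scales

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of compute per module: 256 x
256 px scenes (20 noise seeds for the recovery check), 30 curves per CFS
condition, 16 x 16 QI grids (the acquisition-format 128 x 128 grid is
supported; a full-size map is simply 64 x more pixels of the same
per-pixel pipeline), and 50 cells per spreading-area population. The
fold-change experiments mirror the study's headline comparisons: a 4-fold
Young's-modulus difference recovered from noisy colloidal-probe curves
and a 2.5-fold spreading-area difference recovered by the
threshold-and-measure pipeline, with the deficient population's radii
constructed as the wild-type draws scaled by sqrt(2.5) so the true mean
areas stand in exactly the printed relation and the measurement — not the
sampler — is what is tested.

## Known limitations

* The Huang threshold implements the Shannon-entropy (original) variant;
  tools also ship a "Huang2" approximation, which is not reproduced.
* Rolling-ball background is computed exactly; desktop tools shrink large
  images for speed at large radii, so their output can differ slightly.
* Cytosolic puncta are not assigned to individual cells (no cytoplasm
  ownership); counts are per frame, with a per-nucleus normalization
  reported alongside.
* The cone half-angle for Sneddon fits has no default: it is a required
  probe parameter (quadratic-pyramid probes of the class used for QI are
  typically specified around 17-20 degrees by their manufacturers).
* No vendor binary formats are read; curves enter as plain-text tables
  with metadata headers.

## Worked example

```{r example}
library(plamech)

scene <- make_pla_scene(pla_scene_spec(seed = 1))
quantify_pla_image(scene$dapi, scene$pla)

curve <- make_force_curve(force_scene_spec(E_true = 1000, seed = 1))
analyze_cfs_curve(curve, fit_depth = 50)
```
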