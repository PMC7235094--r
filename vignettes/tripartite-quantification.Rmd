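---
title: "Quantifying tripartite synapse nanostructure in punctate fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tripartite synapse nanostructure in punctate fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripuncta)
```

## The analysis problem

Excitatory synapses in spinal cord tissue can be mapped by imaging a
knock-in fluorescent fusion of PSD95, the major postsynaptic scaffold
protein, together with immunolabels for presynaptic boutons (the
vesicular glutamate transporters VGLUT1/VGLUT2) and perisynaptic
astrocytic processes (EAAT2, phospho-Ezrin or GFAP). Three questions
drive the pipeline in this package:

1. **Mapping**: how do PSD density, size and intensity vary across the
   Rexed laminae of a hemisection?
2. **Nanostructure**: how many ~140 nm PSD95 nanoclusters (NCs) does each
   postsynaptic density (PSD) contain, and how large are they? PSDs are
   resolved with confocal optics (~250 nm), NCs only with gated STED
   (~80 nm).
3. **Tripartite organisation**: what fraction of synapses is contacted by
   an astrocytic process, judged by binarized-object overlap, and is that
   association spatially specific?

The package implements the full measurement chain for all three and a
ground-truth scene simulator so that every stage can be validated without
microscope data.

## Segmentation chain

Each channel is processed with the punctate-analysis chain:

* **Rolling-ball background subtraction**, implemented as grayscale
  opening with a non-flat hemispherical structuring element (ball height
  in intensity units numerically equal to pixel units). Radius 10 px for
  punctate channels, 25 px for GFAP processes. The envelope never
  exceeds the image, so subtraction is non-negative and a flat image maps
  to zero.
* **Gaussian smoothing** at sigma 1.5 px. The source protocol says
  "1.5 pixel radius"; radius versus sigma is ambiguous and this package
  interprets it as sigma (configurable). The kernel is normalised and the
  border is reflective, so total intensity is conserved.
* **Auto-thresholding**: the moment-preserving (Tsai) threshold for
  punctate channels — the cut whose two-level surrogate preserves the
  first three grey-level moments — and the Li minimum-cross-entropy
  threshold for GFAP. Both operate on a 256-bin histogram spanning the
  image's min–max range (the published algorithms are defined on 8-bit
  histograms); the Li iteration runs on bin centres shifted to positive
  support because its objective takes logarithms of grey values. VGLUT2
  accepts a manual threshold override, mirroring practice.
* **Particle detection**: 8-connected components, minimum size 8 px for
  NC detection (the macro's "8-Infinity" filter). The minimum size for
  PSD-scale detection is not stated by the protocol; the default here is
  2 px, explicit in `pipeline_config()`.
* **Measurement redirection**: mean intensities are always measured on
  the raw image under each label, never on the processed intermediate, so
  `integrated_intensity = mean_intensity * pixel_count` refers to real
  photons.

Foreground is `processed > threshold`. Thresholding an already-binary
image reproduces its foreground exactly, and raising the minimum particle
size can only reduce the object count; both properties are tested.

## PSD -> nanocluster hierarchy

Confocal and STED images share stage coordinates, so no registration is
performed. Every STED NC is assigned to the confocal PSD whose mask holds
the majority of the NC's pixels (ties to the lower PSD id); NCs outside
all PSDs are orphans and enter no denominator. PSDs are classified as
0NC / 1NC / 2NC / 3+NC; "2+NC" aggregates the last two. Whether PSDs with
no detected NC belong in NC-fraction denominators is a judgement call;
this package excludes them by default and reports both denominators.

NC geometry is measured as full width at half maximum (FWHM) along the
intensity-weighted principal axes of each isolated NC, through its
weighted centroid. The baseline is the smaller of the two profile end
values (configurable); crossings are located by linear interpolation
around the peak. Isolation defaults to "no other NC centroid within
400 nm", a concrete operationalisation of measuring only NCs that appear
alone — the protocol gives no number.

**Interpolation choice.** Profiles are sampled at quarter-pixel spacing
with separable Catmull–Rom cubic interpolation. Bilinear sampling was
rejected after analysis: it behaves like convolution with a triangle
kernel, flattening the peak of a Gaussian sampled at ~1.5 px per sigma
enough to bias FWHM by 4–7% at half-pixel offsets, which would swamp the
3% accuracy the estimator otherwise achieves. With cubic sampling the
worst-case error over a sub-pixel offset grid is ~2% at sigma 30 nm and
falls below 0.5% at sigma 100 nm (tested).

Measured sizes are apparent sizes: a Gaussian object of intrinsic FWHM
$w$ imaged through a Gaussian PSF of FWHM $p$ measures
$\sqrt{w^2 + p^2}$. Recovery tests therefore compare medians against the
PSF-composed truth, not the intrinsic truth.

## Colocalization and the rotated null

A PSD is VGLUT- or astro-positive when its labelled object overlaps the
binarized partner mask by at least one pixel, evaluated at the native
resolution of the dataset (102.4 nm for mapping, 19.97 nm for STED); with
mixed resolutions the comparison runs on the finer grid with
nearest-neighbour upsampling of the coarser mask. Categories follow the
truth table: neither marker = PSD only; astro only; VGLUT only = synapse;
both = tripartite synapse. The tripartite *fraction of synapses* uses
VGLUT-apposed PSDs as denominator.

Spatial statistics per PSD: the 10 nearest astro puncta centre-centre
distances (ascending, NA-padded), the count of astro puncta within a
3 µm radius, and counts of astro objects within 200 nm edge–edge
(overlap counts as distance 0; otherwise the minimum distance between
boundary-pixel centres). Radius and edge thresholds use closed
boundaries (`<=`), a documented convention the protocol leaves open.

The spatial null rotates the astro channel 180° about the frame centre:
pixel `(r, c) -> (H+1-r, W+1-c)`, points `(x, y) -> (W-x, H-y)`. Rotation
preserves every object-level statistic exactly and is an involution;
under complete spatial randomness the true-minus-rotated difference in
mean count-within-radius is centred on zero, and under astro placement
clustered at PSDs the true arm wins essentially always. All three
behaviours are tested.

## Laminar mapping and statistics

Lamina ROIs are simple polygons labelled I-II … X. Membership is by PSD
centroid under the even-odd rule with boundary points counted inside
(ties between ROIs sharing a border resolve to the first ROI in list
order); overlapping ROIs are rejected with the offending pair named.
Per-lamina summaries: mean raw field intensity over the ROI, PSD density
(default per 100 µm², unit configurable and echoed in output), mean PSD
intensity, median PSD size, mean integrated intensity.

Hemisection summaries average to animals, and animals — the statistical
unit — carry group means and SEMs. The Pearson contingency chi-squared
(`contingency_chi2()`) is implemented from the definition (expected
counts from margins, no continuity correction) because it is the one
test applied to per-PSD NC-count classes; all other inferential tests
(ANOVAs, Tukey, Mann–Whitney, t tests) are expected to be run with
standard R routines on the animal-level tables this package produces.

## The synthetic scene generator

`generate_scene()` draws a ground-truth field; `render_channel()` images
it. Objects are anisotropic 2-D Gaussians carrying total-photon
amplitudes; the PSF convolution is applied analytically (variances add),
so the noiseless image integrates exactly to background plus the summed
amplitudes, and FWHM follows the quadrature composition law — both serve
as closed-form oracles. Poisson shot noise is followed by Gaussian read
noise and clipping to the detector range; all randomness is seeded.

Defaults encode the study conditions:

| parameter | default | basis |
|---|---|---|
| NC axis FWHMs | lognormal, medians 92 x 185 nm | measured NC medians |
| NC count per PSD | P(1,2,3) = 0.53, 0.32, 0.15 | ventral-horn 2+NC fraction 47% |
| bouton fraction | 0.45 | 25% of PSDs tripartite = 56% of synapses |
| tripartite fraction | 0.56 of synapses | reported EAAT2 tripartite fraction |
| VGLUT2 / VGLUT1 substructures | medians 90 / 272 nm | measured bouton substructures |
| astro domain diameter | lognormal, median 119 nm | measured EAAT2 nanodomains |
| pixel sizes / PSFs | 102.4 nm & ~320 nm; 19.97 nm & 250 / 80 nm | stated acquisition parameters |
| edge gap to partners | uniform 0-100 nm | free parameter (apposition geometry unreported) |

Free parameters the source does not constrain were fixed once on
physical grounds:

* **Amplitudes** are lognormal with sdlog 0.15 and medians of several
  thousand photons, giving peak SNR well above 10 for every object so
  that detection operates in its validated high-SNR regime. Wider
  amplitude spreads push dim objects below any global threshold — a real
  phenomenon, but one that would confound ground-truth recovery tests
  with a segmentation-regime effect.
* **PSD separation** defaults to >= 1.2 µm so neighbouring PSDs stay
  resolvable at confocal resolution.
* **NC separation within a PSD** defaults to 350 nm within a 230 nm
  placement disc. Resolvability under threshold-based particle analysis
  requires the intensity dip between two NCs to fall below the operating
  threshold, which sits near 0.4x the typical NC peak: with effective
  sigma 71–91 nm (median axes composed with the 80 nm PSF and 1.5 px
  smoothing) that needs ~330 nm or more. Conversely the confocal PSD
  must remain one connected object, which caps separations near 480 nm.
  350/230 nm sits inside that window; NC pairs whose long axes happen to
  align with their separation axis can still merge, and remain in the
  results as genuine method error.
* **Diffuse PSD95 pool**: each PSD carries a diffuse scaffold component
  (25% of its NC photons, sigma 150 nm) in the PSD95 channel only. PSD95
  is not exclusively nanoclustered in tissue, and the pool keeps the
  confocal punctum contiguous for multi-NC PSDs.

What the generator does **not** emulate: 3-D structure, spectral
bleed-through, astrocyte arbor morphology (astro decoys are scattered
points, GFAP filaments are not simulated), spatially varying background,
or tile-stitching artefacts. Passing recovery tests therefore show the
measurement chain is correct on well-posed planar scenes, not that it is
robust to every tissue artefact.

## Problem sizes and numerical conventions

Validation runs use 30–40 µm fields (roughly 90–190 PSDs, at most
~2000 x 2000 STED pixels), 20-histogram threshold-oracle sweeps,
50-configuration nearest-neighbour checks against an O(n²) reference,
20-seed null-control replicates, and one 10,000-PSD point-level scene
for the binomial convergence of the tripartite fraction. Recovery of the
tripartite and 2+NC fractions is judged against the *realised* scene
truth (what the generator actually placed), which isolates measurement
error from the generator's own binomial sampling noise; the realised
fractions are separately checked against the requested probabilities.

Degenerate inputs have defined behaviour throughout: constant images
raise a degenerate-histogram error that `segment_channel()` converts to
an empty segmentation with a warning; flat or monotone intensity
profiles return `NA` FWHM with a reason; empty astro sets yield zero
counts and NA distances; zero-margin contingency tables are errors.

## A worked example

```{r, eval = FALSE}
library(tripuncta)
res <- run_pipeline(list(scene = list(field_um = c(40, 40))), seed = 7)

res$mapping$tripartite_fraction_of_synapses
res$nanostruct$two_plus_fraction
res$mapping$category_counts

# compare against what the generator actually placed
tr <- res$truth
sum(tr$category == "tripartite") / sum(tr$has_vglut)
mean(tr$nc_count >= 2)

# regional NC-class comparison on two such runs would use:
tidy(contingency_chi2(rbind(c(252, 536), c(139, 156))))
```

## Known limitations

* The rolling-ball construction fixes the ball height scale to pixel
  units, so (like the classical implementation) its effect depends on
  the intensity scale; the protocol's radii assume 8–16-bit punctate
  data.
* Edge–edge distances use boundary-pixel centres, so they are quantised
  at the pixel pitch and can disagree with sub-pixel geometry by up to
  half a pixel per object.
* NC counting is threshold-based and merges NCs closer than the optical
  dip limit; counts are a lower bound at small separations.
* The 180° rotation is the only spatial null implemented; torus shifts
  or Monte-Carlo repositioning are deliberate non-goals.
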