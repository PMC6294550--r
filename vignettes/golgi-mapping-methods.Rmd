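---
title: "Methods: lateral and axial mapping of Golgi mini-stack proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lateral and axial mapping of Golgi mini-stack proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgimap)
```

## The measurement problem

A Golgi cisterna has a flat interior and a dilated rim, and proteins
partition between the two. In light microscopy this lateral organization
is only interpretable in *mini-stacks* — isolated Golgi stacks obtained
by nocodazole treatment — where an en face view renders a rim protein as
a ring and an interior protein as a disk. Single mini-stacks are small
(ring diameters around a micron) and noisy, so the strategy implemented
here is particle averaging: standardize many en face views to a common
size and position using a reference rim marker, average them, and read
localization off the averaged image's radial intensity profile. The
orthogonal, axial coordinate is measured per mini-stack from side views
as a localization quotient (LQ) on the axis between a cis and a trans
reference marker.

Assumptions inherited by everything downstream:

* each analyzed crop contains one mini-stack, background-subtracted,
  with nonnegative intensities;
* the reference channel is a rim marker whose en face appearance is a
  closed ring approximately concentric with the structures of interest;
* en face vs side orientation has already been decided (the original
  protocol classified views by eye; this package does not automate it);
* lateral structure is approximately radially symmetric about the
  fluorescence centroid, which is what makes a radial mean profile a
  sufficient summary.

## Size normalization: the gyradius

The size standard is the intensity-weighted RMS distance of all pixels
from the channel's center of fluorescence mass,
`Rg = sqrt(sum(I_i r_i^2) / sum(I_i))`. For an ideal thin ring `Rg`
equals the ring radius; for a uniform disk of radius R it is `R/sqrt(2)`.
We take the square root deliberately: the quantity must be a length for
"rescale so the reference gyradius is 100 px" to be meaningful, and the
physics definition of a radius of gyration carries the root. Every pixel
participates — no threshold — so the measure is differentiable in the
noise and robust to segmentation choices, at the cost of sensitivity to
residual background (hence the subtraction-and-clamp contract upstream).

Each mini-stack is rescaled isotropically by `s = 100 / Rg(reference)`
about the reference centroid and embedded in a 701 x 701 px canvas. A
separate alignment step then applies **one rigid sub-pixel translation,
computed from the reference channel, identically to all channels** so
the reference centroid lands at (350, 350). We considered aligning each
channel to its own centroid and rejected it as the primary mode: it
would fabricate concentricity between channels and erase genuine
inter-channel offsets, which are part of the signal. The two operations
are kept separate (rather than fused into one resample) to mirror the
two-macro structure of the original protocol and to keep each step's
contract independently testable; the cost is one extra interpolation
pass, which the idempotence tests bound (< 0.5 px gyradius drift,
< 0.25 px residual shift on re-run).

Before averaging, each channel is normalized to unit pixel sum so that
bright stacks do not dominate the average. The original description
("intensity normalization") does not quantify the operation; sum
normalization is our choice, applied per channel. Averaging is the
arithmetic per-pixel mean — the "z-projection" of the aligned set —
because averaging is the point; a maximum projection would not converge
to the mean structure.

## Radial profiles and the half-max radius

The averaged image is summarized as the mean intensity in unit-width
annuli `[r - 0.5, r + 0.5)` for r = 1..350 px about (350, 350). The
phrase "mean intensity of all pixels within a circle ... plotted against
its radius" admits a cumulative-disk reading; annular binning is the
primary implementation because it reproduces the peaked rim profiles the
method depends on (a ring averaged cumulatively has no peak), and the
cumulative mode is available behind `cumulative = TRUE` for comparison.

A marker's radius is the first half-maximum crossing *outward* of the
profile's global peak, linearly interpolated between bracketing integer
radii; a plateau lying exactly at half-max resolves to its outermost
sample (a deterministic tie-break). The outer slope is used because the
inner slope of a rim ring is contaminated by interior signal and by the
geometric crowding of small radii. Normalizing by the reference radius
from the *same* averaged set cancels the arbitrary 100-px scale and most
of the PSF bias. Degenerate profiles fail loudly: a peak at the
outermost radius or a profile that never falls below half-max raises an
error rather than reporting an extrapolated radius.

Ring diameters are measured on a line profile through the ring center:
the two maxima flanking the center are located and each contributes the
half-max crossing on its slope *away* from the center; the diameter is
the distance between the crossings. The original measurement drew one
line by hand; our default averages 36 evenly spaced angles to remove
operator dependence (single-angle mode remains for parity). This is a
documented deviation, not a reproduction.

## The axial LQ

`LQ = ((x - gm130) . (galt - gm130)) / |galt - gm130|^2` — the scalar
projection of the marker centroid onto the cis-to-trans axis, exactly 0
at GM130 and 1 at GalT by construction (the division uses the squared
axis length as a single sum so the anchors are floating-point exact).
The prior protocol's full quality-filter set is not restated in the
source we implement from, so the filters here are labeled surrogates:
records with an axis shorter than `min_axis_px` (default 3 px, since
short axes amplify centroid noise into the quotient) are rejected with a
reason; LQs outside a plausibility window (default [-3, 3]) are flagged
but kept. Both are configurable and reported separately in summaries
(mean, SEM = sd/sqrt(n), n — the shape of the standard LQ table).

## Copy numbers

`copies = (copies_per_standard / relative_brightness) * I_punctum /
I_Nup`, with the ~16-copy GFP-Nup133 nuclear pore as the default
standard. The moxGFP prefactor is computed as 16/1.47 and only rounded
to the conventional 10.9 in display, never internally. ROI totals use a
circular ROI minus a median-annulus local background, clamped at zero;
ROI and annulus radii are parameters because the original radii are not
stated. `calibrate_standard()` records a hash of the acquisition
settings so that mixing calibration and measurement images acquired
under different conditions is detectable.

## The synthetic generator: what a green test establishes

The generator renders the canonical appearances — en face rings, inner
rings and disks; side-view double-puncta and bars; diffraction-limited
puncta — as ideal geometry convolved with an isotropic Gaussian PSF,
scaled to a specified expected photon count, plus constant background,
Poisson shot noise and Gaussian read noise. Structures are laid down as
bilinearly splatted point samples on grids exactly symmetric about the
planted center (polar grids for rings/disks), so planted centroids are
exact to well under 0.01 px and the sum equals the specified intensity
to machine precision — properties the test suite leans on.

Defaults are the stated imaging world: 50 nm pixels (the 40-54 nm range
of the source imaging), PSF sigma 70 nm (~165 nm FWHM, the scale of a
well-corrected Airyscan-class system; the source states no PSF, only
the blur scale matters here), reference ring radii drawn
Normal(475 nm, 50 nm) — ring diameters around the ~950 nm scale of the
largest rim marker — with a 120 nm annulus width and 5 x 10^4 expected
photons, our choices where the source is silent. Per-image seeds derive
deterministically from one master seed, and the manifest round-trips
through CSV.

What the generator does **not** emulate: 3D cisternal geometry and
oblique views (every structure is drawn in-plane), spatially varying
background, photobleaching, chromatic offsets, and the visual en
face/side classification step. A green end-to-end test therefore
establishes that the *pipeline machinery* — normalization, alignment,
averaging, profiling, extraction — recovers planted geometry under
realistic noise; it does not establish anything about real cells.
Accordingly, the acceptance suite compares pipeline output against an
independent analytic oracle (quadrature of the exact radially symmetric
Gaussian-blur kernel over the planted truth radii), so the known PSF
bias on half-max positions is part of the expectation, not an excuse
for tolerance.

## Numerical choices

* Coordinates are 0-based with pixel centers at integers, x along
  columns; (350, 350) is exactly the center pixel of the 701-px canvas.
* All sub-pixel reads (rescale, shift, line profiles) use one bilinear
  interpolator; values outside the support are 0. Bilinear keeps
  intensities nonnegative and sums nearly conserved; higher-order
  schemes ring at the sharp edges these images are full of.
* Background subtraction offers `border_median` (default: median of a
  3-px border frame, deterministic and parameter-light) and a
  `rolling_ball` morphological opening; the original method is unnamed
  in the source, so both are surrogates and the method used is logged.
* Negative pixels after subtraction or read noise are clamped to 0,
  because the centroid and gyradius formulas assume nonnegative mass.
* PSF convolution is separable with a 4-sigma-truncated, sum-normalized
  kernel and zero padding, so total intensity is conserved for interior
  structures (the fits-on-canvas precondition enforces this).
* The pipeline config is JSON (jsonlite is the one hard dependency; no
  YAML/TOML parser is assumed), with precedence CLI > file > defaults,
  and the validated config plus a run log are written next to every
  output.

## Known limitations

* The TIFF codec is minimal by design: uncompressed baseline files
  (float32/float64/uint8/uint16 grayscale pages) only; compressed or
  tiled files are rejected with an explicit error.
* Half-max extraction assumes a unimodal outer slope per channel;
  multi-shell markers (e.g. genuinely bimodal radial distributions)
  report only the outermost shell of the global peak.
* The LQ quality filters approximate, not reproduce, the prior
  protocol's rejection criteria.
* Normalized radii inherit a residual PSF-dependent bias that the
  reference normalization only partially cancels (disk vs annulus edges
  blur differently); the acceptance oracle quantifies it at about 2-5%
  for the default imaging world. Biological values from the original
  study (real LQ tables, the 950 nm Giantin diameter, EM fractions)
  require the original microscopy data and are out of scope.
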