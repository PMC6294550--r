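# golgimap

Quantitative mapping of where a protein sits within a Golgi mini-stack,
from multi-channel fluorescence microscopy images.

Golgi stacks have two spatial axes that matter biologically. Along the
cis-to-trans **axial** direction, cargo is processed by an ordered series
of enzymes; in the **lateral** plane of each cisterna, trafficking
machinery concentrates at the dilated rim while glycosylation enzymes
occupy the flat interior. Nocodazole-induced Golgi *mini-stacks* disperse
the ribbon into isolated stacks small enough to analyze one at a time: a
stack seen *en face* shows rim markers as rings and interior markers as
filled disks; seen from the side, the same markers appear as
double-puncta or bars. `golgimap` implements the image analysis that
turns those appearances into numbers, for cell biologists quantifying
sub-compartmental localization, and ships a synthetic image generator so
the whole pipeline is testable against known ground truth.

## What it computes

**Lateral (rim vs interior) localization.** Individual mini-stacks are
noisy, so many en face views are averaged after bringing them to a common
frame. Size is standardized with the *gyradius* (radius of gyration) of
the reference rim marker (a Giantin-like ring),

    Rg = sqrt( sum_i I_i * r_i^2 / sum_i I_i ),

where `I_i` is pixel `i`'s intensity and `r_i` its distance to the
channel's center of fluorescence mass; for an ideal thin ring `Rg` equals
the ring radius. Each multi-channel mini-stack is rescaled so the
reference gyradius is 100 px, embedded in a 701 x 701 canvas, translated
so the reference centroid sits at (350, 350), and averaged per pixel
across stacks. From the averaged image a radial mean intensity profile
(annular means, radii 1..350 px) is taken, and a marker's radius is the
half-maximum position on the *outer slope* of its profile, normalized by
the reference radius from the same average: values near 1 mean rim,
well below 1 mean interior. Ring diameters are also measured directly as
the distance between outer-slope half-maximum points of a line profile
through the ring center.

**Axial localization (LQ).** The localization quotient places a marker's
centroid on the cis-to-trans axis defined by GM130 (LQ = 0 by definition)
and GalT (LQ = 1):

    LQ = (x - gm130) . (galt - gm130) / |galt - gm130|^2

**Copy-number estimation.** Spot intensities are converted to fluorophore
copies against an in-cell standard, the engineered nuclear pore carrying
~16 GFP-Nup133 copies: `copies = 16 * I_punctum / I_Nup` for GFP fusions,
and `16 / 1.47 ~ 10.9 * I_punctum / I_Nup` for the 1.47-fold brighter
moxGFP.

## Worked example

Thirty synthetic en face mini-stacks — a Giantin-like reference ring
(radius ~475 nm, the ~950 nm diameter scale of the largest rim marker)
plus an interior enzyme planted as a disk at 0.6 of the ring radius —
analyzed end to end:

```r
library(golgimap)
cfg <- list(
  psf_sigma_nm = 70, poisson_noise = TRUE, background_level = 0,
  read_noise_sd = 0,
  reference = list(channel = "giantin", radius_mean_nm = 475,
                   radius_sd_nm = 50, ring_width_nm = 120,
                   total_intensity = 5e4),
  markers = list(list(channel = "mgat2", kind = "disk",
                      radius_ratio = 0.6, total_intensity = 3e4)))
ds <- make_dataset(cfg, n_stacks = 30, seed = 42)
aligned <- lapply(ds$stacks, function(s)
  align_ministack(normalize_ministack(mini_stack(s$image, "giantin"))))
avg  <- average_ministacks(aligned)
prof <- radial_mean_profile(avg)
ref <- extract_marker_radius(prof, "giantin")
mk  <- extract_marker_radius(prof, "mgat2",
                             reference_radius_px = ref$radius_px)
```

This prints:

```
giantin radius: 116.6 px (normalized 1.00)
mgat2   radius: 55.4 px (normalized 0.48)
giantin ring diameter: 233.2 px
```

Reading the numbers: on the standardized canvas the reference ring's
half-max outer radius lands at ~117 px (the gyradius is 100 px; the
outer edge plus PSF blur sits beyond it), and its line-profile diameter
is twice that. The planted interior disk reports a normalized radius of
0.48 — clearly interior (the geometric edge ratio is 0.53; the residual
difference is the known PSF bias on a filled disk versus an annulus,
quantified in the acceptance suite against an analytic blur oracle).
The axial and copy-number stages are one-liners:

```r
compute_lq(x = c(12.4, 9.1), gm130 = c(10, 8), galt = c(14, 11))$lq
#> 0.52   (marker slightly trans of the stack middle)
estimate_copies(i_punctum = 23800, i_nup = 2000, fluor_standard())$copies
#> 190    (GFP copies in the punctum)
```

## Pipeline / CLI

`run_pipeline(run_config(...), stages)` orchestrates
`simulate, preprocess, normalize, average, profile, radius, diameter,
lq, copynumber` with a JSON config, writing CSV/TIFF artifacts, a config
echo and a run log to an output directory. A command-line front end with
the same stage names lives at `inst/cli/golgimap.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","golgimap.R",package="golgimap"))')" \
  simulate,normalize,average,profile,radius --seed 3 --out run
```

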