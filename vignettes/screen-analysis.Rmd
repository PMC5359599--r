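---
title: "Robust hit calling for lipid-droplet high-content screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust hit calling for lipid-droplet high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscreen)
```

## The assay and its readout

Activated hepatic stellate cells (HSC myofibroblasts) drive liver fibrosis;
when they revert to a quiescent state they re-accumulate cytoplasmic lipid
droplets. A phenotypic screen for compounds that induce this reversion
therefore images two channels per well of a 384-well plate: a nuclear DNA
stain (Hoechst 33342) that counts cells, and a neutral-lipid stain (Bodipy
493/503) that marks droplet accumulation. The per-well statistic is

$$x = 100 \times \frac{\#\{\text{Bodipy}^+ \wedge \text{Hoechst}^+\ \text{cells}\}}{\#\{\text{Hoechst}^+\ \text{cells}\}},$$

the percent of cells that are lipid-droplet positive. Vehicle (DMSO) wells
anchor the baseline; wells cultured under droplet-inducing conditions
(Matrigel) serve as positive controls.

## The statistical model

Per plate, the package computes the mean, sample SD, median $m$ and the raw
median absolute deviation of $x$ over the scoring wells,

$$\mathrm{MAD} = \mathrm{median}_i\,\lvert x_i - m \rvert,$$

and scores every well with the MAD-based Z score

$$z_i = \frac{x_i - m}{\mathrm{MAD} \times 1.4826}.$$

The constant $1.4826 = 1/\Phi^{-1}(3/4)$ makes the denominator a consistent
estimate of the SD under normality, so $z$ reads on the familiar z-score
scale while the median/MAD pair stays insensitive to the strong responders
a successful screen hopes to contain. It is kept as the named constant
`MAD_SCALE` so the formula is auditable in one place.

A compound is a **hit** when $z$ strictly exceeds the threshold (default 5)
in at least the required number of replicate plates (default 2). Compounds
whose associated cell death strictly exceeds 60% in any replicate are
**excluded**: droplet signal in a dying well is not evidence of reversion.
Cell death is estimated per replicate from the loss of counted nuclei
relative to the median of that plate's own negative controls,
$d = \mathrm{clamp}(1 - n/\tilde n_{\mathrm{neg}},\,0,\,1)$. The average Z
over all replicates — including sub-threshold ones — is always computed and
ranks the hits (ties broken by compound id), so near-threshold averages and
sub-threshold averages of non-hits remain reportable.

### Decisions where the procedure was genuinely open

* **Scoring scope.** Whether control wells enter the plate median and MAD is
  not fixed by the screen description ("for each plate"). The default here
  is `compound_only`: a 384-well plate carries strong positive controls
  whose inclusion would inflate the MAD and depress every z. The
  alternative (`all_non_empty`) is one argument away and covered by tests.
* **Median convention.** For an even number of scoring wells the median is
  the midpoint of the two central order statistics.
* **Degenerate plates.** If the plate MAD is 0 the robust score is
  undefined; the default is an error naming the plate, with an optional,
  warning-emitting fallback to $(x-\bar x)/s$. Silent substitution would
  hide a broken plate.
* **Replicate semantics.** Z is computed per replicate plate independently;
  replicates are independent plates sharing compound truth but not well
  assignment. Aggregation across replicates happens only at hit calling,
  which is why an *average* Z can sit below the threshold while the
  compound still fails (or passes) the per-replicate rule.
* **Death aggregation.** Exclusion uses the *maximum* death fraction over
  replicates with a strict $> 0.60$ comparison ("more than 60%"); a
  compound lethal in either replicate is excluded.

## Image quantification

The screen's instrument software is proprietary, so the package defines its
own deterministic quantifier and states it exactly:

1. Gaussian smoothing of the nuclear channel (`sigma`, default 1 px).
2. Global threshold: Otsu (256 levels over the observed intensity range) by
   default, or a fixed value. A foreground guard requires the Otsu
   threshold to clear the robust background (median of the smoothed image)
   by at least `min_snr` (default 5) robust SDs; images that fail — e.g.
   empty wells, where Otsu would split the noise itself — yield zero nuclei
   with a warning rather than noise artefacts.
3. 8-connected component labelling; components outside
   `[min_area, max_area]` (default 10–5000 px) are discarded. Touching
   nuclei are not split: the bundled generator guarantees a minimum
   separation of two nucleus radii, and on real images a watershed step
   would slot in before the area filter.
4. Per nucleus, the lipid channel is averaged over the nucleus mask dilated
   by `dilation_radius_px` (default 3 px, Euclidean disc) — a perinuclear
   stand-in for the cell body, since droplets are cytoplasmic and adjacent
   to the nucleus. Each nucleus is measured over its own dilation even
   where dilations overlap.
5. A cell is Bodipy-positive when that mean strictly exceeds a threshold
   $\tau$ calibrated on pooled negative-control cells as
   $\tau = \mathrm{median} + k \times \mathrm{MAD}$ (default $k = 3$, at
   least 50 pooled cells). When the control MAD is 0 (idealized noise-free
   data) $\tau$ degrades to the control median with a warning.

How the original instrument defined "Bodipy positive" is not recorded; the
per-cell mean-intensity criterion is this package's declared substitute,
not a reconstruction. Coordinates are 0-based `(row, col)` pixels
throughout.

## What the synthetic generator emulates

`sim_config()` + `simulate_well_truth()` + `render_well_image()` generate
plates with per-cell ground truth; `simulate_summary_plate()` is the fast
path that draws the quantified counts directly from the same generative
model (survivors binomial in seeded cells, positives binomial in
survivors). Defaults are the screen's structure at desk scale:

| parameter | default | meaning |
|---|---|---|
| `cells_per_well` | 300 | seeded cells (the assay's 1500 retained in `sim_config_screen_scale()`) |
| `image_size` | 512×512 px | one field per well |
| `baseline_percent_positive` | 5% | responder fraction in vehicle/untreated wells |
| `positive_control_fraction` | 0.6 | responder fraction under droplet-inducing culture |
| `hit_effect` | +0.15 | responder-fraction shift of a planted hit |
| `nucleus_radius_px`, `nucleus_intensity` | 5 px, 20000 | nuclear spot geometry/brightness |
| `droplet_count_responder` | Poisson mean 8 | droplets per responder cell (background cells: 0) |
| `droplet_radius_px`, `droplet_intensity` | 1 px, 12000 | droplet puncta |
| `background_level`, `noise_sd` | 500, 200 | additive Gaussian noise on both channels |

Cell centres are placed by rejection sampling with a hard minimum
separation of two nucleus radii (capped at 50×n attempts). Droplet centres
are placed uniformly within `droplet_offset_max_px` of the owning cell's
centre; the default, `max(1, nucleus_radius_px - 3)`, keeps every droplet's
signal inside the 3-px-dilated perinuclear zone the quantifier measures for
that cell and outside any neighbour's zone. That choice is what makes the
noise-free identity *quantified positives = cells with at least one
droplet* exact; widening the offset (the field is set per config) turns
droplet capture into a partial-sampling problem and the identity into an
approximation. Note the distinction between a *biological* responder
(`is_responder`) and an *imageable* positive (`n_droplets >= 1`): a
responder can draw zero droplets from its Poisson, so exactness statements
are made against the rendered signal, by design.

The generator deliberately omits: PSF convolution and chromatic effects,
shot noise, uneven illumination (a linear gradient is available behind a
flag), touching/overlapping nuclei, 3-D stacks and time series, and any
calibration to the original screen's (unreleased) intensity distributions.
Passing tests therefore demonstrate the *pipeline's* correctness and the
rule set's behaviour under a controlled generative model — not performance
on real microscopy, where segmentation error, debris and illumination
artefacts dominate.

## Numerical and reproducibility choices

* Every stochastic draw descends from one integer seed through fixed
  per-well derived seeds, so any well, plate or run is bit-reproducible in
  isolation and byte-identical on rerun; CSV floats are written at 6
  significant digits to make that claim well-defined at the file level.
* Rendering uses a quadratic radial cap profile, strictly decreasing and
  exactly zero at the spot radius: non-overlapping nuclei remain countable
  as distinct bright regions in noise-free images.
* Component labelling is 8-connected; labels that meet only diagonally are
  merged by a union-find pass over diagonal adjacencies.
* Strict inequalities everywhere the rule says "greater than": hit calling
  (`z > 5`), exclusion (`death > 0.60`), positivity (`mean > tau`). Wells
  with zero detected cells report 0% with `low_cell_flag` and never enter
  plate statistics.

## Problem sizes used in validation

The test-suite and acceptance checks run the summary path at full screen
width (320 compounds + 2×16 controls per 384-well plate, two replicates;
100 null screens and 20 planted-effect screens) and the image path at
reduced per-well scale (40–120 cells on 256–512 px frames, 24–96-well
layouts), chosen so a complete run stays in the minutes range on a single
core while preserving the statistical structure — binomial counting noise
at the well level and sparse strong responders at the plate level. One
caveat those sizes expose deliberately: with very few compound wells, or a
planted-hit prevalence approaching tens of percent, the hits themselves
inflate the plate MAD and depress every z (the robust estimator's
breakdown behaviour); a realistic screen sits near 1% prevalence across
hundreds of wells, where the median/MAD pair is effectively
uncontaminated.

## Limitations

* The quantifier is validated against the bundled generator, not against
  annotated real images; on real data the segmentation defaults (Otsu,
  no watershed, fixed area bounds) would need plate-specific review.
* Cell death estimated from nuclei counts conflates death with detachment
  and with segmentation loss; it matches the screen's exclusion intent but
  is not a viability assay.
* The positivity threshold is calibrated per plate from negative controls;
  plates whose controls fail (few cells, MAD 0) fall back with warnings
  rather than borrowing strength across plates.
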