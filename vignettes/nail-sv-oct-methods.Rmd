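---
title: "Quantifying laser-assisted trans-nail drug delivery from speckle-variance OCT"
author: "nailsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying laser-assisted trans-nail drug delivery from speckle-variance OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nailsv)
```

## The measurement problem

The nail plate — a stack of dorsal, intermediate and ventral keratin layers
roughly 0.5–1 mm thick — is an effective barrier to topical drugs, which is
why nail-bed conditions such as onychomycosis respond poorly to creams and
solutions applied on top of it. A fractional CO~2~ laser can open that
barrier: each pulse vaporizes an inverted-pyramid micro-crater (a
*microthermal ablation zone*, MAZ) through the dorsal layer, and the MAZ
array then acts as a set of channels for the drug. Two questions follow:

1. **Morphometry** — how deep and how wide are the MAZs at a given exposure
   energy, and do they spare the nail bed?
2. **Transport** — once a liquid or cream preparation is applied, how fast
   do drug particles actually move through the MAZs into the plate?

Optical coherence tomography (OCT) answers both non-invasively. A B-scan
resolves the plate cross-section at micron scale, so the MAZ geometry can
be measured directly. For transport, the key observation is that moving
sub-resolution scatterers decorrelate the OCT speckle pattern: comparing a
frame at time $t_n$ with a reference frame acquired at the moment of drug
application highlights exactly the pixels where something is moving.

`nailsv` implements this analysis end to end and, because no clinical
scans are distributed with it, ships a synthetic dynamic-speckle phantom
with known ground truth so that every stage is testable at desk scale.

## Speckle variance against a reference frame

For normalized intensities $I_{t_0}$ (reference) and $I_{t_n}$ (current
frame), the per-pixel two-sample speckle variance is

$$\mathrm{SV}_{t_n}(x,z) \;=\;
\sqrt{\tfrac12\Big[(I_{t_0}-m)^2 + (I_{t_n}-m)^2\Big]},\qquad
m = \tfrac12 (I_{t_0} + I_{t_n}),$$

which reduces algebraically to $|I_{t_0}-I_{t_n}|/2$; `compute_sv()`
implements the reduced form, and the test suite checks both forms agree to
$10^{-12}$. SV is computed on **linear intensity normalized to [0, 1]**:
the conventional noise floor of 0.05 is only meaningful on a bounded
scale, and the phantom's 16-bit export/import path preserves that
normalization. Whether a log (dB) scale would be preferable is an open
question for real scanner data; on the phantom the linear scale is the one
the threshold calibration refers to.

Two artifacts have to be handled before SV is interpretable:

* **Bulk motion and the drug film.** The liquid layer on the nail adds
  optical path above the surface and the finger drifts axially. Every
  frame is therefore realigned to the *reference* nail surface by
  integer-pixel column shifts before SV is computed (`realign_series()`).
  Integer shifts are deliberate: sub-pixel interpolation would itself
  change intensities and inject spurious SV.
* **Shadowing.** Strongly scattering drug aggregates attenuate everything
  below them, suppressing SV at depth. The correction
  $$\mathrm{SVR}_{t_n}(x,z) = \mathrm{SV}_{t_n}(x,z)\,
  \exp\!\Big(\pm\tfrac{1}{\gamma}\sum_{i \le z} \mathrm{SV}_{t_n}(x,i)\Big)$$
  re-weights each pixel by the SV accumulated above it
  (`shadow_correct()`). As typeset the exponent is positive — it
  *amplifies* deep SV under columns with strong activity — although the
  stated purpose (reducing shadow) might suggest a negative sign. Both are
  provided (`exponent_sign`); the default follows the positive print, and
  the amplification is capped at $e^3$ so a pathological column cannot
  blow up.

No value of $\gamma$ is published. The default (`gamma = "auto"`) sets
$\gamma$ per frame to 10 times the median over columns of the
depth-integrated raw SV, which keeps the typical exponent near 0.1 — a
mild, scale-free correction. A fixed scalar can be supplied instead, and
the value used is recorded in each `sv_image`.

The noise floor is estimated from the frames acquired *before* drug
application (`estimate_noise_threshold()`): either the fixed conventional
0.05, or the 99th percentile of the pooled pre-application SV
(`policy = "percentile"`). In the pipeline the percentile variant pools SV
processed through the same shadow correction that will be applied later,
so the threshold refers to the same quantity it gates; on a drug-free
simulation this passes ~1% of plate pixels by construction. Only SV inside
the nail-plate mask is reported: tissue beneath the nail bed is perfused,
and blood flow would be indistinguishable from drug motion there.

## Segmentation

*Surface.* Above the air/nail interface the signal is essentially zero, so
the first pixel of an A-scan exceeding a low adaptive threshold (a
configurable fraction of the frame's Otsu threshold, default 0.1) locates
the surface; isolated misses from dark speckle are removed by a
cross-column median (window 7). This recovers a tilted speckled surface to
within one pixel at the 95th percentile. Columns with no qualifying
crossing are interpolated from neighbours and flagged rather than guessed
silently.

*Realignment.* Shifts are the per-column difference to the reference
surface. MAZ aperture (crater) columns give unreliable surface fixes —
the interior is nearly signal-free — and a wrongly shifted column
decorrelates its entire A-scan, so crater-column shifts are interpolated
from the intact flanks (the nail moves rigidly) and the shift field is
median-smoothed across columns. Frames needing more than a quarter of the
image depth are flagged motion-corrupted. Realignment is idempotent.

*Nail bed.* The plate/bed boundary is the strongest negative axial
gradient within an expected-thickness window below the surface. At that
depth single-A-scan speckle fluctuations rival the layer step, so the
search runs in two stages: the cross-column median depth profile
(surface-referenced) fixes the global boundary depth, then each column is
refined within ±2–3 px of it and median-filtered. Columns with no negative
gradient fall back to the global depth and are flagged.

*Masks.* The plate mask spans surface to bed per column. For the liquid
experiment the MAZ interiors stay empty and are excluded
(`policy = "exclude_maz"`); for the cream experiment the craters fill with
drug and are included (`"include_maz"`).

## MAZ morphometry

Voids are dark, but so is the attenuated deep plate, so a global intensity
threshold cannot isolate them. `detect_mazs()` therefore flattens the
median-filtered frame by the *intact-plate depth profile* — the median
intensity at each depth below the (crater-bridged) surface over
non-aperture columns — and thresholds the ratio image at a fraction of its
Otsu threshold. Candidates must open onto the surface aperture; touching
candidates closer than a minimum width merge and are flagged. Because the
criterion is relative, measurements are invariant to a global intensity
rescale. The median filter erodes the thin apex and the aperture edges by
1–3 px, so both are refined on the unfiltered ratio image.

Depth is surface-to-apex (axial), diameter is the aperture extent at the
surface row (the choice of measuring at the surface rather than at maximum
width is a convention; the two coincide for inverted pyramids).
On noise-free renders of the four energy presets (372/321/290/255 µm deep,
203/183/171/137 µm wide, labelled 50/40/30/20 mJ) both axes are recovered
within one pixel; with speckle the mean absolute depth error stays under
10% and the recovered depths remain strictly ordered in energy.

## Diffusion quantification

Three regions, three 10×10 px squares each (`place_rois()`):

* **Region I** at the MAZ apices (tips) — the first tissue the drug
  reaches through the channel walls;
* **Region II** in the upper nail, away from the apertures — supplied from
  the exposed surface;
* **Region III** midway between adjacent MAZs at mid-plate depth — the
  furthest tissue from any source. With fewer than three midpoints the
  remaining squares stack axially at the existing midpoints so they stay
  between the MAZs; with a single MAZ the region is omitted with a
  warning.

The square size is not prescribed anywhere; 10 px (~50 µm) matches the
transverse averaging convention used for A-scan profiles and is
configurable. Per time point the SV inside each square is summed and the
three sums averaged (±sd across squares) — `roi_timecourse()`.

Onset and saturation need explicit criteria, which the source experiments
report only as observed times:

* **onset** — first time the curve exceeds the pre-application baseline
  mean + 3 sd for two consecutive samples (one-sample blips are noise);
* **saturation** — plateau is the mean of the final 10% of samples;
  saturation is the first time the curve reaches 95% of the plateau and
  stays above 90% thereafter; undefined when the plateau never rises above
  baseline. On a curve $1-e^{-t/\tau}$ this lands at the analytic 95%
  crossing within one sample.

The **SV center of mass** is the SV-weighted mean depth *below the local
surface* (so bulk position cannot bias it), `sv_center_of_mass()`; frames
with zero total SV yield `NA`. `compare_formulations()` reports per-region
onset/saturation differences and the ratio of least-squares COM descent
rates over the post-onset window — the package's proxy for relative
diffusion velocity. On matched seeds the liquid-like preset onsets earlier
in Regions II/III than the cream-like one and descends 1.5–1.7× faster.

## The synthetic phantom

`make_fixture()` renders B-scan time series that emulate the in-vivo
experiments; the generator's defaults *are* the study conditions and the
tests run against them unchanged.

| parameter | default | meaning |
|---|---|---|
| grid | 140 × 200 px at 7 × 5 µm | matches ~7 µm axial / ~5 µm transverse resolution |
| plate thickness | 600 µm | dorsal/intermediate/ventral = 15/70/15% |
| layer backscatter | 0.90 / 0.60 / 0.75 / 0.35 | dorsal / intermediate / ventral / bed |
| attenuation | 0.0015 µm⁻¹ | exponential with depth below surface |
| MAZ presets | 372/321/290/255 µm × 203/183/171/137 µm | inverted pyramids, one per energy |
| frame interval | 0.2 s | 10 pre-application + reference + 50 post frames |
| D (liquid / cream) | 300 / 60 µm²/s | drives both concentration and its ordering |
| decorrelation gain | 2.5 (conc·s)⁻¹ | frame-to-frame correlation $e^{-g C \Delta t}$ |
| shadow gain | 0.02 per conc per voxel | cumulative extinction below high C |
| bulk jitter | sd 0.4 px | integer axial shift per frame |
| sensor noise | sd 0.005 | additive Gaussian |

*Speckle.* Fully developed speckle is the intensity of a spatially
low-pass-filtered complex-Gaussian field (exponential marginal, grain size
set by a ~0.7 px Gaussian point-spread). Temporal dynamics blend the
complex field AR(1)-style, which gives the frame-to-frame intensity
correlation $\rho = e^{-g\,C\,\Delta t}$ in closed form; the test suite
verifies the realized correlation against this expression on a
uniform-concentration block. With $C=0$ the speckle is frozen, so the
drug-free preset is an exact null apart from sensor noise and bulk jitter.

*Concentration.* The drug field obeys $\partial_t C = D \nabla^2 C$ on the
plate with constant-concentration sources on the MAZ walls and the exposed
surface, no-flux lateral edges and an absorbing nail bed, solved by an
explicit stencil that sub-steps to the CFL bound
($D\,\Delta t\,(1/\Delta x^2 + 1/\Delta z^2) \le 1/4$). This PDE is an
*emulation target*, not a claim about the physical chemistry of any drug:
it produces the qualitative features the analysis must detect — early
activity at the walls, delayed arrival between MAZs, earlier everything
for the faster formulation. The liquid/cream diffusivities (300 vs
60 µm²/s) were chosen once so that a 600 µm plate shows surface-to-mid
transport on the recorded 10 s window with the liquid onset roughly
2–4× earlier, mirroring the reported early-onset ordering.

*Rendering.* Intensity = layer backscatter × depth attenuation ×
cumulative shadow factor $\prod_{\text{above}} e^{-g_s C}$ × speckle +
sensor noise, normalized to [0, 1] by the series' 99.5th-percentile window
(clipping the exponential tail rather than letting it compress the
dynamic range). All randomness comes from one seeded generator; identical
config + seed is bit-identical.

What the phantom does **not** emulate: blood flow beneath the nail bed
(the pipeline masks that region out rather than modelling it), the liquid
film above the surface (bulk shifts stand in for its optical-path effect),
phase/polarization effects, detector roll-off, and any real
concentration–decorrelation calibration. Passing tests therefore show the
*pipeline* is correct and self-consistent under realistic speckle
statistics — not that a particular clinical nail would yield the same
numbers.

## Numerical choices and degenerate inputs

* CFL sub-stepping uses a 0.25 safety bound; with sources off and closed
  boundaries the solver conserves mass to 10⁻¹⁰.
* Argmin/argmax tie-breaks take the first (shallowest) index throughout.
* All-zero frames raise "no surface found"; a uniform frame makes every
  nail-bed column fall back to the expected thickness, flagged.
* Thresholding at 0 with a full mask is the identity; a threshold above
  the SV maximum empties the image.
* A one-pixel MAZ candidate measures one pixel pitch in both axes.
* Onset on curves shorter than 2 samples and saturation on fewer than 10
  samples are errors, not guesses.

The test suite and the acceptance script run the phantom at the default
140 × 200 grid with 61 frames, 20 seeds for the replicated checks — sizes
chosen so the full statistical battery stays comfortable on one CPU while
leaving the per-seed Monte-Carlo error well below the tolerances tested.

## Known limitations

* Integer-pixel realignment leaves up to half a pixel of residual motion;
  on real scanners with larger inter-frame drift a sub-pixel structural
  registration stage (applied before, not instead of, the SV computation)
  may be needed.
* SV is not proportional to concentration; all transport statements are
  about onset order, saturation and COM descent, never absolute dose.
* The shadow-correction sign ambiguity is resolved by configuration, not
  evidence; with real data the two signs should be compared on a shadowed
  region with known activity below it.
* Diameter is measured at the surface aperture; for non-pyramidal cavities
  the maximum-width convention would differ.
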