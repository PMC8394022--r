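---
title: "Dynamic-threshold white balance for skin imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-threshold white balance for skin imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwb)
```

## The problem

Screening for neonatal jaundice from photographs stands or falls with
colour fidelity: the yellowness of skin is the signal, and the colour
temperature of room lighting is a nuisance variable that shifts every
pixel. A warm (low-CCT) lamp pushes the frame towards red, a cool
(high-CCT) lamp towards blue, and a downstream reader — human or
algorithmic — cannot tell lamp from bilirubin. `dtwb` implements an
automatic white balance for this setting: it estimates the illuminant from
the image itself (no colour chart), corrects it with diagonal von Kries
gains, and quantifies how consistently a method renders the same scene
across lamps.

## The estimator

Work happens in the analog YUV space, `Y = 0.299 R + 0.587 G + 0.114 B`,
`U = 0.492 (B - Y)`, `V = 0.877 (R - Y)`, computed on the encoded 8-bit
values a camera actually delivers. Neutral surfaces lit by the scene
illuminant all share the illuminant's chroma, scaled by their brightness,
so the near-white pixels form a compact, bright cluster displaced from the
origin in the cast direction.

The chroma statistics are the means `Mu`, `Mv` and the average absolute
deviations

    Du = (1/N) * sum |U - Mu|,    Dv = (1/N) * sum |V - Mv|

and a pixel is a *candidate* white reference when

    |U - (Mu + Du * sign(Mu))| < Wr * Du
    |V - (Mv + Dv * sign(Mv))| < Wr * Dv

with `sign(0) = 0`. The centre displacement by one deviation in the
direction of the mean is what aims the region at the cast rather than at
mid-gray; the *weights threshold* `Wr` scales its radius and is searched
over 0.5–1.5 starting from 1 in steps of 0.1, stepping outward
(1.0, 1.1, 0.9, 1.2, ...). The *percentage threshold* `Wp` then retains
the brightest fraction of the candidates (ranked by Y) as the reference,
iterating from 0.1 downward, never above 0.2 and never below 0.001. The
reference's per-channel means give the gains
`g_c = Yref / mean(c over reference)`, which make the reference
achromatic, and the image is corrected channel-wise in float, clipped and
re-quantized.

## Design choices in the open parts

The threshold ranges and starting points above are fixed; the *stopping
rules* of both iterations, and several robustness details, were open
design territory. Each choice below was driven by a failure mode we could
reproduce on the synthetic suite.

**Which `Wr` to accept.** Accepting the first `Wr` whose candidate
fraction lands in a target band fails on frames whose average chroma is
dominated by content rather than by the cast (a nearly neutral lamp over
lots of skin): the displaced centre then points at skin, and the
first-qualifying candidate set contains no white at all. What
distinguishes the true reference is luminance — the white cluster is the
brightest thing that survives the chroma gate. The search therefore
scores every in-band `Wr` by the mean luminance of its candidate set's
five brightest pixels (a fixed depth, so sets of different sizes compare
fairly) and takes the maximum, breaking ties towards the larger set.
Because candidate sets are nested in `Wr`, this score is monotone over
ties and the chosen threshold is reproducible by exhaustive enumeration,
which is how the tests verify it.

**The candidate-fraction band.** The band's lower edge (0.001 of the
frame) plus an absolute floor of 20 pixels guard against anchoring on a
handful of noise pixels. The upper edge is deliberately loose (0.5): a
tight cap turned out to exclude exactly those `Wr` values whose region
reaches the white cluster on near-neutral frames, and pruning inside the
region is the percentage threshold's job, not the band's.

**Where `Wp` stops.** Between successive `Wp` steps the retained sets are
nested and shrink slowly, so "stop when the gain estimate changes by less
than 1%" halts at the first lull — often still inside a content-dominated
mixture. The implemented rule walks the whole ladder
(`0.1, 0.05, 0.025, ...` down to 0.001, multiplicative factor 0.5) and
keeps the **largest retained set after the last change of at least 1% per
channel**: the start of the final plateau. On a clean frame the estimate
never moves and the full `Wp = 0.1` set is kept; on a contaminated frame
the plateau begins exactly where the mixture has been shed. The retained
set never shrinks below 5 pixels, so single-pixel sensor noise cannot
become the reference.

**The luminance reference of the gain rule.** The classic fixed-threshold
method scales the reference to the *maximum* luminance of the frame. A
maximum is a noise order statistic: with sd-2 sensor noise it sits ~2%
above the true white level, so every application of the method brightens
the image by that ratio and re-correction is never a no-op. The default
here is the *mean luminance of the reference pixels*, which preserves
brightness and makes re-correction stable; the classic convention remains
available (`yref = "max_luminance"`) and is what `dh_reference()` pins.

**Saturation.** A clipped channel destroys a pixel's chroma, so saturated
pixels are barred from candidacy. Under extreme warm casts (2800–3200 K
here) everything bright saturates in red; rather than refuse to act, the
pipeline then falls back to admitting saturated pixels and flags the
result (`saturated_admitted`). Restoration in that regime is degraded by
construction — the information is gone — which is exactly the behaviour
reported for the lowest colour temperatures in this literature.

**Reference refinement.** The acceptance region is anchored off-centre,
so the subset of the white cluster it truncates out is chroma-biased
(pixels whose noise leans towards the centre are over-represented). After
`Wp` stabilizes, the reference is re-selected symmetrically: every pixel
within 3 median absolute deviations of the retained set's median chroma,
at or above the retained luminance floor. This removes the truncation
bias (re-correcting a corrected frame changes it by mean dE00 < 0.1 at
4000–6500 K) and discards stray content that slipped past the luminance
ranking.

**Gain cap.** Per-channel gains are clamped at 4. Each doubling of a gain
costs one bit of the 8-bit signal; beyond two doublings the amplified
quantization noise dominates chroma fidelity, and on the suite an
uncapped 6x blue gain at 2800 K produced a visibly worse image than the
capped one. The cap is off (`Inf`) in the classic baseline.

All of these extras are disabled in the pinned configuration that
reproduces the fixed-threshold ancestor, and the equivalence
`dh_reference(img)` = `white_balance(img, pinned cfg)` is asserted
bit-exactly in the tests.

## Baselines

* **WPR** (white-patch retinex): per-channel reference at the 99th
  percentile (configurable to the literal maximum), scaled to the white
  level. Note its contract on a gray card is equal-channel gains, not
  unit gains: it anchors brightness by design.
* **WGE** (gray-world / gray-edge): Minkowski-`p` mean of the channels
  (`deriv_order = 0`) or of Gaussian-smoothed gradient magnitudes
  (`deriv_order = 1`, sigma 2, `p = 6` — the standard gray-edge
  settings), gains normalized to the estimate's own mean.
* **DH**: the fixed-threshold dynamic method — 3x4 block chroma
  statistics, `Wr` pinned at 1.5, brightest 10% retained, max-luminance
  gain rule.

## The synthetic suite

The photographs this method targets are not distributable, so the package
generates its own study conditions: one scene per seed — mid-gray
background (120), a white reference patch covering 2% of the frame
(intensity 160), two skin-tone patches (a yellower high-bilirubin tone
(158, 128, 95) and a low-bilirubin tone (150, 126, 110)), and two bright
coloured distractors ((165, 150, 70), (110, 140, 175)) that keep the
brightest-pixel assumption from being trivially true — rendered under six
lamps at 2800/3200/4000/4800/5600/6500 K with additive Gaussian sensor
noise (sd 2 on the 0–255 scale), then clipped and quantized. The default
frame is 120 x 160 pixels; the packaged fixture uses layout seed
20210816.

Lamps are modelled as blackbody radiators: chromaticity from the standard
Planckian-locus approximation (verified in the tests against the
Illuminant-A anchor, the 2856 K blackbody), converted to linear sRGB and
green-normalized, applied as diagonal von Kries gains — the model all
four correction methods implicitly invert. Two consequences are worth
stating plainly. First, because the scene's reflectances are sRGB (D65)
colours and the Planckian locus does not pass through D65, even the
6500 K lamp carries a small real cast (about (1.06, 1, 1.05)); a
correction method can therefore genuinely improve every member of the
suite, including the reference lamp. Second, patch intensities were
chosen from the clipping physics: the white reference stays unclipped
under all casts at 4000 K and above, and saturates at 2800/3200 K, so the
suite reproduces the low-colour-temperature restoration failure this
method family is known for, without making it universal.

What the generator does **not** emulate: real skin texture and curvature,
specular highlights, spatially varying illumination, camera tone curves
and demosaicing, and any quantitative link between patch colour and
bilirubin. Passing the packaged tests therefore demonstrates the
estimator's behaviour under its own model assumptions — diagonal casts on
a flat-patch scene — not clinical performance.

## Evaluation protocol

`mean_image_de2000()` converts both images to CIELAB (sRGB chain, D65
white point — the source material never states its colorimetry, so this
is our declared convention, not an inference) and averages the per-pixel
CIEDE2000 over the full frame; a mask argument allows region-restricted
pooling. `cross_ct_matrix()` evaluates all 15 unordered lamp pairs and
their mean — the cross-colour-temperature consistency summary, where
lower and flatter is better. `improvement_table()` compares original and
corrected images per lamp against a declared reference; on the synthetic
suite the natural reference is the known noise-free neutral scene.
(Comparing against a member of the set itself makes the reference column
vacuously zero in both rows, which is why the ideal-scene reference is
the default protocol here.)

CIEDE2000 is implemented in full (a' rescaling, SL/SC/SH weights, the
blue-region rotation term RT), defines the hue difference as zero when
either chroma is zero, and is validated against the 34 published worked
pairs and an independently coded scalar implementation on 1000 random Lab
pairs.

## Numerical conventions and degenerate inputs

* Chroma is computed from channel differences, so `R = G = B` gives
  `U = V = 0` exactly in float.
* The strict `<` of the candidate rule is taken literally: a zero-spread
  (uniform) image has an empty acceptance region at every `Wr` and passes
  through with unit gains and a warning (`neutral_policy = "unit"`).
  `Du`/`Dv` below 1e-9 on the 0–255 scale count as degenerate.
* Corrections are computed in float and quantized once, at output;
  unit gains return the input bit-identically, and fixed input plus fixed
  configuration is bit-reproducible (the method has no randomness).
* Ties in the brightness ranking are broken by scan order (column-major
  pixel index); ties in the `Wr` score by scan order of the outward grid.
* 16-bit material is supported by carrying `white_level`; all thresholds
  are relative quantities and transfer unchanged.

## Problem sizes

The packaged suite is 120 x 160 x 6 images; the full test suite
(including the four-method evaluation and 100-image property sweeps) runs
in well under a minute on one CPU, and `scripts/acceptance.R` — which
regenerates the suite from a seed, runs all four methods and recomputes
every reported quantity — in a few seconds.

## Known limitations

* Under casts that saturate the white reference (2800/3200 K here) the
  estimate anchors on whatever unsaturated or degraded material remains;
  gains are then biased and re-correction is not stable. This mirrors the
  documented behaviour of the method family at very low colour
  temperature.
* The whole-frame statistics assume a single global illuminant; mixed
  lighting violates the model (the block mode localizes the statistics
  but was measurably worse on single-illuminant scenes and is not the
  default).
* The luminance-ranked reference assumes the white object is among the
  brightest near-threshold content; a scene whose brightest
  cast-coloured cluster is not neutral will mislead it.
* CIEDE2000 evaluation uses the D65 sRGB chain end to end; images with a
  different encoded colorimetry would need conversion first.
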