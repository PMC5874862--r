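---
title: "Methods: virtual film dosimetry of an HDR Ir-192 source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual film dosimetry of an HDR Ir-192 source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tg43film)
```

## The problem

High-dose-rate (HDR) Ir-192 brachytherapy sources need a source-specific
dosimetric dataset — dose rate constant $\Lambda$, radial dose function
$g(r)$, 2D anisotropy function $F(r,\theta)$ — before clinical use.
Radiochromic film in a solid phantom is a standard way to measure the 2D
dose distribution around such a source, with a sensitive film (EBT-like,
usable roughly 0.5–8 Gy) for the near field and a high-dose film
(HD-810-like, 10–500 Gy) for larger radii. This package implements the
complete film-dosimetry chain *and* a seeded virtual experiment that
replaces the physical films, so every stage is testable end to end without
access to any real scans.

## The dose model

The dose rate at polar point $(r, \theta)$ (cm, degrees; $\theta = 0$ at
the source's proximal/cable end) is the AAPM TG-43 product

$$\dot D(r,\theta) = S_K \, \Lambda \,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)} \, g(r)\, F(r,\theta),$$

with reference point $(r_0, \theta_0) = (1\,\mathrm{cm}, 90^\circ)$ and the
line-source geometry function

$$G_L(r,\theta) = \frac{\beta}{L\,r\sin\theta}, \qquad
  G_L(r, 0^\circ) = G_L(r, 180^\circ) = \left(r^2 - L^2/4\right)^{-1},$$

where $\beta$ is the angle the active length $L$ (0.35 cm here) subtends at
the point. `beta_subtended()` computes $\beta$ from the endpoint vectors
with `atan2`, which is exact for every admissible geometry and trivially
symmetric under $\theta \to 180^\circ - \theta$. A note on provenance: the
published formula for $G_L$ circulates in several typographically mangled
variants (including an on-axis denominator that reads $r^2 - L^2/2$); this
package implements the standard TG-43U1 form with $L^2/4$, and the test
suite pins $G_L$ against a brute-force numerical line integral to a
relative $10^{-6}$.

Angles are degrees at every interface and radians only internally. The
$\theta$-origin convention (proximal vs distal) is recorded on the dataset
(`theta_origin`) so the TG-43U1 tip convention can be obtained by flipping.

## The virtual experiment

`reference_tg43_dataset()` builds the injected ground truth:

* $\Lambda = 1.112$ cGy h⁻¹ U⁻¹ (the Monte Carlo determination for this
  source type);
* $g(r)$ from the packaged reference column
  (`radial_dose_reference()$mcnp`), extended flat below 1 cm with
  $g(0.5) = 1.000$ (configurable) and linearly above its last node so
  that film corners beyond 4 cm can still be rendered — the extension is
  synthetic and never enters any comparison;
* $F(r,\theta) = 1 - d\,|\cos\theta|^p$ with default dip $d = 0.06$ and
  $p = 2.5$, a smooth stand-in for the published anisotropy curves (pole
  dips of 2–10% are typical); the published work prints no full $F$
  table, so a parametric truth is what makes recovery testable.

`dose_map_forward()` evaluates the dose-rate equation at every film pixel
(300 dpi default; pixel centers at $(i-\tfrac12)\cdot 2.54/\mathrm{dpi}$ cm)
and multiplies by the exposure time. The default exposure plans are the
stated experimental conditions: $S_K = 188.5$ U (50 mCi via
$S_K/A = 10.19\times10^{-8}$ U Bq⁻¹), 2.1 h for the EBT-like film and
182.4 h for the HD810-like film.

The film response is a saturating rational $\mathrm{netOD} = aD/(1+bD)$
with per-kind defaults $(a,b) = (0.08, 0.03\,\mathrm{Gy^{-1}})$ (EBT-like)
and $(0.006, 0.001)$ (HD810-like), chosen once so that the stated-order
calibration polynomial (3 / 4) fits the inverse response with residuals
well under 0.5% over the usable range. The scanner model inverts the
optical-density definition, $S = S_0\,10^{-\mathrm{netOD}}$, then applies
noise and quantizes to 16 bits.

Noise terms follow the published uncertainty budget magnitudes:

| term | magnitude (1σ) | model |
|---|---|---|
| film uniformity | 2% (EBT-like), 3% (HD810-like) | multiplicative Gaussian field on netOD, correlation length ~1 cm |
| scanner consistency | 1.5% / 1% | per-pixel white, multiplicative on signal |
| beam flatness (calibration) | 2% / 1.8% | one draw per calibration strip, on delivered dose |
| lateral response artifact | off by default; up to 9% apparent dose at ±5 cm when on | quadratic signal-gain profile across the scan bed |

All randomness flows from a single seed; per-stage sub-seeds are derived
deterministically, and identical configurations produce byte-identical
TIFFs and report tables.

## The analysis chain

Scans are read from baseline TIFF (a minimal uncompressed little-endian
codec is built in, since no TIFF package is available in the supported
dependency set; RGB scans use the red channel, standard single-channel
radiochromic practice). Optical density is $\log_{10}(S_0/S)$ with $S_0$
from a dedicated unirradiated background strip of the same batch; net OD
subtracts the background OD, which with a shared $S_0$ reduces to
$\log_{10}(S_{bg}/S)$.

Calibration fits dose $= P(\mathrm{netOD})$ by unweighted least squares at
the stated order, in the direction actually used for conversion. The fit
is rejected unless monotone increasing on $[0, \max \mathrm{netOD}]$.
Pixels whose net OD falls outside that interval are masked, never
extrapolated, and the masked fraction is tracked (a >50% masked map is a
quality error).

`to_dose_rate_map()` resamples pixel doses onto a polar grid (defaults
$\Delta r = 0.05$ cm, $\Delta\theta = 1^\circ$, matching the conventional
MC scoring grid) and divides by $t \cdot S_K$, giving cGy h⁻¹ U⁻¹ per
cell. Because the Cartesian pixel grid does not tile the thin annular
cells evenly (~5.9 pixel rows per radial cell at 300 dpi), a cell's true
mean radius can sit up to half a pixel off its nominal center — a ±0.4%
inverse-square error at 1 cm that does not average away. Each cell
therefore also stores its pixel-mean $\bar r$, $\bar\theta$ and
$\overline{1/r^2}$, and extraction divides by
$G_L(\bar r, \bar\theta)\cdot \overline{1/r^2}\,\bar r^{\,2}$ rather than
the cell-center value. With this, zero-noise recovery errors are below
0.01% (forward map) and ~0.05% (full film chain, limited by the
polynomial-fit wiggle).

Extraction follows the defining ratios: $g(r)$ from transverse-axis
windows with geometry divided out and $g(1) \equiv 1$; $F(r,\theta)$ from
per-radius ratios with $F(r,90^\circ) \equiv 1$; $\Lambda$ from a window
around the reference point ($\pm 0.05$ cm, $\pm 5^\circ$, both sides of
the axis averaged). For $\Lambda$ the default estimator is the
geometry-corrected window mean; the plain window mean of the spec'd
window carries a ~+0.2% inverse-square curvature bias and is available as
`method = "window_mean"`. $F$ is reported for $\theta \in [10^\circ,
170^\circ]$ by default: closer to the axis, oblique filtration through
the capsule degrades real film measurements.

## Uncertainty bookkeeping

Budgets are lists of Type A (statistical) and Type B (systematic)
components in percent (1σ), combined by plain quadrature per kind and
overall. Two conventions mirror how such budgets are printed:

* values are computed at full precision and rounded half-away-from-zero
  only for display;
* the experimental budget chains the *rounded* calibration overall
  (4.1 / 3.9%) as an extra Type B component — this reproduces the printed
  quadrature rows (0.64/4.56 and 0.58/4.38) and overalls (4.6 / 4.4%)
  exactly, which the full-precision chain would not.

The Monte Carlo budget takes the published bound values (0.1, 0.5, 0.4%)
at face value, because the printed combinations (0.41, 0.64, 0.82, 0.96%)
are only consistent with the bounds themselves; the combined Type B 0.71%
is an opaque aggregate and is not decomposed.

## What a green test does and does not establish

The virtual experiment emulates the geometry, film response shape, noise
magnitudes and digitization of a real film protocol — not film chemistry
or darkening kinetics, multichannel dosimetry, moiré/Newton-ring or
Callier effects, energy-dependence between calibration beams, or Monte
Carlo radiation transport. Parameter-recovery tests therefore establish
that the *analysis chain* is unbiased and correctly normalized under the
stated noise model, not that a physical measurement would achieve the
same accuracy.

Three deliberate deviations from the protocol as written, found during
implementation, are worth knowing:

* **Dose-range inconsistency.** With $S_K = 188.5$ U and the stated times,
  the dose at $r = 0.5$ cm is ≈17 Gy (EBT-like, usable to 8 Gy) and
  ≈1490 Gy (HD810-like, usable to 500 Gy); the stated plans only enter
  their usable ranges at $r \gtrsim 0.75$ / $0.88$ cm. The generator keeps
  the stated world, and the corresponding acceptance check is knowingly
  red at the lower radius.
* **Far-field geometry.** A 5×5 cm film centered on the source cannot
  contain transverse-axis points at $r = 4$ cm (its corners reach only
  3.54 cm). The virtual far-field run uses a 9×9 cm piece
  (`hd810_film_size_cm`), and since any rectangle reaching $r = 4$ on an
  axis necessarily has corners beyond it, `dose_map_forward()` can mask
  (rather than reject) out-of-table corners via `beyond_range = "mask"`.
* **Calibration ROI.** The conventional π cm² disc ROI (radius 1 cm) does
  not fit a 1×1.5 cm calibration piece; calibration strips use a 0.4 cm
  radius disc, experimental films use per-cell polar averaging.

Numerical conventions: ties round half away from zero; interpolation of
$g$ is linear and of $F$ bilinear (tabulated $g$ spans ~1.000–1.021, so
curvature is negligible); queries outside tabulated ranges are errors,
never extrapolations; degenerate on-axis angles use the closed-form
geometry branch.

## A worked example

```{r example, eval = FALSE}
library(tg43film)
res <- run_pipeline(pipeline_config(noise = FALSE), seed = 1)
res$films$HD810$extraction$lambda   # 1.112030 (truth: 1.112)
res$films$HD810$extraction$g        # g(2 cm) = 1.004431 (truth: 1.0044)
combine_budget(chain_film_budget(4.1, experimental_budget("EBT")))$overall
                                    # 4.607874 -> printed 4.6
```
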