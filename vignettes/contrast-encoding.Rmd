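---
title: "Methods: normalized difference-of-Gaussians contrast encoding"
author: "dognorm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized difference-of-Gaussians contrast encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dognorm)
```

## The model and its assumptions

`dognorm` implements a purely spatial, deterministic encoder of luminance
contrast. A luminance image $f(x,y)$, defined on a square pixel lattice
with the origin at the center pixel, is filtered by a difference of
Gaussians (the *antagonistic* stage) and divided by a broad Gaussian
average of local luminance (the *normalization* stage):

$$
r \;=\; \frac{f * \big(g(\sigma_c) - g(\sigma_s)\big)}{f * g(\sigma_n)},
\qquad
g(x,y;\sigma) = \frac{1}{2\pi\sigma^2}
  e^{-\frac{x^2+y^2}{2\sigma^2}} .
$$

Image and filters share one lattice, so each convolution reduces to a dot
product evaluated at the image center and $r$ is a single scalar.
Half-wave rectification splits $r$ into an ON channel $\max(r,0)$ and an
OFF channel $\max(-r,0)$; deliberately, no further nonlinearity is
applied, so every asymmetry between the two channels is attributable to
normalization alone.

Key structural assumptions:

* **Spatial only.** No temporal filtering, no spike generation, no noise.
  The encoder maps one static image to one number.
* **Scale-free luminance.** The ratio form makes the response invariant to
  multiplying the image by any positive constant. Luminance units
  (arbitrary units or cd/m²) are carried as opaque scalars and never
  converted.
* **Normalization pool includes the stimulus.** The pool is a plain
  Gaussian centered on the receptive field; for dark stimuli the pool
  empties, which is exactly what boosts OFF responses. Excluding the
  stimulus region from the pool would destroy the asymmetry.

## Parameters

All lengths are expressed in units of the center scale, $\sigma_c = 1$.

| parameter | meaning | default | why |
|---|---|---|---|
| `sigma_s` | surround scale | — (must be > `sigma_c`) | canonical family spans 1.25–6, consistent with measured surround/center ratios |
| `sigma_n` | normalization-pool scale | — (≥ `sigma_c`) | canonical family spans 1–6 |
| `pixels_per_sigma_c` | lattice resolution | 16 | discretization error below the two-significant-figure precision of the reported statistics (see convergence below) |
| image half-width | lattice extent | 5 × the largest filter scale | truncated Gaussian mass < 1e−5 even at $\sigma = 6\sigma_c$ |
| disk diameter / square width | stimulus size | $4\sigma_c$ (fixed) | stimulus and receptive field sizes are yoked by construction |
| `step_pct` | contrast sampling | 1% | fine enough that finite-difference slopes at 5% contrast are stable |
| `n_targets` | luminance sampling | 60 per background | L50 is interpolated, so density affects only precision |

The canonical family is the full 6 × 7 cross of surround and normalization
ratios: 42 units, enumerated by `canonical_units()`.

## Stimuli and rasterization

`render_disk()` draws uniform disks parameterized by Weber contrast
$100(d-b)/b$; `render_square()` draws uniform squares parameterized by
absolute luminance, with backgrounds 2, 61 and 120 mirroring flashed-spot
protocols used in LGN work (values in cd/m²). Rasterization is a binary
pixel-center membership test with no anti-aliasing: resolution, not edge
blending, is the accuracy knob, and the closed-form oracles quantify the
residual error.

One subtlety deserves a paragraph. The square's edge sits at
$\pm 2\sigma_c$, which is an exact pixel-center coordinate at *every*
integer resolution; the edge bisects those pixels' cells exactly. A strict
"center inside" rule would shrink the footprint by half a pixel on every
side — an $O(h)$ bias that dominates all other discretization error and
does not vanish quickly with resolution. We therefore include edge-center
pixels by index parity (alternate pixels along each edge), which is still
a binary per-pixel decision but makes the rasterized footprint unbiased;
the remaining error is the $O(h^2)$ interior quadrature term. Disk edges
intersect pixel centers only at four axis points, so disks use the plain
strictly-inside rule. The tests verify pipeline/oracle agreement within
0.5% at 32 px/$\sigma_c$ for both shapes, and a convergence order of at
least one from 8 to 32 px/$\sigma_c$.

## Closed-form oracles

Because every stimulus is a uniform figure on a uniform background and the
kernels are unit mass, the continuum response has a closed form. With
$M_\sigma$ the Gaussian mass inside the footprint
($1-e^{-R^2/2\sigma^2}$ for a disk of radius $R$;
$(2\Phi(a/\sigma)-1)^2$ for a square of half-width $a$), the response to
target luminance $d$ on background $b$ is

$$
r = \frac{(d-b)\,\big(M_{\sigma_c}-M_{\sigma_s}\big)}
         {b + (d-b)\,M_{\sigma_n}} .
$$

`analytic_disk_response()` and `analytic_square_response()` implement
these and serve as the independent accuracy oracle for the rasterized
pipeline. Two useful corollaries: the OFF/ON ratio at 100% contrast is
$(1+L)/(1-L)$ with $L = M_{\sigma_n}$, which depends on the normalization
scale only; and the exact L50 proportion on background $B$ with luminance
range $X$ is $B/(2B \mp XL)$.

## Numerical choices

* **Discretely renormalized kernels.** Kernels are divided by their
  lattice sum so they sum to exactly 1. This makes "uniform image → zero
  response" and illumination invariance hold to machine precision on the
  lattice rather than only in the continuum.
* **Algebraic sweeps.** A rendered stimulus is
  $b + (d-b)\,\mathbf{1}_F$, so the response is an explicit function of
  $(d-b)$ once the mask-restricted kernel sums are known. Response-curve
  functions compute those two sums once per unit and sweep luminance
  algebraically; this is exactly equivalent to re-rendering one image per
  level (the tests assert equality against the rendered path) and keeps
  the 42-unit sweep to seconds.
* **Degenerate inputs.** The response is undefined when the normalization
  output is not positive (an all-black image). Such cases raise an error
  in single-response functions and become flagged `NA` points in sweeps —
  never silently clamped. The $\sigma_n = \sigma_c$ unit at −100% contrast
  is *near*-degenerate (the dark disk has luminance 0, so the pool is
  carried by the background annulus alone); it is included, because the
  reported ratio range includes it, but annotated via the
  `near_degenerate` column.
* **Nonlinearity index.** $\log_{10}$ of the ratio of CRF slopes at 50%
  and 5% contrast, slopes by central finite differences on the sampled
  curve. The log base is a reporting convention; the OFF > ON ordering is
  base-invariant, and the tests check it for every slope contrast from 20
  to 90%.
* **L50 convention.** The half-response luminance is located by linear
  interpolation between samples and converted to a proportion of the
  sampled luminance range between the background and the extreme target
  (2 for OFF, 120 for ON). This convention reproduces the closed-form
  $B/(2B \mp XL)$ solution as sampling densifies.
* **Population aggregator.** Cross-background ratios are averaged across
  units with the arithmetic mean by default (`median` available); the mean
  is what matches the closed-form population values, as the test against
  the oracle statistics shows.

## Problem sizes

Default analyses run at 16 px/$\sigma_c$, where the largest canonical unit
uses a 961 × 961 lattice and the full 42-unit population sweep (201
contrast points and 4 × 60 luminance points per unit) completes in a few
seconds on one core. The oracle-equivalence checks run at 32
px/$\sigma_c$. These sizes were chosen so that discretization error is
comfortably below the two-significant-figure precision at which the
population statistics are reported; doubling the resolution changes the
OFF/ON ratio extremes by well under 1%.

## What the synthetic stimuli do and do not emulate

The generator reproduces the *geometry* of classic receptive-field mapping
protocols: uniform disks and squares, sized to the model receptive field,
on uniform backgrounds. It does not emulate gratings, natural images,
white-noise stimulation, temporal presentation (flash duration, adaptation
history), display nonlinearities, or photon/neural noise. Consequently,
passing tests show that the *model* produces ON/OFF asymmetries of the
observed sign, ordering and approximate magnitude under idealized
stimulation — they do not show that real neurons are fit by these
parameters, and the package deliberately contains no fitting machinery.

## Design choices

* The package follows the classic R modelling idiom: `contrast_encoder()`
  returns a classed object with `print`, `coef`, `summary`, `predict` and
  `plot` methods. There is no `formula`/data fitting interface and no
  `simulate` or `residuals` method because the encoder is a deterministic
  forward model with no estimation step and no error distribution.
* Cone-adaptation curves are computed with intensities expressed in units
  of the adaptation constant $I_a$, so the contrast-domain curves are
  bitwise identical for any adaptation level — the model's scale
  invariance is structural, not approximate. The report writer emits one
  file per adaptation level precisely to demonstrate the files are
  byte-identical.
* Reports are CSV (RFC 4180 via `write.csv`) and JSON; plots are optional
  base-graphics conveniences, and no result depends on them.

## Known limitations

* ON responses to dark contrasts and OFF responses to bright contrasts are
  outside the model's scope: rectification discards them by construction.
* The model cannot produce higher ON than OFF sensitivity at low contrast;
  where real populations show that, an additional mechanism is required.
* The ON maximal-response ratio between dark and gray backgrounds is
  sensitive to which luminances a protocol actually presents, since Rmax
  is defined at the largest *presented* contrast; with the default even
  60-point sampling the package reports the value implied by the full
  luminance range.
* Rasterization is binary; sub-pixel stimulus placement or anti-aliased
  edges are not modeled. The oracles bound, but do not remove, lattice
  error at any finite resolution.
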