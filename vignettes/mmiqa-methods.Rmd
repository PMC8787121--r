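---
title: "MM-IQA: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MM-IQA: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmiqa)
```

## The problem

Cameras monitoring swimming pools look through water: lane ropes, tiled
walls and swimmers seen under refraction, ripple and compression. A
full-reference image quality assessment (FR-IQA) metric for this setting
should (a) notice degradation where a human watcher is looking — the
"main targets" (swimmers, lane markings, wall edges) — and (b) track the
structural damage that JPEG compression does to edges and texture.
`mmiqa` implements such a metric plus everything needed to exercise it:
JPEG distortion-database construction, differential mean opinion score
(DMOS) arithmetic, a synthetic pool-scene generator, and the standard
logistic-fit evaluation harness.

## The metric

Both planes are scored in grayscale (Rec. 601 luma; pool footage is
nearly monochrome so chrominance carries little).

**Large scale — main-target extraction.** Each plane is resized to a
small working width and passed through spectral-residual saliency: with
$A = \log(|F| + \epsilon)$ the log-amplitude spectrum and $\varphi$ the
phase of the 2-D DFT, the residual $R = A - \mathrm{box}_{k\times k}(A)$
(default $k = 7$) captures what is *unexpected* in the spectrum, and
$|\,\mathcal{F}^{-1} e^{R + i\varphi}|^2$, Gaussian-smoothed and
max-normalised, concentrates on isolated, structured objects — exactly
the swimmers and markings. An optional amplitude stretch $A^\gamma$
(default $\gamma = 1$, i.e. off) is provided for noise suppression.

The two saliency maps $s_x$ (reference) and $s_y$ (distorted) are
compared pixelwise by the shared similarity transform

$$ s(a,b) = \frac{2ab + C}{a^2 + b^2 + C}, $$

giving the contour similarity map $Con$ (stabiliser $C_1$), and combined
into a positional weight map $w = \max(g*s_x,\, g*s_y)$ — the fuzzy-set
union of the smoothed maps, so attention drawn by *either* plane counts.

**Small scale — feature similarity.** At native resolution three
per-pixel similarity maps use the same transform: luminance $P_l$ on
local means ($C_2$), contrast $P_c$ on local standard deviations
($C_3$), and sharpness $P_s$ on Scharr gradient magnitudes
($S_h = [[3,0,-3],[10,0,-10],[3,0,-3]]/16$, $S_v = S_h^T$; $C_4$).

**Pooling.** With $Con$ and $w$ upsampled to the native grid,

$$ \mathrm{MMIQA} = \frac{\sum_\Omega \left[P_s + w_1 P_l P_c\right]^\theta
Con^\psi\, w}{(1+w_1)^\theta \sum_\Omega w}. $$

The division by $(1+w_1)^\theta$ — the bracket's attainable maximum — is
this package's normalisation: without it the score is unbounded above 1
whenever $w_1 > 0$. It rescales values, never rankings, and makes
`mm_iqa_score(x, x) == 1` exactly.

## Parameters

| parameter | default | role |
|---|---|---|
| `C1` | `1e-4` | stabiliser for maps on [0,1] (saliency/contour) |
| `C2`, `C3` | `(0.01*255)^2`, `(0.03*255)^2` | SSIM's luminance/contrast constants for 8-bit data |
| `C4` | `170` | gradient stabiliser (gradient-similarity family convention) |
| `w1` | `0.6` | weight of $P_l P_c$ against $P_s$; gradient term kept dominant |
| `theta`, `psi` | `1`, `1` | importance exponents of the local bracket and $Con$ |
| `working_width` | `256` px | saliency scale (classic spectral residual uses small widths) |
| `residual_filter_size` | `7` | spectral box filter $k$ |
| `smooth_sigma` | `3` | Gaussian $g$ on the working grid, truncated at $4\sigma$ |
| window | 11×11 Gaussian, $\sigma=1.5$ | locality of $\mu$, $\sigma$ (SSIM convention) |

None of the exponents, weights or stabilisers come with published
values; the defaults above are the field conventions named in the table
and are fixed once here, serialised through the flat config file
(`write_mmiqa_config()`), and fingerprinted into every score
(`params_digest`).

## Open choices and how they were settled

* **Locality of mean/sd.** The luminance/contrast statistics are written
  as whole-image sums but are pooled per pixel, so they must exist
  locally. Default: the 11×11 Gaussian window. `window_spec("box")` and
  `window_spec("global")` give the unweighted and the literal
  whole-image readings; the choice is a recorded config key. The global
  and box modes carry the $1/(N-1)$ sample correction; the Gaussian mode
  uses the plain weighted moment.
* **The spectral "mean filter" $\delta$.** Described in the source
  method as an identity matrix, which would zero the residual; it is the
  7×7 *box* average of the original spectral-residual construction.
* **The union operator** on real-valued maps is the pixelwise maximum
  (fuzzy union); summation was rejected because it double-counts
  co-salient regions.
* **Stretch domain.** Whether $\gamma$ stretches the raw amplitude or
  the log-amplitude is ambiguous; with the default $\gamma = 1$ both
  coincide, and both readings are exposed as
  `saliency_params(stretch_on = "log" | "amplitude")`. Because the
  log-amplitude can be negative, the log-domain stretch operates on the
  min-shifted spectrum and total energy is restored by the
  $\sum A / \sum A'$ normalisation.
* **Exponent scope**: the pooled term is bracketed
  $[P_s + w_1 P_l P_c]^\theta \cdot Con^\psi$, with $\theta$ playing the
  same role for the local bracket as $\psi$ for the contour term.
* **$\psi = 0$** is allowed (contour term off) as a diagnostic
  degenerate mode; with $w_1 = 0$, $\theta = 1$ and uniform weights the
  score reduces exactly to the mean gradient similarity, which the test
  suite asserts.
* **Outlier screening** marks a score missing when it deviates from its
  image's mean by more than $k$ sample standard deviations (default
  $k = 2$; $k = 1$, the literal one-sigma reading, would discard about a
  third of honest Gaussian ratings and is one flag away). Because
  removal shrinks the column deviation, the rule is iterated to its
  fixed point, which makes screening idempotent — the one-pass variant
  is not.
* **DMOS sign**: $D = $ reference score $-$ distorted score, so higher
  DMOS is worse; correlations against similarity metrics are therefore
  negative and reports carry signed values.
* **Logistic fit**: deterministic initialisation ($\tau_1$ = subjective
  range, $\tau_2$ = sd(objective)/4 signed by the raw correlation,
  $\tau_3$ = median, $\tau_4 = 0$, $\tau_5$ = mean), one restart with
  $\tau_2$ negated, BFGS + Nelder–Mead polish, best RMSE wins, and the
  raw initialisations compete so the fit can never lose to its own
  starting point.

## Numerical conventions

Coordinates are row-major `(row, col)`, documented 0-based. Borders use
symmetric (edge-mirroring) padding everywhere. The forward DFT is
unnormalised (R's `fft`); the inverse carries the $1/(PQ)$ factor. The
residual construction is invariant to the constant spectrum shift this
implies, up to the `log_epsilon` guard that also keeps constant images
finite (their maps come out flat ≈ 1 after normalisation, because the
huge positive DC residual dominates). Gradient masks are applied as
correlations. JPEG bytes are codec-dependent, so no test asserts exact
JPEG output — only inequalities and monotonicity (the quality-10 plane
is farther from the reference than the quality-50 plane, quality 100 is
near-lossless). Raster codecs (PNG/JPEG/BMP) are delegated to a bundled
Python/Pillow helper because the target R stack ships no image codec
package; all pixel arithmetic stays in R, and PGM/PPM are parsed
natively.

## The synthetic world, and what green tests mean

The pool database behind the original study (150 references × 5 JPEG
levels, 16 observers) is not publicly deposited, so the package carries
a generator of *synthetic* pool scenes: periodic tile texture (gradient
content), dark lane stripes with bright rims (contour saliency), bright
elliptical blobs standing in for swimmers (main targets), a sinusoidal
ripple warp and Gaussian sensor noise (defaults: 288×512, tile period
32 px, 3 swimmers, ripple 2 px, noise sd 2 — chosen once as a plausible
desk-scale pool frame). The rating simulator maps true quality $q \in
[0,1]$ to a latent opinion $1 + 4q$ with subject bias, score noise and
uniform attention-lapse outliers.

These fixtures exercise every pathway of the metric, but they are
statistically homogeneous, noise-free of real optics (caustics, motion
blur, colour cast) and rated by a toy observer model. A green suite
therefore establishes internal correctness — oracle equivalence of the
FFT path, identity/symmetry/boundedness, monotonicity down the JPEG
ladder, recovery of simulated opinion — and *not* the published
database-scale correlation figures, which would require the original
images and human scores.

## Known limitations

* For additive noise, contrast masking in the gradient term outweighs
  saliency weighting: equal-energy noise hurts the score *more* in flat
  unsalient regions than on busy salient edges. The pooling still
  behaves as designed (for a fixed corruption, saliency weights move the
  score toward the corrupted region's similarity relative to uniform
  pooling), but "salient corruption always scores lower" is not a
  property of this metric family.
* Only JPEG distortion is modelled; blur, noise ladders and transmission
  artifacts are out of scope.
* Scores depend (mildly) on the codec used for the JPEG ladder; rankings
  across quality levels are stable, absolute values may shift between
  libjpeg builds.

## A worked example

```{r example, eval = FALSE}
img <- generate_pool_fixture(fixture_spec(seed = 1))
ds  <- build_distortion_set(img, c(50, 40, 30, 20, 10), "fix1")
mm_iqa_batch(list(ds))[, c("level", "score")]
#>   level     score
#> 1    50 0.9449823
#> 2    40 0.9333090
#> 3    30 0.9230204
#> 4    20 0.8998323
#> 5    10 0.8134497
```
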