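---
title: "Map sharpening by maximizing detail and connectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map sharpening by maximizing detail and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharpmax)
```

## The problem

A cryo-EM reconstruction carries resolution-dependent noise: its Fourier
amplitudes fall off with resolution both because of genuine atomic motion and
because the high-resolution shells are dominated by error. Displayed at a
fixed contour, an under-sharpened map looks smooth and featureless; an
over-sharpened one is detailed but fragments into disconnected islands of
density. `sharpmax` automates the choice of the sharpening level: it rescales
the map's Fourier amplitudes with a four-parameter function and selects the
overall B factor that maximizes an objective balancing *detail* (iso-contour
surface area) against *fragmentation* (the number of disconnected
contour-enclosed regions).

## The sharpening model

A map is represented as a Fourier series. Each term at resolution $d$ (in Å)
is multiplied by the combined scale

$$A(d) = w_s(d)\,A_{\mathrm{sharpen}}(d) + w_b(d)\,A_{\mathrm{blur}}(d),$$

with

$$A_{\mathrm{sharpen}}(d) = e^{+B_{\mathrm{sharpen}}/(4d^2)}, \qquad
  A_{\mathrm{blur}}(d) = e^{-B_{\mathrm{blur}}/(4d^2)},$$

$$w_s(d) = \frac{e^{k(d - d_{\mathrm{cut}})}}
                {e^{k(d - d_{\mathrm{cut}})} + e^{-k(d - d_{\mathrm{cut}})}},
  \qquad w_b(d) = 1 - w_s(d).$$

The sharpening factor acts at low resolution; the blurring factor is a soft
resolution limit at high resolution. The weights are equal at the transition
resolution $d_{\mathrm{cut}}$ and $w_s \to 1$ for $d \gg d_{\mathrm{cut}}$.
When the map is being blurred overall ($B_{\mathrm{sharpen}} \le 0$) no
additional high-resolution blur is applied and $A(d) = A_{\mathrm{sharpen}}(d)$.

Parameter defaults, all exposed in `sharpen_params()`:

| parameter | meaning | unit | default |
|---|---|---|---|
| `b_sharpen` | sharpening (+) / blurring (−) B | Å² | optimized |
| `d_cut` | sharpen-to-blur transition resolution | Å | nominal map resolution |
| `b_blur` | high-resolution soft-limit B | Å² | 200 (≈259-fold attenuation at 3 Å) |
| `k` | transition steepness | Å⁻¹ | 10 (transition ≳96 % complete over ±0.2 Å) |

The unit-test contracts pin the transcription: equal weights at
$d_{\mathrm{cut}}$, weights summing to one for every term, $\ge 90\%$
completion of the transition over $d_{\mathrm{cut}} \pm 0.2$ Å at $k = 10$,
and $1/A_{\mathrm{blur}}(3\,\text{Å}) = e^{200/36} \approx 259$ at the
default `b_blur`.

The overall B of a map is measured Wilson-style from
$F(d) = F_0\,e^{-B_{\mathrm{iso}}/(4d^2)}$: `fit_isotropic_b()` regresses the
per-shell mean of $\ln F$ on the per-shell mean of $1/(4d^2)$, weighted by
shell amplitude. Using shell means of *both* regressands makes the fit exact
for a pure exponential falloff; the lowest-resolution shell is excluded
whenever at least four shells are available, because a handful of very strong
low-order terms otherwise leverages the fit. Amplitude anisotropy is removed
first (`remove_anisotropy()`): $\ln|F|$ is fitted as a quadratic form in the
reciprocal-space vector (six tensor components plus a scale, by linear least
squares), the anisotropic part is divided out, and the isotropic remainder
(trace/3) is reinstated.

## The objective

For a candidate overall B the procedure (`scan_sharpening()`):

1. rescales the coefficients so the fitted overall B moves from its current
   value $b_0$ to the target ($B_{\mathrm{sharpen}} = b_0 - \beta$);
2. finds the iso-contour threshold enclosing a fixed fraction (default 20 %)
   of the molecular volume;
3. counts the contour's surface area SA (outside grid points face-adjacent to
   an inside point) and its contiguous regions $N$ (6-connectivity), and
   records the map kurtosis;
4. forms the adjusted surface area
   $\mathrm{SA}_{\mathrm{adj}} = \mathrm{SA} - C_{\mathrm{scale}}\,N$.

$C_{\mathrm{scale}}$ is calibrated per map so that
$\mathrm{SA}_{\mathrm{adj}}$ is identical at the two scan extremes
(`calibrate_c_scale()`); the chosen B maximizes
$\mathrm{SA}_{\mathrm{adj}}$, with ties broken toward higher B (less
sharpening, less fragmentation risk). The default scan covers $-100$ to
$+300$ Å² in 20 Å² steps.

Two guards decline the method (`applicability_check()`): the objective at the
scanned point nearest 50 Å² must not fall below the (equal) endpoint values,
and the signal (peak objective minus endpoint) must be at least 3 times the
noise, estimated as the r.m.s. deviation of interior scan points from the
linear interpolation of their neighbours. A declined run returns the input
map unchanged together with the diagnostic trace.

The molecular region itself is found from the locally smoothed squared
density (`find_molecule_mask()`): after mean removal the squared density is
smoothed with a Gaussian of radius 1.5× the resolution (kernel truncated at
3σ, σ chosen so the kernel's radius of gyration matches the stated radius),
its square root — a local r.m.s. density — is split by an iterated two-class
(midpoint-of-class-means) rule starting from several volume-fraction guesses,
and the converged fraction defines the mask. A map without variance contrast
is a fixed point of the update, so the guess is returned unchanged; guesses
that fail to agree trigger a warning and the median fraction.

## Alternative targets

* **Kurtosis** (`auto_sharpen_kurtosis()`): the same scan, choosing the B
  that maximizes the raw (Pearson, Gaussian = 3) kurtosis of the whole map.
  Only the argmax matters, so the kurtosis convention is immaterial.
* **Half-map** (`halfmap_sharpen()`): per resolution shell the half-map FSC
  is converted to the estimated true-map correlation
  $CC^\ast = \sqrt{2\,CC/(1+CC)}$ and amplitudes are scaled by
  $R \cdot CC^\ast$, where $R$ is the ratio of the mean zero-B model-map
  amplitude to the mean map amplitude in the shell. Negative FSC carries no
  usable signal and is clipped to $CC^\ast = 0$. A model is required for the
  $R$ normalization in this release.
* **Model-based** (`model_sharpen()`): the map-to-model FSC is corrected for
  assumed model coordinate error through
  $CC = CC^\ast e^{-B_{\mathrm{eff}}/(4d^2)}$ with
  $B_{\mathrm{eff}} = 8\pi^2\,\mathrm{rmse}^2/3$ (the standard B ↔
  mean-square displacement relation) and rmse defaulting to one quarter of
  the resolution; amplitudes are again scaled by $R \cdot CC^\ast$ (clipped
  to $[0,1]$).
* **Direct CC maximization** (`auto_sharpen_model()`): chooses the scan
  candidate maximizing the zero-B map-model correlation.

Map quality throughout is measured by `map_model_cc_zero_b()`: the Pearson
correlation, over grid points within 3 Å of any atom, between the map
(truncated at the working resolution) and a map computed from the model with
all B values set to zero. The 3 Å default is deliberately distinct from the
5 Å radius used by `extract_region_near_model()` for box extraction.

## Local sharpening

`local_sharpen()` tiles the molecular region with overlapping cubes (default
40 grid units, 50 % overlap, clipped at map edges), sharpens each box
independently with the chosen method at the global resolution, and recombines
them with the weight $w = e^{-d/d_o}$, where $d$ is the distance from a grid
point to a box centre and $d_o$ defaults to the mean nearest-neighbour
distance between box centres. The normalized weighted average is exact for
constant fields and independent of box order; the exponential distance
weighting is the sole blending rule (no extra taper). Boxes where the method declines
fall back to the original density with a warning, and grid points outside
every box keep the input density (they are solvent by construction of the
box plan).

## The synthetic generator and what it does (not) emulate

All tests run on generated fixtures (`synthetic_spec()`, `make_model()`,
`model_to_map()`, `degrade_map()`, `make_half_maps()`, `jitter_model()`);
every generator is seed-deterministic. The default fixture is a 200-atom
self-avoiding pseudo-chain (3.8 Å steps, ≥10 Å solvent margin) in a 60³ grid
at 1 Å spacing, truncated at 3 Å — sized so the full suite runs in minutes.
Atoms are single Gaussians; structure factors are accumulated analytically
and truncated, so a zero-B atom is exactly the resolution-limited point
response. Map degradation is modelled two ways: resolution-dependent phase
randomization (amplitudes preserved), and Hermitian Fourier noise added per
shell with $\sigma(d) = \sqrt{3}\,(d_{\min}/d)^2$ times the shell's mean
amplitude, anchored so the shell correlation to the noise-free map falls to
about 0.5 at the nominal resolution, as the FSC-based resolution convention
implies, and approaches 1 at low resolution.

What passing tests show — and what they do not:

* Recovery tests show that on such maps the adjusted-surface-area choice and
  the zero-B-correlation optimum agree to within roughly one or two scan
  steps (20-40 Å²), with the surface-area choice systematically the less
  sharpened of the two. They do not show performance on real reconstructions,
  whose solvent statistics, multi-element scattering, symmetry and masking
  differ.
* On these fixtures kurtosis maximization is consistently more conservative
  (higher chosen B) than surface-area maximization; with real maps the two
  have been reported to give closely similar quality, so the fixture's
  solvent/noise structure is the likely cause, and the kurtosis tests here
  assert only internal consistency of the scan.
* The applicability guards are exercised on a degenerate single-blob map
  (declined) and on noisy chains (accepted); the boundary between those
  regimes on real data is not probed.

## Numerical choices and conventions

* Orthogonal cells and P1 only; $d = 1/|\mathbf{s}|$,
  $\mathbf{s} = (h/a, k/b, l/c)$; 0-based grid indexing with an MRC-style
  start offset; maps are written as mode-2 (float32) little-endian MRC.
* Resolution shells hold equal numbers of terms (default 20 shells); terms
  tied in $d$ at a boundary go to the lower-resolution shell; the
  zero-frequency term is excluded from shell statistics.
* Contour conventions: points exactly at the threshold are inside; regions
  use face (6-)connectivity; points beyond the map bounds are background.
  The connectivity choice is isolated in one labelling routine.
* Even-length axes have a self-conjugate Nyquist plane; analytic structure
  factors keep only the real part of the Nyquist phase factor, and the
  anisotropy correction averages mirrored scale factors there, so every
  operation preserves exact Hermitian symmetry (real maps).
* Phase-error fields are antisymmetrized, $(\theta(\mathbf h) -
  \theta(-\mathbf h))/\sqrt 2$, which preserves the marginal variance and
  zeroes self-conjugate terms.
* Truncation keeps terms with $d \ge d_{\min} - 10^{-9}$ and is idempotent;
  `map_to_coeffs()` refuses $d_{\min}$ below the per-axis Nyquist limit
  (box-diagonal terms extend beyond it and are retained when present).
* Argmax ties break toward higher B everywhere.

## Known limitations

* Non-orthogonal cells, symmetry expansion and map resampling are out of
  scope; inputs on different grids are not interpolated.
* Half-map sharpening requires a model for its amplitude normalization.
* The local-sharpening boxes reuse the global resolution; no local
  resolution estimation is attempted.
* `d_cut` and `k` are taken as fixed (resolution and 10 Å⁻¹); only the
  sharpening B is optimized.
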