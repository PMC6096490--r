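# sharpmax

Automated sharpening of cryo-EM (and crystallographic) density maps by
maximizing detail and connectivity.

## The problem

Cryo-EM reconstructions have resolution-dependent noise, so the level of
"sharpening" — rescaling the map's Fourier amplitudes to emphasize or
suppress high-resolution terms — strongly affects how interpretable the map
is. Too little sharpening hides side-chain detail; too much fragments the
density into disconnected islands. `sharpmax` chooses the sharpening level
automatically, for people building or validating atomic models in density
maps, and provides half-map-, model- and kurtosis-based sharpening as
alternatives, optional local (per-box) sharpening, and a model-based map
quality metric.

## The method

A map is a Fourier series; each term at resolution *d* (Å) is scaled by

    A(d) = w_s(d) exp(+B_sharpen / 4d^2)  +  w_b(d) exp(-B_blur / 4d^2)

where the weights `w_s`, `w_b` cross over (equal at `d = d_cut`, steepness
`k`) so that sharpening acts at low resolution and a soft resolution limit
(`B_blur = 200 A^2` by default, a ~259-fold attenuation at 3 Å) acts at high
resolution. `B_sharpen` is the one tuned parameter: candidate overall B
values are scanned (−100 to 300 Å² in 20 Å² steps by default) and each
candidate map is scored by its **adjusted surface area**

    SA_adjusted = SA − C_scale · N_regions

where SA is the iso-contour surface area at the threshold enclosing 20 % of
the molecular volume (detail) and `N_regions` the number of contiguous
contour regions (fragmentation). `C_scale` is calibrated per map so the
objective is equal at the scan extremes; the chosen B maximizes it. A
signal-to-noise test declines maps where the objective has no clear interior
maximum. Map quality is evaluated as the real-space correlation, near the
atoms, between a map and a model-computed map with all atomic B values set
to zero.

## Worked example

Everything below runs on a generated fixture with known ground truth — a
200-atom pseudo-chain in a 60³ map at 1 Å spacing, blurred to an overall B
of 120 Å² with added noise:

```r
library(sharpmax)
spec <- synthetic_spec(n_atoms = 200, true_b = 120, noise_sigma = 1, seed = 7)
fx   <- make_synthetic_map(spec)          # $map, $model, $truth
res  <- auto_sharpen_sa(fx$map, resolution = 3)
res$trace
#> <optimization_trace> 21 candidates, b0 = 47.8 A^2
#>   C_scale = 11.375, signal = 2198.0, noise = 708.08, applicable: TRUE
#>   chosen overall B = -20.0 A^2
#>    b_candidate    b_fitted surface_area n_regions  kurtosis sa_adjusted
#> 1         -100 -100.236651        46099      3948  5.246325   1188.8738
#> 4          -40  -38.622989         4653       112 16.289040   3378.9539
#> 5          -20  -17.745509         3967        51 26.384998   3386.8540
#> 6            0    3.273457         3640        49 39.159642   3082.6048
#> 11         100  105.668591         1807        10 61.933868   1693.2459
#> 21         300  331.249153         1223         3 49.057600   1188.8738
```

(rows abridged). Reading the trace: as the candidate overall B decreases the
surface area grows (more detail) but below about −40 Å² the region count
explodes (46099 surface points but 3948 fragments at −100 Å²) — the
calibrated objective `sa_adjusted` peaks in between, here at −20 Å², and its
endpoints are equal by construction (1188.87 at both extremes). The
signal-to-noise of the peak (2198 / 708 ≈ 3.1) passes the applicability
test. The quality metric confirms the choice:

```r
map_model_cc_zero_b(fx$map, fx$model, 3)   # 0.725  (input map)
map_model_cc_zero_b(res$map, fx$model, 3)  # 0.896  (auto-sharpened)
```

Half-map, model-based, kurtosis and local variants:

```r
halves <- make_half_maps(fx$truth, noise_sigma = fx$noise_sd, seed = 2)
hm <- halfmap_sharpen(map_to_coeffs(fx$map, d_min = 3),
                      halves$half1, halves$half2, fx$model, resolution = 3)
ms <- model_sharpen(map_to_coeffs(fx$map, d_min = 3), fx$model, resolution = 3)
lk <- local_sharpen(fx$map, 3, method = "sa")    # per-box, recombined
```

A command-line wrapper is installed with the package
(`system.file("exec", "sharpmax", package = "sharpmax")`; in the source tree,
`exec/sharpmax`):

```sh
sharpmax --map in.mrc --resolution 3.0 --method sa --out sharp.mrc --trace trace.csv
```

It exits 0 with a `status: declined` message when the applicability test
fails, leaving the map unchanged.

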