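# arttomo

Simulation and reconstruction toolkit for 2D parallel-beam computed
tomography, built around the question that drives low-dose lung HRCT:
*how much better does iterative algebraic reconstruction hold up than
filtered back projection when the dose is low and the angular range is
restricted?*

The package provides, end to end:

* **Phantoms** — deterministic ellipse/annulus/polyline/patch renderers
  (pixel-center inclusion), the classical ten-ellipse head phantom, and a
  seeded lung-slice phantom carrying the expiratory-HRCT signs of
  obliterative small-airway disease: mosaic low-attenuation patches,
  thick-walled airway rings, thin vessel lines.
* **Geometry** — sparse system matrices `R` with exact strip (area-ratio)
  or line (chord-length) weights, and forward projection `p = R x`
  (the discrete Radon transform).
* **Reconstruction** — Kaczmarz ART
  `x ← x + λ (pᵢ − ⟨aᵢ,x⟩)/‖aᵢ‖² aᵢᵀ` with relaxation, cycle averaging
  for incompatible systems, and a row-norm guard for grazing rays; SIRT;
  smoothness-regularized least squares
  `min ‖p − Rx‖² + w·xᵀ(B + I)x` with `B` the 4-neighbour graph
  Laplacian; and FBP (ramp / Shepp–Logan / Hann) as the analytic
  baseline.
* **Low-dose noise** — Beer–Lambert Poisson counts
  `N ~ Poisson(I₀ e⁻ᵖ)`, `p' = −ln(N/I₀)`, seeded and reproducible.
* **Metrics** — MSE, EMSE (=√MSE), ISNR, PSNR, windowed SSIM, line
  profiles with total variation.
* **Experiments** — scripted comparison and semi-convergence studies with
  YAML manifests that make every run bit-reproducible.

## Worked example

Low-dose (I₀ = 10⁵ photons/bin) limited-angle (views 0°–89°) acquisition
of a 64×64 lung phantom, reconstructed with 30 sweeps of ART and with
ramp-filtered FBP:

```r
library(arttomo)

cfg <- bo_protocol(grid_size = 64, phantom_seed = 7, noise_seed = 11)
out <- run_comparison(cfg)
out$metrics
#>   algorithm metric       value
#> 1       ART    mse  0.01061425
#> 2       ART   emse  0.10302547
#> 3       ART   psnr 19.74110800
#> 4       ART   ssim  0.52398274
#> 5       FBP    mse  0.03342853
#> 6       FBP   emse  0.18283471
#> 7       FBP   psnr 14.75882693
#> 8       FBP   ssim  0.33745309
```

ART reaches roughly a third of FBP's mean squared error (≈ 5 dB PSNR
advantage) and half again its structural similarity: under angular
truncation and counting noise the row-action solver degrades far more
gracefully than analytic back projection, whose reconstruction is
dominated by limited-angle streaks. The same run shows the stability
difference along a fixed cut:

```r
total_variation(line_profile(out$results$ART$image, 32, "row"))
#> [1] 3.879794
total_variation(line_profile(out$results$FBP$image, 32, "row"))
#> [1] 4.514898
```

Iterating ART longer is not monotonically better on noisy data:

```r
curves <- run_convergence_study(bo_protocol(art_sweeps = 400L))
noisy <- subset(curves, variant == "noisy")
noisy$sweep[which.min(noisy$mse)]
#> [1] 170
```

the per-sweep MSE bottoms out near sweep 170 and then grows as the
iteration starts reproducing the noise (semi-convergence), while the
noiseless control curve never increases.

A thin CLI over the same functions lives at `inst/cli/arttomo`
(`phantom`, `project`, `noise`, `recon`, `metrics`, `compare`,
`converge` subcommands).

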