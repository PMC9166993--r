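---
title: "Methods: simulation and algebraic reconstruction of low-dose lung CT"
author: "arttomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and algebraic reconstruction of low-dose lung CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-resolution CT of the lung resolves small-airway disease — mosaic
perfusion from air trapping, thickened bronchiolar walls, attenuated
vessels — but the thin-slice, high-frequency protocols it needs are dose
expensive, which matters most in pediatric imaging. One route to dose
reduction is to acquire fewer or noisier projections and lean on the
reconstruction algorithm. `arttomo` is a desk-scale laboratory for that
trade: it simulates 2D parallel-beam acquisitions of lung-like phantoms,
degrades them with a photon-counting noise model, reconstructs with both
the classical analytic method (filtered back projection, FBP) and
iterative algebraic methods (ART/Kaczmarz, SIRT, regularized least
squares), and quantifies the results with a standard image-quality suite.

## Projection model

The image is a square grid of attenuation values $x_j$ (pixel side
$\delta$), flattened column-major into $x \in \mathbb{R}^n$. A view at
angle $\theta$ sends parallel rays in direction
$(\cos\theta, \sin\theta)$; a point $(x, y)$ projects to detector
coordinate $t = -x\sin\theta + y\cos\theta$. Each detector bin of pitch
$\Delta s$ defines a strip, and the measurement model is the linear system

$$ p = R x, \qquad
   r_{ij} = \frac{\text{area}(\text{strip}_i \cap \text{pixel}_j)}{\delta^2}. $$

The area-ratio ("strip") weights are the default because they model a
detector of finite aperture exactly on a pixel basis; a zero-width
("line") model with chord-length weights is provided for cross-checks
against line-integral formulas. The strip weight reduces to a closed
form: the overlap area of a half-plane with an axis-aligned square is the
CDF of the sum of two independent uniform variables (a trapezoidal
distribution), so each weight is a difference of two trapezoid CDFs. This
is exact, vectorizes over pixels, and is validated entrywise (to $10^{-9}$)
against an independent Sutherland–Hodgman polygon-clipping oracle in the
test suite. Rays are indexed angle-major; both orderings are recorded in
the `system_matrix` object so $R$, $x$ and $p$ always agree.

Conventions chosen once and used everywhere: grid centered on the origin,
x right, y up, row 1 at the top; angles in degrees counterclockwise from
+x; detector array centered on the origin with an odd default bin count so
one bin straddles the center.

## Kaczmarz ART

The algebraic reconstruction technique treats each ray as a hyperplane
$\langle a_i, x\rangle = p_i$ and repeatedly projects the estimate onto
them:

$$ x_{k+1} = x_k + \lambda\,
   \frac{p_i - \langle a_i, x_k\rangle}{\lVert a_i\rVert^2}\, a_i^T . $$

With relaxation $\lambda = 1$ each update satisfies its equation exactly;
$\lambda \in (0, 2)$ trades speed against noise smoothing. On compatible
(consistent) systems the iterates converge to a solution — from a zero
start, to the minimum-norm solution, which the tests verify against the
SVD pseudoinverse. On incompatible systems the iterates settle into a
cycle; `incompatible_mode = "cycle_average"` returns the mean of the
iterates over one further full sweep, which sits near the center of that
cycle and closer to the least-squares solution than any single iterate.

Numerical choices:

* $\lambda$ is held constant within a run.
* Zero-norm rows (rays that miss the grid) are skipped. Under noise this
  is generalized: rays with $\lVert a_i\rVert^2$ below
  `row_threshold` $\times$ the largest squared row norm (default $10^{-3}$)
  are also skipped. A corner-grazing ray has nearly zero coverage, so the
  division by $\lVert a_i\rVert^2$ turns a tiny measurement error into an
  arbitrarily large step; such rays carry almost no information and are
  standard casualties in row-action solvers. Setting `row_threshold = 0`
  restores the textbook iteration.
* Stopping: the run ends when the relative change of the per-sweep
  residual $\lVert Rx - p\rVert$ falls below `stop_tol`, or at
  `max_sweeps`. Convergence studies set `stop_tol = 0` to trace the full
  curve.
* Non-finite iterates abort with the sweep number.

SIRT applies all residuals simultaneously,
$x \leftarrow x + \lambda C^{-1} R^T W^{-1}(p - Rx)$ with $W$/$C$ the
diagonal row/column sums — smoother, strictly sweep-parallel, slower. The
regularized least-squares route minimizes
$\lVert p - Rx\rVert^2 + w\,x^T(B + I)x$ by a sparse Cholesky solve of the
normal equations. $B$ is the graph Laplacian of the 4-neighbour pixel
grid, so $x^TBx$ sums squared differences of adjacent pixels — the natural
operator for "local uniformity between each pixel and its neighbours" —
and the identity term penalizes overall magnitude. The default weight
$w = 0.01\,\mathrm{tr}(R^TR)/n$ scales the penalty to the data term.

## FBP baseline

FBP filters each view in the frequency domain (ramp by default;
Shepp–Logan and Hann apodizations available) after zero-padding to a power
of two, then back-projects with linear interpolation, scaled by
$\pi / (2 N_{\text{views}})$ under the convention that views sample
$[0, 180°)$. With a limited angular range this produces the familiar
streak-and-blur anatomy of limited-angle FBP — deliberately so, since FBP
is the comparison baseline, not the object of study. Strip sinograms are
converted to line-integral units ($\times\,\delta^2/\Delta s$) before
filtering. The implementation is validated against the analytic interior
value of a centered disk (within 5% at full angle) and conserves the
phantom's total attenuation over its support to within 5% on full-angle
noiseless data.

## Low-dose noise model

"Poisson noise" is realized in the intensity domain through Beer–Lambert:
for a clean line integral $p$, the detected count is
$N \sim \text{Poisson}(I_0 e^{-p})$, clamped to at least `floor` (default
1, so the log stays finite under photon starvation), and the noisy line
integral is $p' = -\ln(N / I_0)$. The perturbation variance is
approximately $e^{p}/I_0$: noise grows with attenuation and shrinks with
dose, which is what makes low-dose CT hard. The default
$I_0 = 10^5$ photons per bin puts chest-like paths (total attenuation
$\approx 5$–6, transmission $e^{-5}$–$e^{-6}$) at relative line-integral
errors of a few percent — visibly noisy, not starving. A variance-matched
additive-Gaussian mode exists purely for cross-checks. All draws come from
R's Mersenne–Twister generator under one explicit seed, and the RNG state
of the caller is restored afterwards.

## Phantoms

Rendering is by pixel-center inclusion — a pixel takes an element's value
iff its center is inside the element — with no anti-aliasing. That matches
the discrete pixel model of the system matrix and keeps brute-force
enumeration oracles exact. Primitives: ellipses, annuli, stroked
polylines, disk patches; painted in order, replace or additive.

`make_lung_phantom()` composes a thorax-like slice carrying the three
expiratory-HRCT signs of obliterative small-airway disease: low-value
disk patches inside the lung fields (mosaic perfusion / air trapping,
value 0.03 against lung 0.08), thick-walled rings (bronchiolar
cross-sections, wall 0.35 around an air lumen, wall thickness at least one
pixel), and thin bright polylines (vessels, 0.30). Values are normalized
to $[0, 1]$ (soft tissue 0.5); the physical extent is fixed at 12 length
units across the grid so that peak ray attenuation lands in the chest-like
regime above. Placement is randomized from one seed; a manifest (class,
center, size, value per element) accompanies the image so structures can
be masked in analyses. What this phantom does *not* emulate: anatomic
airway trees, gravity-dependent gradients, beam hardening, scatter,
detector cross-talk, or 3D partial-volume effects — conclusions from
passing tests are about reconstruction algebra and noise response, not
about clinical image quality.

## Image-quality metrics

MSE is the plain pixel mean of squared differences; EMSE is defined here
as $\sqrt{\mathrm{MSE}}$, the same error on the intensity scale;
ISNR $= 10\log_{10}(\mathrm{MSE_{in}}/\mathrm{MSE_{out}})$ compares a
baseline against an improved reconstruction; PSNR
$= 10\log_{10}(L^2/\mathrm{MSE})$ uses the *declared* dynamic range $L$ of
the reference by default (deterministic and independent of the candidate;
the observed-maximum reading is available via `peak_mode = "observed"`).
SSIM uses a uniform $7\times 7$ sliding window, $k_1 = 0.01$,
$k_2 = 0.03$, sample (n−1) moments including the covariance term, averaged
over all windows; it is checked against an independent double-loop
implementation and equals 1 exactly on identical images. Line profiles
plus total variation summarize profile stability.

## The replication protocol

The scripted experiments compare ART and FBP on a 64×64 lung phantom
under a low-dose, angle-restricted acquisition:

* **"90° projection angle"** is ambiguous between an angular *range* and a
  view *count*. The primary reading here is views $0°..89°$ at 1° steps —
  a true limited-angle problem, the harder and more interesting regime.
  The secondary reading (90 views spread over $[0°, 180°)$, a sparse-view
  problem) is available as `angle_mode = "sparse"`.
* Comparison runs use 30 ART sweeps at $\lambda = 1$ — near the quality
  plateau, far from the noise-fitting regime.
* The semi-convergence study runs 400 sweeps with per-sweep snapshots: on
  noisy limited-angle data the MSE-vs-sweep curve falls, bottoms out
  (around sweep 160–240 at these settings), then rises as the iteration
  starts fitting noise; the noiseless control is provably non-increasing
  (each Kaczmarz projection is non-expansive toward every solution, and
  the true image solves the consistent system). The sweep budget must
  comfortably exceed the turn for the phenomenon to be visible; 400 does.

Problem sizes throughout (64×64 and 128×128 grids, ≤ 180 views, ≤ 400
sweeps) are chosen so every experiment runs in seconds to a couple of
minutes on one core; they are an order of magnitude below clinical matrix
sizes but large enough that limited-angle conditioning, semi-convergence
and FBP streaking all behave as they do at scale.

## Worked example

```{r example}
library(arttomo)

cfg <- bo_protocol(grid_size = 64, phantom_seed = 7, noise_seed = 11)
out <- run_comparison(cfg)
out$metrics

curves <- run_convergence_study(cfg)
noisy <- subset(curves, variant == "noisy")
noisy$sweep[which.min(noisy$mse)]   # the semi-convergence turn
```

## Known limitations

* 2D parallel beam only — no fan/cone geometry, no 3D.
* The explicit sparse system matrix is the design point (Kaczmarz needs
  row access); it caps practical grids at a few hundred pixels per side.
* Pixel-center rendering quantizes element boundaries at the pixel scale;
  analytic-oracle comparisons carry an $O(\delta)$ discretization term.
* The noise model is pure counting statistics: no electronic noise floor,
  no detector blur, no scatter.
* `ray_order = "shuffled"` changes the iterate path (not the consistent
  limit); reproducibility then depends on the recorded seed.
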