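---
title: "Stochastic variance-reduced reconstruction with the relative difference prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic variance-reduced reconstruction with the relative difference prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrdp)
```

## The reconstruction model

PET reconstruction with a smoothing prior is the constrained optimisation
problem

$$x^\* \in \arg\min_{x \ge 0} \; D(Ax + r,\, y) \;+\; \beta\, S(x),$$

where $y$ are the measured Poisson counts in a view-binned sinogram, $A$ is
the linear forward model (geometry, resolution blur, attenuation), $r > 0$
is the known additive expectation of scattered and random coincidences, and
$D$ is the Kullback--Leibler data fidelity

$$D(Ax+r, y) = \sum_j d(A_j x + r_j,\, y_j), \qquad
d(s,t) = s - t + t \log(t/s)$$

(with the usual extended-real conventions at $s = 0$ or $t = 0$;
`kl_term()`). Because $D$ is a sum over sinogram bins it splits over view
subsets $S_1, \dots, S_n$, which is what every subset algorithm in this
package exploits.

The regulariser is the relative difference prior (RDP, `rdp_params()`):

$$S(x) = \tfrac12 \sum_i \sum_{j \in N_i} w_{ij}\,\kappa_i \kappa_j\,
\frac{(x_i - x_j)^2}{x_i + x_j + \gamma |x_i - x_j| + \varepsilon}.$$

Its essential scalar kernel is $\phi(s, d) = d^2 / (s + \gamma|d| +
\varepsilon)$: for pair sums $s$ large against $\gamma |d|$ it is a
quadratic penalty damped by the local activity (hence "relative
difference"), while for $s \ll \gamma|d|$ it flattens into a total-variation
regime $\phi \approx |d|/\gamma$. The closed forms used throughout are,
with $u = s + \gamma|d| + \varepsilon$ and $c = 1 + \gamma\,\mathrm{sign}(d)$:

* gradient contribution at voxel $i$: $(2du - d^2 c)/u^2$;
* diagonal Hessian contribution at voxel $i$:
  $2(u - cd)^2/u^3 = 2(2x_j + \varepsilon)^2/u^3$,

which is strictly positive for $\varepsilon > 0$ — the property that makes
the prior-aware preconditioner below well defined everywhere. Both forms
are validated against central finite differences in the test suite (and
nowhere else: no closed-form reference for the derivatives is assumed).

### Parameters of the prior

* `gamma` (default 2): edge preservation; larger values push the penalty
  toward total variation sooner. The default follows common RDP practice.
* `epsilon` (default `1e-9`, squared-activity units): smoothing constant.
  It only matters where *both* voxels of a pair are nearly zero; there the
  diagonal curvature grows like $2/\varepsilon$, a property with real
  numerical consequences discussed below.
* `kappa` (default 1): per-voxel weight factors $\kappa_i$. These are
  accepted as input; the benchmark harness derives them from the data (see
  below). `sign(0) = 0` is used, so the gradient is continuous at equal
  neighbours.
* Neighbourhoods: 8 neighbours in 2D, 26 in 3D, with $w_{ij}$ the inverse
  Euclidean voxel distance; neighbours outside the grid are skipped, which
  keeps $w$ symmetric without padding.

## The stochastic loop

All solvers share the projected, preconditioned stochastic gradient update
(`run_algorithm()`, `prox_step()`):

$$x^{(k+1)} = \max\!\big(0,\; x^{(k)} - \tau^{(k)} D^{(k)} \tilde\nabla^{(k)}\big),$$

where $\tilde\nabla^{(k)}$ estimates the gradient of the smooth objective
from one view subset per update:

* **SGD**: $n \nabla J_{i_k}(x^{(k)})$ — cheap, high variance;
* **SAGA**: a per-subset gradient table $g_i$, estimator
  $n(\nabla J_{i_k}(x) - g_{i_k}) + \sum_i g_i$, table entry $i_k$
  refreshed after each update. The table is initialised with the subset
  gradients at the starting image so the first estimator is exact;
* **SVRG**: a snapshot image $\hat x$ with stored subset gradients
  $\hat g_i$, estimator $n(\nabla J_{i_k}(x) - \hat g_{i_k}) + \hat g$,
  snapshot refreshed every $\omega n$ updates ($\omega = 2$ by default,
  including a snapshot at $k = 0$). The in-memory variant stores all
  $\hat g_i$; a low-memory variant recomputes them from $\hat x$ and is
  bit-identical.

All three estimators are unbiased; the tests verify this by enumeration
over all subset draws on small problems. Iteration accounting: $k$ counts
subset updates from 0 and an epoch is $n$ updates; preconditioners are
recomputed at the *start* of the epochs in `precond_update_epochs` and BB
stepsizes at the *end* of the epochs in `bb_epochs` (preconditioner first
when both land on the same boundary, which is how the two schedules
interleave at snapshot points).

### Preconditioners

`mlem_preconditioner()` is the classic EM diagonal
$D_{\mathrm{MLEM}}(x) = (x + \delta)/(A^\top 1)$. It knows nothing about
the prior. `harmonic_preconditioner()` blends in the prior's diagonal
curvature through half the harmonic mean,

$$D(x) = \big(D_{\mathrm{MLEM}}^{-1}(x) + \alpha\,
\mathrm{diag}(H_{\beta S}(x))\big)^{-1}
= \frac{x + \delta}{A^\top 1 + \alpha\, \mathrm{diag}(H_{\beta S}(x))\,(x+\delta)},$$

so that $D \le \min(D_{\mathrm{MLEM}}, \alpha^{-1} D_{\beta S})$
componentwise: wherever either the data or the prior sees high curvature,
steps shrink accordingly. Defaults: $\alpha = 1$ (the combination weight is
left free by the method; unit weight treats both curvature estimates as
equals) and $\delta = 10^{-6} \times$ the mean of the starting image
(relative scaling keeps behaviour independent of activity units; with
$\delta = 0$ and a positive image the loop with $\tau = 1$, $n = 1$,
$\beta = 0$ reduces *exactly* to MLEM, a property the tests assert to
`1e-10`).

### Stepsizes

`vanishing_stepsize()` implements $\tau^{(k)} = \tau^{(0)}/(1 + \eta k/n)$;
$\eta = 0.02$ gives the gentle decay used in the benchmark.
`alg1_stepsize()` is the fixed piecewise schedule
$3 \to 2 \to 1.5 \to 1 \to 0.5$ with breakpoints at $k = 10, 100, 200,
300$. `capped_bb_stepsize()` applies phase caps $3$, $2.2$, $1$ (switching
at $k = 10$ and $k = 2n$) to the most recent short-form Barzilai--Borwein
value $\tau = p^\top q / q^\top q$, computed from consecutive SVRG
snapshots ($p$ the snapshot image difference, $q$ the full-gradient
difference, plain Euclidean inner products). Non-positive or undefined BB
ratios leave the previous stepsize in place; before the first BB value the
caps themselves are used.

A desk-scale caveat the package makes no attempt to hide: with
$\varepsilon = 10^{-9}$ the prior is nearly kinked where neighbouring
voxels are both close to zero, so the Euclidean BB ratio is dominated by
those huge-curvature components and collapses to very small values at
strong regularisation — the capped-BB presets then crawl while the fixed
ALG1 schedule converges quickly. This is an amplified version of the
general observation that adaptive BB schemes lose to constant or decaying
stepsizes in the medium-to-high regularisation regime; at desk scale the
effect is extreme.

### Subset orderings

`partition_views()` forms subsets from every $n$-th view, so each subset
spans the angular range. The order in which subsets are visited comes from
`new_sampler()`:

* `herman_meyer`: the classic deterministic order built from the prime
  decomposition of $n$;
* `uniform_with` / `uniform_without`: i.i.d. draws / a fresh permutation
  per epoch;
* `fixed_without`: one permutation drawn at creation and reused every
  epoch (the "fixed random sequence" of the ALG1/ALG2 presets);
* `importance`: draws proportional to subset gradient norms
  ($p_i = \|\nabla J_i\| / \sum_j \|\nabla J_j\|$), refreshed at SVRG
  snapshots where those gradients are available for free;
* `cofactor`: each epoch traverses the cyclic group
  $(0, g, 2g, \dots) \bmod n$ with the next generator $g$ from a ranked
  list of all integers $1 < g < n$ coprime with $n$.

The cofactor ranking orders generators by proximity to the two reference
points $0.3n$ and $0.7n$: each generator is assigned to its nearer
reference point, each part is sorted by distance (ties toward the smaller
integer), and the parts are interleaved starting from the $0.3n$ side.
For $n = 15$ this yields generators $\{2,4,7,8,11,13,14\}$ ranked as
$(4, 11, 2, 8, 7, 13, 14)$ and a first traversal
$0,4,8,12,1,5,9,13,2,6,10,14,3,7,11$. The interleaving rule is one
reconstruction of a ranking that is only loosely specified; it is pinned
down by exactly this worked example. The trivial generator 1 is excluded
(a stride of 1 is sequential access, which the ordering exists to avoid).
Every sampler owns a private RNG stream derived from its seed, so runs
are bit-reproducible and never disturb the global RNG.

## The simulation benchmark

`setup_benchmark()` builds the whole desk-scale study: phantom, forward
model, acquisition, prior weights, and objective bundle.

* **Phantom** (`default_phantom_spec()`): 64 x 64 voxels at 2.5 mm, a
  large elliptical background (activity 1, semi-axes 70 x 55 mm), two hot
  inserts (activities 3 and 2) and one cold insert (0.25). Later ellipses
  overwrite earlier ones, and the NRMSE mask is the union of all ellipse
  supports — the cold surround outside the phantom is excluded from
  scoring. The normalisation value is the activity of the largest-area
  (background) ellipse.
* **Forward model** (`build_projector()`): an explicit sparse matrix
  $A = P\,G\,B$ with $G$ a pixel-driven parallel-beam projector (96 views
  over $[0, \pi)$, 128 radial bins at the voxel pitch), $B$ a 4 mm FWHM
  Gaussian image-space resolution model, and $P$ water-attenuation factors
  ($\mu = 0.0096\,\mathrm{mm}^{-1}$ over the phantom support). The
  explicit matrix makes the adjoint exact and subset restrictions trivial.
* **Acquisition** (`simulate_acquisition()`): the noise-free sinogram is
  scaled to 3e5 expected true counts, a smooth background (a heavily
  blurred copy of the trues, floored to stay strictly positive) adds 25%
  of total counts, and Poisson counts are drawn with a seeded, isolated
  RNG. The background is stored exactly, as the model assumes.
* **Count-level scaling**: `scale_beta()` maps the relative strength
  $\tilde\beta$ to $\beta = \tilde\beta \times 2\times 10^{-4} \times
  (\text{true counts})/(3\times 10^7)$, so runs at different count levels
  with the same $\tilde\beta$ are comparably resolved.

### Why the harness calibrates kappa

The $\kappa_i$ weights are free inputs of the prior. The harness supplies
the field-standard perturbation-response surrogate
$\kappa_j = \sqrt{[A^\top \mathrm{diag}(y/\hat y^2) A\, 1]_j}$ (the square
root of the data-Hessian row sums at the OSEM initialiser,
`kappa_perturbation()`), which matches the prior's spatial weighting to
the local information density. The *overall scale* of $\kappa$ is then
fixed by one design constant: the median ratio of prior to likelihood
diagonal curvature over the phantom support equals 0.1 at
$\tilde\beta = 1$ (`kappa_target_ratio`). The $\tilde\beta$ sweep
$\{1, 4, 16\}$ then spans weak (0.1) to strong (1.6) regularisation
relative to the data curvature, independently of the count level and of
this grid's particular size. Without this normalisation the reference
point of the $\beta$ scaling rule — which encodes a full-size scanner
geometry — leaves the prior numerically irrelevant on a 64 x 64 grid, and
no regularisation regime exists to study.

### The reference solver

`reference_reconstruction()` provides the converged target $x^*$ for
NRMSE tracking: bound-constrained L-BFGS-B for 500 iterations, run in
diagonally rescaled variables $z = x/s$, $s = 1/\sqrt{\mathrm{diag}\,H}$,
with the scaling refreshed over four restarts. The rescaling is essential,
not cosmetic: the prior's diagonal curvature spans roughly nine orders of
magnitude between active regions and near-zero background (the
$2/\varepsilon$ effect), and an unpreconditioned quasi-Newton run stalls
measurably short of the optimum — visible as a reconstruction whose
objective is *higher* than what the stochastic loop itself reaches. The
tests verify the reference through its KKT conditions (projected gradient
norm below $10^{-4}$ of the initial) and through agreement of two runs
from different starts.

### Scoring

`nrmse()` is the root mean square difference over the phantom mask,
divided by the background-ellipse activity; the convergence marker is
NRMSE $< 0.01$ against the reference. `run_algorithm()` logs stepsize,
subset, objective and NRMSE per update into a tibble (`tidy()`,
`glance()`, `autoplot()`), stops early at the threshold, and aborts with
a `diverged` flag if the objective exceeds ten times its initial value.

## Problem sizes and what the benchmark does and does not show

The shipped study conditions are: one 64 x 64 phantom dataset (fixed
acquisition seed), 24 subsets (the divisor of 96 views closest to 25;
16 for the seed-stability check), $\tau^{(0)} = 1$ with decay
$\eta = 0.02$, up to 100 epochs, the 500-iteration reference, and five
sampler seeds where run-to-run variation is assessed. These sizes keep a
full benchmark sweep within a few minutes on one core while leaving the
optimisation structure (Poisson fidelity, strong prior, subset variance)
intact.

Desk-scale simulation shares the paper-grade simulation's *inverse crime*:
data are generated by the same linear model used for reconstruction, so
nothing here measures model mismatch, scatter estimation, detector
effects, or time-of-flight. Orderings between algorithms (variance
reduction vs plain SGD; preconditioner variants; sampler variants) are
the meaningful output; wall-clock times and absolute update counts are
not transferable to scanner-scale problems. Two desk-scale findings
deserve emphasis because they *differ* from the full-scale behaviour
under the committed conditions: the EM-only preconditioner remains stable
at the strongest regularisation tested (the step-curvature product stays
near 1, so the overshoot mechanism that breaks it at scale never
triggers), and the Euclidean short-BB stepsize collapses rather than
hovering near 1. Both are documented outcomes of the committed study
conditions rather than adjustable results.

## A short worked run

```{r example, eval = FALSE}
su  <- setup_benchmark(default_phantom_spec(beta_tilde = 16), data_seed = 1)
ref <- benchmark_reference(su, iterations = 500)

cfg <- recon_config(estimator = "svrg", precond_kind = "harmonic",
                    stepsize_kind = "vanishing", tau0 = 1, eta = 0.02,
                    seed = 1, objective_every = su$bundle$n_subsets)
fit <- run_algorithm(su$bundle, cfg, reference = ref,
                     x0 = as.array(su$osem_init))
glance(fit)
autoplot(fit)
```

The `glance()` row reports the updates needed to cross the NRMSE
threshold; `autoplot()` draws the NRMSE trajectory on log-log axes with
the threshold line. The same comparison over estimators, preconditioners
and seeds is automated by `run_experiment_grid()`, and the numbers the
package stands behind are recomputed from scratch by
`scripts/acceptance.R` and the test suite.

## Known limitations

* 2D geometry only in the projector (the prior and solvers handle 3D
  arrays); no time-of-flight, no detector-pair geometry, no
  normalisation-factor modelling.
* The proximal operator of the RDP is not implemented (only gradients and
  diagonal curvature are cheap); non-smooth and anatomical priors are out
  of scope.
* The explicit sparse system matrix is the right tool up to roughly
  128 x 128 grids; beyond that a matrix-free projector would be needed.
* `capped_bb` stepsizes require the SVRG estimator, since BB differences
  are anchored at snapshot points.
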