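---
title: "Methods: response-time analysis and formulation optimization for halochromic films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-time analysis and formulation optimization for halochromic films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halochrom)
```

## The problem

A halochromic wound-pH sensor is a thin polymer film (polyvinyl alcohol
matrix, polyethylene glycol plasticizer, bromothymol blue dye) that changes
color with the pH of the fluid it touches. Two questions drive its design:

* **How fast does the film respond?** The *response time* is the time until
  the film's color trajectory settles after exposure to buffer — the
  completion of the yellow→green→blue transition across pH 6–10.
* **Which formulation responds fastest?** PEG concentration `x1` (6–10 %
  w/v) and BTB concentration `x2` (0.01–0.05 % w/v) are the free variables.

This package implements the full computational chain: feature extraction
from film images, response-time detection, channel selection, symbolic
regression of response time on formulation, metaheuristic minimization of
the fitted surface, and ANOVA validation. Raw experimental data are not
publicly deposited, so a synthetic-data module generates inputs with the
statistical structure the analysis assumes.

## Synthetic kinetics: the stated world

`generate_color_kinetics()` models each of the 12 color channels
(R, G, B, L, a, b, H, S, V, Y, Cb, Cr) as an independent logistic

$$v(t) = v_0 + \frac{v_\infty - v_0}{1 + e^{-r (t - t_0)}} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

sampled at one frame per second for 600 s, clipped to each channel's
admissible range after noise. The per-pH presets (`default_kinetics()`)
encode the qualitative kinetics of the film:

* **Plateau colors**: yellow at pH 6, green at pH 7, blue at pH 8–10 with
  the plateau hue increasing monotonically from pH 8 to pH 10. The pH 6
  transition is visually almost imperceptible (yellow to yellow).
* **Transition midpoints** `t0` (s): 90 (pH 6), 210 (pH 7), 120 (pH 8),
  150 (pH 9), 165 (pH 10) — fastest in acid, slowest at the buffering point
  pH 7, fastest alkaline response at pH 8.
* **Rate** `r = 0.05` s⁻¹, giving a 10–90 % transition width of ~90 s, so
  detected response times land in the observed 2–5 minute band.
* **Noise** `σ = 5e-4` channel units. Each frame's color is the mean over a
  segmented region of ~10⁴–10⁵ pixels, so frame-to-frame noise on the mean
  is far smaller than pixel noise. This choice also matters analytically:
  the detector thresholds the moving-averaged absolute gradient at 0.001
  per frame, and the expected absolute gradient of pure noise is
  $\sqrt{2}/2\,\sigma\sqrt{2/\pi} \approx 0.56\,\sigma$. At σ = 0.002 that
  expectation (≈0.0011) already exceeds the threshold and stabilization can
  essentially never be declared; at σ = 5e-4 (≈0.00028) the detector
  operates in its intended regime.

`generate_formulation_dataset()` draws the 180-record response table
(9 formulations × 5 pH × 4 replicates):
`y = surface(x1, x2) + ph_effect(pH) + N(0, noise_sd²)` with the published
closed-form surface as the default mean, pH offsets (−60, +80, −25, +15,
+35 s for pH 6–10) reproducing the observed pH ordering, and
`noise_sd = 100` s. Offsets plus noise give a within-cell SD of ≈111 s,
matching the scale implied by the published within-cell mean square
(14 043 s² → SD ≈ 119 s). These defaults are fixed once and not tuned.

**What the generator does not emulate:** channel cross-correlations induced
by a shared RGB trajectory (channels are independently logistic), hue
wrap-around, illumination drift, segmentation errors, or any
physical/chemical diffusion model of the dye. A green test therefore
establishes correctness of the *algorithms* on data with the assumed
structure, not reproduction of the original laboratory measurements.

## Stabilization detection

`detect_stabilization()` implements the steady-state rule: compute the
numerical gradient (central differences, one-sided at the ends; units are
channel units per frame at the 1 s frame period), take absolute values,
smooth with a centered moving average (window 10 frames, partial windows at
the edges), and declare stabilization at the first frame starting a run of
50 consecutive frames with smoothed |slope| < 0.001.

Two design points deserve mention:

* **Onset restriction.** A film that has not yet begun its transition is
  also quiet, so a literal "first qualifying run" fires at frame 1 whenever
  the recording starts before the transition. The search is therefore
  restricted to frames after *transition onset* — the first frame whose
  smoothed |slope| reaches the threshold. A series that never crosses the
  threshold (constant, or a visually imperceptible acid-side transition) is
  reported stabilized at the first frame. On a noiseless logistic the
  detected frame then equals the closed-form crossing of the analytic slope
  $|v'(t)| = |\Delta| r s(1-s)$ below the threshold, which is the oracle
  used in the tests.
* **Window length.** The moving-average window is not prescribed by the
  rule itself; 10 frames smooths frame-level noise without masking the
  50-frame run criterion. It is configurable via `stabilization_params()`.

The response time `y` is the stabilization time of the Hue channel (the
channel with the most distinct sigmoidal transition). Whether the original
analysis used Hue alone or a conjunction of the three discriminative
channels is not documented; `response_time(require_all = TRUE)` offers the
conjunction (H, S and a must all settle; `y` is the latest of the three),
with Hue-only as the default.

## Feature selection

`pca_correlation()` performs PCA on the *correlation* matrix. With 12
channels on wildly different scales (L in [0,100], a,b in [−128,127], the
rest in [0,1]) a covariance PCA would be dominated by L, a, b; the
correlation matrix also makes the Kaiser criterion (retain eigenvalues
strictly greater than 1, the variance of one standardized feature)
meaningful. Loadings are unit-norm eigenvectors, signed so that each
component's largest-magnitude loading is positive.

`relieff()` is the Kononenko multiclass ReliefF: for each instance, `k = 10`
nearest hits and, per other class, `k` nearest misses by Manhattan distance
on range-normalized features; hit differences decrease and prior-weighted
miss differences increase each feature's weight, scaled by `1/(m·k)`.
pH is treated as five discrete classes (consistent with a classification
reading of the task), all rows are used as instances by default (making the
result deterministic), and a zero-range feature contributes zero difference
— its weight is exactly 0. Weights are invariant to affine rescaling of any
single feature because distances are range-normalized.

## Multigene GP symbolic regression

A model is `y = b0 + Σ wᵢ gᵢ(x1, x2)` where each gene `gᵢ` is an expression
tree over `{+, −, ×, ln, (·)²}`, the variables and ephemeral constants in
[−10, 10]. The function set is the smallest one able to express every term
of the published response surface (products, squares, natural logs); gene
output weights and bias are re-fit by ordinary least squares at every
fitness evaluation (QR; a singular design falls back to a 1e-8 ridge and is
counted in `ridge_fallbacks`), and fitness is the training RMSE.

Evolution is generational with the published budget: population 100, 50
generations, tournament size 10, elitism 10 %, crossover 0.84 (half
gene-level recombination, half subtree crossover), mutation 0.14 (subtree
mutation, gene addition/deletion), reproduction 0.02, and a 10 % chance
that a tournament picks the lowest-RMSE individual among the
Pareto-nondominated contestants on (RMSE, total node count) — the
complexity measure for Pareto tournaments is total node count, which the
original description leaves unspecified. Structural caps (≤20 genes, tree
depth ≤10) are enforced on every offspring. Offspring whose genes evaluate
to non-finite values on any training point get infinite fitness rather than
repair. Evolution stops early once the best training RMSE reaches 1e-12 —
an exact interpolant has been found and further generations cannot improve
it. All 180 records are used for training (no train/validation split is
documented for the original fit); `train_rmse` is an optimistic estimate.

`model_to_expression()` renders a model with full-precision literals;
`evaluate_expression()` re-parses and evaluates it, and the round trip
agrees with `predict()` to 1e-9, which is the exactness contract for
exporting a fitted surface.

## The published response surface and its reconstruction

The exported fitness function is implemented as `fitness_eq2()`:

$$y = 4.34\times10^4 x_2 - 123 x_1 - 152\ln(x_1 + x_2 + \ln x_2 + x_2^2)
+ 1300\ln x_1 - 668\ln x_2 - 4.17\times10^4 x_1 x_2^2
+ 96.6 x_1^2 x_2 - 4740.$$

The flattened typesetting of the third term admits two groupings; the
implemented reading reproduces the published optimum value at the published
minimizer to the printed precision (188.595634 at (6, 0.020148)), whereas
the alternative grouping misses by ≈25, so the grouping and the natural-log
convention are settled numerically. Note that over the nine *discrete*
design formulations this surface is minimized at (6 % PEG, 0.03 % BTB) —
the continuous optimum ≈(6, 0.0201) lies between the tested BTB levels,
which is exactly why a continuous optimizer adds value over the grid of
tested formulations.

## Bird-inspired metaheuristics

`optimize_formulation()` implements three population minimizers with greedy
acceptance (a candidate replaces its parent only if it improves), bound
clamping (reflection available via `boundary = "reflect"`), and full seed
determinism:

* **Parrot Optimizer** — per individual, one of four behaviours chosen
  uniformly per iteration: foraging (Levy-flight move relative to best and
  flock mean), staying (perch near the best position), communicating
  (toward/away from the flock mean), fear of strangers (flight
  re-orienting toward the best).
* **Pelican Optimization Algorithm** — an exploration phase toward a random
  prey position (direction flipped when the prey is worse) and an
  exploitation phase in a shrinking neighbourhood of radius `0.2(1 − t/T)`.
* **Secretary Bird Optimization Algorithm** — a staged hunting phase
  (differential search between random members, then normal perturbations
  around the best, then Levy refinement of the best) and an escape phase
  mixing local moves around the best with flights relative to random
  members.

The update rules follow the original publications' described behaviours;
where an original leaves a run setting open, the defaults are population 30
and 100 iterations (the original study reports neither its population
sizes, iteration counts, nor repeat counts — these defaults are declared,
not inferred). Greedy acceptance makes the best-so-far curve non-increasing
by construction. On the reconstructed surface all three algorithms reach
the boundary optimum (6, ≈0.0201) in median over 10 seeds, agreeing with
the deterministic `grid_refine_minimize()` cross-check (exhaustive
2000-per-dimension grid plus per-coordinate window refinement, quartering
the window until it falls below 1e-8; ties during refinement keep the
incumbent coordinate, which preserves an exact boundary minimizer).

## Two-factor ANOVA

`two_factor_anova()` uses the classical balanced-design decomposition
(cell/marginal/grand means); it refuses unbalanced designs rather than
silently choosing a Type II/III convention, and flags the all-identical
degenerate case (F = NaN) with a warning. P-values and critical values come
from the F distribution (`pf`/`qf`, i.e. the regularized incomplete beta
function); the accuracy contract is 1e-6, not a named routine.
`complete_anova_table()` reconstructs the deterministic part of a published
table (MS, F, p, critical values) from printed sums of squares and degrees
of freedom. Display rounds to 2 decimals; full precision is kept
internally.

## Pipeline

`run_pipeline()` derives one seed per stage from the master seed in a fixed
order, so disabling a downstream stage cannot change upstream outputs, and
re-running any stage in isolation reproduces it exactly. Each stage output
is hashed into a provenance manifest; identical config + seed gives an
identical manifest. The interface is R functions (per-stage functions plus
the orchestrator); outputs can be written as CSV/JSON via `out_dir`.

Units and scales fixed across the package: BTB concentrations are on the
0.01–0.05 % w/v scale of the formulation table and the fitted surface (a
stock-solution 1–5 % scale also appears in the source protocol; the
package standardizes on the former, which is the scale the optimization
bounds and the surface coefficients use). Hue is stored as a fraction of
the hue circle in [0, 1) — with hue in degrees the 0.001 slope threshold
would be meaningless — and the hue of achromatic pixels is 0. Region
averaging is done in RGB *before* color-space conversion, which avoids hue
circular-mean artifacts.

## Known limitations

* Channel trajectories are generated independently, so synthetic H/S/V are
  not exactly consistent with synthetic R/G/B at intermediate frames.
* The GP search is stochastic; recovering the published surface
  symbol-for-symbol from data is not a goal (the surface itself is
  hard-coded as the reference objective).
* The metaheuristic implementations are structurally faithful to their
  originals but not line-by-line ports; they are validated behaviourally
  (sphere benchmark, agreement with the deterministic minimizer, dominance
  over random search at equal budget).
* Interactive segmentation is out of scope: film masks are inputs.
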