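---
title: "Reconstructing decision landscapes from cursor trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing decision landscapes from cursor trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decisionlandscape)
```

## The model

In a two-alternative mouse-tracking trial the cursor starts near the bottom
centre of the screen and ends at one of two response locations in the upper
corners. After spatial normalization the start sits at $(0,0)$ and the
targets at $(-1,1)$ and $(1,1)$. The package describes the cursor as an
overdamped particle on a potential surface $V(x,y)$:

$$\tau \dot x = -\frac{\partial V}{\partial x}, \qquad
  \tau \dot y = -\frac{\partial V}{\partial y}, \qquad \tau > 0 .$$

$V$ is split into a fixed baseline and a fitted coupling term,
$V = V_x(x) + V_y(y) + V_{xy}(x,y)$, with

$$V_x(x) = \frac{x^4}{4} - \frac{x^2}{2}, \qquad
  V_y(y) = \frac{y^3}{3} - \frac{y^2}{2},$$

chosen so that the gradient vanishes exactly on
$\{-1,0,1\}\times\{0,1\}$, the two target sites $(\pm 1, 1)$ are attractors
and the start $(0,0)$ is a repellor. The coupling term is a polynomial

$$V_{xy}(x,y) = \sum_{k=2}^{\alpha}\;\sum_{\substack{i+j=k\\ i,j\ge 1}}
  c_{ij}\,\frac{x^i y^j}{k-1},$$

whose order $\alpha \ge 2$ controls descriptive flexibility. At $\alpha=2$
the free parameters are $\tau$ and $c_{11}$; $\alpha=3$ adds $c_{21}$ and
$c_{12}$ (four parameters); $\alpha=4$ has seven. $c_{11}$ is the primary
left/right asymmetry parameter: with only $c_{11}$ nonzero,
$V(1,1)-V(-1,1) = 2c_{11}$, so a negative $c_{11}$ deepens the right-hand
well. $\tau$ (seconds) is a pure time scale — doubling it halves every model
velocity. This is a *descriptive* model of movement dynamics, not a process
model of the decision itself.

A note on the $1/(k-1)$ factor: it normalizes term magnitudes across
polynomial orders and reduces the $k=2$ term to plain $c_{11}xy$. Because it
is a fixed constant per term, any other convention only rescales the fitted
$c_{ij}$; the fitted surface is unchanged.

## Preprocessing

Raw logs are long-format delimited text (`participant`, `trial`, `t`, `x`,
`y`), one row per sample. The chain is:

1. **Rescale** (`rescale()`): affine map per axis taking the start to
   $(0,0)$ and the target row to $y=1$. The horizontal scale is the mean of
   the two start-to-target spans, so for layouts symmetric about the start
   (the typical paradigm) both targets land exactly on $x=\pm 1$; strongly
   asymmetric layouts map only approximately. Screen coordinates with a
   downward y-axis are flipped automatically by the signed vertical span.
2. **Trim** (`trim()`): the movement-initiation head (samples within
   `epsilon` of the first position) and the settled tail (samples within
   `epsilon` of the final position) are dropped, keeping one anchor sample
   on each side, and the clock is reset to $t=0$. `epsilon = 0.01`
   normalized units by default — 1% of the start-to-target half-width,
   well below deliberate-motion scale. A trial that never moves beyond
   `epsilon` is degenerate and rejected (the pipeline commands exclude and
   report such trials instead of failing).
3. **Resample** (`resample()`): linear interpolation onto a uniform grid of
   101 points (the mouse-tracking convention), preserving endpoints and
   total duration. Velocities are estimated *after* resampling, on the
   uniform grid.
4. **Velocity** (`estimate_velocity()`): Savitzky–Golay differentiation
   (window 7, polynomial order 2) by default — exact on locally quadratic
   signals and robust to jitter — or central finite differences
   (`method = "fd"`). Endpoints use the filter's own least-squares boundary
   treatment (or one-sided differences).
5. Optionally **mirror** (`mirror_to_canonical()`) so a designated reference
   option (e.g. the higher-reward one) always sits at $x=+1$; mirroring
   negates $x$ and flips the recorded choice.

The final-$x$ sign defines the choice; a trajectory ending exactly at $x=0$
is rejected as undetermined rather than assigned arbitrarily.

## Fitting by velocity matching

Rather than integrating the ODE inside the loss (accurate but expensive),
the fit matches velocities pointwise. For one trajectory with data
velocities $(v^{\mathrm{data}}_{x,i}, v^{\mathrm{data}}_{y,i})$ at positions
$(x_i, y_i)$,

$$H = \frac{1}{m}\sum_i
 \left(v^{\mathrm{model}}_x(x_i,y_i)-v^{\mathrm{data}}_{x,i}\right)^2 +
 \left(v^{\mathrm{model}}_y(x_i,y_i)-v^{\mathrm{data}}_{y,i}\right)^2,$$

where $v^{\mathrm{model}} = -\nabla V / \tau$ uses the *full* potential's
gradient and $m$ is the number of sample points actually summed (a true
mean; any fixed rescaling leaves the minimizer unchanged). For $N$
trajectories the objective is the plain average of per-trajectory $H$
values, so the fit is invariant to trajectory order and weights every trial
equally regardless of duration.

Numerical choices:

- The gradient of the objective in $(\tau, c_{ij})$ is analytic
  (`error_jacobian()`); tests verify it against central finite differences.
- `fit_landscape()` runs L-BFGS-B from the baseline start
  ($\tau_0 = 0.05$ s, all $c_{ij}=0$) with the analytic gradient,
  projected-gradient tolerance $10^{-8}$ and an iteration cap of 500.
- $\tau$ is optimized as $\log\tau$, which keeps the problem smooth and
  unconstrained; $\log\tau$ is boxed to $[-8, 4]$ so the degenerate case of
  near-zero data velocities (which pushes $\tau\to\infty$) is capped and
  flagged (`tau_at_bound`, `converged = FALSE`) rather than an error.
- Because the model velocity is linear in $(1/\tau,\, c_{ij}/\tau)$, the
  global optimum is also available as a linear least-squares solution; the
  test suite uses that closed form as an independent cross-check of the
  optimizer.

## Trajectory measures

`motion_time()` is the duration of the trimmed trajectory (cursor leaves the
start region → settles in the response area; no response-area radius is
assumed beyond the trim threshold). `max_deviation()` is the largest
perpendicular distance from the straight line between the trajectory's own
endpoints, signed **positive toward the non-chosen option** — so a
low-option trial deflected toward the high option carries a positive value.
That convention is deliberately mirror-*invariant*: flipping a trial left
to right (negating $x$ and the choice) does not change what "deflected
toward the alternative" means, so the signed value is unchanged, while the
screen-side deviation `choice * max_d` cancels exactly across mirrored
pairs. The chord reference degrades gracefully when endpoints are
imperfect; `reference = "diagonal"` measures from the idealized
$(0,0)\to(\pm 1,1)$ line instead (both are provided because either reading
of "ideal straight-line trajectory" is defensible; they coincide when the
endpoints are ideal). `summarize_measures()` produces the per-option
count/mean tables and choice percentages.

## The simulator

`simulate_trajectory()` integrates the deterministic field with classical
fixed-step 4th-order Runge–Kutta; `generate_dataset()` draws start offsets
around $(0,0)$ and stamps seeds for exact reproducibility. Defaults:
`dt = 0.001` s, `t_max = 5` s, `stop_radius = 0.05`,
`start_offset_scale = 0.02`, noise 0. With $\tau = 0.05$ these yield
arrival times of a few tenths of a second, the scale typical of real
two-choice cursor data. Vertical start offsets are kept nonnegative because
the cubic $V_y$ is unbounded below beneath the start row.

Termination: first entry into a `stop_radius` ball around either target,
`t_max`, or exit from a bounded arena
($x\in[-1.5,1.5]$, $y\in[-0.25,1.5]$ by default). The arena guard matters
because strong couplings genuinely tilt the field outward — e.g. with
$c_{11}=0.3$ the left attractor moves to roughly $(-1.25, 1.44)$ and
right-side starts can escape downward; the path up to the arena edge is
still a valid trial for velocity fitting, whereas integrating on would
diverge. A state that still becomes non-finite (arena disabled) raises a
numerical-blowup error naming the step; a start at a critical point with no
noise stalls and is reported as degenerate.

The optional noise is an additive isotropic $\sqrt{dt}$ perturbation of the
state per step (Euler–Maruyama-style, on top of the deterministic RK4
step) — the minimal mechanism for nonzero fitted residuals. What the
generator does **not** emulate: measurement jitter of real mice, pauses and
re-accelerations, change-of-mind reversals, or trial-to-trial parameter
drift. Passing recovery tests on simulated data therefore shows the
estimator is correct and well-conditioned, not that real trajectories obey
the model.

## Parameter recovery and problem sizes

The end-to-end check simulates 20 noise-free trials (mirrored start pairs,
`dt = 0.001`) from an order-3 landscape with $\tau=0.08$, $c_{11}=0.3$,
$c_{21}=-0.1$, $c_{12}=0.1$, runs the full preprocessing chain, and fits
from the baseline start. All four parameters come back within a few percent
(the residual error reflects resampling and discrete differentiation, not
the optimizer). Unit tests use smaller designs (5–8 trials, order 2) for
the same property; the symmetric-baseline choice-balance check uses 400–600
trials, where the binomial standard error is already below 2.5 percentage
points.

## Visualization

`evaluate_surface()` tabulates $V$ on a grid (default $x\in[-1.2,1.2]$,
$y\in[-0.2,1.2]$, 101 points per axis — just beyond the normalized arena).
`plot_landscape()` renders a static PNG via `persp()`, can lift
trajectories onto the surface ($z = V(x,y)$ along the path, exactly), and
overlays a second landscape as a wireframe for comparisons. Grids export as
long-format CSV for external plotting tools. Camera and colours are
cosmetic and overridable; there is no interactive output format.

## Known limitations

- The velocity-based objective trades approximation accuracy for speed; a
  position-based (ODE-integrating) loss would track trajectories more
  closely but is out of scope.
- One stationary landscape per fitted group: change-of-mind dynamics and
  time-varying preferences are not representable.
- Two options only; the normalized frame hard-codes targets at $(\pm 1,1)$.
- Exactly symmetric screen layouts are assumed for exact target mapping.
- Large $\alpha$ fits are increasingly hard to interpret; orders 2–4 are
  the intended range.
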