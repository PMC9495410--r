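---
title: "Designing transcription-factor circuits by gradient descent: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing transcription-factor circuits by gradient descent: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcircuit)
```

# The model

`tfcircuit` treats a cell's transcription-factor (TF) network as a small
dynamical system to be *designed*: given a target behaviour — here, an
autonomous circadian rhythm that can also entrain to an external light signal
— the package searches the space of biophysically bounded kinetic parameters
by gradient descent through the simulator itself.

Each of the $n$ genes produces an mRNA with abundance $x_i$ (molecules/cell)
and a TF protein with abundance $y_i$:

$$\dot x_i = m_i f_i(\mathbf{y}) - \delta_i x_i, \qquad
  \dot y_i = s_i x_i - \gamma_i y_i,$$

with $m_i$ the maximum mRNA production rate, $\delta_i$ the mRNA decay rate,
$s_i$ the translation rate per mRNA, and $\gamma_i$ the protein decay rate.
Every TF can potentially regulate every promoter (the fully connected case;
optimization is free to prune connections by driving weights to neutral
values).

## The thermodynamic activation function

The dimensionless factor $f_i \in [0,1]$ is the promoter-occupancy
input–output function from equilibrium thermodynamics. TF $j$ acts on
promoter $i$ with intensity

$$v_j = (y_j / k_{ij})^{h_{ij}},$$

where $k_{ij}$ is the dissociation constant (abundance of half effect) and
$h_{ij}$ a Hill coefficient. Summing over all $2^n$ subsets $S$ of
simultaneously bound TFs,

$$f_i = \frac{\sum_S \alpha_S\, w_S}{\sum_S w_S}, \qquad
  w_S = r_S \prod_{j \in S} v_j,$$

with one expression weight $\alpha_S \in [0,1]$ per bound state
($\alpha_\varnothing$ is basal expression) and one synergy weight $r_S$ per
subset of size $\ge 2$ ($r_S = 1$ implied for smaller subsets). For $n = 1$
and $n = 2$ this reduces to the familiar closed forms
$f = (\alpha_0 + \alpha_1 v)/(1 + v)$ and
$f = (\alpha_0 + \alpha_1 v_1 + \alpha_2 v_2 + \alpha_3 r v_1 v_2)/
(1 + v_1 + v_2 + r v_1 v_2)$, which the test suite uses as oracles for the
general expansion.

Two points about this parameterization were genuinely open and are resolved
as follows:

* **One scalar $r_S$ per subset**, rather than products of pairwise synergy
  terms. This is the only reading consistent with the parameter count
  $n(2^n - n - 1)$ for the $r$ family, which in turn is what makes the total
  count $n(5 + n + 2^{n+1})$ — 164 parameters at $n = 4$.
* **Numerical stability by log-space weights.** With $y$ up to $10^3$,
  $k \ge 10^2$ and $h \le 5$, a single intensity can reach $10^5$ within its
  nominal range (and far more when protein levels transiently overshoot), so
  subset products overflow doubles already at moderate $n$. All weights are
  accumulated as logarithms and rescaled by the maximum before
  exponentiation; $f$ is invariant under that rescaling.

## Biological bounds and the optimization transform

Parameters live in fixed, biologically motivated ranges (rates per second):
$m, \delta \in (10^{-4}, 10^{-2})$, $s, \gamma \in (10^{-3}, 1)$,
$k \in (10^2, 10^4)$, $h \in (0, 5)$, $\alpha \in (0, 1)$, $r \in (0, 10)$.
These imply mRNA abundances of order $(0, 10^2)$ and protein abundances of
order $(0, 10^3)$, which are adopted as the bounds for the (also optimized)
initial conditions $x_0, y_0$ — the bounds themselves do not state
initial-condition ranges, so the implied abundance scales are the natural
choice.

The optimizer works on an unbounded vector. Each coordinate is mapped to
$(0,1)$ by a piecewise sigmoid that is the *identity* on $[d, 1-d]$
(default $d = 0.01$) and bends into logistic tails outside, with constants
chosen so the pieces join continuously; an affine map then lands in each
family's range. Values well inside the range are untouched (so the
optimization geometry is undistorted where it matters), while the tails
enforce the bounds smoothly. The transform is kinked (not differentiable) at
the two joins — a property of this construction, harmless in practice since
the joins are measure-zero and the subgradient convention (interior slope at
the join) is used. The inverse transform stores chosen initial values on the
unbounded scale; exact-boundary values are nudged inside by a machine-epsilon
margin first, because the inverse is undefined at 0 and 1.

Rates are stored in the `TFParams` object in per-second units — the units
the bounds are quoted in — and multiplied by 86 400 inside the simulators,
which run in days (the natural unit for circadian targets, light schedules
and plots).

# The design objective

The target rhythm is $z_t = (\sin(2\pi t + \pi) + 1)/2$ with $t$ in days:
period exactly one day, range $[0,1]$, day onsets (upward 0.5-crossings) at
half-integer days. TF 1 defines the cellular day/night state: abundance
strictly above $10^3$ molecules/cell is "daytime". The loss compares
Hill-normalized curves on a half-open grid of 50 points per day
($t = 0, 0.02, \dots$):

$$L = \sum_t \left( \frac{y_t^2}{1000^2 + y_t^2}
  - \frac{z_t^2}{0.5^2 + z_t^2} \right)^2 .$$

Both half-saturations sit at the respective day/night thresholds (1000
molecules; $z = 0.5$), so the two curves are compared on a common $[0,1)$
scale; both denominators are configurable in `lossSpec()`. The half-open
endpoint convention (the grid stops one step before the horizon) makes "50
equally spaced points per day" exact for integral horizons.

# Stochastic dynamics, light, and entrainment

**Chemical noise.** Each abundance receives an independent Gaussian
increment per step with standard deviation
$\text{amp}(z)\sqrt{dt}$, where $\text{amp}(z) = \sqrt{z}$ for $z > 16$ and
$z/4$ for $z \le 16$. The square-root scaling is the diffusion approximation
of molecular shot noise; the small-abundance replacement (continuous at
$z = 16$, since $\sqrt{16} = 16/4$) stops the *relative* noise from growing
without bound as abundance falls, which otherwise drives abundances negative
at finite step size. States are floored at zero after every step regardless.
A `noiseScale` multiplier (default 1) recovers the deterministic system at 0
from the same code path.

**Light.** External light availability is a telegraph process: initially
off, switching at exponential waiting times with mean $w$ days. While on, it
boosts the production of TF 2 by $g\, z_t^4$ molecules/day with $g = 10^6$:
a strong, midday-peaked boost that carries the phase information the circuit
can entrain to (at night $z_t \approx 0$, so lit nights contribute almost
nothing). Gain, exponent and target gene are configurable in `driveSpec()`.

**Entrainment scoring.** For each measurement day $d$, the target onset is
$t = d - 0.5$. A trajectory's daytime entry is its upward crossing of the
1000-molecule threshold nearest that onset (linear interpolation between
samples), and the signed deviation in hours is folded into $(-12, 12]$ —
deviations are only defined modulo the 24 h period, and the folding
attributes each entry to the nearest onset. Crossings only count if the
trajectory dwelt at or below the threshold for at least 0.05 days
beforehand; without this debouncing, noise chatter around the threshold
produces spurious "entries". Trajectories with no crossing within half a day
of the onset are reported as missing, never silently dropped. Percentiles
(5, 25, 50, 75, 95 by default) use linear interpolation between order
statistics (R's type-7 quantile).

# Optimization

**Differentiable simulation.** Gradients are obtained by
discretize-then-optimize: the fixed-step Euler–Maruyama recursion (step
$dt = 10^{-3}$ days by default) is unrolled, and the loss is backpropagated
step by step through the update map — including the activation function, the
abundance-dependent noise amplitude (with the pre-drawn noise held fixed),
and the zero floor (which zeroes the gradient where active). The reverse
pass is hand-derived and implemented in C++ alongside the forward stepper;
its correctness is established against central finite differences of the
same discrete objective (agreement to $\sim 10^{-4}$ relative; the
finite-difference check is part of the test suite). A
continuous-adjoint alternative was rejected: it is ill-posed for noisy paths
and offers no advantage at these horizon lengths. For plain (non-gradient)
simulation the package defaults to deSolve's adaptive `lsoda`, which also
serves as an independent accuracy reference for the fixed-step path.

**Bounded Adam with curriculum.** Adam (learning rate 0.002; conventional
moments 0.9/0.999, $\epsilon = 10^{-8}$) updates the unbounded vector.
Fitting starts against a short window of the target and doubles the window
each stage (`curriculumWindows()`; e.g. 0.75, 1.5, 3 days for a 3-day
horizon) — early gradients from a short window are far more informative than
from a long mismatched trajectory. Initial parameter sets
(`initParams()`) start from documented base values — decay rates pinned near
their minima so abundances do not collapse before the search finds
structure; $m$ and $\alpha$ uniform across their ranges; $k = 500$, $h = 2$,
$r = 1$ — each multiplied by $1 + z$, $z \sim N(0, 0.25)$ by default, and
clipped just inside the bounds. The initial abundances default to
$x_0 = 10$, $y_0 = 100$ (mid-logarithm of the abundance ranges), a package
choice where no established value exists.

**Stochastic phase.** After the deterministic curriculum fit, the circuit is
fine-tuned on the stochastic system: each Adam step averages the gradient of
4 independent noisy trajectories, each with a freshly sampled light schedule
(mean wait $w = 2$ days by default), using common random numbers within the
step. This phase runs at the *base* learning rate: it is not a polish but
the phase in which the circuit learns to buffer noise and to exploit the
light signal — at strongly reduced rates the fitted circuits entrained
poorly or not at all. A final reduced-rate refinement pass
(`refine_rate`, default $5 \times 10^{-4}$) is available via
`refine_iters` but disabled by default.

**Failure policy.** Non-finite losses or gradients (possible when the
dynamics stiffen as decay rates grow toward their upper bounds, destabilizing
the explicit stepper) restore the best checkpoint of the stage and halve the
learning rate; twenty consecutive failures abort with diagnostics. The
returned parameters are the best-loss iterate of the final stage, so the
best-so-far loss is nonincreasing within each stage by construction.

# What the default conditions emulate — and what they do not

The default problem (`defaultRunConfig()`) is a 4-TF fully connected
circuit, fit deterministically over 3 days in 3 curriculum stages
(600/600/1200 iterations), then stochastically for 800 steps, and evaluated
as ensembles of 100 trajectories per light regime
($w \in \{2, 4, 8, 16, 1000\}$) with entry-time deviations measured at days
10, 20 and 30. These sizes keep a complete
optimize-and-evaluate protocol in the minutes range on a single core; they
are deliberately smaller than a no-compromise design study, which would use
longer fitting horizons, many random restarts with selection of the best,
thousand-trajectory ensembles, and 30-day evaluations throughout. The test
suite exercises the same protocol at these reduced sizes, with the
entrainment comparison (frequent light vs. effectively none at day 10)
checked on 100 trajectories.

The simulator emulates intrinsic molecular noise by a diffusion
approximation with the $\sqrt{z}$ amplitude; it does not perform
exact-jump (Gillespie) simulation, model transcriptional bursting, delays,
cell division, or extrinsic noise, and the light drive is a clean telegraph
signal rather than measured irradiance. Passing tests therefore demonstrate
properties of this model class — that gradient descent through the solver
can design circuits that hold and entrain a rhythm under abundance-scaled
Gaussian noise — not claims about any particular organism's clock.

# Known limitations

* The explicit fixed-step scheme can go unstable if optimization pushes
  decay rates toward their upper bounds ($\gamma$ up to $86\,400$/day);
  the failure policy contains, but does not eliminate, this.
* Optimized circuits are not identifiable: repeated runs converge to
  different parameter sets with similar trajectories. Tests assert
  trajectory agreement, never parameter agreement.
* The activation expansion is $O(2^n)$ per gene per step; practical for the
  $n \le 6$ range the package targets, not for large networks.
* In stochastic mode the best-checkpoint selection uses the minibatch loss,
  which is itself noisy; for small `nRealizations` the returned iterate is
  best only in expectation.
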