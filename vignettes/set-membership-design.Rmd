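---
title: "Set-membership experimental design for ODE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-membership experimental design for ODE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(setdesign)
```

## The problem

Biological time-course data are scarce and noisy, and with a handful of
replicates there is rarely a defensible probability model for the
measurement error.  What is defensible is a hard bound: the observation at
time $t_i$ lies in an interval $[\underline{y}_i, \bar{y}_i]$.  Under this
bounded-error view the natural estimation target is the *set* of all
parameter values consistent with every interval, and the natural design
question is: at which future time points would a new (interval)
measurement shrink that set — or the bounds it implies on unmeasured
states — the most?

`setdesign` implements this programme for nonlinear continuous-time models
$\dot{x} = f(x, \theta)$, $y = g(x, \theta)$ with $g$ a selection of
states.  Its pieces are

1. a validated interval integrator that turns a box of initial states and
   a box of parameters into guaranteed enclosures of all trajectories;
2. SIVIA set inversion, which partitions an a-priori parameter box into
   feasible, unfeasible and indeterminate boxes against the interval data;
3. construction of *candidate measurements* $(t_j, C_j, R_j)$ from the
   propagated uncertainty, so that designs can be scored before any
   experiment is run;
4. evaluation of multi-measurement designs by intersecting the
   single-candidate parameter sets instead of re-estimating;
5. scalar design metrics with direct biological reading: consistent-set
   volume (PV), per-parameter bound widths and their Euclidean
   combinations, and worst-case level/uncertainty of (possibly
   unmeasured) states;
6. a classical comparator: maximum-likelihood fitting, sensitivity ODEs,
   Fisher information and exhaustive D-optimal subset selection under
   Gaussian recharacterizations of the interval data.

## Guaranteed enclosure of ODE solutions

Enclosures are advanced on a uniform grid $t_0 + ih$ by interval Taylor
steps of order $k$.  Each step first validates an a-priori enclosure $B$
of the solution over $[t, t+h]$ by the first-order fixed-point (Picard)
condition $X + [0,h]\,F(B) \subseteq B$.  The candidate is grown only in
the components that violate the condition — taking the hull with the
Picard image and inflating that component's deviation from its midpoint by
$1+\alpha$.  Inflating every component at once (the textbook description)
stalls on coupled systems: the candidate and the requirement then grow at
matched rates and the containment gap never closes.  When a step cannot be
validated at $h$ it is retried at halved sub-steps up to a configurable
depth, with a global sub-step budget per trajectory.

The step map itself is a *parametric mean-value (EMV) form*.  The
enclosure is maintained as

$$x(t) \in \hat{x}(t) + C(t)\,\Delta p + A(t)\,r(t),$$

where $\hat{x}$ is the point trajectory of the box midpoint, $\Delta p$
the fixed centred parameter deviation box, $C$ a *point* matrix tracking
the solution's parameter sensitivity, $A$ a QR-orthonormalized
preconditioning frame, and $r$ an interval deviation vector absorbing
remainders and Jacobian widths.  Keeping the dominant parameter dependence
in the point product $C\,\Delta p$ is decisive: an implementation that
instead appends the parameters to the state vector and preconditions the
augmented system re-multiplies interval Jacobian widths into the deviation
at every step, and on the packaged predator-prey fixture loses roughly two
orders of magnitude of tightness by $t = 6$ (enough to make every
desk-resolution parameter box fail).  Both the preconditioned
representation and a directly evaluated hull are kept and intersected.

All interval endpoint computations are nudged one unit in the last place
outward, so the exact real-arithmetic result is always contained; exact
quantities (the fixture's initial conditions, fixed parameters) travel as
zero-width intervals through the same code paths.

## Classification, certificates and failure refinement

A parameter box is *feasible* when its envelope's observed components are
contained in every measurement interval, *unfeasible* when provably
disjoint from one (the propagation aborts at the first disjoint
measurement), and *indeterminate* otherwise.  SIVIA bisects indeterminate
boxes wider than $\varepsilon$ along their widest dimension.

Two practical extensions matter for sparsely measured systems, where the
first comparison may lie far from $t_0$:

* **Growth-rate certificates.**  For models declared in factored kinetic
  form $x_i' = x_i\,g_i(x, p)$ with nonnegative-invariant states, interval
  bounds on $g_i$ over the positive orthant justify two sound early
  discards: if $\inf g_i \ge 0$ and the enclosure's lower bound already
  exceeds a remaining upper measurement bound, the box can never return
  into the data corridor; and $x_i(t') \le \overline{x}_i(t)\,
  e^{\sup g_i\,(t'-t)}$ discards boxes whose trajectories have collapsed
  below a remaining lower bound.  Without these, entire quadrants of a
  generous search box (where trajectories blow up or crash long before the
  first measurement) can never be discarded at any affordable resolution.
  They are switchable (`enclosure_settings(certificates = )`), and they are
  the package's own device for the few-measurement regime.

* **Failure refinement.**  A box whose enclosure cannot be validated over
  the window is classified indeterminate (conservative), but it carries no
  information.  Such boxes are refined below $\varepsilon$ down to a
  separate limit `eps_fail`, where the integrator usually recovers;
  terminal failures stay in the partition as indeterminate.

State bounds hull the per-box envelopes at each grid time over the boxes
that admit validated full-window enclosures; the count of excluded boxes
is reported on the envelope object.  An excluded box's trajectories admit
no finite validated bound, so including its pre-failure values would
produce an envelope that is neither a bound nor honest.

## Candidate measurements

Candidate times are taken where the envelope is at least as uncertain as
the adjacent measurements; the exactly known initial condition acts as a
zero-width anchor at $t_0$, which is what admits candidate times before
the first measurement (the packaged study places three of its ten there).
The candidate range $R_j$ copies the larger adjacent measurement width — a
deliberately conservative premise: a future measurement will not be less
noisy than its neighbours.  The centre $C_j$ is chosen to *maximize* the
retained parameter volume: $r$ simulated measurements of width $R_j$ are
slid from the lower to the upper envelope bound, the consistent volume is
computed for each, a quadratic is fitted to volume versus centre, and the
vertex (clamped to the sampled span) is used when the fit is concave, the
argmax sample otherwise.  Maximizing is the conservative choice — it
avoids simulated data that would spuriously eliminate parameters a real
measurement might keep.

Because a box's envelope does not depend on which data it is compared
against, adding one candidate measurement to the data reduces to an
overlap test between each cached per-box envelope and the new interval.
`partition_envelopes()` computes and caches the per-box envelopes once;
candidate construction, per-candidate partitions and all design
combinations then cost almost nothing.  The only case where re-estimation
is needed — a feasible box wider than $\varepsilon$ that the new interval
makes indeterminate, which SIVIA would bisect — is detected and routed
through the real seeded estimator, so the shortcut is exact, and the test
suite verifies it against brute-force runs to $10^{-12}$.

## Combining measurements and metrics

The consistent set for a combination of candidates is the intersection of
the single-candidate sets (classification factorizes over measurements).
`intersect_partitions()` implements the general pairwise-box intersection
(with `uniformize()` to make box scales comparable), and recognizes the
common case of partitions that are subsets of one base partition, where
intersection is an index operation.  `enumerate_designs()` scores all
subsets up to size $k_c$; all metrics measure uncertainty, so smaller is
better, ties break to the lexicographically earliest time vector, and an
empty (inconsistent) intersection is never ranked best.

PV excludes parameter dimensions fixed in the search box (they would make
every volume zero) and accepts optional importance weights.  Width metrics
use the hull of box projections.  State metrics (`Xmax`, `Xrange`) read
the combined envelope and are the natural metrics when bounding an
unmeasured component matters more than parameter precision.

## The packaged case study and the desk profile

The fixture is the classical two-species predator-prey system
$\dot{x}_1 = x_1(p_1 - p_2 x_2)$, $\dot{x}_2 = -x_2(p_3 - p_4 x_1)$ with
$x(0) = (50, 50)$ and true rates $(1, 0.01, 1, 0.02)$; $p_1, p_3$ and the
initial state are exactly known; prey ($x_1$) is measured at
$t = 2, 4, 6$ with fixed printed error intervals (widths 21.8255, 26.2758,
18.1668); the predator is unmeasured; ten candidate times span
$1.25, \dots, 3.75$ with $r = 15$ shifts and combinations up to
$k_c = 5$.  Everything is deterministic — the "random" uncertainty is
frozen into the error intervals.

Two resolution profiles are built in.  The `"paper"` profile carries the
full study conditions ($h = 0.005$, $\varepsilon = 10^{-5}$, search
$[-1,1]$ for $p_2, p_4$); exploring that box at that resolution is a
cluster-scale computation and the profile is provided for completeness,
not for routine runs.  The `"desk"` profile is the package's
single-workstation definition of the study: $h = 0.02$,
$\varepsilon = 10^{-3}$ with failure refinement to $2.5\times10^{-4}$,
and an a-priori box $[-0.05, 0.05]$ for $p_2, p_4$.  The numbers behind
these choices, measured on the fixture: validated integration over the
full window survives parameter boxes up to $\approx 2.5\times10^{-4}$
wide near the consistent set (which spans roughly $p_2 \in [0.007,
0.014]$, $p_4 \in [0.017, 0.023]$), so a coarser partition consists
entirely of enclosure failures and carries no design information; and a
thin, genuinely indeterminate filament hugging $p_2 = 0$ stretches to
large $p_4$, so a search box much wider than the consistent set spends
essentially all of its time resolving cells that no desk budget can
classify.  The reduced box still covers the consistent set with a
several-fold margin on every side.  At this profile the full pipeline
(estimation, envelope cache, 150 shifted estimations, 637 design
combinations for each metric) runs in roughly six to eight minutes on one
CPU.

What desk resolution does and does not preserve: the partition cells are
coarse, so volume-versus-shift curves carry visible quantization and
asymmetry, and the quadratic fits degrade on the latest candidate times,
whose envelopes are widest (minimum $R^2 \approx 0.91$ across the ten
candidates; refining `eps_fail` a further factor of two raises it only to
$\approx 0.92$ at $\sim 50\%$ more cost, so this is a property of the
resolution, not a tuning artifact).  The headline single-measurement
selection — the earliest candidate, $t = 1.25$, for the $p_2$ width — is
stable across every resolution profile we ran.  Width-based rankings of
*combinations* are more delicate: the remaining filament cells inflate
the $p_4$ hull width until an early candidate removes them, which biases
combination rankings toward including one early time (the best triple for
the $(p_2, p_4)$ norm at this profile is $\{1.25, 2.5, 3\}$), and
shifting the resolution by one dyadic level moves individual members of
such sets by one adjacent candidate slot.

## The classical comparator

To compare with D-optimal design the interval data are recharacterized as
Gaussians: the mean sits at a chosen fraction of each interval (defaults
0.25 / 0.5 / 0.75 for left / centre / right) and the variance solves
$\Phi((\bar{y}-\mu)/\sigma) - \Phi((\underline{y}-\mu)/\sigma) = 0.9$ by
bracketed root finding.  Note the geometry: an off-centre mean needs a
*smaller* $\sigma$ to keep 0.9 of its mass inside the interval, and a
mean on the interval edge can never reach 0.9 (the supremum is 0.5) — so
the shift fractions must stay strictly inside.  A weighted least-squares
ML fit (Nelder-Mead, five deterministic starts; Brent for one-parameter
problems), forward sensitivity ODEs $\dot{S} = JS + A$ with symbolic
Jacobians, and the Fisher information
$\mathrm{FIM} = \sum_t \sigma_t^{-2} s(t)^\top s(t)$ feed exhaustive
subset selection by $\det(\mathrm{FIM})$; candidate-time variances copy
the larger adjacent initial-measurement variance.  The packaged default
runs the nine combinations with a common shift for the two later
measurement times.  The instructive outcome, reproduced in the test
suite, is the *instability* of the selected time points across these
equally plausible characterizations — the bounded-error route needs no
such characterization at all.

## Numerical choices and limitations

* Outward rounding by one-ulp nudging; no global rounding-mode changes.
* Bisection always at the representable midpoint, so subdivision and
  `uniformize()` preserve point sets exactly and serialization round-trips
  bit-exactly at 17 significant digits.
* Measurement times snap to the nearest grid node and must lie within
  $h/2$; the desk grid places the candidate time 1.25 at node 62
  ($t = 1.24$) under round-half-even.
* At most 10 inflation attempts per a-priori validation; 8-12 step
  halvings and a 2000-20000 sub-step budget per trajectory depending on
  profile; enclosure magnitudes capped at $10^{12}$.
* The integrator's tightness, not its speed, is the binding constraint of
  the whole method: parameter-box width tolerance sets the achievable
  partition resolution, which sets metric smoothness and ranking
  fidelity.
* Extended (Kaucher) arithmetic, affine forms, Taylor models with
  polynomial parts, adaptive step-size control and contractor acceleration
  are out of scope; division by intervals containing zero is an error, not
  a split.
* Parallel evaluation of boxes is not implemented; the classification
  queue is strictly FIFO so any future parallel merge must restore that
  order to preserve determinism.
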