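# setdesign

Bounded-error (set-membership) experimental design for nonlinear
continuous-time models of biological systems.

When only a few noisy measurements of a dynamic system are available,
assigning probability distributions to the measurement error is rarely
defensible; hard bounds are.  `setdesign` treats each observation as an
interval `[y̲ᵢ, ȳᵢ]`, characterizes the set of all model parameters
consistent with every interval, and uses that set to decide **where to
measure next**: which future time points, and how many additional
measurements, most reduce the uncertainty metric the experimenter actually
cares about.

For a model `ẋ = f(x, θ)`, `y = g(x, θ)` the package provides:

- **Guaranteed enclosure of ODE solutions** — interval Taylor series of
  order *k* with validated a-priori step enclosures and a parametric
  mean-value (EMV) propagation: point midpoint trajectory, a point
  sensitivity matrix carrying the parameter-box deviation, and a
  QR-preconditioned interval deviation against the wrapping effect.  All
  arithmetic is outward-rounded.
- **SIVIA set inversion** — recursive bisection of an a-priori parameter
  box into feasible / unfeasible / indeterminate boxes against the
  interval data (threshold ε), plus guaranteed state bounds for measured
  *and unmeasured* components from the resulting partition.
- **Candidate measurements** — time points where the propagated
  uncertainty is at least the neighbouring measurement uncertainty
  (Eq.-style adjacent-width rule for the range `R_j`), with the centre
  `C_j` placed by sliding the range across the state bounds and
  maximizing the retained parameter volume via a quadratic fit.
- **Fast design combination** — the consistent set of a multi-measurement
  design equals the intersection of the single-candidate sets;
  combinations are evaluated by box intersection (verified to `1e-12`
  against brute-force re-estimation) instead of re-running the estimator.
- **Biologically readable metrics** — consistent-set volume `PV`,
  per-parameter bound widths `P:p`, Euclidean combinations
  `Pnorm:p,q`, and worst-case level / uncertainty of any state
  (`Xmax:x`, `Xrange:x`).
- **A classical comparator** — Gaussian recharacterization of the
  intervals (0.9 coverage), weighted ML fitting, forward sensitivity
  ODEs, Fisher information and exhaustive D-optimal subset selection.

The estimation core (interval arithmetic, Taylor recurrences, EMV steps,
SIVIA) is compiled C++ (Rcpp); models are written as plain R expressions
and compiled to an elementary-operation tape.

## Worked example

The packaged case study is the classical predator-prey model
`ẋ₁ = x₁(p₁ − p₂x₂)`, `ẋ₂ = −x₂(p₃ − p₄x₁)` with exactly known initial
populations (50, 50) and rates `p₁ = p₃ = 1`, unknown `p₂` (true 0.01)
and `p₄` (true 0.02), and three interval measurements of the prey at
`t = 2, 4, 6` (widths ≈ 22, 26, 18); the predator is unmeasured.

```r
library(setdesign)

cfg    <- case_study_config("desk")   # h = 0.02, eps = 1e-3, see vignette
report <- run_pipeline(cfg)           # ~6-8 min on one CPU
print(report)
#> design_report (desk scale): 1809 boxes, 10 candidates
#>   PV             best single: t = 1.25  (value 2.59781e-05)
#>   P:p2           best single: t = 1.25  (value 0.0130859)
#>   P:p4           best single: t = 2.75  (value 0.0320312)
#>   Pnorm:p2,p4    best single: t = 3  (value 0.0349822)
#>   Xmax:x2        best single: t = 2.25  (value 7625.49)
#>   Xrange:x2      best single: t = 2.25  (value 15145.1)

best_design(report, "P:p2", 1)        # 1.25
best_design(report, "Pnorm:p2,p4", 3) # 1.25 2.50 3.00
```

Reading the output: with resources for a single extra measurement, a prey
count at `t = 1.25` (before the first existing measurement, where the
propagated uncertainty already exceeds the first measurement's width)
shrinks the `p₂` bound the most — from 0.0148 to 0.0131 at this
resolution; the consistent-set volume `PV` drops to about a third of its
initial 8.0e-5.  The
per-size tables in `report$rankings` flatten after two to three added
measurements: the point of diminishing return.  A small worked primitive,
independent of any run: simulating `r = 3` measurements of range 1.5
across state bounds `[3, 6]`,

```r
shifted_measurements(interval(3, 6), 1.5, 3)
#> [3, 4.5]   [3.75, 5.25]   [4.5, 6]
```

A thin command-line wrapper is installed under
`inst/cli/setdesign.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/setdesign.R", package="setdesign"))')" \
    run --scale desk --out out/
```

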