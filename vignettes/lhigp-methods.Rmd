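---
title: "Methods: stage-structured life-history intraguild predation and the evolution of ontogenetic specialization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-structured life-history intraguild predation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhigp)
```

## The model and its assumptions

`lhigp` implements a bioenergetic model of a three-species module in which
an intraguild predator is split into juvenile (`Pj`) and adult (`Pa`)
biomass compartments, while its prey — a specialist consumer `C` — and the
basal resource `R` are unstructured. Juvenile predators and consumers
compete for the resource; adult predators prey on consumers and, with
preference `beta`, on conspecific juveniles, and may additionally graze the
resource (`a_ar > 0`, "diet broadening") or not (`a_ar = 0`, "diet shift").

The bioenergetic skeleton is the standard stage-structured biomass
framework: Holling type-II ingestion, net biomass production
$\nu = \sigma I - T$ (assimilation minus maintenance), and a maturation rate

$$\gamma(\nu_j, D_j) = \frac{\nu_j - D_j}{1 - z^{\,1 - D_j/\nu_j}}$$

derived so that the two-compartment model has the same equilibria as a
continuously size-structured population in which juveniles grow
exponentially from relative size $z$ to maturation size 1 at rate $\nu_j$
under mortality $D_j$. This equivalence holds *at equilibrium*; transient
dynamics of the two-stage caricature are only qualitatively faithful. The
adult's functional response pools all its food types in one saturating
term, so cannibalism and predation compete with resource grazing for
handling time, and the cannibalistic mortality term shares the adult
denominator.

The evolving trait is the juvenile resource attack rate `a_jr`, bound to
the adult predation attack rate by the ontogenetic trade-off
$a_{ac} = (a_p - a_{jr})/(1 + \varepsilon a_{jr}/a_p)$. The biological
assumption is developmental coupling without metamorphosis: a body built to
forage well as a juvenile is a worse predator as an adult. `a_ar` is
deliberately *not* part of the trade-off; it is a scenario axis.

### Starvation conventions

The printed stage-structured equations use net production $\nu$ in every
flux. When $\nu$ is negative (starvation) a literal reading would make
reproduction a biomass *sink* for the juvenile stage. The package uses the
standard convention: the reproduction flux into the juvenile compartment is
$\nu_a^+ P_a$, the negative part of $\nu_a$ remains as a loss term in the
adult equation, and maturation is zero for $\nu_j \le 0$. Every equilibrium
analysed here has non-starving stages, where the two readings coincide; the
convention only matters for transients deep in the starvation regime.

### Parameters

All quantities are in dimensionless model units. The standard
parameterization (`default_parameters()`) sets the consumer from a
half-saturation constant of 1 (`a_cr = 10`, `h_c = 0.1`, `T_c = 1`,
`mu_c = 0.1`) and the predator from the geometric-mean predator–prey
body-mass ratio of 42 with quarter-power scaling of maximum ingestion,
maintenance and mortality. The printed predator constants
(`h_p = 0.25`, `T_p = 0.4`, `mu_p = 0.04`) correspond to rounding the
allometric factor $42^{1/4} = 2.5457$ to $2.5$ and scaling the consumer
constants — the only rounding rule that reproduces all three
simultaneously, which `allometry_check()` makes explicit. Remaining
constants: $\sigma = 0.5$, $z = 0.01$, $\delta = 1$, $R_{max} = 3$,
$a_p = 6$, $\varepsilon = 0$. The trait `a_jr` and the scenario axes
`a_ar`, `beta` have no defaults and must be given.

## Ecological machinery

**Simulation** (`simulate_lhigp`) integrates the four ODEs with
`deSolve::lsoda` (absolute/relative tolerances `1e-10`/`1e-8`). Any
component falling below the extinction threshold (`1e-9`, configurable) is
clamped to exactly zero between integration segments and the event logged.
The hard clamp is deliberate: near a transcritical exit, densities decay to
exponentially small but positive values that would otherwise fake
persistence. Its flip side is that large transient overshoots count as
extinctions — a strong predator inoculum into a consumer-resource state can
crash the consumer below the clamp before the predators themselves starve.
Establishment questions should therefore be posed the canonical way, as a
small inoculum on the resident attractor.

**Attractor identification** (`find_attractor`) integrates in windows until
the relative change over a window falls below `1e-9`, then polishes the
endpoint by Newton iteration and classifies it (`R`, `CR`, `PR`, `PCR`).
Two shortcuts keep near-degenerate cases tractable: a species that is
already tiny (`< 1e-3`) and declining is dropped analytically if the
boundary equilibrium without it is stable against its re-invasion (slow
exponential and algebraic tails near transcriticals would otherwise need
unbounded integration time); and oscillations are only reported as limit
cycles when the windowed amplitude is stationary *and* non-monotone,
so slowly growing or decaying modes are not mistaken for cycles. Cycles are
flagged with their min/max envelope, not continued: in this model they
occupy a small parameter region and have negligible amplitude.

**Equilibria** (`solve_equilibrium`) are solved by damped Newton iteration
on the reduced system of present species (absent ones pinned to zero), with
finite-difference Jacobians (step $10^{-7}(1+|x|)$); stability is judged on
the full 4×4 Jacobian so that the reported spectrum includes invasion
directions of absent species. Near transcritical boundaries the interior
root has a near-singular Jacobian and plain Newton tends to slide onto the
boundary sheet (where a zero density trivially solves its own equation);
for those cases an internal Levenberg–Marquardt pass (`minpack.lm`) in
log-density coordinates, followed by a Newton polish, finds interior
equilibria with densities down to ~`1e-13`.

**Continuation** (`continue_branch`) follows a branch by secant-predictor /
Newton-corrector steps in the combined (state, parameter) space, which
carries it around folds. Events are refined to a parameter tolerance of
about `1e-6`: folds by re-parameterizing the branch by its fastest-moving
state coordinate and extremizing the parameter along it; invasion
boundaries (sign change of an absent species' invasion growth rate) and
component exits (a present density reaching zero) by bisection. The
adaptive step is bounded by `h_max` (default 0.1), so branch resolution is
a compromise between runtime and density of reported points; all reported
points satisfy the equilibrium conditions to `1e-8` regardless of step.

**Stability maps** (`two_parameter_map`) search each grid cell by direct
Newton solves from four canonical guesses — resource-only, consumer–
resource, and both adult-dominated and juvenile-dominated predator states
(cannibalism shifts the stage distribution strongly toward juveniles) —
plus seeded random starts, with a short dynamics fallback when nothing is
found. Multi-start is not an optimization: the model has documented
bistability, and a single start systematically misses alternative states.

## Evolutionary machinery

Invasion fitness is the closed-form lifetime reproductive success of a rare
mutant in the resident's equilibrium environment:

$$R_0(y', y) = z^{\,D_j'/\nu_j' - 1}\,\frac{\nu_a'^{+}}{\mu_p},
\qquad \nu_j' > 0,$$

and $R_0 = 0$ otherwise. The mutant's juveniles suffer cannibalistic
mortality from *resident* adults (resident attack rate and resident
functional-response denominator); its adults feed on the resident's prey
field with the mutant's own attack rates. This closed form was chosen over
a dominant-eigenvalue computation on the mutant's stage-structured
linearization because it is exact, fast, and provably sign-equivalent: the
identity $\mu_p z^{1 - D_j/\nu_j} = \nu_a$ at the invasion boundary makes
the root of $R_0 = 1$ algebraically identical to the Jacobian-based
transcritical point, and the test suite verifies both the resident
neutrality $R_0(y, y) = 1$ along continued branches and the boundary
agreement (to `1e-4`). Numerical verification of the neutrality identity is
conditioning-limited within ~0.01 of a bifurcation, where the equilibrium
solve itself is near-singular; the tests assert `1e-8` away from detected
boundaries and `1e-4` beside them.

The selection gradient is a central finite difference of $R_0$ in the
mutant trait (step $10^{-6} a_p$; one-sided within two steps of a trait
bound). Singular strategies are roots of the gradient along a branch
(`uniroot`, residents re-solved at every trial trait); evolutionary
stability comes from the mutant curvature $\partial^2 R_0/\partial y'^2$
(step $10^{-4} a_p$) and convergence stability from the slope of the
gradient along the branch. Curvatures below `1e-7` are flagged degenerate
rather than silently classified.

**Trait substitution** (`trait_trajectory`) steps the resident trait by
$\eta\,\mathrm{sign}(\text{gradient})$ (default $\eta = 0.01 a_p$, halved
on gradient sign changes), re-solving the resident equilibrium by
warm-started Newton after each step. Deterministic gradient-sign stepping
was chosen over stochastic mutation draws because the claims at stake
concern directions and endpoints, not waiting times. Terminal states:
a singular strategy ($|$gradient$| <$ `1e-6`), the trait bound $a_p$, or
predator extinction after an ecological collapse (evolutionary suicide) —
in which case the post-collapse attractor is identified from the
pre-collapse state and stored.

Three judgement calls deserve note. First, the resident is tracked
*through* weakly unstable focus regions (complex leading eigenvalues with
small positive real part): the attractor there is a limit cycle of
negligible amplitude around the equilibrium, so the equilibrium still
carries the resident environment, exactly as equilibrium-continuation
treatments of this model do. Second, leading eigenvalues within `1e-3` of
zero are treated as stable for resident tracking — that is the noise floor
of the finite-difference Jacobian near transcritical points, where exact
eigenvalues pass through zero. Third, a composition change along the way
(the consumer starving out of a coexistence state as the trait rises) is a
transcritical handoff, not a collapse: the trajectory resumes on the
reduced community, using the log-density solver to distinguish "tiny but
present" from "absent".

## Competitive-hierarchy thresholds

Three closed or semi-closed forms pre-classify scenarios
(`classify_hierarchy`): the consumer's minimum resource density
$R^*_C = (T_c+\mu_c)/(a_{cr}(\sigma - h_c(T_c+\mu_c))) = 11/39 = 0.2820...$;
the juvenile-growth trait threshold $a_{jr}^{grow} = T_p/(R(\sigma - h_p
T_p))$, which at $R^*_C$ equals $39/11 = 3.5455$ — the lower edge of the
trait range where the coexistence state co-occurs with a stable
consumer-resource state; and the predator's minimum resource density on
resource alone, the root in $R$ of $R_0(R) = 1$ with background juvenile
mortality, found by bisection. With `a_ar = 4` the predator's and
consumer's thresholds cross exactly at `a_jr = 4` (both equal $11/39$
there, since at $a_{jr} = a_{ar}$ both predator stages are identical and
the threshold has the same closed form as the consumer's with predator
constants). Note the distinction between the juvenile-growth threshold
(3.5455) and the trait value where the consumer-resource state actually
becomes invasible by predators (the $R_0 = 1$ root, 3.8460 at default
parameters): juveniles growing is necessary but not sufficient for
invasion, since maturing adults must also find enough prey.

## Scenario generation and what the tests do and do not show

`study_scenarios()` enumerates the six core (a_ar, beta) scenarios and the
robustness-map grid over maximum resource density {1.5, 3, 6} and
trade-off shape {-0.5, 0, 2}; grid values beyond the two core combinations
are marked as inferred. `random_scenario()` draws the scenario axes
uniformly from their admissible box under a mandatory seed — uniform
because the model is a deterministic ODE system and the draws only need
coverage, not a biological noise model; the trade-off shape floor is -0.9,
clear of the pole at -1. `perturb_state()` applies seeded multiplicative
perturbations with absent species held at zero.

All of this exercises the *model*, not nature: passing tests show that the
implementation solves these equations correctly and that the documented
equilibrium and evolutionary structure follows from them, not that any real
ontogenetic omnivore behaves this way. The two-stage biomass caricature,
the single shared resource, the deterministic trait dynamics, and the
absence of demographic stochasticity are all substantive idealizations.

## Problem sizes and reproducibility

The shipped tests continue branches with adaptive steps bounded by
0.05–0.25 in the trait, run trait trajectories at $\eta = 0.06$, and use
2-cell-to-dozens-of-cell stability maps; a full figure-quality sweep at
step 0.005 uses the same code with smaller `h_max`. Every random draw takes
an explicit integer seed; no function reads global RNG state implicitly.
`scripts/acceptance.R` recomputes the four analytic thresholds
($R^*_C$ displayed truncated to four decimals as 0.2820; $a_{jr}^{grow}$ at
$R^*_C$ rounded to 3.55; the hierarchy flip at 4; the trade-off zero at 6)
from the installed package alone.

## Known limitations

Limit cycles are detected and flagged but not continued; Hopf points are
visible only as complex leading eigenvalues crossing the axis. Dimorphic
(post-branching) evolutionary dynamics are out of scope, as is evolution of
`beta`, `a_ar` or `epsilon`. The fold refiner assumes a locally quadratic
fold; degenerate (cusp-like) folds would need smaller continuation steps.
Near-transcritical equilibria are resolved down to densities of about
`1e-13` by the log-density solver, below which a species is treated as
absent.
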