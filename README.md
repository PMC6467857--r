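# lhigp

Stage-structured bioenergetics of life-history intraguild predation:
ecological equilibria, bifurcation structure, and the evolution of
ontogenetic resource specialization.

## The problem

Many predators are *ontogenetic omnivores*: their juveniles compete with a
specialist consumer for a shared resource, while their adults prey on that
consumer (life-history intraguild predation, LHIGP) and often cannibalize
conspecific juveniles. For species without metamorphosis, juvenile and adult
feeding machinery is developmentally coupled, so specializing the juveniles
on the shared resource degrades the adults' predation ability and vice
versa. `lhigp` implements a four-compartment bioenergetic model of this
system — resource `R`, consumer `C`, juvenile predators `Pj`, adult
predators `Pa` — and the adaptive-dynamics machinery needed to ask what this
ontogenetic trade-off does to the predator over evolutionary time. The
headline phenomenon is *evolutionary suicide*: gradual, individually
advantageous trait change that carries the predator population across an
ecological discontinuity (a fold bifurcation or a community-attractor
switch) into extinction, from which re-invasion is impossible. Cannibalism,
it turns out, prevents it.

The package is aimed at theoretical ecologists who want to reproduce,
perturb, or extend this analysis: every rate function, equilibrium, branch,
and selection gradient is an exported, composable R function.

## The model

Attack rates scale linearly with body size; the trait is the juvenile
attack-rate constant on the resource, a_jr, tied to the adult predation
attack rate by the ontogenetic trade-off

    a_ac = (a_p − a_jr) / (1 + ε a_jr / a_p),

with maximum a_p and shape ε (linear at ε = 0). Ingestion is Holling type
II; the adult pools resource (a_ar R) and prey (a_ac (C + β Pj), with
cannibalistic preference β) in one saturating response. Net biomass
production is ν = σ I − T, fuelling growth in juveniles and reproduction in
adults; the juvenile maturation rate

    γ(ν_j, D_j) = (ν_j − D_j) / (1 − z^(1 − D_j/ν_j))

is constructed so that the two-stage model reproduces the equilibria of the
underlying continuously size-structured population (z is the
birth-to-maturation size ratio). The resource renews by semichemostat
dynamics δ(R_max − R). Scenarios: a_ar = 0 is a complete ontogenetic diet
*shift*; a_ar > 0 is diet *broadening*.

Evolution of a_jr is analysed by adaptive dynamics. The invasion fitness of
a rare mutant y′ in the environment of a resident y at equilibrium is its
lifetime reproductive success

    R0(y′, y) = z^(D_j′/ν_j′ − 1) · ν_a′⁺ / μ_p     (ν_j′ > 0),

whose trait derivative is the selection gradient; singular strategies are
classified by convergence and evolutionary stability.

## Worked example: evolutionary suicide of a noncannibalistic diet-shifter

```r
library(lhigp)

p  <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)  # diet shift, no cannibalism
eq <- find_attractor(c(R = 3, C = 0.1, Pj = 0.1, Pa = 0.1), p)$equilibrium
eq
#> PCR equilibrium (stable), residual 5.00e-16
#>   state: R = 0.543756, C = 0.668059, Pj = 0.0679398, Pa = 0.551185
#>   leading eigenvalue: -0.05054+0.251354i

selection_gradient(eq)
#> [1] -319.5626
```

All three species coexist (a `PCR` equilibrium), but the selection gradient
on a_jr is negative: adults are the bottleneck stage, so selection favours
better predation at the cost of juvenile foraging. Following the trait
downhill:

```r
tj <- trait_trajectory(4.5, p)
tj
#> trait trajectory: 61 steps, a_jr 4.5000 -> 0.8400, status fold_crossed_extinction
#>   post-collapse attractor: equilibrium CR
```

The trait walks down to a_jr ≈ 0.84, crosses the fold where the coexistence
state vanishes, and the community collapses to a consumer-resource state.
Re-invasion is impossible — the consumer holds the resource at a density
where predator juveniles cannot grow:

```r
classify_hierarchy(p)
#> competitive hierarchy: juveniles_grow_consumers_superior
#>   R*_C = 0.282051, R*_P = none, a_jr^grow(R*_C) = 3.545455

invasion_fitness_R0(tj$final_trait, tj$post_collapse$equilibrium)
#> [1] 0
```

With cannibalism (`beta = 1`) the same call ends instead at a singular
strategy that is both convergence- and evolutionarily stable — cannibalism
prevents the suicide. `continue_branch()` maps the underlying equilibrium
branches with their folds and invasion boundaries, and
`two_parameter_map()` produces the (a_jr × β) stability maps.

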