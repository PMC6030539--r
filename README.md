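# juvsus

Tools for studying **the evolution of juvenile susceptibility to infectious
disease** in a stage-structured SIS host–parasite model. Juveniles are almost
always more susceptible than adults across host taxa; this package implements
an eco-evolutionary model in which elevated juvenile susceptibility can be
maintained by a trade-off with maturation or adult reproduction, and provides
the full analysis chain: ecological equilibria, invasion fitness and selection
gradients, singular-strategy classification, trade-off-space outcome maps,
polymorphic evolutionary simulation, and the lifespan / maturation-probability
sweep experiments including frequency-dependent calibration and
evolutionary-suicide detection.

It is aimed at theoretical ecologists and evolutionary epidemiologists who
want to reproduce, stress-test or extend this class of adaptive-dynamics
analyses.

## Model

Hosts are juvenile or adult, susceptible or infected, with densities
`S_J, S_A, I_J, I_A` (total `N`). The juvenile transmission coefficient
`β_J ∈ [β_A, d·β_A]` is the evolving trait; adult susceptibility `β_A` is
fixed. Elevated juvenile susceptibility buys either a higher adult
reproduction rate `a(β_J) = a0(1 + z(β_J))` or a faster maturation rate
`g(β_J) = g0(1 + z(β_J))`, with the normalized trade-off

    z(β_J) = c1 · (1 − exp(c2·x)) / (1 − exp(c2)),   x = (β_J − β_A)/(β_A(d−1))

(`c1` = strength, `c2` = shape; `c2 < 0` gives diminishing returns /
accelerating costs). The ecological dynamics are

    dS_J/dt = a(β_J)(S_A + f·I_A)(1 − qN) − (b + g(β_J))S_J − λ_J S_J + γ I_J
    dS_A/dt = g(β_J) S_J − b S_A − λ_A S_A + γ I_A
    dI_J/dt = λ_J S_J − (Γ + g(β_J)) I_J
    dI_A/dt = λ_A S_A + g(β_J) I_J − Γ I_A

with `Γ = b + α + γ` and forces of infection `λ_J = β_J(I_J + I_A)` (per
density) under density-dependent transmission or `λ_J = β_J(I_J + I_A)/N`
under frequency-dependent transmission (likewise `λ_A` with `β_A`).

Invasion fitness of a rare mutant is evaluated at the resident's ecological
equilibrium, as a closed-form sign-equivalent proxy (minus the determinant of
the mutant's linearised subsystem) with the dominant eigenvalue of that
subsystem as an independent oracle; the selection gradient is its exact
mutant-derivative. Singular strategies are classified ES/CS in the usual way
(CSS, branching point, repeller, garden of Eden).

## Worked example

```r
library(juvsus)

p <- preset_params("fig1c")          # base demography, CSS trade-off cell
basic_reproduction_number(p$beta_A, p)
#> [1] 1.690909

run_to_equilibrium(beta_J = p$beta_A, params = p)
#> Ecological equilibrium (beta_J = 0.002): endemic
#>   S_J = 290, S_A = 260, I_J = 85.04, I_A = 112.9 (N = 748)
#>   prevalence = 0.2647, juvenile fraction = 0.5014, residual = 1.42e-14

find_singular_strategies(p)
#> Singular strategies on [beta_A, d*beta_A]
#>   beta_J* = 0.00349947 (ratio 1.750): CSS (ES=TRUE, CS=TRUE)
#>   endpoint attractors: beta_A -, d*beta_A -
```

With these parameters the pathogen is endemic (R0 = 1.69; about 26% of hosts
infected at the unevolved state), and the trade-off with adult reproduction
selects juvenile susceptibility up to an intermediate continuously stable
strategy at 1.75 times the adult level. The polymorphic simulation confirms
the prediction:

```r
tr <- simulate_evolution(p, beta_init = p$beta_A, lattice_n = 31,
                         epochs = 2000, seed = 1)
tr$final_traits / p$beta_A
#> [1] 1.733333        # within one lattice cell of the analytic CSS
```

Sweep experiments reproduce the headline comparative statics — for the
reproduction trade-off the evolved susceptibility ratio is high for short and
long lifespans with an interior minimum; for the maturation trade-off it
falls to 1 as the probability of reaching adulthood approaches 1; and under
frequency-dependent transmission (calibrated so the initial population
matches the density-dependent one) selection can drive short-lived hosts
extinct:

```r
sw <- sweep_experiment("lifespan", c(1.5, 2, 3, 6, 10, 25, 60), preset_params("fig2"))
sw$records$evolved_beta_ratio
#> [1] 3.000000 3.000000 2.782874 2.822294 2.838616 2.844939 2.843978

p_fd <- update_params(preset_params("fig4m"), transmission_mode = "frequency_dependent")
suicide_gap(c(2.1, 2.2, 2.3, 2.5, 3, 4, 8), p_fd)
#> [[1]]
#> [1] 2.1 2.2        # hosts initially viable here are driven extinct by evolution
```

A thin command-line interface over the same functions ships in
`inst/cli/juvsus.R` (verbs `equilibrium`, `pip`, `tradeoff-map`, `evolve`,
`sweep`, `calibrate-fd`; example configs in `inst/extdata/`):

```sh
Rscript inst/cli/juvsus.R sweep --config inst/extdata/fig2_sweep.yaml \
    --out out/ --seed 1 --format csv --plot
```

See `vignettes/model-and-methods.Rmd` for the full account of the model,
its numerical methods and their limitations.

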