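---
title: "Model and methods: the evolution of juvenile susceptibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the evolution of juvenile susceptibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(juvsus)
```

## The question and the model

Juveniles are more susceptible to infection than adults in most host taxa,
even where juvenile resistance is physiologically attainable. One
evolutionary explanation is resource allocation during development: hosts
that divert resources from immune defence while growing mature faster or
reproduce more as adults, at the cost of elevated susceptibility while
juvenile. `juvsus` implements a stage-structured SIS host–parasite model
built around exactly this trade-off and asks when elevated juvenile
susceptibility evolves.

Hosts are juvenile or adult and susceptible or infected
(`S_J, S_A, I_J, I_A`; total density `N`). The model's assumptions:

* **Asexual, well-mixed host population.** The evolving trait is the
  juvenile transmission coefficient `β_J`, constrained to
  `[β_A, d·β_A]`: juveniles are at least as susceptible as adults and at
  most `d` times more so. Adult susceptibility `β_A` is fixed, which
  isolates selection on the juvenile stage.
* **Reproduction only by adults**, at rate `a`, reduced by density-dependent
  competition through the factor `1 − qN`; infected adults reproduce at
  relative fecundity `f ∈ [0, 1]`. Recruits enter `S_J`.
* **Maturation at rate `g`** for susceptible *and* infected juveniles
  (infection does not halt development; an infected juvenile matures into an
  infected adult). This choice makes the infected-lifetime algebra come out
  in terms of the compound rate `D = g + Γ − γ` and is what the
  invasion-fitness expression assumes.
* **SIS epidemiology**: infection at force `λ_J` (juveniles) and `λ_A`
  (adults), recovery without immunity at rate `γ` into the susceptible class
  of the *current* stage, natural mortality `b` everywhere, disease-induced
  mortality `α` for infecteds. `Γ = b + α + γ` is the reciprocal of the
  infectious period.
* **Equal infectiousness of all infecteds**; stages differ only in
  susceptibility. Density-dependent (DD) transmission has
  `λ_J = β_J (I_J + I_A)`; frequency-dependent (FD) transmission divides by
  `N` (and is defined as 0 in an empty population, preventing 0/0).

The trade-off links `β_J` to either the reproduction rate
(`a(β_J) = a0(1 + z(β_J))`) or the maturation rate
(`g(β_J) = g0(1 + z(β_J))`), one at a time, via the normalized curve

```
z(β_J) = c1 (1 − exp(c2 x)) / (1 − exp(c2)),  x = (β_J − β_A)/(β_A (d − 1)),
```

linear in the limit `c2 → 0`. `c1` (strength) fixes the maximum benefit,
attained at `β_J = d β_A`; `c2` (shape) fixes the curvature: negative values
give diminishing returns (accelerating costs), positive values increasing
returns. This normalized-exponential family was chosen over a power law
`x^c2` because a diminishing-returns power law has unbounded marginal benefit
at `β_J = β_A`, which would make minimum susceptibility (`MN`) unattainable
for any positive strength — incompatible with the qualitative outcome
structure the model is meant to exhibit. A consequence of the convention is
that the shape constant is *signed*.

## Parameters

| Parameter | Meaning | Units | Base value |
|---|---|---|---|
| `a0` | baseline adult reproduction | 1/time | 2 (qualitative map), 5 (sweeps) |
| `b` | natural mortality; lifespan is `1/b` | 1/time | 0.1 |
| `g0` | baseline maturation; maturation probability is `g0/(b+g0)` | 1/time | 0.25 |
| `q` | competition coefficient | 1/density | 0.001 |
| `f` | relative fecundity of infecteds | – | 0.75 |
| `α` | disease-induced mortality | 1/time | 0.5 |
| `γ` | recovery rate | 1/time | 0.5 |
| `β_A` | adult transmission | 1/(density·time) DD, 1/time FD | 2q (DD presets) |
| `d` | maximum susceptibility elevation | – | 3 |
| `c1`, `c2` | trade-off strength and shape | – | preset-specific |

With `q = 0.001` the demographic scale is of order one thousand hosts, and
`β_A = 2q` places the unevolved population comfortably in the endemic regime
(R0 ≈ 1.7 at the base demography) — the regime in which the cost of juvenile
susceptibility is real. At `β_A = 2q/3` the pathogen cannot invade anywhere
on the trait interval (R0 ≤ 0.89), so there is no epidemiological feedback
and the analysis degenerates; the shipped presets therefore use `β_A = 2q`.

### Preset calibration

The trade-off constants of the shipped presets were fixed once, by requiring
each preset to sit in the qualitative regime it is meant to illustrate, and
are not tuning knobs:

* `fig1c` (`c1 = 0.4, c2 = −1.5`): an interior CSS cell.
* `fig1d` (`c1 = 0.4, c2 = −0.3`): a repeller cell.
* `fig1e`/`fig1f` (`c1 = 0.4, c2 = −0.7`): the narrow weakly-accelerating
  band in which a branching point and repeller coexist.
* `fig2` (reproduction trade-off, `c1 = 0.7, c2 = −2`): the cell in which
  the evolved ratio `β_J*/β_A` against lifespan is non-monotone with an
  interior minimum.
* `fig3` (maturation trade-off, `c1 = 0.5, c2 = −2`): the cell in which the
  evolved ratio falls to 1 as the maturation probability approaches 1
  (near-certain maturation leaves nothing to gain from speeding it up).
* `fig4m` (maturation trade-off, `g0 = 0.1`, DD reference `β_A = 4q`):
  frequency-dependent evolutionary suicide requires a thin demographic
  margin *and* an endemic density-dependent reference for calibration; with
  `g0 = 0.25` and `β_A = 2q` the endemic region only begins at lifespans
  where the demographic surplus is already large and suicide is unreachable.
  Lowering the maturation rate and raising transmission moves the endemic
  onset down to lifespans near the viability boundary, where the gap opens.

Two remarks on these choices. First, in this model no single `(c1, c2)` pair
makes the evolved ratio non-monotone in *both* the lifespan and the
maturation-probability directions at once (the lifespan dip needs a strong
trade-off, the probability-axis dip a weak one, e.g. `c1 = 0.25, c2 = −3`);
the `fig2` preset prioritizes the lifespan shape. Second, branching-point
cells exist only in a thin band between the CSS and repeller regions and
their disruptive curvature is weak; see *Simulation design* below.

## Invasion analysis

Mutations are assumed rare and small, so invasion fitness of a rare mutant
`β_Jm` is evaluated in the environment set by the resident at its ecological
equilibrium. The mutant's dynamics, linearised while rare, are governed by a
4×4 quasi-positive matrix `A` (its classes: mutant `S_J, S_A, I_J, I_A`;
the resident equilibrium enters through the competition factor `P = 1 − qN*`
and the forces of infection). Because the resident itself solves
`A x* = 0` with a positive vector when mutant and resident coincide,
`−det(A)` vanishes exactly at neutrality and is sign-equivalent to the
dominant eigenvalue near the invasion boundary. Expanding the determinant
gives the closed form used by `invasion_fitness(method = "analytic")`:

```
w = a_m P g_m [(Γ + f λ_A)(Γ + g_m) + λ_m (γ + f (b + λ_A))]
    − [Γ b + (Γ − γ) λ_A] [(Γ + g_m)(b + g_m) + λ_m D_m],     D_m = g_m + Γ − γ.
```

The dominant eigenvalue of `A` (`method = "eigenvalue"`) is kept as an
independent oracle: the two routes share no code beyond the matrix entries,
and the test suite asserts sign agreement on 1000 random admissible
parameter draws (outside a dead band of 1e−8 on the proxy). The selection
gradient is the exact derivative of `w` in the mutant trait via the chain
rule through `a(β)`, `g(β)` and `λ(β)`; it is checked against central finite
differences of `w` to a relative 1e−4.

Singular strategies are sign changes of the gradient on a 201-point trait
grid (equilibria warm-started along the grid), refined by bisection to
1e−8 of the interval. Classification: evolutionary stability from the
second difference of `w` in the mutant direction (step 1e−4 of the interval,
in normalized trait units; absolute curvature below 1e−7 is flagged
*marginal* rather than classified, since `w` is a sign proxy and
magnitude-based curvature needs a guard band), convergence stability from
the gradient's sign at ±1e−4 of the interval around the root. Qualitative
outcome labels (`MN`, `MX`, `CSS`, `RE`, `BR`, `RE_BR`, `RE_CSS`) follow
from the set of interior strategies plus the endpoint attractors;
configurations outside the enumerated patterns are labelled `other`, never
silently coerced. Doubling the grid resolution does not change labels (an
invariant under test).

## Ecological equilibria

The disease-free equilibrium is closed-form
(`N* = (1/q)(1 − b(b+g)/(a g))`, `S_A/S_J = g/b`), and the pathogen invades
it iff `R0 = (β_J S_J* + β_A S_A*)/Γ > 1` (divided by `N*` under FD) — a
next-generation computation that collapses because maturation does not end
infection, so every infected host's expected infectious lifetime is `1/Γ`.

Attracting equilibria are found by stiff-capable integration (`lsoda`) with
an event-based early exit when the right-hand side falls below the
tolerance, followed by a Newton polish; pure root-finding is not trusted
because disease-free, endemic and (under FD) extinct states coexist, and —
crucially for the suicide analysis — a Newton continuation can silently
track an *unstable* endemic branch after a fold. The fast internal solver
therefore accepts a warm-started Newton solution only if it is locally
stable, and falls back to integration otherwise. Two numerical conventions:
densities below 1e−8 (per compartment) are treated as zero — the integration
noise floor, far below biologically meaningful densities at the `q = 0.001`
scale — and because the right-hand side also vanishes along the extinction
manifold, an early exit at a near-zero state triggers further integration
until decay or equilibrium is resolved. Small negative densities produced by
the integrator are clipped at evaluation; anything below −1e−6 of the state
scale is treated as an integration failure rather than noise (the achievable
negativity tracks the solver's absolute tolerance, so a tighter assertion
would misfire).

## Simulation design

`simulate_evolution` relaxes the adaptive-dynamics idealisations: the trait
lives on a discrete lattice (default 61 sites spanning `[β_A, d β_A]`), all
strains interact ecologically through shared competition and infection, and
every epoch (i) integrates the multi-strain system for a fixed ecological
window (default 200 time units), (ii) culls strains below a persistence
threshold (1e−7), and (iii) with probability `mutation_prob` (default 1)
seeds one mutant — parent chosen proportional to abundance, adjacent lattice
site, entering as susceptible juveniles at 1e−4 of the parent's density,
consistent with mutation acting at reproduction. Trajectories are
bit-reproducible given the seed.

What this emulates: mutation-limited trait substitution, ecological
coexistence during branching, basin dependence around repellers, and
eco-evolutionary feedback to extinction (suicide). What it does not:
demographic stochasticity (densities are continuous; there is no drift),
large mutational jumps, sexual reproduction, or any spatial structure. A
passing simulation therefore confirms the deterministic selection analysis,
not the behaviour of small real populations.

Convergence speed is set by the per-cell selection differential, which near
a singular strategy is small. At the default window the CSS run used in the
tests (31-site lattice, 2000 epochs) lands within one lattice cell of the
analytic CSS. Around the model's branching points the disruptive curvature
is weaker still (invasion eigenvalues of order 1e−6 at a few cells'
separation), so branch separation is invisible at the default window; the
branching demonstrations instead use a long ecological window (2×10⁴ time
units per epoch), under which the population splits, the lower branch fixes
at minimum susceptibility and the upper branch diverges past the repeller.
Full divergence of the upper branch to the maximum takes far longer
mutation-limited time than a desk-scale run; tests assert the split and the
direction of travel, not the final resting point. Branching detection uses
mode separation (two occupied runs separated by at least three empty cells
over the final 10% of epochs) rather than variance thresholds, which is
robust to unequal branch sizes.

Problem sizes throughout the test suite and the acceptance script — 15×15
outcome maps at 151-point trait grids, 11-point lifespan sweeps, 2000-epoch
simulations — were chosen as the smallest sizes at which each qualitative
feature is cleanly resolved.

## Frequency-dependent comparisons and suicide

To compare transmission modes fairly, the FD analysis calibrates `β_A` so
that the initial (`β_J = β_A`) population matches the DD one: since
`λ^FD = β I / N`, setting `β_A^FD = β_A^DD · N*` makes the DD initial
equilibrium an exact equilibrium of the FD system. Calibration requires the
DD reference to be endemic (a disease-free state pins nothing down); such
points are flagged infeasible, not guessed. Initial viability under FD is
judged by integrating from the standard initial condition (disease-free
state with 1% of hosts moved to the infected classes), because the
calibrated state can in principle lose stability under FD dynamics.

Under DD transmission the pathogen always dies out before its host, so
evolution can never extinguish the host (asserted over the sweep grids).
Under FD there is no density threshold, and selection for higher maturation
or fecundity can raise juvenile susceptibility until the host crosses its
viability boundary — evolutionary suicide. `suicide_gap` reports the
contiguous axis ranges where the initial population is viable but the
evolved one is not; with the `fig4m` preset this gap sits at short
lifespans, and it is empty for every DD parameterization by construction.

## Known limitations

* The analysis presumes point attractors; persistent oscillation would be
  reported as non-convergence and those grid points excluded, not analysed.
  None of the shipped parameterizations cycles.
* Branching-region phenomenology is slow (see above); the branching band
  itself is thin in trade-off space.
* Stage-dependent infectiousness, assortative mixing between stages, sexual
  transmission and acquired immunity are outside the model's scope.
* Dimorphic adaptive dynamics after branching are handled only by
  simulation, not analytically.
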