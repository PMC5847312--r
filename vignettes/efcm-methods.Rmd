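---
title: "Methods: enzyme-flux cost minimization in efcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-flux cost minimization in efcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efcm)
```

## The model and its assumptions

`efcm` answers one question about a kinetic metabolic model: *which
steady-state flux mode lets the cell grow fastest, and at what yield?* The
workflow rests on three assumptions.

First, at balanced growth the cell's metabolic strategy is a steady-state
flux mode, and in the absence of flux bounds the enzyme cost per unit of
biomass production is minimized at a vertex of the flux polytope — an
elementary flux mode (EFM). Screening all EFMs is therefore an exhaustive
search over candidate optima, not a heuristic.

Second, enzyme demand follows the common modular (CM) rate law. For a
reaction with turnover number $k_{cat}$, equilibrium constant $K_{eq}$ and
Michaelis constants $K_M$, the enzyme concentration needed to sustain flux
$v$ at metabolite concentrations $c$ factorizes as
$$E = \frac{v}{k_{cat}\,\eta_{rev}(\theta)\,\eta_{sat}(c)},\qquad
\theta = \ln K_{eq} - \textstyle\sum_i n_i \ln c_i,$$
$$\eta_{rev} = 1 - e^{-\theta},\qquad
\eta_{sat} = \frac{\prod_{sub} (c_i/K_i)^{|n_i|}}
{\prod_{sub} (1 + c_i/K_i)^{|n_i|} + \prod_{prod} (1 + c_j/K_j)^{|n_j|} - 1}.$$
Both efficiency factors lie in $(0,1]$ for a forward-driven reaction, and
their product is the reaction's capacity utilization (apparent over
maximal catalytic rate). The total cost $E_{met} = \sum_r w_r E_r$, with
$w_r$ the enzyme's molecular mass in Da, is measured in mg/l and is convex
in the log-metabolite vector — the key property that makes the inner
optimization (Enzyme Cost Minimization, ECM) globally solvable. A
substrate-only saturation variant can be emulated by omitting product
$K_M$ entries; the cost weight is the molecular mass, and alternative
weightings can be expressed by rescaling `enzyme_mass_da`.

Third, growth rate follows from minimal cost through a semi-empirical
protein-allocation law,
$$\mu = \frac{a\,f_{prot}\,v_{BM}}{E_{met} + b\,f_{prot}\,v_{BM}},$$
which assumes the metabolic-enzyme fraction of protein declines linearly
with growth rate. It is an organism-level calibration, not mechanism; the
constants therefore live in the model bundle's configuration, never in
code.

## Parameters and units

* Concentrations are mM throughout; $K_{eq}$ uses the mM convention. The
  literature often leaves this implicit, so it is worth stating: changing
  the concentration unit rescales every $K_{eq}$ by the unit ratio raised
  to the net molecularity.
* Fluxes are mM/s; the biomass flux convention defaults to 1 mM/s.
  Enzyme masses in Da (mg/mmol) make $E_{met}$ come out in mg/l.
* Default metabolite bounds, used when a compound row leaves them blank:
  $c \in [10^{-3}, 10]$ mM — the span of typical intracellular metabolite
  measurements. They are per-compound columns, not constants.
* Growth constants default to $a = 0.27$, $b = 0.2$ h, $f_{prot} = 0.5$,
  $v_{BM} = 7.45\times 10^7$ mg l$^{-1}$ h$^{-1}$ (the E. coli
  calibration); toy generators use a scaled-down $v_{BM} = 2.16\times
  10^5$ so that toy costs of order $10^3$–$10^4$ mg/l land in a realistic
  growth range and a unit-uptake chain has a yield of exactly 10 g/C-mol.
* Biomass reactions get $k_{cat} = 10^6$ s$^{-1}$ in the generators so the
  lumped biomass step never limits the optimum; it is an ordinary reaction
  otherwise.
* Yields are grams of biomass per carbon mole of glucose consumed,
  computed from the uptake substrate's `carbon_count` (6 for glucose).

## Numerical choices

**EFM enumeration** runs the classical tableau double-description
algorithm on integer arithmetic: stoichiometric rationals are cleared per
metabolite row (row scaling leaves the nullspace unchanged), every
combined ray is reduced by its gcd, and a guard trips at $2^{50}$ — beyond
that, exactness of double-precision integers is no longer guaranteed, so
the run aborts loudly rather than truncate. Reversible reactions are split
into forward/backward halves; pure two-cycles vanish when halves are
merged back, and modes are reported in net orientation. A fully reversible
mode and its reverse are two distinct modes and both are returned. After
the combinatorial phase, each support is audited by a rank test
(rank = support size − 1). Entries below $10^{-12}$ relative to the mode's
largest flux are zeroed before support computation. An explicit
`max_rays` cap (default $10^5$) turns combinatorial blow-up into an error,
never a silent truncation. Modes that do not produce biomass are kept and
flagged, but excluded from rate/yield analyses; condition-class counts can
therefore be taken before or after biomass filtering via
`biomass_only`.

**ECM** optimizes over $x = \ln c$ of the internal metabolites appearing
in the active subnetwork, inside the box bounds. Feasibility is
established first by maximizing the minimal driving force with an annealed
log-sum-exp softmin (temperatures $1 \to 10^{-3}$); if even the best
profile leaves $\min_r \theta_r \le 10^{-6}$ RT (the positivity floor,
`theta_floor`), the polytope is empty and a typed error names the most
constrained reaction. The main solve is L-BFGS-B with an analytic
gradient, started at the max-min-theta point (well interior); the cost
itself diverges as any $\theta \to 0^+$, acting as a natural barrier, and
trial points that overshoot the floor receive a finite penalized value
with a restoring gradient. Convexity justifies the single start. A restart
from the solution guards against premature line-search termination and is
kept only on strict improvement; convergence is certified by the projected
gradient (bounds-aware) falling below $10^{-6}$ of the cost. Reversible
reactions running backward are re-oriented: stoichiometry negated,
$K_{eq}$ inverted, same $k_{cat}$ and $K_M$ — the factorized
parameterization never uses a backward turnover number, so supplying one
would be ignored (Haldane consistency is moot in this form).

**Sensitivities** use the envelope theorem: at the optimum, the
first-order cost effect of any parameter equals its effect at fixed
metabolite levels, so $\partial E_{met}/\partial \ln k_{cat,r} = -w_r E_r$
and analogous closed forms for $K_{eq}$, $K_M$ and external
concentrations; $d\mu/dp$ follows by the chain rule through the growth
law. No re-optimization is run.

**Winner maps** (Monod scans) break growth-rate ties within $10^{-10}$
h$^{-1}$ by higher yield, then lower mode id, so maps are deterministic.
Cells where no mode is feasible are flagged, not dropped. ECM solutions
are cached by a content hash of (flux mode, condition, kinetics), making
scans and knockout screens re-optimization-free. Grids are log-spaced by
convention in the CLI (`min:max:n`).

**Epistasis** between knockouts is reported as the multiplicative score
$\varepsilon = \mu_{AB}\,\mu_{wt}/(\mu_A\,\mu_B)$. The choice of statistic
is genuinely open — additive and log-scale definitions are equally
defensible — so all four underlying growth rates are returned and the
score is recomputable under any convention; lethal singles yield an `NaN`
score with explicit lethality flags rather than an arbitrary number.

## What the synthetic generators emulate — and what they do not

The generators produce complete, valid model bundles with known structure:
`make_chain_model` (one mode, feasible by construction because every
sampled $K_{eq} \ge 10$ admits the flat metabolite profile),
`make_diamond_model` (two modes), `make_branch_tradeoff_model` (a
*certified* rate/yield trade-off: fixed kinetics make the carbon-wasting
route cheap and the carbon-conserving route expensive, so the high-yield
mode is always the slow one), and `make_random_model` (random sparse
topologies for enumeration property tests). Kinetic constants are sampled
log-uniformly ($k_{cat} \in [1,100]$ s$^{-1}$, $K_M \in [0.01,1]$ mM,
$w \in [10^4,10^5]$ Da) with $K_{eq}$ re-drawn until every biomass mode
has a nonempty polytope — feasibility by construction keeps fixtures
stable across solver versions. A fixed seed fully determines every
bundle.

These toys exercise every code path, but they are small (3–12 reactions),
carbon bookkeeping is simplistic, and the kinetics are not calibrated to
any organism. Passing tests therefore demonstrates correctness of the
algorithms — steady states, elementarity, convex optimality, envelope
identities, monotonicity laws — not predictive accuracy for real
metabolism, which depends entirely on the quality of the kinetic constants
in the user's bundle. The problem sizes used throughout the suite (chains
of 2–6 reactions, random networks of at most 12, grid searches of
400×400, spectra over 2 modes) were chosen as the smallest instances that
make each property non-trivial.

## Degenerate inputs and edge cases

Zero-flux reactions have exactly zero demand. A reaction whose reactants
carry no $K_M$ entries has $\eta_{sat} = 1$ (saturation effects need
binding constants; external reactants without $K_M$ contribute to the
driving force only — supply their $K_M$ when transporter saturation
matters, as the glucose-uptake Monod behaviour does). An external
concentration of zero is legal in a condition and simply makes any mode
touching that compound infeasible; condition filtering by the oxygen tag
classes removes such modes before the solver sees them. Modes consuming no
glucose have undefined yield (`NA`), and knockouts that kill every mode
return an infinite growth advantage rather than an error.

## Known limitations

* Enumeration is exact but exponential; beyond the cap it stops rather
  than samples. Elementary flux *vectors* under flux bounds are out of
  scope.
* Allosteric regulation, non-convex rate laws, and sampling of the
  metabolite polytope are not implemented; the rate-law code is factored
  so a regulation term could be added as another efficiency factor.
* The growth conversion is a two-parameter calibration; mechanistic
  ribosome/proteome partitioning (RBA/ME-style) is deliberately not
  modelled.
* SBML import, when used, supplies stoichiometry only; kinetics always
  come from the TSV tables.
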