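---
title: "Gene-to-phenotype ideotype design for peach fruit quality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-to-phenotype ideotype design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideofruit)
```

## What the package computes

`ideofruit` designs peach fruit *ideotypes* — virtual genotypes optimal for a
set of target traits — by chaining three components:

1. a **QTL genetic model**: an additive linear map from a 31-locus binary
   genotype to the seven parameters of a fruit quality model;
2. a **process-based fruit model** simulating, from those parameters, three
   traits over the 87–150 days-after-bloom (DAB) window: final fruit dry
   mass (DM, g), stone-to-fruit dry mass ratio (SR) and flesh total sugar
   concentration (SU, g per 100 g fresh mass);
3. a from-scratch **NSGA-II** optimizer that maximizes DM and SU and
   minimizes SR — i.e. minimizes the objective triple $(-DM, SR, -SU)$ —
   over four nested search spaces: the observed parameter box, the
   genetically restricted box, the free 31-locus allele space, and the
   allele space under linkage constraints.

A synthetic backcross progeny module closes the loop: it generates the kind
of data the genetic model was estimated from, so the estimation stages
(growth-curve fitting, allele-effect regression) are testable end to end
without any field data.

## The genetic model

Each parameter $\theta$ is predicted as
$\theta = \mu_\theta + \sum_{x} a_{\theta,x}\,\mathrm{loc}[x]$, where
$\mathrm{loc}[x] \in \{0, 1\}$ indicates the allele at locus $x$ (0 = wild
*P. davidiana* D allele, 1 = cultivated S allele) and $a_{\theta,x}$ is the
additive substitution effect. The intercepts therefore describe the all-D
genotype. The packaged peach model (`peach_genetic_model()`) has 37 effect
terms over 31 distinct loci; five loci are pleiotropic. Epistasis and
dominance are out of scope: the progeny design is bi-allelic per locus.

Because effects are additive and loci unconstrained, the extreme value of
each parameter over all $2^{31}$ allele combinations is attained by setting
to 1 exactly the loci with negative (for a minimum) or positive (for a
maximum) effects; `parameter_bounds()` exploits this and also returns the
attaining genotypes. Recomputing the published restricted box this way
reproduces it except for one cell: the `kstone` minimum evaluates to
0.05462 from the packaged coefficients while the source table prints
0.05448, a $1.4\times10^{-4}$ discrepancy attributable to coefficient
rounding. The package reports the recomputed value.

### Linkage

Fourteen pairs of loci closer than 12.5 cM are treated as inseparable.
These pairs chain: their transitive closure (`build_blocks()`, a union-find)
partitions the 31 loci into 8 multi-locus haplotype blocks plus 9
singletons — 17 free binary dimensions. The pair list is packaged data; map
distances are not re-derived. Two constraint-handling modes exist:

* **block encoding** (default): the optimizer works on 17 block bits and
  `decode_blocks()` expands them, so every candidate is feasible by
  construction. This also makes the search space exhaustively enumerable
  ($2^{17} = 131{,}072$ genotypes), which is how the package builds the
  exact reference Pareto front its stochastic runs are judged against.
* **constraint domination**: the optimizer works on all 31 loci; the number
  of broken pairs is the violation measure, and selection applies the
  feasibility rule (feasible beats infeasible; less violation beats more).
  A genotype counts as feasible when its violation is below a tolerance
  $\varepsilon = 10^{-9}$.

Block encoding is the default because it guarantees feasible output and
admits the exhaustive oracle; the constrained formulation is kept as the
declarative alternative.

## The fruit model

Potential fruit dry mass grows logistically in thermal time $d_j$ (growing
degree-days, GDD):

$$DM_{fruit}(d_j) = DM_0 - \frac{A \cdot DM_0^{B}}{1 + e^{-RGR_{ini}(d_{j0} - P_3)}} + \frac{A \cdot DM_0^{B}}{1 + e^{-RGR_{ini}(d_j - P_3)}}$$

anchored so that mass at the initial date $d_{j0}$ is exactly $DM_0$. The
numerator is read as $A \cdot DM_0^{B}$ (the asymptote scale as a power of
the initial mass); the source text is typographically ambiguous between
this and $A \cdot DM_0 \cdot B$, so the alternative reading is available
via `growth_config(asymptote_form = "product")`. Logistic terms are
evaluated with `plogis()`, which saturates instead of overflowing for
arbitrarily extreme arguments.

Stone dry mass follows the saturating allometry
$DM_{stone} = W_{stone}(1 - e^{-k_{stone} DM_{fruit}})$, and the stone
ratio is the quotient of the two curves. For extreme parameter
combinations (large $k_{stone} W_{stone}$, small fruit) the allometry alone
can demand more dry mass than the fruit contains; the realized stone mass
is therefore capped at `sr_max` (default 0.9) times fruit mass. One can
show the cap also keeps the realized flesh growth rate strictly positive,
so flesh mass and the sugar pool stay positive for every parameter
combination in the search boxes.

Sugar carbon in the flesh obeys the linear balance

$$\frac{dC_{sugar}}{dt} = F_{Csupp}\left(1 - \frac{\alpha}{\alpha+\beta}\right) - k_{sugar} C_{sugar},
\qquad SU = \frac{100\, C_{sugar}}{\sigma_{TS}\, FM_{flesh}}$$

with $\alpha$ the growth respiration coefficient and $\beta$ the carbon
concentration of biomass. The surrounding biophysics (photosynthesis,
reserves, water flows, the Lockhart equation) is deliberately out of scope;
three declared closures replace it:

* **demand-driven source**: realized growth equals the logistic potential
  and the flesh carbon supply covers it,
  $F_{Csupp} = (\alpha + \beta)\, dDM_{flesh}/dt$, evaluated analytically
  from the model derivatives. An optional hook
  (`growth_config(sla_ref = )`) multiplies growth by
  $\min(1, SLA/SLA_{ref})$ for source-limitation studies; by default the
  source is non-limiting, under which SLA does not move the three traits —
  a deliberate reflection of its observed low influence.
* **fresh mass**: $FM_{flesh} = DM_{flesh}/dmc$ with flesh dry matter
  content `dmc` = 0.15 g DM/g FM.
* **initial sugar**: $C_{sugar}(t_0) = f_0\, \beta\, DM_{flesh}(t_0)$ with
  $f_0 = 0.5$, since the balance needs an initial condition the equations
  alone do not supply.

### Constants, units and defaults

| constant | default | units | meaning |
|---|---|---|---|
| `dm0` | 2 | g | fruit dry mass at the start of the window |
| `start_dab`, `end_dab` | 87, 150 | d | simulation window (days after bloom) |
| `alpha` | 0.08 | gC/gDM | growth respiration coefficient |
| `beta` | 0.44 | gC/gDM | carbon concentration of biomass |
| `ksugar` | 0.05 | 1/d | sugar-to-other-compounds conversion rate |
| `sigma_ts` | 0.42 | gC/g | mean carbon content of sugars |
| `dmc` | 0.15 | g/g | flesh dry matter content |
| `f0` | 0.5 | — | initial sugar fraction of structural flesh carbon |
| `step` | 1 | d | integration step |
| `base_temp` | 0 | °C | GDD base temperature |
| `sr_max` | 0.9 | — | realized stone share cap |

These are literature-style peach values chosen once; none is
genotype-dependent, all are overridable, and no published comparison in the
test suite depends on them. `ksugar` is a configuration constant, not a
genotype-dependent parameter, because the seven estimated parameters do not
include it. The packaged weather is a constant 22 °C season
(`synthetic_weather()`), making thermal time linear in calendar time with
the inflection-point range of `P3` (1760–2825 GDD) falling around the
middle of the window; any real weather table with `day`/`tmean` columns can
be substituted. The base temperature of 0 °C matches that GDD scale.

### Numerics

The sugar balance is integrated by classical fixed-step 4th-order
Runge–Kutta on the daily grid (`deSolve::ode(method = "rk4")`), with the
forcing evaluated analytically at the half-steps, so the scheme keeps its
nominal order (the suite verifies observed order ≥ 3.5 and a pinned
trajectory stable to $10^{-7}$ under 20× step refinement). The batch
simulator used by the optimizer and the enumerations performs the same
integration vectorized across individuals and agrees with the single-fruit
path to $10^{-10}$. Integrations that would drive the sugar pool negative
(possible only with user-supplied negative forcing) abort with a
smaller-step suggestion rather than returning a negative pool.

## The optimizer

NSGA-II is implemented from scratch: fast non-dominated sorting
($O(MN^2)$, verified against a brute-force oracle), crowding distance
(boundary solutions infinite; zero-range objectives skipped), binary
tournament on (rank, crowding, coin flip), simulated binary crossover with
distribution index 20 and bounded polynomial mutation with index 10 for
continuous decisions, single-point crossover and independent bit flips for
binary ones, and $\mu+\lambda$ elitist truncation. The published settings
are the defaults: population 100, 250 generations, crossover probability
0.9, mutation probability 0.1 per variable (continuous) or 0.01 per bit
(binary).

Reported solution sets can exceed the population size, which is only
consistent with an archive accumulated across generations; the default
`archive = "all_nondominated"` therefore keeps the distinct union of
rank-1 solutions of every generation, pruned by constraint-aware
domination. Duplicates are exact decision-vector matches for binary
problems and componentwise matches at 12 significant digits for continuous
ones. `archive = "final_population"` restricts reporting to the last
population. Published dataset cardinalities are treated as qualitative —
archive semantics are a reporting convention, not a model property.

Front quality is measured by dominated hypervolume (2D staircase sweep
inside 3D slabs, cross-checked against Monte-Carlo integration), with the
reference point fixed at the enumerated front's nadir plus 10% of its
range.

## The synthetic progeny

`progeny_spec()` emulates the mapping population: 159 individuals, wild
D-allele frequency 1/4 per locus (the BC2 expectation), weekly trait
observations over the window, and genetic variance shares of 10–50%
depending on the parameter (defaults: A 0.5, B 0.2, RGRini 0.3, P3 0.4,
kstone 0.5, Wstone 0.4, SLA 0.5 — chosen once inside the published band).
Non-genetic noise is Gaussian with variance calibrated against the
empirical genetic variance of the simulated genotypes; draws that would
make a physical parameter non-positive (≈1% of individuals for the most
affected parameter) are redrawn above a floor of 1% of the intercept.

Three generator choices deserve explanation:

* **Within-block recombination.** Loci under 12.5 cM are tightly linked but
  not absolutely: strict co-inheritance would make two loci that share a
  haplotype block *and* a parameter (loci 23 and 26 both carry effects on
  `A` and sit in block {23,24,25,26}) perfectly collinear, so their effects
  would be unidentifiable from any progeny the generator could produce.
  Within a block, each allele therefore copies its neighbour with
  probability 0.9 and is redrawn otherwise — preserving marginal
  frequencies, correlating linked loci (r ≈ 0.9 per adjacent pair, the
  order of magnitude a 12.5 cM window implies), and keeping every effect
  estimable. Setting `recombination_rate = 0` recovers strict
  co-inheritance, which is what the optimization-facing linkage constraint
  assumes.
* **Several fruits per tree.** Each individual contributes 3 fruits with
  their own initial dry masses (uniform on 1.5–2.5 g, recorded with the
  data). With a single shared $DM_0$ the growth curve constrains only the
  product $A \cdot DM_0^B$, leaving $A$ and $B$ unidentifiable; initial
  mass variation across fruits is what separates them — mirroring the
  real design, where several fruits per genotype were monitored.
* **SLA is measured, not fitted.** Specific leaf area does not enter the
  fruit kinetics under the non-limiting source, and in the field it was
  measured directly on leaves; the pipeline takes the simulated parameter
  value as its "measured" SLA.

Curve fitting uses bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with
multi-start: one start at the observed-box midpoint plus 7 random restarts
inside the observed box, followed by a polish pass from the winner.
Optimizer bounds are the union of the observed box and the genetic-model
box — tight physical bounds matter, because weakly identified fits (an
inflection point outside the observation window, a stone curve short of
its plateau) otherwise run away along trade-off ridges. The stone fit
targets the *realized* (capped) stone curve — exactly the observable the
model produces — regresses on the stage-1 fitted growth curve rather than
the noisy observed mass (shared measurement error in regressor and
response would attenuate the estimates), and is weighted by $1/DM^2$
because the stone *ratio* is what is observed with constant error, so
stone-mass noise scales with fruit mass. Individuals with no converged
fit are excluded and counted.
Allele effects are then re-estimated per parameter by joint ordinary least
squares restricted to that parameter's loci (`estimate_allele_effects()`);
a rank-deficient design — e.g. perfectly linked loci both included — is a
hard error naming the collinear loci rather than a silent pseudo-inverse,
because it signals the identifiability problem linked loci create.

What the generator does **not** emulate: the real 340-marker genetic map
and QTL detection (effects are taken as known structure, only their values
are re-estimated), year/environment effects, allometric diameter-to-mass
conversion, the Z-genome contribution of the second backcross, and
non-Gaussian measurement error. Passing tests therefore show that the
estimation machinery inverts data generated by its own model family under
realistic noise — not that the field estimates themselves were unbiased.

## Study conventions and problem sizes

All datasets of a study run share one configuration and weather series so
phenotypes are comparable. Random exploration uses 500 i.i.d. uniform
draws per space (uniform, absent any stated alternative); allele draws use
fair bits per free dimension. The published observed parameter box is
packaged as constants (observed extremes are data); the restricted box is
recomputed from the genetic model at run time.

The test suite runs the exhaustive $2^{17}$ enumeration once, ten seeded
optimizer runs against it (passing when at least nine reach 95% of the
reference hypervolume), three matched random-versus-optimized space
comparisons (passing when at least 90% of random individuals are
dominated), and twenty seeded estimation-pipeline replicates (passing when
every recovered effect's mean is within three Monte-Carlo standard errors
of its generating value, and a zero-noise replicate inverts exactly to
$10^{-3}$ relative). These sizes are the package's own reproduction
conditions, chosen to keep the whole suite a desk-scale computation.

## Known limitations

* Two-stage estimation (per-individual least squares, then ordinary
  regression of fitted parameters on loci) carries a small structural bias
  on weakly identified parameters: when an individual's logistic inflection
  lies outside the observation window, or its stone curve stops short of
  the plateau, the fit error correlates with genotype through pleiotropy
  (fruit size drives stone-curve coverage). Over twenty seeded replicates
  this leaves 36 of the 37 allele effects within three Monte-Carlo standard
  errors of their generating values; the `Wstone` effect at the pleiotropic
  locus 14 is recovered about 14% low (z ≈ −3.2). A mixed-effects
  (shrinkage) estimator would mitigate this, and is deliberately out of
  scope; the effect is documented rather than hidden.
* The carbon source is demand-driven; no feedback from assimilate
  availability, reserves or water status limits growth, so trait values at
  box corners are more extreme than a full biophysical model would give.
* `SU` implements the sugar balance literally; whether "total sugar"
  should exclude further pools (e.g. starch already counted in the other-
  compounds sink) is not resolvable from the equations alone.
* Linkage is binary (inseparable or free); recombination probabilities are
  not part of the optimization, so the constrained front is a conservative
  subset of what breeding could reach.
* The hypervolume reference point convention (nadir + 10% range) is a
  reporting choice; rankings between fronts are insensitive to it in the
  cases tested, absolute values are not.
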