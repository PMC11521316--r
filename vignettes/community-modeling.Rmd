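---
title: "Guild-level community metabolic modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild-level community metabolic modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildcom)
```

## The modeling problem

Microbial fuel cells treating sulfide-rich wastewater are driven by a
few functional guilds rather than by individual species. `guildcom`
models such a community as a *functionally lumped compartmentalized*
metabolic model: each guild — sulfate-reducing bacteria (SRB),
acetoclastic methanogens (MET), sulfide-oxidizing bacteria (SOB) — is
one metabolic compartment with its own stoichiometry and capacity
bounds, and all guilds exchange metabolites through a fictitious shared
pool (COM). The community pool, in turn, exchanges with the environment
through uptake reactions $u_i \ge 0$ (influx) and export reactions
$e_i \ge 0$ (efflux) whose bounds encode the wastewater condition.

The central simulation is the steady-state community growth problem
(the SteadyCom formulation): find the largest common growth rate $\mu$
such that abundances $X^k \ge 0$ with $\sum_k X^k = X_0$ exist for
which each guild is internally balanced, all fluxes respect
abundance-scaled capacities, and every pool metabolite balances:

$$\max \mu \quad \text{s.t.} \quad
\sum_{j} S_{ijk} V_{jk} = 0, \quad
LB_{jk} X^k \le V_{jk} \le UB_{jk} X^k, \quad
V_{\mathrm{biomass},k} = X^k \mu,$$
$$u_i - e_i + \sum_k V_{ex(i)}^k = 0, \qquad
\sum_k X^k = X_0 .$$

$V_{jk}$ are aggregate fluxes (mmol gO₂-cell⁻¹ h⁻¹ on the community
cell-mass basis); the per-abundance capacities $v_{ex(i)}^k$ (with
$V = vX$) are the biologically meaningful knobs — "how fast can guild
$k$ consume or secrete metabolite $i$ per unit of its abundance".

Two sign conventions run through the package: positive guild exchange
flux means secretion into the pool (negative consumption), and positive
$u_i$/$e_i$ mean influx to / efflux from the pool.

### Solving the bilinear problem

For fixed $\mu$ the constraints are linear in $(V, X, u, e)$, so the
maximal sustainable total abundance $\max \sum_k X^k$ is one LP; the
community supports growth rate $\mu$ iff that optimum reaches $X_0$,
and the optimum is non-increasing in $\mu$. `maximize_growth()`
therefore bisects on $\mu$ (default tolerance $10^{-6}\,h^{-1}$),
seeding the upper bracket from the largest standalone-FBA growth rate
across guilds and doubling it until infeasible — standalone FBA can
underestimate the community optimum under obligate cross-feeding, so
the bracket is always verified, never trusted. The witness at the
converged $\mu^\*$ is rescaled so $\sum_k X^k = X_0$ exactly (the
constraint set is homogeneous in $(V, X, u, e)$ at fixed $\mu$, so
scaling down preserves feasibility); when the abundance maximum is
unbounded — freely supplied substrate — the scale is pinned by adding
$\sum_k X^k = X_0$ as a constraint instead.

$\mu = 0$ is trivially feasible and excluded from the search; if no
$\mu \ge$ tolerance is feasible, the solution reports growth 0 with
status `infeasible-growth` rather than raising.

### Flux degeneracy

SteadyCom optima pin $\mu$ and (usually) the abundances but leave the
flux distribution degenerate. Reported fluxes therefore need a
determinization rule: `resolve_fluxes()` re-solves at fixed
$(\mu, X)$ minimizing $\sum_j |V_j|$ over internal (non-exchange)
reactions — the parsimonious criterion, which zeroes free cycles and
picks the cheapest of alternative routes. Fluxes below the zero
threshold ($10^{-6}$ mmol gO₂-cell⁻¹ h⁻¹, the same threshold used by
the fold-change analytics) are reported as exact zeros. Abundance ties
at the optimum are not broken further; they are returned as the LP
witness produces them, which is deterministic for a fixed model and
settings but is a vertex choice, not a biological claim.

### The LP core

No linear-programming package is available to this package's
installation footprint, so the LP engine is part of the package: a
dense two-phase primal simplex (Rcpp) with bounded variables handled by
shifting/splitting, explicit range rows, pivot hygiene (pivots below
$10^{-7}$ rejected; largest-pivot tie-breaking; Bland's rule after
stalls), reduced costs recomputed from scratch at each termination to
guard against drift, and geometric row/column equilibration in the R
wrapper. It targets the small-to-medium LPs of guild-level models (up
to a few thousand nonzeros); it is not intended for full
genome-scale-times-many-species systems. The test suite cross-checks
it against `boot::simplex` on random problems and against analytic
optima.

## Conditions: from wastewater chemistry to exchange bounds

`cod_to_substrate_rates()` converts a wastewater characterization into
community-level specific rates. The organic load (as chemical oxygen
demand, COD) is assumed to be 63.12% volatile fatty acids (VFA) by
default, fully oxidizable, split between butyrate and acetate at a
molar ratio of 1.29 (the C4:C2 uptake ratio of the low-loading
baseline). Community cell mass is estimated as cell yield × substrate
load on the O₂ basis, with yield 0.15 g cell-O₂ per g substrate-O₂, and
every specific rate is mass rate / cell mass — which makes the VFA
specific rates invariant to the *total* COD (the cell mass scales with
it); what distinguishes seasons is the VFA composition. Because most
VFA in a real reactor is consumed by guilds outside the modeled three
(notably the exoelectrogens on the anode), a `guild_fraction`
parameter sets the share reaching the modeled community; its default
(0.08) was calibrated once so that the low-season wastewater reproduces
the baseline uptake rates, and is config-exposed.

The shipped presets place the two seasons at butyrate/acetate uptakes
of (1.606, 1.245) and (2.505, 1.618) mmol gO₂-cell⁻¹ h⁻¹. These values
are derived, not measured directly: the loading sweep spans butyrate
0.48–3.61 and acetate 0.77–2.09 jointly and linearly, the low-season
point sits at C4:C2 ratio 1.29, and the seasonal butyrate ×1.56 /
acetate ×1.30 fold-changes then fix both points (and imply the
high-season ratio 1.54). Sulfate and sulfide influx are small
(0.10/0.15 low season; sulfide drops to 0.05 in the high season),
ammonium is generous, and the free-exchange list — metabolites the
community may exchange without bounds — defaults to photons, water and
phosphate, with proton influx bounded at the neutral baseline
4.21×10⁻⁴. `apply_condition()` is closed-world: any pool metabolite
not named by the condition or its free list cannot cross the community
boundary (guild-to-guild exchange only).

## Capacity fitting

`fit_exchange_capacities()` fits named capacity bounds to observed
relative abundances by exhaustive grid search (up to three axes;
coordinate-wise sweeps beyond that, selectable by a flag). Each grid
point is one full growth maximization; the objective is the unweighted
mean percent error of abundances, $|pred - obs|/obs \times 100$
averaged over guilds. Ties keep the first point in row-major scan
order, making the fit fully deterministic. Grids are user-supplied;
log-spacing around the unconstrained values is the sensible default
when nothing else is known.

One semantic deserves emphasis: a *negative upper* bound on an exchange
(as fitted for the MET acetate exchange, −11.55) is a forced minimum
specific consumption — the guild must consume at least that much per
unit abundance, which caps its abundance at (available metabolite)/
(forced rate). A *negative lower* bound (SOB acetate, −1.50) is the
usual consumption capacity. Both appear in the fitted parameter set
and both are honoured by the LP through the same
$LB\,X \le V \le UB\,X$ mechanism.

## The synthetic community

`make_toy_community()` generates a fully specified three-guild model
(11–18 reactions per guild) implementing the assumed physiology:

* **SRB** — butyrate activation and β-oxidation to two acetyl units
  (2 NADH), substrate-level phosphorylation to acetate, a lumped
  Apr/Dsr/ATP-synthase chain reducing sulfate to sulfide (1.5 ATP and
  4 NADH per sulfate), and NADH overflow to H₂ or formate at an ATP
  cost. Without sulfate the ATP balance is strictly negative — sulfate
  is obligatory for growth.
* **MET** — acetoclastic methanogenesis (CH₄ + CO₂ + 0.75 ATP per
  acetate, the lumped Mtr/Hdr/Fpo chemiosmosis) plus acetate
  assimilation.
* **SOB** — stepwise sulfide → sulfur → sulfate oxidation yielding
  NADH (photon-dependent reverse electron flow, lumped), cyclic
  photophosphorylation (1 ATP per photon, doubled when external
  protons are available — the lever behind the proton sweep), acetate
  assimilation and a lumped reductive-TCA CO₂ fixation. SOB biomass
  requires reducing power, tying its growth to sulfide throughput.

Atom bookkeeping uses a reduced element alphabet — real C, S, N plus
moiety elements for electron pairs (G), adenosine (E), phosphate (P)
and NAD (Q) — so every internal reaction is exactly balanced and
checkable by `validate_community()`; photons, protons and water are
massless carriers. Community carbon is conserved end to end: influx
carbon equals efflux carbon plus biomass carbon, which the tests assert
to $10^{-6}$.

Capacity presets sit at the fitted scale of the real community (SRB
sulfide secretion 6.28, MET acetate forced uptake 11.55, SOB acetate
1.50, SRB/MET proton exchange 10⁻⁵ mmol gO₂-cell⁻¹ h⁻¹). The remaining
free dials — biomass ATP costs (SRB 8, MET 7, SOB 6 per unit biomass),
SOB biomass NADH (6), the SR chain ATP yield (1.5) and the SOB photon
capacity (12) — were tuned once, against the generator's own
construction, so that the default presets put the low-loading optimum
in an SOB-dominant regime with SRB rarest, flip dominance to MET
between the two seasonal loadings, and plateau SOB growth once SRB
sulfide secretion saturates. They are declared in
`toy_community_spec()` and are not revisited by any test.

`make_synthetic_observation()` provides ground truth for fitting
experiments: it solves the community, multiplies abundances by
log-normal noise (given `noise_sd` and an integer seed, which fully
determines the table and leaves the session RNG untouched) and
renormalizes to $X_0$.

### What the generator does and does not emulate

It reproduces the cross-feeding *topology* (butyrate → SRB → acetate +
sulfide; sulfide ⇄ sulfate cycling with SOB; acetate competition
between MET and SOB; H₂/formate overflow) and the qualitative
community behavior under loading, capacity and proton perturbations.
It does not attempt quantitative genome-scale realism: biomass
equations are single-precursor lump sums, energy stoichiometries are
coarse, there are no amino-acid or nucleotide exchanges, and growth
rates come out an order of magnitude above typical anaerobic reactor
values. Passing tests on the synthetic community therefore validate
the *method* — solver, fitting, analytics, scans — not the numerical
behavior of any real genome-scale model.

## Analytics

Flux fold change compares conditions as
$FFC = \log_2(V_{H}/V_{L})$ after zeroing magnitudes below $10^{-6}$;
zero and sign-discordant pairs are flagged (`zeroed_L`, `zeroed_H`,
`both_zero`, `sign_discordant`) rather than forced into numbers —
the ratio is undefined there and real comparisons must surface such
cases, not bury them. Intensity categories split at $|FFC|$ 0.64 (the
butyrate-uptake anchor; $2^{0.64} \approx 1.56$) and 2. Min–max
normalization for scan trajectories operates on absolute values and
then reinstates the original signs, mapping each series onto
$[-1, 1]$; constant series are defined as all-zero and flagged.

## Scans and transition detection

All scans are embarrassingly simple loops over conditions or
capacities — one growth maximization per grid point, infeasible points
recorded and skipped. Defaults: 25-point loading sweeps (tests and the
acceptance script use 9–13 points; resolution only shifts transition
estimates by a grid step), 3×3 capacity grids, 11–15 point exponential
proton grids. `detect_transition()` formalizes the phase readouts: the
axis values where the dominance label switches; the first point where
a guild's growth slope falls below 10% (configurable) of its initial
slope (the plateau boundary); and the steepest-decline point of the
guild's abundance — reported alongside the switch because "where the
drop happens" admits both readings, and on exponential grids slopes
are taken per log step (`log_axis = TRUE`).

The 2-D capacity scan reports, per capacity pair, the loading at which
SOB dominance is lost, expressed as percent increase over the
low-season baseline, plus a `transient` flag for grid cells where the
top-two abundance gap is below 0.05·$X_0$. One practical note: with
influent sulfide present, tightening the SRB sulfide capacity lowers
the community growth rate, which *raises* SOB abundance per unit of
sulfide and can mask the cross-feeding effect; scanning under a
sulfide-free influent (S cycling as the only sulfide source) isolates
the interaction strength, and is what the analysis driver does.

## Numerical choices and degenerate inputs

* Bisection tolerance $10^{-6}\,h^{-1}$; LP feasibility tolerance
  $10^{-8}$ (phase-1 absolute), pivot tolerance $10^{-9}$.
* Default reaction bounds ±1000 when an SBML file omits them (with a
  warning), the constraint-based-modeling convention; unbounded
  directions are genuine ±∞ internally.
* Empty condition: all exchanges closed, growth 0 — reported, not an
  error. Zero wastewater load: flagged `zero_condition` instead of
  dividing by a zero cell mass.
* Structural loops are *reported* by `validate_community()` (null-space
  support sets of each guild's internal stoichiometry); no loop-law
  constraint is imposed in the solver — parsimonious resolution already
  zeroes cycles that carry no net function.
* SBML: Level 3 + fbc v2 written; Level 2 tolerated on input
  (kineticLaw bounds); the combined-model reader takes the pool
  compartment by pattern or explicitly, because compartment tag schemes
  of combined models vary between tools.

## Known limitations

* The dense simplex bounds practical model size; genome-scale
  communities (thousands of reactions per guild) need an external LP
  backend, which the `solve_lp()` seam is designed to accommodate.
* Abundances at flat optima are vertex choices; where capacities do not
  bind, fitted parameters are unidentifiable (the fit surface is flat)
  — inspect `search_trace` before trusting a fit.
* The condition builder covers the butyrate/acetate/sulfate/sulfide
  chemistry of this system; it does not model pH equilibria or sulfide
  speciation.
* Dynamic (time-course) community modeling, flux variability analysis
  and loopless FBA are out of scope.
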