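# guildcom

Guild-level community metabolic modeling of microbial fuel cells (MFCs)
treating sulfide-rich industrial wastewater.

MFC reactors fed with organic- and sulfide-containing wastewater are run
by a small number of functional guilds rather than by single species:
sulfate-reducing bacteria (SRB) oxidize volatile fatty acids (butyrate)
with sulfate as the terminal electron acceptor, acetoclastic methanogens
(MET) split acetate into methane and CO₂, and photosynthetic
sulfide-oxidizing bacteria (SOB) regenerate sulfate from the sulfide SRB
release while assimilating acetate and CO₂. How this community
re-organizes when the organic loading rate (OLR) changes between
production seasons — and why reactor performance degrades when
methanogens take over — is a question about *metabolic cross-feeding*:
who eats whose products, at what capacity.

`guildcom` implements the full modeling workflow for that question:

* **Community model assembly** — guild-level genome-scale models (read
  from SBML or generated synthetically) are combined into a
  compartmentalized community model with a shared metabolite pool (COM);
  each pool metabolite gets community uptake/export reactions and every
  guild keeps its own stoichiometry.
* **SteadyCom growth optimization** — the community growth problem

  maximize μ subject to, for every guild *k*:

  ```
  Σ_j S_ijk V_jk = 0                      (guild mass balance)
  LB_jk X^k ≤ V_jk ≤ UB_jk X^k            (abundance-scaled capacities)
  V_biomass,k = X^k μ                     (biomass coupling)
  u_i − e_i + Σ_k Vex(i)^k = 0            (pool metabolite balance)
  Σ_k X^k = X₀,  X^k, u_i, e_i ≥ 0
  ```

  is solved by monotone bisection on μ over the linear feasibility
  problem "maximize Σ X^k at fixed μ", with an optional parsimonious
  second stage that picks the flux distribution of minimal total
  magnitude. The LP core is a dense two-phase simplex written for this
  package (no linear-programming backend is assumed).
* **Condition building** — wastewater chemistry (COD, VFA fraction,
  sulfate/sulfide loads, cell yield) is converted into community-level
  specific exchange bounds; presets ship for the low- and high-loading
  seasons (L-OLR, H-OLR).
* **Capacity fitting** — guild exchange capacities vex(i)^k are fitted
  to observed relative abundances by deterministic grid search with the
  unweighted mean percent error as the objective.
* **Analytics and scans** — flux fold changes FFC = log₂(V_H / V_L)
  with a 1×10⁻⁶ zero threshold, min–max normalization with sign
  reinstatement, cross-feeding ratios, reducing-power partitions,
  joint loading sweeps, 2-D SRB–SOB capacity scans and exponential H⁺
  sweeps with dominance/transition detection.
* **Synthetic community** — a fully specified, elementally balanced
  three-guild model that reproduces the assumed cross-feeding topology,
  so the entire pipeline is testable without any external model file.

## Worked example

```r
library(guildcom)

model <- make_toy_community(toy_community_spec())
settings <- solver_settings(flux_resolution = "parsimonious")

low  <- maximize_growth(model, settings)
high <- maximize_growth(apply_condition(model, condition_preset("H-OLR")),
                        settings)
print(low)
#> <steadycom_solution> status = optimal, mu = 0.753698 h^-1
#>   abundances: SRB = 0.1880, MET = 0.3082, SOB = 0.5038
print(high)
#> <steadycom_solution> status = optimal, mu = 1.00009 h^-1
#>   abundances: SRB = 0.1711, MET = 0.5041, SOB = 0.3248
```

At low loading the sulfide oxidizers dominate (50% of the community)
and the sulfate reducers are rarest; raising the butyrate/acetate
loading to the high-season condition flips the community to
methanogen-dominated — the structural transition the workflow is built
to explain. The analytics quantify the mechanism:

```r
exchange_ratio(low,  "ac", "MET", "SOB")$ratio   # 4.71
exchange_ratio(high, "ac", "MET", "SOB")$ratio   # 12.07
nadh_partition(low,  "SRB", "SR", "BUTOX")$percent   # 50.0
nadh_partition(high, "SRB", "SR", "BUTOX")$percent   # 43.6
```

Methanogens out-consume the sulfide oxidizers on acetate 4.7-fold at
low loading and 12-fold at high loading, while the share of SRB
reducing power reaching sulfate respiration falls from 50% to 44% —
the surplus leaves as hydrogen and formate. A loading sweep
(`olr_sweep`) locates the dominance transition about 27% above the
low-season baseline, with SOB growth plateauing once SRB sulfide
secretion saturates its capacity (6.28 mmol gO₂-cell⁻¹ h⁻¹).

The numbered scripts under `analysis/` run the full study — model
building and validation, capacity fitting and two-condition simulation,
flux fold-change comparison, and the three sensitivity scans — writing
tables under `results/`:

```sh
Rscript analysis/01_build_community.R
Rscript analysis/02_fit_and_simulate.R
Rscript analysis/03_flux_comparison.R
Rscript analysis/04_sensitivity_scans.R
```

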