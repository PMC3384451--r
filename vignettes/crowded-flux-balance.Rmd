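---
title: "Crowding-constrained flux balance analysis and metabolic switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding-constrained flux balance analysis and metabolic switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdFBA)
```

## The model

Flux balance analysis (FBA) treats a metabolic network as a linear system at
steady state: with $S$ the stoichiometric matrix and $f$ the flux vector,

$$ S\,f = 0, \qquad f_{lb,i} \le f_i \le f_{ub,i}, $$

and maximizes an objective flux (biomass production for genome-scale models;
an ATP drain for lumped toy models, which have no biomass composition).
Because FBA fixes the glucose uptake bound, it effectively maximizes growth
*yield* and therefore never predicts low-yield fermentation in the presence
of a high-yield pathway.

`crowdFBA` implements the molecular-crowding extension (FBAwMC): only a
finite volume of catalytic protein fits into a cell, so sustaining flux has
a volumetric price. Each reaction $i$ carries a *crowding coefficient*
$c_i$ — the fraction of cell volume that must be occupied by enzyme to
sustain unit flux — and the flux distribution must respect the budget

$$ \sum_i c_i\,|f_i| \;\le\; V_{prot}, $$

where $V_{prot} \in (0, 1]$ is the volume fraction available to metabolic
enzymes. The absolute value matters: a reversible reaction consumes enzyme
whichever way it runs, so the implementation splits every reversible
reaction into two non-negative directional variables that share one
coefficient. A signed sum would let reverse flux subsidize forward crowding.

Crowding coefficients derive from enzyme data as
$c = \frac{M}{V}\,\frac{v}{b}$: $M/V$ is the cell dry-mass density
(default 340 gDW/l, configurable — only its product with the coefficient
scale matters jointly with $V_{prot}$), $v$ the enzyme's molar volume
(specific protein volume 0.73 ml/g times the molar mass, converted to
l/mmol), and $b$ the flux per mole of enzyme, taken as the
substrate-saturated turnover rate $k_{cat} \times 3600$ per hour. Units
work out to gDW·h/mmol, so that $c_i f_i$ is dimensionless.

## Why ensembles

Crowding coefficients for most enzymes are unknown. Rather than committing
to one estimate, the package treats the pool of coefficients derived from a
turnover/mass table as a *distribution of plausible values* and studies the
network over many random assignments: each enzymatic reaction draws a
coefficient uniformly (with replacement) from the pool; non-enzymatic
reactions — exchanges, drains, spontaneous steps — pay nothing. Enzymes are
deliberately not identity-mapped to reactions: the ensemble characterizes
what the network architecture can do over physiologically plausible
parameterizations, not what one parameterization does.

Turnover tables are curated before use (`buildKcatTable()`): per enzyme,
wild-type measurements are preferred when present, the fastest record wins,
and enzymes slower than 0.01/s are dropped (such values typically belong to
non-metabolic activities or atypical substrates; the boundary value itself
is retained, reading the cut strictly).

## The geometry of the optimum, and the mode-counting statistic

At unconstrained glucose influx, if the crowding constraint is the single
binding constraint, the linear program's optimum lies on one *elementary
flux mode* (EFM) — a support-minimal steady-state route — namely the one
maximizing objective-per-crowding-cost; the optimal objective is exactly
that ratio times $V_{prot}$. The test suite exploits this as an independent
oracle: EFMs of networks with at most eight internal reactions are
enumerated by brute force over support sets (SVD null spaces), and the LP
optimum is compared with the best mode ratio to $10^{-6}$ relative
tolerance. The premise requires coefficients large enough that no flux cap
is reached; the oracle checks therefore sample coefficients in roughly
$7\times10^{-3}$–$7$ gDW·h/mmol, for which all optimal fluxes stay well
below the 1000 mmol/gDW/h sentinel caps.

Because each draw's optimum realizes one mode, ensemble growth yields
concentrate on a few values. `countMetabolicModes()` clusters sorted yields
by single linkage with a relative gap (default 1%, robust to LP rounding)
and discards clusters holding under 1% of draws. `runEnsemble()` exposes a
`glucoseBound` argument: with a finite bound, glucose and crowding can bind
simultaneously and optima may mix two modes, smearing the yield
distribution — the default keeps glucose unconstrained.

## The five-reaction network

`buildSimplifiedNetwork()` is a lumped model of the fermentation/respiration
choice in a facultative anaerobe, coupling five reactions through pyruvate,
NADH and ATP:

| reaction | stoichiometry | role |
|---|---|---|
| `R_glycolysis` | glc → 2 pyr + 2 ATP + 2 NADH | backbone |
| `R_acetate` | pyr → ac + CO2 + 1 ATP + 1 NADH | energy-yielding excretion |
| `R_lactate` | pyr + 1 NADH → waste | redox-restoring excretion |
| `R_tca` | pyr → 3 CO2 + 5 NADH + 1 ATP | high-yield oxidation |
| `R_oxphos` | NADH + 0.5 O2 → 2 ATP | P/O = 2 |

FADH2 is lumped into NADH, GTP into ATP, and the pyruvate-dehydrogenase
NADH is folded into the acetate step. Every coefficient is configurable via
the `coef` argument. The network admits exactly three ATP-yielding
elementary modes — lactate fermentation (2 ATP/glc), acetate excretion plus
oxidative phosphorylation (12 ATP/glc), and TCA plus oxidative
phosphorylation (28 ATP/glc) — and the package's tests verify this census
against the brute-force oracle. The count of three is a structural fact,
not a coefficient choice: writing $g$ for NADH per glucose in glycolysis,
$\alpha \ge 0$ for NADH produced per pyruvate on the acetate branch and
$\beta > 0$ for NADH consumed per pyruvate on the lactate branch, a pure
lactate mode exists iff $g = 2\beta$, and under that equality the supports
{glycolysis, acetate, lactate} and {glycolysis, lactate, TCA} force the
acetate/TCA flux to zero. So within this architecture (these five reactions
and exchanges for glucose, oxygen, acetate, waste and CO2), a
redox-consistent coefficient choice cannot have both a pure fermentative
mode and a fourth elementary mode. Reduced models of overflow metabolism
with an *additional* intermediate-yield mode must differ structurally, for
example by an extra redox-decoupled energy-yielding route.

The analysis the ensemble supports is unchanged by the census: acetate
excretion creates an intermediate-yield optimum that is only viable with
respiration running (its NADH must be reoxidized), so blocking acetate
excretion (`knockoutExchange(model, "EX_ac")`) collapses the yield
distribution to exactly two modes, high-yield and low-yield — the signature
of a full metabolic switch rather than overflow behavior. Overexpression of
a water-forming NADH oxidase (`noxReaction()`, forced through
`addOverexpression()`) drains NADH without ATP and weakly suppresses the
fermentative branch at matched coefficient draws; the alternative-oxidase
spec is the same net sink at this lumped resolution, differing only in
localization, which the model does not represent.

## Fitting the crowding budget

$V_{prot}$ is fitted to an observed (maximal growth rate, maximal glucose
uptake) pair by grid search: per grid value an ensemble is run, fitted
values are ensemble means, and the criterion

$$ \left(\frac{\mu_{fit}-\mu_{obs}}{\mu_{obs}}\right)^2 +
   \left(\frac{G_{fit}-G_{obs}}{G_{obs}}\right)^2 $$

is minimized (ties to the smallest budget). `fitVprot()` reuses one master
seed across grid values — common random numbers — so the criterion compares
budgets on identical coefficient draws. The recovery tests use the
round-trip design: `generateObservedGrowth()` produces synthetic
observations at a known budget and the fit shares its master seed. With a
degenerate one-point pool recovery is exact by linearity of the optimum in
$V_{prot}$; with a broad pool it is exact at matched draws. With
*independent* draws, the same linearity makes the recovery error equal the
relative error of the ensemble-mean estimate, which for multi-decade
coefficient pools is irreducibly larger than a 0.01 grid step at ensemble
size 100 — a genuine limitation of mean aggregation over heavy-tailed
ensembles, worth knowing before fitting real data at small $n$.

## Synthetic data: what it emulates and what it does not

`generateKcatTable()` draws turnover numbers log-uniformly over
$10^{-2}$–$10^4$ /s and masses over $10^4$–$10^6$ g/mol, matching the
multi-decade histogram shape of curated database extracts without asserting
a parametric family; 10% of enzymes get an extra non-wild-type record and
10% a sub-threshold turnover, so the curation filters are exercised.
`generateToyNetwork()` builds branched backbone–branch architectures whose
elementary modes and ATP yields are known by construction. These inputs
validate the machinery — they do not emulate genome-scale topology,
enzyme–reaction identity, or correlations between mass and turnover, so
passing tests certify the solver and the ensemble statistics, not
organism-specific predictions. Reproducing published organism-level numbers
(low-yield fractions, repression fractions, fitted budgets near 0.15–0.2)
requires the published genome-scale models and curated turnover tables as
external inputs via `readModel()` and `readKcatTable()`.

## Numerical choices

The LP core is a dense two-phase primal simplex with Bland's smallest-index
anti-cycling rule and row equilibration — chosen over an external solver
dependency because the bundled problems are tiny (tens of variables) and
the ensemble contracts require bitwise-reproducible optimal *vertices*, not
just objective values. It is cross-checked against an independent simplex
implementation on random LPs in the test suite. Optima are degenerate in
general ("the solution is not necessarily unique" is intrinsic to flux
balance problems); the default tie-break re-solves at the optimal objective
pinned by an equality row, minimizing total crowding usage, which makes
excretion classification reproducible. Feasibility tolerance is $10^{-9}$,
objective comparisons use $10^{-6}$, and "unconstrained" bounds are the
1000 mmol/gDW/h sentinel. Infeasible configurations (e.g. a forced
overexpression flux the network cannot sustain) are reported as a status,
never an error, so ensembles continue past pathological draws.

Problem sizes used throughout the bundled analyses — ensembles of 1000
draws on the five-reaction network, oracle sweeps of 100 draws over 21 toy
networks, fitting grids of 16 budgets at ensemble size 100 — were chosen so
the full analysis reruns from scratch in about two minutes on one core
while keeping binomial noise on reported fractions near the percent level.

## Limitations

Gene–protein–reaction rules are not parsed; which reactions count as
enzymatic follows the reader's heuristic (everything except exchanges and
drains) and can be corrected with `setEnzymatic()`. Saturation corrections
to $b$ (Michaelis–Menten) are out of scope — $b = V_{max}$ throughout.
SBML support covers Level 2 kinetic-law bounds and Level 3 `fbc` bounds and
objectives, read-only. The mode-counting statistic assumes well-separated
cluster yields; two modes closer than the relative gap merge by design.
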