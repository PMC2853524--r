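---
title: "Dynamic flux balance analysis of the Streptomyces metabolic switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flux balance analysis of the Streptomyces metabolic switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchFBA)
```

## The problem

*Streptomyces coelicolor* reorganizes its metabolism when an essential
nutrient runs out: exponential growth stops and secondary metabolism —
notably antibiotic biosynthesis — switches on. In a phosphate-limited
fermentation this switch happens at about 34 hours. switchFBA models the
reorganization with constraint-based analysis: a genome-scale stoichiometric
model is solved by flux balance analysis (FBA) at every sampled time point,
with nutrient-uptake measurements as time-varying bounds and an objective
that shifts from biomass toward antibiotic production at the switch. The
predicted flux time courses are then compared with gene expression time
series, gene by gene, to validate the model and to flag genes whose
regulation contradicts their annotation.

## The model and its assumptions

FBA solves the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \;\; l \le v \le u,$$

where $S$ is the metabolites × reactions stoichiometric matrix, $v$ the flux
vector (mmol/gDW/h), and $c$ selects the biomass reaction, whose flux is the
specific growth rate $\mu$ (1/h). Exchange reactions carry one metabolite
across the system boundary; uptake is a negative exchange flux, so a
measured uptake rate $r$ becomes a lower bound $-r$. Secreted by-products
are always free to leave.

Three assumptions matter:

1. **Quasi-steady state.** Each time point is solved as an independent
   steady state. There is no ODE coupling of biomass or by-product
   concentrations between time points; the dynamics enter only through the
   bounds and the objective. This matches a fermentation sampled hourly,
   where intracellular metabolite turnover is much faster than the changes
   in the medium.
2. **Optimal resource allocation.** Before the switch the cell maximizes
   growth. From the switch time $t_s$ (default 34 h) the objective becomes
   $\mu + \sum_k \beta_k(t)\, v_{\text{ab},k}$, where $v_{\text{ab},k}$ is
   the secretion flux of antibiotic $k$ and $\beta_k(t)$ is proportional to
   its measured production rate, converted from µg/gDW/h to mmol/gDW/h via
   the compound's molecular weight (taken from the species formula in the
   model; actinorhodin C~32~H~26~O~14~, 634.5 g/mol). The proportionality
   constant (`weight_scale`) is a free parameter, default 1; any positive
   weight below the biomass weight routes surplus carbon into the
   antibiotic, so results are insensitive to its exact value in the regimes
   we model. An alternative encoding — pin the antibiotic exchange to the
   measured molar rate and maximize biomass (`objective_mode = "forced"`) —
   is provided because "adding antibiotics to the biomass composition" is
   ambiguous between the two; the weighted form is the default.
3. **Parsimonious resolution.** The LP optimum value is unique but the
   optimal flux vector usually is not. Every reported flux vector minimizes
   total absolute flux $\sum_j |v_j|$ among optima (within a floor tolerance
   on the objective). This removes futile cycles and makes flux profiles
   reproducible — essential when they are correlated against expression.
   The floor is re-witnessed inside the 1-norm problem before it is imposed,
   so it can be kept extremely tight ($10^{-12}$); a loose floor would let
   fluxes with small objective weights drift by (floor / weight).

## The linear programming core

The LP is solved by a two-phase bounded-variable primal simplex with
Bland's anti-cycling rule, written for this package. Metabolic LPs are
highly degenerate (many reactions sit exactly at zero in every basis), and
Bland's rule trades speed for guaranteed termination on such bases; the
networks this package targets in testing are small, so robustness wins.
Infinite bounds are replaced by a large finite cap ($10^9$), which keeps
the polytope bounded and turns a genuinely unbounded ray into a variable
pressed against its cap — reported as status `"unbounded"` with the
offending reaction named. Feasibility is accepted when phase-1 artificial
variables sum below $10^{-6}$; mass balance of reported optima is checked
against $\max_i |(Sv)_i| \le 10^{-6}$ throughout the test suite.

As an independent check, `lp_vertex_optimum()` enumerates all basic
solutions of the polytope (every subset of $n - \mathrm{rank}(S)$ variables
fixed at a bound, the rest solved linearly) and takes the best feasible
one. It is exponential and deliberately shares no code with the simplex;
the suite requires agreement to $10^{-8}$ on one hundred seeded random
networks of up to twelve reactions.

## SBML input and output

Models are written as SBML Level 3 Version 1 with the fbc version-2 package
(parameter-referenced flux bounds, `geneProductAssociation` trees, explicit
objective). On read, the package additionally accepts the older COBRA-style
Level 2 dialect — bounds in kineticLaw `LOWER_BOUND`/`UPPER_BOUND`
parameters, gene associations in notes `GENE_ASSOCIATION:` lines, boundary
species flagged with `boundaryCondition="true"` (these are dropped so
exchanges stay single-metabolite) — because genome-scale models of the era
this package addresses predate fbc. Reaction kinds, when not annotated, are
inferred: single-metabolite reactions are exchanges, same-species
cross-compartment reactions are transports, and biomass/maintenance are
matched by configurable id patterns. A test verifies that emitted files are
parsed, and optimized to the same objective, by an independent
constraint-based toolchain (cobrapy).

## Matching, correlation, and screens

Genes are linked to reactions by their GPR (gene-protein-reaction)
associations; a gene on several reactions is matched to the one with the
largest time-averaged $|v|$ (ties broken lexicographically — the matching
norm and tie-break are not canonical, so both are explicit and the
per-timepoint alternative is available via `per_timepoint = TRUE`). Pearson
correlation is computed between the matched reaction's flux profile and the
gene's log2 expression profile on the shared time grid; expression samples
are aligned to flux times by nearest neighbour within 1 h. Genes whose flux
is constant over time (including all-zero flux) carry no correlation
information and are excluded with an explicit reason rather than assigned
$r = 0$; genes with constant expression likewise. Classification uses the
$\pm 0.5$ thresholds. No multiple-testing correction is applied: the output
is a descriptive classification, not a significance screen.

Two screens complete the integration. The **zero-flux screen** returns
genes whose matched reaction never carries flux: expression dynamics in
this set point at pathways the model wrongly excludes. The **essentiality
screen** returns genes whose matched reaction is active at *every* time
point, and compares median log2 expression between essential genes,
non-essential genes, and negative-control probes; essential genes with
median expression below a cutoff (default 5.0 log2 units) are flagged
individually, since a confidently predicted flux with no transcript is
either a model gap or an interesting gene.

## Clustering

Expression profiles entering the correlation analysis are grouped by
agglomerative hierarchical clustering, cut to $k = 12$ clusters by default
(enough resolution to separate the induction, repression, and transient
shapes of a fermentation time course). Profiles are z-scored per gene and
the distance is $1 - r$ between profiles with average linkage, because the
analysis cares about temporal shape, not absolute level; both choices are
configurable, and exact reproduction of any published cluster boundaries is
not claimed since the published method details are not specified. Flat
(zero-variance) profiles, whose correlation distance is undefined, are
treated as mutually identical and maximally distant from everything else.
Cluster labels are arbitrary, so clusters are renumbered by decreasing
size. The `genome_track()` table joins cluster membership and correlation
class in chromosomal gene order — the data behind a two-track genome map in
which co-regulated operons appear as adjacent same-cluster runs.

## What the synthetic generator emulates — and what it does not

`make_toy_model()` builds a small irreversible network shaped like the
biology: a glucose backbone that consumes oxygen and releases CO~2~,
parallel capacity-limited branches into a biomass precursor, an independent
phosphate stream, a biomass reaction consuming both streams in fixed
proportions, an antibiotic branch fed by surplus carbon, a fixed
maintenance drain, and a structurally blocked xylose pathway. Genes
(isozyme `or` groups, one `and` complex, one multi-reaction gene) are
assigned in contiguous blocks, emulating operons. Branch sub-chains have
distinct lengths, so the 1-norm-minimal flux split fills short branches
first and the parsimonious solution is unique — which is what makes a
closed-form counterpart possible: `toy_optimum()` and `toy_flux_series()`
compute the optimum

$$\mu^* = \max\!\Big(0,\ \min\big(\tfrac{\min(u_g, u_o) - m}{d_c},\
\tfrac{\sum_j \mathrm{cap}_j}{d_c},\ \tfrac{u_p}{d_p}\big)\Big)$$

and the full flux matrix without any LP, serving as the generator-side
oracle for the entire pipeline.

`make_schedule()` ramps phosphate linearly to zero at 34 h (glucose stays
available), and ramps antibiotic production linearly from zero after the
switch — the canonical phosphate-limited profile. The default time grid is
hourly from 20-44 h and two-hourly from 46-60 h, the usual sampling design
for such fermentations. `simulate_expression()` derives expression from the
*analytic* flux series (so the simulated data never sees the LP path):
faithful genes are positive affine transforms of the variance-standardized
flux profile plus Gaussian noise (sd 0.1 log2 units by default), injected
anticorrelated genes are sign-flipped transforms, unexpressed genes sit at
a noise floor near 4 log2 units, and genes on maintenance (constant-flux)
or blocked (zero-flux) reactions get flux-unrelated post-switch induction
sigmoids — emulating the signature of genes that are expressed although the
model predicts nothing. Genes on always-active reactions get a +0.6 log2
baseline shift, emulating the higher expression of essential genes.
Defaults (200 genes, 10% anticorrelated, 5% each constant-flux and
unexpressed, 10 control probes) set the study conditions used by the
acceptance checks.

What the generator does **not** emulate: probe-level microarray artifacts,
normalization effects, biological replicate structure (the real design had
single samples per time point), post-transcriptional regulation decoupling
transcript from flux, and fermentation kinetics beyond piecewise-linear
rate interpolation. Passing the recovery checks therefore demonstrates
that the pipeline is correct and sensitive under its own assumptions — not
that those assumptions hold for any particular real dataset.

## Numerical choices

* LP pivot tolerance $10^{-9}$ (configurable via `tol_feas`); phase-1
  feasibility acceptance $10^{-6}$; mass-balance audit $10^{-6}$.
* Parsimonious floor tolerance $10^{-12}$ after re-witnessing (see above).
* Zero-flux tolerance $10^{-9}$ on $|v|$ for the matching, zero-flux, and
  essentiality screens.
* Nearest-neighbour time alignment within 1 h; no extrapolation outside
  the measured schedule window (queries outside it are errors).
* Degenerate inputs: empty models, empty condition tables, empty gene
  groups, and singleton clusters are all defined cases with tests, and
  group medians of empty groups are `NA`, never 0.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic
networks: toy models of ~25 reactions solved over 33 time points, one
hundred random networks of 6-9 reactions for the oracle comparison, and a
200-gene expression bundle for recovery checks. These sizes keep the
brute-force vertex enumeration exact and the full suite fast while
exercising every code path; the package itself has no hard-coded limits,
and the chemostat workflow accepts any genome-scale SBML model (the
published seven-condition validation table ships in
`inst/extdata/chemostat_conditions.tsv` and runs against a genome-scale
*S. coelicolor* model whenever one is placed at
`inst/extdata/sco_model.xml` — that model is not redistributable with the
package).

## Known limitations

* The simplex is pure R and tuned for robustness, not speed; genome-scale
  models (~1000 reactions) solve, but slowly compared to compiled LP
  libraries, and the vertex oracle is strictly for tiny networks.
* Regulatory constraints are not modeled; anticorrelated genes are
  *detected*, not explained.
* Expression is never fed back as a flux constraint (a deliberate
  non-goal; the integration here is diagnostic, not prescriptive).
* The dynamic treatment is a sequence of static optima: storage pools,
  by-product re-uptake, and growth-rate hysteresis are out of scope.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_genes = 200, seed = 1)
tm <- make_toy_model(spec)
sch <- make_schedule(spec)
ts <- run_dynamic_fba(tm$model, sch)
matching <- match_genes(tm$model, ts)
sim <- simulate_expression(toy_flux_series(tm$record, sch),
                           match_genes(tm$model, toy_flux_series(tm$record, sch)),
                           spec)
report <- classify(correlate(ts, sim$expr, matching))
report$class_counts
```

The numbered scripts under `analysis/` run the same pipeline as a
five-step workflow with all intermediate tables written under `results/`.
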