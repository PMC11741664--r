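---
title: "Models and methods behind gemflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gemflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
```

gemflux packages the computational workflow of genome-scale metabolic
modeling for a denitrifying, polymer-producing heterotroph: reconstruction
calibration, model quality control, flux balance analysis, phenotype
prediction, deletion screens, flux sampling and polymer-yield optimization.
This vignette records the models, the numerical choices, and the reasoning
behind the design decisions, in the order a user meets them.

## The constraint-based model

A `gem_model` is a stoichiometric network over three compartments
(cytoplasm `c`, periplasm `p`, extracellular `e`) with BiGG-style lowercase
identifiers suffixed by compartment. Steady-state flux vectors satisfy
$S v = 0$ with bounds $lb \le v \le ub$ in mmol·gDW⁻¹·h⁻¹; the growth rate
$\mu$ (h⁻¹) is the flux of the biomass pseudo reaction.

Directionality comes from bounds alone: a reaction with $lb < 0$ is
reversible. There is deliberately no separate "reversible" flag — a single
source of truth cannot drift. Exchange (`EX_`), sink (`SK_`), demand (`DM_`)
and biomass reactions are *pseudo* reactions; their ids and their `pseudo`
flag must agree or loading fails, so a file whose naming and semantics
disagree is rejected instead of silently mis-handled. The uptake convention
is the standard one: a negative exchange lower bound permits uptake, and
unspecified uptakes are capped at 1000 mmol·gDW⁻¹·h⁻¹.

GPR rules are boolean trees (`and` = enzyme complex, `or` = isozymes); the
empty rule marks an orphan reaction, which gene deletions never disable.

## Linear programming

FBA, producibility tests, energy-cycle screening, deletion screens and the
sampler's warmup all reduce to LPs of the form
$\max c^\top v$ s.t. $S v = b$, $lb \le v \le ub$. The LP core is a
bounded-variable revised simplex (two-phase, Bland's smallest-index rule).
Two properties of metabolic LPs drove this choice:

* metabolite balance rows are rank-deficient (conserved moieties — the CoA,
  NAD and adenosine pools — are linear dependencies), so dependent equality
  rows are removed by pivoted QR before solving; the right-hand side is
  generated by the same matrix, so dropped rows hold automatically and are
  re-verified on the returned solution;
* optima sit on heavily degenerate vertices (parallel routes, idle
  exchanges), which Bland's rule traverses without cycling.

Feasibility tolerance is 1e-9; reported comparisons use 1e-6; one epsilon
(`GROWTH_TOL = 1e-6`) serves every growth-versus-zero decision — growth
calls, essentiality classes, energy-cycle flags and producibility — so no
two thresholds can disagree about whether the organism "grows". Because all
bounds are capped at ±1000, no LP is unbounded, and infeasibility is a
status, never an exception. The test suite cross-checks the simplex against
brute-force vertex enumeration on dozens of random networks.

Only the objective *value* is a contract. Flux vectors at the optimum are
generally non-unique; any analysis that needs the solution set (not a
solution) must sample (see below) or pin secondary objectives.

## The synthetic study system

`make_toy_model()` builds the ~60-reaction network all analyses are
exercised on. It is not a fixture file but first-class, tested code, and it
carries its own analytic truth sheet (`model_truth()`): every headline
number asserted downstream is derived from the planted stoichiometry, never
hard-coded twice.

The network contains acetate, pyruvate, benzoate, L-alanine, L-serine and
formate as carbon sources; ammonium, oxygen, nitrate exchanges; a lumped
TCA oxidation (4 NADH per acetyl-CoA); aerobic respiration at 1 ATP per
NADH; a four-step denitrification chain NO₃⁻→NO₂⁻→NO→N₂O→N₂ with partial-
denitrification exits (nitrite and nitrous oxide export) returning at most
0.5 ATP per NADH; DNRA (NO₂⁻→NH₄⁺); aerobic aromatic degradation through
catechol meta-cleavage (oxygen-dependent) and anaerobic degradation through
benzoyl-CoA to three acetyl-CoA; the PHB branch (2 acetyl-CoA →
acetoacetyl-CoA → 3-hydroxybutyryl-CoA → monomer); and four EPS precursor
syntheses.

Three generator conventions matter for interpretation:

* **Balancing with moiety elements.** Carbon and nitrogen species carry real
  formulas (acetate C2H4O2, ammonium as NH3, benzoate C7H6O2, …) so C:N
  arithmetic is exact; cofactor moieties are placeholder element symbols
  (CoA = `R`, NAD = `Q`, adenosine = `A`) chosen so *every* non-pseudo
  reaction is exactly elementally balanced. EPS precursor formulas are
  synthetic analogs constructed to balance their synthesis reactions, and
  are labeled as such.
* **Planted growth arithmetic.** Biomass consumes 1.25 acetyl-CoA + 1 NH₄⁺ +
  2 ATP per unit. Aerobically, ATP costs 0.25 acetyl-CoA per ATP, so one
  biomass unit costs 1.75 acetyl-CoA = 3.5 C — which is both the aerobic
  acetate growth bottleneck (μ = 10/1.75 on 10 mmol acetate) and the C:N
  threshold of the PHB sweep. The default `biomass_n_per_c = 2/7` encodes
  exactly this; changing it moves both numbers consistently.
* **What the toy does not emulate.** Realistic pathway lengths, kinetic or
  regulatory effects, maintenance ATP demand, and genome-scale redundancy.
  Passing tests demonstrate algorithmic correctness on a network whose
  ground truth is analytic — not predictive accuracy on a real organism.

A known consequence of strict moiety conservation: carrier-bound metabolites
(acetyl-CoA, ATP) cannot be drained by a sink, because the network cannot
synthesize carriers de novo. Producibility is therefore asserted on the
moiety-free products listed in the truth sheet.

## Reconstruction calibration

Homology hits (template gene, target gene, e-value, alignment length,
identity %, bitscore) are filtered by a parameter triple; retained hits are
reduced to one best hit per template gene (highest bitscore, then lowest
e-value, then lexicographic target — a fully deterministic mapping). The
grid search evaluates 4 e-values × 6 lengths × 6 identities = 144 cells
against a curated gold set, counting a proposed target gene as TP if the
curated rule for that reaction contains it. True negatives are counted over
the gold-set gene universe — the only universe that is well-defined without
the full genome. The selected optimum maximizes F1 with ties broken by
fewer retained template genes, then stricter e-value; precision and recall
are reported alongside so users can re-rank under their own cost model.
The grid's length values {50, 80, 100, 120, 150, 200} and identity values
{20, 25, 30, 35, 40, 50} span the conventional bacterial reconstruction
ranges and include every per-template optimum a practitioner would select
in that span. The hit-table generator plants hits that pass exactly one
grid cell best (decoys with superior bitscores sit just below one threshold
each), so calibration recovery is a sharp test, and label noise degrades F1
monotonically by construction.

Merging drafts keeps, for a reaction present in several templates, the copy
whose supporting hit has the highest bitscore; stoichiometry conflicts under
one id are an error, not a silent overwrite. Stripping template genes prunes
`or` branches (an isozyme alternative is lost) and orphans reactions whose
`and` complex lost a subunit, reporting both outcomes for curation.

## Phenotype prediction and growth classes

Growth calls are `μ > 1e-6` per condition; unmappable substrates are
excluded and reported, mirroring phenotyping wells that cannot be assigned
to the network. The high/medium/low classification of predicted rates uses
rank-quantile mapping that preserves the experimental class counts. No
absolute thresholds exist for simulated growth rates, so the experimental
marginals are the only defensible anchor; a useful corollary is that the
classification is invariant under any strictly monotone transform of μ, and
ties are broken by condition id for determinism. Subsystem activity is the
sum of absolute fluxes over member reactions, z-scored per subsystem across
conditions, with never-active subsystems dropped and zero-variance
subsystems scored 0.

## Deletion screens

Gene deletions disable every reaction whose GPR evaluates false without the
gene; reaction deletions pin bounds to zero. Ratios ko/wt classify into
lethal (≤ 1e-6), growth-reducing, and non-essential (≥ 1 − 1e-6), with
ratios in (1, 1+1e-6] clamped to 1. Deletions whose disabled reactions all
carry zero flux in the wild-type optimum are classified without re-solving:
the wild-type solution remains feasible and deletions cannot increase the
optimum, so the ratio is exactly 1. The acceptance tests re-derive every
class with an exhaustive re-solve that does not use this shortcut.

Both aggregation rules seen in practice are explicit parameters:
gene-style global lethality (`lethal in all conditions`) and screen-style
(`lethal in at least one condition`), with lethal taking precedence over
growth-reducing. Upset-style set comparison partitions the union of lethal
sets into exact membership groups.

## ACHR sampling and regulation statistics

Sampling explores the polytope at (a fraction of) optimal growth after
`fix_optimum_and_constrain()`. Warmup points are corners from optimizing
random sparse ±1 objectives (default 2× the free dimension count); the walk
direction is from the running center (mean of all visited points) to a
random warmup corner. The chain state is tracked in null-space coordinates
of the constraint matrix, so `S v = 0` holds to machine precision at every
step rather than drifting over half a million steps; the line search keeps
the walk inside the bounds. Default 5,000 samples; thinning (default 100
steps per kept sample) and warmup count are configurable; given a seed the
sample matrix is bit-reproducible. A practical caveat the tests encode: a
fully determined optimum (zero-dimensional face) yields identical rows by
construction — near-optimal fractions (e.g. 0.9) are the right setting when
the face itself is unique.

Subsystem regulation compares the *distributions* of per-sample subsystem
activity between a condition and the acetate reference with a two-sided
Mann–Whitney U test (exact for small tie-free inputs, normal approximation
otherwise, verified against full enumeration for n₁+n₂ ≤ 10), with
direction given by the median difference. Averaging samples first would
leave nothing to test; comparing the activity distributions is the only
reading under which the test is defined, and is what the package does.
Results are filtered at a configurable `alpha` (default 0.05); p-values are
floored at 1e-300 so the −log10 transform stays finite.

## Polymer yields, C:N ratios and PCA

A polymer is specified by precursor mole fractions (summing to 1), a
(mass-weighted) monomer molar mass, and a dry-weight fraction *f* — 0.50
for PHB (storage under nitrogen limitation), 0.30 for the six EPS variants.
The EPS precursor fractions shipped are configurable placeholders: real
compositions are experimental inputs, not package constants. The demand
reaction drains the precursor mixture; coupling to biomass enforces the
fixed-composition equality
$v_{poly} \cdot M / 1000 = \frac{f}{1-f}\,\mu$
as an extra constraint row — an equality, not a ceiling, because a stated
polymer content is a composition, and an inequality would let the optimizer
silently produce less.

The C:N sweep asks a different question — when does storage switch on — and
therefore runs *without* the hard coupling: growth is maximized first, then
pinned, then the polymer demand is maximized from the carbon left over.
Under a hard coupling any growth would force polymer production and no
threshold could exist; the lexicographic reading reproduces the observed
behavior (below the biomass C:N demand all carbon goes to growth, above it
the surplus goes to polymer, rising with the ratio). The medium supplies
the ratio: carbon uptake is pinned to r mol C per 1 mol N available, with
excess nitrogen left unconsumed, as in nitrogen-limitation experiments.

Yield per carbon is production flux divided by (uptake flux × carbon atoms
per molecule), making it invariant under uniform flux rescaling. C:N uptake
ratios count substrate carbon plus substrate nitrogen (amino acids carry
their own N) plus the inorganic N source — ammonium aerobically, nitrate
anaerobically; substrate N is included in both regimes since the accounting
should not change with the electron acceptor. Zero N uptake reports `Inf`
rather than failing. PCA of the substrate × polymer matrix (flagged records
imputed as 0) is column-centered SVD via `prcomp`; variance fractions sum
to 1, and on the toy panel PC1 separates nitrogen-containing from
nitrogen-free substrates by sign.

## Problem sizes and determinism

The shipped analyses run on the ~60-reaction toy network: 144-cell
calibration grids, 40-condition phenotype panels, 5-condition deletion
screens, 5,000-point sampling chains and 20-scenario C:N sweeps — sizes at
which every expected value is analytically derivable and the whole suite
runs in about a minute. All stochastic components (hit tables, panels,
sampler) are seeded and bit-reproducible; `scripts/acceptance.R` threads a
single `--seed` through every one of them.

## Known limitations

* The simplex refactorizes its basis densely per iteration — right for
  networks up to a few hundred reactions, slow beyond; genome-scale work
  should swap in an industrial LP behind the same `solve_fba()` surface.
* No flux variability analysis, parsimonious FBA, thermodynamic (ΔG) loop
  removal, or double deletions; SBML support covers the fbc subset the
  package writes.
* The phenotype module consumes qualitative growth tables; OD600 curve
  processing and well-to-metabolite chemistry mapping are inputs, not
  package functionality.
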