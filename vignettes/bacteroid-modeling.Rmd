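---
title: "Constraint-based modeling of bacteroid metabolism with BacteroidFBA"
author: "BacteroidFBA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of bacteroid metabolism with BacteroidFBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BacteroidFBA)
```

## The biological problem

Rhizobia inside legume root nodules differentiate into *bacteroids*:
growth-arrested cells that reduce atmospheric N~2~ to ammonia with the
nitrogenase enzyme and secrete the fixed nitrogen to the plant, in
exchange for C~4~-dicarboxylates (malate, succinate). The arrangement
poses a stark metabolic puzzle. Nitrogenase consumes on the order of 16
ATP and 8 low-potential electrons per N~2~, yet it is destroyed by
oxygen, so the nodule keeps free O~2~ in the nanomolar range — exactly
where oxidative ATP synthesis is hardest. Bacteroids respond with a
characteristic phenotype: storage polymer accumulation
(polyhydroxybutyrate, glycogen, lipids), secretion of alanine and
aspartate alongside ammonia, and down-regulation of their own ammonia
assimilation (GS-GOGAT).

BacteroidFBA provides the computational machinery to interrogate this
phenotype with constraint-based models: flux balance analysis (FBA) and
its variants, and exhaustive enumeration of *elementary conversion
modes* (ECMs) — the extreme rays of the cone of net input/output
conversions a network can perform at steady state. ECMs describe what
the cell *can* do without committing to an objective function, which
matters for a non-growing symbiont whose "goal" is not biomass.

## The model container and its conventions

A `MetabolicModel` holds metabolites (with elemental formulas over
C/H/N/O/P/S), reactions (stoichiometry, flux bounds, a boolean
gene-protein-reaction rule), the gene list, and the id of the designated
nitrogenase reaction. Steady state is imposed on internal-compartment
metabolites: \(S\,v = 0\), \(lb \le v \le ub\), with \(S\) the
internal-row stoichiometric matrix.

Boundary reactions (exchange, demand, sink) touch exactly one metabolite
and are written "metabolite →", so *export is positive and uptake is
negative* — the dominant community convention. A bound of
\((-4, 0)\) on a malate exchange therefore means "uptake of at most 4
flux units". Flux units are arbitrary model units throughout.

Reaction bounds absent from an input file default to \((-1000, 1000)\)
for reversible and \((0, 1000)\) for irreversible reactions.

## The synthetic core-bacteroid model

`buildCoreBacteroidModel()` generates a fully specified, elementally
balanced core model of bacteroid metabolism, so that every analysis in
the package can be exercised and tested without any external download.
It is a *synthetic stand-in* for a curated reconstruction, not a
reproduction of any published model's reaction list, gene ids, or
counts.

Pathway content: dicarboxylate uptake; the TCA cycle as individual
steps; malic enzyme and pyruvate dehydrogenase (the canonical
dicarboxylate → acetyl-CoA route); PEP carboxykinase, pyruvate kinase
and PEP carboxylase; lumped gluconeogenesis, glycolysis and a pentose
phosphate branch; an electron transport chain with configurable P/O
ratios; nitrogenase; GS-GOGAT; alanine dehydrogenase; aspartate
transaminase; synthesis of PHB, glycogen, palmitate and glycerolipid
with storage sinks; sucrose/glucose/arabinose/GABA catabolism; and
amino-acid demand reactions standing for residual protein synthesis.

Deliberate lumping choices (documented here because the real pathways
are longer):

* Glycolysis and gluconeogenesis are single lumped reactions between
  G6P and 2 PEP with their net ATP/NADH stoichiometry (+1 ATP for the
  glycolytic direction, −2 ATP for the gluconeogenic one, so the pair
  forms an ATP-dissipating futile cycle rather than a perpetuum
  mobile).
* The pentose phosphate pathway is an oxidative lump (G6P → Ru5P + CO~2~
  + 2 NADH) plus a non-oxidative return (6 Ru5P → 5 G6P); NADPH is not
  distinguished from NADH.
* Sucrose hydrolysis treats fructose as glucose; arabinose is
  catabolized by a lumped oxidative route to 2-oxoglutarate, its actual
  entry point in rhizobia.
* Redox carriers are conserved moiety pairs whose reduced form carries
  the transferred hydrogens (the metabolite called "NADH" stands for
  NADH + H^+^; ferredoxin is a one-electron carrier differing by one H).
  With metabolites in free-acid form this makes every internal reaction
  exactly balanced in C, H, N, O, P and S — `checkElementalBalance()`
  verifies all of them, and `findNetworkGaps()` confirms the absence of
  orphan metabolites, dead-end reactions and stoichiometrically balanced
  cycles.

### Parameters that matter

* `p_o_nadh` (default 1.5 ATP per NADH oxidized) and `p_o_fadh2`
  (default 1.0): effective P/O ratios of the microaerobic respiratory
  chain. The defaults are standard textbook values for bacterial
  branched chains; they also place dicarboxylate catabolism at a higher
  O~2~ demand per carbon than sugar catabolism, which is the
  experimentally observed ordering.
* `nitrogenase_atp_per_n2` (default 16): the textbook nitrogenase
  stoichiometry N~2~ + 8 e^−^ + 8 H^+^ + 16 ATP → 2 NH~3~ + H~2~.
  Configurable for sensitivity analyses.
* `seed` (default 323): drives the randomized GPR assignment, which
  mixes single-gene, AND-complex and OR-isozyme patterns. Three GPRs are
  pinned so canonical essentiality cases always exist: nitrogenase is a
  three-subunit AND complex, citrate synthase an OR isozyme pair, and
  malate dehydrogenase a single-gene reaction.
* Oxygen uptake bounds are *required scenario parameters*, never
  hard-coded defaults: there is no universally meaningful O~2~ bound for
  a bacteroid, and sweeping it is the scientific point of most analyses
  here.

`bacteroidScenario()` encodes the standard condition: one carbon source
(default malate, uptake ≤ 4 flux units), open N~2~, a chosen O~2~
bound, free secretion of ammonia/alanine/aspartate, and glutamate and
glutamine demands constrained to 0.01–0.05 flux units to mimic residual
protein synthesis. With `fixCarbon = TRUE` the carbon uptake is fixed
rather than bounded — the plant controls the supply — which is the
setting for flux variability and ensemble analyses, where the point is
that excess carbon must be *accommodated*, not refused.

## The LP layer

All LP-based analyses run on a dense bounded-variable two-phase revised
simplex implemented in C++ inside the package. It returns primal
solutions, row duals and reduced costs, which the shadow-price and
phase-plane machinery needs; basis refactorization at every iteration
favors robustness over speed, which is the right trade-off at core-model
size (tens of metabolites). The solver is cross-checked in the test
suite against an independent R implementation (`pracma::linprog`),
brute-force vertex enumeration, and COBRApy on serialized models.

Numerical choices: solver tolerance 10^−9^; FBA-optimum fixation for
taxicab (L1) minimization within 10^−12^ relative (comfortably inside
the documented 10^−9^ contract); essentiality threshold 10^−6^ flux
units on the nitrogenase optimum ("prevented flux" made precise);
shadow-price sign tolerance 10^−6^ for phase segmentation;
balanced-cycle flux threshold 10^−6^.

### FBA variants

* `solveFBA()` maximizes an objective (by default nitrogenase flux) over
  the flux cone; infeasibility and unboundedness are reported honestly
  in the `status` slot.
* `solveFBAL1()` is the two-stage taxicab variant: fix the objective at
  its optimum, then minimize \(\sum_j |v_j|\) by splitting fluxes into
  nonnegative forward/backward parts. This removes thermodynamically
  infeasible internal cycles from reported distributions.
* `fluxVariability()` brackets each reaction's flux at a fraction of the
  optimum. With `loopless = TRUE` each extreme solution is
  post-processed CycleFreeFlux-style: boundary fluxes are fixed and the
  L1 norm minimized, so flux that can only circulate in internal cycles
  is removed from the reported extreme and returned separately. A
  mixed-integer loopless formulation was deliberately avoided: the
  cycles in models of this kind are removable by norm minimization, at a
  fraction of the cost.
* `shadowPrices()` reports, per exchanged metabolite, the marginal gain
  of the objective per unit relaxation of the binding uptake bound
  (signs fixed so limiting resources price positive). Degenerate optima
  have non-unique duals; `check = TRUE` flags prices that disagree with
  a finite-difference perturbation.
* `phasePlane()` fixes the uptake rates of two exchange reactions at
  every point of a grid — the classic phenotype phase plane
  construction — records the optimum and both axis shadow prices, and
  labels phases as maximal 4-connected regions of identical
  shadow-price sign signature (zero within tolerance / positive /
  negative). Fixing, rather than bounding, the uptakes is what exposes
  the overflow phases in which extra substrate *hurts* (negative
  prices); infeasible cells carry label 0. Sign-signature segmentation
  was chosen over slope clustering because it is discrete, reproducible
  and matches how phases are interpreted (which resource limits, which
  is in excess). The default grid is 20×20; examples here use coarser
  grids purely for speed, and grid refinement does not move phase labels
  in phase interiors.
* `singleGeneDeletion()` evaluates each gene's GPR rules, disables the
  reactions lost under the deletion, and calls a gene essential when the
  nitrogenase optimum drops below 10^−6^ flux units (or the constrained
  problem becomes infeasible, which can happen when demand lower bounds
  are active). `groundTruthEssentiality()` answers the same question by
  a pure LP feasibility test (phase-1 only, no optimization), providing
  an independent oracle used in the tests.
* `randomObjectiveEnsemble()` probes objective-agnostic network
  tendencies: each member maximizes a random objective (uniformly drawn
  subset of reactions, uniform (0,1] weights) subject to a minimum
  nitrogenase flux of 0.01, and summary statistics are taken per swept
  oxygen bound. The draw stream is generated once from the seed and
  reused across sweep points; infeasible draws are skipped, not
  resampled, so results are bitwise reproducible. The study-scale
  ensemble size is 50,000; the package's tests and the acceptance script
  use 150–500 members, which already resolve the qualitative trends.

## ECM enumeration

`enumerateEcms()` computes the extreme rays of the conversion cone

\[ \{\, c : c = S_{ext} v,\; S_{int} v = 0,\; v \in \text{irreversibility cone},\; \text{direction constraints on } c \,\} \]

by double description in exact integer arithmetic: reversible reactions
are split into irreversible pairs; stoichiometric coefficients are
cleared of denominators *per reaction column* (a flux-unit change that
leaves conversions untouched — row scaling would corrupt the conversion
coefficients of metabolites with fractional stoichiometry); constraints
are inserted one at a time in a greedy order (fewest candidate ray
combinations first) with combinatorial adjacency tests over exact zero
sets; rays recombining both directions of one reaction are discarded as
cycle artifacts; the rays are projected onto the tracked metabolites,
deduplicated by gcd normalization, and reduced to the extreme rays of
the *projected* cone by an LP test that removes any generator expressible
as a nonnegative combination of the others. Exact arithmetic matters:
double description over floats produces spurious rays. Integer overflow
is guarded (entries beyond 2^40^ raise an error advising rescaling).

The `ecmConfig()` partition declares each tracked metabolite an input
(net consumption only), output (net production only), or free; *hidden*
metabolites are removed from the bookkeeping entirely, i.e. treated as
freely exchangeable cofactor pools. Listing an internal metabolite
externalizes it explicitly — this is how storage polymers (whose sinks
are intracellular) are given conversion coordinates. Which cofactors to
hide is always an explicit configuration choice, never a default.

One subtlety worth stating: support minimality — "no ray's support is a
strict subset of another's" — characterizes extreme rays in *flux*
space, but does not survive projection. Genuinely elementary
conversions with nested supports exist (the synthetic model produces
them), so elementarity is defined, implemented, and tested as
non-decomposability into other returned conversions.

`addFluxTracker()` appends a virtual output-only metabolite with
coefficient +1 to a reaction, so its conversion coefficient reads out
that reaction's flux per unit conversion — the device used to quantify
glutamine synthetase (GS) activity inside ECMs.

## Conversion metrics and filters

For each conversion, `conversionMetrics()` reports oxygen uptake per
carbon atom taken up, oxygen per N~2~ fixed, and the carbon cost of
nitrogen delivery

\[ \text{cost} = \frac{12.011\,(C_{in} - C_{out,credited})}{14.007\,(N_{out} - N_{in,organic})} \quad [\text{g C / g N}], \]

plus class flags (polymer-producing; ammonia-only; amino-acid secreting
or consuming, with GABA counted as an amino acid).

The crediting rule is a genuine design decision and is configurable:
*secreted organic* metabolites are credited as carbon outputs, while
CO~2~ (waste) and storage polymers (retained by the bacteroid, invisible
to the plant) are not. This is the only reading under which both
qualitative anchors hold simultaneously — polymer-producing modes raise
the carbon cost toward the experimentally observed ~8 g C/g N, while
polymer-free modes stay near the ~2.5 g C/g N theoretical cost. Atomic
masses 12.011/14.007 are used (integer 12/14 available via the `masses`
argument).

`filterConversions()` applies the biological plausibility rules: a
positive carbon cost below 40 g C/g N, at most one amino-acid input, and
positive net nitrogen output; rejections carry machine-readable reasons.
One documented consequence: glycogen- and lipid-producing modes that
also fix N~2~ are so carbon-expensive that the cost filter removes them,
so the oxygen-per-N~2~ comparison between polymer classes is computed on
the full enumeration, where those modes exist.

`spearmanCorrelation()` (midrank ties; exact permutation p-value by full
enumeration for n ≤ 10, t approximation above) supports the
O~2~-versus-GS-activity analysis.

## What the synthetic model reproduces — and what that means

The test suite and `scripts/acceptance.R` assert, on the synthetic
model, the qualitative structure expected of bacteroid metabolism:

* polymer-producing conversions need less O~2~ per carbon than
  polymer-free ones (polymers act as carbon/redox sinks);
* among polymer-free conversions, alanine/aspartate secretion lowers
  O~2~ demand relative to ammonia-only nitrogen export (alanine
  dehydrogenase regenerates NAD^+^ without oxygen);
* glycogen/lipid co-fixing modes pay more O~2~ per N~2~ (their ATP
  cost adds to nitrogenase's);
* polymer production raises the carbon cost per nitrogen, with
  polymer-free modes near the theoretical minimum;
* O~2~ demand correlates positively with GS flux per carbon (ammonia
  assimilation needs TCA-derived 2-oxoglutarate);
* tightening O~2~ at fixed malate supply lowers the citrate synthase
  maximum and raises the PHB and alanine dehydrogenase maxima at
  optimal nitrogenase activity, and the ensemble shows the same TCA
  decrease with PHB/fatty-acid increase as an objective-free network
  property;
* per carbon atom, sucrose supports more nitrogenase activity at less
  O~2~ than malate, and forcing a glutamate demand raises the minimum
  O~2~ requirement at matched nitrogenase activity.

Passing these checks demonstrates that the *methods* recover the
expected structure from a network with the right pathway content and
energetics. It does not validate any particular organism's
reconstruction: the synthetic model's size (tens of reactions), its
lumped pathways, and its randomized GPRs are not those of a curated
genome-derived model, and quantitative values (phase counts, exact
means) are properties of this network, not predictions. Analyses of a
real reconstruction should load it with `readModel()` (SBML Level 3 +
fbc, or the community JSON dialect) together with its measured boundary
conditions via `readScenario()`.

The FVA and ensemble oxygen sweeps used in tests and acceptance run from
O~2~ bounds of 7 down to 2.5 flux units at a fixed malate uptake of 4 —
spanning carbon limitation to oxygen limitation for this network's
energetics, which is the axis along which the biology unfolds.

## Known limitations

* No thermodynamic (ΔG) constraints; loop removal is by norm
  minimization, not by explicit thermodynamic feasibility.
* Charge balance is stored but not enforced (formulas are free-acid
  conventions; charges are optional).
* The double-description enumeration is exact but single-threaded and
  intended for core-scale models; genome-scale ECM enumeration needs
  the dedicated distributed tools.
* The mock experimental essentiality generator flips calls uniformly at
  random; real screens have structured error (polar effects, growth
  -stage artifacts) that it does not emulate.
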