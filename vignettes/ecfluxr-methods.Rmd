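---
title: "Methods: enzyme-constrained models, proteome integration and flux sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-constrained models, proteome integration and flux sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecfluxr)
```

This vignette documents the models and numerical choices behind `ecfluxr`:
what is computed, under which assumptions, which parameters matter, and
what the synthetic-data tests do and do not demonstrate about real data.

## The constraint-based model

A metabolic network is a stoichiometric matrix $S$ (metabolites x
reactions) with flux bounds $l \le v \le u$ (mmol/gDCW/h). Flux balance
analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

usually with the biomass reaction as objective, so its flux equals the
specific growth rate $\mu$ (1/h) when the biomass equation weighs 1 g/mmol.
Uptake is a negative flux on an exchange reaction; reports convert to
positive uptake rates.

Because no linear-programming package is available to build on, the LP
solver is part of the package: a dense bounded-variable two-phase primal
simplex (`src/simplex.cpp`). Its numerical behaviour is specified rather
than incidental:

* optimality/feasibility pricing tolerance $10^{-9}$; pivot admissibility
  $10^{-7}$ (pivots near the pricing tolerance corrupt the basis inverse);
* a two-pass ratio test that takes, among ratio-tied rows, the largest
  pivot magnitude, with the smallest basis index as deterministic
  tie-break; Bland's rule engages after 60 consecutive degenerate pivots;
* periodic refactorization of the basis inverse, a final residual check
  ($\lVert S v \rVert_\infty \le 10^{-7}$), and a deterministic re-solve
  under Bland's rule from the first iteration if the first pivot path ends
  inaccurate. Solutions are clamped into their bounds (drift at solver
  tolerance only).

The exhaustive reference `fba_enumerate()` enumerates every basic feasible
solution (all basis column sets crossed with all lower/upper assignments of
the nonbasic variables) and is used in tests and in the acceptance script
as an algorithm-independent cross-check on small random networks.

## Enzyme constraints

The capacity of a catalysed reaction is limited by its enzyme:

$$v_r \;\le\; E_e \cdot k_{cat} \cdot 3600,$$

with $E_e$ in mmol/gDCW and $k_{cat}$ in 1/s (3600 converts to hourly
fluxes). This is encoded GECKO-style: each enzyme gets a pseudo-metabolite
whose balance row couples a usage ("draw") reaction, whose flux equals
$E_e$, to every catalysed reaction through the coefficient
$-1/(k_{cat}\cdot 3600)$. Prerequisites:

* **Reversible splitting.** Every reversible reaction becomes a forward and
  a reverse copy (negated stoichiometry), so all fluxes are nonnegative and
  a capacity applies per direction. The mapping is retained and
  `map_to_base()` restores net fluxes (forward - reverse, isozyme copies
  summed, bookkeeping reactions dropped).
* **Isozyme expansion.** A reaction catalysed by $N \ge 2$ alternative
  isozymes becomes $N$ enzyme-specific copies behind one arm reaction, so
  copy fluxes sum exactly to the arm flux. Enzyme complexes (AND within an
  isozyme) give every subunit its own balance with the same $k_{cat}$
  unless per-subunit values are supplied.
* **The protein pool.** Enzymes without individual measurements draw from a
  shared mass budget `pool_ub = sigma * f * Ptot` (g/gDCW), weighted by
  molecular weight: `sigma` is the average enzyme saturation (default
  0.35), `f` the mass fraction of the proteome attributable to model
  enzymes, `Ptot` the total protein content of the biomass.

### kcat matching with stepwise relaxation

`match_kcats()` queries a BRENDA-style table in strictly ordered levels:
(1) EC number + substrate + organism; (2) EC + substrate; (3) EC +
organism; (4) EC only; (5) EC with the last field wildcarded. Within a
level the maximum is taken (the common convention when records are sparse
and biased low; the median is available via `aggregate = "median"`). The
substrate-before-organism ordering is this package's choice - published
pipelines state only that stringency is relaxed stepwise - and the level of
every match is recorded in the model's provenance so downstream users can
see how trustworthy each constraint is.

`sensitivity_top_kcat()` implements the curation loop for over-constrained
models: find the enzyme whose $k_{cat}$ limits growth most, replace it with
the database maximum for its EC numbers, repeat. The limiting enzyme is
ranked by the finite-difference growth gain of a +10% $k_{cat}$ bump rather
than by the shadow price of its balance row: the pool-coupled LP is
routinely dual-degenerate at its optimum (many dual solutions, most of them
uninformative zeros), which makes shadow prices an unreliable ranking; the
finite difference costs one extra LP per candidate on models of this size
and is unambiguous. `top_used_enzymes()` supports the complementary manual
loop, flagging enzymes above 1% of the pool.

## Proteome quantification

`tpa_quantify()` implements the total protein approach with a
heavy-labelled internal standard: light intensities are recovered as
`ibaq_heavy / ratio_hl`, normalized by the mean standard abundance,
adjusted for the injection recovery (default 0.80), and expressed as shares
of $10^6$ ug per g total protein. Both the normalization and the recovery
factor cancel in the shares, which makes the quantification invariant to
global intensity rescaling - an invariant the tests assert. Molar
abundances follow as `conc * Ptot / MW`.

Differential expression uses Welch's t-test on log2 concentrations with
Benjamini-Hochberg adjustment and the conventional cut-offs |log2FC| > 1,
adjusted p < 0.05. With duplicate cultivations (n = 2 per condition, as in
typical bioreactor studies) the test is underpowered and results should be
read as a screen, not an inference; proteins whose replicate SD exceeds the
replicate mean are excluded before testing.

The ribosome translation rate is the protein synthesis demand per ribosome:
`rate = (mu * Ptot / m_aa) / N_rib / 3600` aa/s with the mean residue mass
`m_aa = 110` g/mol (configurable). The ribosome count `N_rib` is estimated
as the median molar abundance of detected ribosomal proteins - the median
is robust to missing subunits; mean and minimum estimators are available
because the choice is not standardized. At fixed proteome the rate is
exactly proportional to $\mu$; on real data that proportionality is an
empirical observation, here it is a structural identity.

## Biomass rescaling and maintenance energy

The biomass equation consumes protein, lipid and carbohydrate
pseudo-components that each weigh 1 g/mmol, so coefficients are mass
fractions and the biomass molar mass must stay exactly 1 g/mmol.
`rescale_biomass()` sets protein and lipid to measured values and lets the
carbohydrate component absorb the residual (standard practice; the absorber
is the component least constrained by direct measurement here). Lipid mass
is split SLIME-style into one backbone pseudo-metabolite (10% of lipid
mass, a triacylglycerol-like glycerol share) and per-chain acyl
pseudo-metabolites in the measured mass proportions; chain molar masses are
tabulated internally for C16:0-C18:2 as free-acid masses.

`fit_gam_ngam()` fixes the non-growth ATP maintenance (NGAM) from the
physiology and finds the growth-associated maintenance (GAM) by bisection
on the biomass ATP coefficient so the predicted maximal growth rate at the
measured uptake matches the measured rate within 0.1%. Predicted growth is
strictly decreasing in GAM, so bisection on the bracket [0, 300] mmol/gDCW
(40 steps) converges far below the reporting precision; bracket failures
are reported as errors, never silently clipped.

## Condition integration

`compute_f_factor()` computes f on the unfiltered quantification -
filtering first would systematically underestimate enzyme coverage.
`constrain_enzymes()` then bounds measured enzymes individually and sets
the unmeasured pool by direct subtraction,

$$\texttt{pool\_ub} = \sigma f P_{tot}^{resc} - \textstyle\sum_{measured} E_e \cdot MW_e,$$

with `Ptot` rescaled upward by one SD of the total-protein assay. The mass
identity (measured mass + pool = sigma * f * Ptot rescaled) holds exactly
and is asserted in the tests. A subtlety follows from the arithmetic: when
individually constrained enzymes hold more than the sigma-discounted
enzyme budget, the pool would be negative - `constrain_enzymes()` refuses
with guidance. The pipeline therefore constrains the *reliably measured,
mass-cheapest* subset (up to half the budget by default,
`measured_budget`) and leaves the heaviest entries on the pool; this is
the same release operation that flexibilization applies later, done up
front.

`flexibilize()` makes the observed growth rate feasible with minimal-greedy
relaxations: while $\mu_{max} < \mu_{target}$, the measured enzyme with the
largest finite-difference growth gain from a +10% bound bump is relaxed -
first to measured + SD, then released to the pool (its allocated mass
returns to the pool, conserving the budget). When no single bump helps
(several bounds bind at once, or the pool itself binds), the binding - or,
if the pool binds, the heaviest - measured enzyme is released directly.
Every action is recorded with old and new bounds.

`set_exchange_windows()` applies the variability windows used before
sampling: 1% on growth and substrate uptake, 10% on gas exchange,
by-product rates and the protein pool, 1% on NGAM. Unmeasured gas rates
are filled from FBA-predicted values. On split models the windows resolve
automatically to the forward or reverse copy; windows never cross zero for
positive rates.

## Flux sampling and derived quantities

`sample_fluxes()` explores the windowed solution space: per iteration three
distinct interior reactions (exchanges, usage reactions and the pool drain
are excluded - objectives should probe the metabolic interior) receive
i.i.d. weights uniform on (0, 1], the weighted flux sum is maximized, and
total flux is then minimized holding that objective within $10^{-6}$
relative (the parsimonious step; on an irreversible model total flux equals
the net model's $\sum |v|$). Weights are nonnegative and maximization-only
by default - the source procedure does not state signs - and everything is
reproducible from one master seed. A failed iteration is retried once with
a fresh seeded objective, then skipped with a warning. Solutions are
polished: usage fluxes are recomputed exactly from their balance rows and
the pool drain rebalanced, so the capacity identity holds to machine
precision rather than solver tolerance.

Summary statistics follow the study conventions: flux value = median over
iterations, variability = 100 * SD / |median|, reported as undefined (`NA`)
when the median is numerically zero rather than as infinity.

Derived quantities operate on net base-model fluxes:

* `normalize_by_uptake()`: percentages of the substrate uptake rate. The
  normalization is mole-based (v/uptake), exactly as defined by the source
  convention, even though such values are often labelled "% of carbon";
  a C-mol-weighted variant can be built from the same primitives but is
  deliberately not the default.
* `compute_kapp()`: apparent catalytic activities `v / (E * 3600)` in 1/s.
  `kapp <= kcat` is a theorem only for enzymes whose measured bound was
  enforced; released or flexibilized enzymes may run above their measured
  level, so the pipeline report flags the guaranteed subset
  (`constrained`).
* `cofactor_turnover()`: turnover as the production half-sum
  $\sum_r \max(0, s_{mr} v_r)$ over all compartment instances, which equals
  consumption at steady state and avoids the double counting a literal
  "sum of fluxes involving" would entail. All compartments are pooled by
  default (`compartments` filters); transport reactions count because they
  carry nonzero stoichiometry for the metabolite. Yield = turnover /
  uptake.
* `tradeoff_report()`: consumption shares of named reactions across
  conditions, flagging a switch of the dominant consumer - the
  NADPH trade-off between nitrogen assimilation (NADP-glutamate
  dehydrogenase) and fatty-acid synthesis.

## The synthetic-data generator

`make_toy_network()` builds a 61-reaction (glucose/acetate) or 69-reaction
(xylose) central-carbon network of an oleaginous yeast: glycolysis and
gluconeogenesis, oxidative and non-oxidative PPP, the phosphoketolase route
to cytosolic acetyl-CoA (with an acetate-kinase arm available as a
scenario), pyruvate-decarboxylase and citrate-lyase alternatives, TCA cycle
with glyoxylate shunt, carnitine shuttle, malic enzyme, NADP-GDH nitrogen
assimilation, ACC/FAS lipid synthesis costing 1 ATP and 2 NADPH per acetyl
unit added, elongation/desaturation to C18:1, SLIME lipid pseudo-reactions,
and a lumped electron transport chain (P/O 1.5 mitochondrial, 0.9 for
cytosolic NADH). The xylose variant adds xylose reductase (NADPH), xylitol
dehydrogenase and xylulokinase plus the D-arabinitol bypass (D-arabinitol
4-dehydrogenase, NADP-dependent D-arabinitol 2-dehydrogenase - swappable to
NAD by scenario - and D-ribulokinase).

Deliberate simplifications: protons and water are not balanced (element
checks are therefore optional), FADH2 is folded into NADH, ATP/ADP, CO2 and
O2 live in single pools, and the glyoxylate-shunt transport steps are
folded into isocitrate lyase. Default compositions are 0.45/0.10/0.45
protein/lipid/carbohydrate (g/gDCW) for nutrient excess and 0.16/0.34/0.50
under nitrogen limitation - the regime that induces lipid accumulation in
oleaginous yeasts - with GAM 120 mmol ATP/gDCW and NGAM 1.5 mmol/gDCW/h as
typical yeast values.

`simulate_condition()` fixes the phase composition, builds the
enzyme-constrained model with the planted true turnover numbers, maximizes
growth, makes the solution parsimonious, and reads ground-truth fluxes,
enzyme usages and exchange rates off that solution; measured physiology
adds multiplicative lognormal noise (`rate_cv`). `simulate_proteomics()`
emits duplicate MS records tied to a heavy internal standard, with planted
abundances at `usage / saturation * headroom` (default 0.35 and 1.3: cells
hold excess enzyme - that excess is what the saturation factor models - plus
30% headroom so the enzyme budget is not exactly tight), a ribosomal block
sized to a planted translation rate (default 3 aa/s), filler proteins
absorbing the remaining mass, and lognormal intensity noise (multiplicative,
as MS error is). Zero-usage enzymes and xylulokinase are withheld as
"not detected" - the latter mirroring the repeated observation that
xylulokinase escapes proteomic detection while the bypass enzymes are
abundant.

What passing tests show - and do not. Recovery tests prove the estimators
are unbiased and exact in the noise-free limit and stable under the planted
noise model; they cannot validate assumptions the generator shares with
the pipeline (lognormal MS error, proportionality of intensity to
concentration, completeness of the enzyme table). Problem sizes are chosen
for exhaustiveness of checking, not realism: networks of ~60-130 reactions
(after splitting), 2000 sampling iterations for production-style runs and
a few hundred where only stability is asserted.

## Known limitations

* The simplex is dense and single-threaded: fine for networks up to a few
  hundred reactions, not for genome-scale models (thousands of reactions) -
  those need a sparse industrial LP code.
* Differential expression at n = 2 has little power; the SD > mean filter
  is a coarse reliability screen.
* The SBML layer covers Level 3 core species/reactions/bounds and
  gene-association attributes; packages, rules and events are dropped with
  a warning.
* Thermodynamic feasibility of cycles (e.g. the NADH-driven malate
  dehydrogenase cycling that sampling can report) is not tested; such
  fluxes are reported, not filtered.
* The "fewer than three eligible reactions" degenerate case samples with
  as many objectives as exist; sampling a fully determined network is then
  a reproducibility check, not an exploration.
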