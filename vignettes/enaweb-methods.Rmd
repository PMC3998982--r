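---
title: "Methods: network indicators of mass-balanced food webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network indicators of mass-balanced food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enaweb)
```

## The model

`enaweb` analyses static, mass-balanced food web models in the Ecopath
tradition. A model is an ordered set of functional groups — species,
species aggregates, or detritus pools — each with biomass `B`
(t km⁻²), production rate `PB` (y⁻¹), consumption rate `QB` (y⁻¹ for
consumers), unassimilated fraction `GS` (default 0.2), fisheries removals
`Y`, non-fishery export `E` and biomass accumulation `BA`
(all t km⁻² y⁻¹, default 0), plus a diet matrix `DC[i, j]` giving the
proportion of prey *i* in the diet of predator *j*. Mixed
producer/consumers carry a `producer_fraction`; their food intake is
scaled by one minus that fraction. Each consumer's diet column plus its
imported-diet fraction must sum to one (tolerance 1e-6; an explicit,
never silent, renormalization flag exists for sloppy input files).

The master balance equation closes the model: for every living group,

> production = predation + catch + export + accumulation + flow to detritus,

so the ecotrophic efficiency `EE` — the fraction of production used
within the system — is estimated as
`EE_i = (Σ_j Q_j DC[i, j] + Y_i + E_i + BA_i) / (B_i PB_i)`.
We require `EE ≤ 1` for a balanced model and only warn otherwise (the
balance report always carries the offending groups); the package never
solves the general Ecopath inversion for missing `B`/`PB`/`QB`. Detritus
`EE` (consumption over inflow) has different semantics and is therefore
excluded from the mean EE indicator, which averages living groups only.

## Flows and throughput

`build_flows()` turns a balanced model into flows: predation flows
`T[i, j] = Q_j DC[i, j]`; respiration of consumers as assimilation minus
heterotrophic production, `(1 − GS) Q − (1 − pf) B PB`, floored at zero
with a warning when rate inputs are inconsistent; flows to detritus
`GS·Q + (1 − EE) B PB`; primary production and imported diet as imports;
catches, exports, accumulation and unconsumed detritus inflow as exports.
Counting the detritus surplus as an export reflects the convention that
unconsumed detritus leaves the steady-state system; the choice only
affects `Ex/TST` and is localized in one place. Every compartment is
checked for input = output to relative 1e-6.

Total system throughput uses the four-component convention

> TST = total consumption + total exports + total respiration + total flows to detritus,

so the four component ratios sum to one by construction. The
Ulanowicz-style extended matrix (a virtual import row and separate export
and respiration sink columns, detritus internal) is exposed separately
via `extended_matrix()` and drives the information and cycling indices.

## Information indices and cycling

On the extended matrix with total flow `T..` and marginals `T_i.`, `T_.j`:
capacity `C = −Σ T_ij log₂(T_ij/T..)`, ascendency
`A = Σ T_ij log₂(T_ij T.. / (T_i. T_.j))`, overhead `O = C − A`, and the
redundancy (internal-flow overhead)
`IFO = −Σ_internal T_ij log₂(T_ij² / (T_i. T_.j))`. Logarithms are base 2
(flowbits); the relative indices `A/C`, `O/C`, `IFO/C` — the quantities
compared across models — are base-invariant and invariant to uniform
flow rescaling, which the tests verify. Both `A` and `O` are partitioned
into import/internal/export/dissipation components that sum exactly to
the whole.

The Finn cycling index uses the Leontief structure matrix of the
input-fraction matrix `G` (`G_ij = T_ij` over the total input of `j`):
with `L = (I − G)⁻¹`, compartment *i* recycles `(L_ii − 1)/L_ii` of its
throughput. By default `FCI = 100·TSTc/TST` uses the same four-component
TST as the throughput module, for internal consistency across
indicators; the extended-matrix total is available behind
`denominator = "extended"`. Because flows between living compartments of
a trophically ordered web are acyclic, recycling in generated webs comes
entirely from the detritus loop, which is the dominant pathway in real
systems too.

## Trophic structure

Trophic levels solve the linear system `TL_j = 1 + Σ_i DC[i, j] TL_i`
with producers and detritus at 1. Imported diet is assigned TL 1 by
default (`import_tl` is configurable); mixed producer/consumers use
`TL = 1 + (1 − pf)·Σ DC·TL`. Cannibalism and mutual predation are
handled naturally by the solve — no diet-loop stripping. The community
mean TL weights groups with TL strictly above 2 by biomass; the catch
mean TL weights by removals and is undefined (not zero) in unfished
models.

The omnivory index of a consumer is the diet-weighted variance of prey
trophic levels; the system index aggregates consumer OI weighted by
`log(Q)`, with zero weight for intakes at or below 1 t km⁻² y⁻¹ so the
weight never goes negative.

The Lindeman spine apportions each group's activity to integer trophic
levels: producers and detritus at level I, consumers as the
diet-weighted average of prey distributions shifted up one level. The
recursion is evaluated level by level, which terminates for arbitrary
webs because cycle mass decays geometrically; the spine is truncated
(cap 50 levels), renormalized, and a residual above 1e-6 warns. The
transfer efficiency of level *k* is the predation flow passed to level
*k*+1 plus exports (catches included) leaving level *k*, over the
level's throughput; the summary `TEm` is the geometric mean over levels
II–IV in percent, dropping (with a warning) levels that carry no flow,
as in a three-level chain.

## Fishing footprint

The primary production required to sustain the catch propagates the
removals backwards through the diet matrix: demand `d` on a consumer
becomes demand `d·Q/P` on its prey's production, split by diet shares,
and demand arriving at producers or detritus is accumulated. The default
mode lets cycles damp themselves (every pass multiplies by trophic
efficiencies below one); a strict mode first deletes the minimum-flow
arc of every remaining diet cycle, matching the "cycles removed"
formulation literally — the two agree exactly on acyclic webs, and the
difference is logged otherwise. Detritus uptake is counted inside
`PPRc`, while the percentage form normalizes by primary production only.

The loss-in-production index converts that footprint into lost secondary
production:

> L = PPRc · TE^(TLc − 1) / (PP · ln(1/TE)),

with TE the mean transfer efficiency as a proportion. L is zero without
catch and strictly increasing in PPRc, and integrates the production
displaced across trophic levels between the primary producers and the
mean level of the catch. The probability that a system is sustainably
fished is a monotone decreasing map of L. The original empirical
calibration was fitted on a reference set of exploited ecosystems that
is not distributed with this package, so `p_sust()` exposes the curve as
a pluggable logistic in log₁₀(L) — maximum at L = 0, halving at
`l50 = 0.05`, width 0.25 decades — and these package defaults should be
re-fitted before absolute probabilities are interpreted; ranks and
trends are insensitive to the constants.

## Mixed trophic impacts and key roles

The direct impact of group *i* on group *j* combines benefit as food and
harm as predator: `q_ij = DC[i, j] − F_ji`, where `F_ji` is the share of
total predation on *j* exerted by *i*. Detritus enters with a
pseudo-diet given by each group's share of detritus inflow, so
detritus-fuelling groups impact the pool positively; fishing fleets are
not compartments (the analysis concerns functional groups), and
predation shares are computed over group predators only. Total impacts
are the closure `m = (I − q)⁻¹ − I`. The equivalent impact-path series
`Σ qᵏ` diverges for strongly linked webs (a two-link chain already has
spectral radius √2), which is why the inverse is the implementation;
the tests compare the two routes on dilute webs where the series
converges.

The overall effect `ε_i` is the Euclidean norm of off-diagonal impacts;
with biomass proportion `p_i` over living groups, keystoneness is
`KS = log₁₀(ε (1 − p))` and dominance `KD = log₁₀(ε p)`, so
`KS − KD = log₁₀((1 − p)/p)` exactly. The top-down fraction uses squared
impacts, consistent with the Euclidean norm (absolute-value weighting is
available). Default role thresholds are `KS ≥ 0` for keystone and
`KD ≥ −0.7` for structuring groups; both are arguments, and percentile
cutoffs over a collection can be recovered with `key_role_cutoffs()`.
Detritus participates in the impact matrix but never in the ranking.

## Collection statistics

The PERMANOVA is implemented directly on the Gower-centred
inner-product matrix of Euclidean distances, with Type I (sequential)
sums of squares: covariates first, the trait factor last, pseudo-F from
the hat-matrix traces. Indicator columns are z-scored by default (the
distance is otherwise dominated by whichever indicator has the largest
units); magnitude-type indicators such as TST are best supplied on a log
scale. P-values are `(exceedances + 1)/(permutations + 1)`; raw rows are
permuted without covariates and reduced-model (covariate-only) residuals
— the Freedman–Lane scheme — with them. Terms aliased with earlier
covariates receive zero degrees of freedom and `NA` statistics rather
than an error, which matters because webs with a single detritus pool
have `n_living = n_groups − 1` identically. `vegan::adonis2` serves as
an independent cross-check in the tests, never as the implementation.

Key-role × trait tables are analysed by the Pearson chi-square
decomposed into per-cell contributions `(O − E)²/E` (they sum exactly to
the statistic), with the upper-tail p-value at `(r−1)(c−1)` degrees of
freedom, and by correspondence analysis of the standardized residuals,
whose total inertia times the table total reproduces the chi-square.

## The synthetic generator

`generate_web()` emulates the model diversity of published marine
collections without reproducing any real system: webs of 6–68 groups
(drawn around a median of 26 in collections), one or more producers, an
optional detritus pool. Topology is trophically ordered — each consumer
samples prey among strictly lower-ranked groups (connectance 0.25 by
default) plus detritus with probability 0.4 — which guarantees solvable
trophic levels and confines cycling to the detritus loop. Diets are
Dirichlet; biomasses are lognormal (median 1 t km⁻², σ = 1) declining
with trophic rank; consumer `PB` declines log-linearly from 12 y⁻¹ at
the bottom to 0.4 y⁻¹ at the apex, `QB = PB/GE` with gross efficiency
uniform on 0.1–0.3; producers have `PB` around 40 y⁻¹. About 30% of
consumer groups carry catches at a tenth of their production. Balance is
enforced by iteratively rescaling the biomass (and catch) of the
predators of any group whose EE exceeds 0.95 — rescaling diets instead
would distort the topology being tested. Everything is deterministic
under the seed.

What the generator does *not* emulate: niche-model topology, multi-stanza
age structure, microbial-loop resolution, import-dominated diets,
nutrient forcing, or the empirical covariance between rates and body
size. Tests passing on generated collections therefore demonstrate the
correctness and statistical behaviour of the pipeline, not ecological
conclusions about real webs.

`generate_collection()` labels each web with categorical traits
(ecosystem type, latitude band, ocean basin, depth, size, period,
exploitation) and can inject known effects as multiplicative shifts on
generator parameters, giving a ground truth for type-I-error and power
checks of the trait statistics. Under null settings the PERMANOVA
rejects at the nominal rate; a large injected primary-production shift
(producer `PB` ×8, biomass ×4, eight webs per level, sizes held at 14
groups) is detected in ≥90% of replicates — those problem sizes keep the
whole statistical suite comfortably reproducible on a laptop.

## Numerical choices

Diet-column tolerance 1e-6 absolute; balance residuals relative 1e-9;
steady-state tolerance relative 1e-6; trophic solve via dense LU
(`solve`), singular systems reported as errors; spine truncation
residual warning at 1e-6; PPR propagation stops when residual demand
falls below 1e-12 of the catch, with an iteration cap that converts
pathological cycles into errors; zero-flow cells are dropped before
logarithms; permutation p-values never report zero. Ties in role
classification resolve keystone before structuring, so a group crossing
both thresholds counts once.

## Limitations

Static snapshots only — no Ecosim/Ecospace dynamics; no native EwE
database reader (bundles are plain CSV/JSON); single-currency
(biomass) networks; the `p_sust` calibration constants are package
defaults, not the original fit; and key-role summaries across
collections inherit whatever balance conventions the source models used.
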