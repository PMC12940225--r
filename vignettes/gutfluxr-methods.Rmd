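---
title: "Methods: community flux modeling and the association battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community flux modeling and the association battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gutfluxr` models the metabolic potential a gut microbial community offers
its host, and tests that potential against host risk factors. This vignette
documents the model, its assumptions, the tunable parameters, the numerical
choices, and the places where the design was genuinely open and a choice had
to be made.

## The constraint-based model

A `stoich_model` is a plain steady-state metabolic network: metabolites with
bracketed compartment tags (`[d]` diet, `[luLI]` large-intestinal lumen,
`[luM]` shared microbiota lumen, `[bc]` blood, `[fe]` feces, `[c]` species
cytosol), reactions with flux bounds in mmol/day/person, and a sparse signed
stoichiometry (substrates negative, products positive). Concentrations are
never simulated; every solve assumes $S v = 0$. Reactions without curated
bounds default to ±1,000,000 mmol/day/person — an "effectively unbounded"
sentinel, which matters for the bound-limited masking rule below.

**Pan-species models.** Strain reconstructions of one species are merged by
reaction-id union. A duplicated id must have identical stoichiometry
(anything else is an assembly error naming both strains); its bounds widen
to the observed extremes, so the pan model can realize any strain's
behavior. One biomass reaction per species is designated by a flag on the
strains.

**Community assembly.** Members with $a_k > 0$ are namespaced (`sp__rxn`),
share the `[luM]` lumen, and feed a `communityBiomass` reaction whose
stoichiometric coefficients are the relative abundances ($-a_k$ per species
biomass metabolite, +1 community biomass). Abundances must already sum to 1;
`build_community()` refuses to renormalize silently because the abundance
floor and renormalization belong to the mapping stage, where their order is
part of the method. Every microbial reaction is coupled to its species'
biomass reaction, $|v_j| \le C\,v_{\text{bio},k}$, $C = 400$
(dimensionless). Coupling is encoded as extra inequality rows of the LP
(slack-completed equalities), not as bound substitutions — S stays pristine
and the rows match the "flux capacity constraint" semantics of the
constraint-based toolboxes this follows.

**Host joining.** The community lumen connects to the host's `[luLI]`
compartment by reversible 1:1 junction transports for each shared
metabolite. The community biomass is routed to feces and its excretion
pinned to exactly 1 mmol/day/person, which forces $v_{\text{bio},k} = a_k$
and makes the coupling cap $400\,a_k$ — the mechanism by which community
*composition* moves flux *potential*. `Whole_body_objective_rxn` is also
pinned at 1 so all samples maintain the same host turnover. Removing the
community and junctions restores the germ-free host exactly (tested as a
round trip).

**Diet.** Dietary exchanges follow the uptake-negative convention: a diet
entry of $f$ mmol/day/person sets bounds $(-f, 0)$; every dietary exchange
the diet does not name is closed to uptake. The toy diet supplies an ample
shared substrate (5000 mmol/day of `fiber`) so that coupling, not diet, is
the binding constraint for microbial products, plus a host-only substrate
(`hsub`, 50 mmol/day) that microbes cannot consume.

## FBA and the solver

Blood potentials are maxima of demand reactions `DM_<met>[bc]`
(`1 met[bc] -> ∅`, bounds (0, 1e6)). The LP is solved by a bounded-variable
two-phase primal simplex written for this package (no LP solver package is
available in the supported environment): dense tableau, Dantzig pricing with
a Bland's-rule fallback against cycling, pivot and reduced-cost tolerance
1e-9, and feasibility asserted at 1e-6. Optimal solutions are checked in the
tests for $\|Sv\|_\infty < 10^{-6}$, bound satisfaction, and coupling
satisfaction; objective values agree with an exhaustive basic-feasible-
solution enumeration oracle on random toy models to 1e-6. Only objective
values are persisted — LP degeneracy affects the flux vector, never the
optimum. An unbounded demand on the toy models is treated as a modeling
error, since every route must be capped by diet or coupling. Infeasible
sample models mask the whole sample row (reason `infeasible`) and the sweep
continues.

Because per-sample models differ *only* in the `communityBiomass`
coefficients, `pipeline_fluxes()` compiles the LP once per sex and patches
that single column per sample, then runs one feasibility phase per sample
and re-uses the tableau across the demand objectives. A test pins this fast
path to the naive build-join-solve route, value for value.

## Flux post-processing

The order is fixed and deliberate: round to six decimals → subtract the
matching sex's germ-free maximum (the *scaled* layer) → mask scaled zeros
(`zero_contribution`) → mask, per metabolite, all samples attaining a
maximum that occurs two or more times after rounding (`bound_limited`; a
shared maximum means a host or diet bound, not the community, set the
value) → drop metabolites masked in more than 90% of samples or identical
(within 1e-6) in at least 90% of samples → group metabolites with pairwise
$R^2 > 0.999$ into connected components, keeping the smallest-max member
under a concatenated name.

Two readings in this chain were open and are declared here: the
bound-limited rule removes the *attaining samples*, not the whole
metabolite (the refinement rules afterwards decide whether the metabolite
survives); and "identical within tolerance" is implemented as
equivalence-by-chaining (adjacent sorted values linked when within 1e-6,
largest class fraction ≥ 0.9), since a tolerance defines a relation but not
a clustering rule. $R^2$ is computed over samples where both metabolites are
unmasked, because masking is per-metabolite; pairs sharing fewer than three
samples are skipped. Grouping uses connected components without requiring a
precursor-of-all relation.

## Metabolomics QC

Batch-median normalization (each intensity divided by its compound's
within-batch median; missing ignored) makes batch medians exactly 1. Sample
exclusion uses mean + 5·SD of the per-sample missing-value counts — the
source description of this rule is ambiguous between "mean + 5 SD" and
"5 SD"; the mean + 5·SD reading is declared and not silently changed.
Compounds missing in >70% of samples or with a mean between-aliquot CV
(SD/mean per replicate group, averaged over groups) >30% are removed; CV is
computed globally, not per batch (also unstated upstream; one global CV per
compound is the declared choice, which is why the synthetic generator emits
replicate-aliquot rows). All values are then log2-transformed and missing
entries imputed by sample-wise KNN: Euclidean distance over co-present
z-standardized compounds, k = 10 neighbours (no k is stated upstream; 10 is
a conventional default), each missing entry the mean of the nearest
observed values. Neighbours are drawn only from *observed* values — never
from already-imputed entries — and distances are computed over name-sorted
columns, so imputation is independent of row and column order.

## Derived scores and statistics

*Global cognition* is the first principal component of the z-standardized
subtest scores, sign-oriented to correlate positively with the mean subtest
so that "higher = better" is reproducible; the variance explained is
reported alongside. *PRS* is the weighted dosage sum
$\sum_i D_i E_i$, with a missing dosage propagating to a missing score
rather than a zero fill. *APOE* risk groups are E2 = {E2/E2, E2/E3},
E3 = {E3/E3}, E4 = {E3/E4, E4/E4}, with E2/E4 excluded as undefined.

The battery: standardized OLS with two-sided Wald p for the focal
coefficient (age model: flux ~ age + sex; cognition model: cognition ~ flux
+ age + sex + BMI + education, education entering as ordinal 1–4);
Kruskal–Wallis with tie correction plus Dunn pairwise z from pooled ranks,
Dunn p reported unadjusted (configurable downstream); Wilcoxon rank-sum
(exact for small tie-free samples, tie-corrected normal otherwise; fully
tied data returns p = 1 by convention); flux-by-sex interaction with
stratified per-sex follow-ups gated at p < 0.05; Welch's t for two-sample
comparisons (the unequal-variance variant is the declared default, Student
available), accepting summary triplets (mean, SD, n) as cohort tables
report them; and an exact Fisher test for 2×C tables by full enumeration of
the multivariate hypergeometric over the C−1 free cells (two-sided by the
"no more likely than observed" rule with 1+1e-7 slack), with a seeded
Monte-Carlo fallback past a configurable enumeration cap. FDR is
Benjamini–Hochberg, applied per analysis family across metabolites,
mirroring per-analysis correction columns.

*Driver attribution* regresses each candidate species' abundance against
the metabolite's scaled flux and ranks by $R^2$. Candidates are species
whose pan model can secrete the metabolite — or a declared precursor — into
the lumen; correlation alone never makes a species a candidate. Abundances
enter on the identity scale by default: for a sole coupling-bound producer,
flux is exactly $400\,a_k$, so the true producer attains $R^2 = 1$; a
log2 + z option mirrors the preprocessing of the regression battery.

## What the synthetic cohort emulates — and what it does not

The generator's defaults are the study conditions: n = 500 samples, female
fraction 608/1065, age ~ N(61.65, 5.4), BMI ~ N(27.4, 4.5), APOE genotype
frequencies and the four-level education distribution taken from the cohort
characteristics the package emulates, per-sample species-rank read coverage
~ N(0.495, 0.097) and resource-mapping coverage of species reads
~ N(0.64, 0.116), five cognitive subtests loading 0.69 on one latent factor
(implying a first component near 47% of subtest variance), and 28 risk SNPs.
Species abundances are log-normal with covariate effects added on the log
scale *before* closure to the simplex, so monotone covariate–abundance links
survive renormalization. Planted ground truths — a sole producer with a
standardized age slope of 0.3 and an APOE multiplier (0.8/1/1.25 for
E2/E3/E4), a lossy two-step chain (yield 0.5) for grouping, a secretion
capped at 10 mmol/day for bound-limited masking, a host-only metabolite for
the germ-free contract, three null producers, and the metabolomics QC
targets (a 10× missingness outlier, an 80%-missing compound, a CV ≈ 0.347
compound, a 1.0 log2 E4 shift) — are recorded in a machine-readable
manifest. Every artifact draws from its own named substream of the master
seed, so adding an output never perturbs existing ones and generation is
bit-reproducible.

The generator does **not** emulate: read-level 16S error, chimeras or
compositional sequencing artifacts; realistic genome-scale reconstruction
content (toy species have 5–15 reactions, one shared substrate); organ-level
host physiology (the host is a minimal multi-compartment network, not an
organ-resolved whole-body model); linkage structure among SNPs; or
metabolite annotation ambiguity. Passing tests therefore demonstrate that
the *pipeline machinery* recovers planted truths under its stated
assumptions — not that those truths hold in real cohorts.

## Problem sizes and numerical settings

Tests and the acceptance script run at n = 500 samples for fixtures whose
statistics need stable moments (coverage means, QC removals, planted-shift
recovery), n = 200 for grouping and germ-free contracts, and 50 independent
seeds at n = 500 for the end-to-end effect-recovery rate — sizes at which
every LP solves in well under a millisecond and the planted slope of 0.3
gives essentially full power, so recovery failures indicate defects rather
than sampling noise. Calibration uses 2000 null replicates per test at
α = 0.05. Simplex tolerances are 1e-9 (pivoting) and 1e-6 (asserted
feasibility); flux values are compared only after the six-decimal rounding
that the processing chain itself prescribes.

## Known limitations

The simplex is dense and suited to hundreds, not tens of thousands, of
reactions; genome-scale models would need a sparse revised implementation
or an external solver behind the same `fba_max()` interface. The exact
Fisher enumeration is practical for 2×C tables up to ~10⁷ candidate tables;
beyond that the Monte-Carlo fallback trades exactness for a seeded
estimate. The KNN imputer is O(n²) in samples. Dunn p-values are unadjusted
by design and should be corrected downstream when many pairs are tested.
The E2/E4 exclusion, the mean + 5·SD reading, the global CV, and the
identity-scale attribution default are declared choices where the upstream
description is ambiguous; each is a single argument away from the
alternative reading.
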