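---
title: "Predicting histone-modification fluxes from expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting histone-modification fluxes from expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmark)
```

This vignette is the package's own account of its methods: the model it
fits, the assumptions behind it, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical choices that were genuinely open.

## The flux model

A constraint-based metabolic network is a stoichiometric matrix $S$
(metabolites $\times$ reactions) together with flux bounds
$l \le v \le u$ (mmol/gDW/h). At steady state $Sv = 0$: no internal
metabolite accumulates. `fluxmark` never optimizes growth; its objective
is agreement with differential expression, in the iMAT tradition but
with a purely linear program. After splitting every reversible reaction
into forward/backward children ($v = v_f - v_b$, both $\ge 0$), the
activity of a reaction is $w = v_f + v_b$ and the fitted state solves

$$\max \; \sum_{r \in \mathrm{UP}} w_r \;-\; \sum_{r \in \mathrm{DOWN}} w_r
  \;-\; \varepsilon \sum_r w_r
  \quad \text{s.t.} \quad Sv = 0,\; 0 \le v \le u.$$

A reaction is UP when at least one gene in its gene–protein–reaction
(GPR) rule is upregulated and none downregulated, DOWN symmetrically,
and NEUTRAL otherwise (empty rules, mixed signals, unmapped genes). This
any-up-and-none-down rule is deliberately simple and isolated in
`map_genes_to_reactions()` so it can be swapped without touching the
solver.

Assumptions worth keeping in mind: expression is treated as a proxy for
the *capacity* of a reaction, not its realized flux; the linear
(non-integer) objective means a strongly UP pathway can drag flux
through NEUTRAL or even DOWN neighbours when stoichiometry demands it;
and all conclusions are about relative activities under the stated
bounds, not absolute rates.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `fdr_cut` | 0.01 | — | DE significance threshold |
| `lfc_cut` | 2 | log2 | DE effect threshold (a laxer `1` is also supported) |
| `epsilon` | 1e-4 | — | parsimony weight; uniquifies the optimum's magnitude |
| `vmax` | 1000 | mmol/gDW/h | hard cap on any single flux |
| `scale` (media) | 1 | (mmol/gDW/h)/mM | concentration-to-uptake-cap map |
| `n`, `jitter`, `seed` | 50, 0.05, — | — | ensemble size, objective jitter amplitude |
| `alpha` | 0.01 | — | significance level on BH-adjusted p |

Two DE thresholds circulate for this kind of workflow (|log2FC| ≥ 2 in
methods sections, |logFC| > 1 in results text); both are accepted via
`lfc_cut` and neither is silently preferred. `epsilon` must stay well
below 1 (a category unit); at 1e-4 it never changes which categories are
satisfied, only suppresses free futile cycles among alternate optima.

The media model maps a nutrient concentration $c$ (mM) to an uptake cap
$\min(\texttt{max\_uptake}, \texttt{scale}\cdot c)$. This is a contract,
not a kinetic claim: published workflows state that bounds were adjusted
to the growth media without giving the mapping, and a single
configurable linear cap is the simplest defensible choice. Fatty-acid
exchanges listed as `closed_fatty_acids` but absent from the nutrient
table get uptake 0, so control media genuinely exclude them.

### The histone augmentation

`default_histone_augmentation()` adds eight reactions: an
acetyl-CoA/CoA nuclear antiporter (one reaction, so the CoA pool stays
closed), SAM nuclear import, SAH nuclear export, an unconstrained
histone supply, the acetylation and methylation writer reactions, and
demand sinks `DM_histone_ac` / `DM_histone_me`. Histone species are
non-conserved pseudo-metabolites: the supply is unconstrained so that
modification fluxes are limited only by donor (acetyl-CoA / SAM)
availability, matching the interpretation that bulk marks track donor
flux. There are no site-specific marks; the model predicts bulk
acetylation and methylation only.

One consequence of the shared (bounded) histone supply: if *both*
writers are maximally rewarded and donors are unlimited, acetylation and
methylation contest the supply with equal marginal objective, and the
optimum is degenerate between them. The package does not hide this —
degeneracy is exactly why differential calls are made on ensembles, not
on single states.

### The ensemble null and differential calls

The LP optimum is often a face, not a point. To attach uncertainty to
each reaction's activity we re-solve the LP `n` times with the ±1
category weights multiplied by independent $U(1-j, 1+j)$ draws
($j$ = `jitter`). Bound-saturated reactions have zero spread by
construction; reactions free to wander across alternate optima show
their spread. Two conditions are compared per reaction with a two-sample
Wilcoxon rank-sum test, BH-corrected across reactions. Reactions
constant in both ensembles are decided without rank degeneracy: equal
constants give p = 1, different constants an exact difference. This
scheme is a documented stand-in — published analyses report per-reaction
p-values without stating their resampling device — so membership of any
particular significant set should be read qualitatively.

### Numerical choices

The LP solver is a dense bounded-variable simplex written for this
package. The zero flux vector is always feasible (the right-hand side is
zero), so no phase-1 is required; upper bounds are handled natively
rather than through slack variables; Bland's smallest-index rule is used
for both entering and leaving choices because these polytopes are
heavily degenerate and cost-ordered pivoting can cycle. Variables pinned
at zero are eliminated and linearly dependent rows of $S$ (conserved
pools such as CoA, folate and the adenosyl carrier) are dropped before
solving; both transformations leave the feasible set unchanged. Mass
balance of every returned state is asserted to
$\lVert Sv\rVert_\infty \le 10^{-6}$, and on small networks the optimum
is cross-checked in the test suite against an exhaustive
vertex-enumeration oracle to $10^{-6}$.

## Chromatin computations

Coordinates are 0-based half-open everywhere inside the package; BED is
native and 1-based inputs are converted at the boundary, preventing
off-by-one drift between tool conventions. "Overlap" means ≥ 1 bp; no
minimum-overlap fraction is applied. The enrichment statistic is

$$\mathrm{enrichment} = \frac{a/b}{c/d}, \qquad
  d = \frac{G}{\overline{\ell}_{\mathrm{peak}} + \overline{\ell}_{\mathrm{feature}}},$$

with $d$ kept real-valued (whether to round the "estimated number of
discrete slots" is unspecified in the field's descriptions; rounding
would only perturb results and lose the algebraic identities
`enrichment = d/c` when peaks equal features and `= d` for one
genome-wide feature). Its calibration property — uniformly placed peaks
give mean enrichment ≈ 1 — is tested over 200 seeded replicates.

Tn5 cut sites are derived from read 5′ ends with the +4 (forward) / −5
(reverse) shift, configurable off; CPM normalization scales each sample
to a $10^6$ column total, leaving all-zero samples at zero. Differential
accessibility testing itself (negative-binomial GLMs) is consumed from
upstream tools, not reimplemented.

## Expression profiles

`response_vs_baseline()` plots-ready output is
$\ln(E_{trt}/E_{ctrl})$ against $\ln(E_{ctrl}/E_{ctrl,avg})$, with
per-gene means over replicates (arithmetic mean; the aggregator is not
specified by convention) and a pseudocount (default 0.5 TPM) so
zero-TPM genes stay finite. An optional minimum-TPM filter exists but
defaults off. The trend is summarized by tie-aware Spearman correlation.
The qPCR transform is $\mathrm{log2RE} = -(Ct_X - Ct_{ref})$, antitone
in $Ct_X$ and invariant to shifting both cycles.

## What the synthetic generators emulate

The toy network is a fixed constant, not random: reproducible
direction-recovery results outweigh generality. It spans glucose →
glycolysis → acetyl-CoA, octanoate/linoleate β-oxidation (octanoate
entering by diffusion, with no transporter gene), lumped
glutaminolysis, the serine/glycine-fed folate cycle, the methionine
cycle, and the nuclear histone chemistry; every named enzyme carries a
gene and subsystem. Bookkeeping is carbon-skeleton only — CoA, folates,
the adenosyl moiety and the histone pool are carbon-free carriers — and
every internal reaction balances against the packaged carbon table.
Lumped reactions deliberately omit ATP/NADH costs, so the toy cannot
exhibit energy-limited behaviour; media bounds are the only resource
limits.

Generator defaults are the study conditions: control media glucose
8.0 mM and glutamine 2.0 mM (the molar equivalents of 1.441 g/L and
0.292 g/L), serine 0.4, glycine 0.4, methionine 0.2 mM; treatment adds
5 mM octanoate (or 0.5 mM linoleate); planted DE effects |log2FC| = 4
with noise SD 0.25 and planted FDR ~ U(0, 1e-4), far beyond the calling
thresholds so recovery is exact (set `effect_lfc` near the threshold
for power experiments); mean-reversion strength `kappa` 0.5; toy genome
2 × 1 Mb with 200 peaks × 500 bp and 20 features × 1500 bp. Peak
placement draws each peak into the feature-proximal region with
probability $p_{in}L_{in}/(p_{in}L_{in}+p_{out}(G-L_{in}))$ and
uniformly within its region, so $p_{in} = p_{out}$ is exactly uniform.

What passing tests do *not* show about real data: planted effects are
cleanly separated, GPR rules are short, the network is small and fully
observable, cut counts are ideal Poisson draws without GC or
mappability structure, and the ensemble null is exactly exchangeable.
On real inputs, threshold sensitivity, id-mapping loss and the
unpublished resampling scheme behind reference p-values are the
dominant divergence risks.

## Problem sizes and determinism

Default analyses use ensembles of 50 LP solves per condition (a few
seconds each on the toy model), 200 replicates for enrichment
calibration, and 5000 genes for trend nulls. Every stochastic entry
point takes a seed, uses a fixed integer-state generator
(Mersenne–Twister with inversion normals), restores the caller's RNG
state, and is byte-identical across repeat runs; pipeline runners write
a provenance record (stage, version, parameters, seeds) next to their
outputs.

## Known limitations

- Bulk marks only; no site-specific histone modifications.
- No flux variability analysis, gap-filling or thermodynamic
  (ΔG-based) machinery beyond bound signs; no biomass objective.
- The concentration-to-bound map is linear by contract, not kinetics.
- Differential calls depend on the jitter ensemble device; absolute
  significant-set membership on genome-scale models should be treated
  as qualitative.
- The SBML reader covers the two dialects Recon-family models circulate
  in (L2 + COBRA notes, L3 + fbc); exotic SBML constructs (algebraic
  rules, events) are out of scope.
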