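---
title: "The unfolding mutation screen: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The unfolding mutation screen: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umscreen)
```

## The two-state unfolding model

The screen treats a protein as populating only two thermodynamic states,
folded and unfolded. A missense mutation shifts the free-energy balance
between them by ΔΔG (kcal/mol; this package stores every value
destabilising-positive). The Boltzmann weight of the unfolded state then
gives the **unfolding propensity**, the implied unfolded fraction:

$$U(\Delta\Delta G) = \frac{1}{1 + e^{-\Delta\Delta G / RT}}$$

This is the unique sigmoid consistent with the three constraints the
propensity scale must satisfy: it ranges 0–1, an identity mutation
(ΔΔG = 0) sits exactly at the folding–unfolding equilibrium 0.5, and
destabilising mutations (ΔΔG > 0) give U > 0.5. Working on the propensity
scale rather than raw ΔΔG bounds every mutation's effect on a common,
protein-independent axis, which is what makes per-residue sums and
cross-protein comparisons meaningful.

**RT** (`default_rt()`, 0.5926 kcal/mol = RT at 298.15 K) is the single
tunable of the transform and sets the steepness of the curve around
equilibrium: a mutation of +RT·ln 9 ≈ +1.30 kcal/mol maps to U = 0.9.
The physiological temperature is the natural default; a user matching
denaturant-derived experimental curves can widen or narrow the transition
by passing another value, since the condition (temperature, denaturant)
under which ΔΔG values were obtained effectively rescales the curve. No
multi-state or denaturant-m-value model is attempted: strictly two-state.

## Effect classes and tie-breaks

Propensities are binned as stabilising (0–0.4), folding–unfolding
equilibrium (0.4–0.6) and destabilising (0.6–1.0). The printed bin edges
overlap at 0.4 and 0.6; `classify_effect()` assigns both edges to the
**equilibrium** bin, on the view that a value sitting exactly on the
boundary has not shown a clear directional effect. The binary scheme
splits at 0.5 and still reports exactly 0.5 as equilibrium rather than
forcing a direction. Both choices are deterministic and documented here
rather than configurable flags, so every report is comparable.

## Foldability and critical residues

Per residue, foldability is the sum of propensities over the 19
substitutions whose U exceeds the **saturation threshold** 0.9 — the
region of the unfolding curve where a mutation can be read as causing
outright unfolding. The gated sum (rather than a mean) tallies severe
mutations without dilution by benign ones, and ranges 0–19.

Two readings of the summand were possible: a sum over all 20 variants or
over the 19 substitutions. Only the 19-substitution sum excluding the
identity cell is consistent with the maximum of 19 and with the critical
cutoff 17.1 = 19 × 0.9, so that is the definition implemented; the
identity cell is excluded even if a poor model pushes it above the
threshold. **Critical residues** are those with foldability strictly
greater than 17.1 — positions where essentially every substitution
unfolds the protein; empirically these concentrate on glycines, prolines
and disulfide cysteines.

Missing matrix cells (mutations without a ΔΔG record) contribute nothing
to the sum and are never imputed. A row with more than two missing
substitutions has an attainable maximum materially below 19, so it is
flagged not-comparable and excluded from critical-residue calls with a
warning, rather than silently compared against a cutoff it could not
reach.

## The internal control

Mutating each residue to itself should leave stability unchanged:
identity propensities should cluster tightly at 0.5. Systematic deviation
indicates strained side-chain rotamers in the input model — the model
disagrees with its own sequence — which is why the control is a useful
quality check on homology models. `internal_control()` reports n, mean,
SD, a t-based 95% confidence interval and the p-value of a one-sample
t-test against 0.5.

The verdict is driven by the confidence interval (pass iff the CI
half-width is ≤ 0.05 and the CI contains 0.5), not by the p-value: a tiny
p-value can coexist with a mean far from 0.5 (it then rejects 0.5!), and
with large n even trivial deviations become "significant", so the p-value
is reported for completeness but cannot certify closeness. The 0.05
half-width default means the mean identity propensity is localised to
±0.05 on a 0–1 scale, i.e. within the equilibrium bin.

## Heat maps and clustering

The standard map fixes both axes — residues in structure order (author
PDB numbering, so cell names match clinical mutation nomenclature like
P23H), amino acids alphabetically — and colours cells on a diverging
scale anchored at U = 0 (blue), 0.5 (white) and 1 (red), with missing
cells grey and each cell annotated to two decimals.

The clustered map applies agglomerative hierarchical clustering
independently to rows and columns. Defaults are Euclidean distance with
complete linkage — the defaults of the interactive heat-map packages this
display style comes from — and both are recorded in the result object and
the plot caption. Missing cells are imputed at 0.5 (the neutral value)
for distance computation only, with a message; the imputation never
touches the matrix itself. Rows are clustered on raw propensities by
default: the propensity scale is already bounded and comparable across
rows, so standardisation (exposed as `standardize = TRUE`) is an option,
not the default. `stats::hclust` breaks merge-height ties by original
index order, making leaf orders deterministic for identical input.

## Validation metrics

Experimental ΔΔG values (ProTherm-style records, which report stability
changes with the opposite sign) are negated on ingest by default and
transformed to propensities with the same logistic curve as the computed
side — the screen compares like with like on the U scale. Pairs are
matched by mutation key; records present on one side only are kept in
`unmatched_*` attributes rather than silently dropped. When a mutation
has several experimental measurements, they are averaged after sign
normalisation (with the count kept), replacing manual best-value
curation by a documented, reproducible rule.

The **match matrix** cross-tabulates ternary classes (diagonal =
agreement); **percent matching** is the diagonal share. The **fit
score** is the mean absolute difference of the paired propensity
vectors: 0 for identical vectors, bounded by 1 because U ∈ [0, 1]. It is
deliberately isolated in one small function so an alternative discrepancy
measure can be substituted without touching the pipeline.

## The synthetic generators: what they emulate and what they do not

`make_toy_structure()` writes an ideal α-helix CA trace (radius 2.3 Å,
rise 1.5 Å, 100° turn — consecutive CA atoms therefore sit
`toy_helix_ca_spacing()` ≈ 3.83 Å apart) with uniformly drawn residue
types. It gives the toy ΔΔG estimator real geometry (terminal residues
are less buried than central ones) while staying tiny and fully seeded.

`make_synthetic_ddg()` emulates a scan with known ground truth: identity
mutations get exactly 0; every substitution at a planted position gets
+4 kcal/mol (U ≈ 0.9988, so planted foldability ≈ 18.98 > 17.1); all
other substitutions draw from Normal(0, 0.5) clipped to ±1.2 kcal/mol.
The clip is set just **below** RT·ln 9 ≈ 1.302 so no background cell can
cross the 0.9 saturation threshold: planted and background foldability
distributions are disjoint by construction and critical-residue recovery
is decidable analytically, not statistically. (A wider clip of ±3 was
considered and rejected: it admits background cells above 0.9 and breaks
that separability guarantee, turning an exact property into a
probabilistic one.)

`make_validation_pairs()` draws experimental propensities uniformly on
[0, 1] and adds Uniform(−ε, ε) noise, clipped; hence fit score ≤ ε with
expectation ≈ ε/2, and percent matching → 100 as ε → 0.

None of these generators mimics real protein energetics — no residue
contact topology beyond the helix, no correlated errors, no
composition bias. Passing tests on them demonstrates correctness of the
bookkeeping and the transforms, the exactness of the anchor values, and
recovery of planted signal; it says nothing about predictive accuracy on
real structures, which depends entirely on the quality of the supplied
ΔΔG source.

The toy ΔΔG estimator (`estimate_ddg_toy()`) is a deterministic,
physically-motivated score — burial-weighted hydropathy and side-chain
volume changes plus fixed penalties for mutating away from Gly/Pro/Cys —
whose role is to make the pipeline self-contained and to give the
internal control its exact-0.5 behaviour. It is labelled a toy throughout
and is not a stability predictor.

## Numerical and degenerate-input choices

- Identity propensity is exact: `U(0)` evaluates to exactly 0.5 in
  floating point (`plogis(0)`), so internal-control statistics on clean
  input are exact, not approximate.
- An all-equal identity vector has SD 0; the t-test is then undefined, so
  the control reports a degenerate CI [mean, mean] and p = 1 when the
  mean is 0.5 (p = 0 otherwise).
- Foldability uses strict `>` at both the saturation threshold and the
  critical cutoff, matching the "greater than" wording of both rules;
  a residue at exactly the cutoff is not critical.
- PDB parsing keeps author numbering, resolves alternate locations to the
  first encountered, maps common modified residues (MSE, SEC, …) to their
  standard parents with a warning, skips residues without a standard
  parent with a warning, and rejects insertion codes outright rather than
  inventing an ordering for them. Gaps in numbering are allowed;
  positions must be strictly increasing within a chain.
- Multi-chain structures are scanned per chain and concatenated in file
  order.

## Problem sizes

The test-suite and acceptance computations run on 3–20-residue toy
structures (60–400-mutation scans), 1,000-point transform grids, and
320–2,000 synthetic validation pairs — sizes at which every oracle
(brute-force enumeration, closed-form chord lengths, hand cross-tabs,
t-interval arithmetic) can be computed independently and exactly, while
the whole suite completes in seconds. The pipeline itself is vectorised
over the mutation list and scales to real proteins (a 20 × N matrix is
N·20 rows; clustering is the only super-linear step).

## Known limitations

- Single missense changes only; no double mutants or cumulative scoring
  of co-occurring variants.
- Strictly two-state thermodynamics; proteins with stable intermediates
  will be mis-modelled near the transition.
- The screen is only as good as its ΔΔG source; the bundled estimator is
  a toy, and FoldX-class accuracy requires running such a tool externally
  and importing its output.
- The exact published functional form of the fit score in the original
  description of this display style is not recoverable from text; the
  mean absolute difference implemented here satisfies all its stated
  properties but may differ from that form.
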