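---
title: "Context-dependent substitution analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent substitution analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Substitution rates at noncoding DNA sites are not homogeneous: they depend
on the flanking bases.  In plant chloroplast genomes this dependence is
strong — transitions are elevated where a C sits 5' of a G (the CpG
deamination effect), transversions rise with the A+T content and with the
purine arrangement of the flanks, and the net effect is that sites in
different contexts drift toward very different equilibrium compositions.

`ctxsub` estimates this structure from aligned sequence **triplets**: two
closely related ingroup sequences plus an outgroup used to infer the
ancestral state.  Every eligible aligned site is treated as the center of a
(2r+1)-mer; with the default radius r = 3 the flanking hexanucleotide
defines the context N3 N2 N1 [N0] N1 N2 N3.  For each context a 4x4 count
matrix `CM[i, j]` accumulates ancestral-to-derived observations (two per
site, one per ingroup; conserved sites fill the diagonal), and everything
else — rates, Ts:Tv biases, equilibrium compositions, CpG odds ratios,
index associations — derives from those matrices.

## Site eligibility

A column of a triplet alignment contributes records only if:

1. at least 8 of the 10 surrounding columns (5 per side) are non-gap bases
   in **both ingroups**;
2. at least 7 of those 10 columns carry identical bases in the two ingroups
   (70% similarity; a gap never matches);
3. the r nearest columns on each side are non-gap and identical in **all
   three** sequences (conserved context, so the ancestral context is known
   and alignment neighbors equal physical neighbors);
4. the focal column is a base (A/C/G/T) in all three sequences;
5. the focal column is at least max(5, r) columns from either end.

The two-ingroup window conditions follow the wording of the original
filters, which name only the ingroups; the outgroup enters through the
context-conservation condition.  "10 surrounding sites" is read
symmetrically (5 per side) — the natural reading, though a split is not
stated.  Ambiguity codes are treated like gaps.  Exclusions are tallied
against the first failing filter in the order edge, focal gap, gap window,
similarity, context, so `columns scanned = eligible + sum(exclusions)`
holds exactly and is asserted by the pipeline log.

Regions must have strictly more than 70 alignment columns.  The original
length filter applied to unaligned region length before alignment; column
count is the available stand-in here.

When the outgroup differs from both ingroups, the site still yields two
substitution records (one per ingroup): the increment rule is applied
literally, with no consensus requirement.  No multiple-hit correction is
applied anywhere — at ~0.066 substitutions/site between ingroups the raw
proportion is the rate estimate, and `rate_ci()` supplies the Wald interval
`p ± 1.96 sqrt(p(1-p)/n)`.

## Complement combining

Reading the opposite strand maps context (left, right) to
(revcomp(right), revcomp(left)) and each base to its complement.
`combine_complements()` pools each context with its reverse complement,
choosing the lexicographically smaller concatenated string as the canonical
representative (deterministic and input-order-free; the choice itself is a
convention).  This folds the 4096 hexanucleotide contexts into 2080
classes, 64 of which are self-complementary.  A self-complementary context
is symmetrized by adding its own complement transform — its events are
counted once per strand reading — so the canonical total equals the raw
total plus the raw total of self-complementary contexts.  After combining,
the A and G rows duplicate the T and C rows, so summaries are reported for
pyrimidines only.

## Equilibrium composition

Each count matrix row-normalizes to a transition matrix `P`
(`to_transition_matrix()`; empty rows are flagged, never NaN).  The
stationary vector solves `phi = phi P` by left eigen-decomposition with a
power-iteration fallback; entries in (-1e-12, 0) are clipped to zero and
the vector renormalized.  A result is **degenerate** when a row is empty,
the unit eigenvalue is not unique (reducible chain, typical of sparse
counts), or the fixed-point residual exceeds 1e-10; degenerate vectors are
reported as flagged rows rather than dropped, because at realistic sample
sizes many sparse contexts produce 0% entries and silently discarding them
would bias the composition ranges.  Note that a *non*-degenerate vector can
still contain structural zeros; its A-T or G-C skew is then undefined and
excluded from correlations.

Composition statistics are `A+T%`, `100 (G - C)/(G + C)` and
`100 (A - T)/(A + T)` — the standard signed-skew convention, which matches
the printed ranges of the motivating analyses.  Observed composition per
context counts the derived (ingroup) bases, two per site, folded onto
canonical contexts exactly like the matrices; counting ancestral bases
instead is available via `observed_from = "ancestral"`.  The site count
(`n_sites`), not the record count, should be used for standard errors: the
two records at a site share an ancestor and are strongly correlated, so the
site-based binomial SE is the conservative choice.

## Composition indices

For radius 3, three 0–28 indices summarize a context
(`ati()`, `ri()`, `rati()`):

* ATI: `sum W_i 2^(4-i)` with `W_i` the A/T count in the N_i pair;
* RI: the same weighting of the purine count on the analyzed strand
  (used for pyrimidine rows; the complementary strand's RI is `28 - RI`);
* RATI: `sum B_i 2^(3-i)` with per-base scores A = 2, C = 0, G = 1, T = 1.

The ATI/RI weight exponent deserves a note: the printed form of these
definitions uses `2^(3-i)`, which caps both indices at 14, while every
figure threshold that uses them (ATI = 28, RI >= 26, RI >= 24) requires a
0–28 range.  ATI and RI therefore use `2^(4-i)` here, which reconciles all
stated thresholds, and RATI keeps `2^(3-i)` (already 0–28).  The weight
base is an explicit argument for sensitivity analysis.

## CpG analysis

CpG hypermutability is quantified on strand-explicit (uncombined) counts,
because the effect is reported per strand: one 2x2 table for focal G by 5'
neighbor (CG vs DG; G→A vs G→B, conserved sites included in B), one for
focal C by 3' neighbor (CG vs CH; C→T vs C→V).  `odds_ratio()` is the raw
cross-product ratio with no continuity correction;
`chi2_heterogeneity()` is the Pearson chi-square (df = 1, uncorrected).
The package ships the published contingency counts for noncoding
chloroplast DNA as a plain-text table (`published_cpg_counts()`); they
reproduce odds ratios of 1.36 (G→A) and 1.37 (C→T).

`duplex_stability()` scores an oligomer by summing dinucleotide-step
ΔG°37 values from the unified nearest-neighbor parameter set (SantaLucia's
1998 compilation), omitting initiation/terminal terms: only relative
comparisons across equal-length oligomers are used, and correlations are
shift-invariant, so those terms cannot change any r².  The tests assert the
table's internal properties (reverse-complement symmetry, additivity), not
the constants themselves.

## The synthetic generator

`generate_triplet_dataset()` supplies ground-truth data for every
downstream stage.  Design choices:

* **Exact simulation.** Neighbor dependence makes sites non-independent, so
  per-site matrix exponentials are wrong in principle.  Evolution is
  simulated as an exact continuous-time process by thinning: candidate
  events arrive at the per-site rate bound `max(site rate)` and are
  accepted with probability (current rate)/(bound), and all neighboring
  contexts are refreshed after every accepted event.  This is equivalent to
  the event-by-event Gillespie scheme but with O(1) work per candidate.
* **Branch units.** Branch lengths are expected substitutions/site under
  the model's mean rate (contexts weighted uniformly), so presets need no
  normalization; the `uniform` preset with `mu = 1/3` has per-site total
  rate exactly 1.
* **Tree shape.** Ancestor → outgroup, and ancestor → two independent
  ingroup branches (star-like ingroup, one shared ancestral node).
  Defaults: 0.033 per ingroup branch (0.066 between ingroups), 0.066 to
  the outgroup, A+T-rich ancestor (GC = 0.35), occasional short indels
  (0.002 events/site, geometric lengths, ingroups only).
* **Ends.** Sites within `radius` of an end have undefined context and
  never mutate; they are also never counted downstream.
* **Indels and homology.** The emitted alignment is constructed from the
  known event history (deletions become gaps in that ingroup; each
  insertion gets its own columns, gapped elsewhere), so the "alignment" is
  exact by construction — there is no realignment step to confound the
  filters.
* **Determinism.** One master seed; each region's stream is derived from it
  (`seed + 7919 k`), so datasets are byte-reproducible and independent of
  evaluation order.
* **Presets.** `uniform` (all 12 changes equal), `cpg` (transitions ×k at
  focal C followed by G and focal G preceded by C), `ati_tv`
  (transversions scaled linearly in the flanking ATI), `hky`
  (context-independent, unequal base frequencies `pi` with transition bias
  `kappa`; analytic stationary distribution `pi` — the calibration case).
* An optional `burnin_branch` evolves the ancestor under the model before
  the triplet branches, bringing its composition to the model's
  context-dependent quasi-equilibrium; this is how predicted-vs-observed
  composition comparisons are calibrated, since an i.i.d. ancestor is far
  from equilibrium for any context-dependent preset.

What the generator does *not* emulate: recombination, selection, rate
variation among regions, realistic chloroplast architecture, or alignment
error (true homology is known).  Passing tests therefore validate the
estimation machinery, not the biological claims; with real alignments the
filters must additionally absorb alignment uncertainty.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle at sizes
chosen to keep a full run around half a minute: binomial/Poisson closed
forms for the generator; a brute-force per-column rescan for count
accumulation; 10,000-step power iteration for 100 random stationary
vectors (residuals ≤ 1e-10); full 4,096-context enumeration for the index
properties; and the published contingency counts for the odds ratios.

Two simulation-based calibrations deserve their rationale:

* **CpG recovery.** 100 regions × 5 kb under `cpg` (k = 1.4), ingroup
  branches 0.05, outgroup branch 0 so the inferred ancestor is exact; the
  estimated CG/non-CG C→T rate ratio must fall within 3 binomial standard
  errors of 1.4.  A subtlety: the recovered ratio sits slightly *above* k
  (~1.45–1.47 across seeds).  This is an ascertainment interaction, not a
  bug: records require the 3' neighbor G to be conserved in all three
  sequences, and that neighbor's own G→A rate is boosted only while the
  focal site is still C — so histories in which the focal C mutated early
  are slightly enriched among surviving CG-context sites.  The effect is
  below one standard error at this scale.  Conversely, when the outgroup
  branch is long (the workflow corpus uses 0.066, twice the ingroup
  branch), direction-misinferred substitutions land symmetrically in the
  CpG and non-CpG rows and strongly attenuate the ratio toward 1; the
  workflow reports both the attenuated corpus estimate and the controlled
  one.
* **Predicted vs observed equilibrium.** Under a context-*independent*
  model every context has the same stationary vector, so the cross-context
  correlation of two noisy estimates of a constant is ~0 by construction;
  a correlation criterion is only meaningful when per-context equilibria
  truly differ.  The calibration therefore has two parts: (a) an `hky`
  simulation started from its analytic stationary distribution, where the
  observed per-context composition must stay within 3 site-based standard
  errors of `pi`; and (b) a `cpg` simulation with k = 3 equilibrated by a
  burn-in branch of 5 substitutions/site (initial deviations decay like
  exp(-t), so the residual is ~1% of the starting offset), where the
  per-context predictions separate (A+T equilibria from 50% to ~67%) and
  predicted-vs-observed A+T% achieves r² > 0.9 at 50 regions × 3 kb.
* **Uniform fold envelope.** A uniform-model run (60 regions × 2 kb) has
  pooled Ts:Tv consistent with 0.5 (one transition vs two transversion
  targets), and its cross-context Ts:Tv fold is compared against the
  envelope of 20 replicate seeds — fold variation under the uniform model
  is sampling noise, and the envelope makes that statement testable
  without inventing an analytic null for an extreme-value statistic.

## Strand symmetry

`find_symmetry_genomes()` orients genomes by five reference genes (rps12
and psbA on one strand; psbK, psbD, psbC on the other), relabeling the
rps12/psbA strand "A"; `find_symmetry_genes()` then keeps genes annotated
in ≥90% of oriented genomes whose strand-A fraction is ≥80% or ≤20%, both
fractions over all oriented genomes.  Gene names are matched after case
normalization only — synonym resolution and coordinate parsing are out of
scope, and fixtures supply annotations directly.
`complementary_context_correlation()` computes, for each complementary
context pair with enough substitutions on both sides, the stationary
statistics of the two strand-explicit matrices independently
(complement-folding one side) and correlates them across pairs.
Self-complementary contexts are excluded — their two "sides" are the same
matrix and would only inflate the correlation.  The statistic is
informative only when per-context equilibria differ; with a weak context
effect it is noise-dominated and low r² does not indicate asymmetry (the
workflow demonstrates both regimes).

## Known limitations

* Rates are per average ingroup branch; no multiple-hit correction, no
  phylogenetic likelihood — by design, matching the raw-proportion method.
* Outgroup-based ancestral inference biases estimates when the outgroup
  branch is long relative to the ingroup branches (see above); the
  generator makes this visible rather than correcting it.
* Degenerate stationary vectors from sparse contexts are flagged, not
  imputed; composition ranges computed over sparse builds should be read
  with the degeneracy flags in hand.
* The simulator's per-candidate loop is plain R; it comfortably covers
  desk-scale corpora (~10^6 candidate events per minute) but is not meant
  for genome-scale simulation.
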