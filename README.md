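# ctxsub

Context-dependent nucleotide substitution analysis for noncoding DNA.

Substitution rates at putatively neutral sites depend strongly on the
flanking bases — in plant chloroplast DNA, transitions are elevated at CpG
dinucleotides, transversions rise with flanking A+T content and purine
arrangement, and sites in different contexts drift toward very different
equilibrium compositions.  `ctxsub` is for molecular-evolution analyses
that need this structure made explicit: it estimates per-context
substitution matrices from aligned sequence triplets (two close ingroups
plus an outgroup for ancestral inference) and derives the downstream
quantities those matrices support.

## The method

Every eligible aligned site is the center of a (2r+1)-mer; with the default
radius r = 3 the flanking hexanucleotide N3 N2 N1 [N0] N1 N2 N3 is the
context.  For each context, a 4x4 count matrix accumulates
ancestral-to-derived observations — `CM[a, s]` is incremented for each
ingroup base `s` under outgroup (ancestral) base `a`, conserved sites
included on the diagonal.  Site filters require ≥8 of the 10 surrounding
columns to be gap-free in both ingroups, ≥70% ingroup identity across
those columns, and the full flanking context conserved in all three
sequences.  Contexts are pooled with their reverse complements (4,096
hexanucleotide contexts → 2,080 canonical classes).  Each matrix
row-normalizes to a transition matrix Π (`Π[i, j] = CM[i, j] / Σ CM[i]`),
read as substitutions/site with Wald intervals, and its stationary vector
φ = φΠ gives the equilibrium base composition implied by that context's
dynamics.  On top of this sit transition/transversion summaries and
max/min fold tables, CpG 2x2 contingency analysis (odds ratios,
chi-square heterogeneity), flanking-composition indices (ATI/RI/RATI,
0–28), nearest-neighbor duplex stability scores, outer neighbor-pair
conditioning, and a strand-symmetry test built from gene-orientation
annotations.

A context-dependent Gillespie-type simulator (exact, neighbor-refreshing)
generates triplet datasets with known ground truth, so every stage of the
estimation is testable without any external data.

## A worked example

Simulate a corpus with a known CpG effect (transitions doubled at CpG
sites), rebuild the matrices from the alignments, and recover the effect:

```r
library(ctxsub)

model  <- builtin_model("cpg", radius = 1, k = 2)
params <- simulation_params(n_regions = 100, region_length = 2000,
                            ingroup_branch = 0.05, outgroup_branch = 0,
                            gc_content = 0.5, seed = 11)
triplets <- dataset_triplets(generate_triplet_dataset(params, model))
records  <- extract_records(triplets, radius = 1)
counts   <- accumulate_counts(records)

tabs <- cpg_tables(counts)
tabs$c_to_t
#>    C>T   C>V
#> CG 595 18939
#> CH 910 60042
rr <- cpg_rate_ratio(tabs$c_to_t)
sprintf("CG/non-CG C->T rate ratio: %.2f (se %.2f)", rr$ratio, rr$se)
#> "CG/non-CG C->T rate ratio: 2.04 (se 0.11)"
```

The C→T rate at CpG sites is twice the rate elsewhere, as simulated.  The
same counts, complement-combined, give per-context transition matrices and
equilibria — in the canonical `A[N]G` context (focal site followed by G)
the C→T probability stands out and the equilibrium drifts T-rich, C-poor:

```r
can <- combine_complements(counts)
tm  <- to_transition_matrix(count_matrix(can, "A", "G"))
round(tm$probs, 4)
#>        A      C      G      T
#> A 0.9508 0.0156 0.0165 0.0171
#> C 0.0173 0.9385 0.0146 0.0296
#> G 0.0158 0.0157 0.9528 0.0156
#> T 0.0143 0.0170 0.0150 0.9537
sv <- stationary_vector(tm)
sv
#> phi: A=0.2409 C=0.2082 G=0.2457 T=0.3053
cs <- composition_stats(sv)
sprintf("equilibrium A+T %.1f%%, G-C skew %.1f, A-T skew %.1f",
        cs$at_percent, cs$gc_skew, cs$at_skew)
#> "equilibrium A+T 54.6%, G-C skew 8.3, A-T skew -11.8"
```

`run_pipeline(run_config(input, out_dir))` chains the whole sequence —
ingest, counts, combining, rate summaries and fold tables, equilibrium
comparison, CpG and index features — and writes TSV/JSON artifacts plus a
log whose filter tallies account for every scanned alignment column.

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the package's own
study on synthetic data, writing to `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_data.R` | simulate the triplet corpus (1,000 regions, CpG k = 1.4, indels) |
| `02_build_matrices.R` | run the pipeline at radius 3 and radius 2 |
| `03_rate_variation.R` | fold-variation tables; Ts:Tv against ATI/RI/RATI; ΔG37 check |
| `04_cpg_effect.R` | published-count odds ratios; corpus and controlled CpG recovery |
| `05_equilibrium.R` | stationary vs observed composition; r² on an equilibrated corpus |
| `06_neighbor_effects.R` | outer neighbor-pair slices controlling the internal context |
| `07_strand_symmetry.R` | genome orientation, symmetry genes, complementary-context r² |

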