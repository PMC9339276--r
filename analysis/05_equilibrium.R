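#!/usr/bin/env Rscript

# Step 5: equilibrium base composition per context.
#
# Each canonical context's transition matrix is converted to its stationary
# vector (the equilibrium composition of a site evolving indefinitely under
# those dynamics) and compared with the composition observed at the sites
# in that context.  The main corpus is not at equilibrium, so a second
# simulation equilibrated by a burn-in branch provides the calibrated
# predicted-vs-observed comparison.

library(ctxsub)

## main corpus (radius 2 for per-context sample size)
counts <- read_counts_tsv("results/pipeline_radius2/counts_canonical.tsv")
tsv <- "results/pipeline_radius2/equilibrium.tsv"
if (file.exists(tsv)) {
  eq <- read.delim(tsv)
  rng <- range(eq$pred_at_percent[!eq$degenerate])
  message(sprintf("main corpus: %d contexts, predicted equilibrium A+T %.1f%% .. %.1f%%",
                  nrow(eq), rng[1], rng[2]))
}

## equilibrated corpus: burn the ancestor in under the model, then compare
model <- builtin_model("cpg", radius = 1, k = 3)
params <- simulation_params(
  n_regions = 50, region_length = 3000,
  ingroup_branch = 0.1, outgroup_branch = 0,
  gc_content = 0.5, burnin_branch = 5, seed = 20260925
)
rec <- extract_records(dataset_triplets(generate_triplet_dataset(params, model)),
                       radius = 1)
pv <- predicted_vs_observed(combine_complements(accumulate_counts(rec)),
                            rec, min_subs = 50)
write.table(pv$table, "results/equilibrium_predicted_vs_observed.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(as.list(pv$r2), "results/equilibrium_r2.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf(
  "equilibrated corpus: r^2 predicted-vs-observed A+T%% = %.3f, G-C skew = %.3f, A-T skew = %.3f (%d contexts)",
  pv$r2[["at_percent"]], pv$r2[["gc_skew"]], pv$r2[["at_skew"]],
  nrow(pv$table)))
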