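#!/usr/bin/env Rscript

# Step 1: build the synthetic triplet corpus used by the downstream steps.
#
# The generator emulates the structure of an intergenic-region alignment
# collection: many independent regions longer than 70 nt, roughly 0.066
# substitutions/site between the two ingroups (0.033 per ingroup branch), an
# A+T-rich base composition, occasional short indels, and a CpG-elevated
# transition rate as the built-in context effect.

library(ctxsub)

out_dir <- "results/simulated_alignments"
model <- builtin_model("cpg", radius = 1, k = 1.4)
params <- simulation_params(
  n_regions = 1000, region_length = 1500,
  ingroup_branch = 0.033, outgroup_branch = 0.066,
  gc_content = 0.35, indel_rate = 0.002, seed = 20260924
)

dataset <- generate_triplet_dataset(params, model)
paths <- write_triplet_dataset(dataset, out_dir)

n_events <- vapply(dataset$regions, function(r) sum(r$truth$n_events), 0)
n_indels <- vapply(dataset$regions, function(r) sum(r$truth$n_indels), 0)
message(sprintf("wrote %d regions to %s", params$n_regions, out_dir))
message(sprintf("substitution events: %d total (%.1f/region); indel events: %d",
                sum(n_events), mean(n_events), sum(n_indels)))
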