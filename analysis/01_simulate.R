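#!/usr/bin/env Rscript
# Generate the synthetic study inputs: 47 up- and 10 downregulated miRNAs,
# three interaction databases with partially overlapping support, planted
# hub mRNAs, planted excluded miRNAs and planted enriched GO terms.
# Writes the six pipeline input files plus the ground truth under
# results/sim_inputs/.

suppressPackageStartupMessages(library(mirhub))

cfg <- generator_config(seed = 20160620L)
truth <- generate_ground_truth(cfg)
manifest <- emit_files(truth, "results/sim_inputs")

cat("simulated study written to results/sim_inputs/\n")
print(manifest)
cat(sprintf(
  "planted: %d hub genes, %d up / %d down excluded miRNAs, %d enriched terms\n",
  length(truth$hub_genes), length(truth$excluded_up),
  length(truth$excluded_down), length(truth$planted_terms)
))
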