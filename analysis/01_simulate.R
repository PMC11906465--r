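#!/usr/bin/env Rscript
# Stage 1: generate the synthetic dual-genome ChIA-PET dataset with planted
# ground truth (vector blocks at 9,000 / 18,000 bp, host TADs and A/B
# compartments, heterochromatin/quiescent-biased vector-host contacts at 27
# planted associated genes, null expression with one induced p53 target).
# Everything downstream reads from results/sim/.

suppressMessages(library(adenoloop))

cfg <- sim_config(seed = 42)
sim <- simulate_dataset(cfg, "results/sim")

cat("simulated inputs written to results/sim/:\n")
for (f in list.files("results/sim")) cat(" -", f, "\n")
cat(sprintf("planted: %d associated genes, %d vector-host sites, blocks at %s bp\n",
            length(sim$truth$associated_genes), nrow(sim$vector_host$sites),
            paste(cfg$vector_block_boundaries, collapse = " / ")))
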