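#!/usr/bin/env Rscript
# Stage 2: classify PETs on the combined genome and cluster each channel
# into loops at the study thresholds: span > 8 kb / extension 500 bp for
# host and vector-host channels, span > 600 bp / extension 0 bp within the
# vector; high-confidence loops carry more than 4 PETs.

suppressMessages(library(adenoloop))

genome <- read_chrom_sizes("results/sim/chrom.sizes")
p53 <- read_pets_bedpe("results/sim/pets_p53.bedpe", genome)
pol <- read_pets_bedpe("results/sim/pets_rnapii.bedpe", genome)

cls_p53 <- classify_pets(p53, genome)
cls_pol <- classify_pets(pol, genome)
cat("p53 channel:\n"); print(table(cls_p53))
cat("RNAPII channel:\n"); print(table(cls_pol))

vec_loops <- cluster_pets(
  filter_pets_by_span(p53[cls_p53 == "intra_vector", ], 600),
  0, genome, factor = "p53")
vh_loops <- cluster_pets(p53[cls_p53 == "vector_host", ], 500, genome,
                         factor = "p53")
pol_loops <- cluster_pets(
  filter_pets_by_span(pol[cls_pol == "intra_host_cis", ], 8000),
  500, genome, factor = "RNAPII")

write_loops_bedpe(vec_loops, "results/loops_vector.bedpe")
write_loops_bedpe(vh_loops, "results/loops_vector_host.bedpe")
write_loops_bedpe(pol_loops, "results/loops_rnapii.bedpe")

vh_hc <- select_vector_host_loops(vh_loops, 4)
cat(sprintf("loops: %d intra-vector, %d vector-host (%d with >4 PETs), %d RNAPII intra-host\n",
            nrow(vec_loops), nrow(vh_loops), nrow(vh_hc), nrow(pol_loops)))
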