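#!/usr/bin/env Rscript
# Stage 3: the vector's internal 3D organization. Bin the intra-vector PETs
# at 500 bp, score insulation with a 2,500 bp sliding square, call
# significant boundaries and segment the 35,722 bp vector into blocks.

suppressMessages(library(adenoloop))

genome <- read_chrom_sizes("results/sim/chrom.sizes")
p53 <- read_pets_bedpe("results/sim/pets_p53.bedpe", genome)
vec <- p53[classify_pets(p53, genome) == "intra_vector", ]
vec <- filter_pets_by_span(vec, 600)

region <- list(seq = genome$vector_name, start = 0,
               end = seq_lengths(genome)[[genome$vector_name]])
m <- bin_contacts(vec, region, 500)
track <- insulation_score(m, 2500)
boundaries <- call_boundaries(track, delta_min = 0.1, p_threshold = 0.05)
segs <- segment_region(boundaries, region,
                       track$scores[match(boundaries, track$positions)])

write_matrix_triples(m, "results/vector_matrix.tsv")
write_bedgraph(region, 500, track$scores, "results/vector_insulation.bedgraph",
               positions = track$positions - 500)
utils::write.table(segs, "results/vector_blocks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

s <- tad_summary(segs)
cat(sprintf("vector map: %d bins, %d PETs; %d blocks\n",
            nrow(m$counts), nrow(vec), s$count))
for (i in seq_len(nrow(segs))) {
  cat(sprintf("  block %d: %s - %s bp (%s bp)\n", i,
              format(segs$start[i], big.mark = ","),
              format(segs$end[i], big.mark = ","),
              format(s$sizes[i], big.mark = ",")))
}
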