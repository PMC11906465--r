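#!/usr/bin/env Rscript
# Stage 5: from high-confidence vector-host loops to vector-associated host
# genes. Merge the host anchors of >4-PET p53-mediated vector-host loops,
# pull in count-filtered RNAPII intra-host loops anchored there, associate
# genes by promoter-extended overlap with either channel, build the gene
# network, and profile chromatin-state composition against top-1% baselines.

suppressMessages(library(adenoloop))

genome <- read_chrom_sizes("results/sim/chrom.sizes")
vh <- read_loops_bedpe("results/loops_vector_host.bedpe")
pol <- read_loops_bedpe("results/loops_rnapii.bedpe")
genes <- read_genes_bed("results/sim/genes.bed")
vgenes <- read_genes_bed("results/sim/vector_genes.bed")
states <- read_states_bed("results/sim/states.bed")
peaks <- read_peaks_bed("results/sim/peaks.bed")

vh_hc <- select_vector_host_loops(vh, 4)
p53_regions <- host_anchor_regions(vh_hc)
pol_hc <- filter_loops_by_count(pol, 4)
pol_kept <- overlap_rnapii_loops(p53_regions, pol_hc)
pol_regions <- merge_intervals(rbind(anchor_df(pol_kept, 1),
                                     anchor_df(pol_kept, 2)))

assoc <- associate_genes(p53_regions, pol_regions, genes,
                         promoter_ext = 2000, genome = genome)
network <- build_network(rbind(vh_hc, pol_kept), genes, vgenes,
                         promoter_ext = 2000, genome = genome)
vec_gene_hits <- vgenes$gene_id[overlaps_any(vgenes, anchor_df(vh_hc, 2))]

utils::write.table(assoc, "results/associated_genes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(network, "results/gene_network.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

comp_sets <- list(
  vh_anchors = p53_regions,
  top1pct_peaks = top_percent_features(peaks, 1)[, c("seq", "start", "end")],
  top1pct_loop_anchors = merge_intervals(rbind(
    anchor_df(top_percent_features(
      transform(pol, score = pol$pet_count), 1), 1),
    anchor_df(top_percent_features(
      transform(pol, score = pol$pet_count), 1), 2))))
comp <- do.call(rbind, lapply(names(comp_sets), function(k) {
  f <- state_composition(comp_sets[[k]], states)
  data.frame(set = k, state = names(f), fraction = round(as.numeric(f), 4))
}))
utils::write.table(comp, "results/state_composition.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("%d vector-associated host genes (evidence: %s)\n", nrow(assoc),
            paste(sprintf("%s=%d", names(table(assoc$evidence)),
                          table(assoc$evidence)), collapse = ", ")))
cat(sprintf("%d vector-derived genes inside vector-side anchors: %s\n",
            length(vec_gene_hits), paste(vec_gene_hits, collapse = ", ")))
hq <- sum(comp$fraction[comp$set == "vh_anchors" &
                          comp$state %in% c("Heterochromatin", "Quiescent")])
tss <- sum(comp$fraction[comp$set == "top1pct_peaks" & comp$state == "TSS"])
cat(sprintf("vector-host anchors: %.1f%% heterochromatin+quiescent; top-1%% peaks: %.1f%% TSS\n",
            100 * hq, 100 * tss))
cat(sprintf("gene network: %d edges\n", nrow(network)))
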