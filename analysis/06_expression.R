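#!/usr/bin/env Rscript
# Stage 6: does vector-host contact change associated-gene expression? One
# paired t-test across the associated gene set per condition contrast
# (treated vs untreated, infected vs wild-type), plus the per-gene
# replicate-level contrast for the induced p53-target control.

suppressMessages(library(adenoloop))

fpkm <- read_fpkm_table("results/sim/fpkm.tsv")
assoc <- utils::read.table("results/associated_genes.tsv", header = TRUE,
                           stringsAsFactors = FALSE)

contrasts <- list(c("KOAd_T0", "KOAd_T9"),  # 5-FU effect in infected KO
                  c("KOAd_T9", "WT_T9"),    # infected KO vs WT, treated
                  c("KOAd_T0", "KO_T0"))    # infection effect, untreated
rows <- lapply(contrasts, function(cc) {
  r <- compare_gene_set(fpkm, assoc$gene_id, cc[1], cc[2])
  data.frame(cond_a = cc[1], cond_b = cc[2], n_genes = r$n,
             t = round(r$t, 4), p = signif(r$p, 4))
})
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/expression_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("associated-gene set expression (paired t-test across genes):\n")
print(tab, row.names = FALSE)
cat("\n")
for (g in c("CDKN1A_like", "SRSF3_like")) {
  r <- per_gene_contrast(fpkm, g, "KOAd_T0", "KOAd_T9")
  cat(sprintf("%s: FPKM %.1f -> %.1f, p = %.3g (%s)\n", g, r$mean_a,
              r$mean_b, r$p,
              if (r$p < 0.05) "induced" else "ns"))
}
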