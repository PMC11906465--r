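mk_loop <- function(seq1, s1, e1, seq2, s2, e2, count, factor = "p53",
                    class = "vector_host") {
  df <- data.frame(seq1 = seq1, start1 = s1, end1 = e1, seq2 = seq2,
                   start2 = s2, end2 = e2, pet_count = as.integer(count),
                   factor = factor, class = class,
                   stringsAsFactors = FALSE)
  class(df) <- c("loop_df", "data.frame")
  df
}

test_that("high-confidence selection keeps only loops with more than 4 PETs", {
  loops <- mk_loop("chr1", c(0, 100), c(50, 150), "AdP53", c(0, 0),
                   c(50, 50), c(5, 9))
  expect_equal(nrow(select_vector_host_loops(loops)), 2)
  low <- mk_loop("chr1", 1:4 * 100, 1:4 * 100 + 50, "AdP53", rep(0, 4),
                 rep(50, 4), 1:4)
  expect_equal(nrow(select_vector_host_loops(low)), 0)
  expect_equal(nrow(select_vector_host_loops(low[0, ])), 0)
  bad <- mk_loop("chr1", 0, 50, "chr1", 500, 550, 9,
                 class = "intra_host_cis")
  expect_error(select_vector_host_loops(bad), "non-vector_host")
})

test_that("host anchor regions merge only strictly overlapping intervals", {
  loops <- mk_loop("chr1", c(100, 150, 400), c(200, 300, 500), "AdP53",
                   rep(0, 3), rep(50, 3), rep(5, 3))
  r <- host_anchor_regions(loops)
  expect_equal(r$start, c(100, 400))
  expect_equal(r$end, c(300, 500))
  touching <- mk_loop("chr1", c(100, 200), c(200, 300), "AdP53", rep(0, 2),
                      rep(50, 2), rep(5, 2))
  expect_equal(nrow(host_anchor_regions(touching)), 2)
  # idempotent and order-invariant
  r2 <- host_anchor_regions(loops[c(3, 1, 2), ])
  expect_equal(r2, r)
})

test_that("RNAPII loop overlap filter matches the all-pairs oracle", {
  anchors <- interval_df("chr1", c(1000, 5000, 9000),
                         c(2000, 6000, 10000))
  loops <- mk_loop("chr1",
                   c(1500, 2500, 5900, 8000, 9990, 3000),
                   c(1600, 2600, 6100, 8100, 10100, 3100),
                   "chr1",
                   c(50000, 60000, 70000, 9500, 80000, 90000),
                   c(50100, 60100, 70100, 9600, 80100, 90100),
                   rep(5, 6), factor = "RNAPII", class = "intra_host_cis")
  kept <- overlap_rnapii_loops(anchors, loops)
  oracle_hit <- vapply(seq_len(nrow(loops)), function(i) {
    any(vapply(seq_len(nrow(anchors)), function(j) {
      (loops$start1[i] < anchors$end[j] &&
         anchors$start[j] < loops$end1[i]) ||
        (loops$start2[i] < anchors$end[j] &&
           anchors$start[j] < loops$end2[i])
    }, logical(1)))
  }, logical(1))
  expect_equal(kept, loops[oracle_hit, , drop = FALSE])
  expect_true(1 %in% which(oracle_hit))   # left anchor inside a region
  expect_false(2 %in% which(oracle_hit))  # neither anchor overlaps
  expect_true(4 %in% which(oracle_hit))   # right anchor overlaps
})

test_that("gene association is promoter-aware and strand-aware", {
  genes <- interval_df("chr1", 10000, 20000, gene_id = "G1", strand = "+")
  near <- interval_df("chr1", 8500, 9000)
  far <- interval_df("chr1", 30000, 31000)
  hit <- associate_genes(near, interval_df(), genes, promoter_ext = 2000)
  expect_equal(hit$gene_id, "G1")
  expect_equal(hit$evidence, "p53")
  expect_equal(nrow(associate_genes(far, interval_df(), genes, 2000)), 0)
  # upstream of a minus-strand gene is past its end
  gm <- interval_df("chr1", 10000, 20000, gene_id = "G2", strand = "-")
  up_minus <- interval_df("chr1", 21000, 21500)
  expect_equal(associate_genes(up_minus, interval_df(), gm, 2000)$gene_id,
               "G2")
  expect_equal(nrow(associate_genes(near, interval_df(), gm, 2000)), 0)
  # both channels -> evidence "both"
  both <- associate_genes(near, near, genes, 2000)
  expect_equal(both$evidence, "both")
})

test_that("network edges expand anchors to all overlapped genes", {
  genes <- interval_df("chr1", c(1000, 1500, 50000),
                       c(1400, 2000, 51000),
                       gene_id = c("GA", "GB", "GC"),
                       strand = c("+", "+", "+"))
  vg <- interval_df("AdP53", c(100, 5000), c(2000, 9000),
                    gene_id = c("V1", "V2"), strand = c("+", "+"))
  # one loop, each anchor over one distinct gene
  l1 <- mk_loop("chr1", 50100, 50200, "AdP53", 200, 300, 5)
  n1 <- build_network(l1, genes, vg, promoter_ext = 0)
  expect_equal(nrow(n1), 1)
  expect_equal(n1$weight, 1L)
  expect_equal(sort(c(n1$gene_a, n1$gene_b)), c("GC", "V1"))
  # two loops supporting the same pair -> weight 2
  n2 <- build_network(rbind(l1, l1), genes, vg, promoter_ext = 0)
  expect_equal(n2$weight, 2L)
  # anchor spanning two genes -> star expansion, checked by oracle
  l3 <- mk_loop("chr1", 1200, 1700, "AdP53", 200, 300, 5)
  n3 <- build_network(l3, genes, vg, promoter_ext = 0)
  expect_equal(nrow(n3), 2)
  expect_setequal(paste(n3$gene_a, n3$gene_b), c("GA V1", "GB V1"))
  # no self-edges, symmetric dedup on a loop over the same gene twice
  l4 <- mk_loop("chr1", 1000, 1400, "chr1", 1000, 1400, 5,
                class = "intra_host_cis")
  expect_equal(nrow(build_network(l4, genes, vg, promoter_ext = 0)), 0)
})

test_that("state composition matches per-bp counting and reports remainder", {
  states <- interval_df("chr1", c(0, 1000), c(1000, 2000),
                        state = c("Quiescent", "TSS"))
  inside <- interval_df("chr1", 100, 600)
  expect_equal(state_composition(inside, states),
               c(Quiescent = 1.0))
  half <- interval_df("chr1", 500, 1500)
  comp <- state_composition(half, states)
  expect_equal(comp[["Quiescent"]], 0.5)
  expect_equal(comp[["TSS"]], 0.5)
  # region extending past the annotated span -> unannotated remainder
  over <- interval_df("chr1", 1500, 2500)
  co <- state_composition(over, states)
  expect_equal(co[["TSS"]], 0.5)
  expect_equal(co[["unannotated"]], 0.5)
  # 10 random regions vs the bp-enumeration oracle
  set.seed(12)
  track <- interval_df("chr1", seq(0, 5400, by = 600),
                       seq(600, 6000, by = 600),
                       state = rep(c("TSS", "Enhancer", "Transcription",
                                     "Repressed", "Heterochromatin",
                                     "Quiescent"), length.out = 10))
  starts <- sort(sample(0:5800, 10))
  regions <- interval_df("chr1", starts, starts + sample(20:150, 10))
  got <- state_composition(regions, track)
  oracle <- oracle_state_composition(regions, track)
  expect_equal(got[sort(names(got))], oracle[sort(names(oracle))],
               tolerance = 1e-12)
  expect_true(all(got >= 0))
  expect_lte(sum(got), 1 + 1e-9)
})

test_that("top-percent selection uses the ceiling rule and keeps ties", {
  set.seed(5)
  peaks <- interval_df("chr1", 1:200 * 1000, 1:200 * 1000 + 100,
                       score = sample(200))
  top <- top_percent_features(peaks, 1)
  expect_equal(nrow(top), 2)
  expect_equal(sort(top$score), c(199, 200))
  tied <- interval_df("chr1", 1:50 * 1000, 1:50 * 1000 + 100,
                      score = rep(7, 50))
  expect_equal(nrow(top_percent_features(tied, 1)), 50)
  one <- top_percent_features(peaks[1:50, ], 1)  # k = ceil(0.5) = 1
  expect_equal(nrow(one), 1)
  expect_equal(nrow(top_percent_features(peaks[0, ], 1)), 0)
})
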