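test_that("generators are deterministic under the seed and leave the RNG alone", {
  cfg <- sim_config(seed = 5, n_pets = list(vector = 2000, host = 5000,
                                            vector_host = 500))
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  a <- generate_vector_pets(cfg)
  after <- stats::runif(1)
  expect_equal(before, after)  # stream isolation
  b <- generate_vector_pets(cfg)
  expect_equal(a, b)
  expect_equal(generate_host_pets(cfg), generate_host_pets(cfg))
  st <- generate_states(cfg)
  expect_equal(st, generate_states(cfg))
  vh1 <- generate_vector_host_pets(cfg, st)
  vh2 <- generate_vector_host_pets(cfg, st)
  expect_equal(vh1, vh2)
  # different seeds give different draws
  cfg2 <- sim_config(seed = 6, n_pets = cfg$n_pets)
  expect_false(identical(generate_vector_pets(cfg2), a))
})

test_that("vector PETs follow the planted block structure", {
  # contrast 1:1 -> no planted structure: within-block fraction matches the
  # analytic expectation from the block lengths
  cfg <- sim_config(seed = 2, block_contrast = 1,
                    n_pets = list(vector = 10000, host = 0,
                                  vector_host = 0))
  pets <- generate_vector_pets(cfg)
  edges <- c(0, 9000, 18000, 35722)
  mid <- function(s, e) floor((s + e) / 2)
  b1 <- findInterval(mid(pets$start1, pets$end1), edges,
                     rightmost.closed = TRUE)
  b2 <- findInterval(mid(pets$start2, pets$end2), edges,
                     rightmost.closed = TRUE)
  p_within <- sum((diff(edges) / 35722)^2)
  sd2 <- 2 * sqrt(p_within * (1 - p_within) / nrow(pets))
  expect_lt(abs(mean(b1 == b2) - p_within), sd2)
  # all anchors inside the vector
  expect_true(all(pets$start1 >= 0 & pets$end2 <= 35722))
})

test_that("host PET span distribution follows the configured power law", {
  cfg <- sim_config(seed = 8, tad_contrast = 1, compartment_mixing = 1,
                    n_pets = list(vector = 0, host = 50000,
                                  vector_host = 0))
  pets <- generate_host_pets(cfg)
  spans <- pet_span(pets)
  spans <- spans[spans > cfg$span_min & spans < 5e6]
  # log-binned counts regress to the density exponent (-1.5)
  br <- exp(seq(log(cfg$span_min), log(5e6), length.out = 15))
  h <- hist(spans, breaks = br, plot = FALSE)
  ok <- h$counts > 0
  fit <- stats::lm(log(h$density[ok]) ~ log(h$mids[ok]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + cfg$span_exponent), 0.2)
})

test_that("state track tiles every chromosome without gaps", {
  cfg <- sim_config(seed = 4)
  st <- generate_states(cfg)
  for (ch in names(cfg$host_chroms)) {
    s <- st[st$seq == ch, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], unname(cfg$host_chroms[[ch]]))
    expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  expect_true(all(st$state %in% c("TSS", "Enhancer", "Transcription",
                                  "Repressed", "Heterochromatin",
                                  "Quiescent")))
})

test_that("vector-host anchors follow the planted chromatin-state bias", {
  cfg <- sim_config(seed = 6)
  st <- generate_states(cfg)
  vh <- generate_vector_host_pets(cfg, st)
  comp <- state_composition(anchor_df(vh$pets, 1), st)
  hq <- sum(comp[c("Heterochromatin", "Quiescent")], na.rm = TRUE)
  n <- nrow(vh$pets)
  expect_lt(abs(hq - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  # degenerate bias 1.0: every host anchor in het/quies chromatin
  cfg1 <- sim_config(seed = 6, vector_host_state_bias = 1,
                     n_pets = list(vector = 0, host = 0,
                                   vector_host = 500))
  vh1 <- generate_vector_host_pets(cfg1, st)
  comp1 <- state_composition(anchor_df(vh1$pets, 1), st)
  expect_equal(sum(comp1[c("Heterochromatin", "Quiescent")], na.rm = TRUE),
               1)
  # planted high-count loops survive clustering + count filter exactly
  loops <- cluster_pets(vh$pets, 500, cfg$genome, factor = "p53")
  hc <- select_vector_host_loops(loops, 4)
  expect_equal(nrow(hc), nrow(vh$sites))
  expect_setequal(hc$pet_count, vh$sites$pet_count)
})

test_that("annotations plant exactly the configured associated genes", {
  cfg <- sim_config(seed = 9)
  st <- generate_states(cfg)
  vh <- generate_vector_host_pets(cfg, st)
  ann <- generate_annotations(cfg, vh$sites, st)
  expect_equal(sum(ann$genes$associated), 27)
  expect_equal(nrow(ann$genes), 27 + cfg$n_decoy_genes + 2)
  expect_equal(nrow(ann$vector_genes), 6)
  expect_false(anyDuplicated(ann$genes$gene_id) > 0)
  # decoy-free config: every gene is associated
  cfg0 <- sim_config(seed = 9, n_decoy_genes = 0)
  ann0 <- generate_annotations(cfg0, vh$sites, st)
  host_only <- ann0$genes[!ann0$genes$gene_id %in%
                            c(cfg0$induced_gene, cfg0$null_neighbor_gene), ]
  expect_true(all(host_only$associated))
})

test_that("expression generator is null except for the induced gene", {
  cfg <- sim_config(seed = 10)
  st <- generate_states(cfg)
  vh <- generate_vector_host_pets(cfg, st)
  ann <- generate_annotations(cfg, vh$sites, st)
  ex <- generate_expression(cfg, ann$genes)
  expect_equal(ex$fold_changes[[cfg$induced_gene]], 5)
  expect_true(all(ex$fold_changes[names(ex$fold_changes) !=
                                    cfg$induced_gene] == 1))
  ind <- per_gene_contrast(ex$table, cfg$induced_gene, "KOAd_T0",
                           "KOAd_T9")
  expect_lt(ind$p, 0.05)
  expect_gt(ind$mean_b / ind$mean_a, 2)
  expect_equal(generate_expression(cfg, ann$genes)$table$values,
               ex$table$values)
})

test_that("a written dataset round-trips through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 12, n_pets = list(vector = 3000, host = 20000,
                                             vector_host = 1000))
  sim <- simulate_dataset(cfg, dir)
  gm <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(seq_lengths(gm), seq_lengths(cfg$genome))
  p53 <- read_pets_bedpe(file.path(dir, "pets_p53.bedpe"), gm)
  expect_equal(nrow(p53), nrow(sim$vector_pets) + nrow(sim$vector_host$pets))
  pol <- read_pets_bedpe(file.path(dir, "pets_rnapii.bedpe"), gm)
  expect_equal(nrow(pol),
               nrow(sim$host_pets) + nrow(sim$vector_host$rnapii_pets))
  genes <- read_genes_bed(file.path(dir, "genes.bed"))
  expect_setequal(genes$gene_id, sim$annotations$genes$gene_id)
  expect_equal(genes[order(genes$gene_id), c("start", "end")],
               sim$annotations$genes[order(sim$annotations$genes$gene_id),
                                     c("start", "end")],
               ignore_attr = TRUE)
  st <- read_states_bed(file.path(dir, "states.bed"))
  expect_equal(sum(st$end - st$start), sum(cfg$host_chroms))
  pk <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_equal(nrow(pk), cfg$n_peaks)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$associated_genes), 27)
  expect_equal(truth$vector_block_boundaries, c(9000, 18000))
  # byte-identical on regeneration
  dir2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
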