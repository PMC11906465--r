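small_sim <- function(seed) {
  sim_config(seed = seed, n_pets = list(vector = 8000, host = 40000,
                                        vector_host = 2000))
}

test_that("run_all produces a complete, truth-consistent report", {
  dir <- withr::local_tempdir()
  rc <- run_config(input_dir = file.path(dir, "sim"),
                   output_dir = file.path(dir, "out"),
                   seed = 21, simulate = TRUE, sim_config = small_sim(21))
  rep <- run_all(rc)
  for (f in c("summary.json", "loops_vector_host.bedpe", "loops_rnapii.bedpe",
              "associated_genes.tsv", "network.tsv", "state_composition.tsv",
              "vector_matrix.tsv", "vector_insulation.bedgraph")) {
    expect_true(file.exists(file.path(dir, "out", f)), label = f)
  }
  summary <- jsonlite::read_json(file.path(dir, "out", "summary.json"))
  expect_equal(summary$n_associated_genes, 27L)
  expect_equal(unlist(summary$vector_segment_ends), c(9000, 18000, 35722))
  truth <- jsonlite::read_json(file.path(dir, "sim", "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(rep$associated_genes$gene_id, truth$associated_genes)
  # evidence classes match the planted split
  got <- rep$associated_genes$evidence[
    order(rep$associated_genes$gene_id)]
  want <- truth$associated_evidence[
    sort(names(truth$associated_evidence))]
  expect_equal(got, unname(unlist(want)))
})

test_that("two identically configured runs are byte-identical", {
  dir <- withr::local_tempdir()
  for (run in c("a", "b")) {
    rc <- run_config(input_dir = file.path(dir, run, "sim"),
                     output_dir = file.path(dir, run, "out"),
                     seed = 33, simulate = TRUE, sim_config = small_sim(33))
    run_all(rc)
  }
  expect_identical(
    readLines(file.path(dir, "a", "out", "summary.json")),
    readLines(file.path(dir, "b", "out", "summary.json")))
})

test_that("an unreachable PET-count threshold empties the association cleanly", {
  dir <- withr::local_tempdir()
  rc <- run_config(input_dir = file.path(dir, "sim"),
                   output_dir = file.path(dir, "out"),
                   seed = 44, simulate = TRUE, sim_config = small_sim(44),
                   min_pet_count = 10)  # planted counts top out at 9
  rep <- run_all(rc)
  expect_equal(nrow(rep$associated_genes), 0)
  expect_true(file.exists(file.path(dir, "out", "summary.json")))
})

test_that("resume reuses existing simulated inputs", {
  dir <- withr::local_tempdir()
  rc <- run_config(input_dir = file.path(dir, "sim"),
                   output_dir = file.path(dir, "out"),
                   seed = 55, simulate = TRUE, sim_config = small_sim(55))
  run_all(rc)
  stamp <- file.mtime(file.path(dir, "sim", "pets_p53.bedpe"))
  rc2 <- run_config(input_dir = file.path(dir, "sim"),
                    output_dir = file.path(dir, "out2"),
                    seed = 55, simulate = TRUE, sim_config = small_sim(55),
                    resume = TRUE)
  run_all(rc2)
  expect_equal(file.mtime(file.path(dir, "sim", "pets_p53.bedpe")), stamp)
  expect_identical(readLines(file.path(dir, "out", "summary.json")),
                   readLines(file.path(dir, "out2", "summary.json")))
})

test_that("run configurations load from YAML with threshold overrides", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("input_dir: in", "output_dir: out", "seed: 9",
               "min_pet_count: 7", "vector_resolution: 250"), f)
  rc <- read_run_config(f)
  expect_equal(rc$min_pet_count, 7)
  expect_equal(rc$vector_resolution, 250)
  expect_equal(rc$min_span_host, 8000)  # untouched default
  expect_equal(rc$seed, 9)
  writeLines(c("input_dir: in", "output_dir: out", "nonsense: 1"), f)
  expect_error(read_run_config(f), "unknown run_config field")
})

test_that("condition comparison reports perfect stability for identical runs", {
  dir <- withr::local_tempdir()
  rc <- run_config(input_dir = file.path(dir, "sim"),
                   output_dir = file.path(dir, "out"),
                   seed = 66, simulate = TRUE, sim_config = small_sim(66))
  rep <- run_all(rc)
  cmp <- compare_conditions(list(T0 = rep, T9 = rep))
  expect_equal(cmp$boundary_jaccard, 1)
  expect_equal(cmp$compartment_r, 1)
  expect_equal(cmp$tad_count_p, 1)
  expect_equal(cmp$tad_size_p, 1)
})
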