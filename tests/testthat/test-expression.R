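test_that("paired t-test follows the closed form and its zero-variance conventions", {
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- paired_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r2$p, 0)
  expect_error(paired_t_test(1, 2), "insufficient")
  # seeded normal pairs vs stats::t.test as the independent cross-check
  set.seed(77)
  for (i in 1:10) {
    x <- stats::rnorm(10)
    y <- x - 0.5 + stats::rnorm(10, sd = 0.3)
    r3 <- paired_t_test(x, y)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(r3$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r3$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired t statistic is antisymmetric and shift-invariant", {
  set.seed(13)
  for (i in 1:20) {
    x <- stats::rlnorm(8)
    y <- stats::rlnorm(8)
    a <- paired_t_test(x, y)
    b <- paired_t_test(y, x)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
    expect_gte(a$p, 0)
    expect_lte(a$p, 1)
    shifted <- paired_t_test(x + 5, y + 5)
    expect_equal(shifted$t, a$t, tolerance = 1e-9)
  }
})

mk_table <- function(genes, ...) {
  cols <- list(...)
  expression_table(genes, do.call(cbind, cols))
}

test_that("gene-set comparison pairs genes across conditions", {
  set.seed(9)
  ids <- sprintf("G%02d", 1:27)
  v <- stats::rlnorm(27, 3, 0.5)
  tab <- mk_table(ids, A = v, B = v * 2)
  same <- compare_gene_set(tab, ids, "A", "A")
  expect_equal(same$p, 1)
  # planted 2x shift with tiny noise is overwhelmingly significant
  tab2 <- mk_table(ids, A = v, B = v * 2 * exp(stats::rnorm(27, 0, 0.01)))
  shift <- compare_gene_set(tab2, ids, "B", "A")
  expect_lt(shift$p, 0.001)
  expect_gt(shift$t, 0)
  expect_equal(length(shift$deltas), 27)
  expect_error(compare_gene_set(tab, c(ids, "NOPE"), "A", "B"), "NOPE")
  expect_error(compare_gene_set(tab, ids, "A", "C"), "condition")
})

test_that("per-gene contrast uses replicate-level equal-variance t-tests", {
  ids <- c("CDKN1A_like", "SRSF3_like")
  set.seed(3)
  base <- c(50, 20)
  cv <- 0.1
  sdlog <- sqrt(log(1 + cv^2))
  mk_cond <- function(mult) {
    sapply(1:2, function(g) base[g] * mult[g] *
             stats::rlnorm(3, -sdlog^2 / 2, sdlog))
  }
  v0 <- t(mk_cond(c(1, 1)))
  v9 <- t(mk_cond(c(5, 1)))
  vals <- cbind(v0, v9)
  colnames(vals) <- c(paste0("T0.rep", 1:3), paste0("T9.rep", 1:3))
  tab <- expression_table(ids, vals)
  induced <- per_gene_contrast(tab, "CDKN1A_like", "T0", "T9")
  expect_lt(induced$p, 0.05)
  expect_gt(induced$mean_b / induced$mean_a, 2)
  # identical replicate sets -> p = 1 by convention
  same <- expression_table("G", matrix(c(5, 5, 5, 5),
                                       1, dimnames = list("G",
                                         c("A.rep1", "A.rep2", "B.rep1",
                                           "B.rep2"))))
  expect_equal(per_gene_contrast(same, "G", "A", "B")$p, 1)
  expect_error(per_gene_contrast(tab, "missing", "T0", "T9"), "missing")
})

test_that("null neighbor gene stays non-significant in most seeded replicates", {
  sdlog <- sqrt(log(1 + 0.1^2))
  hits <- 0
  n_rep <- 50
  set.seed(42)
  for (i in seq_len(n_rep)) {
    vals <- matrix(20 * stats::rlnorm(6, -sdlog^2 / 2, sdlog), 1,
                   dimnames = list("SRSF3_like",
                                   c(paste0("A.rep", 1:3),
                                     paste0("B.rep", 1:3))))
    p <- per_gene_contrast(expression_table("SRSF3_like", vals),
                           "SRSF3_like", "A", "B")$p
    if (p <= 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.1)
})

test_that("FPKM tables round-trip with replicate-aware columns", {
  ids <- c("G1", "G2")
  vals <- matrix(c(1.5, 2.5, 3.5, 4.5), 2,
                 dimnames = list(ids, c("KO_T0.rep1", "KO_T0.rep2")))
  tab <- expression_table(ids, vals)
  expect_equal(tab$conditions, "KO_T0")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fpkm_table(tab, f)
  back <- read_fpkm_table(f)
  expect_equal(back$values, tab$values)
  expect_equal(back$column_condition, tab$column_condition)
  expect_error(expression_table(ids, -vals), "non-negative")
})
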