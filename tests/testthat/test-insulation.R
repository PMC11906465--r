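two_block_matrix <- function(n = 20, junction = 10, high = 10, low = 1) {
  counts <- matrix(low, n, n)
  counts[1:junction, 1:junction] <- high
  counts[(junction + 1):n, (junction + 1):n] <- high
  contact_matrix(list(seq = "chr1", start = 0, end = n * 1000), 1000,
                 counts)
}

test_that("insulation of a constant matrix is identically zero where defined", {
  m <- contact_matrix(list(seq = "chr1", start = 0, end = 20000), 1000,
                      matrix(3, 20, 20))
  tr <- insulation_score(m, 5000)
  def <- !is.na(tr$scores)
  expect_true(any(def))
  expect_equal(unname(tr$scores[def]), rep(0, sum(def)))
  # mean-zero by construction on any matrix
  set.seed(8)
  R <- matrix(stats::runif(400, 1, 5), 20)
  R <- R + t(R)
  tr2 <- insulation_score(contact_matrix(m$region, 1000, R), 5000)
  expect_equal(mean(tr2$scores, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("a two-block matrix has its unique insulation minimum at the junction", {
  m <- two_block_matrix()
  tr <- insulation_score(m, 5000)
  expect_equal(tr$positions[which.min(tr$scores)], 10000)
  # oracle: exhaustive evaluation of the defining formula
  w <- 5
  raw <- sapply(1:19, function(i) {
    if (i < w || i > 20 - w) return(NA_real_)
    mean(m$counts[(i - w + 1):i, (i + 1):(i + w)])
  })
  expected <- log2(raw) - mean(log2(raw), na.rm = TRUE)
  expect_equal(tr$scores, expected)
  b <- call_boundaries(tr, delta_min = 0.1, p_threshold = 0.05)
  expect_equal(b, 10000)
})

test_that("flat or empty matrices yield no boundaries and no crash", {
  m <- contact_matrix(list(seq = "chr1", start = 0, end = 20000), 1000,
                      matrix(2, 20, 20))
  tr <- insulation_score(m, 5000)
  expect_equal(call_boundaries(tr), numeric(0))
  z <- contact_matrix(list(seq = "chr1", start = 0, end = 20000), 1000)
  trz <- insulation_score(z, 5000)
  expect_true(all(is.na(trz$scores)))
  expect_equal(call_boundaries(trz), numeric(0))
})

test_that("window validation rejects bad sizes", {
  m <- contact_matrix(list(seq = "chr1", start = 0, end = 10000), 1000,
                      matrix(1, 10, 10))
  expect_error(insulation_score(m, 1500), "multiple")
  expect_error(insulation_score(m, 6000), "too small")
})

test_that("segmentation tiles the region and collapses duplicates", {
  region <- list(seq = "AdP53", start = 0, end = 35722)
  segs <- segment_region(c(9000, 18000), region)
  expect_equal(segs$start, c(0, 9000, 18000))
  expect_equal(segs$end, c(9000, 18000, 35722))
  expect_equal(sum(segs$end - segs$start), 35722)
  expect_equal(nrow(segment_region(numeric(0), region)), 1)
  expect_equal(nrow(segment_region(c(9000, 9000, 18000), region)), 3)
  expect_error(segment_region(c(0), region), "outside")
  expect_error(segment_region(c(35722), region), "outside")
  s <- tad_summary(segs)
  expect_equal(s$count, 3)
  expect_equal(s$sizes, c(9000, 9000, 17722))
})

test_that("boundary Jaccard scores matching under slack", {
  region <- list(seq = "AdP53", start = 0, end = 35722)
  a <- segment_region(c(9000, 18000), region)
  b <- segment_region(c(9000), region)
  expect_equal(boundary_jaccard(a, a, slack = 0, resolution = 500), 1)
  expect_equal(boundary_jaccard(a, b, slack = 0, resolution = 500), 0.5)
  far <- segment_region(c(5000, 25000), region)
  expect_equal(boundary_jaccard(a, far, slack = 1, resolution = 500), 0)
  near <- segment_region(c(9500, 18000), region)
  expect_equal(boundary_jaccard(a, near, slack = 1, resolution = 500), 1)
})

test_that("planted block boundaries are recovered exactly, no spurious calls", {
  region <- list(seq = "AdP53", start = 0, end = 35722)
  # contrast 5:1 (the hardest condition the recovery property covers)
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s, block_contrast = 5,
                      n_pets = list(vector = 30000, host = 0,
                                    vector_host = 0))
    pets <- filter_pets_by_span(generate_vector_pets(cfg), 600)
    m <- bin_contacts(pets, region, 500)
    b <- call_boundaries(insulation_score(m, 2500), 0.1, 0.05)
    expect_equal(length(b), 2)
    expect_true(all(abs(b - c(9000, 18000)) <= 500))
  }
})
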