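# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (quadratic enumeration, plain fixed-point iteration)
# and share no code with the package implementations they check.

toy_genome <- function() {
  genome_model(c("chr1", "chr2", "AdP53"), c(1e6, 1e6, 35722))
}

# Brute-force single-linkage clustering: O(n^2) pairwise both-anchor
# overlap, then transitive closure by label propagation.
oracle_cluster_partition <- function(pets, ext, genome) {
  n <- nrow(pets)
  if (n == 0) return(integer(0))
  lens <- seq_lengths(genome)
  s1 <- pmax(0, pets$start1 - ext); e1 <- pmin(lens[pets$seq1], pets$end1 + ext)
  s2 <- pmax(0, pets$start2 - ext); e2 <- pmin(lens[pets$seq2], pets$end2 + ext)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      linked[i, j] <- pets$seq1[i] == pets$seq1[j] &&
        pets$seq2[i] == pets$seq2[j] &&
        s1[i] < e1[j] && s1[j] < e1[i] &&
        s2[i] < e2[j] && s2[j] < e2[i]
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (linked[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Canonical form of a partition: sorted list of sorted member index sets.
partition_sets <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort))
}

# Plain symmetric Sinkhorn iteration for matrix balancing (row sums 1).
oracle_sinkhorn <- function(A, tol = 1e-10, max_iter = 1e5) {
  x <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    r <- as.vector(A %*% x) * x
    if (max(abs(r - 1)) < tol) return(x)
    x <- x * sqrt(1 / r)
  }
  stop("sinkhorn oracle did not converge")
}

# Spreadsheet-style O/E: explicit per-diagonal means.
oracle_oe <- function(mat) {
  n <- nrow(mat)
  out <- matrix(0, n, n)
  for (k in 0:(n - 1)) {
    vals <- c()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) if (abs(i - j) == k) vals <- c(vals, mat[i, j])
    }
    mu <- mean(vals)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) == k) out[i, j] <- if (mu > 0) mat[i, j] / mu else 0
      }
    }
  }
  out
}

# Per-bp state counting for composition checks.
oracle_state_composition <- function(regions, states) {
  counts <- numeric(0)
  total <- 0
  for (i in seq_len(nrow(regions))) {
    for (bp in seq(regions$start[i], regions$end[i] - 1)) {
      total <- total + 1
      hit <- which(states$seq == regions$seq[i] & states$start <= bp &
                     states$end > bp)
      if (length(hit) == 1) {
        st <- states$state[hit]
        if (!st %in% names(counts)) counts[st] <- 0
        counts[st] <- counts[st] + 1
      }
    }
  }
  frac <- counts / total
  if (sum(frac) < 1 - 1e-9) frac <- c(frac, unannotated = 1 - sum(frac))
  frac
}

random_cis_pets <- function(n, seq = "chr1", L = 1e5, width = 50) {
  s1 <- floor(runif(n, 0, L - width))
  s2 <- floor(runif(n, 0, L - width))
  lo <- pmin(s1, s2)
  hi <- pmax(s1, s2)
  pet_df(seq, lo, lo + width, seq, hi, hi + width)
}
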