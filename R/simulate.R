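# Seeded synthetic-data generator. Every input the pipeline consumes is
# emitted with planted ground truth: the three vector blocks, host TADs and
# A/B compartments, heterochromatin/quiescent-biased vector-host contacts
# anchored at planted associated genes, and null/induced expression tables.
# Each output draws from its own RNG stream split off the master seed, so
# adding one generator never perturbs the others.

CHROMATIN_STATES <- c("TSS", "Enhancer", "Transcription", "Repressed",
                      "Heterochromatin", "Quiescent")
STATE_PROBS <- c(0.05, 0.10, 0.15, 0.10, 0.30, 0.30)

stream_seed <- function(seed, k) {
  (as.numeric(seed) %% 94906265) * 7 + k * 1009 + 17
}

with_stream <- function(seed, k, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(stream_seed(seed, k))
  expr
}

#' Simulation configuration with planted structure
#'
#' Fixes every parameter of the synthetic dataset and derives the planted
#' host structure (TAD boundaries per chromosome, A/B compartment labels
#' per 500 kb bin) deterministically from the seed. Defaults are the study
#' conditions the pipeline is exercised under: a 35,722 bp vector with
#' blocks at 9,000 and 18,000 bp and 10:1 within:across contact contrast;
#' a two-chromosome desk-scale host (20 Mb each); vector-host contacts with
#' 0.8 heterochromatin+quiescent bias; 27 planted associated genes among
#' decoys; null associated-gene expression with one induced p53-target-like
#' gene (5x).
#'
#' @param seed Master seed; all streams derive from it.
#' @param host_chroms Named numeric vector of host chromosome lengths (bp).
#' @param vector_length,vector_name Vector sequence (bp, name).
#' @param vector_block_boundaries Planted block boundaries on the vector
#'   (bp).
#' @param block_contrast Within:across contact ratio of the vector blocks.
#' @param n_pets Named list: `vector`, `host`, `vector_host` PET counts.
#' @param tad_contrast Within:across contact ratio of planted host TADs.
#' @param compartment_mixing Cross-compartment contact weight relative to
#'   same-compartment (0.2 = strong plaid).
#' @param span_exponent Exponent of the truncated power-law PET span
#'   distribution.
#' @param span_min Lower truncation of the host PET span distribution in bp
#'   (5,000 by default: self-ligation-scale spans carry no interaction
#'   signal, while keeping the 8 kb clustering span filter non-trivial).
#' @param vector_host_state_bias Fraction of vector-host host-side anchors
#'   placed in heterochromatin/quiescent chromatin (the remainder is placed
#'   in the complementary states, so the bias is also the expected
#'   composition).
#' @param n_assoc_genes Number of planted associated genes (split across
#'   p53-only / RNAPII-only / both evidence classes).
#' @param n_decoy_genes Number of decoy genes placed away from any
#'   qualifying region.
#' @param n_peaks Number of scored peaks emitted.
#' @param expression List: `meanlog`, `sdlog` (baseline lognormal), `cv`
#'   (replicate noise), `n_rep`, `induced_fold`, `induced_conditions`.
#' @param compartment_resolution Compartment bin size in bp.
#' @return A `sim_config` list, including `tad_boundaries` and
#'   `compartment_labels` (planted truth) and a [genome_model()].
#' @export
sim_config <- function(seed = 1,
                       host_chroms = c(chrA = 2e7, chrB = 2e7),
                       vector_length = ADP53_LENGTH,
                       vector_name = "AdP53",
                       vector_block_boundaries = c(9000, 18000),
                       block_contrast = 10,
                       n_pets = list(vector = 50000, host = 1e5,
                                     vector_host = 5000),
                       tad_contrast = 10,
                       compartment_mixing = 0.2,
                       span_exponent = 1.5,
                       span_min = 5000,
                       vector_host_state_bias = 0.8,
                       n_assoc_genes = 27,
                       n_decoy_genes = 100,
                       n_peaks = 2000,
                       expression = list(meanlog = 3, sdlog = 1, cv = 0.1,
                                         n_rep = 3, induced_fold = 5,
                                         induced_conditions = c("KOAd_T9",
                                                                "WT_T9")),
                       compartment_resolution = 500000) {
  stopifnot(vector_host_state_bias >= 0, vector_host_state_bias <= 1,
            block_contrast >= 1, n_assoc_genes >= 0, n_decoy_genes >= 0,
            all(diff(vector_block_boundaries) > 0),
            all(vector_block_boundaries > 0 &
                  vector_block_boundaries < vector_length))
  genome <- genome_model(c(names(host_chroms), vector_name),
                         c(unname(host_chroms), vector_length),
                         vector_name = vector_name)
  structure_truth <- with_stream(seed, 1, {
    tads <- lapply(host_chroms, function(L) {
      # TAD sizes 0.5-2 Mb on a 50 kb grid
      sizes <- numeric(0)
      while (sum(sizes) < L) {
        sizes <- c(sizes, sample(seq(5e5, 2e6, by = 5e4), 1))
      }
      b <- cumsum(sizes)
      b[b < L - 2.5e5]
    })
    comps <- lapply(host_chroms, function(L) {
      nb <- ceiling(L / compartment_resolution)
      lab <- character(0)
      cur <- sample(c("A", "B"), 1)
      while (length(lab) < nb) {
        lab <- c(lab, rep(cur, sample(3:8, 1)))
        cur <- if (cur == "A") "B" else "A"
      }
      lab[seq_len(nb)]
    })
    list(tads = tads, comps = comps)
  })
  cfg <- list(seed = seed, host_chroms = host_chroms,
              vector_length = vector_length, vector_name = vector_name,
              vector_block_boundaries = vector_block_boundaries,
              block_contrast = block_contrast, n_pets = n_pets,
              tad_contrast = tad_contrast,
              compartment_mixing = compartment_mixing,
              span_exponent = span_exponent,
              span_min = span_min,
              vector_host_state_bias = vector_host_state_bias,
              n_assoc_genes = n_assoc_genes,
              n_decoy_genes = n_decoy_genes, n_peaks = n_peaks,
              expression = expression,
              compartment_resolution = compartment_resolution,
              conditions = c("KO_T0", "KO_T9", "KOAd_T0", "KOAd_T9",
                             "WT_T0", "WT_T9"),
              induced_gene = "CDKN1A_like",
              null_neighbor_gene = "SRSF3_like",
              genome = genome,
              tad_boundaries = structure_truth$tads,
              compartment_labels = structure_truth$comps,
              anchor_width = 50)
  class(cfg) <- "sim_config"
  cfg
}

make_anchor <- function(seq, mid, width, L) {
  start <- pmin(pmax(mid - width %/% 2, 0), L - width)
  data.frame(seq = seq, start = start, end = start + width)
}

pets_from_mids <- function(seq1, mid1, seq2, mid2, width, lengths) {
  a1 <- make_anchor(seq1, mid1, width, lengths[seq1])
  a2 <- make_anchor(seq2, mid2, width, lengths[seq2])
  pet_df(a1$seq, a1$start, a1$end, a2$seq, a2$start, a2$end)
}

#' Generate intra-vector PETs with three planted blocks
#'
#' Anchor midpoints are drawn uniformly on the vector; a candidate PET is
#' accepted with probability 1 when both midpoints share a planted block
#' and `1 / block_contrast` otherwise, planting block structure with the
#' configured within:across contrast. Anchors are 50 bp.
#'
#' @param cfg A [sim_config()].
#' @param n Number of PETs (default `cfg$n_pets$vector`).
#' @return PET data frame (intra-vector), canonically ordered.
#' @export
generate_vector_pets <- function(cfg, n = cfg$n_pets$vector) {
  L <- cfg$vector_length
  edges <- c(0, cfg$vector_block_boundaries, L)
  with_stream(cfg$seed, 6, {
    mids <- matrix(numeric(0), ncol = 2)
    while (nrow(mids) < n) {
      k <- max(1000, 2 * (n - nrow(mids)))
      m1 <- floor(stats::runif(k, 0, L))
      m2 <- floor(stats::runif(k, 0, L))
      same <- findInterval(m1, edges, rightmost.closed = TRUE) ==
        findInterval(m2, edges, rightmost.closed = TRUE)
      acc <- same | stats::runif(k) < 1 / cfg$block_contrast
      mids <- rbind(mids, cbind(m1[acc], m2[acc]))
    }
    mids <- mids[seq_len(n), , drop = FALSE]
    swap <- mids[, 1] > mids[, 2]
    mids[swap, ] <- mids[swap, 2:1]
    pets_from_mids(cfg$vector_name, mids[, 1], cfg$vector_name, mids[, 2],
                   cfg$anchor_width, seq_lengths(cfg$genome))
  })
}

powerlaw_spans <- function(k, d_min, d_max, alpha) {
  u <- stats::runif(k)
  a1 <- 1 - alpha
  floor((d_min^a1 + u * (d_max^a1 - d_min^a1))^(1 / a1))
}

#' Generate intra-host cis PETs with planted TADs and compartments
#'
#' One anchor midpoint is uniform on a chromosome (chromosomes in
#' proportion to length), the other at a truncated power-law distance
#' (exponent `span_exponent`, 1 kb to half the chromosome). Candidates are
#' accepted in proportion to `tad_contrast` when both midpoints share a
#' planted TAD and down-weighted by `compartment_mixing` when their 500 kb
#' bins carry different planted compartment labels, producing TAD blocks
#' and a plaid.
#'
#' @param cfg A [sim_config()].
#' @param n Number of PETs (default `cfg$n_pets$host`).
#' @param replicate Integer replicate id; each replicate draws from its own
#'   stream over the same planted truth.
#' @return PET data frame (intra-host cis), canonically ordered.
#' @export
generate_host_pets <- function(cfg, n = cfg$n_pets$host, replicate = 1) {
  chroms <- names(cfg$host_chroms)
  lens <- cfg$host_chroms
  res <- cfg$compartment_resolution
  with_stream(cfg$seed, 100 + replicate, {
    out <- vector("list", 0)
    got <- 0
    while (got < n) {
      k <- max(5000, 3 * (n - got))
      ci <- sample(seq_along(chroms), k, replace = TRUE,
                   prob = lens / sum(lens))
      L <- lens[ci]
      m1 <- floor(stats::runif(k) * L)
      d <- powerlaw_spans(k, cfg$span_min, pmax(2 * cfg$span_min, L / 2),
                          cfg$span_exponent)
      m2 <- m1 + ifelse(stats::runif(k) < 0.5, -1, 1) * d
      ok <- m2 >= 0 & m2 < L
      ci <- ci[ok]; m1 <- m1[ok]; m2 <- m2[ok]
      w <- rep(1, length(m1))
      for (j in seq_along(chroms)) {
        sel <- ci == j
        if (!any(sel)) next
        tb <- c(0, cfg$tad_boundaries[[j]], lens[j])
        same_tad <- findInterval(m1[sel], tb, rightmost.closed = TRUE) ==
          findInterval(m2[sel], tb, rightmost.closed = TRUE)
        lab <- cfg$compartment_labels[[j]]
        same_comp <- lab[floor(m1[sel] / res) + 1] ==
          lab[floor(m2[sel] / res) + 1]
        w[sel] <- ifelse(same_tad, cfg$tad_contrast, 1) *
          ifelse(same_comp, 1, cfg$compartment_mixing)
      }
      acc <- stats::runif(length(w)) < w / cfg$tad_contrast
      if (any(acc)) {
        lo <- pmin(m1[acc], m2[acc])
        hi <- pmax(m1[acc], m2[acc])
        out[[length(out) + 1]] <-
          data.frame(seq = chroms[ci[acc]], m1 = lo, m2 = hi)
        got <- got + sum(acc)
      }
    }
    df <- do.call(rbind, out)[seq_len(n), ]
    pets_from_mids(df$seq, df$m1, df$seq, df$m2, cfg$anchor_width,
                   seq_lengths(cfg$genome))
  })
}

#' Generate the chromatin-state track
#'
#' Tiles every host chromosome with contiguous state intervals (50-150 kb,
#' 6-state vocabulary, heterochromatin and quiescent most frequent), no
#' gaps.
#'
#' @param cfg A [sim_config()].
#' @return Interval data frame with a `state` column.
#' @export
generate_states <- function(cfg) {
  with_stream(cfg$seed, 2, {
    per_chrom <- lapply(names(cfg$host_chroms), function(ch) {
      L <- cfg$host_chroms[[ch]]
      sizes <- numeric(0)
      while (sum(sizes) < L) {
        sizes <- c(sizes, sample(seq(5e4, 1.5e5, by = 1e3), 50,
                                 replace = TRUE))
      }
      edges <- pmin(cumsum(sizes), L)
      edges <- unique(c(0, edges[edges <= L]))
      if (edges[length(edges)] < L) edges <- c(edges, L)
      k <- length(edges) - 1
      data.frame(seq = ch, start = edges[-length(edges)], end = edges[-1],
                 state = sample(CHROMATIN_STATES, k, replace = TRUE,
                                prob = STATE_PROBS))
    })
    df <- do.call(rbind, per_chrom)
    interval_df(df$seq, df$start, df$end, state = df$state)
  })
}

# Sample k host positions: with probability `bias` uniformly (by bp) within
# heterochromatin/quiescent intervals, otherwise within the complementary
# states, keeping a margin from interval and chromosome edges so the 50 bp
# anchor stays inside one state.
sample_host_positions <- function(k, states, bias, edge_margin = 1000,
                                  chrom_margin = 5e4, chrom_lens = NULL) {
  hq <- states[states$state %in% c("Heterochromatin", "Quiescent"), ,
               drop = FALSE]
  other <- states[!states$state %in% c("Heterochromatin", "Quiescent"), ,
                  drop = FALSE]
  if (bias > 0 && nrow(hq) == 0) {
    stop("state bias > 0 but no heterochromatin/quiescent intervals")
  }
  if (bias < 1 && nrow(other) == 0) {
    stop("state bias < 1 but only heterochromatin/quiescent intervals")
  }
  draw <- function(pool, m) {
    w <- pmax(pool$end - pool$start - 2 * edge_margin, 0)
    idx <- sample(nrow(pool), m, replace = TRUE, prob = w)
    pos <- pool$start[idx] + edge_margin +
      floor(stats::runif(m) * (pool$end[idx] - pool$start[idx] -
                                 2 * edge_margin))
    data.frame(seq = pool$seq[idx], pos = pos)
  }
  in_hq <- stats::runif(k) < bias
  out <- data.frame(seq = character(k), pos = numeric(k))
  if (any(in_hq)) out[in_hq, ] <- draw(hq, sum(in_hq))
  if (any(!in_hq)) out[!in_hq, ] <- draw(other, sum(!in_hq))
  if (!is.null(chrom_lens)) {
    redo <- out$pos < chrom_margin | out$pos > chrom_lens[out$seq] -
      chrom_margin
    while (any(redo)) {
      out[redo, ] <- sample_host_positions(sum(redo), states, bias,
                                           edge_margin, chrom_margin = 0)
      redo <- out$pos < chrom_margin | out$pos > chrom_lens[out$seq] -
        chrom_margin
    }
  }
  out
}

jitter_mids <- function(pos, k, spread = 200) {
  pos + floor(stats::runif(k, -spread, spread + 1))
}

#' Plant vector-host contact sites and generate vector-host PETs
#'
#' Plants `n_assoc_genes` contact sites on the host (chromatin-state bias
#' applied, pairwise separation >= 50 kb), each supported by 5-9 vector-host
#' PETs tightly jittered so they cluster into one high-confidence loop, and
#' fills up to `n_pets$vector_host` with singleton background PETs under the
#' same state bias. Sites are split across evidence classes: `p53_only`
#' sites carry the gene themselves, `both` sites carry the gene and seed an
#' RNAPII loop, `rnapii` sites carry no gene but seed an RNAPII loop to a
#' distal gene. The RNAPII intra-host loop PETs (5-9 per loop) are returned
#' separately.
#'
#' @param cfg A [sim_config()].
#' @param states State track from [generate_states()].
#' @return List: `pets` (vector-host, p53 channel), `rnapii_pets`
#'   (intra-host planted loops), `sites` (data frame: `site_id`, `type`,
#'   `seq`, `pos`, `distal_pos`, `pet_count`, `vector_gene`).
#' @export
generate_vector_host_pets <- function(cfg, states) {
  lens <- cfg$host_chroms
  n_both <- round(cfg$n_assoc_genes * 6 / 27)
  n_rnapii <- round(cfg$n_assoc_genes * 9 / 27)
  n_p53 <- cfg$n_assoc_genes - n_both - n_rnapii
  vg <- vector_gene_annotation(cfg)
  with_stream(cfg$seed, 3, {
    n_sites <- cfg$n_assoc_genes
    sites <- data.frame(seq = character(0), pos = numeric(0))
    while (nrow(sites) < n_sites) {
      cand <- sample_host_positions(n_sites, states,
                                    cfg$vector_host_state_bias,
                                    chrom_lens = lens)
      for (i in seq_len(nrow(cand))) {
        ok <- !any(sites$seq == cand$seq[i] &
                     abs(sites$pos - cand$pos[i]) < 5e4)
        if (ok && nrow(sites) < n_sites) sites <- rbind(sites, cand[i, ])
      }
    }
    type <- c(rep("p53_only", n_p53), rep("both", n_both),
              rep("rnapii", n_rnapii))
    sites$site_id <- sprintf("site%02d", seq_len(n_sites))
    sites$type <- type
    sites$pet_count <- sample(5:9, n_sites, replace = TRUE)
    sites$vector_gene <- vg$gene_id[(seq_len(n_sites) - 1) %% nrow(vg) + 1]
    # distal RNAPII anchor positions, >= 50 kb from every site
    sites$distal_pos <- NA_real_
    for (i in which(sites$type != "p53_only")) {
      repeat {
        off <- sample(seq(2e5, 1e6, by = 1e3), 1) *
          sample(c(-1, 1), 1)
        cand <- sites$pos[i] + off
        if (cand < 5e4 || cand > lens[sites$seq[i]] - 5e4) next
        same_chr <- sites$seq == sites$seq[i]
        clash <- any(same_chr & abs(sites$pos - cand) < 5e4) ||
          any(abs(stats::na.omit(sites$distal_pos[same_chr]) - cand) < 5e4)
        if (!clash) {
          sites$distal_pos[i] <- cand
          break
        }
      }
    }
    # planted vector-host PETs: host anchors jittered at the site, vector
    # anchors jittered inside the site's vector gene
    planted <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
      k <- sites$pet_count[i]
      g <- vg[vg$gene_id == sites$vector_gene[i], ]
      vmid <- jitter_mids(floor((g$start + g$end) / 2), k)
      data.frame(seq = sites$seq[i],
                 hmid = jitter_mids(sites$pos[i], k), vmid = vmid)
    }))
    n_bg <- max(0, cfg$n_pets$vector_host - nrow(planted))
    bg <- sample_host_positions(n_bg, states, cfg$vector_host_state_bias,
                                chrom_lens = lens)
    host_seq <- c(planted$seq, bg$seq)
    host_mid <- c(planted$hmid, bg$pos)
    vec_mid <- c(planted$vmid,
                 floor(stats::runif(n_bg, 500, cfg$vector_length - 500)))
    pets <- pets_from_mids(host_seq, host_mid,
                           rep(cfg$vector_name, length(host_mid)), vec_mid,
                           cfg$anchor_width, seq_lengths(cfg$genome))
    # planted RNAPII intra-host loops: site anchor <-> distal anchor
    rp <- do.call(rbind, lapply(which(!is.na(sites$distal_pos)),
                                function(i) {
      k <- sample(5:9, 1)
      data.frame(seq = sites$seq[i],
                 m1 = jitter_mids(sites$pos[i], k),
                 m2 = jitter_mids(sites$distal_pos[i], k))
    }))
    rnapii_pets <- if (is.null(rp)) {
      pet_df()
    } else {
      pets_from_mids(rp$seq, pmin(rp$m1, rp$m2), rp$seq,
                     pmax(rp$m1, rp$m2), cfg$anchor_width,
                     seq_lengths(cfg$genome))
    }
    list(pets = pets, rnapii_pets = rnapii_pets, sites = sites)
  })
}

#' Generate a planted two-compartment contact matrix
#'
#' Direct contact-matrix generator for compartment-calling checks: bins
#' carry planted A/B labels in alternating blocks; the expected count for a
#' bin pair is `depth * (|i - j| + 1)^-decay_exponent`, multiplied by
#' `mixing` when the labels differ, and observed counts are Poisson draws
#' symmetrized over the matrix.
#'
#' @param n_bins Number of bins (default 60).
#' @param mixing Cross-compartment contact weight in `(0, 1]`
#'   (default 0.2).
#' @param depth Expected diagonal count per bin (default 200).
#' @param decay_exponent Distance-decay exponent (default 1, Hi-C-like).
#' @param resolution Bin size in bp (default 500000).
#' @param seed RNG seed.
#' @return List: `matrix` (a [contact_matrix()] on a synthetic sequence),
#'   `labels` (planted per-bin labels).
#' @export
generate_compartment_matrix <- function(n_bins = 60, mixing = 0.2,
                                        depth = 200, decay_exponent = 1,
                                        resolution = 500000, seed = 7) {
  stopifnot(n_bins >= 4, mixing > 0, mixing <= 1, depth > 0)
  with_stream(seed, 9, {
    lab <- character(0)
    cur <- sample(c("A", "B"), 1)
    while (length(lab) < n_bins) {
      lab <- c(lab, rep(cur, sample(3:8, 1)))
      cur <- if (cur == "A") "B" else "A"
    }
    lab <- lab[seq_len(n_bins)]
    d <- abs(outer(seq_len(n_bins), seq_len(n_bins), `-`))
    mu <- depth * (d + 1)^(-decay_exponent) *
      ifelse(outer(lab, lab, `==`), 1, mixing)
    counts <- matrix(stats::rpois(n_bins^2, mu), n_bins)
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    region <- list(seq = "synthetic", start = 0,
                   end = n_bins * resolution)
    list(matrix = contact_matrix(region, resolution, counts), labels = lab)
  })
}

vector_gene_annotation <- function(cfg) {
  # six fixed transcription units on the vector (TP53 cassette + adenoviral
  # backbone genes), scaled to the vector length
  f <- cfg$vector_length / ADP53_LENGTH
  df <- data.frame(
    gene_id = c("AdV_TP53", "AdV_pIX", "AdV_E2B", "AdV_L_major",
                "AdV_E2A", "AdV_E4"),
    start = floor(c(500, 3900, 5000, 9800, 22000, 31000) * f),
    end = floor(c(3300, 4700, 8600, 21000, 24000, 35000) * f),
    strand = c("+", "+", "-", "+", "-", "-")
  )
  interval_df(rep(cfg$vector_name, nrow(df)), df$start, df$end,
              gene_id = df$gene_id, strand = df$strand)
}

#' Generate gene, peak and vector-gene annotations
#'
#' Associated genes are placed over their planted sites (gene body covering
#' the site, or the distal RNAPII anchor for `rnapii` sites); decoy genes
#' and the two expression-control genes (`CDKN1A_like` induced p53 target,
#' `SRSF3_like` null neighbor) are placed at least 20 kb away from every
#' qualifying region. Peaks are uniform with lognormal pileup scores
#' boosted 10x inside TSS states, so the top 1% is TSS-enriched.
#'
#' @param cfg A [sim_config()].
#' @param sites Site table from [generate_vector_host_pets()].
#' @param states State track.
#' @return List: `genes` (host genes: `seq`, `start`, `end`, `gene_id`,
#'   `strand`, `associated`, `evidence`), `vector_genes`, `peaks`
#'   (`score` column).
#' @export
generate_annotations <- function(cfg, sites, states) {
  lens <- cfg$host_chroms
  with_stream(cfg$seed, 4, {
    gene_at <- function(seq, pos, id, evidence) {
      len <- sample(seq(2000, 10000, by = 500), 1)
      start <- max(0, pos - len %/% 2)
      data.frame(seq = seq, start = start, end = start + len,
                 gene_id = id, strand = sample(c("+", "-"), 1),
                 associated = TRUE, evidence = evidence)
    }
    assoc <- list()
    gi <- 0
    for (i in seq_len(nrow(sites))) {
      ev <- switch(sites$type[i], p53_only = "p53", both = "both",
                   rnapii = "RNAPII")
      pos <- if (sites$type[i] == "rnapii") sites$distal_pos[i] else
        sites$pos[i]
      gi <- gi + 1
      assoc[[gi]] <- gene_at(sites$seq[i], pos,
                             sprintf("GENE%03d", gi), ev)
    }
    assoc <- do.call(rbind, assoc)
    # decoys: >= 20 kb from every planted site and distal anchor
    keepout <- data.frame(
      seq = c(sites$seq, sites$seq[!is.na(sites$distal_pos)]),
      pos = c(sites$pos, sites$distal_pos[!is.na(sites$distal_pos)]))
    n_extra <- cfg$n_decoy_genes + 2
    decoys <- list()
    while (length(decoys) < n_extra) {
      ch <- sample(names(lens), 1, prob = lens / sum(lens))
      pos <- floor(stats::runif(1, 5e4, lens[[ch]] - 5e4))
      if (any(keepout$seq == ch & abs(keepout$pos - pos) < 2e4)) next
      if (length(decoys) &&
          any(vapply(decoys, function(d) d$seq == ch &&
                       abs((d$start + d$end) / 2 - pos) < 2e4,
                     logical(1)))) next
      id <- if (length(decoys) == 0) cfg$induced_gene else
        if (length(decoys) == 1) cfg$null_neighbor_gene else
          sprintf("DECOY%03d", length(decoys) - 1)
      decoys[[length(decoys) + 1]] <-
        gene_at(ch, pos, id, NA_character_)
    }
    decoys <- do.call(rbind, decoys)
    decoys$associated <- FALSE
    genes <- rbind(assoc, decoys)
    genes <- interval_df(genes$seq, genes$start, genes$end,
                         gene_id = genes$gene_id, strand = genes$strand,
                         associated = genes$associated,
                         evidence = genes$evidence)
    # scored peaks, pileup boosted in TSS states
    ch <- sample(names(lens), cfg$n_peaks, replace = TRUE,
                 prob = lens / sum(lens))
    pos <- floor(stats::runif(cfg$n_peaks) * (lens[ch] - 400))
    peaks <- interval_df(ch, pos, pos + 400,
                         score = stats::rlnorm(cfg$n_peaks, 2, 0.5))
    tss <- states[states$state == "TSS", , drop = FALSE]
    in_tss <- overlaps_any(peaks, tss)
    peaks$score[in_tss] <- peaks$score[in_tss] * 10
    list(genes = genes, vector_genes = vector_gene_annotation(cfg),
         peaks = peaks)
  })
}

#' Generate the expression table with planted truth
#'
#' Every gene draws one lognormal baseline; all conditions and replicates
#' share it up to multiplicative lognormal noise of the configured CV
#' (null), except the induced p53-target-like gene, whose FPKM is scaled by
#' `induced_fold` in the induced conditions (p53-active, treated).
#'
#' @param cfg A [sim_config()].
#' @param genes Host gene annotation from [generate_annotations()].
#' @return List: `table` (an [expression_table()]), `fold_changes` (named
#'   per-gene, per induced condition).
#' @export
generate_expression <- function(cfg, genes) {
  ex <- cfg$expression
  ids <- genes$gene_id
  with_stream(cfg$seed, 7, {
    base <- stats::rlnorm(length(ids), ex$meanlog, ex$sdlog)
    sdlog_noise <- sqrt(log(1 + ex$cv^2))
    cols <- as.vector(t(outer(cfg$conditions,
                              paste0(".rep", seq_len(ex$n_rep)), paste0)))
    vals <- matrix(0, length(ids), length(cols),
                   dimnames = list(ids, cols))
    for (j in seq_along(cols)) {
      vals[, j] <- base * stats::rlnorm(length(ids), -sdlog_noise^2 / 2,
                                        sdlog_noise)
    }
    cond_of <- sub("\\.rep[0-9]+$", "", cols)
    ind <- match(cfg$induced_gene, ids)
    if (!is.na(ind)) {
      vals[ind, cond_of %in% ex$induced_conditions] <-
        vals[ind, cond_of %in% ex$induced_conditions] * ex$induced_fold
    }
    fold <- stats::setNames(rep(1, length(ids)), ids)
    if (!is.na(ind)) fold[ind] <- ex$induced_fold
    list(table = expression_table(ids, vals), fold_changes = fold)
  })
}

#' Generate and write the full synthetic dataset
#'
#' Runs every generator and writes the pipeline's inputs to `outdir`:
#' `chrom.sizes`, `pets_p53.bedpe` (intra-vector + vector-host),
#' `pets_rnapii.bedpe` (intra-host + planted RNAPII loops), `genes.bed`,
#' `vector_genes.bed`, `states.bed`, `peaks.bed`, `fpkm.tsv`, and
#' `truth.json` (planted boundaries, compartment labels, associated genes
#' with evidence, sites, fold changes). Deterministic under
#' `cfg$seed`: identical bytes for identical configuration.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list with all generated objects and the truth
#'   bundle.
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  states <- generate_states(cfg)
  vh <- generate_vector_host_pets(cfg, states)
  ann <- generate_annotations(cfg, vh$sites, states)
  host_pets <- generate_host_pets(cfg)
  vec_pets <- generate_vector_pets(cfg)
  expr <- generate_expression(cfg, ann$genes)

  write_chrom_sizes(cfg$genome, file.path(outdir, "chrom.sizes"))
  write_pets_bedpe(rbind(vec_pets, vh$pets),
                   file.path(outdir, "pets_p53.bedpe"))
  write_pets_bedpe(rbind(host_pets, vh$rnapii_pets),
                   file.path(outdir, "pets_rnapii.bedpe"))
  write_bed(ann$genes, file.path(outdir, "genes.bed"),
            name_col = "gene_id", strand_col = "strand")
  write_bed(ann$vector_genes, file.path(outdir, "vector_genes.bed"),
            name_col = "gene_id", strand_col = "strand")
  write_bed(states, file.path(outdir, "states.bed"), name_col = "state")
  write_bed(ann$peaks, file.path(outdir, "peaks.bed"), score_col = "score")
  write_fpkm_table(expr$table, file.path(outdir, "fpkm.tsv"))

  truth <- list(
    seed = cfg$seed,
    vector_block_boundaries = cfg$vector_block_boundaries,
    tad_boundaries = cfg$tad_boundaries,
    compartment_labels = cfg$compartment_labels,
    associated_genes = ann$genes$gene_id[ann$genes$associated],
    associated_evidence = as.list(stats::setNames(
      ann$genes$evidence[ann$genes$associated],
      ann$genes$gene_id[ann$genes$associated])),
    vector_genes = ann$vector_genes$gene_id,
    sites = vh$sites,
    state_bias = cfg$vector_host_state_bias,
    induced_gene = cfg$induced_gene,
    fold_changes = as.list(expr$fold_changes[expr$fold_changes != 1])
  )
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, states = states, vector_host = vh,
                 annotations = ann, host_pets = host_pets,
                 vector_pets = vec_pets, expression = expr, truth = truth,
                 dir = outdir))
}
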