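#' High-confidence vector-host loops
#'
#' Keeps vector-host loops with more than `min_count_exclusive` supporting
#' PETs (default more than 4, i.e. PET count >= 5). Errors if any input
#' loop is not vector-host.
#'
#' @param loops Loop data frame (class `vector_host`).
#' @param min_count_exclusive Exclusive PET-count bound (default 4).
#' @return Filtered loop data frame.
#' @export
select_vector_host_loops <- function(loops, min_count_exclusive = 4) {
  if (nrow(loops) > 0 && any(loops$class != "vector_host")) {
    stop("non-vector_host loop(s) in input")
  }
  filter_loops_by_count(loops, min_count_exclusive)
}

#' Host-side anchor regions of vector-host loops
#'
#' The host anchor of each vector-host loop (anchor 1 under canonical
#' ordering, since the vector sorts last), merged where overlapping and
#' sorted. These are the host chromatin regions the vector physically
#' contacts.
#'
#' @param loops Vector-host loop data frame.
#' @return Merged interval data frame.
#' @export
host_anchor_regions <- function(loops) {
  if (nrow(loops) > 0 && any(loops$class != "vector_host")) {
    stop("non-vector_host loop(s) in input")
  }
  a <- anchor_df(loops, 1)
  merge_intervals(a)
}

#' Intra-host loops anchored at given regions
#'
#' Retains loops with at least one anchor overlapping (>= 1 bp) at least one
#' of the given anchor regions — e.g. RNAPII-mediated host loops emanating
#' from vector contact sites.
#'
#' @param anchors Interval data frame of anchor regions.
#' @param loops Intra-host loop data frame.
#' @return Filtered loop data frame.
#' @export
overlap_rnapii_loops <- function(anchors, loops) {
  if (nrow(loops) == 0) return(loops)
  hit <- overlaps_any(anchor_df(loops, 1), anchors) |
    overlaps_any(anchor_df(loops, 2), anchors)
  loops[hit, , drop = FALSE]
}

#' Strand-aware promoter-extended gene regions
#'
#' Gene body extended `promoter_ext` bp upstream of the TSS (`+` strand:
#' before `start`; `-` strand: after `end`), clipped at 0 (and the sequence
#' end when a genome is given).
#'
#' @param genes Gene data frame: `seq`, `start`, `end`, `gene_id`, `strand`.
#' @param promoter_ext Upstream extension in bp, `>= 0` (default 2000).
#' @param genome Optional [genome_model()] for clipping.
#' @return Interval data frame with `gene_id`.
#' @export
gene_association_regions <- function(genes, promoter_ext = 2000,
                                     genome = NULL) {
  stopifnot(promoter_ext >= 0)
  start <- ifelse(genes$strand == "+", pmax(0, genes$start - promoter_ext),
                  genes$start)
  end <- ifelse(genes$strand == "-", genes$end + promoter_ext, genes$end)
  if (!is.null(genome)) end <- pmin(end, seq_lengths(genome)[genes$seq])
  interval_df(seq = genes$seq, start = start, end = end,
              gene_id = genes$gene_id)
}

#' Vector-associated host genes with evidence classes
#'
#' A host gene is vector-associated when its promoter-extended region
#' overlaps a qualifying region from either evidence channel: the merged
#' host anchors of high-confidence p53-mediated vector-host loops, or the
#' anchors of count-filtered RNAPII intra-host loops emanating from those
#' anchors. Evidence is `p53`, `RNAPII`, or `both`.
#'
#' @param p53_regions Interval data frame: qualifying regions of the p53
#'   channel (merged vector-host host anchors).
#' @param rnapii_regions Interval data frame: qualifying regions of the
#'   RNAPII channel (anchors of the retained RNAPII loops).
#' @param genes Gene data frame (`seq`, `start`, `end`, `gene_id`,
#'   `strand`).
#' @param promoter_ext Upstream promoter extension in bp (default 2000).
#' @param genome Optional [genome_model()] for clipping.
#' @return Data frame `gene_id`, `evidence`, sorted by `gene_id`.
#' @export
associate_genes <- function(p53_regions, rnapii_regions, genes,
                            promoter_ext = 2000, genome = NULL) {
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(), evidence = character()))
  }
  reg <- gene_association_regions(genes, promoter_ext, genome)
  hit_p53 <- overlaps_any(reg, p53_regions)
  hit_pol <- overlaps_any(reg, rnapii_regions)
  assoc <- hit_p53 | hit_pol
  out <- data.frame(
    gene_id = genes$gene_id[assoc],
    evidence = ifelse(hit_p53[assoc] & hit_pol[assoc], "both",
                      ifelse(hit_p53[assoc], "p53", "RNAPII")),
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Gene interaction network from loops
#'
#' One undirected edge per gene pair connected by at least one loop whose
#' two anchors overlap the two genes respectively (anchors overlapping
#' several genes expand to all pairs); edge weight is the number of
#' supporting loops. Self-edges are dropped and (a,b)/(b,a) deduplicated.
#' Vector-side anchors are resolved against the vector gene annotation,
#' host-side anchors against the promoter-extended host genes.
#'
#' @param loops Loop data frame (any mix of channels; `factor` is carried
#'   onto edges as the supporting evidence).
#' @param genes Host gene data frame.
#' @param vector_genes Vector gene data frame (same columns; `seq` is the
#'   vector sequence).
#' @param promoter_ext Upstream extension applied to host genes (default
#'   2000).
#' @param genome Optional [genome_model()].
#' @return Data frame `gene_a`, `gene_b`, `weight`, `evidence` sorted by
#'   (`gene_a`, `gene_b`).
#' @export
build_network <- function(loops, genes, vector_genes, promoter_ext = 2000,
                          genome = NULL) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      weight = integer(), evidence = character())
  if (nrow(loops) == 0) return(empty)
  host_reg <- gene_association_regions(genes, promoter_ext, genome)
  vec_reg <- interval_df(seq = vector_genes$seq, start = vector_genes$start,
                         end = vector_genes$end,
                         gene_id = vector_genes$gene_id)
  all_reg <- rbind(host_reg, vec_reg)
  anchor_genes <- function(anchors) {
    p <- overlap_pairs(anchors, all_reg)
    split(all_reg$gene_id[p$subject], factor(p$query, seq_len(nrow(anchors))))
  }
  g1 <- anchor_genes(anchor_df(loops, 1))
  g2 <- anchor_genes(anchor_df(loops, 2))
  rows <- lapply(seq_len(nrow(loops)), function(i) {
    if (length(g1[[i]]) == 0 || length(g2[[i]]) == 0) return(NULL)
    e <- expand.grid(a = unique(g1[[i]]), b = unique(g2[[i]]),
                     stringsAsFactors = FALSE)
    e <- e[e$a != e$b, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    swap <- e$a > e$b
    tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
    e$evidence <- loops$factor[i]
    unique(e)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) return(empty)
  key <- paste(rows$a, rows$b, sep = "\r")
  agg_w <- tapply(rep(1L, nrow(rows)), key, sum)
  agg_e <- tapply(rows$evidence, key, function(v) {
    paste(sort(unique(v)), collapse = ",")
  })
  parts <- strsplit(names(agg_w), "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1),
    gene_b = vapply(parts, `[`, character(1), 2),
    weight = as.integer(agg_w),
    evidence = as.character(agg_e[names(agg_w)]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromatin-state composition of a region set
#'
#' Fraction of the total region bp falling in each chromatin state;
#' fractions sum to 1 when the state track covers the regions, with any
#' uncovered remainder reported as `unannotated`.
#'
#' @param regions Interval data frame.
#' @param states State track: interval data frame with a `state` column;
#'   intervals non-overlapping within a sequence.
#' @return Named numeric vector of fractions (states with zero overlap
#'   omitted; `unannotated` present only when > 0).
#' @export
state_composition <- function(regions, states) {
  total <- sum(regions$end - regions$start)
  if (total == 0) return(stats::setNames(numeric(0), character(0)))
  p <- overlap_pairs(regions, states)
  ov <- pmin(regions$end[p$query], states$end[p$subject]) -
    pmax(regions$start[p$query], states$start[p$subject])
  bp <- tapply(ov, states$state[p$subject], sum)
  frac <- as.numeric(bp) / total
  names(frac) <- names(bp)
  rest <- 1 - sum(frac)
  if (rest > 1e-9) frac <- c(frac, unannotated = rest)
  frac
}

#' Top-scoring features by percentage
#'
#' The `ceil(pct/100 * n)` highest-scoring features, with all features tied
#' at the cutoff score included (used for "top 1% pileup" peak and "top 1%
#' PET count" loop-anchor baselines).
#'
#' @param features Interval data frame with a `score` column.
#' @param pct Percentage in `(0, 100]` (default 1).
#' @return The selected rows of `features`.
#' @export
top_percent_features <- function(features, pct = 1) {
  stopifnot(pct > 0, pct <= 100)
  n <- nrow(features)
  if (n == 0) return(features)
  k <- ceiling(pct / 100 * n)
  cutoff <- sort(features$score, decreasing = TRUE)[k]
  features[features$score >= cutoff, , drop = FALSE]
}
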