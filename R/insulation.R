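#' Insulation score of a contact matrix
#'
#' Sliding-square insulation: for every bin boundary with a full `window` on
#' both sides, the mean contact count in the `window x window` square
#' spanning the boundary is taken, and scores are reported as log2 of that
#' mean relative to the geometric mean over all defined boundaries, so the
#' defined track has mean 0 by construction. Boundaries whose square is
#' empty (mean 0) are masked (NA). Local minima of the track mark contact
#' depletion between self-interacting blocks (TAD boundaries).
#'
#' @param m A `contact_matrix`.
#' @param window Window size in bp; must be a positive multiple of the
#'   matrix resolution, and the matrix at least `2 * window / resolution`
#'   bins wide.
#' @param balanced Use balanced counts when weights are present
#'   (default FALSE: small matrices, e.g. the 72-bin vector map, are
#'   segmented on raw counts).
#' @return An `insulation_track`: list with `region`, `resolution`,
#'   `window`, `positions` (bp of each interior bin boundary), `scores`
#'   (parallel, NA where undefined), and the matrix it was computed from
#'   (used by [call_boundaries()] for its significance test).
#' @export
insulation_score <- function(m, window, balanced = FALSE) {
  res <- m$resolution
  w <- window / res
  if (w < 1 || w != round(w)) {
    stop("window must be a positive multiple of the resolution")
  }
  w <- as.integer(w)
  n <- nrow(m$counts)
  if (n < 2 * w) {
    stop(sprintf("matrix too small for window: %d bins, need >= %d", n, 2 * w))
  }
  mat <- if (balanced) balanced_counts(m) else m$counts
  # boundary i sits at the right edge of bin i (i = 1 .. n - 1)
  raw <- rep(NA_real_, n - 1)
  for (i in seq_len(n - 1)) {
    if (i < w || i > n - w) next
    sq <- mat[(i - w + 1):i, (i + 1):(i + w), drop = FALSE]
    raw[i] <- mean(sq)
  }
  defined <- !is.na(raw) & raw > 0
  scores <- rep(NA_real_, n - 1)
  if (any(defined)) {
    lg <- log2(raw[defined])
    scores[defined] <- lg - mean(lg)
  }
  structure(list(region = m$region, resolution = res, window = window,
                 positions = m$region$start + res * seq_len(n - 1),
                 scores = scores, matrix = m),
            class = "insulation_track")
}

#' Call significant insulation boundaries
#'
#' Boundaries are local minima of the insulation track that (1) have
#' prominence (the smaller of the rises to the flanking local maxima of the
#' defined track) of at least `delta_min`, and (2) pass a one-sided
#' Wilcoxon rank-sum test comparing within-side contacts (the two
#' `window x window` triangles flanking the boundary) against cross-boundary
#' contacts (the spanning square) at `p < p_threshold`.
#'
#' @param track An `insulation_track` from [insulation_score()].
#' @param delta_min Minimum prominence on the log2 insulation scale
#'   (default 0.1).
#' @param p_threshold Significance threshold for the rank-sum test
#'   (default 0.05).
#' @return Numeric vector of boundary positions in bp (bin edges), possibly
#'   empty.
#' @export
call_boundaries <- function(track, delta_min = 0.1, p_threshold = 0.05) {
  s <- track$scores
  def <- which(!is.na(s))
  if (length(def) < 3) return(numeric(0))
  sv <- s[def]
  k <- length(sv)
  is_min <- vapply(seq_len(k), function(j) {
    j > 1 && j < k && sv[j] < sv[j - 1] && sv[j] <= sv[j + 1]
  }, logical(1))
  cand <- which(is_min)
  if (length(cand) == 0) return(numeric(0))

  prominence <- vapply(cand, function(j) {
    left <- if (j > 1) max(sv[1:(j - 1)]) else sv[j]
    right <- if (j < k) max(sv[(j + 1):k]) else sv[j]
    # nearest flanking maxima bounded by deeper minima on either side
    lb <- rev(which(sv[seq_len(j - 1)] < sv[j]))
    if (length(lb)) left <- max(sv[(lb[1] + 1):(j - 1)])
    rb <- which(sv[(j + 1):k] < sv[j]) + j
    if (length(rb)) right <- max(sv[(j + 1):(rb[1] - 1)])
    min(left, right) - sv[j]
  }, numeric(1))
  cand <- cand[prominence >= delta_min]
  if (length(cand) == 0) return(numeric(0))

  mat <- if (!is.null(track$matrix$weights)) balanced_counts(track$matrix)
         else track$matrix$counts
  w <- as.integer(track$window / track$resolution)
  n <- nrow(mat)
  keep <- vapply(def[cand], function(i) {
    li <- (i - w + 1):i
    ri <- (i + 1):(i + w)
    # diagonal cells are excluded from the within-side sample: self-ligation
    # span filtering depletes them, which would dilute the contrast
    tri <- upper.tri(matrix(0, w, w), diag = w == 1)
    within <- c(mat[li, li][tri], mat[ri, ri][tri])
    cross <- as.vector(mat[li, ri])
    p <- suppressWarnings(
      stats::wilcox.test(within, cross, alternative = "greater",
                         exact = FALSE)$p.value)
    is.finite(p) && p < p_threshold
  }, logical(1))
  sort(track$positions[def[cand][keep]])
}

#' Segment a region at boundary positions
#'
#' Splits `[region$start, region$end)` at the given interior boundaries into
#' contiguous segments (TAD-style blocks): `n` boundaries give `n + 1`
#' segments tiling the region exactly. Duplicate boundaries collapse.
#'
#' @param boundaries Numeric bp positions strictly inside the region.
#' @param region List with `seq`, `start`, `end`.
#' @param boundary_scores Optional scores attached to each boundary (e.g.
#'   the insulation score at the boundary); recycled NA otherwise.
#' @return A `tad_set`: data frame with `start`, `end`, `boundary_score`
#'   (score at the segment's right boundary, NA for the last segment), plus
#'   attributes `region`.
#' @export
segment_region <- function(boundaries, region, boundary_scores = NULL) {
  b <- sort(unique(as.numeric(boundaries)))
  if (any(b <= region$start | b >= region$end)) {
    stop("boundary outside the open interval (region$start, region$end)")
  }
  if (!is.null(boundary_scores)) {
    stopifnot(length(boundary_scores) == length(boundaries))
    boundary_scores <-
      boundary_scores[match(b, as.numeric(boundaries))]
  } else {
    boundary_scores <- rep(NA_real_, length(b))
  }
  edges <- c(region$start, b, region$end)
  seg <- data.frame(start = edges[-length(edges)], end = edges[-1],
                    boundary_score = c(boundary_scores, NA_real_))
  attr(seg, "region") <- region
  class(seg) <- c("tad_set", "data.frame")
  seg
}

#' Summarise a TAD segmentation
#'
#' @param tads A `tad_set` from [segment_region()].
#' @return List with `count`, `sizes` (bp per segment) and
#'   `boundary_scores`.
#' @export
tad_summary <- function(tads) {
  list(count = nrow(tads), sizes = tads$end - tads$start,
       boundary_scores = tads$boundary_score[-nrow(tads)])
}

#' Boundary agreement between two segmentations (Jaccard)
#'
#' Interior boundaries of two TAD sets over the same region are greedily
#' matched (nearest first) within `slack` bins; the score is
#' `matched / union`, 1 for identical boundary sets, 0 for disjoint sets
#' beyond slack.
#'
#' @param a,b `tad_set` objects over the same region.
#' @param slack Matching tolerance in bins (default 1).
#' @param resolution Bin size in bp used to convert `slack` to bp.
#' @return Jaccard index in `[0, 1]`.
#' @export
boundary_jaccard <- function(a, b, slack = 1, resolution) {
  ba <- a$end[-nrow(a)]
  bb <- b$end[-nrow(b)]
  if (length(ba) == 0 && length(bb) == 0) return(1)
  if (length(ba) == 0 || length(bb) == 0) return(0)
  tol <- slack * resolution
  d <- abs(outer(ba, bb, `-`))
  matched <- 0L
  while (TRUE) {
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[i[1], i[2]] > tol) break
    matched <- matched + 1L
    d[i[1], ] <- Inf
    d[, i[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  matched / (length(ba) + length(bb) - matched)
}
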