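#' Cluster PETs into interaction loops
#'
#' ChIA-PET loop calling: each anchor is extended by `ext` bp, two PETs are
#' linked when their extended first anchors overlap (>= 1 bp) AND their
#' extended second anchors overlap, and loops are the connected components
#' under transitive closure of that link (single linkage). Each loop's
#' anchors are the union span (min start, max end) of its members' extended
#' anchors, and its `pet_count` is the component size.
#'
#' All input PETs must belong to one PET class (cluster one class/antibody
#' channel at a time). Output is sorted by (first-anchor sequence index,
#' first-anchor start, second-anchor start) and is invariant to input order.
#'
#' @param pets PET data frame (one class).
#' @param ext Anchor extension in bp (500 for host and vector-host channels,
#'   0 within the vector).
#' @param genome A [genome_model()].
#' @param factor Antibody channel label carried onto the loops
#'   (e.g. `"p53"`, `"RNAPII"`); `NA` allowed.
#' @return Loop data frame of class `c("loop_df", "data.frame")` with anchor
#'   columns as in [pet_df()] plus `pet_count`, `factor`, `class`.
#' @export
cluster_pets <- function(pets, ext, genome, factor = NA_character_) {
  stopifnot(ext >= 0)
  pets <- canonicalize_pets(pets, genome)
  cls <- classify_pets(pets, genome)
  if (nrow(pets) > 0 && length(unique(cls)) > 1) {
    stop("mixed PET classes in clustering input: ",
         paste(unique(cls), collapse = ", "))
  }
  loop_class <- if (nrow(pets)) as.character(cls[1]) else NA_character_
  a1 <- extend_anchor(anchor_df(pets, 1), ext, genome)
  a2 <- extend_anchor(anchor_df(pets, 2), ext, genome)

  n <- nrow(pets)
  if (n == 0) {
    loops <- data.frame(seq1 = character(), start1 = numeric(),
                        end1 = numeric(), seq2 = character(),
                        start2 = numeric(), end2 = numeric(),
                        pet_count = integer(), factor = character(),
                        class = character(), stringsAsFactors = FALSE)
    class(loops) <- c("loop_df", "data.frame")
    return(loops)
  }
  membership <- integer(0)
  if (n > 0) {
    edges <- matrix(integer(0), ncol = 2)
    key <- paste(pets$seq1, pets$seq2)
    for (grp in split(seq_len(n), key)) {
      h <- IRanges::findOverlaps(as_iranges0(a1$start[grp], a1$end[grp]),
                                 drop.self = TRUE, drop.redundant = TRUE)
      qi <- grp[S4Vectors::queryHits(h)]
      si <- grp[S4Vectors::subjectHits(h)]
      # require the second anchors to overlap too (>= 1 bp, half-open)
      keep <- a2$start[qi] < a2$end[si] & a2$start[si] < a2$end[qi]
      if (any(keep)) edges <- rbind(edges, cbind(qi[keep], si[keep]))
    }
    g <- igraph::make_graph(as.vector(t(edges)), n = n, directed = FALSE)
    membership <- igraph::components(g)$membership
  }

  idx <- split(seq_len(n), membership)
  loops <- data.frame(
    seq1 = vapply(idx, function(i) pets$seq1[i[1]], character(1)),
    start1 = vapply(idx, function(i) min(a1$start[i]), numeric(1)),
    end1 = vapply(idx, function(i) max(a1$end[i]), numeric(1)),
    seq2 = vapply(idx, function(i) pets$seq2[i[1]], character(1)),
    start2 = vapply(idx, function(i) min(a2$start[i]), numeric(1)),
    end2 = vapply(idx, function(i) max(a2$end[i]), numeric(1)),
    pet_count = lengths(idx),
    factor = factor,
    class = loop_class,
    stringsAsFactors = FALSE, row.names = NULL
  )
  ord <- order(seq_index(genome, loops$seq1), loops$start1, loops$start2)
  loops <- loops[ord, , drop = FALSE]
  rownames(loops) <- NULL
  class(loops) <- c("loop_df", "data.frame")
  loops
}

#' Filter loops by supporting PET count
#'
#' Retains loops whose `pet_count` strictly exceeds `min_count_exclusive`.
#' At the high-confidence setting of "more than 4 PETs" this keeps loops
#' with `pet_count >= 5`.
#'
#' @param loops Loop data frame from [cluster_pets()].
#' @param min_count_exclusive Exclusive lower bound, `>= 0`.
#' @return Filtered loop data frame; order preserved.
#' @export
filter_loops_by_count <- function(loops, min_count_exclusive) {
  stopifnot(min_count_exclusive >= 0)
  if (nrow(loops) == 0) return(loops)
  loops[loops$pet_count > min_count_exclusive, , drop = FALSE]
}

#' Read / write loops in BEDPE format
#'
#' Loops are written as BEDPE with `name = factor:class` and
#' `score = pet_count`.
#'
#' @param path File path.
#' @return [read_loops_bedpe()]: a loop data frame.
#' @export
read_loops_bedpe <- function(path) {
  cols <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(cols) < 8) stop("loop BEDPE needs name and score columns: ", path)
  fc <- strsplit(as.character(cols[[7]]), ":", fixed = TRUE)
  loops <- data.frame(
    seq1 = cols[[1]], start1 = as.numeric(cols[[2]]),
    end1 = as.numeric(cols[[3]]),
    seq2 = cols[[4]], start2 = as.numeric(cols[[5]]),
    end2 = as.numeric(cols[[6]]),
    pet_count = as.integer(cols[[8]]),
    factor = vapply(fc, `[`, character(1), 1),
    class = vapply(fc, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  class(loops) <- c("loop_df", "data.frame")
  loops
}

#' @rdname read_loops_bedpe
#' @param loops Loop data frame to write.
#' @export
write_loops_bedpe <- function(loops, path) {
  n <- nrow(loops)
  out <- data.frame(loops$seq1, format_bp(loops$start1),
                    format_bp(loops$end1),
                    loops$seq2, format_bp(loops$start2),
                    format_bp(loops$end2),
                    name = paste(loops$factor, loops$class, sep = ":"),
                    score = loops$pet_count,
                    strand1 = rep(".", n), strand2 = rep(".", n))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
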