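# Interval plumbing. All coordinates in this package are 0-based half-open
# [start, end), the BED/BEDPE convention. IRanges is 1-based closed, so every
# call through it shifts start by +1. "Overlap" always means >= 1 shared bp:
# touching half-open intervals (end == start) do NOT overlap.

#' Interval data frames
#'
#' Intervals are plain data frames with columns `seq` (character), `start`,
#' `end` (numeric bp, 0-based half-open). Extra columns are carried along.
#'
#' @param seq,start,end Vectors of equal length.
#' @param ... Further columns (e.g. `name`, `score`, `strand`).
#' @return A data frame of class `c("interval_df", "data.frame")`.
#' @export
interval_df <- function(seq = character(), start = numeric(),
                        end = numeric(), ...) {
  df <- data.frame(seq = as.character(seq), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("interval_df", "data.frame")
  df
}

validate_intervals <- function(df, genome = NULL) {
  stopifnot(all(c("seq", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad)) {
    stop("invalid interval(s): need 0 <= start < end (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  }
  if (!is.null(genome)) {
    len <- seq_lengths(genome)[df$seq]
    if (anyNA(len)) {
      stop("unknown sequence name(s): ",
           paste(unique(df$seq[is.na(len)]), collapse = ", "))
    }
    over <- df$end > len
    if (any(over)) {
      stop("interval(s) extend past sequence end (rows ",
           paste(utils::head(which(over), 5), collapse = ", "), ")")
    }
  }
  invisible(df)
}

# IRanges on the half-open coordinates (shift to 1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$seq, as_iranges0(df$start, df$end))
}

granges_to_df0 <- function(gr, ...) {
  interval_df(seq = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr), ...)
}

#' Extend an interval symmetrically, clipped to its sequence
#'
#' Anchor extension used before loop clustering: each anchor grows by `ext`
#' bp on both sides, clipped to `[0, length(seq))`.
#'
#' @param iv An interval data frame (any number of rows).
#' @param ext Extension in bp, `>= 0`.
#' @param genome A [genome_model()] supplying sequence lengths for clipping.
#' @return The extended intervals.
#' @export
extend_anchor <- function(iv, ext, genome) {
  stopifnot(ext >= 0)
  validate_intervals(iv, genome)
  if (nrow(iv) == 0) return(iv)
  iv$start <- pmax(0, iv$start - ext)
  iv$end <- pmin(seq_lengths(genome)[iv$seq], iv$end + ext)
  iv
}

#' Merge overlapping intervals
#'
#' Overlapping (>= 1 bp shared) intervals on the same sequence are unioned;
#' touching half-open intervals stay separate. Output sorted by
#' (sequence, start). Idempotent and order-invariant.
#'
#' @param iv Interval data frame.
#' @return Merged, sorted interval data frame (only `seq`/`start`/`end`).
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) {
    return(interval_df())
  }
  gr <- as_granges0(iv)
  # min.gapwidth = 0: merge strictly-overlapping ranges only, keep abutting
  # half-open intervals (gap 0 in closed coordinates) separate
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
  granges_to_df0(red)
}

#' Which query intervals overlap any subject interval?
#'
#' @param query,subject Interval data frames.
#' @return Logical vector over `query` rows.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject))
}

# All overlapping (query, subject) row pairs.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(), subject = integer()))
  }
  h <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}
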