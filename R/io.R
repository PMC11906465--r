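# BED input/output through rtracklayer; package-internal interval frames
# are 0-based half-open like BED itself, rtracklayer's GRanges are 1-based
# closed, so the shift lives in as_granges0()/granges_to_df0().

#' Write an interval data frame as BED
#'
#' @param iv Interval data frame.
#' @param path Output path (`.bed`).
#' @param name_col,score_col,strand_col Optional column names mapped onto
#'   the BED name/score/strand fields.
#' @export
write_bed <- function(iv, path, name_col = NULL, score_col = NULL,
                      strand_col = NULL) {
  gr <- as_granges0(iv)
  if (!is.null(strand_col)) {
    GenomicRanges::strand(gr) <- iv[[strand_col]]
  }
  mcols <- list()
  if (!is.null(name_col)) mcols$name <- iv[[name_col]]
  if (!is.null(score_col)) mcols$score <- iv[[score_col]]
  if (length(mcols)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mcols)
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED files into interval data frames
#'
#' `read_genes_bed` expects BED6 (name = gene id, strand used);
#' `read_states_bed` BED4+ (name = chromatin-state label);
#' `read_peaks_bed` BED5 (score = pileup).
#'
#' @param path BED file path.
#' @return Interval data frame with the format's extra column(s).
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_df0(gr, gene_id = gr$name,
                 strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_genes_bed
#' @export
read_states_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_df0(gr, state = gr$name)
}

#' @rdname read_genes_bed
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_df0(gr, score = gr$score)
}

#' Write a per-bin track as bedGraph
#'
#' @param region List with `seq`, `start`, `end`.
#' @param resolution Bin size in bp.
#' @param values Per-position numeric values; NA entries are skipped.
#' @param positions Optional explicit start positions (defaults to bin
#'   starts).
#' @param path Output path.
#' @export
write_bedgraph <- function(region, resolution, values, path,
                           positions = NULL) {
  if (is.null(positions)) {
    positions <- region$start + resolution * (seq_along(values) - 1)
  }
  ok <- !is.na(values)
  df <- data.frame(region$seq, format_bp(positions[ok]),
                   format_bp(pmin(positions[ok] + resolution, region$end)),
                   values[ok])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a contact matrix in dense triple format
#'
#' Tab-delimited `bin1_start`, `bin2_start`, `count` (upper triangle,
#' non-zero cells) with a `#region=seq:start-end resolution=bp` header
#' line.
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @export
write_matrix_triples <- function(m, path) {
  n <- nrow(m$counts)
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#region=%s:%s-%s resolution=%s", m$region$seq,
                     format_bp(m$region$start), format_bp(m$region$end),
                     format_bp(m$resolution)), con)
  if (nrow(idx)) {
    df <- data.frame(
      format_bp(m$region$start + (idx[, 1] - 1) * m$resolution),
      format_bp(m$region$start + (idx[, 2] - 1) * m$resolution),
      m$counts[idx])
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
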