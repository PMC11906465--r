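#' Paired-end tags (PETs) on a combined genome
#'
#' A PET is one proximity-ligation product: two genomic anchors marking loci
#' that were physically close in the nucleus. PETs are stored as a data frame
#' with columns `seq1`, `start1`, `end1`, `seq2`, `start2`, `end2`
#' (0-based half-open bp). [canonicalize_pets()] enforces the canonical
#' anchor order: anchor 1 `<=` anchor 2 by (sequence index in the genome
#' model, start); the vector sequence sorts after all host chromosomes, so
#' vector-host PETs always carry the host locus in anchor 1.
#'
#' @param seq1,start1,end1,seq2,start2,end2 Anchor coordinates.
#' @return PET data frame of class `c("pet_df", "data.frame")`.
#' @export
pet_df <- function(seq1 = character(), start1 = numeric(), end1 = numeric(),
                   seq2 = character(), start2 = numeric(), end2 = numeric()) {
  df <- data.frame(seq1 = as.character(seq1), start1 = as.numeric(start1),
                   end1 = as.numeric(end1),
                   seq2 = as.character(seq2), start2 = as.numeric(start2),
                   end2 = as.numeric(end2), stringsAsFactors = FALSE)
  validate_pets(df)
  class(df) <- c("pet_df", "data.frame")
  df
}

validate_pets <- function(pets, genome = NULL) {
  stopifnot(all(c("seq1", "start1", "end1", "seq2", "start2", "end2")
                %in% names(pets)))
  validate_intervals(anchor_df(pets, 1), genome)
  validate_intervals(anchor_df(pets, 2), genome)
  invisible(pets)
}

#' Extract one anchor side of a PET or loop table as intervals
#'
#' @param pets PET or loop data frame.
#' @param which 1 (first/left anchor) or 2 (second/right anchor).
#' @return Interval data frame (`seq`, `start`, `end`).
#' @export
anchor_df <- function(pets, which = 1) {
  s <- if (which == 1) c("seq1", "start1", "end1") else
    c("seq2", "start2", "end2")
  df <- pets[, s, drop = FALSE]
  names(df) <- c("seq", "start", "end")
  rownames(df) <- NULL
  class(df) <- c("interval_df", "data.frame")
  df
}

#' @rdname pet_df
#' @param pets A PET data frame.
#' @param genome A [genome_model()] fixing the sequence order.
#' @export
canonicalize_pets <- function(pets, genome) {
  validate_pets(pets, genome)
  if (nrow(pets) == 0) return(pets)
  i1 <- seq_index(genome, pets$seq1)
  i2 <- seq_index(genome, pets$seq2)
  swap <- i1 > i2 | (i1 == i2 & pets$start1 > pets$start2)
  if (any(swap)) {
    tmp <- pets[swap, c("seq1", "start1", "end1")]
    pets[swap, c("seq1", "start1", "end1")] <-
      pets[swap, c("seq2", "start2", "end2")]
    pets[swap, c("seq2", "start2", "end2")] <- tmp
  }
  pets
}

#' PET classes on a combined host + vector genome
#'
#' Every PET falls in exactly one of four classes given a genome model:
#' `intra_vector` (both anchors on the vector), `vector_host` (exactly one
#' anchor on the vector), `intra_host_cis` (both on the same host
#' chromosome), `intra_host_trans` (two different host chromosomes).
#'
#' @param pets PET data frame.
#' @param genome A [genome_model()].
#' @return Factor with levels `intra_vector`, `vector_host`,
#'   `intra_host_cis`, `intra_host_trans`, one per PET.
#' @export
classify_pets <- function(pets, genome) {
  validate_pets(pets, genome)
  v <- genome$vector_name
  on_v1 <- pets$seq1 == v
  on_v2 <- pets$seq2 == v
  cls <- ifelse(on_v1 & on_v2, "intra_vector",
         ifelse(xor(on_v1, on_v2), "vector_host",
         ifelse(pets$seq1 == pets$seq2, "intra_host_cis",
                "intra_host_trans")))
  factor(cls, levels = PET_CLASSES)
}

#' @rdname classify_pets
#' @export
PET_CLASSES <- c("intra_vector", "vector_host", "intra_host_cis",
                 "intra_host_trans")

#' Genomic span of cis PETs
#'
#' The span of a same-sequence PET is the absolute distance between the two
#' anchor midpoints (`floor((start + end) / 2)`); it is 0 when the midpoints
#' coincide and undefined (error) for cross-sequence PETs.
#'
#' @param pets PET data frame; all rows must be same-sequence.
#' @return Numeric vector of spans in bp.
#' @export
pet_span <- function(pets) {
  validate_pets(pets)
  if (any(pets$seq1 != pets$seq2)) {
    stop("span undefined for cross-sequence PET(s) (rows ",
         paste(utils::head(which(pets$seq1 != pets$seq2), 5), collapse = ", "),
         ")")
  }
  m1 <- floor((pets$start1 + pets$end1) / 2)
  m2 <- floor((pets$start2 + pets$end2) / 2)
  abs(m2 - m1)
}

#' Filter cis PETs by genomic span
#'
#' Retains PETs whose span strictly exceeds `min_span_exclusive`, the
#' self-ligation filter applied before clustering (`> 8000` bp for host and
#' vector-host channels; `> 600` bp within the vector). Order preserved;
#' idempotent.
#'
#' @param pets Same-sequence PET data frame.
#' @param min_span_exclusive Exclusive lower bound in bp, `>= 0`.
#' @return Filtered PET data frame.
#' @export
filter_pets_by_span <- function(pets, min_span_exclusive) {
  stopifnot(min_span_exclusive >= 0)
  if (nrow(pets) == 0) return(pets)
  pets[pet_span(pets) > min_span_exclusive, , drop = FALSE]
}

#' Read / write PETs in BEDPE format
#'
#' BEDPE: `chrom1 start1 end1 chrom2 start2 end2 [name score strand1
#' strand2]`, 0-based half-open. PETs are unstranded; on write the strand
#' fields are `"."` and the score 0.
#'
#' @param path File path.
#' @param genome Optional [genome_model()]; when supplied the PETs are
#'   validated and canonicalized against it.
#' @return [read_pets_bedpe()]: a PET data frame.
#' @export
read_pets_bedpe <- function(path, genome = NULL) {
  cols <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(cols) < 6) stop("BEDPE needs at least 6 columns: ", path)
  pets <- pet_df(cols[[1]], cols[[2]], cols[[3]],
                 cols[[4]], cols[[5]], cols[[6]])
  if (!is.null(genome)) pets <- canonicalize_pets(pets, genome)
  pets
}

#' @rdname read_pets_bedpe
#' @param pets PET data frame to write.
#' @export
write_pets_bedpe <- function(pets, path) {
  n <- nrow(pets)
  out <- data.frame(pets$seq1, format_bp(pets$start1), format_bp(pets$end1),
                    pets$seq2, format_bp(pets$start2), format_bp(pets$end2),
                    name = if (n) paste0("PET", seq_len(n)) else character(),
                    score = rep(0L, n),
                    strand1 = rep(".", n), strand2 = rep(".", n))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
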