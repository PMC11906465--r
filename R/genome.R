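#' Combined host + vector genome model
#'
#' A `genome_model` describes the sequences of a combined reference: the host
#' chromosomes plus one episomal vector sequence. Sequence order is
#' significant: it defines the canonical ordering of PET anchors. Host
#' chromosomes keep their input order and the vector always sorts last, so
#' that for a vector-host PET the host anchor is `anchor_a` and the vector
#' anchor is `anchor_b`.
#'
#' @param seqnames Character vector of sequence names (must include
#'   `vector_name`).
#' @param seqlengths Integer vector of sequence lengths in bp, parallel to
#'   `seqnames`; all `> 0`.
#' @param vector_name Name of the vector sequence. Default `"AdP53"`, a
#'   35,722 bp recombinant adenoviral vector carrying wild-type TP53.
#' @return An object of class `genome_model`: a list with `seqnames`,
#'   `seqlengths` (named), and `vector_name`, with the vector placed last.
#' @examples
#' gm <- genome_model(c("chr1", "AdP53"), c(2e6, 35722))
#' seq_lengths(gm)
#' @export
genome_model <- function(seqnames, seqlengths, vector_name = "AdP53") {
  stopifnot(length(seqnames) == length(seqlengths), length(seqnames) >= 1)
  seqnames <- as.character(seqnames)
  seqlengths <- as.numeric(seqlengths)
  if (anyDuplicated(seqnames)) {
    stop("duplicate sequence names in genome model")
  }
  if (any(!is.finite(seqlengths)) || any(seqlengths <= 0)) {
    stop("all sequence lengths must be positive")
  }
  if (!vector_name %in% seqnames) {
    stop("vector sequence '", vector_name, "' not present in genome model")
  }
  ord <- c(setdiff(seq_along(seqnames), match(vector_name, seqnames)),
           match(vector_name, seqnames))
  seqnames <- seqnames[ord]
  seqlengths <- seqlengths[ord]
  names(seqlengths) <- seqnames
  structure(
    list(seqnames = seqnames, seqlengths = seqlengths,
         vector_name = vector_name),
    class = "genome_model"
  )
}

#' Default vector length of the Ad-p53 adenoviral genome (bp)
#' @export
ADP53_LENGTH <- 35722L

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$seqnames), "sequences; vector =",
      x$vector_name, sprintf("(%s bp)\n", format(x$seqlengths[[x$vector_name]],
                                                 big.mark = ",")))
  invisible(x)
}

#' @rdname genome_model
#' @param genome A `genome_model`.
#' @export
seq_lengths <- function(genome) genome$seqlengths

#' Read / write a chromosome-sizes table
#'
#' Two-column headerless TSV (sequence name, length in bp), the conventional
#' `chrom.sizes` format.
#'
#' @param path File path.
#' @param vector_name Vector sequence name, passed to [genome_model()].
#' @return [read_chrom_sizes()]: a `genome_model`.
#' @export
read_chrom_sizes <- function(path, vector_name = "AdP53") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq", "length"),
                          colClasses = c("character", "numeric"))
  genome_model(df$seq, df$length, vector_name = vector_name)
}

#' @rdname read_chrom_sizes
#' @param genome A `genome_model` to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(seq = genome$seqnames, length = genome$seqlengths),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

seq_index <- function(genome, seq) {
  idx <- match(seq, genome$seqnames)
  if (anyNA(idx)) {
    stop("unknown sequence name(s): ",
         paste(unique(seq[is.na(idx)]), collapse = ", "))
  }
  idx
}
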