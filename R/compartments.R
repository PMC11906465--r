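#' A/B compartment calling from an O/E matrix
#'
#' Classic eigenvector compartment calling: the Pearson correlation matrix
#' of the observed/expected columns (masked bins excluded) is decomposed and
#' the eigenvector with the largest-magnitude eigenvalue is taken. Its sign
#' is oriented so that its correlation with `orientation_track` (a per-bin
#' covariate enriched in active chromatin, e.g. gene density) is
#' non-negative; bins with positive entries are labelled `A`, negative `B`,
#' masked bins `NA`.
#'
#' @param oe O/E matrix from [observed_over_expected()] (NA rows/columns =
#'   masked bins).
#' @param orientation_track Numeric per-bin track, same length as the bin
#'   count, fixing the A/B sign convention.
#' @param resolution Bin size in bp (default 500000, the compartment scale).
#' @return A `compartment_track`: list with `resolution`, `eigenvector`
#'   (NA on masked bins) and `labels` (factor `A`/`B`, NA on masked bins or
#'   zero entries).
#' @export
compartment_eigenvector <- function(oe, orientation_track,
                                    resolution = 500000) {
  n <- nrow(oe)
  stopifnot(ncol(oe) == n, length(orientation_track) == n)
  mask <- apply(oe, 1, function(r) all(is.na(r)))
  un <- which(!mask)
  ev <- rep(NA_real_, n)
  if (length(un) >= 3) {
    sub <- oe[un, un, drop = FALSE]
    cc <- suppressWarnings(stats::cor(sub))
    cc[!is.finite(cc)] <- 0
    if (all(cc == 0)) stop("degenerate correlation matrix: rank 0")
    eig <- eigen(cc, symmetric = TRUE)
    lead <- which.max(abs(eig$values))
    v <- eig$vectors[, lead]
    ori <- orientation_track[un]
    if (stats::sd(ori) > 0 && stats::sd(v) > 0 &&
        stats::cor(v, ori) < 0) {
      v <- -v
    }
    ev[un] <- v
  } else if (length(un) > 0) {
    stop("degenerate correlation matrix: fewer than 3 unmasked bins")
  }
  labels <- factor(ifelse(is.na(ev) | ev == 0, NA,
                          ifelse(ev > 0, "A", "B")), levels = c("A", "B"))
  structure(list(resolution = resolution, eigenvector = ev, labels = labels),
            class = "compartment_track")
}

#' Compartment strength correlation between two tracks
#'
#' Pearson correlation of the compartment eigenvector values over jointly
#' unmasked bins; near 1 when two conditions share the same A/B structure.
#'
#' @param a,b `compartment_track` objects with equal resolution and bin
#'   count.
#' @return Pearson r.
#' @export
compartment_strength_correlation <- function(a, b) {
  stopifnot(a$resolution == b$resolution,
            length(a$eigenvector) == length(b$eigenvector))
  ok <- !is.na(a$eigenvector) & !is.na(b$eigenvector)
  if (sum(ok) < 3) stop("fewer than 3 jointly unmasked bins")
  stats::cor(a$eigenvector[ok], b$eigenvector[ok])
}

#' Compartment size distribution
#'
#' Maximal same-label runs of unmasked bins, converted to bp, with an ECDF
#' evaluator per label (fraction of runs of size `<= x`; right-continuous,
#' reaching 1 at the largest run).
#'
#' @param track A `compartment_track`.
#' @return List with `sizes` (named list of run-length vectors in bp, per
#'   label) and `ecdf` (named list of [stats::ecdf()] functions; absent for
#'   labels with no runs).
#' @export
compartment_size_distribution <- function(track) {
  lab <- as.character(track$labels)
  r <- rle(ifelse(is.na(lab), "<masked>", lab))
  keep <- r$values %in% c("A", "B")
  sizes <- split(r$lengths[keep] * track$resolution, r$values[keep])
  out_sizes <- list(A = unname(sizes[["A"]]) %||% numeric(0),
                    B = unname(sizes[["B"]]) %||% numeric(0))
  list(sizes = out_sizes,
       ecdf = lapply(Filter(length, out_sizes), stats::ecdf))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
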