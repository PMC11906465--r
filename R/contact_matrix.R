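#' Binned contact matrices
#'
#' A `contact_matrix` holds symmetric binned contact counts over one genomic
#' region: `region` (seq, start, end), `resolution` (bp), `counts`
#' (`n x n` with `n = ceiling((end - start) / resolution)`), and, after
#' [kr_balance()], per-bin `weights` (NA on masked bins). Bins whose row is
#' all zero are masked.
#'
#' @param region List with `seq`, `start`, `end` (0-based half-open bp).
#' @param resolution Bin size in bp, `> 0`.
#' @param counts Symmetric non-negative matrix; defaults to zeros.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(region, resolution, counts = NULL) {
  stopifnot(resolution > 0, region$end > region$start)
  n <- n_bins(region, resolution)
  if (is.null(counts)) counts <- matrix(0, n, n)
  stopifnot(nrow(counts) == n, ncol(counts) == n)
  if (any(counts < 0)) stop("contact counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts)))) {
    stop("contact counts must be symmetric")
  }
  structure(list(region = region, resolution = resolution, counts = counts,
                 weights = NULL),
            class = "contact_matrix")
}

n_bins <- function(region, resolution) {
  as.integer(ceiling((region$end - region$start) / resolution))
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s:%s-%s @ %s bp (%d bins, %s contacts)\n",
              x$region$seq, format_bp(x$region$start),
              format_bp(x$region$end), format_bp(x$resolution),
              nrow(x$counts), format_bp(sum(x$counts[upper.tri(x$counts,
                                                               diag = TRUE)]))))
  invisible(x)
}

#' Masked (all-zero) bins of a contact matrix
#' @param m A `contact_matrix`.
#' @return Logical vector, `TRUE` for masked bins.
#' @export
masked_bins <- function(m) rowSums(m$counts) == 0

#' Bin cis PETs into a contact matrix
#'
#' Each PET whose two anchor midpoints both fall inside `region` increments
#' the symmetric pair of cells for its midpoint bins (the diagonal cell once
#' for within-bin PETs). PETs with a midpoint outside the region, or on
#' another sequence, are ignored.
#'
#' @param pets Cis PET data frame.
#' @inheritParams contact_matrix
#' @return A `contact_matrix`.
#' @export
bin_contacts <- function(pets, region, resolution) {
  m <- contact_matrix(region, resolution)
  if (nrow(pets) == 0) return(m)
  mid1 <- floor((pets$start1 + pets$end1) / 2)
  mid2 <- floor((pets$start2 + pets$end2) / 2)
  keep <- pets$seq1 == region$seq & pets$seq2 == region$seq &
    mid1 >= region$start & mid1 < region$end &
    mid2 >= region$start & mid2 < region$end
  if (!any(keep)) return(m)
  b1 <- floor((mid1[keep] - region$start) / resolution) + 1L
  b2 <- floor((mid2[keep] - region$start) / resolution) + 1L
  n <- nrow(m$counts)
  # linear index (col - 1) * n + row with col = min bin, row = max bin:
  # every pair lands in the lower triangle (diagonal for within-bin PETs)
  tab <- table(factor((pmin(b1, b2) - 1L) * n + pmax(b1, b2)))
  idx <- as.integer(names(tab))
  lower <- matrix(0, n, n)
  lower[idx] <- as.numeric(tab)
  counts <- lower + t(lower)
  diag(counts) <- diag(counts) / 2
  m$counts <- counts
  m
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Computes per-bin weights `w` such that `diag(w) %*% counts %*% diag(w)`
#' has unit row sums on unmasked bins, using the Knight-Ruiz inner-outer
#' Newton iteration for symmetric matrix scaling. All-zero rows are masked
#' before balancing and receive `NA` weights.
#'
#' @param m A `contact_matrix`.
#' @param tol Convergence tolerance on the row-sum residual (default 1e-6).
#' @param max_iter Maximum matrix-vector products (default 3000).
#' @return The `contact_matrix` with `weights` set (invisibly also in
#'   `$weights`).
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 3000) {
  mask <- masked_bins(m)
  A <- m$counts[!mask, !mask, drop = FALSE]
  w <- rep(NA_real_, nrow(m$counts))
  if (nrow(A) > 0) {
    x <- kr_scale(A, tol = tol, max_iter = max_iter)
    w[!mask] <- x
  }
  m$weights <- w
  m
}

# Knight & Ruiz symmetric scaling: inner CG loop inside an inexact Newton
# outer loop; returns x with (x * (A %*% x)) == 1 within tol.
kr_scale <- function(A, tol = 1e-6, max_iter = 3000, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  mvp <- 0
  while (rout > rt) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + k + 1
    if (mvp > max_iter) {
      stop(sprintf(
        "KR balancing did not converge in %d matrix-vector products (residual %.3g)",
        max_iter, sqrt(rout)))
    }
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

#' Balanced counts of a contact matrix
#'
#' `diag(w) %*% counts %*% diag(w)` with NA on masked rows/columns; raw
#' counts when the matrix has not been balanced.
#'
#' @param m A `contact_matrix`.
#' @return Numeric matrix.
#' @export
balanced_counts <- function(m) {
  if (is.null(m$weights)) return(m$counts)
  sweep(sweep(m$counts, 1, m$weights, `*`), 2, m$weights, `*`)
}

#' Observed-over-expected transform
#'
#' Divides each cell by the mean of its distance stratum (diagonal) over
#' unmasked bins, removing the genomic-distance decay so that compartment
#' structure becomes visible. Strata with zero mean map to 0 (not NaN) to
#' keep downstream correlations defined; masked bins propagate as NA.
#'
#' @param m A `contact_matrix`.
#' @param balanced Use balanced counts when weights are available
#'   (default TRUE).
#' @return Numeric matrix (NA on masked rows/columns).
#' @export
observed_over_expected <- function(m, balanced = TRUE) {
  mat <- if (balanced) balanced_counts(m) else m$counts
  mask <- masked_bins(m)
  n <- nrow(mat)
  oe <- matrix(NA_real_, n, n)
  un <- which(!mask)
  if (length(un) == 0) return(oe)
  d <- abs(row(mat) - col(mat))
  sub <- mat[un, un, drop = FALSE]
  dsub <- d[un, un, drop = FALSE]
  expected <- numeric(n)  # expected[k + 1] = stratum-k mean
  by_d <- tapply(as.vector(sub), as.vector(dsub), mean)
  expected[as.integer(names(by_d)) + 1L] <- by_d
  res <- matrix(0, length(un), length(un))
  nonzero <- expected > 0
  sel <- nonzero[dsub + 1L]
  res[sel] <- sub[sel] / expected[dsub[sel] + 1L]
  oe[un, un] <- res
  oe
}
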