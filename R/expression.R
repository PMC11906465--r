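#' Expression tables (gene x condition FPKM)
#'
#' Expression values are consumed as FPKM tables: TSV with first column
#' `gene_id` and remaining columns named `<condition>` or
#' `<condition>.repN` when replicates are present. An `expression_table` is
#' a list with `genes`, `conditions`, `values` (gene x column matrix), and
#' per-column `condition` / `replicate` assignments.
#'
#' @param path TSV file path.
#' @return An `expression_table`.
#' @export
read_fpkm_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_table(df[[1]], as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_fpkm_table
#' @param gene_ids Character vector of unique gene ids.
#' @param values Numeric matrix, one column per `<condition>[.repN]`.
#' @export
expression_table <- function(gene_ids, values) {
  stopifnot(!anyDuplicated(gene_ids), nrow(values) == length(gene_ids))
  if (any(values < 0)) stop("FPKM values must be non-negative")
  cn <- colnames(values)
  cond <- sub("\\.rep[0-9]+$", "", cn)
  rep_id <- ifelse(grepl("\\.rep[0-9]+$", cn),
                   sub("^.*\\.rep", "", cn), NA)
  rownames(values) <- gene_ids
  structure(list(genes = as.character(gene_ids),
                 conditions = unique(cond),
                 values = values, column_condition = cond,
                 column_replicate = rep_id),
            class = "expression_table")
}

#' @rdname read_fpkm_table
#' @param table An `expression_table` to write.
#' @export
write_fpkm_table <- function(table, path) {
  df <- data.frame(gene_id = table$genes, table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Paired two-sided t-test with explicit zero-variance conventions
#'
#' The statistic on the differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, p two-sided from the t distribution
#' with `n - 1` df. FPKM ties make zero-variance differences a real case,
#' so the conventions are explicit: all differences zero -> `(t = 0,
#' p = 1)` (no evidence of change); constant non-zero difference ->
#' `p = 0`.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 2`.
#' @return List with `t`, `p`, `n`.
#' @export
paired_t_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("paired vectors of unequal length")
  if (n < 2) stop("insufficient data: need n >= 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, n = n))
    return(list(t = sign(m) * Inf, p = 0, n = n))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), n = n)
}

cond_values <- function(table, cond) {
  sel <- table$column_condition == cond
  if (!any(sel)) stop("condition not in table: ", cond)
  table$values[, sel, drop = FALSE]
}

#' Expression change of a gene set between two conditions
#'
#' One paired t-test across the genes of a set: pairs are the per-gene FPKM
#' in the two conditions (replicates averaged per condition first). This
#' asks whether the set as a whole changed — the comparison applied to
#' vector-associated genes across treatment conditions.
#'
#' @param table An `expression_table`.
#' @param gene_set Character vector of gene ids (all present in the table).
#' @param cond_a,cond_b Condition labels present in the table.
#' @return List with `t`, `p`, `n` and `deltas` (named per-gene FPKM
#'   differences `cond_a - cond_b`).
#' @export
compare_gene_set <- function(table, gene_set, cond_a, cond_b) {
  missing <- setdiff(gene_set, table$genes)
  if (length(missing)) {
    stop("gene(s) not in table: ", paste(missing, collapse = ", "))
  }
  va <- rowMeans(cond_values(table, cond_a))[gene_set]
  vb <- rowMeans(cond_values(table, cond_b))[gene_set]
  res <- paired_t_test(va, vb)
  res$deltas <- va - vb
  res
}

#' Per-gene replicate-level condition contrast
#'
#' Two-sample unpaired equal-variance t-test on the replicate FPKMs of one
#' gene in two conditions, with the same zero-variance conventions as
#' [paired_t_test()] (identical replicate sets -> p = 1; zero pooled
#' variance with different means -> p = 0).
#'
#' @param table An `expression_table` with replicate columns.
#' @param gene_id One gene id.
#' @param cond_a,cond_b Condition labels.
#' @return List with `mean_a`, `mean_b`, `t`, `p`, `n_a`, `n_b`.
#' @export
per_gene_contrast <- function(table, gene_id, cond_a, cond_b) {
  if (!gene_id %in% table$genes) stop("gene not in table: ", gene_id)
  xa <- as.numeric(cond_values(table, cond_a)[gene_id, ])
  xb <- as.numeric(cond_values(table, cond_b)[gene_id, ])
  if (length(xa) < 2 || length(xb) < 2) {
    stop("insufficient data: need >= 2 replicates per condition")
  }
  ma <- mean(xa); mb <- mean(xb)
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    if (ma == mb) return(list(mean_a = ma, mean_b = mb, t = 0, p = 1,
                              n_a = length(xa), n_b = length(xb)))
    return(list(mean_a = ma, mean_b = mb, t = sign(ma - mb) * Inf, p = 0,
                n_a = length(xa), n_b = length(xb)))
  }
  tt <- stats::t.test(xa, xb, var.equal = TRUE)
  list(mean_a = ma, mean_b = mb, t = unname(tt$statistic),
       p = tt$p.value, n_a = length(xa), n_b = length(xb))
}
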