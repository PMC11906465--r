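#' Pipeline run configuration
#'
#' All stage thresholds, defaulting to the study settings so a bare run
#' reproduces them: span filters > 8,000 bp (host and vector-host channels)
#' and > 600 bp (intra-vector); anchor extensions 500 / 0 bp; high
#' confidence = more than 4 PETs; promoter extension 2,000 bp; vector map
#' at 500 bp with a 2,500 bp insulation window; host TADs at 25/50/100 kb;
#' compartments at 500 kb; significance 0.05; prominence 0.1.
#'
#' @param input_dir Directory holding the pipeline inputs (as written by
#'   [simulate_dataset()]).
#' @param output_dir Directory for stage outputs and the summary report.
#' @param seed Seed for the simulation stage when `simulate = TRUE`.
#' @param simulate Generate the inputs with [simulate_dataset()] first.
#' @param sim_config Optional [sim_config()] overriding the default
#'   simulation configuration (its seed is taken from `seed`).
#' @param resume Reuse existing simulated inputs in `input_dir` instead of
#'   regenerating them.
#' @param ... Threshold overrides (see defaults in the source).
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, output_dir, seed = 1, simulate = FALSE,
                       sim_config = NULL, resume = FALSE, ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, seed = seed,
    simulate = simulate, sim_config = sim_config, resume = resume,
    vector_name = "AdP53",
    min_span_host = 8000, min_span_vector = 600,
    ext_host = 500, ext_vector = 0,
    min_pet_count = 4, promoter_ext = 2000,
    vector_resolution = 500, vector_window = 2500,
    tad_resolutions = c(25000, 50000, 100000), tad_window_bins = 10,
    compartment_resolution = 500000,
    delta_min = 0.1, p_threshold = 0.05, top_pct = 1,
    expr_contrast = c("KOAd_T0", "KOAd_T9")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with `input_dir`, `output_dir` and optional
#'   threshold overrides (field names as in [run_config()]).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

read_pipeline_inputs <- function(config) {
  d <- config$input_dir
  need <- c("chrom.sizes", "pets_p53.bedpe", "pets_rnapii.bedpe",
            "genes.bed", "vector_genes.bed", "states.bed", "peaks.bed",
            "fpkm.tsv")
  missing <- need[!file.exists(file.path(d, need))]
  if (length(missing)) {
    stop("missing input file(s) in ", d, ": ",
         paste(missing, collapse = ", "))
  }
  genome <- read_chrom_sizes(file.path(d, "chrom.sizes"),
                             vector_name = config$vector_name)
  list(genome = genome,
       pets_p53 = read_pets_bedpe(file.path(d, "pets_p53.bedpe"), genome),
       pets_rnapii = read_pets_bedpe(file.path(d, "pets_rnapii.bedpe"),
                                     genome),
       genes = read_genes_bed(file.path(d, "genes.bed")),
       vector_genes = read_genes_bed(file.path(d, "vector_genes.bed")),
       states = read_states_bed(file.path(d, "states.bed")),
       peaks = read_peaks_bed(file.path(d, "peaks.bed")),
       fpkm = read_fpkm_table(file.path(d, "fpkm.tsv")))
}

gene_density_track <- function(genes, chrom, length, resolution) {
  nb <- ceiling(length / resolution)
  g <- genes[genes$seq == chrom, , drop = FALSE]
  dens <- numeric(nb)
  if (nrow(g)) {
    mid <- floor((g$start + g$end) / 2)
    tab <- table(factor(floor(mid / resolution) + 1, levels = seq_len(nb)))
    dens <- as.numeric(tab)
  }
  dens
}

host_structure <- function(pets, genome, genes, config) {
  host_chroms <- setdiff(genome$seqnames, genome$vector_name)
  tads <- list()
  compartments <- list()
  for (ch in host_chroms) {
    L <- seq_lengths(genome)[[ch]]
    region <- list(seq = ch, start = 0, end = L)
    ch_pets <- pets[pets$seq1 == ch & pets$seq2 == ch, , drop = FALSE]
    for (res in config$tad_resolutions) {
      m <- bin_contacts(ch_pets, region, res)
      tr <- insulation_score(m, config$tad_window_bins * res)
      b <- call_boundaries(tr, config$delta_min, config$p_threshold)
      sc <- tr$scores[match(b, tr$positions)]
      key <- sprintf("%s@%s", ch, format_bp(res))
      tads[[key]] <- list(chrom = ch, resolution = res,
                          tads = segment_region(b, region, sc),
                          insulation = tr)
    }
    mc <- bin_contacts(ch_pets, region, config$compartment_resolution)
    mc <- tryCatch(kr_balance(mc), error = function(e) mc)
    oe <- observed_over_expected(mc)
    dens <- gene_density_track(genes, ch, L, config$compartment_resolution)
    compartments[[ch]] <- compartment_eigenvector(
      oe, dens, config$compartment_resolution)
  }
  list(tads = tads, compartments = compartments)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) simulation of all inputs; PET
#' classification and per-channel loop clustering; vector contact-map
#' binning, insulation and block segmentation; host TAD calling at each
#' configured resolution and A/B compartment calling at 500 kb; the
#' vector-host gene-association procedure with chromatin-state composition
#' and top-percent baselines; and the associated-gene expression
#' comparison. Stage outputs are written under `config$output_dir` along
#' with `summary.json`; the run is deterministic (byte-identical summary)
#' for a fixed seed and configuration.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` (list; see the summary JSON for the main
#'   numbers), invisibly also written to disk.
#' @export
run_all <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(config$simulate)) {
    have <- file.exists(file.path(config$input_dir, "chrom.sizes"))
    if (!(isTRUE(config$resume) && have)) {
      scfg <- config$sim_config %||% sim_config(seed = config$seed)
      simulate_dataset(scfg, config$input_dir)
    }
  }
  inp <- read_pipeline_inputs(config)
  genome <- inp$genome

  # --- per-channel PET classification and loop clustering ---
  cls_p53 <- classify_pets(inp$pets_p53, genome)
  cls_pol <- classify_pets(inp$pets_rnapii, genome)
  vec_pets <- filter_pets_by_span(
    inp$pets_p53[cls_p53 == "intra_vector", , drop = FALSE],
    config$min_span_vector)
  vh_pets <- inp$pets_p53[cls_p53 == "vector_host", , drop = FALSE]
  host_pets <- inp$pets_rnapii[cls_pol == "intra_host_cis", , drop = FALSE]

  vec_loops <- cluster_pets(vec_pets, config$ext_vector, genome,
                            factor = "p53")
  vh_loops <- cluster_pets(vh_pets, config$ext_host, genome, factor = "p53")
  pol_loops <- cluster_pets(
    filter_pets_by_span(host_pets, config$min_span_host),
    config$ext_host, genome, factor = "RNAPII")
  pol_loops_hc <- filter_loops_by_count(pol_loops, config$min_pet_count)

  # --- vector contact map and block segmentation ---
  vregion <- list(seq = genome$vector_name, start = 0,
                  end = seq_lengths(genome)[[genome$vector_name]])
  vmat <- bin_contacts(vec_pets, vregion, config$vector_resolution)
  vtrack <- insulation_score(vmat, config$vector_window)
  vbound <- call_boundaries(vtrack, config$delta_min, config$p_threshold)
  vsegs <- segment_region(vbound, vregion,
                          vtrack$scores[match(vbound, vtrack$positions)])

  # --- host TADs and compartments ---
  host <- host_structure(host_pets, genome, inp$genes, config)

  # --- vector-host gene association ---
  vh_hc <- select_vector_host_loops(vh_loops, config$min_pet_count)
  p53_regions <- host_anchor_regions(vh_hc)
  pol_kept <- overlap_rnapii_loops(p53_regions, pol_loops_hc)
  pol_regions <- merge_intervals(rbind(anchor_df(pol_kept, 1),
                                       anchor_df(pol_kept, 2)))
  assoc <- associate_genes(p53_regions, pol_regions, inp$genes,
                           config$promoter_ext, genome)
  network <- build_network(rbind(vh_hc, pol_kept), inp$genes,
                           inp$vector_genes, config$promoter_ext, genome)
  vector_gene_hits <- inp$vector_genes$gene_id[
    overlaps_any(interval_df(inp$vector_genes$seq, inp$vector_genes$start,
                             inp$vector_genes$end),
                 anchor_df(vh_hc, 2))]
  composition <- list(
    vh_anchors = state_composition(p53_regions, inp$states),
    top_peaks = state_composition(
      top_percent_features(inp$peaks, config$top_pct)[, c("seq", "start",
                                                          "end")],
      inp$states),
    top_loop_anchors = state_composition(
      merge_intervals(rbind(
        anchor_df(top_percent_features(
          transform(pol_loops, score = pol_loops$pet_count),
          config$top_pct), 1),
        anchor_df(top_percent_features(
          transform(pol_loops, score = pol_loops$pet_count),
          config$top_pct), 2))),
      inp$states))

  # --- associated-gene expression comparison ---
  expr_test <- if (nrow(assoc) >= 2) {
    compare_gene_set(inp$fpkm, assoc$gene_id, config$expr_contrast[1],
                     config$expr_contrast[2])
  } else {
    list(t = NA_real_, p = NA_real_, n = nrow(assoc), deltas = numeric(0))
  }

  report <- structure(list(
    config = config,
    n_pets = list(p53 = nrow(inp$pets_p53), rnapii = nrow(inp$pets_rnapii)),
    pet_class_counts = list(p53 = table(cls_p53), rnapii = table(cls_pol)),
    vector_loops = vec_loops, vh_loops = vh_hc, rnapii_loops = pol_kept,
    vector_matrix = vmat, vector_insulation = vtrack,
    vector_boundaries = vbound, vector_segments = vsegs,
    tads = host$tads, compartments = host$compartments,
    p53_regions = p53_regions, associated_genes = assoc,
    vector_gene_hits = vector_gene_hits,
    network = network, composition = composition,
    expression = expr_test
  ), class = "pipeline_report")

  write_report(report)
  invisible(report)
}

write_report <- function(report) {
  out <- report$config$output_dir
  write_loops_bedpe(report$vh_loops, file.path(out, "loops_vector_host.bedpe"))
  write_loops_bedpe(report$rnapii_loops, file.path(out, "loops_rnapii.bedpe"))
  write_matrix_triples(report$vector_matrix,
                       file.path(out, "vector_matrix.tsv"))
  vr <- report$vector_insulation
  write_bedgraph(vr$region, vr$resolution, vr$scores,
                 file.path(out, "vector_insulation.bedgraph"),
                 positions = vr$positions - vr$resolution)
  utils::write.table(report$associated_genes,
                     file.path(out, "associated_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$network, file.path(out, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp_tab <- do.call(rbind, lapply(names(report$composition), function(k) {
    f <- report$composition[[k]]
    if (length(f) == 0) return(NULL)
    data.frame(set = k, state = names(f), fraction = as.numeric(f))
  }))
  utils::write.table(comp_tab, file.path(out, "state_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tad_counts <- lapply(report$tads, function(t) tad_summary(t$tads)$count)
  hq <- sum(report$composition$vh_anchors[
    c("Heterochromatin", "Quiescent")], na.rm = TRUE)
  summary <- list(
    seed = report$config$seed,
    n_pets = report$n_pets,
    n_vector_loops = nrow(report$vector_loops),
    n_vh_loops_high_confidence = nrow(report$vh_loops),
    n_rnapii_loops_retained = nrow(report$rnapii_loops),
    vector_segment_ends = report$vector_segments$end,
    vector_boundaries = report$vector_boundaries,
    tad_counts = tad_counts,
    compartment_fraction_A = lapply(report$compartments, function(tr) {
      mean(tr$labels == "A", na.rm = TRUE)
    }),
    n_associated_genes = nrow(report$associated_genes),
    associated_evidence_counts =
      as.list(table(report$associated_genes$evidence)),
    n_vector_genes_in_loops = length(report$vector_gene_hits),
    vh_anchor_het_quies_fraction = hq,
    n_network_edges = nrow(report$network),
    expression_t = report$expression$t,
    expression_p = report$expression$p
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Compare structural stability across pipeline runs
#'
#' For every pair of reports over the same host model: mean TAD-boundary
#' Jaccard across chromosomes and resolutions (slack 1 bin), mean
#' compartment-eigenvector Pearson r across chromosomes, and a paired
#' t-test across (chromosome x resolution) strata of TAD counts and mean
#' TAD sizes. High Jaccard / r and non-significant t-tests indicate stable
#' host architecture between conditions.
#'
#' @param reports List of >= 2 `pipeline_report` objects.
#' @param slack Boundary matching slack in bins (default 1).
#' @return Data frame, one row per report pair.
#' @export
compare_conditions <- function(reports, slack = 1) {
  stopifnot(length(reports) >= 2)
  keys <- names(reports) %||% paste0("run", seq_along(reports))
  base_keys <- names(reports[[1]]$tads)
  for (r in reports[-1]) {
    if (!identical(names(r$tads), base_keys) ||
        !identical(names(r$compartments), names(reports[[1]]$compartments))) {
      stop("reports cover different host models")
    }
  }
  pairs <- utils::combn(seq_along(reports), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(pi) {
    a <- reports[[pairs[1, pi]]]
    b <- reports[[pairs[2, pi]]]
    jac <- vapply(base_keys, function(k) {
      boundary_jaccard(a$tads[[k]]$tads, b$tads[[k]]$tads, slack = slack,
                       resolution = a$tads[[k]]$resolution)
    }, numeric(1))
    r_comp <- vapply(names(a$compartments), function(ch) {
      compartment_strength_correlation(a$compartments[[ch]],
                                       b$compartments[[ch]])
    }, numeric(1))
    counts_a <- vapply(base_keys, function(k) tad_summary(a$tads[[k]]$tads)$count,
                       numeric(1))
    counts_b <- vapply(base_keys, function(k) tad_summary(b$tads[[k]]$tads)$count,
                       numeric(1))
    sizes_a <- vapply(base_keys, function(k) mean(tad_summary(a$tads[[k]]$tads)$sizes),
                      numeric(1))
    sizes_b <- vapply(base_keys, function(k) mean(tad_summary(b$tads[[k]]$tads)$sizes),
                      numeric(1))
    data.frame(
      run_a = keys[pairs[1, pi]], run_b = keys[pairs[2, pi]],
      boundary_jaccard = mean(jac),
      compartment_r = mean(r_comp),
      tad_count_p = paired_t_test(counts_a, counts_b)$p,
      tad_size_p = paired_t_test(sizes_a, sizes_b)$p
    )
  })
  do.call(rbind, rows)
}
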