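## End-to-end pipeline: global graph -> per-cloud assembly -> clustering ->
## filtering -> outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown names are
#' rejected.
#'
#' @param ... name = value overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    k = 29L,
    min_coverage = 2,
    tip_len = NULL,              # default 2k, resolved at run time
    bulge_similarity = 0.8,
    max_mismatch_rate = 0.03,
    max_tip_len = NULL,          # default 2k
    rel_cov = 0.33,
    cov_ratio = 0.5,
    max_gap_edge_len = 150L,
    max_cycles = 10L,
    min_contig_len = 300L,
    offset_tol = 10L,
    min_barcodes = 1L,
    filter_multi = FALSE,
    barcode_dialect = "bx")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Assemble read clouds (in memory)
#'
#' The core pipeline: builds one global de Bruijn graph from all reads,
#' simplifies it, aligns each cloud back to the graph, simplifies the cloud
#' subgraph, extracts isoform paths with pair-link support, clusters paths
#' across barcodes, and applies the configured filters.
#'
#' @param reads data.frame with columns `pair_id`, `barcode`, `read1`,
#'   `read2` (as returned by [parse_barcoded_fastq()] or
#'   [simulate_clouds()]`$reads`).
#' @param cfg a [run_config()].
#' @return a list: `graph` (simplified global graph), `clusters` (filtered),
#'   `clusters_raw` (before filters), `reports` (filter reports), `log`
#'   (per-stage counts).
#' @export
assemble_clouds <- function(reads, cfg = run_config()) {
  k <- cfg$k
  tip_len <- cfg$tip_len %||% (2L * k)
  max_tip_len <- cfg$max_tip_len %||% (2L * k)
  log <- list(n_pairs = nrow(reads),
              n_barcodes = length(unique(reads$barcode)))

  graph <- build_graph(c(reads$read1, reads$read2), k = k)
  graph <- simplify_global(graph, cfg$min_coverage, tip_len,
                           cfg$bulge_similarity)
  log$n_edges <- length(graph$seq)
  if (length(graph$seq) == 0L) {
    return(list(graph = graph, clusters = empty_clusters(),
                clusters_raw = empty_clusters(),
                reports = list(), log = log))
  }
  idx <- kmer_index(graph)
  adj <- graph_adjacency(graph)

  paths <- list()
  n_unassembled <- 0L
  for (bc in unique(reads$barcode)) {
    rows <- reads[reads$barcode == bc, , drop = FALSE]
    cloud <- read_cloud(bc, rows$read1, rows$read2, rows$pair_id)
    aln <- align_cloud(graph, cloud, cfg$max_mismatch_rate, idx, adj)
    if (nrow(aln) == 0L) { n_unassembled <- n_unassembled + 1L; next }
    links <- build_pair_links(graph, aln)
    sub <- extract_subgraph(graph, aln, bc, adj)
    sub <- simplify_cloud(sub, max_tip_len, cfg$rel_cov, cfg$cov_ratio,
                          cfg$max_gap_edge_len, cfg$max_cycles, links)
    p <- extract_paths(sub, aln, cfg$min_contig_len, links)
    if (nrow(p) > 0L) paths[[length(paths) + 1L]] <- p
    else n_unassembled <- n_unassembled + 1L
  }
  paths <- if (length(paths)) do.call(rbind, paths) else empty_paths()
  log$n_paths <- nrow(paths)
  log$n_unassembled_clouds <- n_unassembled

  clusters <- cluster_paths(paths, graph, cfg$offset_tol)
  log$n_clusters <- nrow(clusters)
  clusters_raw <- clusters
  reports <- list()
  if (isTRUE(cfg$filter_multi)) {
    comp <- gene_components(graph)
    fm <- filter_multi_isoform_barcodes(clusters, comp, graph)
    clusters <- fm$clusters
    reports$multi_isoform <- fm$report
  }
  fb <- filter_min_barcodes(clusters, cfg$min_barcodes)
  clusters <- fb$clusters
  reports$min_barcodes <- fb$report
  log$n_clusters_kept <- nrow(clusters)

  list(graph = graph, clusters = clusters, clusters_raw = clusters_raw,
       reports = reports, log = log)
}

#' Run the full file-to-file pipeline
#'
#' Reads barcoded paired FASTQ, runs [assemble_clouds()], and writes the
#' assembly graph (GFA 1.0), cluster contigs (FASTA), the cluster/abundance
#' table (TSV), a filter report and a plain-text log into `out_dir`.
#'
#' @param reads1,reads2 input FASTQ paths.
#' @param out_dir output directory (created if missing).
#' @param cfg a [run_config()].
#' @return invisibly, the [assemble_clouds()] result.
#' @export
run_pipeline <- function(reads1, reads2, out_dir, cfg = run_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reads <- parse_barcoded_fastq(reads1, reads2, cfg$barcode_dialect)
  res <- assemble_clouds(reads, cfg)
  write_gfa(res$graph, file.path(out_dir, "assembly_graph.gfa"))
  write_contigs_fasta(res$clusters, file.path(out_dir, "contigs.fasta"))
  write_cluster_tsv(res$clusters, file.path(out_dir, "clusters.tsv"))
  rep_lines <- c(sprintf("stage\tcount"),
                 vapply(names(res$log), function(nm)
                   sprintf("%s\t%d", nm, res$log[[nm]]), character(1)))
  writeLines(rep_lines, file.path(out_dir, "run_log.tsv"))
  if (length(res$reports)) {
    rl <- unlist(lapply(names(res$reports), function(nm) {
      r <- res$reports[[nm]]
      sprintf("%s\t%d\t%d\t%d\t%d", nm, r$n_input_clusters, r$n_kept,
              r$n_removed_min_barcode, r$n_removed_multi_isoform)
    }))
    writeLines(c("filter\tn_input\tn_kept\tn_removed_min\tn_removed_multi",
                 rl), file.path(out_dir, "filter_report.tsv"))
  }
  ## serialized config for reproducibility
  writeLines(vapply(names(unclass(cfg)), function(nm)
    sprintf("%s\t%s", nm, paste(format(cfg[[nm]] %||% ""), collapse = ",")),
    character(1)), file.path(out_dir, "config.tsv"))
  invisible(res)
}
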