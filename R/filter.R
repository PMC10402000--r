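## Barcode-based cluster filtering.

new_filter_report <- function(n_input, n_kept, n_min = 0L, n_multi = 0L,
                              log = NULL) {
  structure(list(n_input_clusters = n_input, n_kept = n_kept,
                 n_removed_min_barcode = n_min,
                 n_removed_multi_isoform = n_multi,
                 log = log),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d in, %d kept (%d < min barcodes, %d multi-isoform)\n",
    x$n_input_clusters, x$n_kept, x$n_removed_min_barcode,
    x$n_removed_multi_isoform))
  invisible(x)
}

#' Filter clusters by barcode support
#'
#' Keeps clusters supported by at least `min_barcodes` distinct barcodes.
#'
#' @param clusters cluster data.frame from [cluster_paths()].
#' @param min_barcodes minimal abundance (>= 1).
#' @return list with elements `clusters` (kept) and `report` (a
#'   `filter_report`).
#' @export
filter_min_barcodes <- function(clusters, min_barcodes = 1L) {
  stopifnot(min_barcodes >= 1L)
  keep <- clusters$abundance >= min_barcodes
  list(clusters = clusters[keep, , drop = FALSE],
       report = new_filter_report(nrow(clusters), sum(keep),
                                  n_min = sum(!keep)))
}

## gene-locus proxy of each cluster: the weakly connected component of the
## global graph containing its walk
cluster_components <- function(clusters, components, graph) {
  vapply(clusters$walk, function(w) {
    components[min(w[1L], graph$rc[w[1L]])]
  }, integer(1))
}

#' Remove barcode support repeated within one gene locus
#'
#' A barcode assigned to two or more clusters of the same gene locus signals a
#' fragmented cloud or a barcode collision. For every such (barcode, locus)
#' pair the barcode's support is removed from all its clusters in that locus;
#' clusters whose abundance drops to zero are removed. The gene locus is
#' reference-free: the weakly connected component of the simplified global
#' assembly graph ([gene_components()]).
#'
#' @param clusters cluster data.frame.
#' @param components per-edge component ids from [gene_components()].
#' @param graph the simplified global `assembly_graph`.
#' @return list with elements `clusters` and `report`.
#' @export
filter_multi_isoform_barcodes <- function(clusters, components, graph) {
  n_in <- nrow(clusters)
  if (n_in == 0L) {
    return(list(clusters = clusters, report = new_filter_report(0L, 0L)))
  }
  comp <- cluster_components(clusters, components, graph)
  pairs <- do.call(rbind, lapply(seq_len(n_in), function(i) {
    bcs <- clusters$barcodes[[i]]
    if (length(bcs) == 0L) return(NULL)
    data.frame(cluster = i, barcode = bcs, comp = comp[i],
               stringsAsFactors = FALSE)
  }))
  key <- paste(pairs$barcode, pairs$comp)
  bad <- names(which(table(key) >= 2L))
  strip <- key %in% bad
  log <- pairs[strip, , drop = FALSE]
  for (i in unique(pairs$cluster[strip])) {
    gone <- pairs$barcode[strip & pairs$cluster == i]
    clusters$barcodes[[i]] <- setdiff(clusters$barcodes[[i]], gone)
    clusters$abundance[i] <- length(clusters$barcodes[[i]])
  }
  keep <- clusters$abundance > 0L
  list(clusters = clusters[keep, , drop = FALSE],
       report = new_filter_report(n_in, sum(keep), n_multi = sum(!keep),
                                  log = log))
}

#' Filter summary over barcode thresholds
#'
#' Tabulates how many clusters survive each minimum-barcode threshold, plain
#' and with the multi-isoform ("fixed") filter applied first.
#'
#' @param clusters cluster data.frame.
#' @param components per-edge component ids from [gene_components()].
#' @param graph the simplified global `assembly_graph`.
#' @param thresholds integer vector of minimum-barcode thresholds.
#' @return a data.frame with columns `min_barcodes`, `fixed`, `n_clusters`.
#' @export
filter_summary <- function(clusters, components, graph, thresholds = 1:4) {
  fixed <- filter_multi_isoform_barcodes(clusters, components, graph)$clusters
  do.call(rbind, lapply(thresholds, function(t) {
    rbind(
      data.frame(min_barcodes = t, fixed = FALSE,
                 n_clusters = nrow(filter_min_barcodes(clusters, t)$clusters)),
      data.frame(min_barcodes = t, fixed = TRUE,
                 n_clusters = nrow(filter_min_barcodes(fixed, t)$clusters)))
  }))
}
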