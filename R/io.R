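## Barcoded FASTQ input and tabular/FASTA output.

extract_barcodes <- function(headers, dialect) {
  switch(dialect,
    bx = {
      m <- regmatches(headers, regexpr("BX:Z:[ACGTN]+", headers))
      out <- rep(NA_character_, length(headers))
      out[grepl("BX:Z:[ACGTN]+", headers)] <- sub("^BX:Z:", "", m)
      out
    },
    suffix = {
      has <- grepl("#[ACGTN]+($| )", headers)
      out <- rep(NA_character_, length(headers))
      out[has] <- sub("^.*#([ACGTN]+)($| ).*$", "\\1",
                      headers[has])
      out
    },
    stop("unknown barcode dialect: ", dialect))
}

#' Parse barcoded paired FASTQ files
#'
#' Reads a matched pair of FASTQ files (optionally gzipped) and extracts the
#' per-pair barcode from the read headers, either from a `BX:Z:<barcode>`
#' comment (`dialect = "bx"`) or from a `<name>#<barcode>` suffix
#' (`dialect = "suffix"`). Records without a barcode are skipped with one
#' warning carrying their count.
#'
#' @param path1,path2 FASTQ files for mates 1 and 2, records in matched order.
#' @param dialect barcode dialect.
#' @return a data.frame: `pair_id`, `barcode`, `read1`, `read2`, sorted stably
#'   by barcode (reads grouped by cloud).
#' @export
parse_barcoded_fastq <- function(path1, path2, dialect = c("bx", "suffix")) {
  dialect <- match.arg(dialect)
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) {
    stop("mate files differ in record count: ", length(s1), " vs ", length(s2))
  }
  if (length(s1) == 0L) {
    warning("empty FASTQ input")
    return(data.frame(pair_id = character(0), barcode = character(0),
                      read1 = character(0), read2 = character(0),
                      stringsAsFactors = FALSE))
  }
  bc <- extract_barcodes(names(s1), dialect)
  miss <- is.na(bc)
  if (any(miss)) {
    warning(sum(miss), " read pair(s) without a barcode tag were skipped")
  }
  df <- data.frame(pair_id = sub(" .*$", "", sub("#.*$", "", names(s1))),
                   barcode = bc,
                   read1 = as.character(s1), read2 = as.character(s2),
                   stringsAsFactors = FALSE)[!miss, , drop = FALSE]
  df <- df[order(df$barcode), , drop = FALSE]   # group by cloud
  rownames(df) <- NULL
  df
}

#' Write cluster representatives as FASTA
#'
#' One record per cluster; headers carry the cluster id, abundance, number of
#' edges and length.
#'
#' @param clusters cluster data.frame.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_contigs_fasta <- function(clusters, file) {
  headers <- sprintf(">%s abundance=%d n_edges=%d length=%d",
                     clusters$cluster_id, clusters$abundance,
                     lengths(clusters$walk), nchar(clusters$sequence))
  writeLines(as.vector(rbind(headers, clusters$sequence)), file)
  invisible(file)
}

#' Write the cluster/abundance table as TSV
#'
#' @param clusters cluster data.frame.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_cluster_tsv <- function(clusters, file) {
  df <- data.frame(cluster_id = clusters$cluster_id,
                   abundance = clusters$abundance,
                   barcodes = vapply(clusters$barcodes, paste, character(1),
                                     collapse = ","),
                   edge_walk = vapply(clusters$walk, paste, character(1),
                                      collapse = ","),
                   start_offset = clusters$start_offset,
                   end_offset = clusters$end_offset,
                   length = nchar(clusters$sequence),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
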