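## Sequence-to-graph alignment by exact k-mer anchoring plus substitution-only
## threading across junctions. Indels are not modelled: short-read errors are
## substitution-dominated and threading stays linear in read length.

#' Exact k-mer index of an assembly graph
#'
#' Hash from every k-mer of every directed unitig to its (edge, 0-based offset)
#' location. In a compacted graph each k-mer occurs at exactly one location.
#'
#' @param graph an `assembly_graph`.
#' @return an environment mapping k-mer strings to `c(edge, offset)`.
#' @export
kmer_index <- function(graph) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  k <- graph$k
  for (e in seq_along(graph$seq)) {
    s <- graph$seq[e]
    nkm <- nchar(s) - k + 1L
    kms <- substr(rep(s, nkm), seq_len(nkm), seq_len(nkm) + k - 1L)
    for (i in seq_len(nkm)) idx[[kms[i]]] <- c(e, i - 1L)
  }
  idx
}

## longest suffix (rightmost-anchored) of the comparison a vs b within budget
hamming_suffix <- function(a, b, budget) {
  n <- nchar(a)
  if (n == 0L) return(list(len = 0L, mism = 0L))
  neq <- rev(utf8ToInt(a) != utf8ToInt(b))
  cm <- cumsum(neq)
  over <- which(cm > budget)
  if (length(over) == 0L) return(list(len = n, mism = cm[n]))
  cut <- over[1L] - 1L
  list(len = cut, mism = if (cut > 0L) cm[cut] else 0L)
}

## extend rightwards from read position q aligned to edge position p (both
## 1-based, guaranteed by the caller to start an exact anchor match)
thread_right <- function(g, adj, read, e, p, q, budget) {
  k <- g$k
  L <- nchar(read)
  walk <- e
  mism <- 0L
  repeat {
    elen <- nchar(g$seq[e])
    take <- min(L - q + 1L, elen - p + 1L)
    hp <- hamming_prefix(substr(read, q, q + take - 1L),
                         substr(g$seq[e], p, p + take - 1L), budget - mism)
    mism <- mism + hp$mism
    q <- q + hp$len
    p <- p + hp$len
    if (hp$len < take || q > L) {
      return(list(walk = walk, q_end = q - 1L, p_end = p - 1L, mism = mism))
    }
    ## read continues past this edge: pick a successor
    succ <- adj$out[[e]]
    if (length(succ) == 0L) {
      return(list(walk = walk, q_end = q - 1L, p_end = p - 1L, mism = mism))
    }
    if (length(succ) == 1L) {
      e <- succ
    } else {
      nb <- substr(g$seq[succ], k, k)
      hit <- succ[nb == substr(read, q, q)]
      if (length(hit) != 1L) {
        return(list(walk = walk, q_end = q - 1L, p_end = p - 1L, mism = mism))
      }
      e <- hit
    }
    walk <- c(walk, e)
    p <- k
  }
}

## extend leftwards from just before read position q / edge position p
thread_left <- function(g, adj, read, e, p, q, budget) {
  k <- g$k
  walk <- e
  mism <- 0L
  q <- q - 1L
  p <- p - 1L
  repeat {
    take <- min(q, p)
    hp <- hamming_suffix(substr(read, q - take + 1L, q),
                         substr(g$seq[e], p - take + 1L, p), budget - mism)
    mism <- mism + hp$mism
    q <- q - hp$len
    p <- p - hp$len
    if (hp$len < take || q < 1L) {
      return(list(walk = walk, q_start = q + 1L, p_start = p + 1L, mism = mism))
    }
    pred <- adj$in_[[e]]
    if (length(pred) == 0L) {
      return(list(walk = walk, q_start = q + 1L, p_start = p + 1L, mism = mism))
    }
    plen <- nchar(g$seq[pred])
    if (length(pred) == 1L) {
      e <- pred
    } else {
      nb <- substr(g$seq[pred], plen - k + 1L, plen - k + 1L)
      hit <- which(nb == substr(read, q, q))
      if (length(hit) != 1L) {
        return(list(walk = walk, q_start = q + 1L, p_start = p + 1L, mism = mism))
      }
      e <- pred[hit]
    }
    walk <- c(e, walk)
    p <- nchar(g$seq[e]) - k + 1L
  }
}

align_one_orientation <- function(g, adj, idx, rd, budget, max_anchors = 5L) {
  k <- g$k
  L <- nchar(rd)
  best <- NULL
  tried <- character(0)
  n_tried <- 0L
  for (i in seq_len(L - k + 1L)) {
    km <- substr(rd, i, i + k - 1L)
    hit <- idx[[km]]
    if (is.null(hit)) next
    placement <- paste(hit[1L], hit[2L] - (i - 1L))
    if (placement %in% tried) next
    tried <- c(tried, placement)
    n_tried <- n_tried + 1L
    e <- hit[1L]
    p <- hit[2L] + 1L
    right <- thread_right(g, adj, rd, e, p, i, budget)
    left <- thread_left(g, adj, rd, e, p, i, budget - right$mism)
    walk <- c(left$walk[-length(left$walk)], right$walk)
    cand <- list(walk = walk,
                 start_offset = left$p_start - 1L,
                 end_offset = right$p_end,
                 qstart = left$q_start, qend = right$q_end,
                 mismatches = left$mism + right$mism)
    if (is.null(best) || better_alignment(cand, best)) best <- cand
    if (cand$qstart == 1L && cand$qend == L) break
    if (n_tried >= max_anchors) break
  }
  best
}

better_alignment <- function(a, b) {
  la <- a$qend - a$qstart
  lb <- b$qend - b$qstart
  if (la != lb) return(la > lb)
  if (a$mismatches != b$mismatches) return(a$mismatches < b$mismatches)
  # lexicographically smallest edge-id walk
  cmp <- paste(a$walk, collapse = ",") < paste(b$walk, collapse = ",")
  isTRUE(cmp)
}

#' Align one read to the assembly graph
#'
#' Finds an exact k-mer anchor and threads the read left and right along the
#' graph, allowing substitutions up to `max_mismatch_rate` of the read length.
#' At a junction with several continuations the extension proceeds only when
#' exactly one successor matches the next read base; otherwise the alignment is
#' truncated at the junction. Both orientations are tried and the longest
#' alignment is kept (ties: fewer mismatches, then smallest edge-id walk).
#'
#' @param graph an `assembly_graph`.
#' @param read DNA string of length >= k.
#' @param max_mismatch_rate maximal substitution fraction (default 0.03).
#' @param index,adj optional precomputed [kmer_index()] and adjacency (reused
#'   across many calls by [align_cloud()]).
#' @return a one-row data.frame (columns `walk` (list), `start_offset`,
#'   `end_offset`, `orientation`, `mismatches`, `qstart`, `qend`, `read_len`)
#'   or `NULL` when the read has no exact k-mer anchor.
#' @export
align_read <- function(graph, read, max_mismatch_rate = 0.03,
                       index = NULL, adj = NULL, read_rc = NULL) {
  if (is.null(index)) index <- kmer_index(graph)
  if (is.null(adj)) adj <- graph_adjacency(graph)
  a <- align_read_impl(graph, read, max_mismatch_rate, index, adj, read_rc)
  if (is.null(a)) return(NULL)
  data.frame(walk = I(list(a$walk)), start_offset = a$start_offset,
             end_offset = a$end_offset, orientation = a$orientation,
             mismatches = a$mismatches, qstart = a$qstart, qend = a$qend,
             read_len = nchar(read), stringsAsFactors = FALSE)
}

align_read_impl <- function(graph, read, max_mismatch_rate, index, adj,
                            read_rc = NULL) {
  if (nchar(read) < graph$k) return(NULL)
  budget <- as.integer(ceiling(max_mismatch_rate * nchar(read)))
  fwd <- align_one_orientation(graph, adj, index, read, budget)
  rev <- align_one_orientation(graph, adj, index, read_rc %||% rc_dna(read),
                               budget)
  pick <- if (is.null(fwd)) {
    if (is.null(rev)) return(NULL) else list(rev, "-")
  } else if (is.null(rev) || better_alignment(fwd, rev) ||
             !better_alignment(rev, fwd)) {
    list(fwd, "+")                     # forward preferred on exact ties
  } else list(rev, "-")
  a <- pick[[1L]]
  a$orientation <- pick[[2L]]
  a
}

#' Construct a read cloud
#'
#' @param barcode barcode string (non-empty).
#' @param read1,read2 character vectors of mate sequences.
#' @param pair_id optional pair identifiers (default sequential).
#' @return a `read_cloud` object.
#' @export
read_cloud <- function(barcode, read1, read2, pair_id = NULL) {
  stopifnot(nzchar(barcode), length(read1) == length(read2))
  if (is.null(pair_id)) pair_id <- paste0(barcode, ":", seq_along(read1))
  structure(list(barcode = barcode,
                 pairs = data.frame(pair_id = as.character(pair_id),
                                    read1 = read1, read2 = read2,
                                    stringsAsFactors = FALSE)),
            class = "read_cloud")
}

#' Align every read of a cloud to the graph
#'
#' Aligns both mates of every pair independently, keeping pair linkage through
#' a shared `pair_id`. Unaligned reads are dropped (a normal outcome for sparse
#' clouds); the result is deterministic for a fixed input order.
#'
#' @param graph an `assembly_graph`.
#' @param cloud a [read_cloud()].
#' @inheritParams align_read
#' @return a data.frame of alignments, with `barcode`, `pair_id`, `mate`
#'   columns added; zero rows when nothing aligns.
#' @export
align_cloud <- function(graph, cloud, max_mismatch_rate = 0.03,
                        index = NULL, adj = NULL) {
  if (is.null(index)) index <- kmer_index(graph)
  if (is.null(adj)) adj <- graph_adjacency(graph)
  np <- nrow(cloud$pairs)
  rc1 <- rc_dna(cloud$pairs$read1)
  rc2 <- rc_dna(cloud$pairs$read2)
  walk <- vector("list", 2L * np)
  so <- eo <- mm <- qs <- qe <- rl <- mt <- integer(2L * np)
  ori <- pid <- character(2L * np)
  n <- 0L
  for (i in seq_len(np)) {
    for (mate in 1:2) {
      rd <- if (mate == 1L) cloud$pairs$read1[i] else cloud$pairs$read2[i]
      rdrc <- if (mate == 1L) rc1[i] else rc2[i]
      a <- align_read_impl(graph, rd, max_mismatch_rate, index, adj, rdrc)
      if (is.null(a)) next
      n <- n + 1L
      walk[[n]] <- a$walk
      so[n] <- a$start_offset; eo[n] <- a$end_offset
      mm[n] <- a$mismatches; qs[n] <- a$qstart; qe[n] <- a$qend
      rl[n] <- nchar(rd); mt[n] <- mate
      ori[n] <- a$orientation; pid[n] <- cloud$pairs$pair_id[i]
    }
  }
  if (n == 0L) return(empty_alignments(cloud$barcode))
  idx1 <- seq_len(n)
  data.frame(walk = I(walk[idx1]), start_offset = so[idx1],
             end_offset = eo[idx1], orientation = ori[idx1],
             mismatches = mm[idx1], qstart = qs[idx1], qend = qe[idx1],
             read_len = rl[idx1], barcode = cloud$barcode, pair_id = pid[idx1],
             mate = mt[idx1], stringsAsFactors = FALSE)
}

empty_alignments <- function(barcode = character(0)) {
  data.frame(walk = I(list()), start_offset = integer(0),
             end_offset = integer(0), orientation = character(0),
             mismatches = integer(0), qstart = integer(0), qend = integer(0),
             read_len = integer(0),
             barcode = character(0), pair_id = character(0), mate = integer(0),
             stringsAsFactors = FALSE)
}
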