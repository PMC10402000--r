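## Isoform path extraction over a simplified cloud subgraph, using
## cloud-restricted paired-end linkage, followed by clustering of equivalent
## paths across barcodes.

## pair-links: list of canonical-edge-id sets, one per read pair with both
## mates aligned; each element is list(m1 = edges of mate 1, m2 = edges of
## mate 2)
build_pair_links <- function(graph, alignments) {
  if (nrow(alignments) == 0L) return(list())
  can <- function(w) unique(pmin(w, graph$rc[w]))
  links <- list()
  for (pid in unique(alignments$pair_id)) {
    rows <- which(alignments$pair_id == pid)
    m1 <- rows[alignments$mate[rows] == 1L]
    m2 <- rows[alignments$mate[rows] == 2L]
    if (length(m1) == 0L || length(m2) == 0L) next
    links[[length(links) + 1L]] <-
      list(m1 = can(unlist(alignments$walk[m1])),
           m2 = can(unlist(alignments$walk[m2])))
  }
  links
}

## pair-link support for extending a path (canonical edge set `pset`) into the
## branch with canonical id `b`. Only links not yet fully contained in the
## path contribute: a satisfied link must stop voting or short-repeat
## traversals can never terminate.
link_support <- function(links, pset, b) {
  n <- 0L
  for (ln in links) {
    if (all(c(ln$m1, ln$m2) %in% pset)) next
    if ((b %in% ln$m2 && any(ln$m1 %in% pset)) ||
        (b %in% ln$m1 && any(ln$m2 %in% pset))) n <- n + 1L
  }
  n
}

choose_branch <- function(graph, links, path, branches) {
  if (length(branches) <= 1L) return(branches)
  pset <- unique(pmin(path, graph$rc[path]))
  bc <- pmin(branches, graph$rc[branches])
  sup <- vapply(bc, function(b) link_support(links, pset, b), integer(1))
  top <- max(sup)
  hit <- branches[sup == top]
  if (top == 0L || length(hit) != 1L) return(integer(0))  # unresolved: stop
  hit
}

#' Extract isoform paths from a simplified cloud subgraph
#'
#' Seeds one path per unused longest member edge and extends it in both
#' directions. At a junction with two or more subgraph branches the branch
#' supported by strictly more pair-links (pairs with one mate on the current
#' path and the other on the branch, not counting links already satisfied by
#' the path) is taken; with no strict majority, extension stops. Consumed
#' edges are marked and seeding repeats until all member edges are used.
#' Terminal offsets come from the extreme alignment positions on the terminal
#' edges; paths spelling fewer than `min_contig_len` bases are dropped.
#'
#' @param sub a simplified `cloud_subgraph`.
#' @param cloud_alignments the cloud's alignment data.frame (pair linkage).
#' @param min_contig_len minimal spelled length to report (default 300).
#' @param links optional precomputed pair links (else derived from
#'   `cloud_alignments`).
#' @return a data.frame of isoform paths: `barcode`, `walk` (list of directed
#'   edge ids), `start_offset`, `end_offset`, `sequence`.
#' @export
extract_paths <- function(sub, cloud_alignments, min_contig_len = 300L,
                          links = NULL) {
  g <- sub$graph
  if (nrow(sub$stats) == 0L) return(empty_paths())
  if (is.null(links)) links <- build_pair_links(g, cloud_alignments)
  sa <- sub_adjacency(sub)
  members <- sub$stats$edge
  used <- logical(length(members))
  lens <- nchar(g$seq[members])
  max_steps <- 2L * length(members) + 4L
  out <- list()
  repeat {
    free <- which(!used)
    if (length(free) == 0L) break
    seed <- free[order(-lens[free], members[free])][1L]
    walk <- members[seed]
    ## a branch equal to the reverse complement of the current or previous
    ## edge is a hairpin U-turn through an rc-palindromic unitig, never a
    ## transcript continuation
    no_uturn <- function(branches, recent) {
      branches[!(branches %in% g$rc[recent])]
    }
    repeat {                                    # rightwards
      nlast <- length(walk)
      br <- no_uturn(sa$out[[walk[nlast]]],
                     walk[max(1L, nlast - 1L):nlast])
      br <- choose_branch(g, links, walk, br)
      if (length(br) != 1L || length(walk) >= max_steps) break
      walk <- c(walk, br)
    }
    repeat {                                    # leftwards
      br <- no_uturn(sa$in_[[walk[1L]]], walk[1:min(2L, length(walk))])
      br <- choose_branch(g, links, walk, br)
      if (length(br) != 1L || length(walk) >= max_steps) break
      walk <- c(br, walk)
    }
    used[match(unique(pmin(walk, g$rc[walk])), members)] <- TRUE
    off <- terminal_offsets(sub, walk)
    seqs <- spell_path(g, walk, off[1L], off[2L])
    if (nchar(seqs) >= min_contig_len) {
      out[[length(out) + 1L]] <- data.frame(
        barcode = sub$barcode, walk = I(list(walk)),
        start_offset = off[1L], end_offset = off[2L],
        sequence = seqs, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_paths())
  do.call(rbind, out)
}

empty_paths <- function() {
  data.frame(barcode = character(0), walk = I(list()),
             start_offset = integer(0), end_offset = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

## leftmost extent on the first edge / rightmost on the last, mirrored when an
## edge is traversed in its non-canonical orientation
terminal_offsets <- function(sub, walk) {
  g <- sub$graph
  stat_of <- function(e) sub$stats[match(min(e, g$rc[e]), sub$stats$edge), ]
  first <- walk[1L]; last <- walk[length(walk)]
  sf <- stat_of(first); sl <- stat_of(last)
  start <- if (first <= g$rc[first]) sf$leftmost
           else nchar(g$seq[first]) - sf$rightmost
  end <- if (last <= g$rc[last]) sl$rightmost
         else nchar(g$seq[last]) - sl$leftmost
  c(as.integer(start), as.integer(end))
}

#' Cluster isoform paths across barcodes
#'
#' Greedy representative-based clustering: a path joins the first cluster
#' whose representative has an identical edge walk (or its reverse-complement
#' twin walk) and terminal offsets within `offset_tol`; otherwise it founds a
#' new cluster. A walk and its twin are one isoform; the representative
#' sequence reported is the lexicographically smaller of the spelled sequence
#' and its reverse complement. Abundance is the number of distinct supporting
#' barcodes.
#'
#' @param paths data.frame from [extract_paths()] (possibly pooled over
#'   clouds).
#' @param graph the parent `assembly_graph`.
#' @param offset_tol terminal-offset tolerance in bp (default 10).
#' @return a data.frame of clusters: `cluster_id`, `walk`, `start_offset`,
#'   `end_offset`, `sequence`, `barcodes` (list), `abundance`, `n_members`.
#' @export
cluster_paths <- function(paths, graph, offset_tol = 10L) {
  if (nrow(paths) == 0L) return(empty_clusters())
  g <- graph
  n <- nrow(paths)
  fwd_key <- vapply(paths$walk, paste, character(1), collapse = ",")
  rev_key <- vapply(paths$walk, function(w)
    paste(rev(g$rc[w]), collapse = ","), character(1))
  canon_key <- ifelse(cmp_le(fwd_key, rev_key), fwd_key, rev_key)
  ord <- order(canon_key, -nchar(paths$sequence), paths$barcode,
               paths$start_offset, paths$end_offset)
  reps <- list()     # per cluster: walk, start, end, key
  assign_to <- integer(n)
  ## paths can only co-cluster within one canonical walk key, so the greedy
  ## scan is restricted to the clusters of the current key group
  for (grp in split(ord, canon_key[ord])) {
    group_reps <- integer(0)
    for (i in grp) {
      w <- paths$walk[[i]]
      s <- paths$start_offset[i]; e <- paths$end_offset[i]
      placed <- FALSE
      for (ci in group_reps) {
        r <- reps[[ci]]
        if (identical(fwd_key[i], r$key)) {
          if (abs(s - r$start) <= offset_tol && abs(e - r$end) <= offset_tol) {
            assign_to[i] <- ci; placed <- TRUE; break
          }
        } else if (identical(rev_key[i], r$key)) {
          ## this path's twin orientation: offsets mirror through edge lengths
          s2 <- nchar(g$seq[w[length(w)]]) - e
          e2 <- nchar(g$seq[w[1L]]) - s
          if (abs(s2 - r$start) <= offset_tol &&
              abs(e2 - r$end) <= offset_tol) {
            assign_to[i] <- ci; placed <- TRUE; break
          }
        }
      }
      if (!placed) {
        reps[[length(reps) + 1L]] <- list(walk = w, start = s, end = e,
                                          key = fwd_key[i], founder = i)
        assign_to[i] <- length(reps)
        group_reps <- c(group_reps, length(reps))
      }
    }
  }
  out <- lapply(seq_along(reps), function(ci) {
    r <- reps[[ci]]
    memb <- which(assign_to == ci)
    bcs <- sort(unique(paths$barcode[memb]))
    sq <- paths$sequence[r$founder]
    sqr <- rc_dna(sq)
    data.frame(cluster_id = NA_character_, walk = I(list(r$walk)),
               start_offset = r$start, end_offset = r$end,
               sequence = if (cmp_le(sq, sqr)) sq else sqr,
               barcodes = I(list(bcs)), abundance = length(bcs),
               n_members = length(memb), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(-res$abundance, -nchar(res$sequence),
                   vapply(res$walk, paste, character(1), collapse = ",")), ,
             drop = FALSE]
  res$cluster_id <- sprintf("cluster_%d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

empty_clusters <- function() {
  data.frame(cluster_id = character(0), walk = I(list()),
             start_offset = integer(0), end_offset = integer(0),
             sequence = character(0), barcodes = I(list()),
             abundance = integer(0), n_members = integer(0),
             stringsAsFactors = FALSE)
}
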