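## Compacted double-stranded de Bruijn graph.
##
## Representation: directed unitig edges stored in parallel vectors. Every edge
## has a reverse-complement twin (possibly itself, for rc-palindromic unitigs);
## twins always carry identical coverage. Two edges e -> f are adjacent iff the
## (k-1)-suffix of e equals the (k-1)-prefix of f. Junction identity IS the
## (k-1)-mer string, so adjacency never needs an explicit node table.

#' Construct an assembly graph object
#'
#' Low-level constructor; most users call [build_graph()].
#'
#' @param k k-mer size (odd integer).
#' @param seq character vector of directed unitig sequences.
#' @param cov numeric vector of mean k-mer coverages (one per edge).
#' @param rc integer vector: index of each edge's reverse-complement twin.
#' @return an `assembly_graph` object.
#' @keywords internal
new_assembly_graph <- function(k, seq = character(0), cov = numeric(0),
                               rc = integer(0)) {
  structure(list(k = as.integer(k), seq = as.character(seq),
                 cov = as.numeric(cov), rc = as.integer(rc)),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  nc <- sum(seq_along(x$seq) <= x$rc)
  cat(sprintf(
    "assembly_graph: k=%d, %d unitigs (%d canonical), %d bp total\n",
    x$k, length(x$seq), nc,
    if (length(x$seq)) sum(nchar(x$seq[seq_along(x$seq) <= x$rc])) else 0L))
  invisible(x)
}

## number of k-mers per edge
edge_nkmer <- function(g) nchar(g$seq) - g$k + 1L

## indices of canonical representatives (id <= twin id)
canonical_edges <- function(g) which(seq_along(g$seq) <= g$rc)

canonical_id <- function(g, e) pmin(e, g$rc[e])

## adjacency lists of the directed graph: out[[e]] / in_[[e]] are integer
## vectors of successor / predecessor edge ids
graph_adjacency <- function(g) {
  n <- length(g$seq)
  if (n == 0L) return(list(out = list(), in_ = list()))
  k <- g$k
  lens <- nchar(g$seq)
  pref <- substr(g$seq, 1L, k - 1L)
  suf <- substr(g$seq, lens - k + 2L, lens)
  nodes <- unique(c(pref, suf))
  pn <- match(pref, nodes)
  sn <- match(suf, nodes)
  by_pref <- split(seq_len(n), pn)
  out <- vector("list", n)
  in_ <- vector("list", n)
  empty <- integer(0)
  for (e in seq_len(n)) out[[e]] <- empty
  for (e in seq_len(n)) in_[[e]] <- empty
  key <- as.character(sn)
  for (e in seq_len(n)) {
    succ <- by_pref[[key[e]]]
    if (!is.null(succ)) out[[e]] <- succ
  }
  by_suf <- split(seq_len(n), sn)
  keyp <- as.character(pn)
  for (e in seq_len(n)) {
    pred <- by_suf[[keyp[e]]]
    if (!is.null(pred)) in_[[e]] <- pred
  }
  list(out = out, in_ = in_)
}

## Merge maximal non-branching chains of edges into single unitigs.
## Deterministic; keeps reverse-complement twin pairing consistent.
compact_graph <- function(g) {
  n <- length(g$seq)
  if (n == 0L) return(g)
  k <- g$k
  lens <- nchar(g$seq)
  pref <- substr(g$seq, 1L, k - 1L)
  suf <- substr(g$seq, lens - k + 2L, lens)
  nodes <- unique(c(pref, suf))
  pn <- match(pref, nodes)
  sn <- match(suf, nodes)
  nn <- length(nodes)
  indeg <- tabulate(sn, nn)
  outdeg <- tabulate(pn, nn)
  outedge <- integer(nn); outedge[pn] <- seq_len(n)   # valid where outdeg == 1
  inedge <- integer(nn); inedge[sn] <- seq_len(n)     # valid where indeg == 1

  thru <- indeg == 1L & outdeg == 1L                  # mergeable junctions
  nxt <- ifelse(thru[sn], outedge[sn], NA_integer_)
  prv <- ifelse(thru[pn], inedge[pn], NA_integer_)
  nxt[!is.na(nxt) & nxt == seq_len(n)] <- NA_integer_ # self-loop guard
  prv[!is.na(prv) & prv == seq_len(n)] <- NA_integer_

  visited <- logical(n)
  chains <- list()
  chain_of <- integer(n)

  walk_chain <- function(s) {
    ch <- integer(0)
    e <- s
    repeat {
      ch <- c(ch, e)
      visited[e] <<- TRUE
      f <- nxt[e]
      if (is.na(f) || visited[f]) break
      e <- f
    }
    ch
  }

  for (s in which(is.na(prv))) {
    if (visited[s]) next
    chains[[length(chains) + 1L]] <- walk_chain(s)
  }
  ## leftovers are pure cycles; break each deterministically at the edge with
  ## the smallest canonical sequence, and its rc cycle at the mirrored spot
  if (!all(visited)) {
    canon <- canonical_dna(g$seq)
    repeat {
      left <- which(!visited)
      if (length(left) == 0L) break
      st <- left[order(canon[left], left)][1L]
      ch <- walk_chain(st)
      chains[[length(chains) + 1L]] <- ch
      rc_last <- g$rc[ch[length(ch)]]
      if (!visited[rc_last]) {
        chains[[length(chains) + 1L]] <- walk_chain(rc_last)
      }
    }
  }

  m <- length(chains)
  newseq <- character(m)
  newcov <- numeric(m)
  nk <- edge_nkmer(g)
  for (i in seq_len(m)) {
    ch <- chains[[i]]
    chain_of[ch] <- i
    if (length(ch) == 1L) {
      newseq[i] <- g$seq[ch]
    } else {
      newseq[i] <- paste0(g$seq[ch[1L]],
                          paste(substr(g$seq[ch[-1L]], k, lens[ch[-1L]]),
                                collapse = ""))
    }
    w <- nk[ch]
    newcov[i] <- sum(g$cov[ch] * w) / sum(w)
  }
  newrc <- integer(m)
  for (i in seq_len(m)) {
    ch <- chains[[i]]
    newrc[i] <- chain_of[g$rc[ch[length(ch)]]]
  }
  out <- new_assembly_graph(k, newseq, newcov, newrc)
  stopifnot(identical(rc_dna(out$seq[out$rc]), out$seq))
  out
}

## drop a set of directed edge ids (the rc twins are added automatically),
## keeping twin indexing consistent
drop_edges <- function(g, drop) {
  if (length(drop) == 0L) return(g)
  drop <- unique(c(drop, g$rc[drop]))
  keep <- setdiff(seq_along(g$seq), drop)
  remap <- integer(length(g$seq))
  remap[keep] <- seq_along(keep)
  new_assembly_graph(g$k, g$seq[keep], g$cov[keep], remap[g$rc[keep]])
}

#' Build a compacted de Bruijn graph from reads
#'
#' Constructs the double-stranded compacted de Bruijn graph of the multiset of
#' canonical k-mers of `reads`. Reads containing non-ACGT characters are split
#' at those characters and the fragments shorter than `k` are discarded, so
#' ambiguous bases never seed k-mers. Per-unitig coverage is the mean
#' multiplicity of its constituent k-mers.
#'
#' @param reads character vector of DNA reads.
#' @param k odd k-mer size (>= 11). Odd k rules out reverse-complement
#'   palindromic k-mers, which would collide with their own twin.
#' @return an `assembly_graph`.
#' @examples
#' g <- build_graph("AACCGAGTTTACCGTAGACCAGTTA", k = 11)
#' g
#' @export
build_graph <- function(reads, k = 29L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 11L) stop("k must be >= 11")
  frags <- unlist(strsplit(toupper(as.character(reads)), "[^ACGT]+"))
  frags <- frags[!is.na(frags) & nchar(frags) >= k]
  if (length(frags) == 0L) {
    warning("no read fragment of length >= k; returning empty graph")
    return(new_assembly_graph(k))
  }
  nkm <- nchar(frags) - k + 1L
  starts <- unlist(lapply(nkm, seq_len))
  kmers <- substr(rep(frags, nkm), starts, starts + k - 1L)
  canon <- canonical_dna(kmers)
  uniq <- unique(canon)
  cnt <- tabulate(match(canon, uniq), length(uniq))
  rcu <- rc_dna(uniq)
  nu <- length(uniq)
  g <- new_assembly_graph(k,
                          seq = c(uniq, rcu),
                          cov = c(cnt, cnt),
                          rc = c(seq_len(nu) + nu, seq_len(nu)))
  compact_graph(g)
}

#' Global graph simplification
#'
#' Prunes obvious sequencing-error structure from the global graph:
#' edges with coverage below `min_coverage` are removed outright; short
#' low-covered dead-end/dead-start edges (tips) are clipped; and two-path
#' bulges (two edge-disjoint parallel walks of at most two edges between the
#' same junctions, with spelled-length ratio at least `bulge_similarity`)
#' lose their lower-covered side. Both tip clipping and bulge popping require
#' the removed side to be *low-covered relative to its alternative*
#' (`rel_cov`): genuine alternative-splicing bubbles carry comparable
#' coverage on both sides and must survive, while error-derived structure
#' sits orders of magnitude below the true path at any realistic depth. Tips
#' and bulges are processed to a fixpoint, re-compacting unitigs after each
#' pass. Removal is always applied symmetrically to reverse-complement twins,
#' and the procedure is idempotent on an already simplified graph.
#'
#' @param graph an `assembly_graph`.
#' @param min_coverage coverage threshold for outright pruning.
#' @param tip_len maximal tip length in bp (default 2k).
#' @param bulge_similarity minimal spelled-length ratio of the two sides of a
#'   bulge, in (0, 1].
#' @param rel_cov relative-coverage threshold: a tip (or bulge side) is
#'   removed only when its coverage is below `rel_cov` times its
#'   continuation's (or the parallel walk's) coverage.
#' @return the simplified `assembly_graph`.
#' @export
simplify_global <- function(graph, min_coverage = 2, tip_len = 2L * graph$k,
                            bulge_similarity = 0.8, rel_cov = 0.2) {
  stopifnot(min_coverage >= 0, tip_len >= 0, bulge_similarity >= 0)
  g <- drop_edges(graph, which(graph$cov < min_coverage))
  g <- compact_graph(g)
  for (cycle in seq_len(10L)) {
    n0 <- length(g$seq)
    g <- clip_global_tips(g, tip_len, rel_cov)
    g <- pop_global_bulges(g, bulge_similarity, rel_cov)
    g <- compact_graph(g)
    if (length(g$seq) == n0) break
  }
  g
}

clip_global_tips <- function(g, tip_len, rel_cov) {
  n <- length(g$seq)
  if (n == 0L) return(g)
  adj <- graph_adjacency(g)
  lens <- nchar(g$seq)
  drop <- integer(0)
  for (e in seq_len(n)) {
    no_out <- length(adj$out[[e]]) == 0L
    no_in <- length(adj$in_[[e]]) == 0L
    if (no_out == no_in) next          # isolated or internal: not a tip
    nb <- if (no_out) adj$in_[[e]] else adj$out[[e]]
    nb <- setdiff(nb, c(e, g$rc[e]))
    if (length(nb) == 0L) next
    if (lens[e] < tip_len && g$cov[e] < rel_cov * max(g$cov[nb])) {
      drop <- c(drop, e)
    }
  }
  drop_edges(g, drop)
}

## Bulge popping, candidate-centric: a short edge is removed when the graph
## contains an edge-disjoint parallel walk between its two junctions with a
## similar spelled length and a far higher coverage. The alternative-path
## search is a bounded DFS, so it still finds the parallel true path when
## that path is itself split into many short edges by other error bubbles;
## re-compaction between cycles then dissolves such braids completely.
pop_global_bulges <- function(g, bulge_similarity, rel_cov,
                              max_alt_edges = 60L) {
  n <- length(g$seq)
  if (n == 0L) return(g)
  adj <- graph_adjacency(g)
  k <- g$k
  lens <- nchar(g$seq)
  suf_of <- function(e) substr(g$seq[e], lens[e] - k + 2L, lens[e])
  removed <- logical(n)
  cand <- order(g$cov, lens, seq_len(n))
  cand <- cand[lens[cand] <= 3L * k]
  for (e in cand) {
    if (removed[e]) next
    target <- suf_of(e)
    limit_bp <- ceiling(lens[e] / bulge_similarity)
    min_bp <- floor(lens[e] * bulge_similarity)
    need <- g$cov[e] / rel_cov        # alternative must beat this min-cov
    ## DFS from the start junction of e over walks avoiding e and its twin
    starts <- setdiff(adj$in_[[e]], c(e, g$rc[e]))
    entry <- if (length(starts)) {
      unique(unlist(lapply(starts, function(s) adj$out[[s]])))
    } else integer(0)
    entry <- setdiff(entry, c(e, g$rc[e]))
    found <- FALSE
    dfs <- function(f, bp, mc, depth) {
      if (found || removed[f]) return()
      bp2 <- bp + lens[f] - (k - 1L)
      if (bp2 > limit_bp) return()
      mc2 <- min(mc, g$cov[f])
      if (mc2 <= need) return()
      if (suf_of(f) == target && bp2 >= min_bp) { found <<- TRUE; return() }
      if (depth >= max_alt_edges) return()
      for (h in adj$out[[f]]) {
        if (h == e || h == g$rc[e]) next
        dfs(h, bp2, mc2, depth + 1L)
      }
    }
    for (f in entry) dfs(f, k - 1L, Inf, 1L)
    if (found) {
      removed[e] <- TRUE
      removed[g$rc[e]] <- TRUE
    }
  }
  drop_edges(g, which(removed))
}

#' Spell the sequence of an edge walk
#'
#' Concatenates the unitig sequences of consecutive adjacent edges, collapsing
#' the (k-1)-base overlaps, then trims to the given offsets on the first and
#' last edge. Offsets are 0-based and half-open: `start_offset` is the first
#' used base of the first edge, `end_offset` one past the last used base of the
#' last edge.
#'
#' @param graph an `assembly_graph`.
#' @param edge_walk integer vector of directed edge ids; consecutive edges must
#'   be adjacent.
#' @param start_offset,end_offset trimming offsets (defaults: untrimmed).
#' @return a DNA string.
#' @export
spell_path <- function(graph, edge_walk, start_offset = 0L,
                       end_offset = nchar(graph$seq[edge_walk[length(edge_walk)]])) {
  stopifnot(length(edge_walk) >= 1L)
  k <- graph$k
  lens <- nchar(graph$seq[edge_walk])
  if (length(edge_walk) > 1L) {
    a <- edge_walk[-length(edge_walk)]
    b <- edge_walk[-1L]
    ok <- substr(graph$seq[a], nchar(graph$seq[a]) - k + 2L, nchar(graph$seq[a])) ==
      substr(graph$seq[b], 1L, k - 1L)
    if (!all(ok)) stop("spell_path(): walk contains non-adjacent consecutive edges")
  }
  s <- paste0(graph$seq[edge_walk[1L]],
              paste(substr(graph$seq[edge_walk[-1L]], k, nchar(graph$seq[edge_walk[-1L]])),
                    collapse = ""))
  total <- nchar(s)
  last_len <- lens[length(lens)]
  if (start_offset < 0L || start_offset >= lens[1L] ||
      end_offset < 1L || end_offset > last_len) {
    stop("spell_path(): offsets out of edge bounds")
  }
  substr(s, start_offset + 1L, total - (last_len - end_offset))
}

## walk along unique extensions from edge e in direction "out"/"in" is not
## needed globally; per-cloud logic builds its own restricted adjacency.

#' Connected components of the assembly graph
#'
#' Weakly connected components over canonical unitigs (an edge and its
#' reverse-complement twin always share a component). Used as the
#' reference-free gene-locus proxy by [filter_multi_isoform_barcodes()].
#'
#' @param graph an `assembly_graph`.
#' @return integer vector: component id per edge (twins share ids).
#' @export
gene_components <- function(graph) {
  n <- length(graph$seq)
  if (n == 0L) return(integer(0))
  adj <- graph_adjacency(graph)
  edges_from <- rep(seq_len(n), lengths(adj$out))
  edges_to <- unlist(adj$out)
  ig <- igraph::graph_from_edgelist(
    cbind(c(edges_from, seq_len(n)), c(edges_to %||% integer(0), graph$rc)),
    directed = FALSE)
  comp <- igraph::components(ig)$membership[seq_len(n)]
  as.integer(comp)
}

#' Write the assembly graph as GFA 1.0
#'
#' One S-line per canonical unitig with a `dp:f:` depth tag; L-lines carry the
#' (k-1)M overlap. Reverse complements are implicit through orientation signs.
#'
#' @param graph an `assembly_graph`.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_gfa <- function(graph, file) {
  g <- graph
  canon <- canonical_edges(g)
  seg_id <- integer(length(g$seq))
  seg_id[canon] <- seq_along(canon)
  seg_id[g$rc[canon]] <- seq_along(canon)
  orient <- ifelse(seq_along(g$seq) %in% canon, "+", "-")
  # self-rc edges: canonical and twin coincide, orientation "+"
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\te%d\t%s\tdp:f:%.4f", seq_along(canon),
                     g$seq[canon], g$cov[canon]))
  adj <- graph_adjacency(g)
  links <- character(0)
  for (e in seq_along(g$seq)) {
    for (f in adj$out[[e]]) {
      a <- sprintf("e%d\t%s\te%d\t%s", seg_id[e], orient[e], seg_id[f], orient[f])
      # the rc twin of link e->f is rc(f)->rc(e); keep one representative
      b <- sprintf("e%d\t%s\te%d\t%s", seg_id[g$rc[f]], orient[g$rc[f]],
                   seg_id[g$rc[e]], orient[g$rc[e]])
      links <- c(links, if (cmp_le(a, b)) a else b)
    }
  }
  links <- sort(unique(links))
  if (length(links)) {
    lines <- c(lines, sprintf("L\t%s\t%dM", links, g$k - 1L))
  }
  writeLines(lines, file)
  invisible(file)
}
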