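## Per-barcode (cloud) subgraph of the global assembly graph.
##
## Member edges are stored by their canonical id (an edge and its
## reverse-complement twin are one member). Stats follow the canonical
## orientation; coverage is aligned-base depth, not k-mer multiplicity --
## per-cloud coverage around 1x makes k-mer counts too sparse to be useful.

new_cloud_subgraph <- function(barcode, stats, graph, adj = NULL) {
  structure(list(barcode = barcode, stats = stats, graph = graph,
                 adj = adj %||% graph_adjacency(graph)),
            class = "cloud_subgraph")
}

empty_cloud_stats <- function() {
  data.frame(edge = integer(0), cov = numeric(0), leftmost = integer(0),
             rightmost = integer(0), n_reads = integer(0), gap = logical(0))
}

#' @export
print.cloud_subgraph <- function(x, ...) {
  cat(sprintf("cloud_subgraph: barcode %s, %d edges (%d gap-filled)\n",
              x$barcode, nrow(x$stats), sum(x$stats$gap)))
  invisible(x)
}

## directed edge ids of the induced subgraph (members plus their twins)
sub_directed <- function(sub) {
  m <- sub$stats$edge
  sort(unique(c(m, sub$graph$rc[m])))
}

## adjacency of the induced subgraph over directed edge ids; out/in_ are
## parent-sized lists filled only at member positions (O(|members|) work)
sub_adjacency <- function(sub) {
  d <- sub_directed(sub)
  n <- length(sub$graph$seq)
  memb <- logical(n)
  memb[d] <- TRUE
  out <- vector("list", n)
  in_ <- vector("list", n)
  for (e in d) {
    out[[e]] <- sub$adj$out[[e]][memb[sub$adj$out[[e]]]]
    in_[[e]] <- sub$adj$in_[[e]][memb[sub$adj$in_[[e]]]]
  }
  list(out = out, in_ = in_, directed = d)
}

## mirror an aligned span on edge e to canonical coordinates
canonical_span <- function(g, e, s, t) {
  ce <- min(e, g$rc[e])
  if (e == ce) c(ce, s, t) else {
    len <- nchar(g$seq[e])
    c(ce, len - t, len - s)
  }
}

#' Extract the alignment-induced cloud subgraph
#'
#' The subgraph consists of every edge touched by at least one alignment of
#' the cloud, with barcode-specific coverage (aligned bases divided by edge
#' length), per-edge extreme alignment positions (leftmost/rightmost, 0-based
#' half-open) and read counts. Reverse-complement twins are unified to one
#' canonical member.
#'
#' @param graph an `assembly_graph`.
#' @param alignments alignment data.frame from [align_cloud()].
#' @param barcode the cloud's barcode.
#' @param adj optional precomputed adjacency of `graph`.
#' @return a `cloud_subgraph`.
#' @export
extract_subgraph <- function(graph, alignments, barcode, adj = NULL) {
  if (nrow(alignments) > 0L && !all(alignments$barcode == barcode)) {
    stop("extract_subgraph(): alignments from a different barcode")
  }
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(alignments))) {
    walk <- alignments$walk[[i]]
    nw <- length(walk)
    lens <- nchar(graph$seq[walk])
    starts <- c(alignments$start_offset[i], rep(0L, nw - 1L))
    ends <- c(lens[-nw], alignments$end_offset[i])
    if (nw == 1L) { starts <- alignments$start_offset[i]; ends <- alignments$end_offset[i] }
    for (j in seq_len(nw)) {
      cs <- canonical_span(graph, walk[j], starts[j], ends[j])
      key <- as.character(cs[1L])
      prev <- acc[[key]]
      if (is.null(prev)) {
        acc[[key]] <- c(cs[1L], cs[3L] - cs[2L], cs[2L], cs[3L], 1L)
      } else {
        acc[[key]] <- c(cs[1L], prev[2L] + cs[3L] - cs[2L],
                        min(prev[3L], cs[2L]), max(prev[4L], cs[3L]),
                        prev[5L] + 1L)
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L) {
    return(new_cloud_subgraph(barcode, empty_cloud_stats(), graph, adj))
  }
  m <- do.call(rbind, lapply(keys, function(k) acc[[k]]))
  o <- order(m[, 1L])
  m <- m[o, , drop = FALSE]
  stats <- data.frame(edge = as.integer(m[, 1L]),
                      cov = m[, 2L] / nchar(graph$seq[m[, 1L]]),
                      leftmost = as.integer(m[, 3L]),
                      rightmost = as.integer(m[, 4L]),
                      n_reads = as.integer(m[, 5L]),
                      gap = FALSE)
  new_cloud_subgraph(barcode, stats, graph, adj)
}

## connected component id per member (undirected, over canonical members);
## plain union-find, cheap for the small per-cloud graphs
sub_components <- function(sub, sa = NULL) {
  m <- sub$stats$edge
  if (length(m) == 0L) return(integer(0))
  if (is.null(sa)) sa <- sub_adjacency(sub)
  g <- sub$graph
  parent <- seq_along(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in sa$directed) {
    i <- find(match(min(e, g$rc[e]), m))
    for (f in sa$out[[e]]) {
      j <- find(match(min(f, g$rc[f]), m))
      if (i != j) parent[j] <- i
    }
  }
  roots <- vapply(seq_along(m), find, integer(1))
  match(roots, unique(roots))
}

#' Clip cloud-local tips
#'
#' Removes member edges that are dead ends or dead starts within the subgraph
#' and are either shorter than `max_tip_len` or have barcode-specific coverage
#' below `rel_cov` times the coverage of their adjacent subgraph neighbour. An
#' edge that is the sole member of its connected component is never removed.
#'
#' @param sub a `cloud_subgraph`.
#' @param max_tip_len maximal tip length in bp.
#' @param rel_cov relative-coverage threshold.
#' @return the clipped `cloud_subgraph`.
#' @export
clip_cloud_tips <- function(sub, max_tip_len = 2L * sub$graph$k, rel_cov = 0.33) {
  if (nrow(sub$stats) == 0L) return(sub)
  g <- sub$graph
  sa <- sub_adjacency(sub)
  comp <- sub_components(sub, sa)
  comp_size <- table(comp)
  m <- sub$stats$edge
  covs <- structure(sub$stats$cov, names = as.character(m))
  drop <- logical(length(m))
  for (i in seq_along(m)) {
    if (comp_size[[as.character(comp[i])]] == 1L) next
    e <- m[i]
    no_out <- length(setdiff(sa$out[[e]], c(e, g$rc[e]))) == 0L
    no_in <- length(setdiff(sa$in_[[e]], c(e, g$rc[e]))) == 0L
    if (no_out == no_in) next                       # internal or isolated
    nb <- if (no_out) sa$in_[[e]] else sa$out[[e]]
    nb <- setdiff(nb, c(e, g$rc[e]))
    nbcov <- max(covs[as.character(pmin(nb, g$rc[nb]))])
    short <- nchar(g$seq[e]) < max_tip_len
    lowcov <- sub$stats$cov[i] < rel_cov * nbcov
    if (short || lowcov) drop[i] <- TRUE
  }
  sub$stats <- sub$stats[!drop, , drop = FALSE]
  sub
}

## enumerate directed walks of <= max_edges edges within the induced subgraph
enumerate_sub_walks <- function(sub, max_edges = 3L) {
  sa <- sub_adjacency(sub)
  walks <- list()
  grow <- function(w) {
    walks[[length(walks) + 1L]] <<- w
    if (length(w) >= max_edges) return()
    for (f in sa$out[[w[length(w)]]]) {
      can <- pmin(c(w, f), sub$graph$rc[c(w, f)])
      if (anyDuplicated(can)) next                  # no repeated member
      grow(c(w, f))
    }
  }
  for (e in sa$directed) grow(e)
  walks
}

walk_nodes <- function(g, w) {
  k <- g$k
  first <- g$seq[w[1L]]
  last <- g$seq[w[length(w)]]
  c(substr(first, 1L, k - 1L),
    substr(last, nchar(last) - k + 2L, nchar(last)))
}

#' Remove cloud-local bulges
#'
#' For each pair of edge-disjoint walks of at most three edges sharing both
#' end junctions, removes the private edges of the side whose minimal
#' barcode-specific coverage is at most `cov_ratio` times the other side's;
#' exact coverage ties are broken by removing the walk with the
#' lexicographically larger spelled sequence.
#'
#' @param sub a `cloud_subgraph`.
#' @param cov_ratio coverage ratio threshold in (0, 1].
#' @return the `cloud_subgraph` with bulges removed.
#' @export
remove_cloud_bulges <- function(sub, cov_ratio = 0.5) {
  if (nrow(sub$stats) < 2L) return(sub)
  g <- sub$graph
  ## a bulge needs a junction node with out-degree (or in-degree) >= 2 within
  ## the subgraph; most cloud subgraphs are linear after tip clipping
  d <- sub_directed(sub)
  k <- g$k
  lens <- nchar(g$seq[d])
  pr <- substr(g$seq[d], 1L, k - 1L)
  sf <- substr(g$seq[d], lens - k + 2L, lens)
  if (max(table(pr)) < 2L && max(table(sf)) < 2L) return(sub)
  walks <- enumerate_sub_walks(sub, 3L)
  if (length(walks) < 2L) return(sub)
  keys <- vapply(walks, function(w) paste(walk_nodes(g, w), collapse = " "),
                 character(1))
  ids <- vapply(walks, function(w) paste(w, collapse = ","), character(1))
  o <- order(keys, ids)
  walks <- walks[o]; keys <- keys[o]
  covs <- structure(sub$stats$cov, names = as.character(sub$stats$edge))
  removed <- new.env(parent = emptyenv())
  gone <- function(w) {
    can <- as.character(pmin(w, g$rc[w]))
    any(vapply(can, function(x) !is.null(removed[[x]]), logical(1)))
  }
  by_key <- split(seq_along(walks), keys)
  for (grp in by_key) {
    if (length(grp) < 2L) next
    for (i in grp) for (j in grp) {
      if (i >= j) next
      wi <- walks[[i]]; wj <- walks[[j]]
      ci_ids <- pmin(wi, g$rc[wi]); cj_ids <- pmin(wj, g$rc[wj])
      if (length(intersect(ci_ids, cj_ids)) > 0L) next
      if (gone(wi) || gone(wj)) next
      ci <- min(covs[as.character(ci_ids)])
      cj <- min(covs[as.character(cj_ids)])
      lose <- if (ci <= cov_ratio * cj && !(cj <= cov_ratio * ci)) wi
      else if (cj <= cov_ratio * ci && !(ci <= cov_ratio * cj)) wj
      else if (ci == cj) {
        si <- spell_path(g, wi); sj <- spell_path(g, wj)
        if (cmp_le(si, sj)) wj else wi
      } else NULL
      if (is.null(lose)) next
      keepw <- if (identical(lose, wi)) cj_ids else ci_ids
      private <- setdiff(pmin(lose, g$rc[lose]), keepw)
      for (x in private) removed[[as.character(x)]] <- TRUE
    }
  }
  dead <- vapply(as.character(sub$stats$edge),
                 function(x) !is.null(removed[[x]]), logical(1))
  sub$stats <- sub$stats[!dead, , drop = FALSE]
  sub
}

#' Close coverage gaps with short parent-graph edges
#'
#' For each ordered pair (dead end, dead start) of subgraph path endpoints,
#' searches the parent graph for a connecting walk of at most three edges, all
#' absent from the subgraph, contributing at most `max_gap_edge_len` novel
#' bases. If exactly one such walk exists it is added to the subgraph (with
#' coverage 0, flagged as gap-filled, extents covering the full edges);
#' ambiguous or over-length gaps are left open.
#'
#' When pair links are supplied, a gap between two fragments is closed only
#' if some read pair of the cloud has one mate on each fragment: a genuine
#' coverage gap shorter than the insert size is spanned by read pairs, while
#' a "gap" that actually hides an unsequenced exon of a longer isoform is
#' not, and closing it would spell a different isoform's sequence.
#'
#' @param sub a `cloud_subgraph`.
#' @param max_gap_edge_len maximal total novel bases of a gap walk.
#' @param links optional pair links (internal form) used as cross-fragment
#'   evidence.
#' @return the `cloud_subgraph` with closable gaps filled.
#' @export
close_gaps <- function(sub, max_gap_edge_len = 150L, links = NULL) {
  if (nrow(sub$stats) == 0L) return(sub)
  g <- sub$graph
  sa <- sub_adjacency(sub)
  members <- sub$stats$edge
  is_member <- function(e) pmin(e, g$rc[e]) %in% members
  dead_end <- sa$directed[vapply(sa$directed, function(e)
    length(sa$out[[e]]) == 0L, logical(1))]
  dead_start <- sa$directed[vapply(sa$directed, function(e)
    length(sa$in_[[e]]) == 0L, logical(1))]
  comp <- sub_components(sub, sa)
  comp_of <- function(e) comp[match(min(e, g$rc[e]), members)]
  linked_comps <- NULL
  if (!is.null(links)) {
    linked_comps <- character(0)
    for (ln in links) {
      c1 <- unique(comp[match(intersect(ln$m1, members), members)])
      c2 <- unique(comp[match(intersect(ln$m2, members), members)])
      for (a in c1) for (b in c2) {
        if (!is.na(a) && !is.na(b) && a != b) {
          linked_comps <- c(linked_comps,
                            paste(min(a, b), max(a, b)))
        }
      }
    }
    linked_comps <- unique(linked_comps)
  }
  lens <- nchar(g$seq)
  novel <- lens - (g$k - 1L)
  add <- integer(0)
  for (e in dead_end) {
    for (f in dead_start) {
      if (pmin(e, g$rc[e]) == pmin(f, g$rc[f])) next
      if (!is.null(linked_comps)) {
        ce <- comp_of(e); cf <- comp_of(f)
        if (is.na(ce) || is.na(cf) || ce == cf) next
        if (!(paste(min(ce, cf), max(ce, cf)) %in% linked_comps)) next
      }
      ## DFS over non-member parent edges from e towards f
      found <- list()
      search <- function(path, budget) {
        if (length(found) > 1L) return()
        last <- if (length(path)) path[length(path)] else e
        for (w in sub$adj$out[[last]]) {
          if (w == f && length(path) > 0L) {
            found[[length(found) + 1L]] <<- path
            next
          }
          if (is_member(w) || length(path) >= 3L) next
          if (budget - novel[w] < 0L) next
          if (pmin(w, g$rc[w]) %in% pmin(path, g$rc[path])) next
          search(c(path, w), budget - novel[w])
        }
      }
      search(integer(0), max_gap_edge_len)
      if (length(found) == 1L) add <- c(add, found[[1L]])
    }
  }
  add <- setdiff(unique(pmin(add, g$rc[add])), members)
  if (length(add)) {
    extra <- data.frame(edge = add, cov = 0, leftmost = 0L,
                        rightmost = nchar(g$seq[add]),
                        n_reads = 0L, gap = TRUE)
    sub$stats <- rbind(sub$stats, extra)
    sub$stats <- sub$stats[order(sub$stats$edge), , drop = FALSE]
  }
  sub
}

#' Cloud-local simplification to a fixpoint
#'
#' Applies [clip_cloud_tips()], [remove_cloud_bulges()] and [close_gaps()] in
#' that order, in repeated cycles, until a full cycle changes nothing or
#' `max_cycles` is reached.
#'
#' @param sub a `cloud_subgraph`.
#' @param max_tip_len,rel_cov,cov_ratio,max_gap_edge_len see the individual
#'   procedures.
#' @param max_cycles hard cap on cycles.
#' @param links optional pair links forwarded to [close_gaps()].
#' @return the simplified `cloud_subgraph`.
#' @export
simplify_cloud <- function(sub, max_tip_len = 2L * sub$graph$k, rel_cov = 0.33,
                           cov_ratio = 0.5, max_gap_edge_len = 150L,
                           max_cycles = 10L, links = NULL) {
  state <- function(s) paste(s$stats$edge, s$stats$gap, collapse = ";")
  for (i in seq_len(max_cycles)) {
    before <- state(sub)
    sub <- clip_cloud_tips(sub, max_tip_len, rel_cov)
    sub <- remove_cloud_bulges(sub, cov_ratio)
    sub <- close_gaps(sub, max_gap_edge_len, links)
    if (identical(state(sub), before)) break
  }
  sub
}
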