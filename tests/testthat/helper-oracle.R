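# Independent naive de Bruijn builder used as an oracle: hash-map k-mer
# counting, explicit (k-1)-mer node table, then naive path compression.
# Deliberately simple and separate from the package's vectorised builder.

oracle_rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

naive_debruijn <- function(reads, k) {
  counts <- new.env(parent = emptyenv())
  for (r in reads) {
    r <- toupper(r)
    for (frag in strsplit(r, "[^ACGT]+")[[1]]) {
      if (is.na(frag) || nchar(frag) < k) next
      for (i in seq_len(nchar(frag) - k + 1)) {
        km <- substr(frag, i, i + k - 1)
        rcm <- oracle_rc(km)
        can <- if (km <= rcm) km else rcm
        counts[[can]] <- (counts[[can]] %or0% 0) + 1
      }
    }
  }
  kmers <- ls(counts)
  if (length(kmers) == 0) {
    return(list(unitigs = character(0), degrees = character(0), total = 0))
  }
  # directed edge set: every canonical k-mer and its reverse complement
  edges <- c(kmers, oracle_rc(kmers))
  pre <- substr(edges, 1, k - 1)
  suf <- substr(edges, 2, k)
  nodes <- unique(c(pre, suf))
  outd <- table(factor(pre, levels = nodes))
  ind <- table(factor(suf, levels = nodes))
  through <- function(nd) outd[[nd]] == 1 && ind[[nd]] == 1
  next_edge <- function(e) {
    nd <- substr(e, 2, k)
    if (!through(nd)) return(NA_character_)
    cand <- edges[pre == nd]
    if (length(cand) != 1) return(NA_character_)
    cand
  }
  prev_exists <- function(e) {
    nd <- substr(e, 1, k - 1)
    if (!through(nd) || sum(suf == nd) != 1) return(FALSE)
    edges[suf == nd] != e          # a self-loop never continues a chain
  }
  visited <- new.env(parent = emptyenv())
  unitigs <- character(0)
  walk_from <- function(e) {
    seqs <- e
    visited[[e]] <- TRUE
    repeat {
      f <- next_edge(e)
      if (is.na(f) || !is.null(visited[[f]]) || f == e) break
      seqs <- paste0(seqs, substr(f, k, k))
      visited[[f]] <- TRUE
      e <- f
    }
    seqs
  }
  for (e in edges) {
    if (!is.null(visited[[e]]) || prev_exists(e)) next
    unitigs <- c(unitigs, walk_from(e))
  }
  for (e in edges) {          # leftover cycles
    if (is.null(visited[[e]])) unitigs <- c(unitigs, walk_from(e))
  }
  canon_unitigs <- vapply(unitigs, function(u) {
    r <- oracle_rc(u)
    if (u <= r) u else r
  }, character(1), USE.NAMES = FALSE)
  canon_unitigs <- sort(unique(canon_unitigs))
  list(unitigs = canon_unitigs,
       degrees = unitig_degrees(canon_unitigs, k),
       total = sum(vapply(kmers, function(x) counts[[x]], numeric(1))))
}

# junction degree signature of a compacted unitig set (both strands)
unitig_degrees <- function(canon_unitigs, k) {
  directed <- unique(c(canon_unitigs, oracle_rc(canon_unitigs)))
  pre <- substr(directed, 1, k - 1)
  suf <- substr(directed, nchar(directed) - k + 2, nchar(directed))
  nodes <- unique(c(pre, suf))
  sort(paste(as.integer(table(factor(suf, levels = nodes))),
             as.integer(table(factor(pre, levels = nodes)))))
}

`%or0%` <- function(a, b) if (is.null(a)) b else a

# package-side view in the same shape as the oracle output. The k-mer total
# sums coverage x k-mers over ALL directed edges and halves it: exact both
# for twin pairs (each canonical k-mer counted once per strand) and for
# self-rc unitigs (each counted twice within the single edge).
graph_signature <- function(g) {
  can <- which(seq_along(g$seq) <= g$rc)
  seqs <- vapply(g$seq[can], function(s) {
    r <- isocloud::rc_dna(s)
    if (s <= r) s else r
  }, character(1), USE.NAMES = FALSE)
  seqs <- sort(unique(seqs))
  list(unitigs = seqs, degrees = unitig_degrees(seqs, g$k),
       total = sum(g$cov * (nchar(g$seq) - g$k + 1)) / 2)
}

random_reads <- function(n, len_range = c(30L, 70L)) {
  lens <- len_range[1] +
    sample.int(len_range[2] - len_range[1] + 1L, n, replace = TRUE) - 1L
  vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_base <- function(s, pos) {
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  s
}
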