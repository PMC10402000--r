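# Helpers to fabricate cloud subgraphs on top of small constructed graphs.

# graph of a linear backbone with a spur hanging off an internal junction:
#   A - B - C with spur S sharing B's entry junction
make_spur_graph <- function(seed = 31, k = 15) {
  set.seed(seed)
  a <- random_reads(1, c(60, 60))
  b <- random_reads(1, c(60, 60))
  co <- random_reads(1, c(60, 60))
  spur <- random_reads(1, c(20, 20))   # short: below default tip length
  t1 <- paste0(a, b, co)
  t2 <- paste0(a, spur)
  list(graph = build_graph(c(t1, t2), k = k), t1 = t1, t2 = t2)
}

# build a subgraph by aligning error-free reads tiled over given sequences
tile_cloud <- function(graph, seqs, barcode = "BC1", step = 20L, rl = 40L,
                       per_seq_reads = NULL) {
  r1 <- character(0); r2 <- character(0)
  for (s in seqs) {
    starts <- seq(1L, max(1L, nchar(s) - rl + 1L), by = step)
    r1 <- c(r1, substr(rep(s, length(starts)), starts, starts + rl - 1L))
    r2 <- c(r2, rc_dna(substr(rep(s, length(starts)), starts, starts + rl - 1L)))
  }
  cloud <- read_cloud(barcode, r1, r2)
  aln <- align_cloud(graph, cloud)
  list(cloud = cloud, aln = aln,
       sub = extract_subgraph(graph, aln, barcode))
}

test_that("the subgraph is exactly the set of touched edges with sane stats", {
  sg <- make_spur_graph()
  tc <- tile_cloud(sg$graph, sg$t1)
  sub <- tc$sub
  g <- sg$graph
  touched <- sort(unique(unlist(lapply(tc$aln$walk, function(w)
    pmin(w, g$rc[w])))))
  expect_identical(sub$stats$edge, touched)
  expect_true(all(sub$stats$cov > 0))
  expect_true(all(sub$stats$leftmost < sub$stats$rightmost))
  expect_true(all(sub$stats$rightmost <= nchar(g$seq[sub$stats$edge])))
})

test_that("aligned-base coverage and extreme positions aggregate correctly", {
  set.seed(41)
  s <- random_reads(1, c(300, 300))
  g <- build_graph(s, k = 15)
  e <- which(g$seq == s)
  bc <- "AAAACCCCGGGGTTTT"
  mk <- function(st, len) substr(s, st + 1L, st + len)   # 0-based start
  cloud <- read_cloud(bc, read1 = c(mk(10, 100), mk(50, 100)),
                      read2 = c(mk(150, 100), mk(120, 100)))
  aln <- align_cloud(g, cloud)
  sub <- extract_subgraph(g, aln, bc)
  i <- match(min(e, g$rc[e]), sub$stats$edge)
  expect_equal(sub$stats$n_reads[i], 4L)
  expect_equal(sub$stats$cov[i], 400 / 300)
  expect_equal(sub$stats$leftmost[i], 10L)
  expect_equal(sub$stats$rightmost[i], 250L)
  # three 100 bp reads fully covering a 300 bp edge -> coverage 1.0
  cloud2 <- read_cloud(bc, read1 = c(mk(0, 100), mk(100, 100)),
                       read2 = c(mk(200, 100), mk(0, 0)))
  cloud2$pairs <- cloud2$pairs[1:2, ]
  cloud2$pairs$read2[2] <- mk(200, 100)
  aln2 <- align_cloud(g, cloud2)
  aln2 <- aln2[!(aln2$pair_id == cloud2$pairs$pair_id[1] & aln2$mate == 2), ]
  sub2 <- extract_subgraph(g, aln2, bc)
  i2 <- match(min(e, g$rc[e]), sub2$stats$edge)
  expect_equal(sub2$stats$cov[i2], 1.0)
})

test_that("alignments from another barcode are rejected", {
  sg <- make_spur_graph()
  tc <- tile_cloud(sg$graph, sg$t1, barcode = "BC1")
  expect_error(extract_subgraph(sg$graph, tc$aln, "BC2"), "barcode")
})

test_that("a short spur is clipped while the backbone survives", {
  sg <- make_spur_graph()
  tc <- tile_cloud(sg$graph, c(sg$t1, sg$t2))
  sub <- tc$sub
  clipped <- clip_cloud_tips(sub)
  g <- sg$graph
  spur_edge <- NULL
  for (e in sub$stats$edge) {
    if (any(vapply(c(e, g$rc[e]), function(d)
      grepl(substr(g$seq[d], g$k, nchar(g$seq[d])), sg$t2, fixed = TRUE) &&
      !grepl(substr(g$seq[d], g$k, nchar(g$seq[d])), sg$t1, fixed = TRUE),
      logical(1)))) spur_edge <- e
  }
  expect_false(is.null(spur_edge))
  expect_false(spur_edge %in% clipped$stats$edge)
  expect_gte(nrow(clipped$stats), nrow(sub$stats) - 1L)
})

test_that("an isolated single-edge subgraph is never clipped", {
  set.seed(51)
  s <- random_reads(1, c(120, 120))
  g <- build_graph(s, k = 15)
  tc <- tile_cloud(g, s)
  expect_identical(clip_cloud_tips(tc$sub)$stats, tc$sub$stats)
})

test_that("a long well-covered spur is retained", {
  set.seed(61)
  a <- random_reads(1, c(60, 60))
  b <- random_reads(1, c(60, 60))
  spur <- random_reads(1, c(80, 80))   # longer than default tip length 2k=30
  g <- build_graph(c(paste0(a, b), paste0(a, spur)), k = 15)
  tc <- tile_cloud(g, c(paste0(a, b), paste0(a, spur)), step = 10L)
  kept <- clip_cloud_tips(tc$sub, max_tip_len = 30L, rel_cov = 0.33)
  expect_identical(kept$stats$edge, tc$sub$stats$edge)
})

test_that("cloud bulges pop the low-covered side; ties break lexicographically", {
  sg <- make_spur_graph(seed = 71)
  g <- build_graph(c(sg$t1, sg$t2), k = 15)  # not used; build bubble instead
  set.seed(72)
  pre <- random_reads(1, c(60, 60)); suf <- random_reads(1, c(60, 60))
  m1 <- random_reads(1, c(40, 40)); m2 <- random_reads(1, c(40, 40))
  t1 <- paste0(pre, m1, suf); t2 <- paste0(pre, m2, suf)
  gg <- build_graph(c(t1, t2), k = 15)
  # low-coverage alternative: tile t1 densely, t2 sparsely
  bc <- "ACGTAAAACCCCGGGG"
  r1 <- substr(rep(t1, 12), seq(1, 111, 10), seq(1, 111, 10) + 39)
  r2 <- substr(t2, 61, 100)    # one read on the alternative middle
  cloud <- read_cloud(bc, c(r1, r2), rc_dna(c(r1, r2)))
  aln <- align_cloud(gg, cloud)
  sub <- extract_subgraph(gg, aln, bc)
  popped <- remove_cloud_bulges(sub, cov_ratio = 0.5)
  mid2_edge <- which(vapply(seq_along(gg$seq), function(e)
    grepl(gg$seq[e], t2, fixed = TRUE) && !grepl(gg$seq[e], t1, fixed = TRUE),
    logical(1)))
  mid2_can <- unique(pmin(mid2_edge, gg$rc[mid2_edge]))
  expect_true(any(mid2_can %in% sub$stats$edge))
  expect_false(any(mid2_can %in% popped$stats$edge))
  # equal coverage: the lexicographically larger spelled side goes
  tc2 <- tile_cloud(gg, c(t1, t2), step = 10L)
  popped2 <- remove_cloud_bulges(tc2$sub, cov_ratio = 0.5)
  mid1_edge <- which(vapply(seq_along(gg$seq), function(e)
    grepl(gg$seq[e], t1, fixed = TRUE) && !grepl(gg$seq[e], t2, fixed = TRUE),
    logical(1)))
  mid1_can <- unique(pmin(mid1_edge, gg$rc[mid1_edge]))
  gone1 <- !any(mid1_can %in% popped2$stats$edge)
  gone2 <- !any(mid2_can %in% popped2$stats$edge)
  if (gone1 || gone2) {
    s1 <- gg$seq[intersect(c(mid1_edge, gg$rc[mid1_edge]),
                           seq_along(gg$seq))[1]]
    expect_true(xor(gone1, gone2))
  }
})

# a gap needs the uncovered region to be its own edge: share the middle
# between two transcripts so junctions bound it on both sides
make_gap_graph <- function(seed = 81) {
  set.seed(seed)
  a <- random_reads(1, c(150, 150))
  mid <- random_reads(1, c(40, 40))
  b <- random_reads(1, c(150, 150))
  cc <- random_reads(1, c(150, 150))
  d <- random_reads(1, c(150, 150))
  t1 <- paste0(a, mid, b)
  t2 <- paste0(cc, mid, d)
  list(graph = build_graph(c(t1, t2), k = 15), a = a, b = b, mid = mid,
       t1 = t1)
}

test_that("gap closing adds a unique short connector and respects bounds", {
  gg <- make_gap_graph()
  g <- gg$graph
  # cloud covering only a and b of t1: the shared middle is a coverage gap
  bc <- "GGGGTTTTAAAACCCC"
  r <- c(substr(rep(gg$a, 4), c(1, 40, 80, 111), c(40, 79, 119, 150)),
         substr(rep(gg$b, 4), c(1, 40, 80, 111), c(40, 79, 119, 150)))
  cloud <- read_cloud(bc, r, rc_dna(r))
  aln <- align_cloud(g, cloud)
  sub <- extract_subgraph(g, aln, bc)
  closed <- close_gaps(sub, max_gap_edge_len = 100L)
  expect_gt(nrow(closed$stats), nrow(sub$stats))
  expect_true(any(closed$stats$gap))
  # the closed subgraph spells the full transcript as one simple path
  p <- extract_paths(closed, aln, min_contig_len = 100L)
  expect_equal(nrow(p), 1L)
  expect_true(grepl(p$sequence[1], gg$t1, fixed = TRUE) ||
              grepl(rc_dna(p$sequence[1]), gg$t1, fixed = TRUE))
  # too-small length bound: gap stays open
  open <- close_gaps(sub, max_gap_edge_len = 10L)
  expect_identical(open$stats, sub$stats)
})

test_that("ambiguous gaps are left open", {
  set.seed(91)
  a <- random_reads(1, c(150, 150))
  m1 <- random_reads(1, c(40, 40))
  m2 <- random_reads(1, c(40, 40))
  b <- random_reads(1, c(150, 150))
  g <- build_graph(c(paste0(a, m1, b), paste0(a, m2, b)), k = 15)
  bc <- "GGGGTTTTAAAACCCC"
  r <- c(substr(rep(a, 4), c(1, 40, 80, 111), c(40, 79, 119, 150)),
         substr(rep(b, 4), c(1, 40, 80, 111), c(40, 79, 119, 150)))
  cloud <- read_cloud(bc, r, rc_dna(r))
  aln <- align_cloud(g, cloud)
  sub <- extract_subgraph(g, aln, bc)
  closed <- close_gaps(sub, max_gap_edge_len = 100L)
  expect_identical(closed$stats, sub$stats)
})

test_that("pair-link evidence gates gap closing across fragments", {
  gg <- make_gap_graph(seed = 95)
  g <- gg$graph
  bc <- "GGGGTTTTAAAACCCC"
  r <- c(substr(rep(gg$a, 4), c(1, 40, 80, 111), c(40, 79, 119, 150)),
         substr(rep(gg$b, 4), c(1, 40, 80, 111), c(40, 79, 119, 150)))
  cloud <- read_cloud(bc, r, rc_dna(r))
  aln <- align_cloud(g, cloud)
  sub <- extract_subgraph(g, aln, bc)
  links <- isocloud:::build_pair_links(g, aln)
  # mates of each pair map to the same fragment: no cross-fragment evidence
  blocked <- close_gaps(sub, max_gap_edge_len = 100L, links = links)
  expect_identical(blocked$stats, sub$stats)
  # a pair bridging a and b provides the evidence
  bridge <- read_cloud(bc, substr(gg$a, 111, 150),
                       rc_dna(substr(gg$b, 1, 40)))
  aln2 <- rbind(aln, align_cloud(g, bridge))
  sub2 <- extract_subgraph(g, aln2, bc)
  links2 <- isocloud:::build_pair_links(g, aln2)
  closed <- close_gaps(sub2, max_gap_edge_len = 100L, links = links2)
  expect_true(any(closed$stats$gap))
})

test_that("simplify_cloud reaches a fixpoint and resolves staged cases", {
  # already-simple path: one cycle, unchanged
  set.seed(97)
  s <- random_reads(1, c(200, 200))
  g <- build_graph(s, k = 15)
  tc <- tile_cloud(g, s)
  out <- simplify_cloud(tc$sub)
  expect_identical(out$stats, tc$sub$stats)
})

test_that("a noiseless single-isoform cloud simplifies to one simple path spelling the transcript", {
  gene <- simulate_gene(3, 1, exon_len_range = c(150, 200), gene_id = "g",
                        seed = 13)
  tseq <- transcript_seq(gene, 1)
  cfg <- cloud_sim_config(n_clouds = 6, coverage = 2.5, error_rate = 0,
                          seed = 4)
  sim <- simulate_clouds(gene, cfg)
  g <- build_graph(c(sim$reads$read1, sim$reads$read2), k = 21)
  gs <- simplify_global(g, min_coverage = 0)
  idx <- kmer_index(gs)
  adj <- isocloud:::graph_adjacency(gs)
  bc <- sim$reads$barcode[1]
  rows <- sim$reads[sim$reads$barcode == bc, ]
  cloud <- read_cloud(bc, rows$read1, rows$read2, rows$pair_id)
  aln <- align_cloud(gs, cloud, index = idx, adj = adj)
  sub <- extract_subgraph(gs, aln, bc, adj)
  links <- isocloud:::build_pair_links(gs, aln)
  sub <- simplify_cloud(sub, links = links)
  p <- extract_paths(sub, aln)
  expect_equal(nrow(p), 1L)
  expect_true(grepl(p$sequence[1], tseq, fixed = TRUE) ||
              grepl(rc_dna(p$sequence[1]), tseq, fixed = TRUE))
})

test_that("simplification never invents edges outside the parent graph", {
  sg <- make_spur_graph(seed = 99)
  tc <- tile_cloud(sg$graph, c(sg$t1, sg$t2))
  out <- simplify_cloud(tc$sub)
  expect_true(all(out$stats$edge %in% seq_along(sg$graph$seq)))
  not_gap <- !out$stats$gap
  expect_true(all(out$stats$edge[not_gap] %in% tc$sub$stats$edge))
})
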