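test_that("a single non-repetitive read compacts to one unitig pair", {
  s <- "AACCGAGTTTACCGTAGACCAGTTA"
  g <- build_graph(s, k = 11)
  expect_length(g$seq, 2L)
  expect_true(s %in% g$seq)
  expect_identical(g$seq[g$rc], rc_dna(g$seq))
  expect_equal(g$cov, c(1, 1))
  expect_identical(spell_path(g, which(g$seq == s)), s)
})

test_that("empty and too-short inputs give an empty graph with a warning", {
  expect_warning(g <- build_graph(character(0), k = 11), "empty graph")
  expect_length(g$seq, 0L)
  expect_warning(build_graph("ACGTACGT", k = 11))
  expect_error(build_graph("ACGTACGTACGTACGT", k = 12), "odd")
})

test_that("reads with N are split, not discarded", {
  left <- "ACCGTAGACCAGTTACCA"
  right <- "TTGACCGTTAGGACCAGT"
  g <- build_graph(paste0(left, "N", right), k = 11)
  expect_true(left %in% g$seq || rc_dna(left) %in% g$seq)
  expect_true(right %in% g$seq || rc_dna(right) %in% g$seq)
})

test_that("two transcripts sharing ends around distinct middles match the naive oracle", {
  set.seed(11)
  pre <- random_reads(1, c(40, 40))
  mids <- random_reads(2, c(30, 30))
  suf <- random_reads(1, c(40, 40))
  reads <- paste0(pre, mids, suf)
  g <- build_graph(reads, k = 15)
  sig <- graph_signature(g)
  ora <- naive_debruijn(reads, 15)
  expect_identical(sig$unitigs, ora$unitigs)
  expect_identical(sig$degrees, ora$degrees)
  expect_equal(sig$total, ora$total)
})

test_that("compacted structure matches the naive builder on random read sets", {
  set.seed(101)
  for (case in 1:25) {
    reads <- random_reads(sample(1:15, 1))
    g <- build_graph(reads, k = 15)
    sig <- graph_signature(g)
    ora <- naive_debruijn(reads, 15)
    expect_identical(sig$unitigs, ora$unitigs)
    expect_identical(sig$degrees, ora$degrees)
    expect_equal(sig$total, ora$total)
  }
})

test_that("the graph is skew-symmetric and canonically invariant", {
  set.seed(5)
  reads <- random_reads(10, c(40, 80))
  g <- build_graph(reads, k = 15)
  # rc(rc(e)) = e and spell(rc(e)) = revcomp(spell(e))
  expect_identical(g$rc[g$rc], seq_along(g$seq))
  expect_identical(g$seq[g$rc], rc_dna(g$seq))
  # building from reverse-complemented reads gives the same canonical edges
  g2 <- build_graph(rc_dna(reads), k = 15)
  expect_identical(graph_signature(g)$unitigs, graph_signature(g2)$unitigs)
  expect_identical(graph_signature(g)$degrees, graph_signature(g2)$degrees)
})

test_that("compaction is maximal: no junction has exactly one in and one out edge", {
  set.seed(21)
  for (case in 1:10) {
    g <- build_graph(random_reads(8), k = 15)
    if (length(g$seq) == 0L) next
    k <- g$k
    lens <- nchar(g$seq)
    pre <- substr(g$seq, 1, k - 1)
    suf <- substr(g$seq, lens - k + 2, lens)
    nodes <- unique(c(pre, suf))
    ind <- table(factor(suf, levels = nodes))
    outd <- table(factor(pre, levels = nodes))
    # a 1-in/1-out junction may only survive as a self-joint (cycle break)
    # or as the centre of an rc-palindromic region (twin halves)
    oneone <- names(which(ind == 1 & outd == 1))
    for (nd in oneone) {
      e_in <- which(suf == nd)
      e_out <- which(pre == nd)
      expect_true(e_in == e_out || e_out == g$rc[e_in])
    }
    expect_gte(length(nodes), 1L)
  }
})

test_that("coverage times k-mer count conserves the extracted k-mer total", {
  set.seed(33)
  for (case in 1:10) {
    reads <- random_reads(12, c(35, 90))
    g <- build_graph(reads, k = 15)
    # over all directed edges, halved: exact for twin pairs and for
    # self-rc unitigs alike
    got <- sum(g$cov * (nchar(g$seq) - g$k + 1)) / 2
    expect_equal(got, sum(nchar(reads) - 15 + 1))
  }
})

test_that("simplification prunes below min_coverage and is identity at zero thresholds", {
  s <- "ACCGTAGACCAGTTACCAGGT"
  g <- build_graph(s, k = 11)
  expect_length(simplify_global(g, min_coverage = 2)$seq, 0L)
  g2 <- simplify_global(g, min_coverage = 0, tip_len = 0,
                        bulge_similarity = 0)
  expect_identical(sort(g2$seq), sort(g$seq))
  # idempotent
  g3 <- simplify_global(g2, min_coverage = 0, tip_len = 0,
                        bulge_similarity = 0)
  expect_identical(sort(g3$seq), sort(g2$seq))
})

test_that("default simplification of a 30x 2-isoform gene keeps every sequenced true k-mer", {
  gene <- simulate_gene(4, 2, exon_len_range = c(150, 220), gene_id = "toy",
                        seed = 9)
  cfg <- cloud_sim_config(n_clouds = 40, coverage = 3, error_rate = 0.005,
                          read_len = 100, seed = 2)
  sim <- simulate_clouds(gene, cfg)
  g <- build_graph(c(sim$reads$read1, sim$reads$read2), k = 29)
  gs <- simplify_global(g)
  raw <- kmer_index(g)
  idx <- kmer_index(gs)
  truth <- unique(unlist(lapply(names(gene$isoforms), function(i) {
    s <- transcript_seq(gene, i)
    n <- nchar(s) - 28
    substr(rep(s, n), 1:n, 1:n + 28)
  })))
  has <- function(ix, km) !is.null(ix[[km]]) || !is.null(ix[[rc_dna(km)]])
  sequenced <- vapply(truth, function(km) has(raw, km), logical(1))
  survived <- vapply(truth, function(km) has(idx, km), logical(1))
  # uniform read placement barely samples the extreme transcript ends, so a
  # handful of terminal k-mers may never be sequenced; simplification must
  # preserve every true k-mer the reads do support
  expect_gt(mean(sequenced), 0.98)
  expect_true(all(survived[sequenced]))
  expect_false(any(survived & !sequenced))
})

test_that("spell_path collapses (k-1)-overlaps and honours offsets", {
  set.seed(4)
  pre <- random_reads(1, c(30, 30))
  mids <- random_reads(2, c(25, 25))
  suf <- random_reads(1, c(30, 30))
  g <- build_graph(paste0(pre, mids, suf), k = 11)
  # find a 2-edge walk by adjacency
  k <- g$k
  lens <- nchar(g$seq)
  pre <- substr(g$seq, 1, k - 1)
  suf <- substr(g$seq, lens - k + 2, lens)
  hit <- NULL
  for (e in seq_along(g$seq)) {
    f <- which(pre == suf[e])
    if (length(f) == 1) { hit <- c(e, f); break }
  }
  expect_false(is.null(hit))
  sp <- spell_path(g, hit)
  expect_identical(nchar(sp), sum(lens[hit]) - (k - 1L))
  expect_identical(substr(sp, 1, lens[hit[1]]), g$seq[hit[1]])
  # trimming
  expect_identical(spell_path(g, hit, 3L, lens[hit[2]] - 2L),
                   substr(sp, 4, nchar(sp) - 2))
  # non-adjacent edges error
  e1 <- hit[1]
  bad <- which(pre != suf[e1])[1]
  expect_error(spell_path(g, c(e1, bad)), "non-adjacent")
  expect_error(spell_path(g, hit, -1L, 5L), "offsets")
})

test_that("the GFA writer emits one S line per canonical edge with overlaps", {
  set.seed(4)
  g <- build_graph(paste0(random_reads(1, c(30, 30)),
                          random_reads(2, c(25, 25)),
                          random_reads(1, c(30, 30))), k = 11)
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  lines <- readLines(f)
  s_lines <- grep("^S\t", lines, value = TRUE)
  l_lines <- grep("^L\t", lines, value = TRUE)
  expect_length(s_lines, sum(seq_along(g$seq) <= g$rc))
  expect_true(all(grepl("dp:f:", s_lines)))
  expect_true(all(grepl("\t10M$", l_lines)))
})
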