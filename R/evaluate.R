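## Evaluation against simulated truth: contig-to-isoform assignment by direct
## sequence comparison, and per-barcode precision / recall / fixed recall.
## Valid only against synthetic truth (it replaces annotation-based assignment
## tools, which need a reference genome).

## minimal edit distance of `contig` against an infix of `iso` (free ends on
## the subject, global on the pattern)
infix_edit_distance <- function(contig, iso) {
  if (nchar(contig) <= nchar(iso) && grepl(contig, iso, fixed = TRUE)) {
    return(0L)
  }
  mat <- matrix(-1L, 5L, 5L, dimnames = list(c("A", "C", "G", "T", "N"),
                                             c("A", "C", "G", "T", "N")))
  diag(mat) <- 0L
  al <- Biostrings::pairwiseAlignment(
    pattern = contig, subject = iso, type = "global-local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  as.integer(-Biostrings::score(al))
}

## banded infix edit distance around an anchored diagonal. Exact for every
## alignment whose subject offset stays within `off` +/- `lim`; since any
## alignment with at most `lim` edits drifts at most `lim` diagonals from the
## offset of any k-mer it matches exactly, anchoring on a shared k-mer makes
## the band rigorous for deciding d <= lim. Returns lim + 1 when no banded
## alignment does better (i.e. "more than lim").
banded_infix_distance <- function(q, s, off, lim) {
  L <- nchar(q)
  S <- nchar(s)
  W <- 2L * lim + 1L
  qi <- utf8ToInt(q)
  si <- utf8ToInt(s)
  bs <- seq_len(W)
  big <- lim + 1
  ## j(i, b) = i + off - lim - 1 + b  (0-based subject prefix length)
  j0 <- off - lim - 1L
  prev <- ifelse(j0 + bs >= 0L, 0, big)    # free subject prefix
  for (i in seq_len(L)) {
    j <- i + j0 + bs
    valid <- j >= 1L & j <= S
    mis <- rep(big, W)
    mis[valid] <- (si[j[valid]] != qi[i]) * 1
    cur <- pmin(prev + mis,                          # match / substitution
                c(prev[-1L], big) + 1)               # deletion of q[i]
    cur <- pmin(cummin(cur - bs) + bs, big)          # subject-char insertions
    cur[j < 0L | j > S] <- big                       # outside the subject
    prev <- cur
  }
  min(c(prev, big))
}

## k-mer index over truth isoforms for candidate prefiltering: an alignment
## with d edits preserves at least L-k+1 - d*k of the contig's k-mers, so
## isoforms sharing fewer k-mers cannot be within the edit tolerance
truth_index <- function(truth, k = 21L) {
  kms <- lapply(truth, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    substr(rep(s, n), 1:n, 1:n + k - 1L)
  })
  list(kms = kms, k = k, seqs = truth, names = names(truth))
}

## anchored substitution-only distance: place the contig on the isoform at
## the offset implied by a shared k-mer and count mismatches over the
## overhang-free span; an upper bound on the infix edit distance (exact when
## the differences are pure substitutions, which is what a substitution-only
## threading assembler produces), with overhanging bases counted as edits
anchored_hamming <- function(contig, iso, qpos, spos) {
  off <- spos - qpos                   # 0-based start of contig on iso
  L <- nchar(contig)
  S <- nchar(iso)
  a <- max(0L, -off)                   # clipped contig prefix
  b <- max(0L, off + L - S)            # clipped contig suffix
  if (a + b >= L) return(Inf)
  cmp_q <- substr(contig, a + 1L, L - b)
  cmp_s <- substr(iso, off + a + 1L, off + L - b)
  hamming(cmp_q, cmp_s) + a + b
}

## edit distance of the contig against every isoform, Inf where the k-mer
## prefilter rules the isoform out; strand-agnostic
contig_distances <- function(contig, ti, tol) {
  k <- ti$k
  L <- nchar(contig)
  d <- rep(Inf, length(ti$seqs))
  if (L < k) return(d)
  lim <- ceiling(tol * L)
  rcc <- rc_dna(contig)
  for (orient in 1:2) {
    q <- if (orient == 1L) contig else rcc
    n <- L - k + 1L
    kms <- substr(rep(q, n), 1:n, 1:n + k - 1L)
    for (i in seq_along(ti$seqs)) {
      m <- match(kms, ti$kms[[i]])
      shared <- which(!is.na(m))
      if (length(shared) < n - lim * k || length(shared) == 0L) next
      ## an alignment with <= lim edits matches >= n - lim*k contig k-mers
      ## exactly, and their subject offsets span at most lim (total gap
      ## budget); an offset whose +/- lim window holds fewer shared k-mers
      ## can therefore be rejected outright
      offs <- m[shared] - shared
      so <- sort(offs)
      uo <- unique(so)
      wc <- findInterval(uo + lim, so) - findInterval(uo - lim - 0.5, so)
      keep <- wc >= n - lim * k
      if (!any(keep)) next
      top <- uo[keep][order(-wc[keep])]
      for (off in utils::head(top, 2L)) {
        j <- shared[offs == off][1L]
        dh <- anchored_hamming(q, ti$seqs[[i]], j - 1L, m[j] - 1L)
        if (dh > lim) {
          dh <- min(dh, banded_infix_distance(q, ti$seqs[[i]], off, lim))
        }
        d[i] <- min(d[i], dh)
        if (d[i] == 0) break
      }
    }
  }
  d
}

#' Assign a contig to a truth isoform
#'
#' Strand-agnostic comparison of an assembled contig against the set of truth
#' isoform sequences. The contig qualifies for an isoform when its best infix
#' edit distance is at most `tol` times the contig length. Categories follow
#' the standard assignment scheme: `unique` (one qualifying isoform, distance
#' 0), `unique_minor_difference` (one qualifying isoform, nonzero distance),
#' `ambiguous` (two or more), `inconsistent` (none), `non_informative`
#' (contig shorter than `min_len`).
#'
#' @param contig DNA string.
#' @param truth named character vector of isoform sequences (names are
#'   isoform ids).
#' @param tol edit-distance tolerance as a fraction of contig length.
#' @param min_len minimal informative contig length (default 300).
#' @return a one-row data.frame: `category`, `isoform_id` (or NA),
#'   `edit_distance`, `n_qualifying`.
#' @export
assign_contig <- function(contig, truth, tol = 0.01, min_len = 300L) {
  stopifnot(length(truth) > 0L)
  assign_contig_impl(contig, truth_index(truth), tol, min_len)$record
}

assign_contig_impl <- function(contig, ti, tol, min_len) {
  if (nchar(contig) < min_len) {
    return(list(record = data.frame(category = "non_informative",
                                    isoform_id = NA_character_,
                                    edit_distance = NA_integer_,
                                    n_qualifying = 0L,
                                    stringsAsFactors = FALSE),
                qual = integer(0)))
  }
  d <- contig_distances(contig, ti, tol)
  lim <- tol * nchar(contig)
  qual <- which(d <= lim)
  if (length(qual) == 0L) {
    cat_ <- "inconsistent"; iso <- NA_character_
    ed <- if (all(is.infinite(d))) NA_integer_ else as.integer(min(d))
  } else if (length(qual) == 1L) {
    iso <- ti$names[qual]
    ed <- as.integer(d[qual])
    cat_ <- if (ed == 0L) "unique" else "unique_minor_difference"
  } else {
    cat_ <- "ambiguous"; iso <- NA_character_
    ed <- as.integer(min(d[qual]))
  }
  list(record = data.frame(category = cat_, isoform_id = iso,
                           edit_distance = ed, n_qualifying = length(qual),
                           stringsAsFactors = FALSE),
       qual = qual)
}

## isoform sequences and isoform -> gene map from a list of gene models
truth_isoforms <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  seqs <- character(0)
  gene_of <- character(0)
  for (g in genes) {
    s <- vapply(names(g$isoforms), function(i) transcript_seq(g, i),
                character(1))
    seqs <- c(seqs, s)
    gene_of <- c(gene_of, stats::setNames(rep(g$gene_id, length(s)), names(s)))
  }
  list(seqs = seqs, gene_of = gene_of)
}

#' Assign every cluster and expand to per-barcode records
#'
#' Runs [assign_contig()] on each cluster representative and expands the
#' result over the cluster's supporting barcodes. The gene of a contig is the
#' gene of its qualifying isoforms when they agree (NA otherwise).
#'
#' @param clusters cluster data.frame from [cluster_paths()].
#' @param genes list of `gene_model` objects used for the simulation.
#' @param tol,min_len see [assign_contig()].
#' @return a data.frame: `contig_id`, `barcode`, `category`, `isoform_id`,
#'   `gene_id`, `edit_distance`.
#' @export
evaluate_run <- function(clusters, genes, tol = 0.01, min_len = 300L) {
  tiso <- truth_isoforms(genes)
  ti <- truth_index(tiso$seqs)
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    a <- assign_contig_impl(clusters$sequence[i], ti, tol, min_len)
    gene <- NA_character_
    qual_genes <- unique(unname(tiso$gene_of[a$qual]))
    if (length(qual_genes) == 1L) gene <- qual_genes
    bcs <- clusters$barcodes[[i]]
    if (length(bcs) == 0L) return(NULL)
    data.frame(contig_id = clusters$cluster_id[i], barcode = bcs,
               category = a$record$category,
               isoform_id = a$record$isoform_id,
               gene_id = gene, edit_distance = a$record$edit_distance,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(0), barcode = character(0),
                      category = character(0), isoform_id = character(0),
                      gene_id = character(0), edit_distance = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Score an assembly run against simulated truth
#'
#' Scoring units are (barcode, gene) molecules, so barcode collisions are
#' scored per molecule. A unit is *uniquely assigned* when exactly one contig
#' of that barcode is attributed to the gene and that contig's category is
#' unique/unique_minor_difference; it is *correct* when the assigned isoform
#' equals the simulated one. Then: precision = correct / uniquely assigned;
#' recall = correct / truth units with at least `min_pairs` read pairs; fixed
#' recall = recall after excluding from the denominator the units whose
#' barcode produced two or more contigs for that gene (fragmented clouds and
#' collisions diagnose themselves).
#'
#' @param assignments per-barcode assignment data.frame from [evaluate_run()].
#' @param truth truth data.frame from [simulate_clouds()].
#' @param min_pairs minimal pairs for a truth unit to count in recall.
#' @return an `eval_metrics` list: `precision`, `recall`, `fixed_recall`,
#'   `per_gene` (data.frame), `n_barcodes`, `n_barcodes_ge5`.
#' @export
score_run <- function(assignments, truth, min_pairs = 5L) {
  if (nrow(assignments) == 0L) {
    return(structure(list(precision = NA_real_, recall = NA_real_,
                          fixed_recall = NA_real_, per_gene = NULL,
                          n_barcodes = length(unique(truth$barcode)),
                          n_barcodes_ge5 = sum(truth$n_pairs >= min_pairs)),
                     class = "eval_metrics"))
  }
  a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  unit <- paste(a$barcode, a$gene_id)
  n_contigs <- table(unit)
  uniq_cat <- a$category %in% c("unique", "unique_minor_difference")
  one_contig <- as.vector(n_contigs[unit]) == 1L
  assigned <- a[uniq_cat & one_contig, , drop = FALSE]
  tkey <- paste(truth$barcode, truth$gene_id)
  sim_iso <- stats::setNames(truth$isoform_id, tkey)
  akey <- paste(assigned$barcode, assigned$gene_id)
  correct <- !is.na(sim_iso[akey]) & assigned$isoform_id == sim_iso[akey]

  precision <- if (nrow(assigned) > 0L) mean(correct) else NA_real_
  denom_units <- tkey[truth$n_pairs >= min_pairs]
  recall <- if (length(denom_units) > 0L) {
    sum(akey[correct] %in% denom_units) / length(denom_units)
  } else NA_real_
  multi_units <- names(n_contigs)[n_contigs >= 2L]
  fixed_denom <- setdiff(denom_units, multi_units)
  fixed_recall <- if (length(fixed_denom) > 0L) {
    sum(akey[correct] %in% fixed_denom) / length(fixed_denom)
  } else NA_real_

  per_gene <- do.call(rbind, lapply(unique(truth$gene_id), function(gid) {
    du <- tkey[truth$n_pairs >= min_pairs & truth$gene_id == gid]
    fu <- setdiff(du, multi_units)
    sel <- assigned$gene_id == gid
    data.frame(
      gene_id = gid,
      precision = if (any(sel)) mean(correct[sel]) else NA_real_,
      recall = if (length(du)) sum(akey[correct] %in% du) / length(du)
               else NA_real_,
      fixed_recall = if (length(fu)) sum(akey[correct] %in% fu) / length(fu)
                     else NA_real_,
      n_units = length(du), stringsAsFactors = FALSE)
  }))
  structure(list(precision = precision, recall = recall,
                 fixed_recall = fixed_recall, per_gene = per_gene,
                 n_barcodes = length(unique(truth$barcode)),
                 n_barcodes_ge5 = sum(truth$n_pairs >= min_pairs)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "eval_metrics: precision %.3f, recall %.3f, fixed recall %.3f (%d barcodes, %d with >=5 pairs)\n",
    x$precision, x$recall, x$fixed_recall, x$n_barcodes, x$n_barcodes_ge5))
  invisible(x)
}
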