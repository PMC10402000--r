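#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. Small inputs
#' are handled with base string ops (no per-call container overhead); large
#' batches go through Biostrings.
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of the same length.
#' @export
rc_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (length(x) <= 500L) {
    y <- chartr("ACGTacgtN", "TGCAtgcaN", x)
    return(vapply(y, function(s) intToUtf8(rev(utf8ToInt(s))),
                  character(1), USE.NAMES = FALSE))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## canonical form of a k-mer / sequence: the lexicographically smaller of the
## string and its reverse complement (plain C-locale byte comparison)
canonical_dna <- function(x) {
  r <- rc_dna(x)
  ifelse(cmp_le(x, r), x, r)
}

## locale-independent string comparison (byte order); A<C<G<T under ASCII
cmp_le <- function(a, b) {
  # `<=` on characters is locale dependent; for pure ACGT uppercase all common
  # collations agree with byte order, but be explicit for determinism
  old <- Sys.getlocale("LC_COLLATE")
  if (!identical(old, "C")) {
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
  }
  a <= b
}

## number of mismatching characters between equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths")
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## longest prefix of the comparison a vs b whose cumulative mismatch count
## stays within `budget`; returns list(len, mism) for that prefix
hamming_prefix <- function(a, b, budget) {
  n <- nchar(a)
  if (n == 0L) return(list(len = 0L, mism = 0L))
  neq <- utf8ToInt(a) != utf8ToInt(b)
  cm <- cumsum(neq)
  over <- which(cm > budget)
  if (length(over) == 0L) return(list(len = n, mism = cm[n]))
  cut <- over[1L] - 1L
  list(len = cut, mism = if (cut > 0L) cm[cut] else 0L)
}

## random DNA of given lengths (uses the current RNG stream)
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
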