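## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a plain character DNA string
#' @param x single character string (ACGT alphabet, case preserved as upper)
#' @return reverse-complemented string
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                       collapse = ""))
}

## Vectorised revcomp through Biostrings (faster for many sequences).
revcomp_many <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards.  All stochastic package code funnels through
## this so that a seed pins every output byte.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Random DNA of length n (uniform ACGT unless probs given).
random_dna <- function(n, probs = rep(0.25, 4)) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

## Random coding sequence of `aa` amino acids: ATG + aa-1 non-stop codons +
## one stop codon.  (The start codon counts as the first amino acid.)
random_cds <- function(aa) {
  codons <- character(aa - 1L)
  i <- 1L
  while (i <= aa - 1L) {
    cand <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
    if (!(cand %in% STOP_CODONS)) {
      codons[i] <- cand
      i <- i + 1L
    }
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

## substring of all k-mers (1-based start positions)
all_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## Summarise the op vector of .lf_align (0 match, 1 mismatch, 2 gap-in-b,
## 3 gap-in-a) into counts and the longest internal gap run.
summarise_ops <- function(ops) {
  if (length(ops) == 0L) {
    return(list(n_match = 0L, n_mismatch = 0L, n_gap = 0L, max_gap_run = 0L,
                columns = 0L))
  }
  is_gap <- ops >= 2L
  max_run <- 0L
  if (any(is_gap)) {
    r <- rle(is_gap)
    max_run <- max(r$lengths[r$values])
  }
  list(n_match = sum(ops == 0L), n_mismatch = sum(ops == 1L),
       n_gap = sum(is_gap), max_gap_run = as.integer(max_run),
       columns = length(ops))
}

## Pairwise alignment wrapper around the banded affine C++ kernel.
## mode "overlap": free leading/trailing gaps on both sequences;
## mode "fit":     `a` aligned end-to-end inside `b` (free ends on b only);
## mode "global":  no free end gaps.
pair_align <- function(a, b, mode = c("overlap", "fit", "global"),
                       match = 1, mismatch = -2, gap_open = -3, gap_ext = -1,
                       band = NULL, k = 15L) {
  mode <- match.arg(mode)
  n <- nchar(a); m <- nchar(b)
  off <- .lf_kmer_offset(a, b, as.integer(k))
  offset <- if (is.na(off[["offset"]])) m - n else off[["offset"]]
  if (is.null(band)) {
    band <- max(64L, as.integer(0.08 * max(n, m)) + 32L)
  }
  ## a second well-supported diagonal signals a large internal indel
  ## (e.g. a skipped exon): widen the band so the alignment spans it and
  ## the gap becomes visible instead of being clipped at the band edge.
  ## The widening is capped: an indel beyond ~500 nt is rejected by the
  ## coverage/overhang rules regardless, and an uncapped band on long
  ## sequences would allocate multi-gigabyte DP matrices.
  if (!is.na(off[["offset2"]]) && off[["votes2"]] >= 0.2 * off[["votes"]] &&
      off[["votes2"]] >= 10) {
    band <- max(band, min(512L, abs(off[["offset"]] - off[["offset2"]]) + 24L))
  }
  band <- min(band, 1500L)
  ## hard cap on the DP size (~1 GB at 4e7 cells across three matrices)
  max_cells <- 4e7
  if ((n + 1) * (2 * band + 1) > max_cells) {
    band <- max(64L, as.integer(max_cells / (n + 1) / 2))
  }
  if (mode == "global") {
    offset <- 0L
    band <- max(band, abs(m - n) + 16L)
  } else {
    band <- max(band, 16L)
  }
  fa <- mode == "overlap"
  fb <- mode %in% c("overlap", "fit")
  res <- .lf_align(a, b, match, mismatch, gap_open, gap_ext,
                   fa, fb, fa, fb, as.integer(band), as.integer(offset))
  if (is.null(res$ops)) return(NULL)
  s <- summarise_ops(res$ops)
  c(res, s)
}

## log-sum-exp
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
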