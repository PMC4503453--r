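## Poly(A)-site location and classification, upstream sequence composition
## profiles per site class, and NUE/FUE element detection.

#' Locate and classify poly(A) sites
#'
#' The terminal poly(A) site of a transcript is the genomic position of
#' its last aligned base (strand-aware).  Termini of polycistronic calls
#' are class `pORF2`; termini of monocistronic transcripts are `nORF`,
#' except at loci that act as an upstream (internal) ORF of a
#' polycistronic unit, where the independent transcripts' termini are the
#' attributed internal sites, class `pORF1`.
#'
#' @param alignments list of `lf_alignment` objects.
#' @param calls named list of `lf_ptu_call` objects (names are transcript
#'   ids of polycistronic transcripts).
#' @param genes annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @return data.frame `transcript_id`, `chrom`, `strand`, `pos`, `class`;
#'   transcripts at PTU loci without an independent upstream transcript
#'   simply contribute no `pORF1` row.
#' @export
locate_pas <- function(alignments, calls = list(), genes = NULL) {
  ptu_ids <- names(calls)
  ## loci (gene ids) acting as upstream/internal ORFs of some call
  upstream_genes <- character(0)
  if (length(calls)) {
    for (call in calls) {
      cg <- call$contained_genes
      if (length(cg) >= 2L)
        upstream_genes <- c(upstream_genes, cg[-length(cg)])
    }
  }
  rows <- lapply(alignments, function(a) {
    pos <- three_prime_end(a)
    cls <- if (a$query_id %in% ptu_ids) "pORF2" else "nORF"
    if (cls == "nORF" && length(upstream_genes) && !is.null(genes)) {
      g <- genes[genes$gene_id %in% upstream_genes, , drop = FALSE]
      span <- c(min(a$exons[, 1]), max(a$exons[, 2]))
      over <- g$chrom == a$chrom & g$strand == a$strand &
        g$start <= span[2] & g$end >= span[1]
      if (any(over)) cls <- "pORF1"
    }
    data.frame(transcript_id = a$query_id, chrom = a$chrom,
               strand = a$strand, pos = pos, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Upstream sequence composition profile of poly(A) sites
#'
#' Samples up to `n_sample` sites of one class without replacement
#' (seeded) and computes, for each transcript-strand position -W..-1
#' relative to (and including) the cleavage site, the frequency of each
#' base (T reported as U).  The expected frequency under a uniform
#' background (0.25) is attached as reference.
#'
#' @param sites data.frame from [locate_pas()] (or the simulator
#'   manifest): `chrom`, `strand`, `pos`, `class`.
#' @param genome named character vector of contig sequences.
#' @param class site class to profile.
#' @param W window width (nt).
#' @param n_sample maximum number of sites sampled.
#' @param seed RNG seed for the sampling.
#' @return list of class `lf_pas_profile`: `class`, `positions`
#'   (-W..-1), `freq` (4 x W matrix, rows A/C/G/U), `n_sites`,
#'   `n_skipped` (windows off the contig edge), `baseline` (0.25),
#'   `seed`.
#' @export
composition_profile <- function(sites, genome, class, W = 100L,
                                n_sample = 200L, seed = 1L) {
  sub <- sites[sites$class == class, , drop = FALSE]
  if (!nrow(sub)) stop("no sites of class ", class)
  with_rng(seed, {
    take <- min(n_sample, nrow(sub))
    sub <- sub[sort(sample.int(nrow(sub), take)), , drop = FALSE]
    counts <- matrix(0, nrow = 4, ncol = W,
                     dimnames = list(c("A", "C", "G", "U"), NULL))
    n_used <- 0L; n_skipped <- 0L
    for (i in seq_len(nrow(sub))) {
      g <- genome[[sub$chrom[i]]]
      p <- sub$pos[i]
      if (sub$strand[i] == "+") {
        if (p - W < 0L) { n_skipped <- n_skipped + 1L; next }
        win <- substring(g, p - W + 1L, p)
      } else {
        if (p + W - 1L > nchar(g)) { n_skipped <- n_skipped + 1L; next }
        win <- revcomp(substring(g, p, p + W - 1L))
      }
      chars <- chartr("T", "U", win)
      m <- match(strsplit(chars, "")[[1]], c("A", "C", "G", "U"))
      ok <- !is.na(m)
      counts[cbind(m[ok], which(ok))] <- counts[cbind(m[ok], which(ok))] + 1
      n_used <- n_used + 1L
    }
    if (n_used == 0L) stop("all windows of class ", class,
                           " fell off a contig edge")
    structure(list(class = class, positions = seq.int(-W, -1L),
                   freq = counts / n_used, n_sites = n_used,
                   n_skipped = n_skipped, baseline = 0.25, seed = seed),
              class = "lf_pas_profile")
  })
}

#' Detect NUE and FUE elements in a composition profile
#'
#' The A-rich near upstream element (NUE) is present when the maximum
#' sliding-window (width `win`) mean A frequency over `nue_range` reaches
#' `baseline + margin`; the U-rich far upstream element (FUE) likewise
#' for U over `fue_range`.
#'
#' @param profile an `lf_pas_profile`.
#' @param margin required excess over the 0.25 baseline (default 0.15).
#' @param win sliding window width (nt).
#' @param nue_range,fue_range position ranges searched (relative to the
#'   cleavage site).
#' @return list with `nue` and `fue`: each `NULL` when absent, else
#'   `position` (window start) and `excess` (window mean minus baseline).
#' @export
detect_elements <- function(profile, margin = 0.15, win = 6L,
                            nue_range = c(-35L, -5L),
                            fue_range = c(-70L, -25L)) {
  stopifnot(inherits(profile, "lf_pas_profile"))
  scan <- function(base, range) {
    ix <- which(profile$positions >= range[1] & profile$positions <= range[2])
    if (length(ix) < win) return(NULL)
    v <- profile$freq[base, ix]
    means <- vapply(seq_len(length(ix) - win + 1L), function(s)
      mean(v[s:(s + win - 1L)]), 0)
    best <- which.max(means)
    if (means[best] >= profile$baseline + margin)
      list(position = profile$positions[ix[best]],
           excess = means[best] - profile$baseline)
    else NULL
  }
  list(nue = scan("A", nue_range), fue = scan("U", fue_range))
}
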