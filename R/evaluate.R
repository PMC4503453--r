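## Exact splice-chain matching between transcript sets, with sensitivity /
## specificity stratified by per-locus isoform complexity.

#' Exact splice-chain match between two transcripts
#'
#' Multi-exon transcripts match when they lie on the same chromosome and
#' strand, have the same exon count, and identical ordered donor-acceptor
#' coordinates; the outer boundaries of the terminal exons are not
#' compared (5'/3' end slack).  Single-exon transcripts match when they
#' share a strand and their intervals reciprocally overlap by at least
#' `min_single_overlap`.
#'
#' @param query,reference `lf_alignment` objects (exon chains).
#' @param min_single_overlap reciprocal-overlap fraction for single-exon
#'   transcripts (default 0.5).
#' @return logical.
#' @export
exact_match <- function(query, reference, min_single_overlap = 0.5) {
  if (query$chrom != reference$chrom || query$strand != reference$strand)
    return(FALSE)
  nq <- nrow(query$exons); nr <- nrow(reference$exons)
  if (nq != nr) return(FALSE)
  if (nq == 1L) {
    s <- max(query$exons[1, 1], reference$exons[1, 1])
    e <- min(query$exons[1, 2], reference$exons[1, 2])
    ov <- max(0L, e - s + 1L)
    lq <- query$exons[1, 2] - query$exons[1, 1] + 1L
    lr <- reference$exons[1, 2] - reference$exons[1, 1] + 1L
    return(ov / lq >= min_single_overlap && ov / lr >= min_single_overlap)
  }
  junction_key(query) == junction_key(reference)
}

#' Score a transcript set against a reference set
#'
#' Loci are assigned jointly over both sets (exon overlap, same strand)
#' and scoring is restricted to loci detected in both.  Sensitivity is
#' the fraction of reference transcripts with at least one exactly
#' matching query; specificity is the fraction of query transcripts
#' exactly matching at least one reference.  Both are also stratified by
#' reference isoforms per locus (1, 2, ..., capped at `max_bin`).
#'
#' @param query,reference lists of `lf_alignment` objects.
#' @param max_bin largest complexity bin; loci with more reference
#'   isoforms are pooled into it.
#' @return list with `sensitivity`, `specificity`, `by_bin` (data.frame),
#'   `n_query`, `n_reference`, `loci` (the joint assignment).
#' @export
score_sets <- function(query, reference, max_bin = 5L) {
  qids <- vapply(query, function(a) a$query_id, "")
  rids <- vapply(reference, function(a) a$query_id, "")
  qtag <- paste0("q|", qids); rtag <- paste0("r|", rids)
  all <- c(query, reference)
  for (i in seq_along(all)) all[[i]]$query_id <- c(qtag, rtag)[i]
  loci <- assign_loci(all)
  qloc <- loci[qtag]; rloc <- loci[rtag]
  shared <- intersect(unique(qloc), unique(rloc))
  if (!length(shared)) {
    warning("no loci detected in both sets")
    return(list(sensitivity = NA_real_, specificity = NA_real_,
                by_bin = data.frame(), n_query = 0L, n_reference = 0L,
                loci = loci))
  }
  qk <- which(qloc %in% shared); rk <- which(rloc %in% shared)
  rmatched <- logical(length(rk)); qmatched <- logical(length(qk))
  for (ri in seq_along(rk)) {
    locus <- rloc[rk[ri]]
    for (qi in seq_along(qk)) {
      if (qloc[qk[qi]] != locus) next
      if (exact_match(query[[qk[qi]]], reference[[rk[ri]]])) {
        rmatched[ri] <- TRUE
        qmatched[qi] <- TRUE
      }
    }
  }
  rbin <- pmin(table(rloc[rk])[rloc[rk]], max_bin)
  bins <- sort(unique(as.integer(rbin)))
  by_bin <- do.call(rbind, lapply(bins, function(b) {
    rix <- which(as.integer(rbin) == b)
    qb <- which(as.integer(pmin(table(rloc[rk])[qloc[qk]], max_bin)) == b)
    data.frame(bin = b,
               n_reference = length(rix),
               sensitivity = mean(rmatched[rix]),
               n_query = length(qb),
               specificity = if (length(qb)) mean(qmatched[qb]) else NA_real_)
  }))
  list(sensitivity = mean(rmatched), specificity = mean(qmatched),
       by_bin = by_bin, n_query = length(qk), n_reference = length(rk),
       loci = loci)
}

#' Per-transcript recovery frequency across several query sets
#'
#' For each reference transcript, counts how many of the query sets
#' contain an exact match (the 0, 1, 2, ... frequency profile).
#'
#' @param query_sets named list of lists of `lf_alignment`.
#' @param reference list of `lf_alignment`.
#' @return data.frame `reference_id`, `n_sets_matched`.
#' @export
recovery_frequency <- function(query_sets, reference) {
  counts <- vapply(reference, function(r) {
    sum(vapply(query_sets, function(qs)
      any(vapply(qs, function(q) exact_match(q, r), TRUE)), TRUE))
  }, 0L)
  data.frame(reference_id = vapply(reference, function(a) a$query_id, ""),
             n_sets_matched = counts, stringsAsFactors = FALSE)
}
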