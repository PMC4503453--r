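## Redundancy removal: merge transcripts that differ only at the 5' start
## of their first exon, keeping the longest, while preserving alternative
## splicing and alternative polyadenylation.

## strand-aware 3' terminal genomic position of an alignment
three_prime_end <- function(a) {
  if (a$strand == "+") max(a$exons[, 2]) else min(a$exons[, 1])
}

aligned_span <- function(a) sum(a$exons[, 2] - a$exons[, 1] + 1L)

## single-linkage bucketing of 3' end positions within tol
bucket_ends <- function(ends, tol) {
  ord <- order(ends)
  b <- integer(length(ends))
  cur <- 1L
  b[ord[1]] <- cur
  if (length(ends) > 1L) {
    for (i in 2:length(ends)) {
      if (ends[ord[i]] - ends[ord[i - 1L]] > tol) cur <- cur + 1L
      b[ord[i]] <- cur
    }
  }
  b
}

#' Collapse mapped transcripts into a non-redundant set
#'
#' Multi-exon transcripts are grouped when they share an identical
#' junction chain (same chromosome and strand) and their 3' terminal
#' positions lie within `tol3p`; single-exon transcripts are grouped when
#' they share a strand, their 3' ends lie within `tol3p`, and the shorter
#' interval is contained in the longer.  Within each group only the
#' transcript with the longest aligned span survives, so 5'-degraded
#' copies are absorbed while alternative splicing and alternative
#' polyadenylation isoforms (3' ends differing by more than `tol3p`) are
#' preserved.  Merged ids are recorded for audit.
#'
#' @param alignments list of `lf_alignment` objects (already filtered).
#' @param tol3p 3'-end tolerance in nt (default 30).
#' @return list with `survivors` (list of `lf_alignment`) and `audit`
#'   (data.frame survivor_id, merged_id).
#' @export
collapse_mapped <- function(alignments, tol3p = 30L) {
  if (!length(alignments))
    return(list(survivors = list(),
                audit = data.frame(survivor_id = character(0),
                                   merged_id = character(0))))
  ids <- vapply(alignments, function(a) a$query_id, "")
  multi <- vapply(alignments, function(a) nrow(a$exons) > 1L, TRUE)
  keys <- vapply(alignments, function(a)
    paste(a$chrom, a$strand, junction_key(a), sep = "|"), "")
  ends <- vapply(alignments, three_prime_end, 0L)
  spans <- vapply(alignments, aligned_span, 0L)

  group_of <- rep(NA_integer_, length(alignments))
  ngroup <- 0L

  ## multi-exon: identical junction chain + 3'-end bucket
  for (key in unique(keys[multi])) {
    ix <- which(multi & keys == key)
    bk <- bucket_ends(ends[ix], tol3p)
    for (b in unique(bk)) {
      ngroup <- ngroup + 1L
      group_of[ix[bk == b]] <- ngroup
    }
  }

  ## single-exon: same strand, close 3' ends, containment (transitive)
  se <- which(!multi)
  if (length(se)) {
    parent <- seq_along(se)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (ai in seq_along(se)) {
      for (bi in seq_len(ai - 1L)) {
        a <- alignments[[se[ai]]]; b <- alignments[[se[bi]]]
        if (a$chrom != b$chrom || a$strand != b$strand) next
        if (abs(ends[se[ai]] - ends[se[bi]]) > tol3p) next
        sa <- a$exons[1, ]; sb <- b$exons[1, ]
        contained <- (sa[1] >= sb[1] && sa[2] <= sb[2]) ||
          (sb[1] >= sa[1] && sb[2] <= sa[2])
        if (contained) parent[find(ai)] <- find(bi)
      }
    }
    roots <- vapply(seq_along(se), find, 0L)
    for (r in unique(roots)) {
      ngroup <- ngroup + 1L
      group_of[se[roots == r]] <- ngroup
    }
  }

  surv <- logical(length(alignments))
  audit <- list()
  for (g in unique(group_of)) {
    ix <- which(group_of == g)
    win <- ix[order(-spans[ix], ids[ix])][1]
    surv[win] <- TRUE
    for (m in setdiff(ix, win))
      audit[[length(audit) + 1L]] <- data.frame(
        survivor_id = ids[win], merged_id = ids[m],
        stringsAsFactors = FALSE)
  }
  list(survivors = alignments[surv],
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(survivor_id = character(0), merged_id = character(0)))
}

#' Collapse unmapped transcripts (reference-free)
#'
#' A shorter transcript is merged into a longer one when an overlap
#' alignment covers at least `min_cov` of the shorter at `min_ident`
#' identity, the only free gap is at the 5' end, and the 3' ends agree
#' within `tol3p`.  Merging is transitive; the longest member of each
#' group survives.
#'
#' @param transcripts named character vector of oriented (transcript-
#'   sense) polished sequences.
#' @param tol3p 3'-end tolerance (nt).
#' @param min_cov,min_ident thresholds for polished sequences.
#' @param params a [cluster_params()] used for alignment scoring.
#' @return list with `survivors` (named character vector) and `audit`
#'   (data.frame survivor_id, merged_id).
#' @export
collapse_unmapped <- function(transcripts, tol3p = 30L, min_cov = 0.99,
                              min_ident = 0.99,
                              params = cluster_params(error_rate = 0.02)) {
  n <- length(transcripts)
  if (n == 0L)
    return(list(survivors = transcripts,
                audit = data.frame(survivor_id = character(0),
                                   merged_id = character(0))))
  ids <- names(transcripts)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- transcripts[[i]]; b <- transcripts[[j]]
      if (nchar(a) <= nchar(b)) { s <- a; l <- b } else { s <- b; l <- a }
      al <- pair_align(s, l, mode = "overlap",
                       match = params$match, mismatch = params$mismatch,
                       gap_open = params$gap_open, gap_ext = params$gap_ext,
                       band = params$band, k = params$k)
      if (is.null(al) || is.na(al$score[1])) next
      cov_s <- (al$a_end - al$a_start) / nchar(s)
      ident <- if (al$columns > 0) al$n_match / al$columns else 0
      trail_s <- nchar(s) - al$a_end
      trail_l <- nchar(l) - al$b_end
      lead_s <- al$a_start
      if (cov_s >= min_cov && ident >= min_ident &&
          lead_s <= tol3p && trail_s <= tol3p && trail_l <= tol3p)
        parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  surv <- logical(n)
  audit <- list()
  for (r in unique(roots)) {
    ix <- which(roots == r)
    win <- ix[order(-nchar(transcripts[ix]), ids[ix])][1]
    surv[win] <- TRUE
    for (m in setdiff(ix, win))
      audit[[length(audit) + 1L]] <- data.frame(
        survivor_id = ids[win], merged_id = ids[m],
        stringsAsFactors = FALSE)
  }
  list(survivors = transcripts[surv],
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(survivor_id = character(0), merged_id = character(0)))
}
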