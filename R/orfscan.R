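## ORF prediction on transcripts, polycistronic transcription-unit calling
## with annotation containment and short-read validation, per-ORF
## independent expression tiers, and tandem-duplicate enrichment.

#' Find non-overlapping ORFs on a transcript
#'
#' Enumerates all complete forward-frame ORFs (ATG to in-frame stop,
#' inclusive) of at least `min_aa` amino acids (the start codon counts,
#' the stop does not), then greedily selects a non-overlapping subset by
#' descending amino-acid length (ties: leftmost), reported in transcript
#' order.
#'
#' @param seq transcript-sense sequence.
#' @param min_aa minimum ORF length in amino acids (default 100).
#' @return data.frame `start`, `end` (1-based inclusive, includes the
#'   stop codon), `aa_length`, `frame` (0..2).
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      aa_length = integer(0), frame = integer(0))
  n <- nchar(seq)
  if (n < 3L * (min_aa + 1L)) return(empty)
  all_orfs <- list()
  for (f in 0:2) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stp)) next
    nxt <- stp[findInterval(atg, stp) + 1L]
    ok <- !is.na(nxt)
    for (i in which(ok)) {
      aa <- nxt[i] - atg[i] - 1L + 1L      # codons between ATG and stop + ATG
      if (aa >= min_aa)
        all_orfs[[length(all_orfs) + 1L]] <- c(
          start = starts[atg[i]], end = starts[nxt[i]] + 2L,
          aa_length = aa, frame = f)
    }
  }
  if (!length(all_orfs)) return(empty)
  orfs <- as.data.frame(do.call(rbind, all_orfs))
  orfs <- orfs[order(-orfs$aa_length, orfs$start), ]
  sel <- integer(0)
  for (i in seq_len(nrow(orfs))) {
    ok <- TRUE
    for (j in sel)
      if (orfs$start[i] <= orfs$end[j] && orfs$end[i] >= orfs$start[j]) {
        ok <- FALSE; break
      }
    if (ok) sel <- c(sel, i)
  }
  out <- orfs[sel, ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Check for stop codons in all frames of an inter-ORF gap
#'
#' @param seq transcript sequence.
#' @param orf_a_end 1-based end of the upstream ORF (inclusive).
#' @param orf_b_start 1-based start of the downstream ORF.
#' @return list with `frames` (logical of length 3: a stop codon exists
#'   in that frame of the gap), `all_frames` and `degenerate` (gap < 3
#'   nt, all frames reported FALSE).
#' @export
check_inter_orf_stops <- function(seq, orf_a_end, orf_b_start) {
  gap <- substring(seq, orf_a_end + 1L, orf_b_start - 1L)
  glen <- nchar(gap)
  if (glen < 3L)
    return(list(frames = c(FALSE, FALSE, FALSE), all_frames = FALSE,
                degenerate = TRUE))
  frames <- vapply(0:2, function(f) {
    starts <- seq.int(1L + f, glen - 2L, by = 3L)
    if (!length(starts)) return(FALSE)
    any(substring(gap, starts, starts + 2L) %in% STOP_CODONS)
  }, TRUE)
  list(frames = frames, all_frames = all(frames), degenerate = FALSE)
}

#' Call a polycistronic transcript
#'
#' A transcript is called polycistronic when it carries two or more
#' qualifying (>= `min_aa`) non-overlapping ORFs.  Annotated same-strand
#' genes whose full span lies within the alignment span are its contained
#' genes; the call is categorised `contained_2_4` when 2-4 genes are
#' fully contained, `readthrough_partial` when at least 2 genes are
#' merely overlapped, and `NA` in annotation-free mode.  Inter-ORF
#' stop-codon checks are attached per gap.
#'
#' @param id transcript id.
#' @param seq transcript sequence.
#' @param alignment its `lf_alignment` (genomic span and strand).
#' @param genes annotation data.frame with `gene_id`, `start`, `end`,
#'   `strand` (may be empty / NULL for annotation-free mode).
#' @param min_aa ORF size threshold (amino acids).
#' @return `NULL` (not polycistronic) or a list of class `lf_ptu_call`:
#'   `transcript_id`, `orfs`, `contained_genes` (5'->3'),
#'   `overlapped_genes`, `inter_orf_gaps`, `stops_all_frames` (per gap),
#'   `category`.
#' @export
call_polycistronic <- function(id, seq, alignment, genes = NULL,
                               min_aa = 100L) {
  orfs <- find_orfs(seq, min_aa)
  if (nrow(orfs) < 2L) return(NULL)
  span <- c(min(alignment$exons[, 1]), max(alignment$exons[, 2]))
  contained <- character(0); overlapped <- character(0)
  if (!is.null(genes) && nrow(genes)) {
    same <- genes$strand == alignment$strand
    within <- same & genes$start >= span[1] & genes$end <= span[2]
    over <- same & genes$start <= span[2] & genes$end >= span[1]
    contained <- genes$gene_id[within]
    overlapped <- genes$gene_id[over]
    ## order 5' -> 3' along the transcript
    ord <- if (alignment$strand == "+")
      order(genes$start[match(contained, genes$gene_id)]) else
        order(-genes$end[match(contained, genes$gene_id)])
    contained <- contained[ord]
  }
  gaps <- integer(0); stops <- logical(0)
  for (i in seq_len(nrow(orfs) - 1L)) {
    gaps <- c(gaps, orfs$start[i + 1L] - orfs$end[i] - 1L)
    stops <- c(stops,
               check_inter_orf_stops(seq, orfs$end[i],
                                     orfs$start[i + 1L])$all_frames)
  }
  category <- if (is.null(genes) || !nrow(genes)) NA_character_
  else if (length(contained) >= 2L && length(contained) <= 4L)
    "contained_2_4"
  else if (length(overlapped) >= 2L) "readthrough_partial"
  else NA_character_
  structure(list(transcript_id = id, orfs = orfs,
                 contained_genes = contained,
                 overlapped_genes = overlapped,
                 inter_orf_gaps = gaps, stops_all_frames = stops,
                 category = category), class = "lf_ptu_call")
}

#' Scan a transcript set for polycistronic calls
#'
#' @param sequences named character vector of transcript sequences.
#' @param alignments list of `lf_alignment` for those transcripts.
#' @param genes annotation data.frame (see [call_polycistronic()]).
#' @param min_aa ORF threshold.
#' @return named list of `lf_ptu_call` objects (callable transcripts only).
#' @export
scan_polycistronic <- function(sequences, alignments, genes = NULL,
                               min_aa = 100L) {
  byid <- setNames(alignments,
                   vapply(alignments, function(a) a$query_id, ""))
  out <- list()
  for (id in names(sequences)) {
    a <- byid[[id]]
    if (is.null(a)) next
    call <- call_polycistronic(id, sequences[[id]], a, genes, min_aa)
    if (!is.null(call)) out[[id]] <- call
  }
  out
}

## transcript position -> genomic position map for an exon chain
transcript_to_genomic <- function(alignment) {
  pos <- unlist(lapply(seq_len(nrow(alignment$exons)), function(i)
    alignment$exons[i, 1]:alignment$exons[i, 2]))
  if (alignment$strand == "-") rev(pos) else pos
}

#' Validate a polycistronic call with short-read support
#'
#' TRUE iff every base of the inter-ORF region(s) has short-read coverage
#' of at least `min_cov` and every junction of the transcript's alignment
#' has support >= 1 in the junction table.
#'
#' @param call an `lf_ptu_call`.
#' @param alignment the transcript's `lf_alignment`.
#' @param coverage data.frame `chrom`, `pos`, `cov` (genomic per-base).
#' @param junctions data.frame `chrom`, `donor`, `acceptor`, `strand`,
#'   `support`.
#' @param min_cov minimum per-base coverage over inter-ORF bases.
#' @return list `valid` (logical) and `reason`.
#' @export
validate_shortread <- function(call, alignment, coverage, junctions,
                               min_cov = 10) {
  t2g <- transcript_to_genomic(alignment)
  covmap <- setNames(coverage$cov,
                     paste0(coverage$chrom, ":", coverage$pos))
  orfs <- call$orfs
  for (i in seq_len(nrow(orfs) - 1L)) {
    tpos <- seq.int(orfs$end[i] + 1L, orfs$start[i + 1L] - 1L)
    tpos <- tpos[tpos >= 1L & tpos <= length(t2g)]
    if (!length(tpos)) next
    key <- paste0(alignment$chrom, ":", t2g[tpos])
    cv <- covmap[key]
    if (any(is.na(cv)))
      return(list(valid = FALSE, reason = "missing coverage rows"))
    if (any(cv < min_cov))
      return(list(valid = FALSE, reason = "inter-ORF coverage below minimum"))
  }
  if (nrow(alignment$exons) > 1L) {
    for (i in seq_len(nrow(alignment$exons) - 1L)) {
      d <- alignment$exons[i, 2] + 1L
      a <- alignment$exons[i + 1L, 1] - 1L
      hit <- junctions$chrom == alignment$chrom &
        junctions$donor == d & junctions$acceptor == a &
        junctions$strand == alignment$strand
      if (!any(hit) || all(junctions$support[hit] < 1))
        return(list(valid = FALSE, reason = "unsupported junction"))
    }
  }
  list(valid = TRUE, reason = NA_character_)
}

#' Independent expression tiers of polycistronic ORFs
#'
#' For each polycistronic call, the independent expression of the k-th
#' contained gene is the summed full-length read count of monocistronic
#' transcripts overlapping that gene (same strand), excluding transcripts
#' that are themselves polycistronic calls.  The table preserves ORF
#' order 5' to 3'.
#'
#' @param calls named list of `lf_ptu_call` objects.
#' @param alignments list of `lf_alignment` for all transcripts.
#' @param fl_counts named full-length read counts per transcript.
#' @param genes annotation data.frame.
#' @return data.frame `transcript_id`, `orf_index`, `gene_id`,
#'   `independent_fl`, `flagged` (TRUE when no independent transcript
#'   exists).
#' @export
expression_tiers <- function(calls, alignments, fl_counts, genes) {
  if (!length(calls))
    return(data.frame(transcript_id = character(0), orf_index = integer(0),
                      gene_id = character(0), independent_fl = numeric(0),
                      flagged = logical(0)))
  ptu_ids <- names(calls)
  mono <- Filter(function(a) !(a$query_id %in% ptu_ids), alignments)
  rows <- list()
  for (id in names(calls)) {
    call <- calls[[id]]
    for (k in seq_along(call$contained_genes)) {
      gid <- call$contained_genes[k]
      g <- genes[genes$gene_id == gid, ]
      cnt <- 0
      found <- FALSE
      for (a in mono) {
        if (a$chrom != g$chrom || a$strand != g$strand) next
        span <- c(min(a$exons[, 1]), max(a$exons[, 2]))
        if (span[1] <= g$end && span[2] >= g$start) {
          cnt <- cnt + (if (a$query_id %in% names(fl_counts))
            fl_counts[[a$query_id]] else 0)
          found <- TRUE
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, orf_index = k, gene_id = gid,
        independent_fl = cnt, flagged = !found, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric upper-tail enrichment test for tandem duplicates
#'
#' Probability of observing `k` or more tandem-duplicate genes among the
#' `n` polycistronic genes when `K` of the `N` genes are tandem
#' duplicates: `p = sum_{i=k..min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`,
#' evaluated in log space.
#'
#' @param N total genes.
#' @param K tandem-duplicate genes.
#' @param n genes in polycistronic units.
#' @param k tandem-duplicate genes in polycistronic units.
#' @return upper-tail p-value.
#' @export
tandem_enrichment <- function(N, K, n, k) {
  if (!(k >= 0 && k <= min(K, n) && K <= N && n <= N))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
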