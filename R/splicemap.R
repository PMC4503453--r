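## Spliced alignment of transcripts to a (toy) genome: unique-k-mer
## anchoring, collinear chaining, small-gap closure, intron calling with
## GT..AG boundary refinement; plus the coverage/identity acceptance
## filter, locus assignment, and BED12/GFF3 round-trip I/O.

#' Spliced-alignment parameters
#'
#' @param k anchor k-mer size (genome-unique k-mers only).
#' @param min_anchors minimum anchors required to attempt an alignment.
#' @param min_intron smallest genomic gap treated as an intron (nt);
#'   smaller gaps are closed by direct alignment.
#' @param max_small_gap largest transcript-side gap (nt) closed by direct
#'   alignment inside an exon.
#' @param max_clip head/tail length (nt) beyond which the transcript end
#'   is left unaligned (clipped) instead of force-aligned.
#' @param max_intron_span largest genomic gap (nt) the anchor chain may
#'   jump; stray far-away anchor runs are never chained.
#' @return list of parameters.
#' @export
splicemap_params <- function(k = 15L, min_anchors = 3L, min_intron = 40L,
                             max_small_gap = 30L, max_clip = 40L,
                             max_intron_span = 5000L) {
  as.list(environment())
}

#' Build a unique k-mer index of a genome
#'
#' @param genome named character vector (or [Biostrings::DNAStringSet]) of
#'   contig sequences.
#' @param k k-mer size.
#' @return an index object passed to [spliced_align()].
#' @export
genome_index <- function(genome, k = 15L) {
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  kmers <- character(0); contig <- character(0); pos <- integer(0)
  for (ctg in names(genome)) {
    km <- all_kmers(genome[[ctg]], k)
    kmers <- c(kmers, km)
    contig <- c(contig, rep(ctg, length(km)))
    pos <- c(pos, seq_along(km))
  }
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  structure(list(kmers = kmers[!dup], contig = contig[!dup],
                 pos = pos[!dup], genome = genome, k = as.integer(k)),
            class = "lf_genome_index")
}

## count matching characters of two equal-length strings
count_matches <- function(a, b) {
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

## align one orientation of a transcript; returns NULL or an alignment
spliced_align_one <- function(seq_q, idx, strand, params) {
  k <- idx$k
  tk <- all_kmers(seq_q, k)
  hit <- match(tk, idx$kmers)
  anchors <- which(!is.na(hit))
  if (length(anchors) < params$min_anchors) return(NULL)
  ctg <- idx$contig[hit[anchors]]
  main_ctg <- names(sort(table(ctg), decreasing = TRUE))[1]
  keep <- ctg == main_ctg
  tpos <- anchors[keep]
  gpos <- idx$pos[hit[anchors]][keep]
  genome <- idx$genome[[main_ctg]]
  if (length(tpos) < params$min_anchors) return(NULL)

  ## collapse anchors into collinear runs per diagonal
  diag <- gpos - tpos
  ord <- order(tpos)
  tpos <- tpos[ord]; gpos <- gpos[ord]; diag <- diag[ord]
  grp <- cumsum(c(TRUE, diff(diag) != 0L))
  runs <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ix) {
    c(tstart = tpos[ix[1]], tend = tpos[ix[length(ix)]] + k - 1L,
      gstart = gpos[ix[1]], gend = gpos[ix[length(ix)]] + k - 1L,
      n = length(ix))
  }))
  runs <- runs[order(runs[, "tstart"]), , drop = FALSE]
  ## chain: keep runs strictly increasing in both coordinates (greedy by
  ## run weight via longest-increasing-chain DP on anchor count)
  n <- nrow(runs)
  best <- runs[, "n"]; prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (runs[j, "tend"] < runs[i, "tstart"] + k &&
          runs[j, "gend"] < runs[i, "gstart"] &&
          runs[i, "gstart"] - runs[j, "gend"] <= params$max_intron_span &&
          best[j] + runs[i, "n"] > best[i]) {
        best[i] <- best[j] + runs[i, "n"]
        prev[i] <- j
      }
    }
  }
  chain <- integer(0)
  i <- which.max(best)
  while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
  runs <- runs[chain, , drop = FALSE]

  ## trim overlapping neighbours (repeat-induced) defensively
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      ov <- max(runs[i - 1L, "tend"] - runs[i, "tstart"] + 1L,
                runs[i - 1L, "gend"] - runs[i, "gstart"] + 1L, 0L)
      if (ov > 0L) {
        runs[i, "tstart"] <- runs[i, "tstart"] + ov
        runs[i, "gstart"] <- runs[i, "gstart"] + ov
      }
    }
    runs <- runs[runs[, "tend"] >= runs[, "tstart"], , drop = FALSE]
  }
  if (nrow(runs) == 0L) return(NULL)

  donor_ok <- function(istart, iend) {
    d <- substring(genome, istart, istart + 1L)
    a <- substring(genome, iend - 1L, iend)
    if (strand == "+") d == "GT" && a == "AG" else d == "CT" && a == "AC"
  }

  nmatch <- 0L; ncol_al <- 0L
  exons <- NULL
  cur_ex_start <- NA_integer_
  junctions <- NULL
  tlen <- nchar(seq_q)
  t_aligned <- 0L

  ## head: align right-anchored against the genome just upstream (gapped,
  ## so an indel near the read start does not spoil downstream columns)
  head_len <- runs[1, "tstart"] - 1L
  g_ex_start <- runs[1, "gstart"]
  if (head_len > 0L && head_len <= params$max_clip &&
      runs[1, "gstart"] - head_len - 8L >= 1L) {
    hseq <- substring(seq_q, 1L, head_len)
    gwin <- substring(genome, runs[1, "gstart"] - head_len - 8L,
                      runs[1, "gstart"] - 1L)
    al <- pair_align(hseq, gwin, mode = "fit", band = head_len + 16L)
    if (!is.null(al) && !is.na(al$score[1])) {
      nmatch <- nmatch + al$n_match
      ncol_al <- ncol_al + al$columns
      t_aligned <- t_aligned + head_len
      g_ex_start <- runs[1, "gstart"] - (nchar(gwin) - al$b_start)
    }
  }
  cur_ex_start <- g_ex_start

  for (i in seq_len(nrow(runs))) {
    rl <- runs[i, "tend"] - runs[i, "tstart"] + 1L
    nmatch <- nmatch + count_matches(
      substring(seq_q, runs[i, "tstart"], runs[i, "tend"]),
      substring(genome, runs[i, "gstart"], runs[i, "gend"]))
    ncol_al <- ncol_al + rl
    t_aligned <- t_aligned + rl
    if (i == nrow(runs)) break
    tgap <- runs[i + 1L, "tstart"] - runs[i, "tend"] - 1L
    ggap <- runs[i + 1L, "gstart"] - runs[i, "gend"] - 1L
    if (ggap - tgap >= params$min_intron && tgap <= params$max_small_gap) {
      ## intron: place the tgap leftover transcript bases on the flanks.
      ## The boundary may shift within +/- `refine` anchored bases and the
      ## intron length may differ from the anchor-implied length (indels
      ## in the unanchored gap distort it), so candidate donor/acceptor
      ## positions are enumerated by their canonical dinucleotides and the
      ## flank bases are scored by a small gapped alignment against the
      ## concatenated exonic flanks.
      refine <- min(8L,
                    runs[i, "tend"] - runs[i, "tstart"],
                    runs[i + 1L, "tend"] - runs[i + 1L, "tstart"])
      tL <- runs[i, "tend"] - refine       # last fixed transcript base left
      tR <- runs[i + 1L, "tstart"] + refine # first fixed base right
      gL0 <- runs[i, "gend"] - refine
      gR0 <- runs[i + 1L, "gstart"] + refine
      m <- tR - tL - 1L                    # movable transcript bases
      bases <- substring(seq_q, tL + 1L, tR - 1L)
      ilen0 <- (gR0 - gL0 - 1L) - m        # anchor-implied intron length
      don_pat <- if (strand == "+") "GT" else "CT"
      acc_pat <- if (strand == "+") "AG" else "AC"
      dcand <- (gL0 + 1L):(gL0 + m + 1L)
      dcand <- dcand[substring(genome, dcand, dcand + 1L) == don_pat]
      acand <- (gR0 - m - 1L):(gR0 - 1L)
      acand <- acand[substring(genome, acand - 1L, acand) == acc_pat]
      flank_score <- function(istart, iend) {
        fl <- paste0(substring(genome, gL0 + 1L, istart - 1L),
                     substring(genome, iend + 1L, gR0 - 1L))
        if (m == 0L && nchar(fl) == 0L) return(list(sc = 0, nm = 0L, nc = 0L))
        al <- pair_align(bases, fl, mode = "global")
        if (is.null(al) || is.na(al$score[1]))
          return(list(sc = -Inf, nm = 0L, nc = max(m, nchar(fl))))
        list(sc = al$score, nm = al$n_match, nc = al$columns)
      }
      best <- NULL; best_sc <- -Inf
      for (istart in dcand) {
        for (iend in acand) {
          il <- iend - istart + 1L
          if (il < params$min_intron || abs(il - ilen0) > 12L) next
          fs <- flank_score(istart, iend)
          sc <- fs$sc + 1000
          if (sc > best_sc) {
            best_sc <- sc
            best <- list(istart = istart, iend = iend, nm = fs$nm,
                         nc = fs$nc)
          }
        }
      }
      if (is.null(best)) {
        ## no canonical pair: fall back to the anchor-implied length with
        ## the split maximising flank matches
        for (s in 0:m) {
          istart <- gL0 + s + 1L
          iend <- istart + ilen0 - 1L
          if (iend - istart + 1L < params$min_intron) next
          fs <- flank_score(istart, iend)
          if (fs$sc > best_sc) {
            best_sc <- fs$sc
            best <- list(istart = istart, iend = iend, nm = fs$nm,
                         nc = fs$nc)
          }
        }
      }
      exons <- rbind(exons, c(cur_ex_start, best$istart - 1L))
      junctions <- rbind(junctions, c(best$istart, best$iend))
      cur_ex_start <- best$iend + 1L
      ## the 2*refine anchored bases were already counted inside the runs;
      ## count only the leftover gap columns here
      nmatch <- nmatch + max(0L, best$nm - 2L * refine)
      ncol_al <- ncol_al + max(0L, best$nc - 2L * refine)
      t_aligned <- t_aligned + tgap
    } else {
      ## small gap inside an exon: close by direct (banded) alignment
      tseq <- substring(seq_q, runs[i, "tend"] + 1L,
                        runs[i + 1L, "tstart"] - 1L)
      gseq <- substring(genome, runs[i, "gend"] + 1L,
                        runs[i + 1L, "gstart"] - 1L)
      if (nchar(tseq) == 0L && nchar(gseq) == 0L) {
        ## nothing to do
      } else if (nchar(tseq) == nchar(gseq)) {
        nmatch <- nmatch + count_matches(tseq, gseq)
        ncol_al <- ncol_al + nchar(tseq)
      } else if (max(nchar(tseq), nchar(gseq)) <= 400L) {
        al <- pair_align(tseq, gseq, mode = "global")
        if (!is.null(al) && !is.na(al$score[1])) {
          nmatch <- nmatch + al$n_match
          ncol_al <- ncol_al + al$columns
        } else {
          ncol_al <- ncol_al + max(nchar(tseq), nchar(gseq))
        }
      } else {
        ## oversized unanchored stretch: count as unmatched columns; the
        ## final chain alignment provides the real identity
        ncol_al <- ncol_al + max(nchar(tseq), nchar(gseq))
      }
      t_aligned <- t_aligned + nchar(tseq)
    }
  }

  ## tail (gapped, left-anchored at the last run)
  last <- nrow(runs)
  tail_len <- tlen - runs[last, "tend"]
  g_ex_end <- runs[last, "gend"]
  if (tail_len > 0L && tail_len <= params$max_clip &&
      runs[last, "gend"] + tail_len + 8L <= nchar(genome)) {
    tseq <- substring(seq_q, runs[last, "tend"] + 1L, tlen)
    gwin <- substring(genome, runs[last, "gend"] + 1L,
                      runs[last, "gend"] + tail_len + 8L)
    al <- pair_align(tseq, gwin, mode = "fit", band = tail_len + 16L)
    if (!is.null(al) && !is.na(al$score[1])) {
      nmatch <- nmatch + al$n_match
      ncol_al <- ncol_al + al$columns
      t_aligned <- t_aligned + tail_len
      g_ex_end <- runs[last, "gend"] + al$b_end
    }
  }
  exons <- rbind(exons, c(cur_ex_start, g_ex_end))

  ## final coverage/identity: one gapped alignment of the whole transcript
  ## against the spliced sequence of the called exon chain (robust to the
  ## fragmented anchor runs that indel errors produce)
  exmat <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  chain_seq <- paste(substring(genome, exmat[, 1], exmat[, 2]),
                     collapse = "")
  al <- pair_align(seq_q, chain_seq, mode = "overlap")
  if (is.null(al) || is.na(al$score[1])) return(NULL)
  list(chrom = main_ctg, strand = strand,
       exons = exmat,
       junctions = junctions,
       n_match = al$n_match, columns = al$columns,
       coverage = (al$a_end - al$a_start) / tlen,
       identity = if (al$columns > 0) al$n_match / al$columns else 0)
}

#' Spliced alignment of a transcript to a genome
#'
#' Anchors genome-unique k-mer matches, chains collinear anchor runs,
#' closes small gaps by direct alignment, calls genomic gaps >=
#' `min_intron` as introns with boundary refinement that prefers GT..AG
#' donors/acceptors (strand-aware), and reports alignment coverage (of
#' the query) and identity.  Both orientations are tried; the better one
#' is returned.
#'
#' @param transcript transcript sequence (character).
#' @param idx a [genome_index()].
#' @param params a [splicemap_params()] list.
#' @param id query id attached to the result.
#' @return `NULL` if no anchor chain is found, else a list of class
#'   `lf_alignment`: `query_id`, `chrom`, `strand`, `exons` (1-based
#'   inclusive genomic intervals, ascending), `coverage`, `identity`.
#' @export
spliced_align <- function(transcript, idx, params = splicemap_params(),
                          id = "query") {
  stopifnot(inherits(idx, "lf_genome_index"))
  fw <- spliced_align_one(transcript, idx, "+", params)
  rv <- spliced_align_one(revcomp(transcript), idx, "-", params)
  pick <- if (is.null(fw) && is.null(rv)) return(NULL)
  else if (is.null(rv)) fw
  else if (is.null(fw)) rv
  else if (fw$n_match >= rv$n_match) fw else rv
  pick$query_id <- id
  class(pick) <- "lf_alignment"
  pick
}

#' Map a set of transcripts to a genome
#'
#' @param transcripts named character vector of transcript sequences.
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param params a [splicemap_params()] list.
#' @return list of `lf_alignment` objects (unmapped queries are dropped).
#' @export
map_transcripts <- function(transcripts, genome,
                            params = splicemap_params()) {
  idx <- if (inherits(genome, "lf_genome_index")) genome else
    genome_index(genome, params$k)
  alns <- lapply(names(transcripts), function(id)
    spliced_align(transcripts[[id]], idx, params, id = id))
  alns[!vapply(alns, is.null, TRUE)]
}

#' Filter alignments by coverage and identity
#'
#' Keeps exactly the alignments with `coverage >= min_cov` and
#' `identity >= min_ident` (boundary values accepted).
#'
#' @param alignments list of `lf_alignment` objects.
#' @param min_cov minimum query coverage (default 0.99).
#' @param min_ident minimum alignment identity (default 0.85).
#' @return the accepted subset (same structure).
#' @export
filter_alignments <- function(alignments, min_cov = 0.99, min_ident = 0.85) {
  Filter(function(a) a$coverage >= min_cov && a$identity >= min_ident,
         alignments)
}

#' Assign transcripts to loci by exon overlap
#'
#' Transcripts whose exons overlap by at least 1 bp on the same strand and
#' chromosome are merged transitively into one locus; locus ids are
#' assigned in order of leftmost genomic coordinate.
#'
#' @param alignments list of `lf_alignment` objects.
#' @return named character vector: query id -> locus id.
#' @export
assign_loci <- function(alignments) {
  if (!length(alignments)) return(setNames(character(0), character(0)))
  gr <- alignment_exon_granges(alignments)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::mcols(gr)$idx[S4Vectors::queryHits(hits)]
  si <- S4Vectors::mcols(gr)$idx[S4Vectors::subjectHits(hits)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = qi, to = si), directed = FALSE,
    vertices = data.frame(name = seq_along(alignments)))
  comp <- igraph::components(g)$membership
  starts <- vapply(alignments, function(a) min(a$exons[, 1]), 0L)
  locus_start <- tapply(starts, comp, min)
  ord <- rank(locus_start, ties.method = "first")
  ids <- sprintf("locus_%04d", ord[as.character(comp)])
  setNames(ids, vapply(alignments, function(a) a$query_id, ""))
}

## one GRanges row per exon, with idx = index of the parent alignment
alignment_exon_granges <- function(alignments) {
  rows <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    GenomicRanges::GRanges(a$chrom,
                           IRanges::IRanges(a$exons[, 1], a$exons[, 2]),
                           strand = a$strand, idx = i)
  })
  do.call(c, rows)
}

## ---------------------------------------------------------------------------
## interval-format I/O (1-based inclusive internally, per GRanges)
## ---------------------------------------------------------------------------

#' Write alignments/exon chains as BED12
#'
#' @param alignments list of `lf_alignment` objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed12 <- function(alignments, path) {
  gr <- GenomicRanges::GRanges(
    vapply(alignments, function(a) a$chrom, ""),
    IRanges::IRanges(vapply(alignments, function(a) min(a$exons[, 1]), 0L),
                     vapply(alignments, function(a) max(a$exons[, 2]), 0L)),
    strand = vapply(alignments, function(a) a$strand, ""))
  S4Vectors::mcols(gr)$name <- vapply(alignments,
                                      function(a) a$query_id, "")
  blocks <- IRanges::IRangesList(lapply(alignments, function(a) {
    off <- min(a$exons[, 1])
    IRanges::IRanges(a$exons[, 1] - off + 1L, a$exons[, 2] - off + 1L)
  }))
  S4Vectors::mcols(gr)$blocks <- blocks
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED12 file as alignment exon chains
#'
#' @param path BED12 file.
#' @return list of `lf_alignment` objects (coverage/identity `NA`).
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    off <- GenomicRanges::start(gr)[i]
    bl <- S4Vectors::mcols(gr)$blocks[[i]]
    exons <- cbind(start = off + IRanges::start(bl) - 1L,
                   end = off + IRanges::end(bl) - 1L)
    out[[i]] <- structure(list(
      query_id = S4Vectors::mcols(gr)$name[i],
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exons, coverage = NA_real_, identity = NA_real_),
      class = "lf_alignment")
  }
  out
}

#' Write a GFF3 annotation
#' @param gr a `GRanges` with `type`, `ID`, `Parent` metadata.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation
#' @param path GFF3 file.
#' @return a `GRanges`.
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

## junction chain of an alignment as a canonical string key
junction_key <- function(a) {
  if (nrow(a$exons) < 2L) return("")
  d <- a$exons[-nrow(a$exons), 2] + 1L
  ac <- a$exons[-1L, 1] - 1L
  paste(paste0(d, "-", ac), collapse = ",")
}
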