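## Conservation of adjacent same-strand gene pairs across annotated
## genomes: per-species best protein hits and gene-order adjacency.

#' Best protein hits between two proteomes
#'
#' For each query protein, the subject with the maximum Smith-Waterman
#' local alignment score (BLOSUM62, gap open 11, gap extension 1) is
#' reported when that score reaches `min_score`; ties go to the
#' lexicographically smallest subject id.
#'
#' @param query,subject named character vectors of protein sequences.
#' @param min_score minimum alignment score.
#' @return named character vector: query id -> best subject id (queries
#'   without a qualifying hit are absent).
#' @export
best_hits <- function(query, subject, min_score = 50) {
  if (!length(subject) || !length(query))
    return(setNames(character(0), character(0)))
  subj_set <- Biostrings::AAStringSet(subject)
  out <- character(0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (qid in names(query)) {
    sc <- Biostrings::pairwiseAlignment(
      subj_set, Biostrings::AAString(query[[qid]]),
      type = "local", substitutionMatrix = B62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    best <- max(sc)
    if (best >= min_score) {
      winners <- sort(names(subject)[sc >= best - 1e-9])
      out[qid] <- winners[1]
    }
  }
  out
}

#' Conservation of adjacent same-strand gene pairs across species
#'
#' A pair (A, B) is conserved in a species when both genes have best hits
#' there, the two hits are directly adjacent in that species' gene order
#' (consecutive ranks on the same contig, no intervening gene) and lie on
#' the same strand.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (source gene ids).
#' @param species named list; each element has `proteins` (named
#'   character vector) and `gene_order` (data.frame `contig`, `rank`,
#'   `gene_id`, `strand`).
#' @param source_proteins named character vector of source proteomes for
#'   the pair genes.
#' @param min_score minimum best-hit alignment score.
#' @param reciprocal require the best hit to hold in both directions.
#' @return list with `matrix` (logical, pairs x species), `totals`
#'   (conserved pairs per species).
#' @export
pair_conservation <- function(pairs, species, source_proteins,
                              min_score = 50, reciprocal = FALSE) {
  mat <- matrix(FALSE, nrow = nrow(pairs), ncol = length(species),
                dimnames = list(paste(pairs$gene_a, pairs$gene_b,
                                      sep = "|"),
                                names(species)))
  need <- unique(c(pairs$gene_a, pairs$gene_b))
  qprot <- source_proteins[need]
  for (sp in names(species)) {
    spec <- species[[sp]]
    bh <- best_hits(qprot, spec$proteins, min_score)
    if (reciprocal) {
      back <- best_hits(spec$proteins[unique(bh)], qprot, min_score)
      bh <- bh[!is.na(back[bh]) & back[bh] == names(bh)]
    }
    go <- spec$gene_order
    for (p in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[p]; b <- pairs$gene_b[p]
      ha <- if (a %in% names(bh)) bh[[a]] else NA_character_
      hb <- if (b %in% names(bh)) bh[[b]] else NA_character_
      if (is.na(ha) || is.na(hb)) next
      ra <- go[go$gene_id == ha, , drop = FALSE]
      rb <- go[go$gene_id == hb, , drop = FALSE]
      if (nrow(ra) != 1L || nrow(rb) != 1L) next
      mat[p, sp] <- ra$contig == rb$contig &&
        abs(ra$rank - rb$rank) == 1L && ra$strand == rb$strand
    }
  }
  list(matrix = mat, totals = colSums(mat))
}
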