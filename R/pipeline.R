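## End-to-end driver: classify -> cluster -> polish -> map -> collapse,
## plus helpers binding pipeline output to the simulator's ground truth.

#' Ground-truth isoforms as exon chains
#'
#' @param sim an `lf_sim` object.
#' @return list of `lf_alignment` objects, one per true isoform.
#' @export
sim_truth_alignments <- function(sim) {
  iso <- sim$isoforms$isoforms
  lapply(seq_len(nrow(iso)), function(i) {
    structure(list(query_id = iso$iso_id[i], chrom = iso$chrom[i],
                   strand = iso$strand[i],
                   exons = sim$isoforms$exons[[iso$iso_id[i]]],
                   coverage = 1, identity = 1), class = "lf_alignment")
  })
}

#' Run the full long-read isoform pipeline
#'
#' Classifies reads, clusters full-length reads and polishes consensus
#' sequences with non-full-length reads, maps the retained consensus
#' transcripts to the genome, applies the coverage/identity filter and
#' collapses 5' redundancy.
#'
#' @param reads named character vector of read sequences.
#' @param quals optional named quality strings.
#' @param genome named character vector of contigs.
#' @param primer5,primer3 cDNA primer sequences.
#' @param error_rate expected per-base error rate of the reads (drives
#'   alignment thresholds).
#' @param cl_params optional [cluster_params()] override.
#' @param map_params a [splicemap_params()] list.
#' @param min_cov,min_ident alignment acceptance thresholds.
#' @param tol3p collapse 3'-end tolerance.
#' @param min_nfl_len shortest trimmed non-full-length read recruited for
#'   polishing.
#' @return list of class `lf_pipeline`: `classification` (data.frame),
#'   `transcripts` (`lf_transcripts`), `alignments` (accepted), `collapsed`
#'   (survivors + audit), `fl_counts` (per surviving transcript, merged
#'   counts absorbed), `loci`, `sequences` (surviving consensus).
#' @export
run_pipeline <- function(reads, quals = NULL, genome, primer5, primer3,
                         error_rate = 0.15, cl_params = NULL,
                         map_params = splicemap_params(),
                         min_cov = 0.99, min_ident = 0.85, tol3p = 30L,
                         min_nfl_len = 50L) {
  cls <- classify_reads(reads, primer5, primer3, quals)
  fl_ids <- cls$read_id[cls$classification == "full_length"]
  nfl_ids <- cls$read_id[cls$classification == "non_full_length" &
                           nchar(cls$trimmed_seq) >= min_nfl_len]
  fl <- setNames(cls$trimmed_seq[match(fl_ids, cls$read_id)], fl_ids)
  nfl <- setNames(cls$trimmed_seq[match(nfl_ids, cls$read_id)], nfl_ids)
  flq <- if (!is.null(quals)) quals[fl_ids] else NULL
  nflq <- if (!is.null(quals)) quals[nfl_ids] else NULL

  params <- if (is.null(cl_params)) cluster_params(error_rate = error_rate)
  else cl_params
  tr <- cluster_isoforms(fl, flq, nfl, nflq, params)

  idx <- genome_index(genome, map_params$k)
  alns <- map_transcripts(tr$consensus, idx, map_params)
  acc <- filter_alignments(alns, min_cov = min_cov, min_ident = min_ident)
  coll <- collapse_mapped(acc, tol3p = tol3p)

  counts <- setNames(tr$clusters$fl_count, tr$clusters$cluster_id)
  fl_counts <- setNames(numeric(length(coll$survivors)),
                        vapply(coll$survivors, function(a) a$query_id, ""))
  for (id in names(fl_counts)) fl_counts[id] <- counts[id]
  if (nrow(coll$audit)) {
    for (r in seq_len(nrow(coll$audit)))
      fl_counts[coll$audit$survivor_id[r]] <-
        fl_counts[coll$audit$survivor_id[r]] +
        counts[coll$audit$merged_id[r]]
  }
  surv_ids <- names(fl_counts)
  structure(list(classification = cls, transcripts = tr,
                 alignments = acc, collapsed = coll,
                 fl_counts = fl_counts,
                 loci = assign_loci(coll$survivors),
                 sequences = tr$consensus[surv_ids]),
            class = "lf_pipeline")
}

#' @export
print.lf_pipeline <- function(x, ...) {
  cat("longform pipeline result\n")
  cat("  reads classified:   ", nrow(x$classification), "\n")
  cat("  full-length:        ",
      sum(x$classification$classification == "full_length"), "\n")
  cat("  retained clusters:  ", sum(x$transcripts$clusters$retained), "\n")
  cat("  accepted alignments:", length(x$alignments), "\n")
  cat("  final transcripts:  ", length(x$collapsed$survivors), "\n")
  invisible(x)
}

#' @export
print.lf_transcripts <- function(x, ...) {
  cat("longform cluster set: ", nrow(x$clusters), "clusters,",
      sum(x$clusters$retained), "retained\n")
  invisible(x)
}
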