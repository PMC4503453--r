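## Full-length read classification: primer detection, polyA detection,
## orientation and trimming.  A read is full-length when the 5' primer, a
## polyA tail and the 3' primer are all present in one orientation; an
## extra internal primer occurrence marks a chimeric artifact.

#' Classification parameters
#'
#' @param end_window nt from each read end within which a primer hit must
#'   start.
#' @param max_edit_fraction maximum edit distance for a primer hit, as a
#'   fraction of primer length.
#' @param chimera_edit_fraction stricter edit fraction for internal primer
#'   hits that trigger a chimera call (more specific, so high-error reads
#'   are not spuriously discarded).
#' @param min_polyA_len minimum polyA tail length (nt).
#' @param min_A_fraction minimum A fraction maintained while scanning the
#'   tail 3' to 5'.
#' @param polyA_end_slack nt of non-A sequence tolerated at the extreme 3'
#'   end of the tail (primer-boundary jitter from indel errors).
#' @return list of parameters.
#' @export
classify_params <- function(end_window = 100L, max_edit_fraction = 0.3,
                            chimera_edit_fraction = 0.15,
                            min_polyA_len = 15L, min_A_fraction = 0.8,
                            polyA_end_slack = 5L) {
  list(end_window = as.integer(end_window),
       max_edit_fraction = max_edit_fraction,
       chimera_edit_fraction = chimera_edit_fraction,
       min_polyA_len = as.integer(min_polyA_len),
       min_A_fraction = min_A_fraction,
       polyA_end_slack = as.integer(polyA_end_slack))
}

#' Find the best primer occurrence near a read end
#'
#' Semi-global search: the whole primer is aligned against a window at the
#' requested end of the read; the hit with the lowest edit distance whose
#' start lies within `end_window` of that end is returned, or `NULL` if the
#' minimum edit distance exceeds `max_edit_fraction * nchar(primer)`.
#'
#' @param seq read sequence (character).
#' @param primer primer sequence, length >= 10.
#' @param end which read end to search, `"5"` or `"3"`.
#' @param end_window nt from the read end within which the hit must start.
#' @param max_edit_fraction maximum allowed edit distance fraction.
#' @return `NULL` or a list with `start`, `end` (1-based, inclusive, in
#'   read coordinates) and `edits`.
#' @export
find_primer <- function(seq, primer, end = c("5", "3"), end_window = 100L,
                        max_edit_fraction = 0.3) {
  end <- match.arg(end)
  plen <- nchar(primer)
  if (plen < 10L) stop("primer length must be >= 10")
  n <- nchar(seq)
  win <- min(n, end_window + plen + ceiling(max_edit_fraction * plen))
  if (end == "5") {
    region <- substring(seq, 1L, win)
    hit <- .lf_edit_find(region, primer)
    if (is.na(hit[["start"]])) return(NULL)
    start <- hit[["start"]]; stop_ <- hit[["end"]]
  } else {
    region <- substring(seq, n - win + 1L, n)
    hit <- .lf_edit_find(region, primer)
    if (is.na(hit[["start"]])) return(NULL)
    start <- n - win + hit[["start"]]
    stop_ <- n - win + hit[["end"]]
  }
  max_edits <- max_edit_fraction * plen
  in_window <- if (end == "5") (start - 1L) <= end_window else
    (n - stop_) <= end_window
  if (hit[["dist"]] > max_edits || !in_window) return(NULL)
  list(start = as.integer(start), end = as.integer(stop_),
       edits = as.integer(hit[["dist"]]))
}

#' Detect a trailing polyA tail
#'
#' Scans 3' to 5' from the end of `seq` and keeps the longest trailing
#' segment whose overall A fraction is at least `min_A_fraction`; the
#' reported interval is trimmed to the outermost A bases and must be at
#' least `min_len` long.  Up to `end_slack` non-A bases at the extreme 3'
#' end are skipped before anchoring the scan.
#'
#' @param seq transcript-sense sequence ending where the polyA tail would
#'   end (i.e. upstream of the 3' primer hit or the read end).
#' @param min_len minimum accepted tail length.
#' @param min_A_fraction minimum maintained A fraction.
#' @param end_slack non-A bases tolerated at the extreme end.
#' @return `NULL` or list with `start`, `end`, `length`, `a_fraction`.
#' @export
detect_polyA <- function(seq, min_len = 15L, min_A_fraction = 0.8,
                         end_slack = 5L) {
  n <- nchar(seq)
  if (n == 0L) return(NULL)
  chars <- strsplit(seq, "")[[1]] == "A"
  anchor <- n
  while (anchor > 0L && !chars[anchor] && (n - anchor) < end_slack)
    anchor <- anchor - 1L
  if (anchor == 0L || !chars[anchor]) return(NULL)
  ## longest trailing segment [i, anchor] whose A fraction >= min
  acum <- rev(cumsum(rev(chars[seq_len(anchor)])))   # A count of [i, anchor]
  lens <- anchor - seq_len(anchor) + 1L
  ok <- acum / lens >= min_A_fraction
  if (!any(ok)) return(NULL)
  best_start <- min(which(ok))
  while (best_start <= anchor && !chars[best_start])
    best_start <- best_start + 1L
  len <- anchor - best_start + 1L
  if (len < min_len) return(NULL)
  a_frac <- sum(chars[best_start:anchor]) / len
  list(start = as.integer(best_start), end = as.integer(anchor),
       length = as.integer(len), a_fraction = a_frac)
}

classify_one <- function(seq, primer5, primer3rc, params, err = NULL) {
  n <- nchar(seq)
  p5len <- nchar(primer5)
  ## primer edit budget adapts to the read's own error rate (from its
  ## qualities) up to the configured ceiling, so clean reads are not hit
  ## by chance matches that a high-error budget would admit
  edit_frac <- if (is.null(err)) params$max_edit_fraction else
    min(params$max_edit_fraction, 3 * err + 0.08)
  chim_frac <- if (is.null(err)) params$chimera_edit_fraction else
    min(params$chimera_edit_fraction, 1.5 * err + 0.04)
  orient <- function(s) {
    h5 <- find_primer(s, primer5, end = "5", end_window = params$end_window,
                      max_edit_fraction = edit_frac)
    h3 <- find_primer(s, primer3rc, end = "3",
                      end_window = params$end_window,
                      max_edit_fraction = edit_frac)
    score <- (if (is.null(h5)) p5len else h5$edits) +
      (if (is.null(h3)) nchar(primer3rc) else h3$edits)
    list(h5 = h5, h3 = h3, score = score)
  }
  fwd <- orient(seq)
  rc <- revcomp(seq)
  rev <- orient(rc)
  ## lower summed primer edit distance wins; ties prefer the + orientation
  if (rev$score < fwd$score) {
    pick <- rev; strand <- "-"; s <- rc
  } else {
    pick <- fwd; strand <- "+"; s <- seq
  }

  if (n < p5len + nchar(primer3rc) + params$min_polyA_len) {
    return(list(classification = "non_full_length", strand = strand,
                trimmed_seq = s, reason = "too_short",
                primer5 = pick$h5, primer3 = pick$h3, polyA_len = 0L))
  }

  ## internal primer occurrence (outside the end windows) => chimera
  interior_from <- params$end_window + p5len + 1L
  interior_to <- n - params$end_window - nchar(primer3rc)
  chimera <- FALSE
  if (interior_to - interior_from + 1L >= 2L * p5len) {
    interior <- substring(s, interior_from, interior_to)
    for (p in unique(c(primer5, primer3rc, revcomp(primer5),
                       revcomp(primer3rc)))) {
      hit <- .lf_edit_find(interior, p)
      if (!is.na(hit[["start"]]) &&
          hit[["dist"]] <= chim_frac * nchar(p)) {
        chimera <- TRUE
        break
      }
    }
  }

  tail_end <- if (!is.null(pick$h3)) pick$h3$start - 1L else n
  tail_region <- substring(s, 1L, tail_end)
  pa <- detect_polyA(tail_region, min_len = params$min_polyA_len,
                     min_A_fraction = params$min_A_fraction,
                     end_slack = params$polyA_end_slack)

  cls <- if (chimera) "artifact_chimera"
  else if (!is.null(pick$h5) && !is.null(pick$h3) && !is.null(pa))
    "full_length"
  else "non_full_length"

  from <- if (!is.null(pick$h5)) pick$h5$end + 1L else 1L
  to <- if (!is.null(pa)) pa$start - 1L else tail_end
  trimmed <- if (to >= from) substring(s, from, to) else ""
  list(classification = cls, strand = strand, trimmed_seq = trimmed,
       reason = NA_character_, primer5 = pick$h5, primer3 = pick$h3,
       polyA_len = if (is.null(pa)) 0L else pa$length)
}

#' Classify reads as full-length / non-full-length / chimeric
#'
#' Tries both orientations of each read; a read is full-length when the 5'
#' primer is found at the 5' end, the 3' primer (reverse-complemented) at
#' the 3' end, and a polyA tail immediately precedes the 3' primer hit.
#' An additional primer occurrence away from the read ends marks the read
#' as a chimeric artifact.  The trimmed sequence excludes primers and
#' polyA and is reported transcript-sense, so classification is invariant
#' under reverse-complementing the input (the strand flips).
#'
#' @param reads named character vector of read sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param primer5 5' cDNA primer (transcript-sense at the 5' end).
#' @param primer3 3' cDNA primer; reads end with its reverse complement.
#' @param quals optional named Phred+33 quality strings; when present the
#'   per-read primer edit budget scales with the read's error rate
#'   (capped by `max_edit_fraction`).
#' @param params a [classify_params()] list.
#' @return a data.frame (one row per read): `read_id`, `classification`,
#'   `strand`, `polyA_len`, `primer5_edits`, `primer3_edits`,
#'   `trimmed_seq`.
#' @export
classify_reads <- function(reads, primer5, primer3, quals = NULL,
                           params = classify_params()) {
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  if (nchar(primer5) == 0L || nchar(primer3) == 0L)
    stop("primers must be non-empty")
  p3rc <- revcomp(primer3)
  rows <- lapply(names(reads), function(id) {
    err <- if (!is.null(quals) && id %in% names(quals))
      qual_error(quals[[id]]) else NULL
    r <- classify_one(reads[[id]], primer5, p3rc, params, err = err)
    data.frame(read_id = id, classification = r$classification,
               strand = r$strand, polyA_len = r$polyA_len,
               primer5_edits = if (is.null(r$primer5)) NA_integer_ else
                 r$primer5$edits,
               primer3_edits = if (is.null(r$primer3)) NA_integer_ else
                 r$primer3$edits,
               trimmed_seq = r$trimmed_seq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
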