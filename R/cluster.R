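## Isoform-level clustering of full-length reads: similarity graph, greedy
## clique cover, partial-order (DAG) consensus, likelihood reassignment,
## non-full-length recruitment and expected-error polishing.

#' Clustering parameters
#'
#' Alignment-derived thresholds for deciding whether two full-length reads
#' come from the same isoform, and for consensus/polish.  Alignment scoring
#' and the identity threshold are derived from the library's per-base error
#' rate: at the raw-read default of 0.15 the identity floor is 0.70; for
#' low-error (polished-equivalent) libraries it tightens to about
#' `1 - 3 * error_rate`.
#'
#' @param error_rate expected total per-base error rate of the input reads.
#' @param tol3 both sequences' 3' ends must be reached within this many nt.
#' @param min_cov minimum aligned fraction of the shorter sequence.
#' @param max_internal_gap longest internal gap run (nt) still compatible
#'   with same-isoform identity (larger gaps indicate a skipped exon).
#' @param min_ident minimum alignment identity; defaults to
#'   `max(0.70, 1 - 3 * error_rate - 0.03)`.
#' @param window_ident_len,min_window_ident length and identity floor of
#'   the sliding-window local-identity check: two random 50-nt blocks
#'   reach ~55% gapped identity by chance, so a local floor separates
#'   variant pairs whose global identity stays high.
#' @param k,stride,min_shared,max_bucket shared-k-mer prefilter: candidate
#'   read pairs must share at least `min_shared` seeded k-mers (content-
#'   hashed seeding, one in `stride` k-mers; buckets larger than
#'   `max_bucket` sequences are skipped as repetitive).
#' @param band half-width of the banded alignment around the k-mer
#'   estimated diagonal.
#' @param match,mismatch,gap_open,gap_ext affine alignment scores.
#' @param poa_match,poa_mismatch,poa_gap scores for the partial-order
#'   consensus alignment (linear gap).
#' @param max_iter maximum reassignment iterations.
#' @param max_errors clusters with more predicted consensus errors than
#'   this are discarded at the polish stage.
#' @param nfl_min_cov minimum aligned fraction of a non-full-length read
#'   for recruitment to a cluster.
#' @return list of parameters.
#' @export
cluster_params <- function(error_rate = 0.15,
                           tol3 = 30L,
                           min_cov = 0.90,
                           max_internal_gap = 20L,
                           min_ident = max(0.70, 1 - 3 * error_rate - 0.03),
                           window_ident_len = 50L,
                           min_window_ident = max(0.45, min_ident - 0.2),
                           k = 15L, stride = 5L, min_shared = 3L,
                           max_bucket = 500L,
                           band = 48L,
                           match = 1, mismatch = -2, gap_open = -3,
                           gap_ext = -1,
                           poa_match = 2, poa_mismatch = -3, poa_gap = -2,
                           max_iter = 10L,
                           max_errors = 10,
                           nfl_min_cov = 0.95) {
  as.list(environment())
}

## per-read correctness weight from a Phred+33 quality string
qual_weight <- function(qual) {
  if (is.null(qual) || is.na(qual) || nchar(qual) == 0L) return(0.9)
  ph <- as.integer(charToRaw(qual)) - 33L
  max(0.05, 1 - mean(10^(-ph / 10)))
}

qual_error <- function(qual) 1 - qual_weight(qual)

#' Same-isoform predicate for two full-length reads
#'
#' Overlap-aligns the two transcript-sense sequences (free end gaps) and
#' declares them same-isoform when the alignment reaches both 3' ends
#' within `tol3`, has a free 5' overhang on at most one sequence (5'
#' degradation), covers at least `min_cov` of the shorter sequence, has no
#' internal gap run longer than `max_internal_gap` (a long internal gap is
#' the signature of a skipped exon), and attains `min_ident` identity.
#'
#' @param a,b transcript-sense sequences.
#' @param params a [cluster_params()] list.
#' @return list with `same` (logical) and the alignment summary
#'   (`identity`, `coverage`, `max_gap_run`, `score`, overhangs).
#' @export
same_isoform <- function(a, b, params = cluster_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(list(same = FALSE, reason = "empty sequence"))
  al <- pair_align(a, b, mode = "overlap",
                   match = params$match, mismatch = params$mismatch,
                   gap_open = params$gap_open, gap_ext = params$gap_ext,
                   band = params$band, k = params$k)
  if (is.null(al) || is.na(al$score[1]))
    return(list(same = FALSE, reason = "no alignment"))
  na <- nchar(a); nb <- nchar(b)
  lead_a <- al$a_start; lead_b <- al$b_start
  trail_a <- na - al$a_end; trail_b <- nb - al$b_end
  cov_a <- (al$a_end - al$a_start) / na
  cov_b <- (al$b_end - al$b_start) / nb
  cov_short <- if (na <= nb) cov_a else cov_b
  identity <- if (al$columns > 0) al$n_match / al$columns else 0
  ## local identity: minimum over sliding windows of aligned columns
  wlen <- params$window_ident_len
  min_window <- if (al$columns >= wlen) {
    good <- cumsum(c(0, al$ops == 0L))
    min((good[(wlen + 1):(al$columns + 1)] -
           good[1:(al$columns - wlen + 1)]) / wlen)
  } else identity
  same <- trail_a <= params$tol3 && trail_b <= params$tol3 &&
    min(lead_a, lead_b) <= params$tol3 &&
    cov_short >= params$min_cov &&
    al$max_gap_run <= params$max_internal_gap &&
    identity >= params$min_ident &&
    min_window >= params$min_window_ident
  list(same = same, identity = identity, coverage = cov_short,
       min_window_ident = min_window,
       max_gap_run = al$max_gap_run, score = al$score,
       lead_a = lead_a, lead_b = lead_b,
       trail_a = trail_a, trail_b = trail_b)
}

#' Build the read similarity graph
#'
#' Nodes are full-length reads; an undirected edge joins two reads that
#' satisfy [same_isoform()].  Candidate pairs are restricted by a shared
#' seeded-k-mer prefilter (a superset of true edges on error-free data,
#' since identical subsequences share identical seed sets); set
#' `prefilter = FALSE` to evaluate all pairs.
#'
#' @param seqs named character vector of transcript-sense sequences.
#' @param params a [cluster_params()] list.
#' @param prefilter use the k-mer prefilter (default) or all pairs.
#' @return list of class `lf_graph`: `nodes` (ids) and `edges`
#'   (data.frame `i`, `j`, `identity`).
#' @export
build_similarity_graph <- function(seqs, params = cluster_params(),
                                   prefilter = TRUE) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%05d", seq_along(seqs))
  ids <- names(seqs)
  if (prefilter) {
    cand <- .lf_kmer_pairs(unname(seqs), as.integer(params$k),
                           as.integer(params$stride),
                           as.integer(params$min_shared),
                           as.integer(params$max_bucket))
    pairs <- cand[, 1:2, drop = FALSE]
  } else {
    n <- length(seqs)
    pairs <- if (n < 2L) matrix(integer(0), ncol = 2) else
      t(utils::combn(n, 2L))
  }
  keep <- logical(nrow(pairs))
  ident <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    res <- same_isoform(seqs[[pairs[r, 1]]], seqs[[pairs[r, 2]]], params)
    keep[r] <- isTRUE(res$same)
    ident[r] <- if (is.null(res$identity)) NA_real_ else res$identity
  }
  edges <- data.frame(i = ids[pairs[keep, 1]], j = ids[pairs[keep, 2]],
                      identity = ident[keep], stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges), class = "lf_graph")
}

#' Greedy maximal-clique cover of a similarity graph
#'
#' Deterministic partition: repeatedly seed a cluster with the
#' highest-degree unassigned node (degree in the full graph; ties broken
#' by lexicographic id), then grow it by adding the unassigned neighbour
#' adjacent to every current member with the highest degree (same tie
#' break) until none remains.
#'
#' @param graph an `lf_graph` from [build_similarity_graph()].
#' @return named list of character vectors (cluster id -> member ids).
#' @export
initial_clusters <- function(graph) {
  nodes <- graph$nodes
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges$i[r]; j <- graph$edges$j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  degree <- vapply(adj, length, 0L)
  unassigned <- rep(TRUE, length(nodes))
  names(unassigned) <- nodes
  clusters <- list()
  pick_best <- function(cands) {
    d <- degree[cands]
    cands <- cands[d == max(d)]
    sort(cands)[1L]
  }
  while (any(unassigned)) {
    seed <- pick_best(nodes[unassigned])
    members <- seed
    unassigned[seed] <- FALSE
    repeat {
      cands <- adj[[seed]]
      for (m in members) cands <- intersect(cands, adj[[m]])
      cands <- cands[unassigned[cands]]
      ## candidates adjacent to all current members
      cands <- Filter(function(x) all(members %in% adj[[x]]), cands)
      if (!length(cands)) break
      nxt <- pick_best(cands)
      members <- c(members, nxt)
      unassigned[nxt] <- FALSE
    }
    clusters[[sprintf("c%04d", length(clusters) + 1L)]] <- sort(members)
  }
  clusters
}

#' Partial-order alignment consensus of a read group
#'
#' Members are threaded into a partial-order graph in decreasing length
#' order; each node accumulates the quality-derived correctness weight of
#' the reads supporting its base, and the consensus is the heaviest path
#' through the final DAG.  A single member is returned unchanged.
#'
#' @param seqs character vector of member sequences.
#' @param quals optional Phred+33 quality strings (same length/order).
#' @param params a [cluster_params()] list.
#' @return consensus sequence (character scalar).
#' @export
dag_consensus <- function(seqs, quals = NULL, params = cluster_params(),
                          refine = TRUE) {
  stopifnot(length(seqs) >= 1L)
  if (length(seqs) == 1L) return(unname(seqs[[1]]))
  w <- if (is.null(quals)) rep(0.9, length(seqs)) else
    vapply(quals, qual_weight, 0)
  nm <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  ord <- order(-nchar(seqs), nm)
  res <- .lf_poa_consensus(unname(seqs[ord]), w[ord],
                           params$poa_match, params$poa_mismatch,
                           params$poa_gap)
  cons <- res$consensus
  if (refine && length(seqs) >= 3L && nchar(cons) > 0L) {
    ## one column-plurality pass over member realignments polishes the
    ## residual indel errors the heaviest path retains at high depth
    M <- column_profile(cons, unname(seqs), w, params)
    tot <- colSums(M)
    winner <- rownames(M)[apply(M, 2, which.max)]
    keep <- tot == 0 | winner != "-"
    bases <- ifelse(tot == 0, strsplit(cons, "")[[1]], winner)
    cons <- paste(bases[keep], collapse = "")
  }
  cons
}

## alignment log-likelihood of a read against a cluster consensus
read_loglik <- function(read, consensus, e, params) {
  al <- pair_align(read, consensus, mode = "overlap",
                   match = params$match, mismatch = params$mismatch,
                   gap_open = params$gap_open, gap_ext = params$gap_ext,
                   band = params$band, k = params$k)
  if (is.null(al) || is.na(al$score[1])) return(list(ll = -Inf, al = NULL))
  e <- min(max(e, 1e-4), 0.5)
  ll <- al$n_match * log(1 - e) + al$n_mismatch * log(e / 3) +
    al$n_gap * log(e) +
    ## unaligned read bases count as errors so partial hits do not win
    (nchar(read) - (al$a_end - al$a_start)) * log(e)
  list(ll = ll, al = al)
}

#' Likelihood reassignment of reads between clusters
#'
#' Each read is scored by alignment log-likelihood against the consensus
#' of its candidate clusters (clusters containing one of its similarity-
#' graph neighbours, plus its current cluster) and moved to the best one
#' (ties keep the current cluster, then prefer the lexicographically
#' smallest cluster id).  Consensus sequences are recomputed after every
#' sweep; iteration stops when no read moves or after `max_iter` sweeps.
#'
#' @param seqs named character vector of full-length reads.
#' @param clusters named list of member id vectors.
#' @param graph the `lf_graph` used to build the clusters.
#' @param quals optional named quality strings.
#' @param params a [cluster_params()] list.
#' @return list with `clusters` (updated partition), `consensus` (named
#'   character vector) and `iterations`.
#' @export
reassign <- function(seqs, clusters, graph, quals = NULL,
                     params = cluster_params()) {
  neighbours <- setNames(vector("list", length(seqs)), names(seqs))
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges$i[r]; j <- graph$edges$j[r]
      neighbours[[i]] <- c(neighbours[[i]], j)
      neighbours[[j]] <- c(neighbours[[j]], i)
    }
  }
  errs <- if (is.null(quals)) setNames(rep(0.1, length(seqs)), names(seqs))
  else vapply(quals, qual_error, 0)[names(seqs)]

  consensus <- vapply(clusters, function(m)
    dag_consensus(seqs[m], quals[m], params), "")
  membership <- setNames(rep(names(clusters), lengths(clusters)),
                         unlist(clusters))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    moved <- FALSE
    changed <- character(0)
    for (id in sort(names(seqs))) {
      cur <- membership[[id]]
      cand <- unique(c(cur, membership[unlist(neighbours[[id]])]))
      cand <- cand[!is.na(cand)]
      if (length(cand) <= 1L) next
      lls <- vapply(cand, function(cl)
        read_loglik(seqs[[id]], consensus[[cl]], errs[[id]], params)$ll, 0)
      best <- max(lls)
      winners <- cand[lls >= best - 1e-9]
      target <- if (cur %in% winners) cur else sort(winners)[1L]
      if (target != cur) {
        membership[[id]] <- target
        moved <- TRUE
        changed <- unique(c(changed, cur, target))
      }
    }
    if (!moved || iter >= params$max_iter) break
    clusters <- split(names(membership), membership)
    clusters <- clusters[lengths(clusters) > 0L]
    for (cl in intersect(changed, names(clusters)))
      consensus[[cl]] <- dag_consensus(seqs[clusters[[cl]]],
                                       quals[clusters[[cl]]], params)
    consensus <- consensus[names(clusters)]
  }
  clusters <- split(names(membership), membership)
  clusters <- lapply(clusters, sort)
  consensus <- consensus[names(clusters)]
  list(clusters = clusters, consensus = consensus, iterations = iter)
}

## per-column weighted base/deletion profile of members against a consensus
column_profile <- function(consensus, seqs, weights, params) {
  L <- nchar(consensus)
  M <- matrix(0, nrow = 5L, ncol = L,
              dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (s in seq_along(seqs)) {
    al <- pair_align(seqs[[s]], consensus, mode = "overlap",
                     match = params$match, mismatch = params$mismatch,
                     gap_open = params$gap_open, gap_ext = params$gap_ext,
                     band = params$band, k = params$k)
    if (is.null(al) || is.na(al$score[1])) next
    ops <- al$ops
    apos <- al$a_start + cumsum(ops != 3L)   # read coordinate per column
    bpos <- al$b_start + cumsum(ops != 2L)   # consensus coordinate
    w <- weights[s]
    obs <- ops != 2L                          # columns touching the consensus
    rows <- ifelse(ops == 3L, "-",
                   substring(seqs[[s]], apos, apos))
    ri <- match(rows[obs], rownames(M))
    ci <- bpos[obs]
    ok <- !is.na(ri) & ci >= 1L & ci <= L
    ind <- (ci[ok] - 1L) * 5L + ri[ok]
    M <- M + w * matrix(tabulate(ind, nbins = 5L * L), nrow = 5L)
  }
  M
}

## Expected number of consensus errors: per column, the posterior
## probability that the weighted-plurality call is wrong under a
## symmetric per-observation error model with rate `e`.  The log-odds of
## the plurality call grow with the weight margin over the runner-up
## votes, so deep well-agreeing columns contribute ~0 while a 50/50
## split contributes exactly 0.5 (the plurality carries half the mass).
predicted_errors_from_profile <- function(M, e = 0.1) {
  tot <- colSums(M)
  obs <- tot > 0
  if (!any(obs)) return(0)
  e <- min(max(e, 1e-3), 0.3)
  mx <- apply(M[, obs, drop = FALSE], 2, max)
  margin <- 2 * mx - tot[obs]                 # plurality minus the rest
  llr <- margin * log(3 * (1 - e) / e)
  sum(1 / (1 + exp(llr)))
}

#' Recruit non-full-length reads and polish cluster consensus
#'
#' Each non-full-length read is assigned to the cluster whose consensus it
#' aligns to over at least `nfl_min_cov` of its own length, with its 3'
#' end within `tol3` of the consensus 3' end, choosing the best alignment
#' log-likelihood.  The consensus is then recomputed over full-length plus
#' recruited members by quality-weighted column plurality, and the
#' cluster's expected consensus error count is the sum over columns of
#' the posterior probability that the plurality call is wrong (a 50/50
#' column contributes 0.5; deep well-supported columns contribute ~0).
#' Clusters whose predicted error count exceeds `max_errors` are
#' discarded.
#'
#' @param clusters named list of full-length member ids.
#' @param consensus named character vector of cluster consensus sequences.
#' @param fl_seqs,fl_quals named full-length sequences and qualities.
#' @param nfl_seqs,nfl_quals named non-full-length sequences/qualities
#'   (may be empty).
#' @param params a [cluster_params()] list.
#' @return object of class `lf_transcripts`: data.frame `clusters`
#'   (cluster_id, fl_count, nfl_count, predicted_errors, retained) plus
#'   `consensus` (named character vector of retained polished sequences)
#'   and `members` (list of all member ids per cluster).
#' @export
polish <- function(clusters, consensus, fl_seqs, fl_quals = NULL,
                   nfl_seqs = character(0), nfl_quals = NULL,
                   params = cluster_params()) {
  recruits <- setNames(vector("list", length(clusters)), names(clusters))
  if (length(nfl_seqs)) {
    ## candidate clusters via shared k-mers with the consensus set
    comb <- c(unname(consensus), unname(nfl_seqs))
    nc <- length(consensus)
    cand <- .lf_kmer_pairs(comb, as.integer(params$k),
                           as.integer(params$stride),
                           as.integer(params$min_shared),
                           as.integer(params$max_bucket))
    cross <- cand[cand[, 1] <= nc & cand[, 2] > nc, , drop = FALSE]
    errs <- if (is.null(nfl_quals)) rep(0.1, length(nfl_seqs)) else
      vapply(nfl_quals, qual_error, 0)
    for (ri in seq_along(nfl_seqs)) {
      cls <- names(consensus)[cross[cross[, 2] == nc + ri, 1]]
      if (!length(cls)) next
      best_ll <- -Inf; best_cl <- NULL
      for (cl in cls) {
        sc <- read_loglik(nfl_seqs[[ri]], consensus[[cl]], errs[[ri]], params)
        if (is.null(sc$al)) next
        cov <- (sc$al$a_end - sc$al$a_start) / nchar(nfl_seqs[[ri]])
        trail <- nchar(consensus[[cl]]) - sc$al$b_end
        if (cov >= params$nfl_min_cov && trail <= params$tol3 &&
            sc$ll > best_ll) {
          best_ll <- sc$ll; best_cl <- cl
        }
      }
      if (!is.null(best_cl))
        recruits[[best_cl]] <- c(recruits[[best_cl]],
                                 names(nfl_seqs)[ri])
    }
  }

  rows <- list(); polished <- character(0); members_all <- list()
  for (cl in names(clusters)) {
    fl_m <- clusters[[cl]]
    nfl_m <- recruits[[cl]]
    seqs <- c(fl_seqs[fl_m], nfl_seqs[nfl_m])
    quals <- c(if (is.null(fl_quals)) setNames(rep(NA_character_,
                                                   length(fl_m)), fl_m)
               else fl_quals[fl_m],
               if (is.null(nfl_quals)) setNames(rep(NA_character_,
                                                    length(nfl_m)), nfl_m)
               else nfl_quals[nfl_m])
    w <- vapply(quals, qual_weight, 0)
    cons <- if (length(nfl_m)) dag_consensus(seqs, quals, params) else
      consensus[[cl]]
    M <- column_profile(cons, seqs, w, params)
    pe <- predicted_errors_from_profile(M, e = 1 - mean(w))
    ## quality-weighted column consensus: plurality base per column,
    ## plurality deletions removed
    tot <- colSums(M)
    winner <- rownames(M)[apply(M, 2, which.max)]
    keep <- tot > 0 & winner != "-"
    newcons <- paste(winner[keep], collapse = "")
    retained <- pe <= params$max_errors
    rows[[cl]] <- data.frame(cluster_id = cl, fl_count = length(fl_m),
                             nfl_count = length(nfl_m),
                             predicted_errors = pe, retained = retained,
                             stringsAsFactors = FALSE)
    members_all[[cl]] <- c(fl_m, nfl_m)
    if (retained) polished[cl] <- newcons
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(clusters = out, consensus = polished,
                 members = members_all), class = "lf_transcripts")
}

#' Cluster full-length reads into polished isoform consensus sequences
#'
#' End-to-end clustering: similarity graph, greedy clique cover, DAG
#' consensus, likelihood reassignment, non-full-length recruitment and
#' expected-error filtering.
#'
#' @param fl_seqs named character vector of full-length transcript-sense
#'   reads.
#' @param fl_quals optional named quality strings.
#' @param nfl_seqs,nfl_quals optional non-full-length reads used for
#'   polishing only.
#' @param params a [cluster_params()] list.
#' @return an `lf_transcripts` object (see [polish()]).
#' @export
cluster_isoforms <- function(fl_seqs, fl_quals = NULL,
                             nfl_seqs = character(0), nfl_quals = NULL,
                             params = cluster_params()) {
  graph <- build_similarity_graph(fl_seqs, params)
  cl0 <- initial_clusters(graph)
  re <- reassign(fl_seqs, cl0, graph, fl_quals, params)
  polish(re$clusters, re$consensus, fl_seqs, fl_quals,
         nfl_seqs, nfl_quals, params)
}
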