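## Shared fixtures (memoised small simulations) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## small error-free simulation with polycistronic clusters
sim_errorfree <- function() fixture("sim_ef", function() {
  simulate_dataset(sim_config(seed = 9L, n_genes = 24L,
                              error_rates = c(sub = 0, ins = 0, del = 0)))
})

## small 2% ("polished-equivalent") error simulation
sim_lowerr <- function() fixture("sim_le", function() {
  simulate_dataset(sim_config(seed = 5L, n_genes = 10L,
                              error_rates = c(sub = 0.0013, ins = 0.012,
                                              del = 0.0067)))
})

err2_rates <- function() c(sub = 0.0013, ins = 0.012, del = 0.0067)

## classified full-length reads of the low-error simulation
fl_lowerr <- function() fixture("fl_le", function() {
  sim <- sim_lowerr()
  cl <- classify_reads(sim$reads$sequences, sim$config$primer5,
                       sim$config$primer3, sim$reads$qualities)
  ids <- cl$read_id[cl$classification == "full_length"]
  list(seqs = setNames(cl$trimmed_seq[match(ids, cl$read_id)], ids),
       quals = sim$reads$qualities[ids],
       classification = cl)
})


## full-size error-free simulation: per-class poly(A) profiles need
## enough internal-locus sites for element detection to be noise-proof
sim_errorfree_full <- function() fixture("sim_ef_full", function() {
  simulate_dataset(sim_config(seed = 9L,
                              error_rates = c(sub = 0, ins = 0, del = 0)))
})

## classified sites + accepted alignments for the error-free simulation
pas_fixture <- function() fixture("pas_fix", function() {
  sim <- sim_errorfree_full()
  idx <- genome_index(sim$genome$genome)
  acc <- filter_alignments(map_transcripts(sim$isoforms$sequences, idx))
  calls <- scan_polycistronic(sim$isoforms$sequences, acc, sim$genome$genes)
  ptu <- Filter(function(c) identical(c$category, "contained_2_4"), calls)
  list(sim = sim, acc = acc, calls = ptu,
       sites = locate_pas(acc, ptu, sim$genome$genes))
})

## random DNA helper usable in tests
rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

## --- independent oracles ---------------------------------------------------

## exhaustive sliding-substring edit-distance oracle for primer search
oracle_best_infix <- function(text, pattern) {
  n <- nchar(text)
  best <- Inf
  for (i in seq_len(n)) {
    for (j in i:min(n, i + nchar(pattern) + 10L)) {
      d <- utils::adist(substring(text, i, j), pattern)
      if (d < best) best <- d
    }
  }
  best
}

## direct simulation of the stated greedy clique-cover rule
oracle_greedy_cover <- function(nodes, edges) {
  adj <- setNames(lapply(nodes, function(x) character(0)), nodes)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[[edges$i[r]]] <- c(adj[[edges$i[r]]], edges$j[r])
      adj[[edges$j[r]]] <- c(adj[[edges$j[r]]], edges$i[r])
    }
  }
  deg <- vapply(adj, length, 0L)
  left <- nodes
  out <- list()
  while (length(left)) {
    d <- deg[left]
    seed <- sort(left[d == max(d)])[1]
    members <- seed
    left <- setdiff(left, seed)
    repeat {
      cand <- left[vapply(left, function(x)
        all(members %in% adj[[x]]) && x %in% adj[[seed]], TRUE)]
      if (!length(cand)) break
      d2 <- deg[cand]
      nxt <- sort(cand[d2 == max(d2)])[1]
      members <- c(members, nxt)
      left <- setdiff(left, nxt)
    }
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

## transitive-closure locus oracle by brute-force union-find over exon
## overlaps (same chrom and strand)
oracle_loci <- function(alignments) {
  n <- length(alignments)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  overlaps <- function(a, b) {
    if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
    for (i in seq_len(nrow(a$exons)))
      for (j in seq_len(nrow(b$exons)))
        if (a$exons[i, 1] <= b$exons[j, 2] && a$exons[i, 2] >= b$exons[j, 1])
          return(TRUE)
    FALSE
  }
  for (i in seq_len(n))
    for (j in seq_len(i - 1L))
      if (overlaps(alignments[[i]], alignments[[j]]))
        parent[find(i)] <- find(j)
  vapply(seq_len(n), find, 0L)
}

## exact combinatorial upper-tail hypergeometric sum (choose() is exact
## for the sizes used here)
oracle_hyper <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## small affine-gap Smith-Waterman (BLOSUM62, 11/1) for protein pairs
oracle_sw_score <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1); X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - 11 - 1, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 11 - 1, Y[i, j - 1] - 1)
      s <- B[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

## brute-force grouping oracle for collapse_mapped (pairwise rule +
## transitive closure, longest survivor)
oracle_collapse <- function(alignments, tol3p = 30L) {
  n <- length(alignments)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  key <- function(a) paste(a$chrom, a$strand,
                           longform:::junction_key(a), sep = "|")
  e3 <- vapply(alignments, longform:::three_prime_end, 0L)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- alignments[[i]]; b <- alignments[[j]]
      same <- FALSE
      if (nrow(a$exons) > 1L && nrow(b$exons) > 1L) {
        same <- key(a) == key(b) && abs(e3[i] - e3[j]) <= tol3p
      } else if (nrow(a$exons) == 1L && nrow(b$exons) == 1L) {
        cont <- (a$exons[1, 1] >= b$exons[1, 1] &&
                   a$exons[1, 2] <= b$exons[1, 2]) ||
          (b$exons[1, 1] >= a$exons[1, 1] && b$exons[1, 2] <= a$exons[1, 2])
        same <- a$chrom == b$chrom && a$strand == b$strand &&
          abs(e3[i] - e3[j]) <= tol3p && cont
      }
      if (same) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  surv <- vapply(unique(roots), function(r) {
    ix <- which(roots == r)
    sp <- vapply(alignments[ix], longform:::aligned_span, 0L)
    ids <- vapply(alignments[ix], function(a) a$query_id, "")
    ids[order(-sp, ids)][1]
  }, "")
  sort(surv)
}

## all-pairs exact-match scoring oracle
oracle_scores <- function(query, reference) {
  qm <- vapply(query, function(q)
    any(vapply(reference, function(r) exact_match(q, r), TRUE)), TRUE)
  rm_ <- vapply(reference, function(r)
    any(vapply(query, function(q) exact_match(q, r), TRUE)), TRUE)
  list(sensitivity = mean(rm_), specificity = mean(qm))
}

## minimal lf_alignment constructor for synthetic chains
chain <- function(id, chrom, strand, exons, coverage = 1, identity = 1) {
  structure(list(query_id = id, chrom = chrom, strand = strand,
                 exons = matrix(as.integer(exons), ncol = 2, byrow = TRUE,
                                dimnames = list(NULL, c("start", "end"))),
                 coverage = coverage, identity = identity),
            class = "lf_alignment")
}
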