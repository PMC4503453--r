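## build a codon string of n non-stop codons (deterministic filler)
codons <- function(n) strrep("GCT", n)
orf_seq <- function(aa) paste0("ATG", codons(aa - 1L), "TAA")

test_that("find_orfs returns qualifying non-overlapping ORFs in order", {
  expect_equal(nrow(find_orfs(strrep("C", 2000))), 0L)
  tx <- paste0(rnd_dna(50), orf_seq(120), rnd_dna(300), orf_seq(150),
               rnd_dna(60))
  orfs <- find_orfs(tx)
  expect_equal(nrow(orfs), 2L)
  expect_equal(orfs$aa_length, c(120L, 150L))
  expect_true(all(diff(orfs$start) > 0))
  ## the 100-aa threshold is inclusive
  expect_equal(nrow(find_orfs(orf_seq(100))), 1L)
  expect_equal(nrow(find_orfs(orf_seq(99))), 0L)
})

test_that("greedy ORF selection equals exhaustive enumeration with the same rule", {
  set.seed(71)
  oracle_orfs <- function(seq, min_aa = 30L) {
    n <- nchar(seq)
    all <- list()
    for (f in 0:2) {
      starts <- seq.int(1L + f, n - 2L, by = 3L)
      cods <- substring(seq, starts, starts + 2L)
      for (ai in which(cods == "ATG")) {
        si <- which(cods %in% c("TAA", "TAG", "TGA") & seq_along(cods) > ai)
        if (!length(si)) next
        s <- min(si)
        aa <- s - ai
        if (aa >= min_aa)
          all[[length(all) + 1L]] <- c(starts[ai], starts[s] + 2L, aa, f)
      }
    }
    if (!length(all)) return(NULL)
    m <- do.call(rbind, all)
    m <- m[order(-m[, 3], m[, 1]), , drop = FALSE]
    sel <- matrix(nrow = 0, ncol = 4)
    for (r in seq_len(nrow(m))) {
      ok <- !any(m[r, 1] <= sel[, 2] & m[r, 2] >= sel[, 1])
      if (ok) sel <- rbind(sel, m[r, ])
    }
    sel[order(sel[, 1]), , drop = FALSE]
  }
  for (rep in 1:25) {
    tx <- rnd_dna(sample(300:900, 1))
    got <- find_orfs(tx, min_aa = 30L)
    want <- oracle_orfs(tx, 30L)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(as.matrix(got)), unname(want))
    }
  }
})

test_that("greedy selection is consistent under winner removal", {
  set.seed(72)
  tx <- paste0(rnd_dna(30), orf_seq(80), rnd_dna(100), orf_seq(60),
               rnd_dna(100), orf_seq(40))
  sel <- find_orfs(tx, min_aa = 30L)
  top <- sel[which.max(sel$aa_length), ]
  ## blank the winner and re-run: remainder of the selection is unchanged
  masked <- tx
  substr(masked, top$start, top$end) <- strrep("C", top$end - top$start + 1L)
  rest <- find_orfs(masked, min_aa = 30L)
  expect_equal(rest$start, sel$start[sel$start != top$start])
})

test_that("inter-ORF stop detection matches a frame-by-frame scanning oracle", {
  expect_true(check_inter_orf_stops(
    paste0(orf_seq(30), "TAGATAGATAGA", orf_seq(30)),
    nchar(orf_seq(30)), nchar(orf_seq(30)) + 13L)$all_frames)
  nostop <- paste0(orf_seq(30), strrep("C", 60), orf_seq(30))
  res <- check_inter_orf_stops(nostop, nchar(orf_seq(30)),
                               nchar(orf_seq(30)) + 61L)
  expect_false(any(res$frames))
  expect_true(check_inter_orf_stops("ATGTAA", 3L, 4L)$degenerate)
  set.seed(73)
  for (rep in 1:20) {
    gap <- rnd_dna(300)
    seq <- paste0("ATG", gap, "TAA")
    got <- check_inter_orf_stops(seq, 3L, 304L)
    want <- vapply(0:2, function(f) {
      st <- seq.int(4L + f, 301L, by = 3L)
      any(substring(seq, st, st + 2L) %in% c("TAA", "TAG", "TGA"))
    }, TRUE)
    expect_identical(got$frames, want)
  }
})

test_that("polycistronic calls on error-free simulated transcripts match the manifest", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  acc <- filter_alignments(map_transcripts(sim$isoforms$sequences, idx))
  calls <- scan_polycistronic(sim$isoforms$sequences, acc, sim$genome$genes)
  ptu <- Filter(function(c) identical(c$category, "contained_2_4"), calls)
  truth <- sim$isoforms$isoforms$iso_id[sim$isoforms$isoforms$is_ptu]
  expect_setequal(names(ptu), truth)
  for (call in ptu) {
    expect_true(all(call$stops_all_frames))
    want <- strsplit(sim$isoforms$isoforms$gene_ids[
      sim$isoforms$isoforms$iso_id == call$transcript_id], ",")[[1]]
    expect_identical(call$contained_genes, want)
  }
  ## a monocistronic transcript is not called
  mono_id <- sim$isoforms$isoforms$iso_id[
    !sim$isoforms$isoforms$is_ptu &
      sim$isoforms$isoforms$kind == "canonical"][1]
  byid <- setNames(acc, vapply(acc, function(a) a$query_id, ""))
  expect_null(call_polycistronic(mono_id,
                                 sim$isoforms$sequences[[mono_id]],
                                 byid[[mono_id]], sim$genome$genes))
})

test_that("short-read validation enforces the 10x inter-ORF coverage floor", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  acc <- filter_alignments(map_transcripts(sim$isoforms$sequences, idx))
  calls <- scan_polycistronic(sim$isoforms$sequences, acc, sim$genome$genes)
  ptu <- Filter(function(c) identical(c$category, "contained_2_4"), calls)
  byid <- setNames(acc, vapply(acc, function(a) a$query_id, ""))
  call <- ptu[[1]]
  a <- byid[[call$transcript_id]]
  ## uniform coverage 20 validates
  t2g <- longform:::transcript_to_genomic(a)
  cov <- data.frame(chrom = a$chrom, pos = t2g, cov = 20)
  jun <- sim$support$junctions
  expect_true(validate_shortread(call, a, cov, jun)$valid)
  ## boundary: coverage exactly 10 passes, 9 fails
  cov10 <- cov; cov10$cov <- 10
  expect_true(validate_shortread(call, a, cov10, jun)$valid)
  gap_start <- call$orfs$end[1] + 1L
  cov9 <- cov; cov9$cov[cov9$pos == t2g[gap_start]] <- 9
  res <- validate_shortread(call, a, cov9, jun)
  expect_false(res$valid)
  ## a missing row also fails, with a reason
  covm <- cov[cov$pos != t2g[gap_start], ]
  expect_false(validate_shortread(call, a, covm, jun)$valid)
})

test_that("independent expression decreases along polycistronic tiers", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  acc <- filter_alignments(map_transcripts(sim$isoforms$sequences, idx))
  calls <- scan_polycistronic(sim$isoforms$sequences, acc, sim$genome$genes)
  ptu <- Filter(function(c) identical(c$category, "contained_2_4"), calls)
  iso <- sim$isoforms$isoforms
  fl_counts <- setNames(round(iso$abundance), iso$iso_id)
  tiers <- expression_tiers(ptu, acc, fl_counts, sim$genome$genes)
  for (id in unique(tiers$transcript_id)) {
    v <- tiers$independent_fl[tiers$transcript_id == id]
    expect_true(all(diff(v) < 0))
  }
  expect_equal(nrow(expression_tiers(list(), acc, fl_counts,
                                     sim$genome$genes)), 0L)
})

test_that("tandem enrichment matches exact combinatorial summation", {
  expect_equal(tandem_enrichment(10, 5, 5, 5), 1 / 252)
  expect_equal(tandem_enrichment(10, 5, 5, 0), 1)
  set.seed(77)
  for (rep in 1:40) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    got <- tandem_enrichment(N, K, n, k)
    want <- oracle_hyper(N, K, n, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
  ## monotone non-increasing in k
  p <- vapply(0:10, function(k) tandem_enrichment(40, 12, 15, k), 0)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(tandem_enrichment(10, 5, 5, 6), "inconsistent")
})
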