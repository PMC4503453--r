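test_that("error-free transcripts map back to exact annotated exon chains", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  alns <- map_transcripts(sim$isoforms$sequences, idx)
  expect_length(alns, length(sim$isoforms$sequences))
  truth <- sim_truth_alignments(sim)
  names(truth) <- vapply(truth, function(a) a$query_id, "")
  for (a in alns) {
    t <- truth[[a$query_id]]
    expect_identical(a$strand, t$strand)
    expect_equal(a$exons, t$exons, ignore_attr = TRUE)
    expect_equal(a$coverage, 1)
    expect_equal(a$identity, 1)
  }
})

test_that("an unrelated random sequence does not align", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  set.seed(10)
  expect_null(spliced_align(rnd_dna(800), idx))
})

test_that("2% error transcripts keep junction chains and >= 0.97 identity", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  truth <- sim_truth_alignments(sim)
  names(truth) <- vapply(truth, function(a) a$query_id, "")
  set.seed(19)
  multi <- names(Filter(function(t) nrow(t$exons) > 1L, truth))
  for (id in multi[1:6]) {
    noisy <- longform:::mutate_seq(sim$isoforms$sequences[[id]],
                                   0.0013, 0.012, 0.0067)
    a <- spliced_align(noisy, idx, id = id)
    expect_gte(a$identity, 0.97)
    expect_identical(longform:::junction_key(a),
                     longform:::junction_key(truth[[id]]))
  }
})

test_that("filter_alignments applies inclusive coverage/identity bounds", {
  mk <- function(cov, id) chain("x", "chr1", "+", c(1, 100),
                                coverage = cov, identity = id)
  alns <- list(mk(0.99, 0.85), mk(0.989, 0.99), mk(1, 0.849),
               mk(1, 1), mk(0.995, 0.86))
  acc <- filter_alignments(alns)
  expect_length(acc, 3L)
  ## brute-force re-evaluation
  want <- Filter(function(a) a$coverage >= 0.99 && a$identity >= 0.85, alns)
  expect_identical(acc, want)
})

test_that("locus assignment equals the transitive-closure oracle", {
  ## overlapping and strand-separated chains
  alns <- list(
    chain("t1", "chr1", "+", c(100, 200, 300, 400)),
    chain("t2", "chr1", "+", c(150, 250)),
    chain("t3", "chr1", "-", c(100, 200)),          # same span, other strand
    chain("t4", "chr1", "+", c(1000, 1200)),
    chain("t5", "chr1", "+", c(395, 500)),          # chains to t1 via exon 2
    chain("t6", "chr2", "+", c(100, 200)))
  loci <- assign_loci(alns)
  expect_identical(loci[["t1"]], loci[["t2"]])
  expect_identical(loci[["t1"]], loci[["t5"]])
  expect_false(loci[["t1"]] == loci[["t3"]])
  expect_false(loci[["t1"]] == loci[["t4"]])
  ## random instances against the union-find oracle
  set.seed(30)
  for (rep in 1:5) {
    rnd <- lapply(1:12, function(i) {
      s <- sample(1:500, 1)
      chain(paste0("r", i), "chr1", sample(c("+", "-"), 1),
            c(s, s + sample(50:150, 1)))
    })
    got <- assign_loci(rnd)
    want <- oracle_loci(rnd)
    ## same partition: equal locus <=> equal oracle root
    for (i in 1:12) for (j in 1:12)
      expect_identical(got[[paste0("r", i)]] == got[[paste0("r", j)]],
                       want[i] == want[j])
  }
})

test_that("BED12 and GFF3 round-trip exon chains exactly", {
  sim <- sim_errorfree()
  idx <- genome_index(sim$genome$genome)
  alns <- map_transcripts(sim$isoforms$sequences[1:10], idx)
  f <- tempfile(fileext = ".bed")
  write_bed12(alns, f)
  back <- read_bed12(f)
  for (i in seq_along(alns)) {
    expect_identical(back[[i]]$query_id, alns[[i]]$query_id)
    expect_identical(back[[i]]$strand, alns[[i]]$strand)
    expect_equal(back[[i]]$exons, alns[[i]]$exons, ignore_attr = TRUE)
  }
  g <- tempfile(fileext = ".gff3")
  gr <- sim_annotation_granges(sim)
  write_gff3(gr, g)
  gr2 <- read_gff3(g)
  expect_equal(GenomicRanges::start(gr), GenomicRanges::start(gr2))
  expect_equal(GenomicRanges::end(gr), GenomicRanges::end(gr2))
  expect_identical(as.character(S4Vectors::mcols(gr)$type),
                   as.character(S4Vectors::mcols(gr2)$type))
})
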