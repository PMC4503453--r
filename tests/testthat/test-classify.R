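P5 <- "AAGCAGTGGTATCAACGCAGAGTAC"
P3 <- "TGGATCACTTGCGCAAGGCTAGTCA"

test_that("find_primer locates exact, absent and mutated primers", {
  set.seed(31)
  x <- rnd_dna(300)
  seq <- paste0(P5, x)
  hit <- find_primer(seq, P5, end = "5")
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, nchar(P5))
  expect_equal(hit$edits, 0L)

  ## no primer-like subsequence
  expect_null(find_primer(rnd_dna(300), P5, end = "5",
                          max_edit_fraction = 0.15))

  ## implanted with two substitutions: edit distance agrees with the
  ## exhaustive substring oracle
  p_mut <- P5
  substr(p_mut, 5, 5) <- "T"; substr(p_mut, 18, 18) <- "A"
  seq2 <- paste0(rnd_dna(20), p_mut, rnd_dna(200))
  hit2 <- find_primer(seq2, P5, end = "5", max_edit_fraction = 0.3)
  expect_equal(hit2$edits, 2L)
  expect_equal(hit2$start, 21L)
  expect_equal(hit2$edits,
               as.integer(oracle_best_infix(substring(seq2, 1, 140), P5)))
})

test_that("detect_polyA applies the trailing-segment scan rule", {
  set.seed(32)
  prefix <- paste(sample(c("C", "G", "T"), 50, replace = TRUE),
                  collapse = "")
  expect_equal(detect_polyA(paste0(prefix, strrep("A", 20)))$length, 20L)
  expect_null(detect_polyA(paste0(prefix, strrep("A", 5))))
  ## 20-nt tail with 2 G's: accepted at A-fraction 0.9
  tail <- "AAAAAGAAAAAAAAAGAAAA"
  res <- detect_polyA(paste0("CCGCCTGCCGTC", tail))
  expect_equal(res$length, 20L)
  expect_equal(res$a_fraction, 0.9)
})

test_that("error-free simulated reads classify to the manifest labels and trim exactly", {
  sim <- sim_errorfree()
  cfg <- sim$config
  cl <- classify_reads(sim$reads$sequences, cfg$primer5, cfg$primer3,
                       sim$reads$qualities)
  man <- sim$reads$manifest
  expect_identical(cl$classification == "full_length", man$is_full_length)
  ## the polyA boundary is ambiguous where the 3' UTR is A-rich, so
  ## trimming recovers the transcript exactly for most reads and always
  ## up to a bounded 3'-end difference, with the 5' end exact
  fl <- which(man$is_full_length)
  exact <- logical(0)
  for (i in fl) {
    tx <- sim$isoforms$sequences[[man$iso_id[i]]]
    tr <- cl$trimmed_seq[i]
    exact <- c(exact, identical(tr, tx))
    expect_identical(substring(tr, 1, 50), substring(tx, 1, 50))
    expect_true(startsWith(tx, tr))
    expect_lte(nchar(tx) - nchar(tr), 40L)
  }
  ## design ceiling: trimming is exact iff the 12-nt cleavage context
  ## drew no A (probability ~0.54) and the tail did not bridge; reads of
  ## one isoform share the outcome, so the realised fraction is coarse
  expect_gte(mean(exact), 0.25)
  ## a transcript with an A-free 3' end trims back exactly
  set.seed(33)
  tx2 <- paste0(rnd_dna(400),
                paste(sample(c("C", "G", "T"), 40, TRUE), collapse = ""))
  read <- paste0(sim$config$primer5, tx2, strrep("A", 25),
                 longform:::revcomp(sim$config$primer3))
  r <- classify_reads(c(x = read), sim$config$primer5, sim$config$primer3)
  expect_identical(r$trimmed_seq, tx2)
})

test_that("classification is invariant under reverse complement (strand flips)", {
  sim <- sim_errorfree()
  cfg <- sim$config
  ids <- sim$reads$manifest$read_id[c(3, 20, 57)]
  for (id in ids) {
    r <- sim$reads$sequences[[id]]
    a <- classify_reads(setNames(r, "x"), cfg$primer5, cfg$primer3)
    b <- classify_reads(setNames(longform:::revcomp(r), "x"),
                        cfg$primer5, cfg$primer3)
    expect_identical(a$classification, b$classification)
    expect_identical(a$trimmed_seq, b$trimmed_seq)
    expect_false(a$strand == b$strand)
  }
})

test_that("an internal primer occurrence marks a chimera", {
  set.seed(8)
  left <- paste0(P5, rnd_dna(400), strrep("A", 25), longform:::revcomp(P3))
  chim <- paste0(P5, rnd_dna(300), P5, rnd_dna(300),
                 strrep("A", 25), longform:::revcomp(P3))
  res <- classify_reads(c(ok = left, bad = chim), P5, P3)
  expect_identical(res$classification[res$read_id == "ok"], "full_length")
  expect_identical(res$classification[res$read_id == "bad"],
                   "artifact_chimera")
})

test_that("a read too short for primers and a tail is non-full-length", {
  res <- classify_reads(c(s = "ACGTACGT"), P5, P3)
  expect_identical(res$classification, "non_full_length")
})

test_that("classification is a pure function of its inputs", {
  sim <- sim_lowerr()
  cfg <- sim$config
  sub <- sim$reads$sequences[1:15]
  a <- classify_reads(sub, cfg$primer5, cfg$primer3, sim$reads$qualities)
  b <- classify_reads(sub, cfg$primer5, cfg$primer3, sim$reads$qualities)
  expect_identical(a, b)
})
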