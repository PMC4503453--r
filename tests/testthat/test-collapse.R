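test_that("a 5'-truncated copy merges into the full transcript, keeping the longer", {
  full <- chain("full", "chr1", "+", c(100, 300, 400, 600, 700, 900))
  trunc <- chain("trunc", "chr1", "+", c(350, 300 + 100, 400, 600, 700, 900))
  ## same junctions, same 3' end: exon1 outer start differs only
  trunc$exons[1, ] <- c(250L, 300L)
  res <- collapse_mapped(list(full, trunc))
  expect_length(res$survivors, 1L)
  expect_identical(res$survivors[[1]]$query_id, "full")
  expect_identical(res$audit$merged_id, "trunc")
})

test_that("junction or 3'-end differences are preserved", {
  a <- chain("a", "chr1", "+", c(100, 300, 400, 600))
  b <- chain("b", "chr1", "+", c(100, 300, 450, 600))   # different acceptor
  apa <- chain("apa", "chr1", "+", c(100, 300, 400, 700)) # 3' +100
  res <- collapse_mapped(list(a, b, apa))
  expect_length(res$survivors, 3L)
})

test_that("single-exon grouping needs strand, 3' agreement and containment", {
  a <- chain("a", "chr1", "+", c(100, 500))
  b <- chain("b", "chr1", "+", c(200, 490))   # contained in a, 3' within 30
  c_ <- chain("c", "chr1", "-", c(100, 500))  # other strand: kept
  d <- chain("d", "chr1", "+", c(600, 900))   # disjoint: kept
  res <- collapse_mapped(list(a, b, c_, d))
  ids <- sort(vapply(res$survivors, function(x) x$query_id, ""))
  expect_identical(ids, c("a", "c", "d"))
  ## grouping is transitive through intermediate transcripts
  e <- chain("e", "chr1", "+", c(200, 460))   # pairs with b, not with a
  res2 <- collapse_mapped(list(a, b, e))
  expect_identical(vapply(res2$survivors, function(x) x$query_id, ""), "a")
})

test_that("collapse equals the brute-force grouping oracle and is idempotent", {
  set.seed(44)
  mk_instance <- function() {
    alns <- list()
    for (g in 1:6) {
      base <- g * 2000
      ne <- sample(1:3, 1)
      ex <- integer(0)
      pos <- base
      for (e in 1:ne) {
        ex <- c(ex, pos, pos + sample(80:200, 1))
        pos <- ex[length(ex)] + sample(60:120, 1)
      }
      full <- chain(sprintf("g%d_full", g), "chr1",
                    sample(c("+", "-"), 1), ex)
      alns[[length(alns) + 1L]] <- full
      ## planted 5' truncations
      for (t in seq_len(sample(0:3, 1))) {
        tr <- full
        tr$query_id <- sprintf("g%d_t%d", g, t)
        if (full$strand == "+") tr$exons[1, 1] <- tr$exons[1, 1] + 10L * t
        else tr$exons[nrow(tr$exons), 2] <- tr$exons[nrow(tr$exons), 2] - 10L * t
        alns[[length(alns) + 1L]] <- tr
      }
    }
    alns
  }
  for (rep in 1:4) {
    alns <- mk_instance()
    res <- collapse_mapped(alns)
    got <- sort(vapply(res$survivors, function(a) a$query_id, ""))
    expect_identical(got, oracle_collapse(alns))
    res2 <- collapse_mapped(res$survivors)
    expect_identical(sort(vapply(res2$survivors, function(a) a$query_id, "")),
                     got)
    expect_equal(nrow(res2$audit), 0L)
  }
})

test_that("reference-free collapse keeps one survivor per truncation ladder", {
  set.seed(45)
  tx <- rnd_dna(900)
  ladder <- setNames(c(tx, substring(tx, 101), substring(tx, 301),
                       substring(tx, 501)), paste0("L", 1:4))
  res <- collapse_unmapped(ladder)
  expect_length(res$survivors, 1L)
  expect_identical(names(res$survivors), "L1")
  ## exact suffix merges; internal deletion variant stays separate
  del <- paste0(substring(tx, 1, 400), substring(tx, 501))
  res2 <- collapse_unmapped(c(full = tx, suf = substring(tx, 201), del = del))
  expect_setequal(names(res2$survivors), c("full", "del"))
})
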