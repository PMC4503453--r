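test_that("exact splice-chain matching compares junctions with end slack", {
  a <- chain("a", "chr1", "+", c(100, 300, 400, 600, 700, 900))
  expect_true(exact_match(a, a))
  ## terminal exon outer boundaries are not compared
  b <- a; b$exons[1, 1] <- 150L; b$exons[3, 2] <- 950L
  expect_true(exact_match(a, b))
  ## one acceptor off by 1 bp
  d <- a; d$exons[2, 1] <- 401L
  expect_false(exact_match(a, d))
  expect_false(exact_match(a, chain("s", "chr1", "-", c(100, 300, 400, 600,
                                                        700, 900))))
  expect_false(exact_match(a, chain("e", "chr1", "+", c(100, 300, 400, 900))))
  ## single exon: reciprocal overlap >= 50%
  s1 <- chain("s1", "chr1", "+", c(100, 500))
  expect_true(exact_match(s1, chain("s2", "chr1", "+", c(250, 600))))
  expect_false(exact_match(s1, chain("s3", "chr1", "+", c(420, 900))))
})

test_that("random perturbations agree with a field-by-field comparison oracle", {
  set.seed(50)
  for (rep in 1:30) {
    ex <- sort(sample(100:2000, 2 * sample(2:4, 1)))
    a <- chain("a", "chr1", "+", ex)
    b <- a
    if (runif(1) < 0.5) {
      r <- sample(nrow(b$exons) * 2, 1)
      b$exons[ceiling(r / 2), 2 - r %% 2] <-
        b$exons[ceiling(r / 2), 2 - r %% 2] + sample(c(-2, -1, 1, 2), 1)
    }
    internal_equal <- identical(longform:::junction_key(a),
                                longform:::junction_key(b))
    expect_identical(exact_match(a, b), internal_equal)
  }
})

test_that("scoring a set against itself is perfect; metrics swap with arguments", {
  sim <- sim_errorfree()
  truth <- sim_truth_alignments(sim)
  sc <- score_sets(truth, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)
  expect_true(all(sc$by_bin$sensitivity == 1))
  ## dropping minor isoforms from multi-isoform loci: bin-1 sensitivity
  ## stays 1, query set keeps specificity 1
  loci <- assign_loci(truth)
  ids <- vapply(truth, function(a) a$query_id, "")
  keep <- !duplicated(loci[ids])
  query <- truth[keep]
  sc2 <- score_sets(query, truth)
  expect_equal(sc2$specificity, 1)
  expect_lt(sc2$sensitivity, 1)
  if (1 %in% sc2$by_bin$bin)
    expect_equal(sc2$by_bin$sensitivity[sc2$by_bin$bin == 1], 1)
  ## swapping the roles swaps the metrics
  sc3 <- score_sets(truth, query)
  expect_equal(sc3$sensitivity, sc2$specificity)
  expect_equal(sc3$specificity, sc2$sensitivity)
})

test_that("set scores equal the all-pairs oracle on random subsets", {
  sim <- sim_errorfree()
  truth <- sim_truth_alignments(sim)
  set.seed(52)
  for (rep in 1:3) {
    q <- truth[sample(length(truth), 25)]
    r <- truth[sample(length(truth), 25)]
    sc <- score_sets(q, r)
    ## restrict the oracle to the same shared loci
    loci <- sc$loci
    qtag <- paste0("q|", vapply(q, function(a) a$query_id, ""))
    rtag <- paste0("r|", vapply(r, function(a) a$query_id, ""))
    shared <- intersect(unique(loci[qtag]), unique(loci[rtag]))
    qk <- q[loci[qtag] %in% shared]
    rk <- r[loci[rtag] %in% shared]
    want <- oracle_scores(qk, rk)
    expect_equal(sc$sensitivity, want$sensitivity)
    expect_equal(sc$specificity, want$specificity)
  }
})

test_that("metrics are invariant to transcript order and ids", {
  sim <- sim_errorfree()
  truth <- sim_truth_alignments(sim)
  q <- truth[seq(1, length(truth), by = 2)]
  sc1 <- score_sets(q, truth)
  set.seed(53)
  q2 <- q[sample(length(q))]
  for (i in seq_along(q2)) q2[[i]]$query_id <- sprintf("renamed%03d", i)
  sc2 <- score_sets(q2, truth)
  expect_equal(sc1$sensitivity, sc2$sensitivity)
  expect_equal(sc1$specificity, sc2$specificity)
})

test_that("recovery frequency counts matching query sets per reference transcript", {
  sim <- sim_errorfree()
  truth <- sim_truth_alignments(sim)
  sets <- list(all = truth, half = truth[seq(1, length(truth), 2)],
               none = list(chain("z", "chrZ", "+", c(1, 50))))
  rf <- recovery_frequency(sets, truth)
  expect_equal(nrow(rf), length(truth))
  expect_true(all(rf$n_sets_matched >= 1))
  expect_true(any(rf$n_sets_matched == 2))
})
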