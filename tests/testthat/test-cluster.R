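test_that("same_isoform accepts identity and 5' degradation, rejects exon skips", {
  set.seed(21)
  a <- rnd_dna(800)
  p <- cluster_params(error_rate = 0.02)
  expect_true(same_isoform(a, a, p)$same)
  ## 5'-degraded copy
  expect_true(same_isoform(a, substring(a, 201), p)$same)
  ## internal 120-nt deletion (skipped exon): long internal gap
  b <- paste0(substring(a, 1, 400), substring(a, 521))
  res <- same_isoform(a, b, p)
  expect_false(res$same)
  expect_gt(res$max_gap_run, 20L)
  ## 3' ends must agree
  expect_false(same_isoform(a, substring(a, 1, 700), p)$same)
  expect_false(same_isoform(a, "", p)$same)
})

test_that("similarity graph matches brute-force all-pairs evaluation", {
  fl <- fl_lowerr()
  p <- cluster_params(error_rate = 0.02)
  sub <- fl$seqs[seq_len(min(90L, length(fl$seqs)))]
  g1 <- build_similarity_graph(sub, p, prefilter = TRUE)
  g2 <- build_similarity_graph(sub, p, prefilter = FALSE)
  key <- function(e) sort(paste(pmin(e$i, e$j), pmax(e$i, e$j)))
  expect_identical(key(g1$edges), key(g2$edges))
})

test_that("identical reads form a complete graph and one cluster", {
  s <- setNames(rep(rnd_dna(300), 5), paste0("r", 1:5))
  g <- build_similarity_graph(s, cluster_params(error_rate = 0))
  expect_equal(nrow(g$edges), choose(5, 2))
  cl <- initial_clusters(g)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]], names(s))
})

test_that("greedy clique cover equals a direct simulation of the stated rule", {
  ## fixed small graphs, including a bridge
  graphs <- list(
    list(nodes = paste0("n", 1:7),
         edges = data.frame(i = c("n1","n1","n2","n4","n4","n5","n3"),
                            j = c("n2","n3","n3","n5","n6","n6","n4"))),
    list(nodes = paste0("m", 1:6),
         edges = data.frame(i = c("m1","m1","m2","m4","m5"),
                            j = c("m2","m3","m3","m5","m6"))))
  for (g in graphs) {
    got <- unname(initial_clusters(structure(g, class = "lf_graph")))
    want <- oracle_greedy_cover(g$nodes, g$edges)
    expect_identical(got[order(vapply(got, `[`, "", 1))],
                     want[order(vapply(want, `[`, "", 1))])
  }
})

test_that("DAG consensus reproduces members and denoises errorful reads", {
  p <- cluster_params(error_rate = 0.1)
  one <- rnd_dna(400)
  expect_identical(dag_consensus(c(x = one), params = p), one)
  expect_identical(dag_consensus(setNames(rep(one, 5), paste0("r", 1:5)),
                                 params = p), one)
  ## 20 reads at 10% error from a 1-kb transcript
  set.seed(41)
  tx <- rnd_dna(1000)
  reads <- setNames(vapply(1:20, function(i)
    longform:::mutate_seq(tx, 0.01, 0.06, 0.03), ""), paste0("r", 1:20))
  cons <- dag_consensus(reads, params = p)
  al <- longform:::pair_align(cons, tx, "global")
  expect_lte(al$n_mismatch + al$n_gap, 2L)
})

test_that("reassignment reaches a fixed point and corrects a mis-seeded read", {
  set.seed(13)
  txA <- rnd_dna(500); txB <- rnd_dna(500)
  reads <- c(setNames(rep(txA, 4), paste0("a", 1:4)),
             setNames(rep(txB, 4), paste0("b", 1:4)))
  p <- cluster_params(error_rate = 0.01)
  g <- build_similarity_graph(reads, p)
  ## correct partition is a fixed point
  cl_ok <- list(c1 = paste0("a", 1:4), c2 = paste0("b", 1:4))
  re <- reassign(reads, cl_ok, g, params = p)
  expect_equal(re$iterations, 1L)
  expect_setequal(re$clusters[[1]], cl_ok[[1]])
  ## a read seeded into the wrong cluster moves home
  cl_bad <- list(c1 = c(paste0("a", 1:3), "b1"),
                 c2 = c("a4", paste0("b", 2:4)))
  re2 <- reassign(reads, cl_bad, g, params = p)
  members <- re2$clusters[vapply(re2$clusters, function(m) "b1" %in% m, TRUE)]
  expect_setequal(members[[1]], paste0("b", 1:4))
})

test_that("polish discards clusters above the 10-error threshold and keeps those below", {
  ## two reads disagreeing at k positions give k tied columns, 0.5
  ## predicted errors each: k = 21 -> 10.5 discarded, k = 19 -> 9.5 kept
  set.seed(55)
  base <- rnd_dna(400)
  flip <- function(s, pos) {
    for (p in pos) {
      cur <- substring(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    s
  }
  p <- cluster_params(error_rate = 0.05)
  hiq <- function(seqs) vapply(seqs, function(s) strrep("I", nchar(s)), "")
  for (k in c(21L, 19L)) {
    pos <- seq(10, 390, length.out = k)
    r2 <- flip(base, round(pos))
    seqs <- c(x1 = base, x2 = r2)
    cons <- dag_consensus(seqs, hiq(seqs), params = p)
    tr <- polish(list(c1 = names(seqs)), c(c1 = cons), seqs, hiq(seqs),
                 params = p)
    expect_equal(tr$clusters$predicted_errors, k / 2, tolerance = 1e-3)
    expect_identical(tr$clusters$retained, k == 19L)
  }
  ## error-free members predict (essentially) zero errors
  seqs0 <- setNames(rep(base, 4), paste0("e", 1:4))
  tr0 <- polish(list(c1 = names(seqs0)),
                c(c1 = dag_consensus(seqs0, hiq(seqs0), params = p)),
                seqs0, hiq(seqs0), params = p)
  expect_equal(tr0$clusters$predicted_errors, 0, tolerance = 1e-3)
  expect_true(tr0$clusters$retained)
})

test_that("5'-degraded non-full-length reads are recruited to the right cluster", {
  set.seed(66)
  txA <- rnd_dna(600); txB <- rnd_dna(600)
  p <- cluster_params(error_rate = 0.01)
  fl <- c(setNames(rep(txA, 5), paste0("a", 1:5)),
          setNames(rep(txB, 5), paste0("b", 1:5)))
  nfl <- c(setNames(vapply(1:6, function(i)
    substring(txA, sample(100:300, 1)), ""), paste0("na", 1:6)),
    setNames(vapply(1:6, function(i)
      substring(txB, sample(100:300, 1)), ""), paste0("nb", 1:6)))
  tr <- cluster_isoforms(fl, nfl_seqs = nfl, params = p)
  mem <- tr$members
  homeA <- names(mem)[vapply(mem, function(m) "a1" %in% m, TRUE)]
  recruitsA <- grep("^na", mem[[homeA]], value = TRUE)
  expect_gte(length(recruitsA), 5L)
  expect_false(any(grepl("^nb", mem[[homeA]])))
})

test_that("clustering is invariant to input read order", {
  fl <- fl_lowerr()
  p <- cluster_params(error_rate = 0.02)
  sub <- fl$seqs[seq_len(min(80L, length(fl$seqs)))]
  qs <- fl$quals[names(sub)]
  t1 <- cluster_isoforms(sub, qs, params = p)
  set.seed(3); perm <- sample(length(sub))
  t2 <- cluster_isoforms(sub[perm], qs[perm], params = p)
  expect_identical(sort(unname(t1$consensus)), sort(unname(t2$consensus)))
})
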