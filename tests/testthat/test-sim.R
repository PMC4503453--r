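test_that("degenerate single-gene single-exon genome equals its transcript", {
  cfg <- sim_config(seed = 2L, n_genes = 1L, exon_count_range = c(1L, 1L),
                    ptu_fraction = 0, tandem_dup_fraction = 0,
                    error_rates = c(sub = 0, ins = 0, del = 0))
  gen <- simulate_genome(cfg)
  expect_equal(nrow(gen$genes), 1L)
  expect_equal(nrow(gen$introns), 0L)
  g <- gen$genes[1, ]
  slice <- substring(gen$genome[["chr1"]], g$start, g$end)
  isos <- simulate_isoforms(gen, cfg)
  canon <- isos$sequences[[which(isos$isoforms$kind == "canonical")]]
  expected <- if (g$strand == "+") slice else longform:::revcomp(slice)
  expect_identical(canon, expected)
})

test_that("tandem duplication produces the requested adjacent same-strand pairs", {
  cfg <- sim_config(seed = 4L, n_genes = 10L, ptu_fraction = 0,
                    tandem_dup_fraction = 0.2)
  gen <- simulate_genome(cfg)
  tp <- gen$tandem_pairs
  expect_equal(nrow(tp), 2L)
  for (r in seq_len(nrow(tp))) {
    a <- gen$genes[gen$genes$gene_id == tp$gene_a[r], ]
    b <- gen$genes[gen$genes$gene_id == tp$gene_b[r], ]
    expect_identical(a$strand, b$strand)
    ## adjacent: no other gene between them
    lo <- min(a$end, b$end); hi <- max(a$start, b$start)
    others <- gen$genes[!(gen$genes$gene_id %in% c(a$gene_id, b$gene_id)), ]
    expect_false(any(others$start < hi & others$end > lo))
  }
})

test_that("identical config reproduces byte-identical outputs", {
  cfg <- sim_config(seed = 6L, n_genes = 5L)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  sim_write(simulate_dataset(cfg), d1)
  sim_write(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("all introns are GT..AG on their transcribed strand", {
  sim <- sim_errorfree()
  g <- sim$genome$genome[["chr1"]]
  ii <- sim$genome$introns
  strand <- sim$genome$genes$strand[match(ii$gene_id,
                                          sim$genome$genes$gene_id)]
  don <- substring(g, ii$start, ii$start + 1L)
  acc <- substring(g, ii$end - 1L, ii$end)
  ok <- ifelse(strand == "+", don == "GT" & acc == "AG",
               don == "CT" & acc == "AC")
  expect_true(all(ok))
})

test_that("readthrough isoforms span >= 2 genes with stop codons in all inter-ORF frames", {
  sim <- sim_errorfree()
  iso <- sim$isoforms$isoforms
  ptu <- iso[iso$is_ptu, ]
  expect_gte(nrow(ptu), 1L)
  for (r in seq_len(nrow(ptu))) {
    gids <- strsplit(ptu$gene_ids[r], ",")[[1]]
    expect_gte(length(gids), 2L)
    genes <- sim$genome$genes[match(gids, sim$genome$genes$gene_id), ]
    expect_true(all(genes$strand == ptu$strand[r]))
    seq <- sim$isoforms$sequences[[ptu$iso_id[r]]]
    orfs <- find_orfs(seq)
    expect_gte(nrow(orfs), 2L)
    for (i in seq_len(nrow(orfs) - 1L)) {
      st <- check_inter_orf_stops(seq, orfs$end[i], orfs$start[i + 1L])
      expect_true(st$all_frames)
    }
  }
})

test_that("terminal poly(A) sites carry A-rich NUE signal, internal sites do not", {
  sim <- sim_errorfree()
  g <- sim$genome$genome[["chr1"]]
  iso <- sim$isoforms$isoforms
  window_a <- function(pos, strand) {
    win <- if (strand == "+") substring(g, pos - 29L, pos - 9L) else
      longform:::revcomp(substring(g, pos + 9L, pos + 29L))
    mean(strsplit(win, "")[[1]] == "A")
  }
  term <- iso[iso$pas_class %in% c("nORF", "pORF2-terminal"), ]
  intn <- iso[iso$pas_class == "pORF1-internal", ]
  a_term <- mean(mapply(window_a, term$pas_pos, term$strand))
  a_int <- mean(mapply(window_a, intn$pas_pos, intn$strand))
  expect_gt(a_term, 0.5)
  expect_lt(abs(a_int - 0.25), 0.12)  # ~ uniform background
})

test_that("read counts match the manifest and non-FL reads are 5'-truncated", {
  sim <- sim_lowerr()
  expect_equal(length(sim$reads$sequences), nrow(sim$reads$manifest))
  expect_identical(names(sim$reads$sequences), sim$reads$manifest$read_id)
  man <- sim$reads$manifest
  expect_true(all(man$truncation[man$is_full_length] == 0L))
  expect_true(all(man$truncation[!man$is_full_length] > 0L))
})

test_that("observed per-base error rate matches the configured 15% total", {
  cfg <- sim_config(seed = 12L, n_genes = 4L, ptu_fraction = 0)
  sim <- simulate_dataset(cfg)
  man <- sim$reads$manifest
  fl <- man[man$is_full_length, ][1:60, ]
  p3rc <- longform:::revcomp(cfg$primer3)
  rates <- vapply(seq_len(nrow(fl)), function(i) {
    tx <- sim$isoforms$sequences[[fl$iso_id[i]]]
    truth <- paste0(cfg$primer5, tx)
    read <- sim$reads$sequences[[fl$read_id[i]]]
    if (fl$strand[i] == "-") read <- longform:::revcomp(read)
    al <- longform:::pair_align(read, truth, mode = "overlap", band = 150L)
    (al$n_mismatch + al$n_gap) / nchar(truth)
  }, 0)
  expect_lt(abs(mean(rates) - 0.15), 0.02)
})

test_that("short-read coverage equals the abundance-weighted exon sum with Poisson noise", {
  cfg <- sim_config(seed = 3L, n_genes = 6L, ptu_fraction = 0,
                    tandem_dup_fraction = 0, shortread_noise = FALSE,
                    shortread_scale = 1)
  sim <- simulate_dataset(cfg)
  sup <- sim$support
  ## noiseless: coverage at a position covered by exactly the canonical
  ## isoform of one gene equals that isoform's abundance
  iso <- sim$isoforms$isoforms
  exp_cov <- numeric(nchar(sim$genome$genome[["chr1"]]))
  for (i in seq_len(nrow(iso))) {
    ex <- sim$isoforms$exons[[iso$iso_id[i]]]
    for (e in seq_len(nrow(ex)))
      exp_cov[ex[e, 1]:ex[e, 2]] <- exp_cov[ex[e, 1]:ex[e, 2]] +
        iso$abundance[i]
  }
  expect_equal(sup$coverage$cov, exp_cov[sup$coverage$pos])

  ## Poisson noise: mean/variance ratio ~ 1 at constant expected coverage
  cfgN <- sim_config(seed = 3L, n_genes = 6L, ptu_fraction = 0,
                     tandem_dup_fraction = 0, shortread_noise = TRUE,
                     shortread_scale = 5)
  simN <- simulate_dataset(cfgN)
  supN <- simN$support$coverage
  expN <- 5 * exp_cov[supN$pos]
  one_level <- supN$cov[abs(expN - 100) < 1e-9]
  if (length(one_level) > 200L) {
    ratio <- stats::var(one_level) / mean(one_level)
    expect_lt(abs(ratio - 1), 0.35)
  }
})

test_that("empty isoform abundance yields an empty read set with a warning", {
  cfg <- sim_config(seed = 2L, n_genes = 2L, ptu_fraction = 0,
                    fl_coverage_per_isoform = 20)
  gen <- simulate_genome(cfg)
  isos <- simulate_isoforms(gen, cfg)
  isos$isoforms <- isos$isoforms[0, ]
  expect_warning(reads <- simulate_reads(isos, cfg), "empty")
  expect_length(reads$sequences, 0L)
})

test_that("infeasible geometry is rejected with a named constraint", {
  expect_error(sim_config(cds_aa_range = c(50L, 80L)), "100 aa")
  expect_error(sim_config(utr3_len_range = c(30L, 50L)), "70 nt")
  expect_error(sim_config(ptu_span_range = c(2L, 6L)), "\\[2, 4\\]")
  expect_error(sim_config(error_rates = c(sub = -0.1, ins = 0, del = 0)),
               "non-negative")
})
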