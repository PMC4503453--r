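## Synthetic genome / transcriptome / long-read simulator with ground truth.
##
## The generator builds a toy multi-gene genome in which every feature the
## downstream pipeline looks for is planted explicitly: spliced genes with
## GT..AG introns, tandem near-duplicate genes, several isoforms per locus
## (exon skipping, alternative donors/acceptors, alternative polyadenylation,
## alternative TSS), readthrough polycistronic transcripts spanning 2-4
## adjacent same-strand genes, A-rich NUE / U-rich FUE signals upstream of
## terminal (but not internal) poly(A) sites, and an indel-dominant read
## error model.  A manifest binds every read to its source isoform.

#' Simulation configuration
#'
#' Returns a validated configuration list for the synthetic-data generator.
#' Every stochastic choice in the simulator is driven by `seed`, so a fixed
#' configuration reproduces byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of primary genes (tandem duplicates are added on
#'   top of this count).
#' @param exon_count_range integer range of exons per gene drawn uniformly.
#' @param exon_len_range approximate exon length range (nt) used to place
#'   introns inside the coding sequence.
#' @param intron_len_range intron length range (nt), minimum 20.
#' @param isoform_lambda Poisson rate for extra isoforms per locus; each
#'   locus gets `1 + rpois(1, isoform_lambda)` isoforms (capped by the
#'   number of feasible distinct alternative events).
#' @param as_event_probs named sampling weights over alternative-isoform
#'   event types (exon_skip, alt_donor, alt_acceptor, apa, alt_tss);
#'   infeasible types at a locus are dropped and the rest renormalised.
#' @param ptu_fraction fraction of genes placed into readthrough
#'   (polycistronic) clusters.
#' @param ptu_span_range genes per polycistronic cluster; must lie in [2,4].
#' @param inter_orf_distance_mean mean transcript-level distance (nt)
#'   between the stop codon of one ORF and the start codon of the next in a
#'   readthrough transcript.
#' @param tandem_dup_fraction fraction of genes receiving an adjacent
#'   same-strand near-duplicate copy.
#' @param tandem_divergence per-base substitution rate applied to tandem
#'   duplicate copies.
#' @param ptu_tandem_fraction fraction of polycistronic clusters in which
#'   one adjacent member pair is a tandem duplication.
#' @param fl_coverage_per_isoform mean full-length reads per isoform.
#' @param nonfl_fraction fraction of reads that are 5'-truncated.
#' @param error_rates named vector `c(sub=, ins=, del=)` of per-base error
#'   rates; the defaults total 0.15 with indels dominating.
#' @param polyA_len_range poly(A) tail length range (nt).
#' @param primer5,primer3 cDNA primer sequences; a full-length read is
#'   `primer5 + transcript + polyA + revcomp(primer3)`.
#' @param downstream_tier_factor ratio of independent expression of gene
#'   k+1 to gene k within a polycistronic cluster (< 1).
#' @param ptu_abundance_factor abundance of the readthrough isoform
#'   relative to `fl_coverage_per_isoform`.
#' @param cds_aa_range CDS length range in amino acids (>= 100 so every
#'   gene passes the ORF size filter).
#' @param utr5_len_range,utr3_len_range UTR length ranges (nt); the 3' UTR
#'   minimum must be >= 70 so signal windows fit upstream of the poly(A)
#'   site.
#' @param apa_ext_range length range of the alternative-poly(A) extension
#'   region (nt).
#' @param intergenic_len_range intergenic spacer range between independent
#'   loci (nt).
#' @param nue_a_prob,fue_u_prob per-base implant probabilities for the
#'   A-rich NUE (positions -30..-10) and U-rich FUE (-60..-30).
#' @param cleavage_context_len,cleavage_a_prob length and residual A rate
#'   of the A-poor (pyrimidine-biased) context immediately upstream of
#'   every cleavage site.
#' @param shortread_scale coverage scale factor for the simulated
#'   short-read support tables.
#' @param shortread_noise logical; add Poisson noise to coverage/junction
#'   support.
#' @return a list of class `lf_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       exon_count_range = c(1L, 4L),
                       exon_len_range = c(150L, 400L),
                       intron_len_range = c(120L, 200L),
                       isoform_lambda = 2.5,
                       as_event_probs = c(exon_skip = 0.3, alt_donor = 0.15,
                                          alt_acceptor = 0.15, apa = 0.25,
                                          alt_tss = 0.15),
                       ptu_fraction = 0.55,
                       ptu_span_range = c(2L, 4L),
                       inter_orf_distance_mean = 364,
                       tandem_dup_fraction = 0.05,
                       tandem_divergence = 0.12,
                       ptu_tandem_fraction = 0.9,
                       fl_coverage_per_isoform = 20,
                       nonfl_fraction = 0.3,
                       error_rates = c(sub = 0.01, ins = 0.09, del = 0.05),
                       polyA_len_range = c(15L, 40L),
                       primer5 = "AAGCAGTGGTATCAACGCAGAGTAC",
                       primer3 = "TGGATCACTTGCGCAAGGCTAGTCA",
                       downstream_tier_factor = 0.5,
                       ptu_abundance_factor = 0.5,
                       cds_aa_range = c(120L, 300L),
                       utr5_len_range = c(30L, 60L),
                       utr3_len_range = c(70L, 120L),
                       apa_ext_range = c(80L, 140L),
                       intergenic_len_range = c(200L, 500L),
                       nue_a_prob = 0.6,
                       fue_u_prob = 0.65,
                       cleavage_context_len = 12L,
                       cleavage_a_prob = 0.05,
                       shortread_scale = 3,
                       shortread_noise = TRUE) {
  cfg <- as.list(environment())
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (any(error_rates < 0)) stop("error_rates must be non-negative")
  if (sum(error_rates) >= 1) stop("error_rates must sum to < 1")
  if (is.null(names(error_rates)) ||
      !all(c("sub", "ins", "del") %in% names(error_rates)))
    stop("error_rates must be named c(sub=, ins=, del=)")
  if (ptu_span_range[1] < 2 || ptu_span_range[2] > 4)
    stop("ptu_span_range must lie within [2, 4]")
  if (intron_len_range[1] < 20)
    stop("infeasible geometry: intron_len_range minimum below 20 nt")
  if (cds_aa_range[1] < 100)
    stop("infeasible geometry: cds_aa_range minimum below 100 aa, genes would fail the ORF filter")
  if (utr3_len_range[1] < 70)
    stop("infeasible geometry: utr3_len_range minimum below 70 nt, poly(A) signal windows would overrun the CDS")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (ptu_fraction > 0 && n_genes < 2 && ptu_fraction * n_genes >= 2)
    stop("infeasible geometry: not enough genes for a polycistronic cluster")
  class(cfg) <- "lf_sim_config"
  cfg
}

runif_int <- function(n, range) {
  if (range[1] >= range[2]) return(rep(as.integer(range[1]), n))
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

## sample() that never auto-expands a length-1 vector
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

## 12-mer with a stop codon in each of the three reading frames regardless
## of the frame in which scanning begins (TAG at offsets 0, 4, 8).
STOP_BLOCK <- "TAGATAGATAGA"

## Build one gene template on the sense strand.  All coordinates are
## 1-based and relative to the start of the gene region.
build_gene_template <- function(cfg) {
  u5 <- runif_int(1L, cfg$utr5_len_range)
  u3 <- runif_int(1L, cfg$utr3_len_range)
  ext <- runif_int(1L, cfg$apa_ext_range)
  aa <- runif_int(1L, cfg$cds_aa_range)
  cds <- random_cds(aa)
  cds_len <- nchar(cds)
  tss_alt_off <- runif_int(1L, c(10L, 25L))

  n_exons <- runif_int(1L, cfg$exon_count_range)
  cuts <- integer(0)
  if (n_exons > 1L) {
    cand <- cumsum(runif_int(n_exons - 1L, cfg$exon_len_range))
    cand <- cand[cand >= u5 + 40L & cand <= u5 + cds_len - 40L]
    cuts <- sort(unique(cand))
  }
  intron_lens <- runif_int(length(cuts), cfg$intron_len_range)

  ## assemble genomic sequence: utr5 + cds-with-introns + utr3 + ext
  utr5_seq <- random_dna(u5)
  utr3_seq <- random_dna(u3)
  ext_seq <- random_dna(ext)
  tx_cds <- cds

  pieces <- character(0)
  introns_rel <- matrix(integer(0), ncol = 2)
  prev_tx <- 0L       # transcript-coordinate position already emitted
  gpos <- 0L          # genomic length emitted so far
  tx_prefix_len <- u5
  for (j in seq_along(cuts)) {
    cds_cut <- cuts[j] - u5            # position within CDS after which intron goes
    pieces <- c(pieces, substring(tx_cds, prev_tx + 1L, cds_cut))
    gpos <- gpos + (cds_cut - prev_tx)
    ilen <- intron_lens[j]
    inner <- random_dna(ilen - 4L)
    intron <- paste0("GT", inner, "AG")
    ## plant alternative donor (+48) and acceptor (-48) sites inside the
    ## intron; the 48-nt shift keeps frame and is wide enough that the
    ## clustering internal-gap and identity rules separate the variants
    if (ilen >= 110L) {
      substr(intron, 49L, 50L) <- "GT"
      substr(intron, ilen - 49L, ilen - 48L) <- "AG"
    }
    istart <- u5 + gpos + sum(intron_lens[seq_len(j - 1L)]) + 1L
    introns_rel <- rbind(introns_rel, c(istart, istart + ilen - 1L))
    pieces <- c(pieces, intron)
    prev_tx <- cds_cut
  }
  pieces <- c(pieces, substring(tx_cds, prev_tx + 1L, cds_len))
  cds_genomic <- paste(pieces, collapse = "")
  gene_seq <- paste0(utr5_seq, cds_genomic, utr3_seq, ext_seq)

  pas <- u5 + nchar(cds_genomic) + u3          # canonical cleavage site (rel)
  pas_alt <- pas + ext
  list(seq = gene_seq, len = nchar(gene_seq),
       u5 = u5, u3 = u3, ext = ext, ext2 = 0L,
       tss = 1L, tss_alt = 1L + tss_alt_off,
       cds_start = u5 + 1L, cds_len = cds_len, aa = aa,
       cds_genomic_len = nchar(cds_genomic),
       pas = pas, pas_alt = pas_alt, pas_rt = NA_integer_,
       introns = introns_rel)
}

## Append a readthrough termination zone: polycistronic transcripts that
## end at this gene terminate downstream of both monocistronic sites.
add_readthrough_zone <- function(tpl, cfg) {
  ext2 <- runif_int(1L, cfg$apa_ext_range)
  tpl$seq <- paste0(tpl$seq, random_dna(ext2))
  tpl$len <- nchar(tpl$seq)
  tpl$ext2 <- ext2
  tpl$pas_rt <- tpl$pas_alt + ext2
  tpl
}

## Rewrite the sequence upstream of a cleavage site `pas` (gene-relative):
## U-rich FUE at -60..-30 and A-rich NUE at -30..-10 when `signals` is on,
## and always an A-poor cleavage-proximal context over the last
## `cleavage_context_len` bases (as at real sites, where the region just
## before the cleavage position is pyrimidine-rich; this also keeps the
## polyA-tail scan from running into the 3' UTR).
implant_pas_signals <- function(seq, pas, cfg, signals = TRUE) {
  set_window <- function(seq, from, to, base, prob) {
    idx <- seq.int(from, to)
    idx <- idx[idx >= 1L & idx <= nchar(seq)]
    chars <- strsplit(substring(seq, min(idx), max(idx)), "")[[1]]
    pick <- runif(length(chars)) < prob
    chars[pick] <- base
    chars[!pick] <- sample(BASES, sum(!pick), replace = TRUE)
    substr(seq, min(idx), max(idx)) <- paste(chars, collapse = "")
    seq
  }
  if (signals) {
    seq <- set_window(seq, pas - 59L, pas - 29L, "T", cfg$fue_u_prob)
    seq <- set_window(seq, pas - 29L, pas - 9L, "A", cfg$nue_a_prob)
  }
  ctx <- cfg$cleavage_context_len
  idx <- seq.int(max(1L, pas - ctx + 1L), pas)
  chars <- sample(c("C", "G", "T"), length(idx), replace = TRUE)
  keepA <- runif(length(idx)) < cfg$cleavage_a_prob
  chars[keepA] <- "A"
  substr(seq, min(idx), max(idx)) <- paste(chars, collapse = "")
  seq
}

## near-copy of a gene template: substitutions only (coordinates preserved),
## with splice dinucleotides, start/stop codons and CDS frame kept intact.
mutate_gene_template <- function(tpl, rate) {
  chars <- strsplit(tpl$seq, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    repl <- vapply(chars[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    chars[hit] <- repl
  }
  s <- paste(chars, collapse = "")
  ## restore splice sites and alternative sites
  if (nrow(tpl$introns)) {
    for (j in seq_len(nrow(tpl$introns))) {
      is <- tpl$introns[j, 1]; ie <- tpl$introns[j, 2]
      substr(s, is, is + 1L) <- "GT"
      substr(s, ie - 1L, ie) <- "AG"
      if (ie - is + 1L >= 110L) {
        substr(s, is + 48L, is + 49L) <- "GT"
        substr(s, ie - 49L, ie - 48L) <- "AG"
      }
    }
  }
  ## restore start codon and repair any in-frame stops introduced in the CDS
  tx <- spliced_substring(s, tpl)
  cds_tx <- substring(tx, tpl$u5 + 1L, tpl$u5 + tpl$cds_len)
  substr(cds_tx, 1L, 3L) <- "ATG"
  ncod <- tpl$cds_len / 3L
  for (ci in seq_len(ncod - 1L)) {
    cod <- substring(cds_tx, 3L * ci - 2L, 3L * ci)
    if (ci > 1L && cod %in% STOP_CODONS) {
      ## second position C turns any stop codon into a sense codon
      substr(cds_tx, 3L * ci - 1L, 3L * ci - 1L) <- "C"
    }
  }
  if (!(substring(cds_tx, tpl$cds_len - 2L, tpl$cds_len) %in% STOP_CODONS))
    substr(cds_tx, tpl$cds_len - 2L, tpl$cds_len) <- "TAA"
  ## write the repaired CDS back through the exon structure
  s <- unspliced_patch(s, tpl, paste0(substring(tx, 1L, tpl$u5), cds_tx,
                                      substring(tx, tpl$u5 + tpl$cds_len + 1L)))
  tpl$seq <- s
  tpl
}

## transcript-sense spliced sequence of the canonical region [tss, pas_alt]
spliced_substring <- function(seq, tpl) {
  keep <- rep(TRUE, nchar(seq))
  if (nrow(tpl$introns))
    for (j in seq_len(nrow(tpl$introns)))
      keep[tpl$introns[j, 1]:tpl$introns[j, 2]] <- FALSE
  paste(strsplit(seq, "")[[1]][keep], collapse = "")
}

unspliced_patch <- function(seq, tpl, tx) {
  chars <- strsplit(seq, "")[[1]]
  keep <- rep(TRUE, length(chars))
  if (nrow(tpl$introns))
    for (j in seq_len(nrow(tpl$introns)))
      keep[tpl$introns[j, 1]:tpl$introns[j, 2]] <- FALSE
  txc <- strsplit(tx, "")[[1]]
  chars[which(keep)[seq_along(txc)]] <- txc
  paste(chars, collapse = "")
}

#' Simulate a toy genome with annotation
#'
#' Lays out genes (with spliced GT..AG introns), tandem duplicates and
#' adjacent same-strand polycistronic clusters on a single contig, implants
#' poly(A)-signal elements upstream of terminal cleavage sites, and plants
#' stop codons in all three frames in every readthrough inter-ORF gap.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `lf_genome` with elements `genome` (named
#'   character vector of contigs), `genes` (data.frame), `introns`
#'   (data.frame of genomic intron coordinates per gene), `ptus`
#'   (data.frame of cluster memberships), `tandem_pairs` (data.frame) and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "lf_sim_config"))
  cfg <- config
  with_rng(cfg$seed, {
    n <- as.integer(cfg$n_genes)
    ## partition genes into polycistronic clusters and singletons
    n_ptu_genes <- round(cfg$ptu_fraction * n)
    spans <- integer(0)
    left <- n_ptu_genes
    while (left >= 2L) {
      s <- runif_int(1L, cfg$ptu_span_range)
      s <- min(s, left)
      if (s < 2L) break
      spans <- c(spans, s)
      left <- left - s
    }
    n_singles <- n - sum(spans)
    n_dup <- round(cfg$tandem_dup_fraction * n)
    n_dup <- min(n_dup, n_singles)

    ## block plan: each entry is a cluster (span k) or single gene
    blocks <- c(lapply(spans, function(s) list(type = "ptu", span = s)),
                rep(list(list(type = "single", span = 1L)), n_singles))
    blocks <- blocks[sample.int(length(blocks))]
    dup_blocks <- resample(which(vapply(blocks, function(b) b$type == "single",
                                        TRUE)), n_dup)

    genome_parts <- character(0)
    offset <- 0L
    genes <- list(); introns <- list(); ptus <- list(); tpairs <- list()
    templates <- list()
    gid <- 0L; pid <- 0L

    emit_gene <- function(tpl, strand, block_rel_start, internal_ptu) {
      ## caller tracks offsets; returns record with relative coordinates
      list(tpl = tpl, strand = strand, rel = block_rel_start,
           internal = internal_ptu)
    }

    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      strand <- sample(c("+", "-"), 1L)
      members <- list()
      rel <- 1L
      if (blk$type == "ptu") {
        pid <- pid + 1L
        k <- blk$span
        ## with probability ptu_tandem_fraction one adjacent member pair
        ## of the cluster is a tandem duplication
        dup_pos <- if (runif(1) < cfg$ptu_tandem_fraction)
          resample(seq_len(k - 1L), 1L) else 0L
        tandem_cluster <- dup_pos > 0L
        tpls <- vector("list", k)
        for (m in seq_len(k)) {
          if (tandem_cluster && m == dup_pos + 1L) {
            tpls[[m]] <- mutate_gene_template(tpls[[dup_pos]],
                                              cfg$tandem_divergence)
          } else {
            tpls[[m]] <- build_gene_template(cfg)
          }
        }
        tpls[[k]] <- add_readthrough_zone(tpls[[k]], cfg)
        gaps <- integer(k - 1L)
        seqs <- character(0)
        for (m in seq_len(k)) {
          tpl <- tpls[[m]]
          internal <- m < k
          tpl$seq <- implant_pas_signals(tpl$seq, tpl$pas, cfg,
                                         signals = !internal)
          tpl$seq <- implant_pas_signals(tpl$seq, tpl$pas_alt, cfg,
                                         signals = !internal)
          if (!internal)
            tpl$seq <- implant_pas_signals(tpl$seq, tpl$pas_rt, cfg)
          members[[m]] <- emit_gene(tpl, strand, rel, internal)
          seqs <- c(seqs, tpl$seq)
          rel <- rel + tpl$len
          if (m < k) {
            nxt <- tpls[[m + 1L]]
            target <- round(rnorm(1L, cfg$inter_orf_distance_mean, 25))
            gap <- max(30L, as.integer(target -
                                         (tpl$u3 + tpl$ext + tpl$ext2 +
                                            nxt$u5)))
            gseq <- random_dna(gap)
            substr(gseq, 4L, 15L) <- STOP_BLOCK
            seqs <- c(seqs, gseq)
            gaps[m] <- gap
            rel <- rel + gap
          }
        }
        block_seq <- paste(seqs, collapse = "")
        ptus[[pid]] <- list(ptu_id = sprintf("ptu%02d", pid),
                            n_genes = k, tandem = tandem_cluster,
                            dup_pos = dup_pos)
      } else {
        tpl <- build_gene_template(cfg)
        tpl$seq <- implant_pas_signals(tpl$seq, tpl$pas, cfg)
        tpl$seq <- implant_pas_signals(tpl$seq, tpl$pas_alt, cfg)
        members[[1L]] <- emit_gene(tpl, strand, rel, FALSE)
        seqs <- tpl$seq
        rel <- rel + tpl$len
        if (bi %in% dup_blocks) {
          dup <- mutate_gene_template(tpl, cfg$tandem_divergence)
          gap <- runif_int(1L, c(150L, 300L))
          members[[2L]] <- emit_gene(dup, strand, rel + gap, FALSE)
          seqs <- c(seqs, random_dna(gap), dup$seq)
          rel <- rel + gap + dup$len
        }
        block_seq <- paste(seqs, collapse = "")
      }
      blocklen <- nchar(block_seq)

      ## flip block to genome coordinates if on the minus strand
      if (strand == "-") block_seq <- revcomp(block_seq)
      genome_parts <- c(genome_parts, block_seq,
                        random_dna(runif_int(1L, cfg$intergenic_len_range)))

      flip_pos <- function(p) blocklen - p + 1L
      for (m in seq_along(members)) {
        mem <- members[[m]]
        tpl <- mem$tpl
        gid <- gid + 1L
        gene_id <- sprintf("g%03d", gid)
        templates[[gene_id]] <- tpl
        abs_pos <- function(p) {
          if (strand == "+") offset + mem$rel - 1L + p
          else offset + flip_pos(mem$rel - 1L + p)
        }
        g_start <- min(abs_pos(tpl$tss), abs_pos(tpl$pas))
        g_end <- max(abs_pos(tpl$tss), abs_pos(tpl$pas))
        irec <- NULL
        if (nrow(tpl$introns)) {
          a <- vapply(tpl$introns[, 1], abs_pos, 0L)
          b <- vapply(tpl$introns[, 2], abs_pos, 0L)
          irec <- data.frame(gene_id = gene_id,
                             start = pmin(a, b), end = pmax(a, b))
          irec <- irec[order(irec$start), , drop = FALSE]
        }
        is_ptu <- blk$type == "ptu"
        genes[[gid]] <- data.frame(
          gene_id = gene_id, chrom = "chr1",
          start = g_start, end = g_end, strand = strand,
          tss = abs_pos(tpl$tss), tss_alt = abs_pos(tpl$tss_alt),
          pas = abs_pos(tpl$pas), pas_alt = abs_pos(tpl$pas_alt),
          pas_rt = if (is.na(tpl$pas_rt)) NA_integer_ else
            abs_pos(tpl$pas_rt),
          cds_len = tpl$cds_len, aa = tpl$aa,
          n_introns = nrow(tpl$introns),
          ptu_id = if (is_ptu) sprintf("ptu%02d", pid) else NA_character_,
          ptu_tier = if (is_ptu) m else 1L,
          internal_ptu = mem$internal,
          stringsAsFactors = FALSE)
        if (!is.null(irec)) introns[[length(introns) + 1L]] <- irec
        if (blk$type == "single" && m == 2L) {
          tpairs[[length(tpairs) + 1L]] <-
            data.frame(gene_a = sprintf("g%03d", gid - 1L), gene_b = gene_id,
                       in_ptu = FALSE, stringsAsFactors = FALSE)
        }
        if (is_ptu && isTRUE(ptus[[pid]]$tandem) &&
            m == ptus[[pid]]$dup_pos + 1L) {
          tpairs[[length(tpairs) + 1L]] <-
            data.frame(gene_a = sprintf("g%03d", gid - 1L), gene_b = gene_id,
                       in_ptu = TRUE, stringsAsFactors = FALSE)
        }
        if (is_ptu) {
          ptus[[pid]]$genes <- c(ptus[[pid]]$genes, gene_id)
        }
      }
      offset <- offset + blocklen +
        nchar(genome_parts[length(genome_parts)])
    }

    genome <- c(chr1 = paste(genome_parts, collapse = ""))
    genes <- do.call(rbind, genes)
    introns <- if (length(introns)) do.call(rbind, introns) else
      data.frame(gene_id = character(0), start = integer(0), end = integer(0))
    ptu_df <- if (length(ptus)) do.call(rbind, lapply(ptus, function(p)
      data.frame(ptu_id = p$ptu_id, genes = paste(p$genes, collapse = ","),
                 n_genes = p$n_genes, tandem = isTRUE(p$tandem),
                 stringsAsFactors = FALSE))) else
      data.frame(ptu_id = character(0), genes = character(0),
                 n_genes = integer(0), tandem = logical(0))
    tpair_df <- if (length(tpairs)) do.call(rbind, tpairs) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 in_ptu = logical(0))
    structure(list(genome = genome, genes = genes, introns = introns,
                   ptus = ptu_df, tandem_pairs = tpair_df,
                   templates = templates, config = cfg),
              class = "lf_genome")
  })
}

## ---------------------------------------------------------------------------
## isoforms
## ---------------------------------------------------------------------------

## exons of an isoform given its genomic span and intron set (both 1-based
## inclusive); returns a matrix with columns start, end in ascending order.
exons_from_introns <- function(span_start, span_end, introns) {
  if (is.null(introns) || nrow(introns) == 0L)
    return(cbind(start = span_start, end = span_end))
  ord <- order(introns[, 1])
  introns <- introns[ord, , drop = FALSE]
  starts <- c(span_start, introns[, 2] + 1L)
  ends <- c(introns[, 1] - 1L, span_end)
  keep <- starts <= ends
  cbind(start = starts[keep], end = ends[keep])
}

## extract the transcript-sense sequence of an exon chain
extract_transcript <- function(genome, chrom, exons, strand) {
  seq <- genome[[chrom]]
  parts <- substring(seq, exons[, 1], exons[, 2])
  s <- paste(parts, collapse = "")
  if (strand == "-") s <- revcomp(s) else s
}

#' Simulate isoforms for a synthetic genome
#'
#' Draws per-locus isoform counts and generates distinct isoforms by
#' alternative splicing (exon skip, alternative donor/acceptor),
#' alternative polyadenylation and alternative TSS, plus one readthrough
#' isoform per polycistronic cluster.  Assigns per-isoform expected read
#' counts with geometric tiers inside polycistronic clusters.
#'
#' @param gen an `lf_genome` from [simulate_genome()].
#' @param config the same [sim_config()] used for the genome.
#' @return a list of class `lf_isoforms`: `isoforms` (data.frame with
#'   genomic span, poly(A) site and class, abundance), `exons` (named list
#'   of exon matrices), `sequences` (named character vector of spliced
#'   transcript-sense sequences) and `skipped_events` (log of alternative
#'   events that did not fit their locus).
#' @export
simulate_isoforms <- function(gen, config = gen$config) {
  stopifnot(inherits(gen, "lf_genome"))
  cfg <- config
  with_rng(cfg$seed + 1L, {
    genes <- gen$genes
    iso <- list(); exon_l <- list(); skipped <- character(0)
    iid <- 0L

    gene_introns <- function(gene_id) {
      gi <- gen$introns[gen$introns$gene_id == gene_id, c("start", "end"),
                        drop = FALSE]
      as.matrix(gi[order(gi$start), , drop = FALSE])
    }

    add_iso <- function(gene_row, span, introns, pas_pos, pas_class, kind,
                        gene_ids, is_ptu = FALSE, abundance) {
      iid <<- iid + 1L
      iso_id <- sprintf("iso%04d", iid)
      ex <- exons_from_introns(span[1], span[2], introns)
      exon_l[[iso_id]] <<- ex
      iso[[iid]] <<- data.frame(
        iso_id = iso_id, gene_ids = paste(gene_ids, collapse = ","),
        chrom = "chr1", strand = gene_row$strand,
        span_start = span[1], span_end = span[2],
        pas_pos = pas_pos, pas_class = pas_class, kind = kind,
        is_ptu = is_ptu, abundance = abundance, stringsAsFactors = FALSE)
      iso_id
    }

    for (r in seq_len(nrow(genes))) {
      g <- genes[r, ]
      introns <- gene_introns(g$gene_id)
      plus <- g$strand == "+"
      span_canon <- if (plus) c(g$tss, g$pas) else c(g$pas, g$tss)
      tier_ab <- cfg$fl_coverage_per_isoform *
        cfg$downstream_tier_factor^(g$ptu_tier - 1L)
      pas_class <- if (!is.na(g$ptu_id) && g$internal_ptu)
        "pORF1-internal" else "nORF"
      add_iso(g, sort(span_canon), introns, g$pas, pas_class, "canonical",
              g$gene_id, abundance = tier_ab)

      ## readthrough-cluster members keep a single canonical isoform so
      ## their independent expression reflects the tier structure alone;
      ## isoform diversity is simulated at the independent loci
      if (!is.na(g$ptu_id)) next

      ## feasible alternative events by type (each usable once)
      n_int <- nrow(introns)
      ilens <- if (n_int) introns[, 2] - introns[, 1] + 1L else integer(0)
      avail <- list(
        exon_skip = if (n_int >= 2L) seq_len(n_int - 1L) else integer(0),
        alt_donor = which(ilens >= 110L),
        alt_acceptor = which(ilens >= 110L),
        apa = 1L, alt_tss = 1L)

      n_extra <- rpois(1L, cfg$isoform_lambda)
      picked <- list()
      while (length(picked) < n_extra) {
        types <- names(avail)[lengths(avail) > 0L]
        if (!length(types)) break
        w <- cfg$as_event_probs[types]
        ty <- sample(types, 1L, prob = w)
        j <- resample(avail[[ty]], 1L)
        avail[[ty]] <- setdiff(avail[[ty]], j)
        picked[[length(picked) + 1L]] <- list(type = ty, j = j)
      }
      if (length(picked)) {
        for (ev in picked) {
          span <- sort(span_canon)
          ivs <- introns
          pas_pos <- g$pas
          cls <- pas_class
          if (ev$type == "exon_skip") {
            ## splice from donor of intron j through acceptor of intron j+1
            ivs <- introns
            ivs[ev$j, 2] <- introns[ev$j + 1L, 2]
            ivs <- ivs[-(ev$j + 1L), , drop = FALSE]
          } else if (ev$type == "alt_donor") {
            ## donor side = transcript-5' end of the intron
            if (plus) ivs[ev$j, 1] <- ivs[ev$j, 1] + 48L
            else ivs[ev$j, 2] <- ivs[ev$j, 2] - 48L
          } else if (ev$type == "alt_acceptor") {
            if (plus) ivs[ev$j, 2] <- ivs[ev$j, 2] - 48L
            else ivs[ev$j, 1] <- ivs[ev$j, 1] + 48L
          } else if (ev$type == "apa") {
            pas_pos <- g$pas_alt
            span <- if (plus) c(span[1], g$pas_alt) else c(g$pas_alt, span[2])
            span <- sort(span)
          } else if (ev$type == "alt_tss") {
            span <- if (plus) c(g$tss_alt, span[2]) else c(span[1], g$tss_alt)
            span <- sort(span)
          }
          add_iso(g, span, ivs, pas_pos, cls, ev$type, g$gene_id,
                  abundance = tier_ab)
        }
      }
    }

    ## readthrough isoforms, one per polycistronic cluster
    if (nrow(gen$ptus)) {
      for (p in seq_len(nrow(gen$ptus))) {
        gids <- strsplit(gen$ptus$genes[p], ",")[[1]]
        sub <- genes[match(gids, genes$gene_id), ]
        plus <- sub$strand[1] == "+"
        first <- sub[which(sub$ptu_tier == 1L), ]
        last <- sub[which.max(sub$ptu_tier), ]
        span <- sort(c(first$tss, last$pas_rt))
        ivs <- do.call(rbind, lapply(gids, gene_introns))
        g1 <- first
        add_iso(g1, span, ivs, last$pas_rt, "pORF2-terminal", "readthrough",
                gids, is_ptu = TRUE,
                abundance = cfg$fl_coverage_per_isoform *
                  cfg$ptu_abundance_factor)
      }
    }

    iso <- do.call(rbind, iso)
    seqs <- vapply(iso$iso_id, function(id) {
      row <- iso[iso$iso_id == id, ]
      extract_transcript(gen$genome, row$chrom, exon_l[[id]], row$strand)
    }, "")
    structure(list(isoforms = iso, exons = exon_l, sequences = seqs,
                   skipped_events = skipped, genome = gen, config = cfg),
              class = "lf_isoforms")
  })
}

## ---------------------------------------------------------------------------
## reads
## ---------------------------------------------------------------------------

## apply the iid per-base error model; returns the corrupted sequence
mutate_seq <- function(s, sub, ins, del) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(s)
  u <- runif(n)
  keep <- u >= del
  do_sub <- keep & (u < del + sub)
  if (any(do_sub)) {
    chars[do_sub] <- vapply(chars[do_sub],
                            function(b) sample(setdiff(BASES, b), 1L), "")
  }
  out <- chars
  out[!keep] <- ""
  ## insertions: before each base with prob ins
  nins <- runif(n) < ins
  if (any(nins)) {
    insb <- sample(BASES, sum(nins), replace = TRUE)
    out[nins] <- paste0(insb, out[nins])
  }
  paste(out, collapse = "")
}

#' Simulate long reads from isoforms
#'
#' Emits full-length reads (`primer5 + transcript + polyA +
#' revcomp(primer3)`) and 5'-truncated non-full-length reads (missing the
#' 5' primer and a random 5' portion of the transcript), each on a random
#' strand, corrupted by the configured indel-dominant error model.
#' Per-isoform read counts are the rounded expected abundances, so the
#' library composition is fully determined by the configuration.
#'
#' @param isos an `lf_isoforms` object.
#' @param config the simulation configuration.
#' @return list of class `lf_reads`: `sequences` (named character vector),
#'   `qualities` (named character vector of Phred+33 strings), `manifest`
#'   (data.frame: read_id, iso_id, is_full_length, truncation, strand).
#' @export
simulate_reads <- function(isos, config = isos$config) {
  stopifnot(inherits(isos, "lf_isoforms"))
  cfg <- config
  with_rng(cfg$seed + 2L, {
    iso <- isos$isoforms
    if (nrow(iso) == 0L) {
      warning("empty isoform set: emitting no reads")
      return(structure(list(sequences = character(0),
                            qualities = character(0),
                            manifest = data.frame()), class = "lf_reads"))
    }
    er <- cfg$error_rates
    total_err <- sum(er)
    q <- if (total_err <= 0) 40L else
      max(2L, min(40L, as.integer(round(-10 * log10(total_err)))))
    qchar <- rawToChar(as.raw(q + 33L))
    p3rc <- revcomp(cfg$primer3)

    seqs <- character(0); quals <- character(0); man <- list()
    rid <- 0L
    for (i in seq_len(nrow(iso))) {
      tx <- isos$sequences[[iso$iso_id[i]]]
      n_fl <- round(iso$abundance[i])
      n_nfl <- if (cfg$nonfl_fraction > 0)
        round(n_fl * cfg$nonfl_fraction / (1 - cfg$nonfl_fraction)) else 0L
      for (j in seq_len(n_fl + n_nfl)) {
        is_fl <- j <= n_fl
        tail_len <- runif_int(1L, cfg$polyA_len_range)
        trunc <- 0L
        if (is_fl) {
          insert <- paste0(cfg$primer5, tx, strrep("A", tail_len), p3rc)
        } else {
          trunc <- as.integer(floor(nchar(tx) * runif(1L, 0.1, 0.5)))
          insert <- paste0(substring(tx, trunc + 1L),
                           strrep("A", tail_len), p3rc)
        }
        read <- mutate_seq(insert, er[["sub"]], er[["ins"]], er[["del"]])
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") read <- revcomp(read)
        rid <- rid + 1L
        read_id <- sprintf("r%05d", rid)
        seqs[read_id] <- read
        quals[read_id] <- strrep(qchar, nchar(read))
        man[[rid]] <- data.frame(read_id = read_id, iso_id = iso$iso_id[i],
                                 is_full_length = is_fl, truncation = trunc,
                                 strand = strand, stringsAsFactors = FALSE)
      }
    }
    structure(list(sequences = seqs, qualities = quals,
                   manifest = do.call(rbind, man), config = cfg),
              class = "lf_reads")
  })
}

#' Simulate short-read support tables
#'
#' Per-base genomic coverage is the abundance-weighted sum over isoform
#' exons times `shortread_scale`, optionally with Poisson noise; junction
#' support is proportional to the abundance of isoforms using each exact
#' junction.
#'
#' @param isos an `lf_isoforms` object.
#' @param config the simulation configuration.
#' @return list with `coverage` (data.frame chrom, pos, cov) and
#'   `junctions` (data.frame chrom, donor, acceptor, strand, support).
#' @export
simulate_short_read_support <- function(isos, config = isos$config) {
  stopifnot(inherits(isos, "lf_isoforms"))
  cfg <- config
  with_rng(cfg$seed + 3L, {
    glen <- nchar(isos$genome$genome[["chr1"]])
    cov <- numeric(glen)
    junc <- list()
    iso <- isos$isoforms
    for (i in seq_len(nrow(iso))) {
      ex <- isos$exons[[iso$iso_id[i]]]
      ab <- iso$abundance[i] * cfg$shortread_scale
      for (e in seq_len(nrow(ex)))
        cov[ex[e, 1]:ex[e, 2]] <- cov[ex[e, 1]:ex[e, 2]] + ab
      if (nrow(ex) > 1L) {
        for (e in seq_len(nrow(ex) - 1L)) {
          key <- paste0(ex[e, 2] + 1L, ":", ex[e + 1L, 1] - 1L, ":",
                        iso$strand[i])
          junc[[key]] <- (if (is.null(junc[[key]])) 0 else junc[[key]]) + ab
        }
      }
    }
    if (cfg$shortread_noise) cov <- rpois(glen, cov)
    idx <- which(cov > 0)
    coverage <- data.frame(chrom = "chr1", pos = idx, cov = cov[idx])
    if (length(junc)) {
      parts <- strsplit(names(junc), ":", fixed = TRUE)
      support <- unlist(junc, use.names = FALSE)
      if (cfg$shortread_noise) support <- rpois(length(support), support)
      junctions <- data.frame(
        chrom = "chr1",
        donor = as.integer(vapply(parts, `[`, "", 1L)),
        acceptor = as.integer(vapply(parts, `[`, "", 2L)),
        strand = vapply(parts, `[`, "", 3L),
        support = support, stringsAsFactors = FALSE)
      junctions <- junctions[order(junctions$donor, junctions$acceptor), ]
      rownames(junctions) <- NULL
    } else {
      junctions <- data.frame(chrom = character(0), donor = integer(0),
                              acceptor = integer(0), strand = character(0),
                              support = numeric(0))
    }
    list(coverage = coverage, junctions = junctions)
  })
}

#' Run the full simulator
#'
#' Convenience wrapper: genome, isoforms, reads and short-read support in
#' one seeded call.
#'
#' @param config a [sim_config()].
#' @return list of class `lf_sim` with elements `genome` (`lf_genome`),
#'   `isoforms`, `reads`, `support` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  isos <- simulate_isoforms(gen, config)
  reads <- simulate_reads(isos, config)
  support <- simulate_short_read_support(isos, config)
  structure(list(genome = gen, isoforms = isos, reads = reads,
                 support = support, config = config), class = "lf_sim")
}

#' Write simulator outputs to a directory
#'
#' Emits genome FASTA, annotation GFF3 (gene/mRNA/exon records, 1-based
#' inclusive), reads FASTQ, ground-truth manifest JSON and the short-read
#' coverage/junction TSV tables.  Outputs are byte-identical for a fixed
#' configuration.
#'
#' @param sim an `lf_sim` object.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
sim_write <- function(sim, outdir) {
  stopifnot(inherits(sim, "lf_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  f_genome <- file.path(outdir, "genome.fasta")
  f_gff <- file.path(outdir, "annotation.gff3")
  f_fq <- file.path(outdir, "reads.fastq")
  f_man <- file.path(outdir, "manifest.json")
  f_cov <- file.path(outdir, "coverage.tsv")
  f_jun <- file.path(outdir, "junctions.tsv")

  gseq <- Biostrings::DNAStringSet(sim$genome$genome)
  Biostrings::writeXStringSet(gseq, f_genome)

  write_gff3(sim_annotation_granges(sim), f_gff)

  sq <- Biostrings::DNAStringSet(sim$reads$sequences)
  qual <- Biostrings::BStringSet(sim$reads$qualities)
  Biostrings::writeXStringSet(sq, f_fq, format = "fastq", qualities = qual)

  man <- list(genes = sim$genome$genes,
              ptus = sim$genome$ptus,
              tandem_pairs = sim$genome$tandem_pairs,
              isoforms = sim$isoforms$isoforms,
              exons = lapply(sim$isoforms$exons, function(m)
                data.frame(start = m[, 1], end = m[, 2])),
              reads = sim$reads$manifest)
  jsonlite::write_json(man, f_man, dataframe = "columns", digits = NA)

  write.table(sim$support$coverage, f_cov, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$support$junctions, f_jun, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(f_genome, f_gff, f_fq, f_man, f_cov, f_jun))
}

#' Annotation of a simulated genome as GRanges
#'
#' @param sim an `lf_sim` or `lf_genome` object.
#' @return a [GenomicRanges::GRanges] with `type` gene/mRNA/exon metadata
#'   suitable for GFF3 export.
#' @export
sim_annotation_granges <- function(sim) {
  gen <- if (inherits(sim, "lf_sim")) sim$genome else sim
  genes <- gen$genes
  rows <- list()
  for (r in seq_len(nrow(genes))) {
    g <- genes[r, ]
    gi <- gen$introns[gen$introns$gene_id == g$gene_id, , drop = FALSE]
    ex <- exons_from_introns(g$start, g$end,
                             as.matrix(gi[, c("start", "end"), drop = FALSE]))
    rows[[r]] <- data.frame(
      start = c(g$start, g$start, ex[, 1]),
      end = c(g$end, g$end, ex[, 2]),
      type = c("gene", "mRNA", rep("exon", nrow(ex))),
      ID = c(g$gene_id, paste0(g$gene_id, ".t1"),
             paste0(g$gene_id, ".t1.exon", seq_len(nrow(ex)))),
      Parent = c(NA, g$gene_id, rep(paste0(g$gene_id, ".t1"), nrow(ex))),
      strand = g$strand, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  gr
}

#' Simulate related species for conservation analysis
#'
#' For each simulated species, emits a proteome (per-gene translated CDS
#' with per-species amino-acid divergence) and a gene-order table; a known
#' subset of the source genome's adjacent polycistronic gene pairs is left
#' intact while the rest are broken by relocating the downstream gene.
#'
#' @param sim an `lf_sim` object.
#' @param n_species number of species to generate.
#' @param keep_fraction per-species fraction of polycistronic adjacent
#'   pairs whose configuration is conserved.
#' @param aa_divergence per-species amino-acid substitution rate.
#' @param seed RNG seed.
#' @return list with `species` (named list of `proteins` (named character
#'   vector) and `gene_order` data.frame) and `truth` (data.frame pair x
#'   species conserved flags).
#' @export
simulate_species_set <- function(sim, n_species = 3L, keep_fraction = 0.5,
                                 aa_divergence = 0.15, seed = 1L) {
  stopifnot(inherits(sim, "lf_sim"))
  gen <- sim$genome
  with_rng(seed, {
    genes <- gen$genes[order(gen$genes$start), ]
    prots <- vapply(genes$gene_id, function(id)
      translate_cds(gen, id), "")
    ## adjacent same-strand pairs inside polycistronic clusters
    pairs <- list()
    if (nrow(gen$ptus)) {
      for (p in seq_len(nrow(gen$ptus))) {
        gids <- strsplit(gen$ptus$genes[p], ",")[[1]]
        for (m in seq_len(length(gids) - 1L))
          pairs[[length(pairs) + 1L]] <- c(gids[m], gids[m + 1L])
      }
    }
    if (!length(pairs)) stop("no polycistronic gene pairs in this simulation")
    pair_df <- data.frame(gene_a = vapply(pairs, `[`, "", 1L),
                          gene_b = vapply(pairs, `[`, "", 2L),
                          stringsAsFactors = FALSE)

    species <- list(); truth <- list()
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (s in seq_len(n_species)) {
      sp <- sprintf("sp%02d", s)
      keep <- runif(nrow(pair_df)) < keep_fraction
      ## species proteome: diverged copies, same ids prefixed
      sp_prot <- vapply(prots, function(p) {
        ch <- strsplit(p, "")[[1]]
        hit <- which(runif(length(ch)) < aa_divergence)
        if (length(hit))
          ch[hit] <- vapply(ch[hit], function(a)
            sample(setdiff(aas, a), 1L), "")
        paste(ch, collapse = "")
      }, "")
      names(sp_prot) <- paste0(sp, "_", genes$gene_id)
      ## gene order: genomic order; each broken pair has gene_b relocated
      ## to its own contig (so chained breaks cannot re-create adjacency)
      ord <- genes$gene_id
      moved <- pair_df$gene_b[!keep]
      ord <- c(setdiff(ord, moved), moved)
      ctg <- rep("ctg1", length(ord))
      ctg[ord %in% moved] <- paste0("ctgX", match(ord[ord %in% moved], moved))
      go <- data.frame(contig = ctg,
                       rank = NA_integer_,
                       gene_id = paste0(sp, "_", ord),
                       strand = genes$strand[match(ord, genes$gene_id)],
                       stringsAsFactors = FALSE)
      go$rank <- stats::ave(seq_len(nrow(go)), go$contig, FUN = seq_along)
      species[[sp]] <- list(proteins = sp_prot, gene_order = go)
      truth[[sp]] <- keep
    }
    truth_df <- cbind(pair_df, as.data.frame(truth))
    list(species = species, pairs = pair_df, truth = truth_df,
         source_proteins = prots)
  })
}

## translate the canonical CDS of a gene (transcript-sense)
translate_cds <- function(gen, gene_id) {
  g <- gen$genes[gen$genes$gene_id == gene_id, ]
  gi <- gen$introns[gen$introns$gene_id == gene_id, c("start", "end"),
                    drop = FALSE]
  ex <- exons_from_introns(g$start, g$end, as.matrix(gi))
  tx <- extract_transcript(gen$genome, g$chrom, ex, g$strand)
  tpl <- gen$templates[[gene_id]]
  cds <- substring(tx, tpl$u5 + 1L, tpl$u5 + tpl$cds_len - 3L) # strip stop
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}
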