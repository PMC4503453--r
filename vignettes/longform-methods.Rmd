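---
title: "Methods: reference-optional long-read isoform discovery and polycistronic transcript analysis"
author: "longform authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read isoform discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`longform` implements a full-length-cDNA long-read analysis pipeline for
transcript isoform discovery that does not require a reference genome,
together with the downstream analyses that such data enables in compact
fungal genomes: calling polycistronic transcription units (PTUs) —
single mRNAs that completely contain two to four independently annotated
same-strand ORFs — profiling the sequence composition upstream of
poly(A) sites (the A-rich near upstream element, NUE, and the U-rich far
upstream element, FUE), scoring transcript sets against one another by
exact splice-chain matching, and testing whether adjacent PTU gene pairs
have conserved configurations in other annotated genomes.  A seeded
synthetic-data generator produces a toy genome, transcriptome, long-read
library and short-read support tables with a complete ground-truth
manifest, so every stage is testable end to end on a desk machine.

# The pipeline

## Stage 1 — full-length read classification

A read of insert is *full length* when it contains the 5' cDNA primer at
its 5' end, a polyA tail, and the 3' cDNA primer (as its reverse
complement) at its 3' end.  Primers are located by semi-global edit
distance within `end_window` (default 100 nt) of the read ends.  The
edit budget is `max_edit_fraction` (default 0.3) of the primer length;
when per-base qualities are available the budget shrinks with the
read's own expected error rate (`min(0.3, 3e + 0.08)`), so a clean
library is classified exactly while a 15%-error library keeps the full
budget.  Reads are tried in both orientations; the orientation with the
lower summed primer edit distance wins, ties preferring the input
orientation.

The polyA tail is the longest trailing segment whose overall A fraction
is at least `min_A_fraction` (default 0.8) and whose trimmed-to-A length
is at least `min_len` (default 15 nt), with up to 5 non-A bases
tolerated at the extreme 3' end (indel jitter at the primer boundary).
When a transcript's own 3' end is A-rich the cleavage boundary is
intrinsically ambiguous and the scan may include a few genomic A's; the
downstream stages absorb this (the collapse tolerance and the end slack
of splice-chain matching are both larger).

An additional primer occurrence away from both read ends marks the read
as a chimeric artifact and it is discarded, not split.  The internal hit
uses a stricter edit fraction (default 0.15) than the end hits: a loose
internal threshold produces spurious chimera calls on high-error reads.

## Stage 2 — isoform clustering

Full-length reads are clustered with an iterative isoform-clustering
strategy: a similarity graph over reads, a greedy maximal-clique cover
as the initial partition, a partial-order-alignment consensus per
cluster, and likelihood-based reassignment.

Two reads are *same-isoform* when an overlap alignment (affine gaps:
match +1, mismatch -2, gap open -3, gap extend -1; banded around the
modal shared-k-mer diagonal) reaches both 3' ends within `tol3` (30 nt),
has a free 5' overhang on at most one read (5' degradation), covers at
least 90% of the shorter read, contains no internal gap run longer than
20 nt (the signature of a skipped exon), and attains both a global
identity floor and a 50-nt sliding-window local identity floor.  The
global floor derives from the library error rate, `max(0.70, 1 - 3e -
0.03)`: 0.70 for 15%-error raw reads, about 0.91 for a 2% library.  The
local floor (`min_ident - 0.2`, at least 0.45) exists because two
unrelated blocks of ~50 nt — e.g. the alternative-donor block of one
variant against the alternative-acceptor block of another — reach ~55%
identity under gapped alignment by chance while barely denting global
identity; a windowed floor separates such variant pairs.

Candidate pairs come from a shared-k-mer prefilter (15-mers, seeded by
content hash so seeding is invariant to 5' truncation, at least 3
shared seeds).  On error-free data the prefilter admits a superset of
the true edges; the package's tests assert edge-set equality with the
brute-force all-pairs evaluation on instances of up to ~200 reads at 2%
error.  At 15% error 15-mer survival is ~9% per read, so the prefilter
(and the graph itself) is designed for polished-equivalent error levels;
raw 15% reads are handled by classification and by consensus polishing,
not by direct read-to-read clustering.

The initial partition is a deterministic greedy maximal-clique cover:
seed with the highest-degree unassigned node (degree taken in the full
graph, ties by lexicographic id), grow by the unassigned neighbour
adjacent to all current members with the highest degree, repeat.
Determinism of the full pipeline under read-order permutation follows
from these stated tie-breaks (and is asserted in the tests).

The cluster consensus threads members into a partial-order graph in
decreasing length order (reads aligned to the graph semi-globally, so a
5'-truncated member aligns into the graph's interior).  Matching bases
accumulate the read's quality-derived correctness weight on the shared
node; mismatches and insertions open low-weight branches.  The consensus
is the heaviest path by *edge* weight — read bundles — not node weight:
a node-weight criterion would happily detour through every single-read
insertion branch, because any extra node adds positive weight, and the
consensus would inflate by roughly the per-read insertion rate.
Weakly supported dangling ends (below a quarter of the median path
support) are trimmed.

Reassignment scores each read against the consensus of its candidate
clusters — the clusters containing one of its graph neighbours, plus
its own; a read has no plausible home in a cluster it shares no edge
with, and this keeps the sweep linear rather than quadratic.  The score
is an alignment log-likelihood with the read's error rate `e`:
matches contribute `log(1-e)`, mismatches `log(e/3)`, gap columns and
unaligned read bases `log(e)`.  Ties keep the current cluster.  Sweeps
iterate (in sorted read order) until no read moves, at most `max_iter =
10` times.

## Stage 3 — polishing and the expected-error filter

Non-full-length reads are recruited to the cluster whose consensus they
align to over at least 95% of their own length with a 3' end within
`tol3`, best likelihood winning.  The consensus is then recomputed and
every member is realigned to it, giving a per-column weighted profile of
base and deletion observations.  The polished consensus is the
column-wise weighted plurality; the cluster's *predicted error count* is
the sum over columns of the posterior probability that the plurality
call is wrong, computed from the weight margin between the plurality and
the rest under a symmetric error model (`logistic(-margin *
log(3(1-e)/e))` per column).  A 50/50 split contributes exactly 0.5; a
deeply supported column contributes ~0.  Clusters predicted to contain
more than 10 errors are discarded, reproducing the published filter.
In practice this discards singleton and two-read clusters from raw
high-error data (a 600-nt two-read cluster at 2% error has ~24 tied
columns, i.e. ~12 expected errors) while keeping anything with three or
more consistent members.

The signal-level polisher used with real instrument data is out of
scope here; the quality-weighted column consensus above preserves its
contract (polish, then discard predicted-error > 10) at desk scale.

## Mapping, acceptance filter and collapse

Consensus transcripts are spliced-aligned to the genome by anchoring
genome-unique 15-mers, chaining collinear anchor runs, closing small
gaps by direct alignment, and calling genomic gaps of at least 40 nt as
introns.  Intron boundaries may shift within ±8 anchored bases:
candidate donor/acceptor positions are enumerated by their canonical
dinucleotides (GT..AG, CT..AC on the minus strand) with the intron
length free to differ from the anchor-implied length by up to 12 nt
(indels in the unanchored gap distort the implied length), and the
leftover transcript bases are scored by a small gapped alignment
against the concatenated exonic flanks.  Read ends beyond the outermost
anchors are aligned gapped as well (clipped beyond 40 nt).  Coverage
and identity are computed from one banded alignment of the whole
transcript against the spliced sequence of the called chain.
Alignments are accepted when query coverage is at least 0.99 and
identity at least 0.85 (boundary inclusive), the thresholds used
throughout.  External alignments in BED12 may substitute for the
built-in aligner.

Accepted transcripts collapse into the non-redundant final set:
transcripts with identical junction chains whose 3' ends agree within
`tol3p = 30` nt are grouped and only the longest aligned span survives
(single-exon transcripts group by strand, 3' agreement and containment).
The 30-nt tolerance absorbs polyA-trimming jitter while keeping
alternative-polyadenylation isoforms (3' ends differing by more than
30 nt) separate; alternative-TSS isoforms are deliberately lost, and the
merge audit records every absorbed id so TSS diversity remains
auditable.

## Downstream analyses

**ORFs and PTU calls.**  ORFs are complete forward-frame ATG-to-stop
spans of at least 100 amino acids, selected greedily by descending
length into a non-overlapping set.  A transcript with two or more such
ORFs is a polycistronic candidate; annotated same-strand genes fully
contained in its aligned span categorise it (`contained_2_4` for 2–4
contained genes — the PTU definition used for precision/recall —
`readthrough_partial` for mere overlap).  Every inter-ORF gap is checked
for stop codons in all three frames, ruling out a misannotated single
ORF.  Short-read validation demands per-base coverage of at least 10
over every inter-ORF base and support of at least 1 for every junction;
"minimum of 10 mapped bases" is interpreted as per-base depth (the
alternative reading, minimum aligned bases per read, is noted as an
open interpretation).

**Expression tiers.**  The independent expression of the k-th ORF of a
PTU is the summed full-length read count of monocistronic transcripts
overlapping that gene on the same strand, excluding polycistronic
calls themselves.

**Enrichment.**  Tandem-duplicate enrichment among PTU genes is an
upper-tail hypergeometric test (`stats::phyper`, log-space); its test
oracle is an exact combinatorial summation.

**Poly(A) profiles.**  The terminal site of every transcript is its
last aligned base.  Sites class as `pORF2` (termini of polycistronic
transcripts), `pORF1` (termini of independent transcripts at
upstream/internal PTU loci — attributed internal sites) or `nORF` (all
other monocistronic termini; this includes transcripts of the
*terminal* PTU gene, whose site is a signal-bearing terminal site).
Profiles sample up to 200 sites per class without replacement (seeded)
and tabulate per-position base frequencies over the 100 nt upstream of
and including the cleavage position.  NUE presence is a 6-nt sliding
window of mean A frequency over positions -35..-5 reaching the 0.25
baseline + 0.15; FUE likewise for U over -70..-25.  These windows are
declared defaults; the published figure does not state numeric spans,
so acceptance rests on class contrasts only.

**Evaluation.**  Two transcripts match exactly when they share
chromosome, strand, exon count and the ordered donor-acceptor list;
terminal exon outer boundaries are not compared.  Single-exon
transcripts match by 50% reciprocal overlap (declared rule).  Scoring
restricts to loci detected in both sets (loci = transitive closure of
same-strand exon overlap over the union), reports sensitivity (reference
transcripts recovered) and specificity (query transcripts validated),
stratifies by reference isoforms per locus, and can tabulate how many of
several query sets recover each reference transcript.

**Conservation.**  Best protein hits use local alignment with BLOSUM62
and affine gaps 11/1 (one-way by default, reciprocal as an option — the
published description names one-way best hits).  A gene pair is
conserved in a species when both best hits exist, sit on consecutive
ranks of the same contig in that species' gene order, and share strand.

# The synthetic-data generator

The generator is first-class, fully seeded code (`sim_config()`,
`simulate_dataset()`); a fixed configuration reproduces byte-identical
FASTA/GFF3/FASTQ/JSON/TSV outputs.

What it emulates, and the defaults:

* **Genes.**  60 primary genes on one contig; CDS of 120–300 aa
  (bracketing the reported ~256/277-aa ORF sizes); 1–4 exons with
  GT..AG introns of 120–200 nt placed in the CDS interior; UTRs of
  30–60 / 70–120 nt.  Strands are random per locus block.
* **Readthrough clusters.**  55% of genes sit in clusters of 2–4
  adjacent same-strand genes (11 clusters at the default size — the
  desk-scale study condition; the genome-wide share reported for real
  data is far smaller).  The transcript-level inter-ORF distance is
  drawn around 364 nt.  A 12-mer with a stop codon in each frame
  (`TAGATAGATAGA`) is planted in every inter-ORF gap, so the
  all-frames stop property holds by construction.  The readthrough
  transcript of a cluster terminates in a dedicated zone downstream of
  the terminal gene's own sites: readthrough 3' ends are distinct from
  monocistronic 3' ends, which is also what keeps a full-length
  transcript of the last gene distinguishable from a 5'-degraded
  readthrough read.
* **Isoforms.**  Non-cluster loci draw `1 + Poisson(2.5)` isoforms;
  alternative events are exon skips, 48-nt alternative donors and
  acceptors (planted GT/AG sites; 48 nt keeps frame and is wide enough
  for the clustering rules to separate the variants), alternative
  polyadenylation (an 80–140-nt extension with its own signal-bearing
  site) and alternative TSS.  Cluster member genes keep a single
  canonical isoform so that their independent expression reflects the
  tier structure alone.
* **Poly(A) signals.**  Terminal sites get a U-rich FUE (-60..-30,
  per-base T probability 0.65) and an A-rich NUE (-30..-10, per-base A
  probability 0.6); internal (upstream-ORF) sites get neither.  Every
  site ends in a 12-nt A-poor, pyrimidine-biased cleavage context, as
  at real sites; this is also what lets the polyA scan stop at the true
  tail instead of walking into the NUE.
* **Expression.**  20 full-length reads per isoform; gene k of a
  cluster is scaled by `0.5^(k-1)`; the readthrough isoform by 0.5.
  Read counts are the *rounded expected* abundances rather than Poisson
  draws: the per-unit tier comparison (ORF1 > ORF2 in every unit) is a
  stated property of the study conditions, and at depth 20 a Poisson
  draw would flip it in ~3% of units by chance.  The sampling law is
  otherwise unspecified, and abundances are configurable.
* **Reads.**  Full-length reads are
  `primer5 + transcript + polyA(15–40) + revcomp(primer3)` on a random
  strand; 30% of reads are 5'-truncated (missing the 5' primer and
  10–50% of the transcript).  Errors are i.i.d. per base, defaults
  sub/ins/del = 0.01/0.09/0.05 (total 0.15, indel-dominant); qualities
  are flat at the Phred equivalent of the total rate.
* **Tandem duplicates.**  5% of singleton genes get an adjacent
  same-strand near-copy, and 90% of readthrough clusters contain one
  adjacent duplicated member pair, at 12% nucleotide divergence —
  "near copies" whose proteins align at high identity, yet far enough
  apart that 2%-error reads from distinct copies fall below the
  clustering identity floor (0.91) while same-isoform read pairs
  (~0.96) stay above it.  Concentrating duplication inside the
  readthrough clusters gives the toy genome a qualitative
  tandem-duplicate enrichment among polycistronic genes; the magnitude
  of the hypergeometric p-value at 60 genes is orders weaker than what
  genome-scale counts produce, so it is reported descriptively, not
  asserted.
* **Short-read support.**  Emitted as per-base genomic coverage and
  junction-support tables (abundance-weighted sums, scale 3, Poisson
  noise), not as raw short reads: the pipeline consumes evidence
  tables, and short-read assembly is out of scope.
* **Related species.**  `simulate_species_set()` emits diverged
  proteomes and gene-order tables in which a known subset of adjacent
  cluster pairs is kept and the rest broken, for exercising the
  conservation module against a planted truth.

What the generator does **not** emulate: instrument-specific error
profiles and quality calibration, transcript-length biased sampling,
sequence-composition biases, genome repeats beyond the planted tandem
duplicates, incomplete or wrong annotations, and expression noise
beyond the configured tiers.  Passing the seeded tests therefore shows
that the algorithms implement their contracts on data with the stated
structure — not that real libraries will reach the same accuracies.

# Numerical and design choices

* Internal coordinates are 1-based inclusive (GRanges convention);
  BED12 is written/read 0-based half-open and GFF3 1-based inclusive
  via `rtracklayer`.
* All alignment work is a single banded affine-gap kernel (C++), band
  centred on the modal shared-k-mer diagonal (half-width
  `max(64, 0.08·len + 32)`, 48 for clustering); at 2–15% indel error
  the diagonal drift is a random walk with standard deviation well
  inside the band for the transcript lengths simulated.
* Degenerate inputs: empty sequences are never "same isoform"; an
  empty isoform set yields an empty, warned read set; inter-ORF gaps
  shorter than 3 nt are flagged degenerate and fail the stop check;
  profile windows that would run off a contig edge are skipped and
  counted; infeasible generator geometry (CDS below the ORF filter,
  3' UTR too short for the signal windows, cluster span outside 2–4)
  fails with the violated constraint named.
* Ties are broken deterministically everywhere (lexicographic ids,
  leftmost coordinates, input orientation), which is what makes
  byte-identical re-runs and read-order invariance hold.
* Problem sizes in the tests and the acceptance script (a 60-gene
  default simulation, smaller module fixtures) were chosen so the whole
  suite exercises every stage, including two full pipeline runs, in a
  few minutes on one CPU.

# Known limitations

* The read-to-read similarity graph targets polished-equivalent error
  levels; at 15% raw error the k-mer prefilter loses sensitivity, so
  clustering raw reads directly would need a different seeding scheme
  (e.g. spaced seeds).
* A full-length transcript that is an exact 3'-suffix of a longer
  isoform with the same terminus is indistinguishable from a
  5'-degraded read of that isoform by the stated rules; the simulator's
  distinct readthrough termini reflect the biology (different
  termination zones) but suffix isoforms sharing a terminus would be
  absorbed.
* The polyA boundary is ambiguous when the transcript's 3' end is
  A-rich; trimming may differ from the true cleavage site by a few
  bases, which downstream tolerances absorb.
* `collapse_mapped` loses alternative-TSS isoforms by design (the
  5'-degradation ambiguity of the library protocol); the audit table
  records what merged.
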