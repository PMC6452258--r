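---
title: "Profiling CRISPR spacer repertoires with spacerscope"
author: "spacerscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CRISPR spacer repertoires with spacerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerscope)
```

## The problem

CRISPR arrays record a bacterium's history of encounters with phages and
plasmids as an ordered series of short *spacers* between near-identical
direct repeats. In thermophile communities such as environmental *Thermus*,
spacers can be surveyed without isolating strains: degenerate primers
anchored in the repeat consensus amplify ladders of repeat–spacer units,
which are then sequenced. `spacerscope` implements the computational side
of such a survey end to end:

1. locate degenerate repeat consensi in reads and genomes
   (`scanRepeats()`),
2. extract spacers — sequences of an expected length between two
   same-type repeats — from reads (`extractSpacers()`) and mine whole
   arrays from assembled genomes (`mineGenomeArrays()`),
3. collapse reads into identity clusters per sample and type
   (`clusterSpacers()`, `filterClusters()`), the cluster centre (most
   abundant member) being the unit of comparison,
4. compare repertoires within and across sites (`matchAcross()`,
   `alphaDiversityTable()`, `betaDiversity()`,
   `sharedAbundanceCorrelation()`),
5. rebuild CRISPR array fragments from spacer adjacency in multi-spacer
   reads (`buildAdjacency()`, `assembleFragments()`,
   `compareFragments()`),
6. map spacers onto phage genomes, infer PAMs from protospacer flanks and
   quantify locality and strand bias of targeting
   (`searchProtospacers()`, `buildPam()`, `localityTable()`,
   `strandBias()`).

A ground-truthed simulator (`simulateCommunity()`, `simulatePhages()`,
`simulateReads()`) generates communities, phages and reads with known
provenance, so every stage is tested against planted truth without any
external data. `runPipeline()` chains all stages behind one config.

## The repeat model

A CRISPR type is represented by its repeat consensus — an IUPAC-degenerate
string (e.g. `GTAGTCCCCACRCRYGTGGGGATGGMCSD` for I-E) with the expected
spacer length of that type. The packaged default (`thermusRepeats()`)
carries the six dominant *Thermus* system types (IIIAB, I-E, I-C, I-B,
I-U, I-A) with expected spacer lengths 41/32/38/36/36/36 nt. Matching is
per-position set membership (R matches A or G, and so on); a subject `N`
matches any pattern symbol but is tallied separately, and windows with
more than 2 Ns are flagged. Scanning reports every window on either strand
with at most `max_mismatch` violations; overlapping same-type windows are
resolved greedily to the lower-mismatch, then leftmost one.

**Parameters.** `max_mismatch` (default 3 per repeat window) governs
sensitivity to repeat mutations; the default tolerates the mutation load
seen in terminal repeat copies while keeping random 29–37 nt matches
vanishingly unlikely. The spacer-length band is `expected ± 10` nt,
configurable per type in the repeat TSV. Coordinates are 0-based
half-open in machine-facing tables and 1-based in reports.

## Spacer extraction

A spacer is emitted only for a gap bounded by two full-length, same-type,
same-strand repeat matches whose length lies in the type's band. Reads are
truncated at the first base below Phred 20 (when qualities are present);
spacers containing ambiguous bases are dropped; junctions whose flanking
repeats disagree in type or strand flag the read as a chimera candidate
and emit nothing. Every spacer is stored in the repeat-consensus (+)
orientation, so a read and its reverse complement yield identical spacer
strings, and `index_in_source` orders the spacers of one read in a
consistent array direction — the property array assembly relies on.

One guard deserves a note: an emitted spacer must not contain either
flanking repeat's first or last 8 nt at fewer than two mismatches. This
rejects mis-anchored windows that would smuggle repeat fragments into the
repertoire. Symmetrically, the simulator never plants a spacer containing
such a fragment — a realistic constraint, since a real spacer of that
composition would be systematically unextractable by any repeat-anchored
method (and invisible to the PCR itself).

## Clustering and cross-sample matching

Sequencing and PCR errors inflate apparent diversity, so reads are
collapsed at 85% full-length identity with free end gaps (internal gaps
are not allowed; the identity denominator is the shorter sequence). The
greedy scheme processes unique sequences in decreasing read-count order
(ties broken lexicographically for reproducibility); each joins the first
cluster whose centre it matches, else seeds a new one. Centres are the
most abundant member. Downstream analysis keeps clusters with more than
10 reads (`min_size = 11`), the guard against undersequenced singletons.

Across samples, sites and genomes, two centres are "the same spacer" when
they differ by fewer than two mismatches: Hamming distance at most 1 for
equal lengths; for unequal lengths, the best end-gap-free overlap with at
most 1 mismatch and a total overhang of at most 2 nt (an extension of the
rule, distinguishable in the edge table). Unique spacers are the connected
components of this match graph. Two countings are reported deliberately:
the global component count, and the per-site union (summing each site's
distinct components) — collapsing across sites merges near-identical
variants that per-site counting keeps apart, so the two differ and both
are useful. Pairs of centres of *different* types sharing at least 20 nt
at one mismatch are listed separately as candidates for independent
acquisition from the same locus.

## Diversity statistics

Per sample: Shannon entropy in nats on cluster read counts, the
bias-corrected Chao1 estimate `S_obs + f1(f1-1)/(2(f2+1))`, and Good's
coverage `1 - n1/N` (`n1` singleton clusters, `N` total reads). Both
read-count and unique-sequence tallies are emitted, since amplicon
conventions differ. Shannon and the beta-diversity matrices (Bray-Curtis
on counts; Jaccard on presence/absence) are computed with **vegan**;
Chao1 is the formula above, cross-checked against `vegan::estimateR` in
the test suite. Samples are clustered by UPGMA (average linkage) on the
dissimilarity matrix and exported as Newick via **ape**. Fisher's exact
test (two-sided, probability-mass rule) and the exact binomial test come
from **stats**; the tests verify them against full hypergeometric
enumeration.

Abundances of shared spacers are correlated on log10 counts (cluster
sizes span orders of magnitude), with the linear-scale coefficient also
reported; fewer than 3 shared clusters gives NA.

## Array-fragment assembly

Consecutive spacers of one read become directed adjacency edges between
their clusters; three-spacer reads also yield triples. Edges below
`min_support = 2` reads are pruned — a single-read adjacency is
indistinguishable from a PCR chimera. Fragments are maximal chains of
unambiguous edges (source out-degree 1, target in-degree 1); branch nodes
terminate fragments unless triples pair every in-neighbour with exactly
one out-neighbour, in which case the flanking chains are phased through
the branch. Cycles — possible when an identical spacer recurs — are broken
at the weakest edge and flagged. No probabilistic phasing is attempted:
conservatism favours correctness of reported spacer order.

Fragments are compared by their longest common contiguous spacer block
(centres equated under the fewer-than-two-mismatches rule) and classified
`identical`, `end-trimmed`, `partially-renewed` or `unrelated`. The end at
which both fragments carry their own spacers is labelled the putative
leader-proximal end: leader-end inference is purely comparative (the end
showing turnover), never from sequence context.

## Protospacer mapping and PAM inference

A hit is an ungapped, full-spacer-length match with identity strictly
above 0.85 — for a 32-mer, 28 matches (0.875) pass and 27 (0.844) fail.
The search examines every offset of every target on both strands, so it
is exactly equivalent to brute force; `word_size` (8) survives as the
minimum spacer length admitted. Target Ns count as mismatches. Eight
nucleotides upstream and downstream of each hit are extracted in
protospacer-strand orientation (minus-strand hits take reverse-complement
flanks from the opposite sides); flanks truncated by a contig end are
excluded from PAM counting.

PAM models are per-position counts over the 16 flank positions with
information content `2 + Σ p log2 p` bits; the consensus calls a base at
frequency ≥ 0.75, a two-fold IUPAC code when the top two jointly reach
0.9, else N. At least 5 usable flank pairs are required for a call.

**Strand convention.** The protospacer strand is the strand whose
sequence equals the crRNA spacer. Type III interference requires the
crRNA to pair with the transcript, which happens when the protospacer
lies on the template strand — i.e. when the hit strand is opposite to the
annotated gene strand. `strandBias()` reports, per type, the fraction of
gene-overlapping hits (≥ 50% of hit length within the gene) in that
configuration, with a two-sided exact binomial test against 0.5. This
convention is the package's own and is stated here because conventions in
the literature vary.

Locality is tested per target with a known isolation site: the 2×2 table
(spacer local vs foreign) × (hits the target vs not) under Fisher's exact
test, next to a site-by-target hit-count matrix.

## The simulator: what it emulates, and what it does not

`simulateCommunity()` draws strain lineages per site, each carrying
arrays of 10–35 spacers (the fragment-length range the analysis targets)
with types and spacer lengths from the repeat table. A configurable
fraction of lineages is shared across all sites; shared arrays receive
site-specific spacers prepended at the leader end and lose spacers from
the distal end, mimicking acquisition and decay. Strain abundances are
log-normal: a heavy-tailed site-level component (sdlog 1.5, producing the
singleton tail that Good's coverage and the >10-read filter act on)
modulated by milder per-sample noise (sdlog 0.3), so samples from one
site have correlated repertoire frequencies. `simulatePhages()` plants
community spacers into random phage genomes with per-type PAM motifs
written on the 5′ flank, a toy annotation of alternating-strand 2 kb gene
blocks, an isolation site per phage with a configurable local fraction of
plantings, and optional transcribed-strand-only placement for IIIAB.
`simulateReads()` emits 1–4 repeat–spacer units per read (the
amplification ladder), random orientation, substitution errors at a
uniform rate with a flat Phred model, and full per-read provenance.

The simulator deliberately omits: PCR amplification bias, instrument
quality profiles, indel errors (off by default; the clustering absorbs
substitutions, which dominate on this platform class), phage evolution
and within-strain array heterogeneity. Passing tests therefore show the
*pipeline's* correctness on data with the assumed structure, not that
real communities satisfy those assumptions — e.g. real within-site
Pearson correlations reflect ecology as well as sampling noise.

## Numerical and design choices

- Identity denominator: the shorter sequence (the clustering threshold is
  stated over "the full length of the spacer"; the shorter-length
  denominator is the conservative reading for unequal lengths).
- Tie-breaks are lexicographic everywhere (cluster seeding order, centre
  choice), so results are order-invariant and reproducible.
- "Fewer than two mismatches" is Hamming ≤ 1 for equal lengths; the
  unequal-length extension (overhang ≤ 2) is flagged distinctly in edge
  tables.
- Strict inequality at the 85% identity bound for protospacer hits.
- The protospacer search is exhaustive rather than seeded: with >85%
  identity a 32-mer may carry 4 mismatches, enough to break every exact
  8-mer seed, so a literal word-size-8 seed-and-extend can miss valid
  hits that the definition admits; exhaustive ungapped scanning in
  compiled code is both exact and fast at these scales.
- Assembly resolves branches only through pair+triple evidence;
  min_support 2 kills single-read chimeras.
- Test problem sizes: the bundled tests use communities of 2-8 strains
  across 1-3 sites, 400-9000 reads per sample, arrays of 5-35 spacers
  and targets up to 100 kb; the acceptance run uses three sites, six
  lineages per site (a third shared), arrays of 10-35 spacers and 4000
  reads per sample - sizes at which planted truth is fully determined,
  every stated coverage condition (50x spacer depth, 10x junction
  coverage) is realized, and each check isolates one property.
- Chao1 uses the bias-corrected form (defined at `f2 = 0`); the variant
  is recorded in output metadata.
- Shannon is reported in nats on read counts; unique-sequence tallies are
  emitted alongside for the alternative convention.

## Limitations

- Paired-end mates are treated as independent reads; merging is out of
  scope, and a spacer seen in both mates counts twice (read ids are
  recorded so either convention can be recomputed).
- Leader-end calls are comparative labels, not genomic leader detection;
  cas-operon typing is out of scope (the repeat consensus stands in for
  the system type).
- De novo repeat discovery is not attempted: consensi are always
  user-supplied.
- The assembler reports unambiguous fragments only; it will not scaffold
  across branch nodes lacking triple support, so deeply shared spacers
  fragment the reconstruction rather than risk a wrong order.

## A small worked run

```{r, eval = FALSE}
cfg <- list(
  seed = 11, out_dir = "demo_run",
  simulate = list(
    community = list(sites = 2, samples_per_site = 2,
                     strains_per_site = 3, arrays_per_strain = 1,
                     array_length = c(6, 9), sharing = 0.34),
    phages = list(n_phages = 2, protospacers_per_phage = 12),
    reads = list(reads_per_sample = 600, error_rate = 0.005)))
res <- runPipeline(cfg)
res$sharing$n_components       # unique spacers across sites
res$pams[["I-E"]]              # PAM model with AAG consensus recovered
```

Every table the run writes (`observations.tsv`, `clusters.tsv`,
`sample_stats.tsv`, `sharing.tsv`, `fragments.tsv`, `hits.tsv`,
`pam_consensus.tsv`, the Bray-Curtis matrix and UPGMA Newick tree) is a
plain text file under `out_dir`, together with the serialized config and
its hash, so a run is auditable and exactly repeatable.
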