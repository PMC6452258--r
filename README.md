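# spacerscope

CRISPR arrays are chronological records of a bacterium's encounters with
phages: short **spacers** captured between near-identical direct repeats,
new ones added at the leader end. In hot-spring *Thermus* communities the
spacer repertoire can be surveyed culture-free, by amplifying
repeat–spacer ladders with degenerate primers anchored in the repeat
consensus of each CRISPR-Cas system type and sequencing the amplicons.
`spacerscope` is an R package implementing the complete computational
pipeline for such surveys, for microbial ecologists comparing spacer
repertoires within and between sampling sites:

- **Repeat scanning** — IUPAC-degenerate consensus matching on both
  strands with a mismatch budget (`scanRepeats()`); the six dominant
  *Thermus* repeat consensi (IIIAB, I-E, I-C, I-B, I-U, I-A) ship as the
  default (`thermusRepeats()`).
- **Spacer extraction** — a spacer is a sequence of expected length
  *l* ± tolerance between two same-type repeat matches
  (`extractSpacers()` for reads, `mineGenomeArrays()` for genomes).
- **Identity clustering** — UCLUST-style greedy clustering per sample and
  type at 85% full-length identity with free end gaps; the cluster centre
  (most abundant sequence) is the repertoire unit; clusters with > 10
  reads are retained (`clusterSpacers()`, `filterClusters()`).
- **Repertoire comparison** — centres matched across samples/sites/genomes
  at fewer than two mismatches; unique spacers = connected components
  (`matchAcross()`); Shannon entropy, bias-corrected Chao1
  S<sub>obs</sub> + f₁(f₁−1)/(2(f₂+1)), Good's coverage 1 − n₁/N,
  Bray–Curtis/Jaccard β-diversity with UPGMA clustering, abundance
  correlation of shared spacers, Fisher's exact tests.
- **Array-fragment assembly** — spacer pairs and triplets observed in
  multi-spacer reads become an adjacency graph; unambiguous chains are
  reported as array fragments and compared across samples (identical /
  end-trimmed / partially renewed), labelling the turnover end as
  putative leader-proximal (`buildAdjacency()`, `assembleFragments()`,
  `compareFragments()`).
- **Protospacer mapping and PAMs** — ungapped full-length search at
  identity > 0.85 (a 32-mer needs ≥ 28 matches) against phage genomes;
  8-nt flanks feed per-position PAM count models with information
  content and IUPAC consensus calls; locality (local vs foreign spacers,
  Fisher) and transcription-strand bias (exact binomial) of targeting
  (`searchProtospacers()`, `buildPam()`, `localityTable()`,
  `strandBias()`).
- **Ground-truthed simulation** — multi-site communities with shared
  strain lineages, leader-proximal turnover, log-normal abundances,
  phages with planted protospacers and PAMs, and error-bearing
  repeat–spacer ladder reads, with full provenance
  (`simulateCommunity()`, `simulatePhages()`, `simulateReads()`).

`runPipeline()` chains every stage from one config (list, JSON or YAML)
and writes auditable TSV/FASTA/Newick reports;
`inst/scripts/spacerscope.R` is a thin command-line wrapper.

## A worked example

```r
library(spacerscope)
cfg <- list(
  seed = 11, out_dir = "demo_run",
  simulate = list(
    community = list(sites = 2, samples_per_site = 2,
                     strains_per_site = 3, arrays_per_strain = 1,
                     array_length = c(6, 9), sharing = 0.34),
    phages = list(n_phages = 2, protospacers_per_phage = 12),
    reads = list(reads_per_sample = 600, error_rate = 0.005)))
res <- runPipeline(cfg)
```

The log reports per-stage record counts:

```
simulate: 2 sites, 4 samples, 600 reads/sample
extract: 4760 spacer observations, 0 flagged reads
cluster: 89 clusters from 4760 reads
filter: retained 79/89 clusters (size >= 11)
share: 34 unique spacers globally, 40 per-site union
assemble: 69 edges -> 10 fragments
map: 46 protospacer hits
```

and the result object carries every table. Per-sample repertoire
statistics (`res$stats`):

```
  sample_id    N clusters  shannon chao1 goods_coverage
1  site1_s1 1215       23 2.903954    23         1.0000
2  site1_s2 1196       23 2.804760    23         1.0000
3  site2_s1 1200       24 2.685893    25         0.9975
4  site2_s2 1149       19 2.644632    19         1.0000
```

`N` is the read count behind the clusters of each sample, `shannon` the
entropy (nats) of cluster abundances, `chao1` the estimated richness and
`goods_coverage` the estimated fraction of the repertoire captured
(≈ 1 here because this tiny demo is sequenced to saturation). Site
sharing (`res$sharing$shared_by`) shows 28 spacers private to one site
and 6 found at both — the generator planted roughly a third of lineages
as common to the two sites. The I-E PAM model recovers the planted
motif on the 5′ flank:

```
PamModel [I-E]: 20 flank pair(s)
  5' (upstream, -8..-1): NNWNNAAG
  3' (downstream, +1..+8): NNNWNYNN
```

— `AAG` at positions −3..−1 (the sporadic degenerate calls elsewhere are
small-sample noise from 20 correlated flanks; they vanish at realistic
hit counts). `res$strand_bias` tabulates, per CRISPR type, the fraction
of gene-overlapping protospacers on the transcribed (template) strand
with an exact binomial p-value against 0.5 — the signature that
distinguishes transcription-coupled type III targeting from
strand-indifferent type I targeting.

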