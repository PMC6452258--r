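#' Repeat consensus set
#'
#' Holds one IUPAC-degenerate repeat consensus per CRISPR type/subtype,
#' together with the expected spacer length (nt) and the half-width of the
#' accepted spacer-length band. The unit of "type" throughout the package is
#' the repeat consensus: in *Thermus*, each cas-operon type has a specific
#' adjacent repeat, so the repeat stands in for the CRISPR-Cas system type.
#'
#' @slot table data.frame with columns `type_label`, `sequence`,
#'   `expected_spacer_length`, `length_tolerance`.
#' @seealso [thermusRepeats()], [readRepeatTable()]
#' @export
setClass("RepeatSet", representation(table = "data.frame"))

IUPAC_LETTERS <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

setValidity("RepeatSet", function(object) {
  tb <- object@table
  need <- c("type_label", "sequence", "expected_spacer_length",
            "length_tolerance")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)),
                                           collapse = ", ")))
  if (nrow(tb) == 0) return("empty consensus set")
  if (anyDuplicated(tb$type_label)) return("type labels must be unique")
  if (any(nchar(tb$sequence) == 0)) return("empty consensus sequence")
  bad <- vapply(strsplit(toupper(tb$sequence), ""), function(ch)
    any(!ch %in% IUPAC_LETTERS), logical(1))
  if (any(bad))
    return(paste("non-IUPAC symbol in consensus for",
                 paste(tb$type_label[bad], collapse = ", ")))
  if (any(tb$expected_spacer_length <= 0))
    return("expected_spacer_length must be positive")
  if (any(tb$length_tolerance < 0))
    return("length_tolerance must be non-negative")
  TRUE
})

#' Spacer observations extracted from reads or genomes
#'
#' One row per extracted spacer occurrence. Sequences are always stored in
#' the repeat-consensus (+) orientation so forward and reverse reads of one
#' array yield identical spacer strings; `index_in_source` numbers the
#' spacers of one source (read or contig) in that same consistent array
#' direction.
#'
#' @slot observations data.frame with columns `sequence`, `sample_id`,
#'   `site_id`, `type_label`, `source_id`, `index_in_source` (0-based),
#'   `read_support`.
#' @slot flags data.frame of per-source flags (`source_id`, `flag`), e.g.
#'   `chimeric-candidate` for reads whose adjacent repeats disagree in type.
#' @slot params list of extraction parameters recorded for the report.
#' @export
setClass("SpacerObservations",
         representation(observations = "data.frame", flags = "data.frame",
                        params = "list"))

setValidity("SpacerObservations", function(object) {
  need <- c("sequence", "sample_id", "site_id", "type_label", "source_id",
            "index_in_source", "read_support")
  if (!all(need %in% names(object@observations)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(object@observations)),
                       collapse = ", ")))
  if (nrow(object@observations) &&
      any(object@observations$read_support < 1))
    return("read_support must be >= 1")
  TRUE
})

#' CRISPR arrays mined from genome sequence
#'
#' @slot arrays data.frame: `array_id`, `genome_id`, `contig`, `type_label`,
#'   `start`, `end` (0-based half-open on the forward strand), `orientation`
#'   (strand of the repeat consensus), `n_spacers`.
#' @slot spacers data.frame: `array_id`, `position` (0-based along the
#'   array in consensus orientation), `sequence`.
#' @slot repeats data.frame: `array_id`, `start`, `end`, `mismatches`.
#' @export
setClass("GenomeArraySet",
         representation(arrays = "data.frame", spacers = "data.frame",
                        repeats = "data.frame"))

#' Spacer identity clusters
#'
#' UCLUST-style clusters built separately per sample and repeat type. The
#' centre is the most abundant member sequence (ties broken toward the
#' lexicographically smallest), and `size` is the total read count of the
#' cluster - the quantity the ">10 reads" retention filter acts on.
#'
#' @slot clusters data.frame: `cluster_id`, `sample_id`, `site_id`,
#'   `type_label`, `centre`, `size`, `n_unique`.
#' @slot members data.frame: `cluster_id`, `sequence`, `count`.
#' @slot params list (identity threshold etc.).
#' @export
setClass("SpacerClusterSet",
         representation(clusters = "data.frame", members = "data.frame",
                        params = "list"))

setValidity("SpacerClusterSet", function(object) {
  cl <- object@clusters
  if (nrow(cl) && any(cl$size < 1)) return("cluster size must be >= 1")
  if (anyDuplicated(cl$cluster_id)) return("cluster ids must be unique")
  if (nrow(object@members) &&
      !all(object@members$cluster_id %in% cl$cluster_id))
    return("member rows reference unknown clusters")
  TRUE
})

#' Spacer adjacency graph from multi-spacer reads
#'
#' @slot edges data.frame: `type_label`, `from`, `to` (cluster ids),
#'   `support` (reads showing the two spacers adjacent, in this order),
#'   `self_loop` flag.
#' @slot triples data.frame: `type_label`, `a`, `b`, `c`, `support`.
#' @slot params list (`min_support` etc.).
#' @export
setClass("AdjacencyGraph",
         representation(edges = "data.frame", triples = "data.frame",
                        params = "list"))

#' Reconstructed CRISPR array fragments
#'
#' @slot fragments data.frame: `fragment_id`, `type_label`, `n_spacers`,
#'   `samples`, `flag` (e.g. broken cycles).
#' @slot path data.frame: `fragment_id`, `position` (0-based),
#'   `cluster_id`, `support_next` (reads supporting the junction to the
#'   next spacer; NA at the last position).
#' @export
setClass("ArrayFragmentSet",
         representation(fragments = "data.frame", path = "data.frame"))

#' Position count model of a protospacer adjacent motif (PAM)
#'
#' Per-position nucleotide counts over the 8 nt upstream and 8 nt
#' downstream flanks of protospacers (protospacer-strand orientation:
#' "upstream"/"5'" is 5' of the strand whose sequence equals the crRNA
#' spacer). Information content is `2 + sum(p * log2(p))` bits per position.
#'
#' @slot type_label character.
#' @slot up_counts,down_counts 4 x 8 count matrices (rows A,C,G,T; columns
#'   are flank positions; upstream columns ordered -8..-1, downstream
#'   +1..+8).
#' @slot n_flanks number of non-truncated flank pairs counted.
#' @slot consensus_up,consensus_down 8-letter IUPAC consensus strings (empty
#'   when too few flanks were available for a call).
#' @export
setClass("PamModel",
         representation(type_label = "character", up_counts = "matrix",
                        down_counts = "matrix", n_flanks = "integer",
                        consensus_up = "character",
                        consensus_down = "character"))

setValidity("PamModel", function(object) {
  for (m in list(object@up_counts, object@down_counts)) {
    if (!all(dim(m) == c(4, 8))) return("count matrices must be 4 x 8")
    if (any(m < 0)) return("negative counts")
    if (object@n_flanks > 0 && !all(colSums(m) == object@n_flanks))
      return("column sums must equal the number of contributing flanks")
  }
  TRUE
})

#' Ground truth of a simulated spacer community
#'
#' @slot sites character vector of site ids.
#' @slot samples data.frame: `sample_id`, `site_id`.
#' @slot lineages data.frame: `lineage_id`, `shared` (logical).
#' @slot strains data.frame: `strain_id`, `lineage_id`, `site_id`.
#' @slot abundances data.frame: `sample_id`, `strain_id`, `weight`.
#' @slot arrays list: per strain, a list of arrays, each a list with
#'   `type_label`, `repeat_instance` (concrete repeat used in that array)
#'   and `spacers` (character vector, leader-proximal first).
#' @slot phages list: `genomes` (named character), `plantings` data.frame,
#'   `genes` data.frame - filled by [simulatePhages()].
#' @slot reads list: per sample, `seqs`, `quals`, `provenance` data.frame -
#'   filled by [simulateReads()].
#' @slot config list of generator parameters, including the seed.
#' @export
setClass("CommunityTruth",
         representation(sites = "character", samples = "data.frame",
                        lineages = "data.frame", strains = "data.frame",
                        abundances = "data.frame", arrays = "list",
                        phages = "list", reads = "list", config = "list"))
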