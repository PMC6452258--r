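#' Write pipeline tables
#'
#' TSV writers for the pipeline's tabular artifacts. All human-facing
#' coordinates are 1-based inclusive; machine-facing hit tables carry
#' BED-convertible 0-based `start0`/`end0` columns as well.
#'
#' @param x object to write (see individual functions).
#' @param path output file.
#' @return the path, invisibly.
#' @name writers
NULL

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeObservationsTSV <- function(x, path) {
  stopifnot(is(x, "SpacerObservations"))
  .write_tsv(x@observations, path)
}

#' @rdname writers
#' @export
writeClustersTSV <- function(x, path) {
  stopifnot(is(x, "SpacerClusterSet"))
  .write_tsv(x@clusters, path)
}

#' @rdname writers
#' @export
writeCentresFasta <- function(x, path) {
  stopifnot(is(x, "SpacerClusterSet"))
  cl <- x@clusters
  seqs <- Biostrings::DNAStringSet(cl$centre)
  names(seqs) <- sprintf("%s type=%s sample=%s size=%d", cl$cluster_id,
                         cl$type_label, cl$sample_id, cl$size)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writers
#' @export
writeHitsTSV <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  df <- data.frame(target = as.character(GenomicRanges::seqnames(x)),
                   start0 = GenomicRanges::start(x) - 1L,
                   end0 = GenomicRanges::end(x),
                   spacer_id = x$spacer_id,
                   strand = as.character(GenomicRanges::strand(x)),
                   type_label = x$type_label, site_id = x$site_id,
                   mismatches = x$mismatches,
                   identity = round(x$identity, 4),
                   up_flank = x$up_flank, down_flank = x$down_flank,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname writers
#' @export
writeFragmentsTSV <- function(x, path) {
  stopifnot(is(x, "ArrayFragmentSet"))
  fr <- x@fragments
  pa <- x@path
  fr$spacer_path <- vapply(fr$fragment_id, function(id) {
    p <- pa[pa$fragment_id == id, ]
    paste(p$cluster_id[order(p$position)], collapse = ",")
  }, character(1))
  fr$junction_support <- vapply(fr$fragment_id, function(id) {
    p <- pa[pa$fragment_id == id, ]
    s <- p$support_next[order(p$position)]
    paste(s[!is.na(s)], collapse = ",")
  }, character(1))
  .write_tsv(fr, path)
}

#' @rdname writers
#' @export
writeAdjacencyDOT <- function(x, path) {
  stopifnot(is(x, "AdjacencyGraph"))
  ed <- x@edges
  lines <- c("digraph spacer_adjacency {",
             sprintf('  "%s" -> "%s" [label="%d"];', ed$from, ed$to,
                     ed$support),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write mined genome arrays as GFF3 (array + child repeat/spacer rows)
#' @rdname writers
#' @export
writeArraysGFF3 <- function(x, path) {
  stopifnot(is(x, "GenomeArraySet"))
  ar <- x@arrays; rp <- x@repeats; sp <- x@spacers
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ar))) {
    aid <- ar$array_id[i]
    lines <- c(lines, sprintf(
      "%s\tspacerscope\tCRISPR_array\t%d\t%d\t.\t%s\t.\tID=%s;type_label=%s",
      ar$contig[i], ar$start[i] + 1L, ar$end[i], ar$orientation[i],
      aid, ar$type_label[i]))
    rr <- rp[rp$array_id == aid, ]
    lines <- c(lines, sprintf(
      "%s\tspacerscope\tdirect_repeat\t%d\t%d\t.\t%s\t.\tParent=%s;mismatches=%d",
      ar$contig[i], rr$start + 1L, rr$end, ar$orientation[i], aid,
      rr$mismatches))
    ss <- sp[sp$array_id == aid, ]
    # spacer genomic coordinates lie between consecutive repeat copies
    rr <- rr[order(rr$start), ]
    if (nrow(rr) >= 2) {
      gs <- rr$end[-nrow(rr)] + 1L
      ge <- rr$start[-1]
      lines <- c(lines, sprintf(
        "%s\tspacerscope\tCRISPR_spacer\t%d\t%d\t.\t%s\t.\tParent=%s",
        ar$contig[i], gs, ge, ar$orientation[i], aid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writers
#' @export
writeArraysFasta <- function(x, path) {
  stopifnot(is(x, "GenomeArraySet"))
  sp <- x@spacers
  seqs <- Biostrings::DNAStringSet(sp$sequence)
  names(seqs) <- sprintf("%s|spacer%02d", sp$array_id, sp$position)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
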