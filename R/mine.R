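#' Mine complete CRISPR arrays from genome sequence
#'
#' Chains same-type, same-strand repeat matches whose inter-repeat gaps lie
#' within the expected spacer-length band into arrays of >= 2 repeat
#' copies, and reports the intervening spacers in consensus-array order
#' (for minus-strand arrays the genomic order is reversed and spacers are
#' reverse-complemented, so the content of an array is invariant to contig
#' reverse-complementation).
#'
#' @param genomes named character vector, DNAStringSet, or FASTA path.
#' @param repeats a [RepeatSet-class].
#' @param max_mismatch maximum IUPAC mismatches per repeat copy (default 3).
#' @param genome_id label recorded on every array (defaults to "genome").
#' @return a [GenomeArraySet-class].
#' @export
mineGenomeArrays <- function(genomes, repeats, max_mismatch = 3L,
                             genome_id = "genome") {
  stopifnot(is(repeats, "RepeatSet"))
  if (is.character(genomes) && length(genomes) == 1 &&
      file.exists(genomes) && grepl("\\.(fa|fasta|fna)(\\.gz)?$", genomes))
    genomes <- Biostrings::readDNAStringSet(genomes)
  if (is(genomes, "DNAStringSet") || is(genomes, "DNAString")) {
    nm <- names(genomes)
    genomes <- as.character(genomes)
    names(genomes) <- nm
  }
  if (is.null(names(genomes)))
    names(genomes) <- paste0("contig", seq_along(genomes))
  names(genomes) <- sub("\\s.*$", "", names(genomes))

  tb <- repeats@table
  band_lo <- setNames(tb$expected_spacer_length - tb$length_tolerance,
                      tb$type_label)
  band_hi <- setNames(tb$expected_spacer_length + tb$length_tolerance,
                      tb$type_label)
  matches <- scanRepeats(genomes, repeats, max_mismatch = max_mismatch)

  arrays <- list(); spacers <- list(); reps <- list()
  aid <- 0L
  grp <- paste(matches$seqname, matches$type_label, matches$strand)
  for (idx in split(seq_len(nrow(matches)), grp)) {
    m <- matches[idx[order(matches$start[idx])], , drop = FALSE]
    ty <- m$type_label[1]
    # split the sorted matches into runs with in-band gaps
    run_id <- cumsum(c(1L, as.integer(
      m$start[-1] - m$end[-nrow(m)] < band_lo[[ty]] |
        m$start[-1] - m$end[-nrow(m)] > band_hi[[ty]])))
    for (r in split(seq_len(nrow(m)), run_id)) {
      if (length(r) < 2) next
      mm <- m[r, , drop = FALSE]
      aid <- aid + 1L
      contig <- mm$seqname[1]
      array_id <- sprintf("%s:%s:%s:%d", genome_id, contig, ty, aid)
      sp <- substring(genomes[[contig]], mm$end[-nrow(mm)] + 1L,
                      mm$start[-1])
      if (mm$strand[1] == "-") sp <- rev(.revcomp(sp))
      arrays[[aid]] <- data.frame(
        array_id = array_id, genome_id = genome_id, contig = contig,
        type_label = ty, start = mm$start[1], end = mm$end[nrow(mm)],
        orientation = mm$strand[1], n_spacers = length(sp),
        stringsAsFactors = FALSE)
      spacers[[aid]] <- data.frame(
        array_id = array_id, position = seq_along(sp) - 1L, sequence = sp,
        stringsAsFactors = FALSE)
      reps[[aid]] <- data.frame(
        array_id = array_id, start = mm$start, end = mm$end,
        mismatches = mm$mismatches, stringsAsFactors = FALSE)
    }
  }
  empty_a <- data.frame(array_id = character(), genome_id = character(),
                        contig = character(), type_label = character(),
                        start = integer(), end = integer(),
                        orientation = character(), n_spacers = integer())
  empty_s <- data.frame(array_id = character(), position = integer(),
                        sequence = character())
  empty_r <- data.frame(array_id = character(), start = integer(),
                        end = integer(), mismatches = integer())
  new("GenomeArraySet",
      arrays = if (aid) do.call(rbind, arrays) else empty_a,
      spacers = if (aid) do.call(rbind, spacers) else empty_s,
      repeats = if (aid) do.call(rbind, reps) else empty_r)
}

#' Convert mined arrays to spacer observations
#'
#' Lets genome-mined spacers enter the same clustering/sharing machinery as
#' read-extracted ones (one observation per array spacer, read_support 1).
#'
#' @param x a [GenomeArraySet-class].
#' @param sample_id,site_id labels for the observations (default: the
#'   genome id of each array).
#' @return a [SpacerObservations-class].
#' @export
arraysAsObservations <- function(x, sample_id = NULL, site_id = NULL) {
  stopifnot(is(x, "GenomeArraySet"))
  sp <- x@spacers
  gid <- setNames(x@arrays$genome_id, x@arrays$array_id)[sp$array_id]
  df <- data.frame(
    sequence = sp$sequence,
    sample_id = if (is.null(sample_id)) unname(gid) else sample_id,
    site_id = if (is.null(site_id)) unname(gid) else site_id,
    type_label = setNames(x@arrays$type_label,
                          x@arrays$array_id)[sp$array_id],
    source_id = sp$array_id, index_in_source = sp$position,
    read_support = 1L, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new("SpacerObservations", observations = df,
      flags = data.frame(source_id = character(), flag = character()),
      params = list(origin = "genome-mining"))
}

#' Per-type spacer length profile
#'
#' Arithmetic mean and standard deviation of spacer length per repeat
#' type, with the mean additionally rounded to the nearest integer for
#' reporting (the convention of the consensus-repeat table's "average
#' length of spacer" column).
#'
#' @param x a [GenomeArraySet-class] or [SpacerObservations-class].
#' @return data.frame: `type_label`, `n`, `mean_length`, `sd_length`,
#'   `mean_rounded`.
#' @export
spacerLengthProfile <- function(x) {
  if (is(x, "GenomeArraySet")) {
    ty <- setNames(x@arrays$type_label, x@arrays$array_id)[
      x@spacers$array_id]
    len <- nchar(x@spacers$sequence)
  } else if (is(x, "SpacerObservations")) {
    ty <- x@observations$type_label
    len <- nchar(x@observations$sequence)
  } else stop("unsupported input")
  if (!length(len)) {
    warning("no spacers to profile")
    return(data.frame(type_label = character(), n = integer(),
                      mean_length = numeric(), sd_length = numeric(),
                      mean_rounded = integer()))
  }
  agg <- lapply(split(len, ty), function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0))
  data.frame(type_label = names(agg),
             n = vapply(agg, `[[`, numeric(1), "n"),
             mean_length = vapply(agg, `[[`, numeric(1), "mean"),
             sd_length = vapply(agg, `[[`, numeric(1), "sd"),
             mean_rounded = as.integer(round(
               vapply(agg, `[[`, numeric(1), "mean"))),
             row.names = NULL, stringsAsFactors = FALSE)
}
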