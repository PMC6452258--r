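#' Extract spacer observations from amplicon reads
#'
#' Implements the repeat-anchored spacer definition: a spacer is a sequence
#' of an expected length located between two full-length repeat matches of
#' the same type (and strand) on one read. Reads are quality-truncated at
#' the first base below `min_qual` (Phred), spacers containing ambiguous
#' bases are dropped, gaps outside the per-type length band are logged as
#' out-of-band, and reads whose adjacent repeat matches disagree in type
#' (or strand) are flagged as chimera candidates and contribute no spacer
#' from the offending junction. All emitted spacers are reported in the
#' repeat-consensus (+) orientation, so forward and reverse reads of the
#' same array yield identical spacer strings, and `index_in_source` counts
#' spacers of one read in a consistent array direction.
#'
#' @param reads a named character vector, [Biostrings::DNAStringSet-class],
#'   [Biostrings::QualityScaledDNAStringSet-class], or a FASTQ file path.
#' @param repeats a [RepeatSet-class].
#' @param max_mismatch maximum IUPAC mismatches per repeat window
#'   (default 3).
#' @param min_qual Phred threshold for 3'-truncation (default 20; only
#'   applied when qualities are available).
#' @param sample_id,site_id labels attached to every observation.
#' @return a [SpacerObservations-class].
#' @export
extractSpacers <- function(reads, repeats, max_mismatch = 3L,
                           min_qual = 20L, sample_id = "S1",
                           site_id = sample_id) {
  stopifnot(is(repeats, "RepeatSet"))
  quals <- NULL
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(reads))
  }
  if (is(reads, "QualityScaledDNAStringSet")) {
    quals <- as(Biostrings::quality(reads), "IntegerList")
    reads <- suppressWarnings(as(reads, "DNAStringSet"))
  }
  if (is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads)) || anyNA(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  # strip anything after the first whitespace in FASTQ ids
  names(reads) <- sub("\\s.*$", "", names(reads))
  if (!is.null(quals)) {
    for (i in seq_along(reads)) {
      q <- quals[[i]]
      bad <- which(q < min_qual)
      if (length(bad))
        reads[i] <- substr(reads[i], 1L, bad[1] - 1L)
    }
    reads <- reads[nchar(reads) > 0]
  }

  tb <- repeats@table
  band_lo <- setNames(tb$expected_spacer_length - tb$length_tolerance,
                      tb$type_label)
  band_hi <- setNames(tb$expected_spacer_length + tb$length_tolerance,
                      tb$type_label)
  # degenerate 8-nt termini of each consensus, used to reject spacers that
  # still contain a repeat fragment
  term8 <- lapply(setNames(tb$sequence, tb$type_label), function(p) {
    n <- nchar(p)
    unique(c(substr(p, 1, min(8, n)), substr(p, max(1, n - 7), n)))
  })

  matches <- scanRepeats(reads, repeats, max_mismatch = max_mismatch)
  counters <- c(out_of_band = 0L, ambiguous_dropped = 0L,
                repeat_contaminated = 0L)
  flags <- list()
  obs <- list(sequence = list(), source_id = list(), type_label = list(),
              strand = list(), start = list())
  ok <- 0L
  m_start <- matches$start; m_end <- matches$end
  m_type <- matches$type_label; m_strand <- matches$strand
  for (idx0 in split(seq_len(nrow(matches)), matches$seqname)) {
    if (length(idx0) < 2) next
    idx <- idx0[order(m_start[idx0])]
    rid <- matches$seqname[idx[1]]
    s <- reads[[rid]]
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      gap <- m_start[b] - m_end[a]
      if (gap < 0) next
      if (m_type[a] != m_type[b] || m_strand[a] != m_strand[b]) {
        flags[[length(flags) + 1L]] <-
          data.frame(source_id = rid, flag = "chimeric-candidate",
                     stringsAsFactors = FALSE)
        next
      }
      ty <- m_type[a]
      if (gap < band_lo[[ty]] || gap > band_hi[[ty]]) {
        counters["out_of_band"] <- counters["out_of_band"] + 1L
        next
      }
      sp <- substr(s, m_end[a] + 1L, m_start[b])
      if (grepl("[^ACGT]", sp)) {
        counters["ambiguous_dropped"] <- counters["ambiguous_dropped"] + 1L
        next
      }
      ok <- ok + 1L
      obs$sequence[[ok]] <- sp
      obs$source_id[[ok]] <- rid
      obs$type_label[[ok]] <- ty
      obs$strand[[ok]] <- m_strand[a]
      obs$start[[ok]] <- m_end[a]
    }
  }
  df <- data.frame(
    sequence = unlist(obs$sequence) %||% character(),
    source_id = unlist(obs$source_id) %||% character(),
    type_label = unlist(obs$type_label) %||% character(),
    strand = unlist(obs$strand) %||% character(),
    start = unlist(obs$start) %||% integer(),
    stringsAsFactors = FALSE)
  # normalize to the consensus (+) frame in one batched call, then drop
  # spacers still carrying a repeat-terminus fragment (<= 1 mismatch)
  if (nrow(df)) {
    minus <- df$strand == "-"
    if (any(minus)) df$sequence[minus] <- .revcomp(df$sequence[minus])
    contam <- rep(FALSE, nrow(df))
    for (ty in unique(df$type_label)) {
      sel <- which(df$type_label == ty)
      for (t8 in term8[[ty]]) {
        hit <- .scan_iupac_many(df$sequence[sel], t8, 1L, TRUE)
        contam[sel[unique(hit$seq)]] <- TRUE
      }
    }
    counters["repeat_contaminated"] <- sum(contam)
    df <- df[!contam, , drop = FALSE]
    rownames(df) <- NULL
  }
  # index spacers of one read/type in consensus-array direction: reverse
  # the read order for minus-strand matches
  df$index_in_source <- rep(NA_integer_, nrow(df))
  if (nrow(df)) {
    grp <- paste(df$source_id, df$type_label, df$strand)
    for (idx in split(seq_len(nrow(df)), grp)) {
      o <- order(df$start[idx])
      if (df$strand[idx[1]] == "-") o <- rev(o)
      df$index_in_source[idx[o]] <- seq_along(idx) - 1L
    }
  }
  df$sample_id <- rep(sample_id, nrow(df))
  df$site_id <- rep(site_id, nrow(df))
  df$read_support <- rep(1L, nrow(df))
  df <- df[, c("sequence", "sample_id", "site_id", "type_label",
               "source_id", "index_in_source", "read_support")]
  fl <- if (length(flags)) unique(do.call(rbind, flags)) else
    data.frame(source_id = character(), flag = character())
  rownames(fl) <- NULL
  new("SpacerObservations", observations = df, flags = fl,
      params = list(max_mismatch = max_mismatch, min_qual = min_qual,
                    counters = as.list(counters)))
}

#' Combine spacer observation sets
#' @param ... [SpacerObservations-class] objects (e.g. one per sample).
#' @return a single [SpacerObservations-class].
#' @export
combineObservations <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !is(xs[[1]], "SpacerObservations"))
    xs <- xs[[1]]
  stopifnot(all(vapply(xs, is, logical(1), "SpacerObservations")))
  new("SpacerObservations",
      observations = do.call(rbind, lapply(xs, slot, "observations")),
      flags = do.call(rbind, lapply(xs, slot, "flags")),
      params = xs[[1]]@params)
}
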