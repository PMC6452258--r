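#' Locate approximate repeat occurrences in a DNA sequence
#'
#' Slides every consensus of `repeats` along `seq` on both strands and
#' reports all windows with at most `max_mismatch` IUPAC mismatches.
#' Coordinates are 0-based half-open on the forward strand of `seq`;
#' `strand == "-"` means the reverse complement of the window matches the
#' consensus. An `N` in the subject matches any pattern symbol but is
#' tallied separately (`n_count`); windows with more than `max_subject_n`
#' Ns are flagged. Overlapping matches of the same type are resolved
#' greedily to the lower-mismatch (then leftmost) one.
#'
#' @param seq a single DNA string, a named character vector, or a
#'   [Biostrings::DNAStringSet-class].
#' @param repeats a [RepeatSet-class].
#' @param max_mismatch maximum IUPAC mismatches per window (default 3).
#' @param max_subject_n windows with more subject Ns than this are flagged
#'   (default 2).
#' @param resolve_overlaps drop overlapping same-type matches (default
#'   TRUE)?
#' @return data.frame with columns `seqname`, `type_label`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`, `n_count`, `n_flagged`,
#'   sorted by (`seqname`, `start`).
#' @examples
#' rs <- repeatSet("I-E", "GTAGTCCCCACRCRYGTGGGGATGGMCSD", 32)
#' scanRepeats(paste0(strrep("T", 20), "GTAGTCCCCACACACGTGGGGATGGACSD",
#'                    strrep("A", 20)), rs)
#' @export
scanRepeats <- function(seq, repeats, max_mismatch = 3L,
                        max_subject_n = 2L, resolve_overlaps = TRUE) {
  stopifnot(is(repeats, "RepeatSet"), max_mismatch >= 0)
  if (is(seq, "DNAStringSet") || is(seq, "DNAString"))
    seq <- as.character(seq)
  if (is.null(names(seq)))
    names(seq) <- if (length(seq) == 1) "seq" else paste0("seq", seq_along(seq))
  tb <- repeats@table
  # pre-compute reverse-complemented patterns once; scan all sequences
  # per (consensus, strand) in one compiled pass
  rcpat <- vapply(tb$sequence, .revcomp, character(1))
  subjects <- toupper(unname(unlist(seq)))
  snames <- names(seq)
  acc <- list(seqname = list(), type_label = list(), start = list(),
              strand = list(), mismatches = list(), n_count = list(),
              plen = list())
  k <- 0L
  for (i in seq_len(nrow(tb))) {
    for (std in c("+", "-")) {
      p <- if (std == "+") tb$sequence[i] else rcpat[i]
      hit <- .scan_iupac_many(subjects, p, as.integer(max_mismatch), TRUE)
      nh <- length(hit$start)
      if (nh == 0) next
      k <- k + 1L
      acc$seqname[[k]] <- snames[hit$seq]
      acc$type_label[[k]] <- rep(tb$type_label[i], nh)
      acc$start[[k]] <- hit$start
      acc$strand[[k]] <- rep(std, nh)
      acc$mismatches[[k]] <- hit$mismatches
      acc$n_count[[k]] <- hit$n_count
      acc$plen[[k]] <- rep(nchar(tb$sequence[i]), nh)
    }
  }
  if (k == 0L)
    return(data.frame(seqname = character(), type_label = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      n_count = integer(), n_flagged = logical()))
  m <- data.frame(
    seqname = unlist(acc$seqname), type_label = unlist(acc$type_label),
    start = unlist(acc$start),
    end = unlist(acc$start) + unlist(acc$plen),
    strand = unlist(acc$strand), mismatches = unlist(acc$mismatches),
    n_count = unlist(acc$n_count), stringsAsFactors = FALSE)
  if (resolve_overlaps) m <- .resolve_overlaps(m)
  m$n_flagged <- m$n_count > max_subject_n
  m <- m[order(m$seqname, m$start, m$type_label), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Greedy non-overlapping selection among same-type matches of one sequence:
# accept in (mismatches asc, start asc) order, reject anything overlapping
# an accepted match of the same type.
.resolve_overlaps <- function(m) {
  keep <- rep(TRUE, nrow(m))
  keyv <- paste(m$seqname, m$type_label)
  for (idx in split(seq_len(nrow(m)), keyv)) {
    if (length(idx) < 2) next
    sub <- m[idx, ]
    ord <- order(sub$mismatches, sub$start)
    taken <- logical(length(idx))
    accepted <- matrix(numeric(0), ncol = 2)
    for (k in ord) {
      s <- sub$start[k]; e <- sub$end[k]
      if (nrow(accepted) == 0 ||
          all(e <= accepted[, 1] | s >= accepted[, 2])) {
        taken[k] <- TRUE
        accepted <- rbind(accepted, c(s, e))
      }
    }
    keep[idx[!taken]] <- FALSE
  }
  m[keep, , drop = FALSE]
}
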