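#' IUPAC mismatch count between a degenerate pattern and a concrete window
#'
#' Counts the positions at which the concrete base is not in the degenerate
#' class of the pattern symbol (standard IUPAC semantics, e.g. R = \{A,G\}).
#' Pattern and window must have equal length.
#'
#' @param pattern IUPAC-degenerate DNA string.
#' @param window concrete DNA string (A/C/G/T/N) of the same length.
#' @param n_matches should an `N` in the window match any pattern symbol
#'   (`TRUE`, the convention for sequencing-read scanning) or count as a
#'   mismatch (`FALSE`, the convention for protospacer identity)?
#' @return integer mismatch count.
#' @examples
#' iupacMismatches("R", "A")  # 0
#' iupacMismatches("R", "C")  # 1
#' @export
iupacMismatches <- function(pattern, window, n_matches = TRUE) {
  stopifnot(is.character(pattern), is.character(window),
            length(pattern) == 1, length(window) == 1)
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have the same length")
  hit <- .scan_iupac(window, toupper(pattern), nchar(pattern), n_matches)
  hit$mismatches[1L]
}

#' Read a repeat-consensus table
#'
#' Reads a tab-separated table with columns `type_label`, `sequence`,
#' `expected_spacer_length` and `length_tolerance` into a
#' [RepeatSet-class]. Sequences are uppercased and validated against the
#' IUPAC alphabet.
#'
#' @param path TSV file path.
#' @return a [RepeatSet-class].
#' @seealso [thermusRepeats()] for the packaged default set.
#' @export
readRepeatTable <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  tb$sequence <- toupper(tb$sequence)
  new("RepeatSet", table = tb)
}

#' The six dominant Thermus repeat consensi
#'
#' The packaged default consensus set: one degenerate repeat per dominant
#' *Thermus* CRISPR-Cas system (IIIAB, I-E, I-C, I-B, I-U, I-A), with the
#' average spacer length observed in complete *Thermus* genomes
#' (41/32/38/36/36/36 nt) and a +/- 10 nt acceptance band.
#'
#' @return a [RepeatSet-class].
#' @examples
#' thermusRepeats()
#' @export
thermusRepeats <- function() {
  readRepeatTable(system.file("extdata", "thermus_repeats.tsv",
                              package = "spacerscope", mustWork = TRUE))
}

#' Make a single-consensus RepeatSet
#'
#' Convenience constructor used heavily in simulations and tests.
#'
#' @param type_label CRISPR type label.
#' @param sequence IUPAC-degenerate repeat string.
#' @param expected_spacer_length expected spacer length, nt.
#' @param length_tolerance accepted half-width of the spacer-length band.
#' @return a [RepeatSet-class] with one row.
#' @export
repeatSet <- function(type_label, sequence, expected_spacer_length,
                      length_tolerance = 10L) {
  new("RepeatSet", table = data.frame(
    type_label = type_label, sequence = toupper(sequence),
    expected_spacer_length = as.integer(expected_spacer_length),
    length_tolerance = as.integer(length_tolerance),
    stringsAsFactors = FALSE))
}

#' Subset a RepeatSet by type
#' @param x a [RepeatSet-class]
#' @param types type labels to keep
#' @return a [RepeatSet-class]
#' @export
subsetRepeats <- function(x, types) {
  stopifnot(is(x, "RepeatSet"))
  miss <- setdiff(types, x@table$type_label)
  if (length(miss))
    stop("unknown type label(s): ", paste(miss, collapse = ", "))
  new("RepeatSet", table = x@table[x@table$type_label %in% types, ,
                                   drop = FALSE])
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Instantiate the degenerate positions of an IUPAC consensus
#'
#' Replaces every degenerate symbol by a concrete base drawn uniformly from
#' its class (used by the simulator: real repeat copies are concrete
#' instances of the consensus).
#'
#' @param sequence IUPAC string.
#' @return concrete A/C/G/T string matching the consensus with 0
#'   mismatches.
#' @export
instantiateConsensus <- function(sequence) {
  classes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  ch <- strsplit(toupper(sequence), "")[[1]]
  paste(vapply(ch, function(b) {
    opts <- classes[[b]]
    if (is.null(opts)) stop("invalid IUPAC symbol: ", b)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}
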