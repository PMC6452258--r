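# Independent brute-force oracles, written in plain R against the
# definitions (never calling the package's search/identity code paths).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y",
            Y = "R", S = "S", W = "W", K = "M", M = "K", B = "V",
            V = "B", D = "H", H = "D")
  vapply(x, function(s) paste(rev(comp[strsplit(s, "")[[1]]]),
                              collapse = ""), character(1),
         USE.NAMES = FALSE)
}

# all-offset sliding scan: mismatch count of `pattern` (IUPAC) at every
# start of `subject`; subject N matches anything when n_matches
bf_scan <- function(subject, pattern, n_matches = TRUE) {
  sc <- strsplit(subject, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc); n <- length(sc)
  if (n < L) return(integer(0))
  vapply(0:(n - L), function(off) {
    w <- sc[off + seq_len(L)]
    sum(vapply(seq_len(L), function(j) {
      if (w[j] == "N") return(if (n_matches) FALSE else TRUE)
      !(w[j] %in% IUPAC_SETS[[pc[j]]])
    }, logical(1)))
  }, integer(1))
}

# best ungapped overlap matches over all offsets (free end gaps)
bf_overlap <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  best <- list(matches = -1L, overlap = 0L, mismatches = NA)
  for (off in -(nb - 1):(na - 1)) {
    lo <- max(0, -off); hi <- min(nb, na - off)
    if (hi <= lo) next
    j <- (lo + 1):hi
    m <- sum(bc[j] == ac[j + off])
    if (m > best$matches) {
      best <- list(matches = m, overlap = hi - lo,
                   mismatches = (hi - lo) - m, offset = off)
    }
  }
  best
}

# the cross-sample matching rule: equal length -> Hamming <= max_mm;
# unequal -> best overlap with mismatches <= max_mm and overhang <= 2
bf_spacers_match <- function(a, b, max_mm = 1L, max_overhang = 2L) {
  if (nchar(a) == nchar(b)) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    return(sum(ac != bc) <= max_mm)
  }
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  for (off in -(nb - 1):(na - 1)) {
    lo <- max(0, -off); hi <- min(nb, na - off)
    if (hi <= lo) next
    ov <- hi - lo
    if ((na - ov) + (nb - ov) > max_overhang) next
    j <- (lo + 1):hi
    if ((ov - sum(bc[j] == ac[j + off])) <= max_mm) return(TRUE)
  }
  FALSE
}

# union-find connected components over a match-rule predicate
bf_components <- function(seqs, types = rep("t", length(seqs)),
                          max_mm = 1L) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (types[i] != types[j]) next
    if (bf_spacers_match(seqs[i], seqs[j], max_mm)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# exact two-sided Fisher p by enumeration over all tables with the
# observed margins (probability-mass rule)
bf_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)),
    numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mutate a sequence with k random substitutions
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a concrete I-E-like test repeat (no degeneracy) for constructed reads
TEST_REPEAT <- "GTAGTCCCCACACACGTGGGGATGGACCG"

test_repeat_set <- function(spacer_len = 32L, tol = 10L,
                            type = "I-E", seq = TEST_REPEAT) {
  repeatSet(type, seq, spacer_len, tol)
}

# build a repeat/spacer ladder read
ladder_read <- function(spacers, rep_seq = TEST_REPEAT) {
  paste0(rep_seq, paste(paste0(spacers, rep_seq), collapse = ""))
}

# random spacer free of the repeat's 8-nt termini (at <= 1 mismatch), so
# the extractor's repeat-contamination guard cannot fire on it
clean_spacer <- function(len, rep_seq = TEST_REPEAT) {
  t8 <- c(substr(rep_seq, 1, 8),
          substr(rep_seq, nchar(rep_seq) - 7, nchar(rep_seq)))
  repeat {
    s <- rand_dna(len)
    if (all(vapply(t8, function(p) all(bf_scan(s, p) > 1), logical(1))))
      return(s)
  }
}
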