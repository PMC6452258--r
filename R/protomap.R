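#' Search spacers against target genomes (ungapped, full length)
#'
#' Implements the protospacer hit definition directly: a hit is an
#' ungapped, full-spacer-length match on either strand with identity
#' strictly greater than `min_identity` (a 32-mer needs >= 28 matching
#' positions: 28/32 = 0.875 is accepted, 27/32 = 0.844 rejected). Every
#' offset of every target is examined on both strands, so the search is
#' exactly equivalent to a brute-force scan; `word_size` is retained as
#' the minimum spacer length admitted to the search (short sequences
#' cannot produce meaningful hits under the identity rule). `N` positions
#' in targets count as mismatches. Hit coordinates follow Bioconductor
#' convention (1-based [GenomicRanges::GRanges-class] on the + strand);
#' the TSV writer emits BED-convertible 0-based columns.
#'
#' @param spacers named character vector or DNAStringSet of spacer (centre)
#'   sequences; names become `spacer_id`.
#' @param targets named character vector, DNAStringSet, or FASTA path.
#' @param min_identity identity threshold, strict lower bound
#'   (default 0.85).
#' @param word_size minimum admissible spacer length (default 8).
#' @param spacer_meta optional data.frame with `spacer_id`, `type_label`,
#'   `site_id` to annotate hits.
#' @param flank width of extracted flanks, nt (default 8).
#' @return [GenomicRanges::GRanges-class] with mcols `spacer_id`,
#'   `type_label`, `site_id`, `mismatches`, `identity`, `up_flank`,
#'   `down_flank`, `up_truncated`, `down_truncated`. Flanks are reported
#'   in protospacer-strand orientation.
#' @export
searchProtospacers <- function(spacers, targets, min_identity = 0.85,
                               word_size = 8L, spacer_meta = NULL,
                               flank = 8L) {
  if (is(spacers, "DNAStringSet") || is(spacers, "DNAString")) {
    nm <- names(spacers); spacers <- as.character(spacers)
    names(spacers) <- nm
  }
  if (is.null(names(spacers)))
    names(spacers) <- paste0("sp", seq_along(spacers))
  if (is.character(targets) && length(targets) == 1 &&
      file.exists(targets) && grepl("\\.(fa|fasta|fna)(\\.gz)?$", targets))
    targets <- Biostrings::readDNAStringSet(targets)
  if (is(targets, "DNAStringSet") || is(targets, "DNAString")) {
    nm <- names(targets); targets <- as.character(targets)
    names(targets) <- nm
  }
  if (is.null(names(targets)))
    names(targets) <- paste0("target", seq_along(targets))
  names(targets) <- sub("\\s.*$", "", names(targets))
  short <- nchar(spacers) < word_size
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than word_size skipped")
    spacers <- spacers[!short]
  }

  rows <- list(); k <- 0L
  for (si in seq_along(spacers)) {
    sp <- toupper(spacers[[si]])
    L <- nchar(sp)
    # largest mismatch count with (L - mm)/L strictly > min_identity
    max_mm <- L - floor(min_identity * L + 1e-9) - 1L
    if (max_mm < 0) next
    for (ti in seq_along(targets)) {
      tg <- toupper(targets[[ti]])
      for (std in c("+", "-")) {
        pat <- if (std == "+") sp else .revcomp(sp)
        hit <- .scan_iupac(tg, pat, as.integer(max_mm), FALSE)
        nh <- length(hit$start)
        if (!nh) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          target = names(targets)[ti], start0 = hit$start,
          end0 = hit$start + L, strand = std,
          spacer_id = names(spacers)[si], mismatches = hit$mismatches,
          identity = (L - hit$mismatches) / L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      spacer_id = character(), type_label = character(),
      site_id = character(), mismatches = integer(), identity = numeric(),
      up_flank = character(), down_flank = character(),
      up_truncated = logical(), down_truncated = logical())
    return(gr)
  }
  df <- do.call(rbind, rows)
  df <- unique(df)  # one report per (spacer, locus, strand)
  gr <- GenomicRanges::GRanges(
    seqnames = df$target,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = df$strand)
  meta <- S4Vectors::DataFrame(spacer_id = df$spacer_id,
                               type_label = NA_character_,
                               site_id = NA_character_,
                               mismatches = df$mismatches,
                               identity = df$identity)
  if (!is.null(spacer_meta)) {
    m <- match(df$spacer_id, spacer_meta$spacer_id)
    if ("type_label" %in% names(spacer_meta))
      meta$type_label <- spacer_meta$type_label[m]
    if ("site_id" %in% names(spacer_meta))
      meta$site_id <- spacer_meta$site_id[m]
  }
  S4Vectors::mcols(gr) <- meta
  gr <- extractFlanks(gr, targets, flank = flank)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), gr$spacer_id)
  gr[ord]
}

#' Extract protospacer flanks in protospacer-strand orientation
#'
#' Adds `up_flank`/`down_flank` (and truncation flags) to a hit set:
#' "upstream" is 5' of the protospacer strand, so for minus-strand hits
#' the flanks come from the opposite sides of the forward-strand window
#' and are reverse-complemented. Flanks cut short by a contig end are
#' flagged truncated and excluded from PAM counting.
#'
#' @param hits GRanges of hits (as from [searchProtospacers()]).
#' @param targets named character vector of target sequences.
#' @param flank flank width, nt (default 8).
#' @return the GRanges with flank mcols filled in.
#' @export
extractFlanks <- function(hits, targets, flank = 8L) {
  if (is(targets, "DNAStringSet")) {
    nm <- names(targets); targets <- as.character(targets)
    names(targets) <- nm
  }
  names(targets) <- sub("\\s.*$", "", names(targets))
  n <- length(hits)
  up <- character(n); dn <- character(n)
  upt <- logical(n); dnt <- logical(n)
  for (i in seq_len(n)) {
    tg <- targets[[as.character(GenomicRanges::seqnames(hits)[i])]]
    s <- GenomicRanges::start(hits)[i]; e <- GenomicRanges::end(hits)[i]
    left_lo <- s - flank; left_hi <- s - 1L
    right_lo <- e + 1L; right_hi <- e + flank
    left <- substr(tg, max(1L, left_lo), left_hi)
    right <- substr(tg, right_lo, min(nchar(tg), right_hi))
    left_trunc <- left_lo < 1L
    right_trunc <- right_hi > nchar(tg)
    if (as.character(GenomicRanges::strand(hits)[i]) == "-") {
      up[i] <- .revcomp(right); upt[i] <- right_trunc
      dn[i] <- .revcomp(left); dnt[i] <- left_trunc
    } else {
      up[i] <- left; upt[i] <- left_trunc
      dn[i] <- right; dnt[i] <- right_trunc
    }
  }
  hits$up_flank <- up; hits$down_flank <- dn
  hits$up_truncated <- upt; hits$down_truncated <- dnt
  hits
}

#' Build a PAM count model from protospacer flanks
#'
#' Per-position nucleotide counts over the 8 nt upstream and downstream
#' flanks (protospacer-strand orientation), per-position information
#' content `2 + sum(p * log2(p))` bits, and an IUPAC consensus call per
#' position: the base if its frequency is >= 0.75, the two-fold degenerate
#' code if the top two bases jointly reach >= 0.9, else N. Hits with
#' truncated flanks are excluded; with fewer than `min_flanks` usable
#' flank pairs the counts are still returned but no consensus is called.
#'
#' @param hits GRanges with flank mcols (one model per call; subset by
#'   type first, or use the convenience grouping in [pamByType()]).
#' @param type_label label stored on the model.
#' @param min_flanks minimum flank pairs for a consensus call (default 5).
#' @return a [PamModel-class].
#' @export
buildPam <- function(hits, type_label = "all", min_flanks = 5L) {
  ok <- !hits$up_truncated & !hits$down_truncated &
    nchar(hits$up_flank) == 8L & nchar(hits$down_flank) == 8L &
    !grepl("[^ACGT]", hits$up_flank) & !grepl("[^ACGT]", hits$down_flank)
  up <- hits$up_flank[ok]; dn <- hits$down_flank[ok]
  cnt <- function(flanks) {
    m <- matrix(0L, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (f in flanks) {
      ch <- strsplit(f, "")[[1]]
      for (j in 1:8) if (ch[j] %in% rownames(m))
        m[ch[j], j] <- m[ch[j], j] + 1L
    }
    m
  }
  upc <- cnt(up); dnc <- cnt(dn)
  colnames(upc) <- paste0("m", 8:1)  # -8 .. -1
  colnames(dnc) <- paste0("p", 1:8)  # +1 .. +8
  n <- length(up)
  if (n < min_flanks) {
    warning("only ", n, " usable flank pair(s); no consensus called")
    cons_up <- cons_dn <- ""
  } else {
    cons_up <- .pam_consensus(upc)
    cons_dn <- .pam_consensus(dnc)
  }
  new("PamModel", type_label = type_label, up_counts = upc,
      down_counts = dnc, n_flanks = as.integer(n),
      consensus_up = cons_up, consensus_down = cons_dn)
}

.pam_consensus <- function(m) {
  two_fold <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  paste(apply(m, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) return("N")
    p <- col / tot
    o <- order(-p)
    if (p[o[1]] >= 0.75) return(names(col)[o[1]])
    if (p[o[1]] + p[o[2]] >= 0.9) {
      pair <- paste(sort(names(col)[o[1:2]]), collapse = "")
      return(two_fold[[pair]])
    }
    "N"
  }), collapse = "")
}

#' Per-position information content of a PAM model
#' @param pam a [PamModel-class]
#' @return named numeric vector (bits, positions -8..-1 then +1..+8).
#' @export
pamInformation <- function(pam) {
  stopifnot(is(pam, "PamModel"))
  ic <- function(m) apply(m, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) return(0)
    p <- col[col > 0] / tot
    2 + sum(p * log2(p))
  })
  c(ic(pam@up_counts), ic(pam@down_counts))
}

#' PAM models per CRISPR type
#' @param hits GRanges with `type_label` and flank mcols.
#' @param min_flanks see [buildPam()].
#' @return named list of [PamModel-class].
#' @export
pamByType <- function(hits, min_flanks = 5L) {
  tys <- sort(unique(hits$type_label))
  setNames(lapply(tys, function(ty)
    buildPam(hits[hits$type_label == ty], type_label = ty,
             min_flanks = min_flanks)), tys)
}

#' Locality of targeting: local versus foreign spacers
#'
#' For each target with a known isolation site, builds the 2x2 table
#' (spacer local to the target's site vs foreign) x (has a hit on the
#' target vs not) over all supplied spacers, and tests association with
#' Fisher's exact test. Also returns the per-site hit-count matrix.
#'
#' @param hits GRanges from [searchProtospacers()] (with `site_id` filled).
#' @param spacer_sites named character vector: spacer_id -> site of origin
#'   (the universe of spacers, including those with no hit).
#' @param target_sites named character vector: target -> site of
#'   isolation (NA for targets without one; their test is skipped).
#' @return list: `tables` (named list of 2x2 matrices), `p_values`,
#'   `site_counts` (site x target matrix of hits).
#' @export
localityTable <- function(hits, spacer_sites, target_sites) {
  targets <- names(target_sites)
  sites <- sort(unique(spacer_sites))
  counts <- matrix(0L, length(sites), length(targets),
                   dimnames = list(sites, targets))
  hit_df <- unique(data.frame(
    target = as.character(GenomicRanges::seqnames(hits)),
    spacer_id = hits$spacer_id, stringsAsFactors = FALSE))
  for (r in seq_len(nrow(hit_df))) {
    st <- spacer_sites[[hit_df$spacer_id[r]]]
    if (!is.null(st) && hit_df$target[r] %in% targets)
      counts[st, hit_df$target[r]] <- counts[st, hit_df$target[r]] + 1L
  }
  tables <- list(); pv <- setNames(rep(NA_real_, length(targets)), targets)
  for (tg in targets) {
    tsite <- target_sites[[tg]]
    if (is.na(tsite)) next
    local <- names(spacer_sites)[spacer_sites == tsite]
    foreign <- names(spacer_sites)[spacer_sites != tsite]
    hit_sp <- hit_df$spacer_id[hit_df$target == tg]
    tab <- matrix(c(sum(local %in% hit_sp), sum(!local %in% hit_sp),
                    sum(foreign %in% hit_sp), sum(!foreign %in% hit_sp)),
                  2, 2, dimnames = list(c("hit", "no_hit"),
                                        c("local", "foreign")))
    tables[[tg]] <- tab
    pv[tg] <- fisherExactTest(tab)
  }
  list(tables = tables, p_values = pv, site_counts = counts)
}

#' Strand/transcription bias of protospacer hits
#'
#' Fraction of gene-overlapping hits lying on the transcribed (template)
#' strand of their gene, per CRISPR type, with a two-sided exact binomial
#' test against 0.5. Convention: the protospacer strand is the strand
#' whose sequence equals the crRNA spacer; type III interference requires
#' crRNA:transcript pairing, which happens when the protospacer lies on
#' the template strand, i.e. when the hit strand is opposite to the
#' annotated gene strand. A hit is assigned to a gene when at least
#' `min_overlap_frac` of its length overlaps the gene; hits overlapping
#' no gene (or only fractionally) are excluded from the test.
#'
#' @param hits GRanges from [searchProtospacers()].
#' @param genes GRanges of gene features with strand (e.g. imported from
#'   GFF3 via [rtracklayer::import()]), seqnames matching the targets.
#' @param min_overlap_frac minimum overlap fraction (default 0.5).
#' @return data.frame per type: `n_assigned`, `n_transcribed`, `fraction`,
#'   `p_value`; NA rows when nothing is assignable.
#' @export
strandBias <- function(hits, genes, min_overlap_frac = 0.5) {
  if (length(genes) == 0 || length(hits) == 0) {
    warning("no annotation or no hits; strand bias undefined")
    return(data.frame(type_label = character(), n_assigned = integer(),
                      n_transcribed = integer(), fraction = numeric(),
                      p_value = numeric()))
  }
  ov <- GenomicRanges::findOverlaps(hits, genes, ignore.strand = TRUE)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(hits)[S4Vectors::queryHits(ov)],
    GenomicRanges::ranges(genes)[S4Vectors::subjectHits(ov)]))
  frac <- w / GenomicRanges::width(hits)[S4Vectors::queryHits(ov)]
  ov <- ov[frac >= min_overlap_frac]
  # a hit overlapping several genes adequately: use the first (toy and
  # real annotations rarely overlap on the same strand)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  hs <- as.character(GenomicRanges::strand(hits))[qh]
  gs <- as.character(GenomicRanges::strand(genes))[sh]
  transcribed <- hs != gs
  ty <- hits$type_label[qh]
  res <- lapply(split(seq_along(qh), ty), function(idx) {
    n <- length(idx); x <- sum(transcribed[idx])
    data.frame(type_label = ty[idx[1]], n_assigned = n,
               n_transcribed = x, fraction = x / n,
               p_value = binom.test(x, n, 0.5)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
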