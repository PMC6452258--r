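#' Simulate a ground-truthed spacer community
#'
#' Generates per-site strain lineages carrying CRISPR arrays with known
#' spacers, emulating the structure the pipeline assumes: several samples
#' per site, heavy-tailed strain abundances (log-normal, sdlog 1.5 by
#' default, which produces the singleton tail that coverage estimates and
#' the cluster-size filter act on), a configurable fraction of lineages
#' shared across all sites, and - for shared lineages - site-specific
#' turnover: spacers prepended at the leader-proximal end and trimmed from
#' the leader-distal end. Arrays store spacers leader-first; each array
#' fixes one concrete instance of its degenerate repeat consensus, as real
#' arrays do. Identical seed and configuration give identical truth.
#'
#' @param sites number of sites (default 3).
#' @param samples_per_site samples per site (default 2).
#' @param strains_per_site strain lineages present per site (default 4).
#' @param arrays_per_strain CRISPR arrays per strain (default 2).
#' @param array_length integer range of spacers per array (default
#'   c(10, 35), the fragment-length range the analysis targets).
#' @param sharing fraction of each site's lineages drawn from a pool
#'   common to all sites, in \[0, 1\] (default 0.25).
#' @param leader_add range of site-specific spacers prepended at the
#'   leader end of shared arrays (default c(0, 3)).
#' @param distal_trim range of spacers trimmed from the distal end of
#'   shared arrays (default c(0, 3)).
#' @param repeats a [RepeatSet-class] (default [thermusRepeats()]); array
#'   types are drawn uniformly from it and spacer lengths uniformly
#'   within each type's expected band (+/- 2 nt jitter).
#' @param abundance_sdlog sdlog of the log-normal site-level strain
#'   abundances (default 1.5).
#' @param sample_sdlog sdlog of the per-sample log-normal abundance noise
#'   around the site-level component (default 0.3).
#' @param seed RNG seed (required; part of the recorded config).
#' @return a [CommunityTruth-class].
#' @export
simulateCommunity <- function(sites = 3L, samples_per_site = 2L,
                              strains_per_site = 4L,
                              arrays_per_strain = 2L,
                              array_length = c(10L, 35L),
                              sharing = 0.25,
                              leader_add = c(0L, 3L),
                              distal_trim = c(0L, 3L),
                              repeats = thermusRepeats(),
                              abundance_sdlog = 1.5, sample_sdlog = 0.3,
                              seed = 1L) {
  if (sharing < 0 || sharing > 1)
    stop("sharing fraction must lie in [0, 1]")
  stopifnot(sites >= 1, strains_per_site >= 1, arrays_per_strain >= 1,
            length(array_length) == 2, array_length[1] >= 2)
  set.seed(seed)
  tb <- repeats@table
  site_ids <- paste0("site", seq_len(sites))
  samples <- data.frame(
    sample_id = paste0(rep(site_ids, each = samples_per_site), "_s",
                       rep(seq_len(samples_per_site), sites)),
    site_id = rep(site_ids, each = samples_per_site),
    stringsAsFactors = FALSE)

  n_shared <- round(sharing * strains_per_site)
  n_private <- strains_per_site - n_shared
  lineage_ids <- c(if (n_shared) paste0("Lsh", seq_len(n_shared)),
                   if (n_private) paste0("Lpr", seq_len(n_private * sites)))
  lineages <- data.frame(lineage_id = lineage_ids,
                         shared = grepl("^Lsh", lineage_ids),
                         stringsAsFactors = FALSE)

  # real spacers containing a repeat-terminus fragment are unextractable
  # (the repeat-anchored definition rejects them); draw spacers clean of
  # the first/last 8 nt of their type's consensus at <= 1 mismatch
  term8 <- lapply(setNames(tb$sequence, tb$type_label), function(p) {
    n <- nchar(p)
    unique(c(substr(p, 1, min(8, n)), substr(p, max(1, n - 7), n)))
  })
  rand_spacer <- function(len, type) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      clean <- !any(vapply(term8[[type]], function(t8)
        length(.scan_iupac(s, t8, 1L, TRUE)$start) > 0, logical(1)))
      if (clean) return(s)
    }
  }
  mk_array <- function() {
    i <- sample.int(nrow(tb), 1)
    n_sp <- .sample1(seq(array_length[1], array_length[2]))
    len0 <- tb$expected_spacer_length[i]
    lens <- len0 + sample(-2:2, n_sp, replace = TRUE)
    list(type_label = tb$type_label[i],
         repeat_instance = instantiateConsensus(tb$sequence[i]),
         spacers = vapply(lens, rand_spacer, character(1),
                          type = tb$type_label[i]))
  }
  base_arrays <- lapply(lineage_ids, function(l)
    replicate(arrays_per_strain, mk_array(), simplify = FALSE))
  names(base_arrays) <- lineage_ids

  strains <- list(); arrays <- list(); si <- 0L
  private_pool <- lineage_ids[!lineages$shared]
  for (s in seq_len(sites)) {
    mine <- c(lineage_ids[lineages$shared],
              private_pool[seq_len(n_private) + (s - 1L) * n_private])
    for (l in mine) {
      si <- si + 1L
      strain_id <- sprintf("str%03d", si)
      strains[[si]] <- data.frame(strain_id = strain_id, lineage_id = l,
                                  site_id = site_ids[s],
                                  stringsAsFactors = FALSE)
      aa <- base_arrays[[l]]
      if (lineages$shared[lineages$lineage_id == l]) {
        aa <- lapply(aa, function(ar) {
          add <- .sample1(seq(leader_add[1], leader_add[2]))
          trim <- .sample1(seq(distal_trim[1], distal_trim[2]))
          trim <- min(trim, length(ar$spacers) - 2L)
          sp <- ar$spacers
          if (trim > 0) sp <- sp[seq_len(length(sp) - trim)]
          if (add > 0) {
            len0 <- tb$expected_spacer_length[tb$type_label ==
                                                ar$type_label]
            sp <- c(vapply(len0 + sample(-2:2, add, replace = TRUE),
                           rand_spacer, character(1),
                           type = ar$type_label), sp)
          }
          ar$spacers <- sp
          ar
        })
      }
      arrays[[strain_id]] <- aa
    }
  }
  strains <- do.call(rbind, strains)
  # strain abundance: a heavy-tailed site-level component shared by all
  # samples of a site (so within-site repertoire frequencies correlate),
  # modulated by milder per-sample noise
  site_weight <- setNames(
    stats::rlnorm(nrow(strains), 0, abundance_sdlog), strains$strain_id)
  abund <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    st <- strains$strain_id[strains$site_id == samples$site_id[i]]
    data.frame(sample_id = samples$sample_id[i], strain_id = st,
               weight = site_weight[st] *
                 stats::rlnorm(length(st), 0, sample_sdlog),
               stringsAsFactors = FALSE)
  }))
  rownames(abund) <- NULL
  new("CommunityTruth", sites = site_ids, samples = samples,
      lineages = lineages, strains = strains, abundances = abund,
      arrays = arrays, phages = list(), reads = list(),
      config = list(sites = sites, samples_per_site = samples_per_site,
                    strains_per_site = strains_per_site,
                    arrays_per_strain = arrays_per_strain,
                    array_length = array_length, sharing = sharing,
                    leader_add = leader_add, distal_trim = distal_trim,
                    abundance_sdlog = abundance_sdlog,
                    sample_sdlog = sample_sdlog, seed = seed))
}

#' All distinct spacers of a truth object, with site presence
#' @param truth a [CommunityTruth-class]
#' @return data.frame: `sequence`, `type_label`, `sites`
#'   (comma-separated), `n_sites`.
#' @export
truthSpacerTable <- function(truth) {
  rows <- list(); k <- 0L
  for (st in names(truth@arrays)) {
    site <- truth@strains$site_id[truth@strains$strain_id == st]
    for (ar in truth@arrays[[st]]) {
      k <- k + 1L
      rows[[k]] <- data.frame(sequence = ar$spacers,
                              type_label = ar$type_label, site_id = site,
                              stringsAsFactors = FALSE)
    }
  }
  df <- unique(do.call(rbind, rows))
  agg <- lapply(split(df, paste(df$sequence, df$type_label)), function(d)
    data.frame(sequence = d$sequence[1], type_label = d$type_label[1],
               sites = paste(sort(unique(d$site_id)), collapse = ","),
               n_sites = length(unique(d$site_id)),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Plant protospacers (with PAMs) in synthetic phage genomes
#'
#' Draws protospacers from the community's spacers, writes them - with the
#' per-type PAM trinucleotide/tetramer on the 5' flank - at random
#' non-overlapping loci of random-background genomes, and records every
#' planting in the truth. Each phage is assigned an isolation site;
#' `local_fraction` of its protospacers come from spacers of that site
#' (the remainder from other sites), creating the locality structure the
#' Fisher test measures. IIIAB plantings receive no PAM; when
#' `iiiab_transcribed_only` is set they are placed on the transcribed
#' (template) strand of the toy gene at their locus. A toy annotation of
#' alternating-strand gene blocks is generated for strand-bias analysis.
#'
#' @param truth a [CommunityTruth-class].
#' @param n_phages number of phage genomes (default 2).
#' @param protospacers_per_phage plantings per phage (default 20).
#' @param pam named character vector: type -> 5'-flank motif written
#'   immediately upstream (IUPAC allowed; default AAG for I-E, GGTN for
#'   I-B, TTC for I-C and I-U).
#' @param genome_length phage genome length, nt (default 30000).
#' @param mutations substitutions applied to each planted protospacer
#'   (default 0).
#' @param local_fraction fraction of plantings drawn from the phage's own
#'   site (default 0.9).
#' @param iiiab_transcribed_only place IIIAB protospacers on the template
#'   strand of their gene (default TRUE).
#' @param gene_block toy gene length, nt (default 2000; genes alternate
#'   strand).
#' @param seed RNG seed.
#' @return the truth with `@phages` filled: `genomes` (named character),
#'   `plantings` (data.frame: phage, site_id, spacer sequence/type/site,
#'   start0, strand, pam), `genes` (data.frame: phage, start, end,
#'   strand), `gff` lines.
#' @export
simulatePhages <- function(truth, n_phages = 2L,
                           protospacers_per_phage = 20L,
                           pam = c("I-E" = "AAG", "I-B" = "GGTN",
                                   "I-C" = "TTC", "I-U" = "TTC"),
                           genome_length = 30000L, mutations = 0L,
                           local_fraction = 0.9,
                           iiiab_transcribed_only = TRUE,
                           gene_block = 2000L, seed = 1L) {
  stopifnot(is(truth, "CommunityTruth"))
  set.seed(seed)
  sp_tab <- truthSpacerTable(truth)
  sp_tab$site_first <- vapply(strsplit(sp_tab$sites, ","), `[`, "", 1)
  max_need <- max(nchar(sp_tab$sequence)) + 8L
  if (genome_length < protospacers_per_phage * (max_need + 20L) * 2L)
    stop("genome too short for the requested number of plantings")
  genomes <- character(0); plant <- list(); genes <- list(); pk <- 0L
  for (ph in seq_len(n_phages)) {
    phid <- paste0("phage", ph)
    g <- paste(sample(c("A", "C", "G", "T"), genome_length,
                      replace = TRUE), collapse = "")
    phage_site <- truth@sites[1 + (ph - 1) %% length(truth@sites)]
    # toy genes: alternating strand blocks
    gstart <- seq(1L, genome_length - gene_block + 1L, by = gene_block)
    gdf <- data.frame(phage = phid, start = gstart,
                      end = pmin(gstart + gene_block - 1L, genome_length),
                      strand = rep(c("+", "-"),
                                   length.out = length(gstart)),
                      stringsAsFactors = FALSE)
    genes[[ph]] <- gdf
    is_local <- sp_tab$site_first == phage_site
    n_loc <- round(local_fraction * protospacers_per_phage)
    loc_idx <- which(is_local); for_idx <- which(!is_local)
    n_loc_take <- min(n_loc, length(loc_idx))
    n_for_take <- min(protospacers_per_phage - n_loc_take, length(for_idx))
    pick <- c(loc_idx[sample.int(length(loc_idx), n_loc_take)],
              for_idx[sample.int(length(for_idx), n_for_take)])
    used <- IRanges::IRanges()
    for (i in pick) {
      sp <- sp_tab$sequence[i]; ty <- sp_tab$type_label[i]
      L <- nchar(sp)
      # find a free locus (8 nt flank margins, inside one gene block so
      # the toy annotation assigns the hit unambiguously)
      for (try in 1:200) {
        s0 <- .sample1(9L:(genome_length - L - 8L))  # 1-based start
        cand <- IRanges::IRanges(s0 - 8L, s0 + L + 7L)
        blk <- findInterval(c(s0, s0 + L - 1L), gdf$start)
        if (blk[1] == blk[2] &&
            (length(used) == 0 ||
             !any(IRanges::overlapsAny(cand, used)))) break
        s0 <- NA
      }
      if (is.na(s0)) next
      used <- c(used, IRanges::IRanges(s0 - 8L, s0 + L + 7L))
      if (ty == "IIIAB" && iiiab_transcribed_only) {
        gene_strand <- gdf$strand[findInterval(s0, gdf$start)]
        std <- if (gene_strand == "+") "-" else "+"
      } else std <- sample(c("+", "-"), 1)
      proto <- sp
      if (mutations > 0) {
        pos <- sample.int(L, min(mutations, L))
        ch <- strsplit(proto, "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1)
        proto <- paste(ch, collapse = "")
      }
      pm <- if (ty %in% names(pam)) instantiateConsensus(pam[[ty]]) else ""
      ins <- if (std == "+") paste0(pm, proto) else
        .revcomp(paste0(pm, proto))
      at <- if (std == "+") s0 - nchar(pm) else s0
      substr(g, at, at + nchar(ins) - 1L) <- ins
      proto_start0 <- s0 - 1L  # protospacer occupies [s0, s0+L-1] on both strands
      pk <- pk + 1L
      plant[[pk]] <- data.frame(
        phage = phid, phage_site = phage_site, sequence = sp,
        protospacer = proto, type_label = ty,
        spacer_sites = sp_tab$sites[i], start0 = proto_start0,
        strand = std, pam = if (nzchar(pm)) pm else NA_character_,
        stringsAsFactors = FALSE)
    }
    genomes[phid] <- g
  }
  plantings <- if (pk) do.call(rbind, plant) else
    data.frame(phage = character(), phage_site = character(),
               sequence = character(), protospacer = character(),
               type_label = character(), spacer_sites = character(),
               start0 = integer(), strand = character(),
               pam = character())
  rownames(plantings) <- NULL
  gn <- do.call(rbind, genes)
  truth@phages <- list(genomes = genomes, plantings = plantings,
                       genes = gn,
                       sites = setNames(
                         truth@sites[1 + (seq_len(n_phages) - 1) %%
                                       length(truth@sites)],
                         paste0("phage", seq_len(n_phages))))
  truth
}

#' Simulate repeat-spacer amplicon reads
#'
#' Builds reads spanning 1-4 repeat-spacer units (a spacer run flanked by
#' full repeats on both sides, the amplification ladder the protocol
#' produces): a strain is drawn by abundance, one of its arrays and a
#' window of consecutive spacers are chosen, the read is assembled as
#' repeat-spacer-...-repeat using the array's concrete repeat instance,
#' reverse-complemented with probability 0.5, and per-base substitution
#' errors applied under a uniform Phred quality model. Per-read provenance
#' (strain, array, spacer window, orientation) is recorded in the truth.
#'
#' @param truth a [CommunityTruth-class].
#' @param reads_per_sample reads per sample (default 2000).
#' @param unit_probs probabilities of 1-4 spacers per read (default
#'   c(0.4, 0.3, 0.2, 0.1)).
#' @param error_rate per-base substitution probability in \[0, 0.05\]
#'   (default 0.005).
#' @param phred constant Phred score of simulated bases (default 37).
#' @param seed RNG seed.
#' @return the truth with `@reads` filled: per sample a list with `seqs`
#'   (named character), `quals` (character), `provenance` (data.frame).
#' @export
simulateReads <- function(truth, reads_per_sample = 2000L,
                          unit_probs = c(0.4, 0.3, 0.2, 0.1),
                          error_rate = 0.005, phred = 37L, seed = 1L) {
  stopifnot(is(truth, "CommunityTruth"))
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (smp in truth@samples$sample_id) {
    ab <- truth@abundances[truth@abundances$sample_id == smp, ]
    seqs <- character(reads_per_sample)
    prov <- vector("list", reads_per_sample)
    for (r in seq_len(reads_per_sample)) {
      st <- sample(ab$strain_id, 1, prob = ab$weight)
      ars <- truth@arrays[[st]]
      ai <- sample.int(length(ars), 1)
      ar <- ars[[ai]]
      k <- min(sample.int(length(unit_probs), 1, prob = unit_probs),
               length(ar$spacers))
      first <- sample.int(length(ar$spacers) - k + 1L, 1)
      win <- seq(first, first + k - 1L)
      read <- paste0(ar$repeat_instance,
                     paste(vapply(win, function(i)
                       paste0(ar$spacers[i], ar$repeat_instance),
                       character(1)), collapse = ""))
      flip <- stats::runif(1) < 0.5
      if (flip) read <- .revcomp(read)
      if (error_rate > 0) {
        ch <- strsplit(read, "")[[1]]
        err <- which(stats::runif(length(ch)) < error_rate)
        for (p in err) ch[p] <- sample(setdiff(bases, ch[p]), 1)
        read <- paste(ch, collapse = "")
      }
      seqs[r] <- read
      prov[[r]] <- data.frame(read_id = sprintf("%s_r%06d", smp, r),
                              strain_id = st, array_index = ai,
                              first_spacer = first, n_spacers = k,
                              flipped = flip, stringsAsFactors = FALSE)
    }
    names(seqs) <- sprintf("%s_r%06d", smp, seq_len(reads_per_sample))
    out[[smp]] <- list(seqs = seqs,
                       quals = vapply(nchar(seqs), function(n)
                         strrep(rawToChar(as.raw(phred + 33L)), n),
                         character(1)),
                       provenance = do.call(rbind, prov))
  }
  truth@reads <- out
  truth@config$reads <- list(reads_per_sample = reads_per_sample,
                             unit_probs = unit_probs,
                             error_rate = error_rate, phred = phred,
                             read_seed = seed)
  truth
}

#' Write simulated reads as FASTQ
#' @param truth a [CommunityTruth-class] with reads simulated.
#' @param dir output directory (created if needed).
#' @return named character vector of written FASTQ paths.
#' @export
writeReadsFastq <- function(truth, dir) {
  stopifnot(length(truth@reads) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (smp in names(truth@reads)) {
    rd <- truth@reads[[smp]]
    p <- file.path(dir, paste0(smp, ".fastq"))
    con <- file(p, "w")
    writeLines(paste0("@", names(rd$seqs), "\n", rd$seqs, "\n+\n",
                      rd$quals), con)
    close(con)
    paths[smp] <- p
  }
  paths
}

#' Write simulated phage genomes as FASTA (+ toy GFF3)
#' @param truth a [CommunityTruth-class] with phages simulated.
#' @param dir output directory.
#' @return list with `fasta` and `gff3` paths.
#' @export
writePhageFiles <- function(truth, dir) {
  stopifnot(length(truth@phages) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "phages.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth@phages$genomes), fa)
  gf <- file.path(dir, "phages.gff3")
  gn <- truth@phages$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tspacerscope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     gn$phage, gn$start, gn$end, gn$strand,
                     sprintf("gene_%s_%d", gn$phage, gn$start)))
  writeLines(lines, gf)
  list(fasta = fa, gff3 = gf)
}

#' Toy gene annotation as GRanges
#' @param truth a [CommunityTruth-class] with phages simulated.
#' @return GRanges of gene features.
#' @export
truthGenes <- function(truth) {
  gn <- truth@phages$genes
  GenomicRanges::GRanges(gn$phage,
                         IRanges::IRanges(gn$start, gn$end),
                         strand = gn$strand)
}

#' Serialize / restore a CommunityTruth
#'
#' Round-trip-safe JSON serialization of the whole ground truth (reads
#' included), so simulated datasets can be archived alongside FASTQ/FASTA
#' outputs.
#'
#' @param truth a [CommunityTruth-class].
#' @param path JSON file path.
#' @return `writeTruth` the path, invisibly; `readTruth` the restored
#'   [CommunityTruth-class].
#' @export
writeTruth <- function(truth, path) {
  # flatten the nested array list into two tables so the JSON round-trip
  # is unambiguous
  arr_rows <- list(); sp_rows <- list(); k <- 0L
  for (st in names(truth@arrays)) {
    for (ai in seq_along(truth@arrays[[st]])) {
      ar <- truth@arrays[[st]][[ai]]
      k <- k + 1L
      arr_rows[[k]] <- data.frame(strain_id = st, array_index = ai,
                                  type_label = ar$type_label,
                                  repeat_instance = ar$repeat_instance,
                                  stringsAsFactors = FALSE)
      sp_rows[[k]] <- data.frame(strain_id = st, array_index = ai,
                                 position = seq_along(ar$spacers),
                                 sequence = ar$spacers,
                                 stringsAsFactors = FALSE)
    }
  }
  phages <- truth@phages
  if (length(phages)) {
    # named atomic vectors lose names in JSON arrays; store as objects
    phages$genomes <- as.list(phages$genomes)
    phages$sites <- as.list(phages$sites)
  }
  reads <- lapply(truth@reads, function(rd)
    list(seqs = as.list(rd$seqs), quals = rd$quals,
         provenance = rd$provenance))
  x <- list(sites = truth@sites, samples = truth@samples,
            lineages = truth@lineages, strains = truth@strains,
            abundances = truth@abundances,
            array_table = do.call(rbind, arr_rows),
            array_spacers = do.call(rbind, sp_rows),
            phages = phages, reads = reads,
            config = truth@config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  at <- as.data.frame(x$array_table)
  asp <- as.data.frame(x$array_spacers)
  arrays <- list()
  for (r in seq_len(nrow(at))) {
    st <- at$strain_id[r]; ai <- at$array_index[r]
    sel <- asp$strain_id == st & asp$array_index == ai
    sp <- asp$sequence[sel][order(asp$position[sel])]
    if (is.null(arrays[[st]])) arrays[[st]] <- list()
    arrays[[st]][[ai]] <- list(type_label = at$type_label[r],
                               repeat_instance = at$repeat_instance[r],
                               spacers = sp)
  }
  reads <- lapply(x$reads, function(rd)
    list(seqs = setNames(unlist(rd$seqs), names(rd$seqs)),
         quals = unlist(rd$quals),
         provenance = as.data.frame(rd$provenance)))
  phages <- x$phages
  if (length(phages)) {
    phages$genomes <- setNames(unlist(phages$genomes),
                               names(phages$genomes))
    phages$sites <- setNames(unlist(phages$sites), names(phages$sites))
  }
  new("CommunityTruth", sites = x$sites,
      samples = as.data.frame(x$samples),
      lineages = as.data.frame(x$lineages),
      strains = as.data.frame(x$strains),
      abundances = as.data.frame(x$abundances),
      arrays = arrays,
      phages = if (length(phages)) phages else list(),
      reads = reads, config = x$config)
}

# length-safe single draw (sample() treats a scalar as 1:n)
.sample1 <- function(x) x[sample.int(length(x), 1L)]
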