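#' Run the spacer-profiling pipeline end to end
#'
#' Orchestrates simulate (optional) -> extract -> cluster -> diversity /
#' sharing -> assemble -> protospacer map, writing every stage's table to
#' `out_dir` along with the serialized configuration, its MD5 hash and a
#' per-stage record-count log. Stages communicate through documented
#' TSV/FASTA files so a run is auditable and resumable; the same config
#' and seed give bit-identical reports.
#'
#' @param config either a list or a path to a JSON/YAML file. Recognized
#'   entries (defaults in parentheses): `seed` (1); `out_dir` (required);
#'   `simulate`: list passed to [simulateCommunity()] /
#'   [simulatePhages()] / [simulateReads()] - or instead `reads`: named
#'   FASTQ paths with `samples` data.frame (sample_id, site_id),
#'   `targets`: FASTA path, `gff`: GFF3 path; `repeats`: TSV path
#'   (packaged default); `max_mismatch` (3); `identity` (0.85);
#'   `min_size` (11); `min_support` (2); `min_identity` (0.85).
#' @return invisibly, a list with every stage's objects and the report
#'   paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  logf <- file.path(out, "run.log")
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  log("config hash %s", unname(tools::md5sum(cfg_path)))

  repeats <- if (!is.null(config$repeats))
    readRepeatTable(config$repeats) else thermusRepeats()
  max_mm <- config$max_mismatch %||% 3L

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth <- do.call(simulateCommunity, c(
      sim$community %||% list(),
      list(repeats = repeats, seed = seed)))
    truth <- do.call(simulatePhages, c(sim$phages %||% list(),
                                       list(truth = truth, seed = seed + 1L)))
    truth <- do.call(simulateReads, c(sim$reads %||% list(),
                                      list(truth = truth, seed = seed + 2L)))
    writeTruth(truth, file.path(out, "truth.json"))
    read_sets <- lapply(truth@reads, `[[`, "seqs")
    samples <- truth@samples
    targets <- truth@phages$genomes
    genes <- truthGenes(truth)
    target_sites <- truth@phages$sites
    log("simulate: %d sites, %d samples, %d reads/sample",
        length(truth@sites), nrow(samples),
        length(read_sets[[1]]))
  } else {
    stopifnot(!is.null(config$reads), !is.null(config$samples))
    samples <- as.data.frame(config$samples)
    missing <- !file.exists(unlist(config$reads))
    if (any(missing))
      stop("missing read file(s): ",
           paste(unlist(config$reads)[missing], collapse = ", "))
    read_sets <- config$reads
    targets <- if (!is.null(config$targets)) config$targets else NULL
    genes <- if (!is.null(config$gff)) rtracklayer::import(config$gff)
      else NULL
    target_sites <- config$target_sites %||% NULL
  }

  obs <- combineObservations(lapply(seq_len(nrow(samples)), function(i) {
    smp <- samples$sample_id[i]
    extractSpacers(read_sets[[smp]], repeats, max_mismatch = max_mm,
                   sample_id = smp, site_id = samples$site_id[i])
  }))
  writeObservationsTSV(obs, file.path(out, "observations.tsv"))
  log("extract: %d spacer observations, %d flagged reads",
      nrow(observationTable(obs)), nrow(obs@flags))

  cset <- clusterSpacers(obs, identity = config$identity %||% 0.85)
  log("cluster: %d clusters from %d reads",
      nrow(clusterTable(cset)), sum(clusterTable(cset)$size))
  kept <- filterClusters(cset, min_size = config$min_size %||% 11L)
  log("filter: retained %d/%d clusters (size >= %d)",
      kept@params$filter$retained, kept@params$filter$total,
      kept@params$filter$min_size)
  writeClustersTSV(kept, file.path(out, "clusters.tsv"))
  writeCentresFasta(kept, file.path(out, "centres.fasta"))

  stats <- alphaDiversityTable(cset)
  .write_tsv(stats, file.path(out, "sample_stats.tsv"))

  mt <- matchAcross(kept, group_by = "site_id")
  sharing <- data.frame(shared_by_sites = names(mt$shared_by),
                        components = as.integer(mt$shared_by))
  .write_tsv(sharing, file.path(out, "sharing.tsv"))
  log("share: %d unique spacers globally, %d per-site union",
      mt$n_components, mt$n_union)

  beta <- NULL
  if (nrow(samples) >= 2) {
    mt_s <- matchAcross(kept, group_by = "sample_id")
    am <- abundanceMatrix(mt_s)
    if (nrow(am) >= 2) {
      beta <- betaDiversity(am)
      .write_tsv(data.frame(sample = rownames(beta$bray), beta$bray),
                 file.path(out, "beta_bray.tsv"))
      writeLines(beta$newick, file.path(out, "samples.upgma.nwk"))
    }
  }

  adj <- buildAdjacency(obs, kept,
                        min_support = config$min_support %||% 2L)
  frags <- assembleFragments(adj)
  writeFragmentsTSV(frags, file.path(out, "fragments.tsv"))
  writeAdjacencyDOT(adj, file.path(out, "adjacency.dot"))
  log("assemble: %d edges -> %d fragments", nrow(edgeTable(adj)),
      nrow(fragmentTable(frags)))

  hits <- NULL; pams <- NULL; locality <- NULL; bias <- NULL
  if (!is.null(targets)) {
    cl <- clusterTable(kept)
    meta <- data.frame(spacer_id = cl$cluster_id,
                       type_label = cl$type_label, site_id = cl$site_id,
                       stringsAsFactors = FALSE)
    hits <- searchProtospacers(
      setNames(cl$centre, cl$cluster_id), targets,
      min_identity = config$min_identity %||% 0.85, spacer_meta = meta)
    writeHitsTSV(hits, file.path(out, "hits.tsv"))
    log("map: %d protospacer hits", length(hits))
    if (length(hits)) {
      # types with too few flanks get count matrices but no consensus
      pams <- suppressWarnings(pamByType(hits))
      pam_df <- data.frame(
        type_label = names(pams),
        n_flanks = vapply(pams, slot, integer(1), "n_flanks"),
        consensus_up = vapply(pams, slot, character(1), "consensus_up"),
        consensus_down = vapply(pams, slot, character(1),
                                "consensus_down"))
      .write_tsv(pam_df, file.path(out, "pam_consensus.tsv"))
      if (!is.null(target_sites)) {
        locality <- localityTable(hits,
                                  setNames(cl$site_id, cl$cluster_id),
                                  target_sites)
        .write_tsv(as.data.frame(locality$site_counts),
                   file.path(out, "hits_by_site.tsv"))
      }
      if (!is.null(genes) && length(genes))
        bias <- strandBias(hits, genes)
      if (!is.null(bias))
        .write_tsv(bias, file.path(out, "strand_bias.tsv"))
    }
  }
  log("done")
  invisible(list(truth = truth, observations = obs, clusters = cset,
                 retained = kept, stats = stats, sharing = mt,
                 beta = beta, adjacency = adj, fragments = frags,
                 hits = hits, pams = pams, locality = locality,
                 strand_bias = bias, out_dir = out))
}
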