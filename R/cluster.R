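#' Full-length identity with free end gaps
#'
#' Best ungapped overlap alignment of two sequences (internal gaps
#' disallowed, terminal overhangs free), maximizing matches; identity is
#' matches divided by the length of the shorter sequence - the denominator
#' convention used by the clustering threshold.
#'
#' @param a,b DNA strings.
#' @return identity fraction in \[0, 1\].
#' @examples
#' endgapIdentity("ACGTACGT", "CGTACGT")  # 1: one terminal base trimmed
#' @export
endgapIdentity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  al <- .overlap_align(toupper(a), toupper(b))
  al$matches / min(nchar(a), nchar(b))
}

#' Cluster spacer observations at an identity threshold
#'
#' UCLUST-style greedy clustering, run separately for every (sample, repeat
#' type) group: unique sequences are processed in decreasing read-count
#' order (ties broken lexicographically); each sequence joins the first
#' existing cluster whose centre it matches at `>= identity` (full-length
#' identity, free end gaps, shorter-sequence denominator), otherwise it
#' seeds a new cluster. Centres are finalized as the most abundant member
#' (ties toward the lexicographically smallest sequence). The procedure is
#' deterministic and invariant to the input record order.
#'
#' @param obs a [SpacerObservations-class].
#' @param identity identity threshold in (0, 1\]; default 0.85.
#' @return a [SpacerClusterSet-class].
#' @export
clusterSpacers <- function(obs, identity = 0.85) {
  stopifnot(is(obs, "SpacerObservations"), identity > 0, identity <= 1)
  df <- obs@observations
  clusters <- list(); members <- list(); ci <- 0L
  grp <- paste(df$sample_id, df$type_label, sep = "\r")
  for (key in sort(unique(grp))) {
    sub <- df[grp == key, , drop = FALSE]
    cnt <- tapply(sub$read_support, sub$sequence, sum)
    uq <- data.frame(sequence = names(cnt), count = as.integer(cnt),
                     stringsAsFactors = FALSE)
    uq <- uq[order(-uq$count, uq$sequence), , drop = FALSE]
    centres <- character(0); assign <- integer(nrow(uq))
    for (i in seq_len(nrow(uq))) {
      hit <- 0L
      for (k in seq_along(centres)) {
        if (endgapIdentity(uq$sequence[i], centres[k]) >= identity) {
          hit <- k; break
        }
      }
      if (hit == 0L) {
        centres <- c(centres, uq$sequence[i])
        hit <- length(centres)
      }
      assign[i] <- hit
    }
    for (k in seq_along(centres)) {
      mem <- uq[assign == k, , drop = FALSE]
      # centre = most abundant member; seed order guarantees the seed is
      # maximal, but re-derive for the tie rule
      best <- mem[order(-mem$count, mem$sequence), , drop = FALSE][1, ]
      ci <- ci + 1L
      id <- sprintf("%s|%s|c%05d", sub$sample_id[1], sub$type_label[1], ci)
      clusters[[ci]] <- data.frame(
        cluster_id = id, sample_id = sub$sample_id[1],
        site_id = sub$site_id[1], type_label = sub$type_label[1],
        centre = best$sequence, size = sum(mem$count),
        n_unique = nrow(mem), stringsAsFactors = FALSE)
      members[[ci]] <- data.frame(cluster_id = id, sequence = mem$sequence,
                                  count = mem$count,
                                  stringsAsFactors = FALSE)
    }
  }
  empty_c <- data.frame(cluster_id = character(), sample_id = character(),
                        site_id = character(), type_label = character(),
                        centre = character(), size = integer(),
                        n_unique = integer())
  empty_m <- data.frame(cluster_id = character(), sequence = character(),
                        count = integer())
  cl <- if (ci) do.call(rbind, clusters) else empty_c
  rownames(cl) <- NULL
  new("SpacerClusterSet", clusters = cl,
      members = if (ci) do.call(rbind, members) else empty_m,
      params = list(identity = identity))
}

#' Retain clusters above a read-count floor
#'
#' Keeps clusters whose total read count is at least `min_size` (the
#' default 11 implements the "more than 10 reads" retention rule that
#' guards downstream repertoire comparisons against undersequenced
#' singletons).
#'
#' @param cset a [SpacerClusterSet-class].
#' @param min_size minimum retained size (default 11).
#' @return a filtered [SpacerClusterSet-class]; the retained/total tally is
#'   stored in `@params$filter`.
#' @export
filterClusters <- function(cset, min_size = 11L) {
  stopifnot(is(cset, "SpacerClusterSet"))
  keep <- cset@clusters$size >= min_size
  if (!any(keep)) warning("all clusters removed by the size filter")
  cl <- cset@clusters[keep, , drop = FALSE]
  rownames(cl) <- NULL
  mem <- cset@members[cset@members$cluster_id %in% cl$cluster_id, ,
                      drop = FALSE]
  rownames(mem) <- NULL
  p <- cset@params
  p$filter <- list(min_size = min_size, retained = sum(keep),
                   total = length(keep),
                   reads_retained = sum(cl$size),
                   reads_total = sum(cset@clusters$size))
  new("SpacerClusterSet", clusters = cl, members = mem, params = p)
}

#' Match cluster centres across samples, sites or genomes
#'
#' Applies the "fewer than two mismatches" identity rule between centres of
#' the same repeat type: equal-length pairs are matched at Hamming
#' distance <= `max_mismatch`; length-mismatched pairs by the best
#' end-gap-free overlap with <= `max_mismatch` mismatches and total
#' overhang <= `max_overhang` (an extension of the rule, flagged in the
#' edge table via `overlap`). Matched centres are merged into connected
#' components; the component count is the number of unique spacers.
#' Cross-type coincidences (>= 20 nt overlap at <= 1 mismatch between
#' centres of different types) are reported separately as independent
#' acquisition candidates.
#'
#' @param cset a [SpacerClusterSet-class] (typically several samples
#'   combined, after [filterClusters()]).
#' @param max_mismatch maximum mismatches (default 1, i.e. "fewer than
#'   two").
#' @param max_overhang maximum total overhang for unequal lengths
#'   (default 2).
#' @param group_by which label defines a repertoire group for sharing
#'   counts: "sample_id" (default) or "site_id".
#' @return list with `centres` (data.frame incl. `component`), `edges`,
#'   `cross_type_edges`, `n_components` (unique spacers over all groups),
#'   `n_union` (sum over groups of per-group component presence, i.e. the
#'   per-location merged counting), `shared_by` (table: number of
#'   components present in k groups), `group_by`.
#' @export
matchAcross <- function(cset, max_mismatch = 1L, max_overhang = 2L,
                        group_by = c("sample_id", "site_id")) {
  stopifnot(is(cset, "SpacerClusterSet"))
  group_by <- match.arg(group_by)
  cl <- cset@clusters
  if (!nrow(cl))
    return(list(centres = cl, edges = NULL, cross_type_edges = NULL,
                n_components = 0L, n_union = 0L,
                shared_by = table(integer(0)), group_by = group_by))
  cl$group <- cl[[group_by]]
  edges <- list(); k <- 0L
  for (ty in unique(cl$type_label)) {
    idx <- which(cl$type_label == ty)
    mp <- .match_pairs(cl$centre[idx], as.integer(max_mismatch),
                       as.integer(max_overhang), 1L, TRUE)
    if (length(mp$i)) {
      k <- k + 1L
      edges[[k]] <- data.frame(
        a = cl$cluster_id[idx[mp$i]], b = cl$cluster_id[idx[mp$j]],
        type_label = ty, mismatches = mp$mismatches,
        overlap = mp$overlap,
        context = ifelse(cl$site_id[idx[mp$i]] == cl$site_id[idx[mp$j]],
                         "within-site", "between-site"),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (k) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), type_label = character(),
               mismatches = integer(), overlap = integer(),
               context = character())
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = cl$cluster_id))
  comp <- igraph::components(g)$membership
  cl$component <- as.integer(unname(comp[cl$cluster_id]))

  # cross-type coincidences: candidates for independent acquisition
  ct <- .match_pairs(cl$centre, 1L, 2L * max(nchar(cl$centre)), 20L, FALSE)
  keep <- cl$type_label[ct$i] != cl$type_label[ct$j]
  cross <- data.frame(a = cl$cluster_id[ct$i[keep]],
                      b = cl$cluster_id[ct$j[keep]],
                      type_a = cl$type_label[ct$i[keep]],
                      type_b = cl$type_label[ct$j[keep]],
                      mismatches = ct$mismatches[keep],
                      overlap = ct$overlap[keep], stringsAsFactors = FALSE)

  pres <- unique(cl[, c("component", "group")])
  groups_per_comp <- table(table(pres$component))
  list(centres = cl, edges = edges, cross_type_edges = cross,
       n_components = as.integer(max(cl$component)),
       n_union = nrow(pres),
       shared_by = table(factor(as.integer(table(pres$component)),
                                levels = seq_len(length(unique(cl$group))))),
       group_by = group_by)
}
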