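#' Build the spacer adjacency graph from multi-spacer reads
#'
#' Consecutive spacers of one read (ordered by `index_in_source`, which is
#' already normalized to a consistent array direction) become directed
#' edges between their clusters, and runs of three consecutive spacers
#' become triples; support counts the reads showing each adjacency. Edges
#' (and triples) below `min_support` are pruned - the default of 2 kills
#' single-read PCR/sequencing chimeras. Observations whose sequence
#' belongs to no cluster of `cset` (e.g. removed by [filterClusters()])
#' are skipped.
#'
#' @param obs a [SpacerObservations-class].
#' @param cset a [SpacerClusterSet-class] used to translate spacer
#'   sequences into cluster ids (matched within the same sample and type).
#' @param min_support minimum read support per edge (default 2).
#' @param node_ids optional named vector mapping cluster_id to a pooled
#'   node id (e.g. `matchAcross()` components) so adjacency can be pooled
#'   across samples; default: per-sample cluster ids.
#' @return an [AdjacencyGraph-class].
#' @export
buildAdjacency <- function(obs, cset, min_support = 2L, node_ids = NULL) {
  stopifnot(is(obs, "SpacerObservations"), is(cset, "SpacerClusterSet"))
  df <- obs@observations
  mem <- cset@members
  cl <- cset@clusters
  key_cl <- setNames(cl$cluster_id, cl$cluster_id)
  # sequence -> cluster lookup within (sample, type)
  samp <- setNames(cl$sample_id, cl$cluster_id)[mem$cluster_id]
  ty <- setNames(cl$type_label, cl$cluster_id)[mem$cluster_id]
  lookup <- setNames(mem$cluster_id, paste(samp, ty, mem$sequence))
  node <- unname(lookup[paste(df$sample_id, df$type_label, df$sequence)])
  if (!is.null(node_ids)) node <- unname(node_ids[node])

  pair_keys <- list(); triple_keys <- list(); pk <- 0L; tk <- 0L
  grp <- paste(df$source_id, df$type_label, sep = "\r")
  ord <- order(df$index_in_source)
  for (idx in split(ord, grp[ord])) {
    nodes <- node[idx]
    keep <- !is.na(nodes)
    # adjacency requires truly consecutive spacers in the read
    ii <- df$index_in_source[idx]
    n <- length(nodes)
    if (n < 2) next
    tyl <- df$type_label[idx[1]]
    for (j in seq_len(n - 1)) {
      if (!keep[j] || !keep[j + 1] || ii[j + 1] != ii[j] + 1) next
      pk <- pk + 1L
      pair_keys[[pk]] <- c(tyl, nodes[j], nodes[j + 1])
    }
    if (n >= 3) for (j in seq_len(n - 2)) {
      if (!all(keep[j:(j + 2)]) || ii[j + 2] != ii[j] + 2) next
      tk <- tk + 1L
      triple_keys[[tk]] <- c(tyl, nodes[j], nodes[j + 1], nodes[j + 2])
    }
  }
  edges <- if (pk) {
    pm <- do.call(rbind, pair_keys)
    agg <- table(paste(pm[, 1], pm[, 2], pm[, 3], sep = "\r"))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    data.frame(type_label = vapply(parts, `[`, "", 1),
               from = vapply(parts, `[`, "", 2),
               to = vapply(parts, `[`, "", 3),
               support = as.integer(agg), stringsAsFactors = FALSE)
  } else data.frame(type_label = character(), from = character(),
                    to = character(), support = integer())
  triples <- if (tk) {
    tm <- do.call(rbind, triple_keys)
    agg <- table(paste(tm[, 1], tm[, 2], tm[, 3], tm[, 4], sep = "\r"))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    data.frame(type_label = vapply(parts, `[`, "", 1),
               a = vapply(parts, `[`, "", 2),
               b = vapply(parts, `[`, "", 3),
               c = vapply(parts, `[`, "", 4),
               support = as.integer(agg), stringsAsFactors = FALSE)
  } else data.frame(type_label = character(), a = character(),
                    b = character(), c = character(), support = integer())
  edges <- edges[edges$support >= min_support, , drop = FALSE]
  triples <- triples[triples$support >= min_support, , drop = FALSE]
  edges$self_loop <- edges$from == edges$to
  rownames(edges) <- rownames(triples) <- NULL
  new("AdjacencyGraph", edges = edges, triples = triples,
      params = list(min_support = min_support,
                    pooled = !is.null(node_ids)))
}

#' Assemble array fragments from the adjacency graph
#'
#' Walks maximal unambiguous chains: an edge is followed only when its
#' source has out-degree 1 and its target in-degree 1, so branching nodes
#' terminate fragments. Where a branching node can be phased - its triples
#' pair every in-neighbour with exactly one out-neighbour and vice versa -
#' the flanking chains are stitched through it. Cycles (possible when an
#' identical spacer recurs in an array) are broken at their lowest-support
#' edge and the affected fragments flagged. Output order is deterministic
#' (type, then first cluster id).
#'
#' @param g an [AdjacencyGraph-class].
#' @return an [ArrayFragmentSet-class]; single-spacer fragments are not
#'   reported (a fragment is at least one junction, i.e. 2 spacers).
#' @export
assembleFragments <- function(g) {
  stopifnot(is(g, "AdjacencyGraph"))
  ed_all <- g@edges[!g@edges$self_loop, , drop = FALSE]
  frag_rows <- list(); path_rows <- list(); fi <- 0L
  for (ty in unique(ed_all$type_label)) {
    ed <- ed_all[ed_all$type_label == ty, , drop = FALSE]
    tr <- g@triples[g@triples$type_label == ty, , drop = FALSE]
    nodes <- unique(c(ed$from, ed$to))
    outdeg <- table(factor(ed$from, levels = nodes))
    indeg <- table(factor(ed$to, levels = nodes))
    # unambiguous edges: unique successor of `from`, unique predecessor
    # of `to`
    unamb <- ed[outdeg[ed$from] == 1 & indeg[ed$to] == 1, , drop = FALSE]
    flag <- setNames(rep("", length(nodes)), nodes)
    nxt <- setNames(unamb$to, unamb$from)
    supp <- setNames(unamb$support, paste(unamb$from, unamb$to))
    # in/out degree <= 1 in the unambiguous subgraph, so its components
    # are simple paths or simple cycles; walk paths from their starts
    starts <- setdiff(unamb$from, unamb$to)
    chains <- list()
    for (s in sort(starts)) {
      p <- s
      while (!is.na(nxt[p[length(p)]] %||% NA))
        p <- c(p, unname(nxt[p[length(p)]]))
      chains[[length(chains) + 1L]] <- p
    }
    # any node with an unambiguous successor but not on a path lies on a
    # cycle (an identical spacer recurring): break at the weakest edge
    on_path <- unique(unlist(chains))
    cyc_nodes <- setdiff(unamb$from, on_path)
    while (length(cyc_nodes)) {
      s0 <- sort(cyc_nodes)[1]
      p <- s0
      repeat {
        nx <- unname(nxt[p[length(p)]])
        if (nx == s0) break
        p <- c(p, nx)
      }
      ring <- c(p, s0)
      es <- supp[paste(ring[-length(ring)], ring[-1])]
      weak <- which.min(es)
      # drop edge ring[weak] -> ring[weak + 1]; path starts after it
      ordered <- ring[-length(ring)]
      ordered <- c(ordered[-(seq_len(weak))], ordered[seq_len(weak)])
      flag[ordered] <- "cycle-broken"
      chains[[length(chains) + 1L]] <- ordered
      cyc_nodes <- setdiff(cyc_nodes, ordered)
    }
    # phase through branch nodes where triples give a perfect pairing
    branch <- nodes[indeg > 1 | outdeg > 1]
    for (x in branch) {
      txs <- tr[tr$b == x, , drop = FALSE]
      ins <- ed$from[ed$to == x]
      outs <- ed$to[ed$from == x]
      txs <- txs[txs$a %in% ins & txs$c %in% outs, , drop = FALSE]
      ok <- nrow(txs) >= 2 && length(ins) == length(outs) &&
        nrow(txs) == length(ins) && !anyDuplicated(txs$a) &&
        !anyDuplicated(txs$c) && setequal(txs$a, ins) &&
        setequal(txs$c, outs)
      if (!ok) next
      for (r in seq_len(nrow(txs))) {
        a <- txs$a[r]; cc <- txs$c[r]
        left <- Filter(function(ch) ch[length(ch)] == a, chains)
        right <- Filter(function(ch) ch[1] == cc, chains)
        lch <- if (length(left)) left[[1]] else a
        rch <- if (length(right)) right[[1]] else cc
        chains <- Filter(function(ch)
          !(identical(ch, lch) || identical(ch, rch)), chains)
        chains[[length(chains) + 1L]] <- c(lch, x, rch)
        supp[paste(a, x)] <- ed$support[ed$from == a & ed$to == x]
        supp[paste(x, cc)] <- ed$support[ed$from == x & ed$to == cc]
      }
    }
    # residual branch-to-branch edges still uncovered become 2-spacer
    # fragments only if both endpoints sit in no chain
    chains <- chains[order(vapply(chains, `[`, "", 1))]
    for (p in chains) {
      if (length(p) < 2) next
      fi <- fi + 1L
      id <- sprintf("frag%04d", fi)
      js <- supp[paste(p[-length(p)], p[-1])]
      frag_rows[[fi]] <- data.frame(
        fragment_id = id, type_label = ty, n_spacers = length(p),
        flag = paste(unique(flag[p][nzchar(flag[p])]), collapse = ";"),
        stringsAsFactors = FALSE)
      path_rows[[fi]] <- data.frame(
        fragment_id = id, position = seq_along(p) - 1L, cluster_id = p,
        support_next = c(as.integer(js), NA_integer_),
        stringsAsFactors = FALSE)
    }
  }
  empty_f <- data.frame(fragment_id = character(), type_label = character(),
                        n_spacers = integer(), flag = character())
  empty_p <- data.frame(fragment_id = character(), position = integer(),
                        cluster_id = character(), support_next = integer())
  fr <- if (fi) do.call(rbind, frag_rows) else empty_f
  fr$samples <- rep(NA_character_, nrow(fr))
  new("ArrayFragmentSet", fragments = fr,
      path = if (fi) do.call(rbind, path_rows) else empty_p)
}

#' Compare two array fragments
#'
#' Finds the longest common contiguous spacer block between two fragments
#' of the same type (spacers equated by the "fewer than two mismatches"
#' rule on their centre sequences) and classifies the relationship:
#' `identical`, `end-trimmed` (one fragment is an end block of the other;
#' the trimmed end and spacer count are reported), `partially-renewed`
#' (a shorter shared block with fragment-specific spacers on both sides),
#' or `unrelated`. When both fragments carry fragment-specific spacers at
#' the same end of the shared block, that end is labelled the putative
#' leader-proximal end (the end showing turnover) - a comparative call
#' only, never inferred from sequence context.
#'
#' @param path_a,path_b character vectors of cluster ids in array order.
#' @param centres_a,centres_b named character vectors mapping those
#'   cluster ids to centre sequences.
#' @param max_mismatch spacer equivalence threshold (default 1).
#' @return list: `classification`, `shared_block` (length), `a_range`,
#'   `b_range` (1-based index ranges of the block), `trimmed_end`,
#'   `n_trimmed`, `leader_proximal_end` ("left"/"right"/NA, in the
#'   coordinate frame of fragment a).
#' @export
compareFragments <- function(path_a, path_b, centres_a, centres_b,
                             max_mismatch = 1L) {
  stopifnot(length(path_a) >= 2, length(path_b) >= 2)
  # equate b's spacers with a's via centre sequences
  seq_a <- unname(centres_a[path_a]); seq_b <- unname(centres_b[path_b])
  stopifnot(!anyNA(seq_a), !anyNA(seq_b))
  eq <- matrix(FALSE, length(seq_a), length(seq_b))
  for (i in seq_along(seq_a)) for (j in seq_along(seq_b)) {
    eq[i, j] <- if (nchar(seq_a[i]) == nchar(seq_b[j]))
      .hamming(seq_a[i], seq_b[j]) <= max_mismatch
    else {
      al <- .overlap_align(seq_a[i], seq_b[j])
      ov <- al$overlap
      (ov - al$matches) <= max_mismatch &&
        (nchar(seq_a[i]) + nchar(seq_b[j]) - 2 * ov) <= 2
    }
  }
  # longest common contiguous block by dynamic programming
  best <- 0L; bi <- 0L; bj <- 0L
  L <- matrix(0L, length(seq_a) + 1L, length(seq_b) + 1L)
  for (i in seq_along(seq_a)) for (j in seq_along(seq_b)) {
    if (eq[i, j]) {
      L[i + 1L, j + 1L] <- L[i, j] + 1L
      if (L[i + 1L, j + 1L] > best) {
        best <- L[i + 1L, j + 1L]; bi <- i; bj <- j
      }
    }
  }
  if (best == 0L)
    return(list(classification = "unrelated", shared_block = 0L,
                a_range = NULL, b_range = NULL, trimmed_end = NA,
                n_trimmed = NA, leader_proximal_end = NA))
  a_range <- c(bi - best + 1L, bi)
  b_range <- c(bj - best + 1L, bj)
  na <- length(seq_a); nb <- length(seq_b)
  a_left <- a_range[1] - 1L; a_right <- na - a_range[2]
  b_left <- b_range[1] - 1L; b_right <- nb - b_range[2]
  leader <- if (a_left > 0 && b_left > 0) "left"
    else if (a_right > 0 && b_right > 0) "right" else NA
  if (best == na && best == nb) {
    cls <- "identical"; trimmed <- NA; ntrim <- NA
  } else if (best == min(na, nb) &&
             ((a_left == 0 && b_left == 0) ||
              (a_right == 0 && b_right == 0))) {
    cls <- "end-trimmed"
    # the longer fragment keeps spacers the shorter one lost
    if (na >= nb) {
      trimmed <- if (a_left > 0) "left" else "right"
      ntrim <- na - best
    } else {
      trimmed <- if (b_left > 0) "left" else "right"
      ntrim <- nb - best
    }
  } else {
    cls <- "partially-renewed"; trimmed <- NA; ntrim <- NA
  }
  list(classification = cls, shared_block = best, a_range = a_range,
       b_range = b_range, trimmed_end = trimmed, n_trimmed = ntrim,
       leader_proximal_end = leader)
}
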