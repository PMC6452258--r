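#' Shannon entropy of an abundance vector (nats)
#'
#' `-sum(p_i * log(p_i))` with `p_i = count_i / N`, natural logarithm
#' (computed by vegan); 0 for a single cluster.
#'
#' @param counts positive integer vector of per-cluster read counts.
#' @return entropy in nats.
#' @export
shannonDiversity <- function(counts) {
  counts <- .check_counts(counts)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))` where `f1`/`f2` are the
#' singleton and doubleton cluster counts; the bias-corrected form is
#' defined even when no doubletons are observed.
#'
#' @param counts positive integer vector of per-cluster read counts.
#' @return estimated richness (>= number of observed clusters).
#' @export
chao1Richness <- function(counts) {
  counts <- .check_counts(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Good's coverage of a spacer sample
#'
#' `1 - n1/N`: the estimated fraction of the repertoire captured, where `N`
#' is the total read count and `n1` the number of singleton clusters.
#'
#' @param counts positive integer vector of per-cluster read counts.
#' @return coverage fraction in \[0, 1\].
#' @export
goodsCoverage <- function(counts) {
  counts <- .check_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

.check_counts <- function(counts) {
  if (length(counts) == 0) stop("empty abundance vector")
  if (any(counts < 1)) stop("counts must be >= 1")
  as.numeric(counts)
}

#' Per-sample alpha-diversity summary
#'
#' One row per sample: total reads `N`, observed clusters, Shannon entropy
#' (nats, on read counts), bias-corrected Chao1, Good's coverage, plus the
#' unique-sequence tallies (`N_unique`, `coverage_unique`) so either
#' counting convention can be examined.
#'
#' @param cset a [SpacerClusterSet-class] covering one or more samples.
#' @return data.frame with one row per sample.
#' @export
alphaDiversityTable <- function(cset) {
  stopifnot(is(cset, "SpacerClusterSet"))
  cl <- cset@clusters
  res <- lapply(split(cl, cl$sample_id), function(s) {
    data.frame(sample_id = s$sample_id[1], site_id = s$site_id[1],
               N = sum(s$size), clusters = nrow(s),
               shannon = shannonDiversity(s$size),
               chao1 = chao1Richness(s$size),
               goods_coverage = goodsCoverage(s$size),
               N_unique = sum(s$n_unique),
               coverage_unique = 1 - sum(s$n_unique == 1) / sum(s$n_unique),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Sample-by-component abundance matrix
#'
#' Builds the matrix underlying beta-diversity: rows are repertoire groups
#' (samples or sites, per the `group_by` of [matchAcross()]), columns are
#' matched-spacer components, entries are summed read counts.
#'
#' @param match a [matchAcross()] result.
#' @return numeric matrix.
#' @export
abundanceMatrix <- function(match) {
  cl <- match$centres
  stopifnot(!is.null(cl$component))
  groups <- sort(unique(cl$group))
  comps <- sort(unique(cl$component))
  m <- matrix(0, length(groups), length(comps),
              dimnames = list(groups, paste0("u", comps)))
  for (i in seq_len(nrow(cl)))
    m[cl$group[i], paste0("u", cl$component[i])] <-
      m[cl$group[i], paste0("u", cl$component[i])] + cl$size[i]
  m
}

#' Pairwise beta-diversity with UPGMA clustering
#'
#' Pairwise dissimilarity between repertoires (Bray-Curtis on read counts
#' and Jaccard on presence/absence, both via vegan) and the UPGMA
#' (average-linkage) dendrogram of samples, exported as Newick.
#'
#' @param m abundance matrix from [abundanceMatrix()] (rows = groups).
#' @param metric any subset of `c("bray", "jaccard")`.
#' @return list: one symmetric dissimilarity matrix per metric, plus
#'   `upgma` (hclust, on the first metric) and `newick`.
#' @export
betaDiversity <- function(m, metric = c("bray", "jaccard")) {
  bad <- setdiff(metric, c("bray", "jaccard"))
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "),
         "; supported: bray, jaccard")
  if (nrow(m) < 2) stop("need >= 2 repertoire groups")
  out <- list()
  for (mt in metric) {
    d <- if (mt == "jaccard")
      vegan::vegdist(m > 0, method = "jaccard", binary = TRUE)
    else vegan::vegdist(m, method = "bray")
    out[[mt]] <- as.matrix(d)
  }
  d1 <- as.dist(out[[metric[1]]])
  hc <- hclust(d1, method = "average")
  out$upgma <- hc
  out$newick <- ape::write.tree(ape::as.phylo(hc))
  out
}

#' Abundance correlation of spacers shared by two repertoires
#'
#' Pearson correlation of the abundances of matched spacer components
#' present in both groups, computed on log10 read counts (cluster sizes
#' span orders of magnitude) with the linear-scale coefficient also
#' reported. NA with fewer than 3 shared components.
#'
#' @param m abundance matrix from [abundanceMatrix()].
#' @param a,b row names (groups) to compare.
#' @return list: `r_log10`, `r_linear`, `n_shared`.
#' @export
sharedAbundanceCorrelation <- function(m, a, b) {
  stopifnot(a %in% rownames(m), b %in% rownames(m))
  shared <- m[a, ] > 0 & m[b, ] > 0
  n <- sum(shared)
  if (n < 3)
    return(list(r_log10 = NA_real_, r_linear = NA_real_, n_shared = n))
  x <- m[a, shared]; y <- m[b, shared]
  list(r_log10 = cor(log10(x), log10(y)), r_linear = cor(x, y),
       n_shared = n)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass rule (summation of
#' hypergeometric probabilities not exceeding that of the observed table).
#' A table with a zero margin carries no information: p = 1 with a
#' warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisherExactTest <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: test undefined, returning p = 1")
    return(1)
  }
  fisher.test(tab)$p.value
}
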