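# helper: observations + clusters for a set of reads over known arrays
.assemble_input <- function(reads, rs = test_repeat_set()) {
  obs <- extractSpacers(reads, rs, sample_id = "S")
  cset <- clusterSpacers(obs)
  list(obs = obs, cset = cset)
}

# reads covering every junction of `spacers` k times (pairs), in order
.pair_reads <- function(spacers, times = 3, prefix = "p") {
  reads <- character(0)
  for (j in seq_len(length(spacers) - 1))
    for (t in seq_len(times))
      reads[sprintf("%s_%d_%d", prefix, j, t)] <-
        ladder_read(spacers[j:(j + 1)])
  reads
}

test_that("a fully covered planted array becomes one path fragment", {
  set.seed(501)
  sps <- replicate(5, clean_spacer(32))
  inp <- .assemble_input(.pair_reads(sps, times = 3))
  adj <- buildAdjacency(inp$obs, inp$cset, min_support = 2)
  ed <- edgeTable(adj)
  expect_identical(nrow(ed), 4L)
  expect_true(all(ed$support == 3))
  fr <- assembleFragments(adj)
  expect_identical(nrow(fragmentTable(fr)), 1L)
  pa <- fragmentPath(fr)
  centre_of <- setNames(clusterTable(inp$cset)$centre,
                        clusterTable(inp$cset)$cluster_id)
  expect_identical(unname(centre_of[pa$cluster_id[order(pa$position)]]),
                   sps)
})

test_that("single-read chimeric adjacencies are pruned at min support", {
  set.seed(502)
  sps <- replicate(5, clean_spacer(32))
  reads <- .pair_reads(sps[1:3], times = 2)
  reads["chimera"] <- ladder_read(sps[c(1, 5)])
  inp <- .assemble_input(c(reads,
                           setNames(ladder_read(sps[5]), "single")))
  adj <- buildAdjacency(inp$obs, inp$cset, min_support = 2)
  ed <- edgeTable(adj)
  centre_of <- setNames(clusterTable(inp$cset)$centre,
                        clusterTable(inp$cset)$cluster_id)
  expect_false(any(centre_of[ed$from] == sps[1] &
                     centre_of[ed$to] == sps[5]))
  expect_identical(nrow(ed), 2L)
})

test_that("a spacer shared by two arrays breaks the path at the branch", {
  set.seed(503)
  x <- clean_spacer(32)
  a <- c(clean_spacer(32), x, clean_spacer(32))
  b <- c(clean_spacer(32), x, clean_spacer(32))
  # only pair reads: the branch node X is unresolvable
  reads <- c(.pair_reads(a, 2, "a"), .pair_reads(b, 2, "b"))
  inp <- .assemble_input(reads)
  adj <- buildAdjacency(inp$obs, inp$cset, min_support = 2)
  ed <- edgeTable(adj)
  cl <- clusterTable(inp$cset)
  xid <- cl$cluster_id[cl$centre == x]
  expect_identical(sum(ed$to == xid), 2L)   # in-degree 2
  expect_identical(sum(ed$from == xid), 2L) # out-degree 2
  fr <- assembleFragments(adj)
  # no fragment runs through X: X appears in no 3-spacer-or-longer chain
  pa <- fragmentPath(fr)
  for (id in unique(pa$fragment_id)) {
    p <- pa$cluster_id[pa$fragment_id == id]
    if (xid %in% p)
      expect_false(xid %in% p[c(-1, -length(p))])
  }
})

test_that("triples phase a shared spacer into two full fragments", {
  set.seed(504)
  x <- clean_spacer(32)
  a <- c(clean_spacer(32), x, clean_spacer(32))
  b <- c(clean_spacer(32), x, clean_spacer(32))
  # triple-spanning reads resolve the X shape
  reads <- c(r1 = ladder_read(a), r2 = ladder_read(a),
             r3 = ladder_read(b), r4 = ladder_read(b))
  inp <- .assemble_input(reads)
  adj <- buildAdjacency(inp$obs, inp$cset, min_support = 2)
  expect_identical(nrow(adj@triples), 2L)
  fr <- assembleFragments(adj)
  ft <- fragmentTable(fr)
  expect_identical(nrow(ft), 2L)
  expect_true(all(ft$n_spacers == 3))
  centre_of <- setNames(clusterTable(inp$cset)$centre,
                        clusterTable(inp$cset)$cluster_id)
  pa <- fragmentPath(fr)
  paths <- lapply(split(pa, pa$fragment_id), function(p)
    unname(centre_of[p$cluster_id[order(p$position)]]))
  expect_true(any(vapply(paths, identical, logical(1), a)))
  expect_true(any(vapply(paths, identical, logical(1), b)))
})

test_that("a clean 12-node path graph yields a 12-spacer fragment", {
  set.seed(505)
  sps <- replicate(12, clean_spacer(32))
  inp <- .assemble_input(.pair_reads(sps, 2))
  fr <- assembleFragments(buildAdjacency(inp$obs, inp$cset))
  expect_identical(fragmentTable(fr)$n_spacers, 12L)
})

test_that("assembly is invariant to read order and orientation", {
  set.seed(506)
  sps <- replicate(6, clean_spacer(32))
  reads <- .pair_reads(sps, 3)
  inp1 <- .assemble_input(reads)
  flip <- seq_along(reads) %% 2 == 0
  reads2 <- reads[rev(seq_along(reads))]
  reads2[flip] <- rc_oracle(reads2[flip])
  inp2 <- .assemble_input(reads2)
  f1 <- assembleFragments(buildAdjacency(inp1$obs, inp1$cset))
  f2 <- assembleFragments(buildAdjacency(inp2$obs, inp2$cset))
  c1 <- setNames(clusterTable(inp1$cset)$centre,
                 clusterTable(inp1$cset)$cluster_id)
  c2 <- setNames(clusterTable(inp2$cset)$centre,
                 clusterTable(inp2$cset)$cluster_id)
  p1 <- unname(c1[fragmentPath(f1)$cluster_id])
  p2 <- unname(c2[fragmentPath(f2)$cluster_id])
  expect_identical(p1, p2)
})

test_that("a recurring spacer (cycle) is broken and flagged", {
  set.seed(507)
  a <- clean_spacer(32); b <- clean_spacer(32); cc <- clean_spacer(32)
  # reads describe a -> b -> c -> a
  reads <- c(.pair_reads(c(a, b), 2, "x"), .pair_reads(c(b, cc), 2, "y"),
             .pair_reads(c(cc, a), 2, "z"))
  inp <- .assemble_input(reads)
  fr <- assembleFragments(buildAdjacency(inp$obs, inp$cset))
  ft <- fragmentTable(fr)
  expect_identical(nrow(ft), 1L)
  expect_identical(ft$n_spacers, 3L)
  expect_match(ft$flag, "cycle-broken")
})

test_that("planted array at high coverage with errors is recovered exactly", {
  tr <- simulateCommunity(sites = 1, samples_per_site = 1,
                          strains_per_site = 1, arrays_per_strain = 1,
                          array_length = c(15, 15), sharing = 0,
                          seed = 508)
  tr <- simulateReads(tr, reads_per_sample = 400, error_rate = 0.005,
                      unit_probs = c(0.2, 0.4, 0.3, 0.1), seed = 509)
  smp <- tr@samples$sample_id[1]
  obs <- extractSpacers(tr@reads[[smp]]$seqs, thermusRepeats(),
                        sample_id = smp)
  cset <- filterClusters(clusterSpacers(obs), 2)
  fr <- assembleFragments(buildAdjacency(obs, cset, min_support = 2))
  truth_sps <- tr@arrays[[1]][[1]]$spacers
  ft <- fragmentTable(fr)
  expect_identical(nrow(ft), 1L)
  expect_identical(ft$n_spacers, 15L)
  centre_of <- setNames(clusterTable(cset)$centre,
                        clusterTable(cset)$cluster_id)
  pa <- fragmentPath(fr)
  expect_identical(
    unname(centre_of[pa$cluster_id[order(pa$position)]]), truth_sps)
  expect_true(all(pa$support_next[-nrow(pa)] >= 2))
})

test_that("fragment comparison classifies end losses and renewal", {
  set.seed(510)
  sps <- replicate(10, rand_dna(32))
  ids_a <- paste0("a", 1:10); ids_b <- paste0("b", 1:10)
  ca <- setNames(sps, ids_a)
  # identical
  r <- compareFragments(ids_a, ids_a, ca, ca)
  expect_identical(r$classification, "identical")
  expect_identical(r$shared_block, 10L)
  # B lost three spacers from one end
  cb <- setNames(sps[1:7], paste0("b", 1:7))
  r2 <- compareFragments(ids_a, paste0("b", 1:7), ca, cb)
  expect_identical(r2$classification, "end-trimmed")
  expect_identical(r2$n_trimmed, 3L)
  expect_identical(r2$trimmed_end, "right")
  # only a 2-spacer block in common, both renewed elsewhere
  mixed <- c(replicate(4, rand_dna(32)), sps[4:5],
             replicate(3, rand_dna(32)))
  cm <- setNames(mixed, paste0("m", 1:9))
  r3 <- compareFragments(ids_a, paste0("m", 1:9), ca, cm)
  expect_identical(r3$classification, "partially-renewed")
  expect_identical(r3$shared_block, 2L)
  # nothing shared
  cu <- setNames(replicate(5, rand_dna(32)), paste0("u", 1:5))
  expect_identical(
    compareFragments(ids_a, paste0("u", 1:5), ca, cu)$classification,
    "unrelated")
})

test_that("turnover at a common end marks the putative leader end", {
  set.seed(511)
  core <- replicate(6, rand_dna(32))
  a <- c(replicate(2, rand_dna(32)), core)
  b <- c(replicate(3, rand_dna(32)), core)
  ca <- setNames(a, paste0("a", seq_along(a)))
  cb <- setNames(b, paste0("b", seq_along(b)))
  r <- compareFragments(names(ca), names(cb), ca, cb)
  expect_identical(r$classification, "partially-renewed")
  expect_identical(r$shared_block, 6L)
  expect_identical(r$leader_proximal_end, "left")
})

test_that("spacer equivalence in comparison tolerates one mismatch", {
  set.seed(512)
  sps <- replicate(5, rand_dna(32))
  noisy <- sps
  noisy[3] <- mutate_seq(noisy[3], 1)
  ca <- setNames(sps, paste0("a", 1:5))
  cb <- setNames(noisy, paste0("b", 1:5))
  r <- compareFragments(names(ca), names(cb), ca, cb)
  expect_identical(r$classification, "identical")
})
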