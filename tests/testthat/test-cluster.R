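test_that("end-gap identity follows the free-end-gap overlap definition", {
  expect_equal(endgapIdentity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(endgapIdentity("ACGTACGT", "CGTACGT"), 1)
  set.seed(301)
  s <- rand_dna(32)
  s5 <- mutate_seq(s, 5)
  expect_equal(endgapIdentity(s, s5), 27 / 32)
  expect_lt(endgapIdentity(s, s5), 0.85)
  # agreement with the brute-force overlap oracle on random pairs
  for (i in 1:25) {
    a <- rand_dna(sample(25:35, 1)); b <- rand_dna(sample(25:35, 1))
    expect_equal(endgapIdentity(a, b),
                 bf_overlap(a, b)$matches / min(nchar(a), nchar(b)))
  }
})

.obs_from_counts <- function(seq_counts, sample_id = "S", type = "I-E") {
  df <- data.frame(
    sequence = rep(names(seq_counts), seq_counts),
    sample_id = sample_id, site_id = sample_id, type_label = type,
    source_id = paste0("r", seq_along(rep(names(seq_counts),
                                          seq_counts))),
    index_in_source = 0L, read_support = 1L, stringsAsFactors = FALSE)
  new("SpacerObservations", observations = df,
      flags = data.frame(source_id = character(), flag = character()),
      params = list())
}

test_that("distinct planted spacers form one cluster each", {
  set.seed(302)
  sps <- replicate(3, rand_dna(32))
  cs <- clusterSpacers(.obs_from_counts(setNames(c(100, 100, 100), sps)))
  cl <- clusterTable(cs)
  expect_identical(nrow(cl), 3L)
  expect_setequal(cl$centre, sps)
  expect_true(all(cl$size == 100))
})

test_that("substitution variants join their planted centre", {
  set.seed(303)
  sp <- rand_dna(32)
  variants <- replicate(20, mutate_seq(sp, 1))
  counts <- table(c(rep(sp, 80), variants))
  cs <- clusterSpacers(.obs_from_counts(
    setNames(as.integer(counts), names(counts))))
  cl <- clusterTable(cs)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$centre, sp)
  expect_identical(cl$size, 100L)
  expect_identical(sum(memberTable(cs)$count), 100L)
})

test_that("sequences below the identity threshold never merge", {
  set.seed(304)
  a <- rand_dna(32)
  b <- mutate_seq(a, 7)  # 25/32 = 0.78 < 0.85 if end-gapped best is direct
  # confirm with the oracle that the pair is below threshold at any offset
  expect_lt(bf_overlap(a, b)$matches / 32, 0.85)
  cs <- clusterSpacers(.obs_from_counts(setNames(c(90, 10), c(a, b))))
  expect_identical(nrow(clusterTable(cs)), 2L)
})

test_that("clustering is invariant to input record order", {
  set.seed(305)
  sps <- replicate(4, rand_dna(32))
  counts <- setNames(c(50, 30, 12, 5), sps)
  obs <- .obs_from_counts(counts)
  df <- observationTable(obs)
  perm <- new("SpacerObservations",
              observations = df[sample(nrow(df)), ],
              flags = obs@flags, params = list())
  a <- clusterTable(clusterSpacers(obs))
  b <- clusterTable(clusterSpacers(perm))
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("every observation lands in exactly one cluster", {
  set.seed(306)
  sp <- replicate(6, rand_dna(32))
  counts <- setNames(sample(1:40, 6), sp)
  cs <- clusterSpacers(.obs_from_counts(counts))
  mem <- memberTable(cs)
  expect_identical(sum(mem$count), sum(counts))
  expect_identical(anyDuplicated(mem$sequence), 0L)
  expect_setequal(mem$sequence, names(counts))
})

test_that("greedy clustering equals brute-force partition on clean input", {
  set.seed(307)
  # well-separated planted groups whose members are within threshold of
  # each other and below it across groups
  centres <- replicate(6, rand_dna(32))
  seqs <- counts <- list()
  for (i in seq_along(centres)) {
    mem <- unique(c(centres[i], replicate(4, mutate_seq(centres[i], 2))))
    seqs[[i]] <- mem
    counts[[i]] <- c(50, rep(3, length(mem) - 1))
  }
  all_seqs <- unlist(seqs); all_counts <- unlist(counts)
  # cleanliness precondition: within >= 0.85, across < 0.85
  grp <- rep(seq_along(seqs), lengths(seqs))
  clean <- TRUE
  for (i in seq_along(all_seqs)) for (j in seq_len(i - 1)) {
    idy <- bf_overlap(all_seqs[i], all_seqs[j])$matches / 32
    if (grp[i] == grp[j] && idy < 0.85) clean <- FALSE
    if (grp[i] != grp[j] && idy >= 0.85) clean <- FALSE
  }
  expect_true(clean)
  cs <- clusterSpacers(.obs_from_counts(setNames(all_counts, all_seqs)))
  cl <- clusterTable(cs)
  expect_identical(nrow(cl), length(centres))
  expect_setequal(cl$centre, centres)
  mem <- memberTable(cs)
  got_grp <- setNames(mem$cluster_id, mem$sequence)[all_seqs]
  expect_identical(length(unique(paste(grp, got_grp))),
                   length(unique(grp)))
})

test_that("the size filter keeps clusters with more than 10 reads", {
  set.seed(308)
  sps <- replicate(3, rand_dna(32))
  cs <- clusterSpacers(.obs_from_counts(setNames(c(12, 10, 11), sps)))
  kept <- filterClusters(cs, min_size = 11)
  expect_setequal(clusterTable(kept)$size, c(12L, 11L))
  expect_identical(kept@params$filter$retained, 2L)
  expect_identical(kept@params$filter$total, 3L)
  # empty input passes through with a warning
  empty <- clusterSpacers(.obs_from_counts(setNames(1L, rand_dna(32))))
  expect_warning(out <- filterClusters(empty, 11), "removed")
  expect_identical(nrow(clusterTable(out)), 0L)
})

.cluster_sets <- function(site_seqs) {
  # site_seqs: named list site -> named count vector
  obs <- lapply(names(site_seqs), function(s)
    .obs_from_counts(site_seqs[[s]], sample_id = s))
  cs <- clusterSpacers(combineObservations(obs))
  cs
}

test_that("cross-site matching links centres under the <2 mismatch rule", {
  set.seed(309)
  shared <- rand_dna(32)
  near <- mutate_seq(shared, 1)
  far <- mutate_seq(shared, 2)
  other <- rand_dna(32)
  cs <- .cluster_sets(list(A = setNames(c(20, 15), c(shared, other)),
                           B = setNames(c(25), near),
                           C = setNames(c(25), far)))
  mt <- matchAcross(cs, group_by = "site_id")
  ed <- mt$edges
  # shared-near at Hamming 1: edge; shared-far at Hamming 2: no edge
  cl <- mt$centres
  id_of <- function(seqq) cl$cluster_id[cl$centre == seqq]
  has_edge <- function(x, y) any((ed$a == id_of(x) & ed$b == id_of(y)) |
                                 (ed$a == id_of(y) & ed$b == id_of(x)))
  expect_true(has_edge(shared, near))
  expect_false(has_edge(shared, far))
  expect_identical(
    cl$component[cl$centre == shared],
    cl$component[cl$centre == near])
})

test_that("planted overlap structure yields exact sharing counts", {
  set.seed(310)
  ab <- replicate(10, rand_dna(32))   # in A and B
  abc <- replicate(3, rand_dna(32))   # in all three
  a_only <- replicate(5, rand_dna(32))
  b_only <- replicate(4, rand_dna(32))
  c_only <- replicate(6, rand_dna(32))
  mk <- function(seqs) setNames(rep(20L, length(seqs)), seqs)
  cs <- .cluster_sets(list(A = mk(c(ab, abc, a_only)),
                           B = mk(c(ab, abc, b_only)),
                           C = mk(c(abc, c_only))))
  mt <- matchAcross(cs, group_by = "site_id")
  shared <- mt$shared_by
  expect_identical(unname(shared[["2"]]), 10L)
  expect_identical(unname(shared[["3"]]), 3L)
  expect_identical(mt$n_components, 10L + 3L + 5L + 4L + 6L)
})

test_that("component counting matches brute-force union-find", {
  set.seed(311)
  base <- replicate(40, rand_dna(30))
  seqs <- c(base,
            vapply(sample(base, 30, TRUE), mutate_seq, character(1), 1),
            vapply(sample(base, 20, TRUE), function(s)
              substr(s, 2, 30), character(1)),
            replicate(30, rand_dna(30)))
  counts <- setNames(rep(20L, length(seqs)), seqs)
  counts <- counts[!duplicated(names(counts))]
  # split across three pseudo-sites deterministically
  nm <- names(counts)
  grp <- rep_len(c("A", "B", "C"), length(nm))
  site_seqs <- split(counts, grp)
  cs <- .cluster_sets(lapply(site_seqs, identity))
  mt <- matchAcross(cs, group_by = "site_id")
  cl <- mt$centres
  want <- bf_components(cl$centre)
  # same partition: component labels equal up to renaming
  expect_identical(length(unique(cl$component)), length(unique(want)))
  expect_identical(
    as.vector(table(table(cl$component))),
    as.vector(table(table(want))))
  key_got <- split(cl$centre, cl$component)
  key_want <- split(cl$centre, want)
  norm <- function(l) sort(vapply(l, function(x)
    paste(sort(x), collapse = ","), character(1)))
  expect_identical(norm(key_got), norm(key_want))
})

test_that("cross-type coincidences are reported separately", {
  set.seed(312)
  sp <- rand_dna(32)
  obs <- combineObservations(list(
    .obs_from_counts(setNames(20L, sp), sample_id = "A", type = "I-E"),
    .obs_from_counts(setNames(20L, sp), sample_id = "A", type = "I-C")))
  cs <- clusterSpacers(obs)
  mt <- matchAcross(cs)
  expect_identical(nrow(mt$edges), 0L)   # same-type edges only
  expect_identical(nrow(mt$cross_type_edges), 1L)
  expect_setequal(c(mt$cross_type_edges$type_a,
                    mt$cross_type_edges$type_b), c("I-E", "I-C"))
})
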