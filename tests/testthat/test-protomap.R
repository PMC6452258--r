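.plant <- function(genome, seq, at, strand = "+") {
  ins <- if (strand == "+") seq else rc_oracle(seq)
  substr(genome, at, at + nchar(ins) - 1L) <- ins
  genome
}

test_that("a verbatim planted spacer is found once at its locus", {
  set.seed(601)
  sp <- rand_dna(32)
  g <- .plant(rand_dna(5000), sp, 1001)
  hits <- searchProtospacers(c(s1 = sp), c(t1 = g))
  expect_identical(length(hits), 1L)
  expect_identical(GenomicRanges::start(hits), 1001L)
  expect_identical(GenomicRanges::end(hits), 1032L)
  expect_identical(as.character(GenomicRanges::strand(hits)), "+")
  expect_equal(hits$identity, 1)
  # minus-strand planting is found with the strand flipped
  g2 <- .plant(rand_dna(5000), sp, 2001, "-")
  h2 <- searchProtospacers(c(s1 = sp), c(t1 = g2))
  expect_identical(as.character(GenomicRanges::strand(h2)), "-")
  expect_identical(GenomicRanges::start(h2), 2001L)
})

test_that("the identity threshold is strict at the 85% boundary", {
  set.seed(602)
  sp <- rand_dna(32)
  g3 <- .plant(rand_dna(3000), mutate_seq(sp, 3), 501)   # 29/32 = 0.906
  g4 <- .plant(rand_dna(3000), mutate_seq(sp, 4), 501)   # 28/32 = 0.875
  g5 <- .plant(rand_dna(3000), mutate_seq(sp, 5), 501)   # 27/32 = 0.844
  expect_identical(length(searchProtospacers(c(s = sp), c(t = g3))), 1L)
  h4 <- searchProtospacers(c(s = sp), c(t = g4))
  expect_identical(length(h4), 1L)
  expect_identical(h4$mismatches, 4L)
  expect_identical(length(searchProtospacers(c(s = sp), c(t = g5))), 0L)
})

test_that("gapped-only similarity is not a hit (no indels)", {
  set.seed(603)
  sp <- rand_dna(32)
  # insert 2 nt in the middle of the planted copy: every ungapped window
  # now disagrees in >15% of positions (verified by the planting itself)
  gapped <- paste0(substr(sp, 1, 16), "CA", substr(sp, 17, 32))
  g <- .plant(rand_dna(3000), gapped, 701)
  expect_identical(length(searchProtospacers(c(s = sp), c(t = g))), 0L)
})

test_that("search equals the brute-force all-offset scan", {
  set.seed(604)
  g <- rand_dna(8000)
  sps <- replicate(12, rand_dna(32))
  # plant some noisy copies on both strands
  g <- .plant(g, mutate_seq(sps[1], 2), 101)
  g <- .plant(g, mutate_seq(sps[2], 4), 1501, "-")
  g <- .plant(g, mutate_seq(sps[3], 5), 3001)      # below threshold
  g <- .plant(g, sps[4], 4501, "-")
  hits <- searchProtospacers(setNames(sps, paste0("s", 1:12)),
                             c(t = g))
  for (i in seq_along(sps)) {
    for (std in c("+", "-")) {
      pat <- if (std == "+") sps[i] else rc_oracle(sps[i])
      mmv <- bf_scan(g, pat, n_matches = FALSE)
      want <- which((32 - mmv) / 32 > 0.85) - 1L
      sub <- hits[hits$spacer_id == paste0("s", i) &
                    as.character(GenomicRanges::strand(hits)) == std]
      expect_identical(GenomicRanges::start(sub) - 1L, want)
      expect_identical(sub$mismatches, unname(mmv[mmv <= 4]))
    }
  }
})

test_that("flanks come out in protospacer orientation with truncation", {
  set.seed(605)
  sp <- rand_dna(32)
  g <- rand_dna(1000)
  g <- .plant(g, sp, 101)
  h <- searchProtospacers(c(s = sp), c(t = g))
  expect_identical(h$up_flank, substr(g, 93, 100))
  expect_identical(h$down_flank, substr(g, 133, 140))
  # minus strand: flanks are reverse complements of the opposite sides
  g2 <- .plant(rand_dna(1000), sp, 301, "-")
  h2 <- searchProtospacers(c(s = sp), c(t = g2))
  expect_identical(h2$up_flank, rc_oracle(substr(g2, 333, 340)))
  expect_identical(h2$down_flank, rc_oracle(substr(g2, 293, 300)))
  # a hit near the contig start has a truncated upstream flank
  g3 <- .plant(rand_dna(500), sp, 4)
  h3 <- searchProtospacers(c(s = sp), c(t = g3))
  expect_true(h3$up_truncated)
  expect_false(h3$down_truncated)
})

test_that("reverse-complementing the target mirrors hits, PAM unchanged", {
  set.seed(606)
  sps <- replicate(8, rand_dna(32))
  g <- rand_dna(6000)
  for (i in 1:6) g <- .plant(g, paste0("AAG", sps[i]), 500 * i)  # AAG 5'
  g <- .plant(g, sps[7], 3500, "-")
  names(sps) <- paste0("s", 1:8)
  h1 <- searchProtospacers(sps, c(t = g))
  h2 <- searchProtospacers(sps, c(t = rc_oracle(g)))
  n <- nchar(g)
  expect_identical(length(h1), length(h2))
  m1 <- data.frame(s = GenomicRanges::start(h1),
                   e = GenomicRanges::end(h1),
                   std = as.character(GenomicRanges::strand(h1)),
                   id = h1$spacer_id)
  m2 <- data.frame(s = n - GenomicRanges::end(h2) + 1L,
                   e = n - GenomicRanges::start(h2) + 1L,
                   std = ifelse(as.character(
                     GenomicRanges::strand(h2)) == "+", "-", "+"),
                   id = h2$spacer_id)
  o1 <- m1[order(m1$s, m1$id), ]; o2 <- m2[order(m2$s, m2$id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
  p1 <- buildPam(h1)
  p2 <- buildPam(h2)
  expect_identical(p1@up_counts, p2@up_counts)
  expect_identical(p1@down_counts, p2@down_counts)
})

test_that("a planted 5' motif dominates the PAM model", {
  set.seed(607)
  sps <- replicate(10, rand_dna(32))
  g <- rand_dna(9000)
  for (i in seq_along(sps))
    g <- .plant(g, paste0("AAG", sps[i]), 800 * i,
                strand = c("+", "-")[1 + i %% 2])
  h <- searchProtospacers(setNames(sps, paste0("s", seq_along(sps))),
                          c(t = g))
  pam <- buildPam(h, type_label = "I-E")
  expect_identical(pam@n_flanks, 10L)
  expect_identical(substr(pam@consensus_up, 6, 8), "AAG")
  ic <- pamInformation(pam)
  expect_true(all(ic >= 0 & ic <= 2 + 1e-9))
  expect_true(all(ic[c("m3", "m2", "m1")] > 1.5))
})

test_that("uniform flanks give an all-N call; constant flanks 2 bits", {
  set.seed(608)
  mk_hits <- function(up, dn) {
    gr <- GenomicRanges::GRanges(rep("t", length(up)),
                                 IRanges::IRanges(1, 32))
    gr$up_flank <- up; gr$down_flank <- dn
    gr$up_truncated <- FALSE; gr$down_truncated <- FALSE
    gr
  }
  rnd <- mk_hits(replicate(200, rand_dna(8)), replicate(200, rand_dna(8)))
  p <- buildPam(rnd)
  expect_identical(p@consensus_up, "NNNNNNNN")
  expect_lt(max(pamInformation(p)), 0.25)
  const <- mk_hits(rep("ACGTACGT", 6), rep("TTTTCCCC", 6))
  p2 <- buildPam(const)
  expect_identical(p2@consensus_up, "ACGTACGT")
  expect_equal(unname(pamInformation(p2)), rep(2, 16))
  expect_warning(buildPam(rnd[1:3]), "no consensus")
})

test_that("locality tables separate local from foreign targeting", {
  set.seed(609)
  # 40 local spacers (30 hit), 400 foreign (2 hit)
  spacer_sites <- setNames(c(rep("here", 40), rep("there", 400)),
                           paste0("sp", 1:440))
  hit_ids <- c(paste0("sp", 1:30), paste0("sp", 41:42))
  hits <- GenomicRanges::GRanges(rep("phageA", length(hit_ids)),
                                 IRanges::IRanges(seq_along(hit_ids) * 50,
                                                  width = 32))
  hits$spacer_id <- hit_ids
  loc <- localityTable(hits, spacer_sites,
                       c(phageA = "here", phageB = NA))
  tab <- loc$tables$phageA
  expect_identical(unname(tab["hit", "local"]), 30L)
  expect_identical(unname(tab["hit", "foreign"]), 2L)
  expect_lt(loc$p_values["phageA"], 1e-6)
  expect_equal(loc$p_values["phageA"], c(phageA = bf_fisher(tab)),
               tolerance = 1e-8)
  expect_true(is.na(loc$p_values["phageB"]))
  expect_identical(unname(loc$site_counts["here", "phageA"]), 30L)
})

test_that("proportional targeting gives a null locality test", {
  set.seed(610)
  spacer_sites <- setNames(rep(c("a", "b"), each = 100),
                           paste0("sp", 1:200))
  hit_ids <- paste0("sp", c(1:10, 101:110))  # 10% of each site
  hits <- GenomicRanges::GRanges(rep("ph", 20),
                                 IRanges::IRanges(1:20 * 40, width = 32))
  hits$spacer_id <- hit_ids
  loc <- localityTable(hits, spacer_sites, c(ph = "a"))
  expect_gt(loc$p_values["ph"], 0.9)
})

test_that("strand bias separates transcribed-strand targeting from none", {
  set.seed(611)
  genes <- GenomicRanges::GRanges("t", IRanges::IRanges(
    start = seq(1, 9001, by = 1000), width = 1000),
    strand = rep(c("+", "-"), 5))
  mk <- function(n, transcribed) {
    starts <- seq(100, by = 950, length.out = n) %% 9500 + 1
    gene_strand <- as.character(GenomicRanges::strand(genes))[
      findInterval(starts, GenomicRanges::start(genes))]
    flip <- ifelse(gene_strand == "+", "-", "+")
    # balanced case: alternate template/coding relative to each gene
    std <- if (transcribed) flip
      else ifelse(seq_len(n) %% 2 == 0, gene_strand, flip)
    gr <- GenomicRanges::GRanges("t", IRanges::IRanges(starts, width = 32),
                                 strand = std)
    gr$type_label <- if (transcribed) "IIIAB" else "I-E"
    gr
  }
  h <- c(mk(8, TRUE), mk(8, FALSE))
  sb <- strandBias(h, genes)
  iii <- sb[sb$type_label == "IIIAB", ]
  expect_equal(iii$fraction, 1)
  expect_equal(iii$p_value, 2 * 0.5^8)
  ie <- sb[sb$type_label == "I-E", ]
  expect_equal(ie$fraction, 0.5)
  expect_gt(ie$p_value, 0.05)
  # no annotation -> warning and empty result
  expect_warning(out <- strandBias(h, GenomicRanges::GRanges()),
                 "undefined")
  expect_identical(nrow(out), 0L)
})

test_that("short spacers are refused by the word-size guard", {
  set.seed(612)
  expect_warning(
    h <- searchProtospacers(c(s = "ACGTA"), c(t = rand_dna(500))),
    "shorter than word_size")
  expect_identical(length(h), 0L)
})
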