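test_that("simulated genomes tile non-overlapping genes over >= 70% of the sequence", {
  set.seed(41)
  for (len in c(5000, 2000, 9000)) {
    g <- simulateGenome(len)
    expect_equal(nchar(g$sequence), len)
    expect_gte(nrow(g$genes), 3)
    expect_true(all(g$genes$length_bp == g$genes$end - g$genes$start))
    expect_true(all(g$genes$length_bp >= 300 & g$genes$length_bp <= 1500))
    # non-overlap (genes are emitted in order)
    expect_true(all(diff(g$genes$start) > 0))
    expect_true(all(g$genes$start[-1] >= g$genes$end[-nrow(g$genes)]))
    expect_gte(sum(g$genes$length_bp) / len, 0.7)
    # annotation passes the screen
    expect_gte(g$anno$viral_genes, 1)
    expect_lte(g$anno$host_genes, 4)
    expect_gte(g$anno$completeness_pct, 90)
  }
  expect_error(simulateGenome(900), "too short")
})

test_that("genome simulation is deterministic under a fixed seed", {
  set.seed(5); a <- simulateGenome(4000)
  set.seed(5); b <- simulateGenome(4000)
  expect_identical(a, b)
})

test_that("mutateClone realizes the requested divergence", {
  set.seed(42)
  s <- randSeq(10000)
  expect_identical(mutateClone(s, 0)$sequence, s)
  m <- mutateClone(s, 0.002)
  expect_equal(nchar(m$sequence), nchar(s))
  expect_equal(m$substitutions, 10000 - sum(
    strsplit(s, "")[[1]] == strsplit(m$sequence, "")[[1]]))
  # ~20 substitutions, identity about 99.8%
  expect_gt(m$substitutions, 5); expect_lt(m$substitutions, 40)
  expect_gt(hammingIdentity(s, m$sequence), 99.4)
  # non-clone band
  m2 <- mutateClone(s, 0.03)
  expect_lt(hammingIdentity(s, m2$sequence), 99.4)
})

test_that("simulated cohorts are deterministic and internally consistent", {
  sim1 <- simulateCohort(tinySimConfig(seed = 9))
  sim2 <- simulateCohort(tinySimConfig(seed = 9))
  expect_identical(as.character(uvigSequences(cohortUvigs(sim1))),
                   as.character(uvigSequences(cohortUvigs(sim2))))
  expect_identical(cohortCounts(sim1), cohortCounts(sim2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(sim1, d1); writeCohort(sim2, d2)
  for (f in c("genomes.fasta", "annotations.tsv", "metadata.tsv",
              "genes.tsv", "gene_counts.tsv", "truth/transfers.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("no transfer targets a placebo recipient and clones stay above threshold", {
  sim <- simulateCohort(tinySimConfig(seed = 10))
  md <- as.data.frame(cohortMetadata(sim))
  tr <- as.data.frame(truthTransfers(sim))
  placebo <- md$subject_id[md$treatment == "placebo"]
  expect_false(any(tr$recipient_id %in% placebo))
  # every transferred lineage appears in at least one donor sample
  donors <- md$subject_id[md$role == "donor"]
  lin <- cohortTruth(sim)@lineageOfUvig
  anno <- as.data.frame(uvigAnnotations(cohortUvigs(sim)))
  donor_lin <- unique(lin[anno$uvig_id[
    md$role[match(anno$sample_id, md$sample_id)] == "donor"]])
  expect_true(all(tr$lineage_id %in% donor_lin))
  # realized identity of truth clone pairs exceeds the clone threshold
  seqs <- as.character(uvigSequences(cohortUvigs(sim)))
  cp <- as.data.frame(truthClonePairs(sim))
  some <- cp[sample.int(nrow(cp), min(30, nrow(cp))), ]
  for (i in seq_len(nrow(some)))
    expect_gte(hammingIdentity(seqs[[some$uvig_a[i]]],
                               seqs[[some$uvig_b[i]]]), 99.4)
})

test_that("all simulated genomes pass the contig screen end-to-end", {
  sim <- simulateCohort(tinySimConfig(seed = 11))
  dec <- suppressMessages(screenUViGs(cohortUvigs(sim)))
  expect_true(all(dec$retained))
})

test_that("gene counts scale with abundance and length and vanish with absence", {
  cfg <- defaultSimConfig(seed = 1, count_dispersion = 0.3, mean_depth = 5e4)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      uvig_id = c("u1", "u1", "u2"),
                      start = 0L, end = c(500L, 1000L, 800L),
                      length_bp = c(500L, 1000L, 800L))
  anno <- data.frame(uvig_id = c("u1", "u2"), sample_id = c("s1", "s2"))
  lin <- c(u1 = "L1", u2 = "L2")
  ab <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("L1", "L2"), c("s1", "s2")))
  set.seed(12)
  tot1 <- tot2 <- 0
  for (i in 1:1000) {
    cc <- simulateGeneCounts(genes, anno, lin, ab, cfg)
    # absent lineage: all its genes are zero in that sample
    expect_equal(unname(cc["g3", "s1"]), 0)
    expect_equal(unname(cc["g1", "s2"]), 0)
    tot1 <- tot1 + cc["g1", "s1"]; tot2 <- tot2 + cc["g2", "s1"]
  }
  # doubling gene length doubles the expected count (within 5%)
  expect_lt(abs(tot2 / tot1 - 2), 2 * 0.05)
})

test_that("the null configuration removes all arm differences at the source", {
  sim <- simulateCohort(nullSimConfig(seed = 13, n_donors_per_sex = 2L,
                                      donor_richness_range = c(4L, 6L),
                                      recipient_richness = 4L, n_fmt = 3L,
                                      n_placebo = 3L,
                                      genome_length_range = c(2000L, 3000L)),
                        sequences = FALSE)
  expect_equal(nrow(truthTransfers(sim)), 0)
})
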