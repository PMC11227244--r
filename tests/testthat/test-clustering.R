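test_that("a single record forms a singleton cluster with itself as representative", {
  set.seed(31)
  v <- suppressMessages(clusterVOTUs(c(a = randSeq(2000))))
  tab <- votuTable(v)
  expect_equal(nrow(tab), 1)
  expect_equal(as.character(tab$representative), "a")
  expect_equal(sort(tab$members[[1]]), "a")
})

test_that("clone-divergence pairs share a vOTU; distant pairs do not", {
  set.seed(32)
  s <- randSeq(6000)
  near <- mutateClone(s, 0.002)$sequence
  far <- mutateClone(s, 0.08)$sequence
  v <- suppressMessages(clusterVOTUs(c(p = s, q = near, r = far)))
  membership <- votuMembership(v)
  expect_equal(membership[["p"]], membership[["q"]])
  expect_false(membership[["p"]] == membership[["r"]])
  # oracle confirms the far pair is outside the vOTU band
  expect_lt(hammingIdentity(s, far), 95)
})

test_that("clustering partitions the input and representatives are longest members", {
  set.seed(33)
  # three families of different sizes plus singletons
  fams <- lapply(c(7000, 5000, 3000), randSeq)
  seqs <- c()
  for (fi in seq_along(fams)) {
    n <- 3
    for (j in seq_len(n)) {
      s <- mutateClone(fams[[fi]], runif(1, 0, 0.03))$sequence
      # shorten some members so representatives differ in length
      if (j > 1) s <- substr(s, 1, nchar(s) - j * 250)
      seqs[sprintf("f%d_%d", fi, j)] <- s
    }
  }
  seqs["lone1"] <- randSeq(2600)
  seqs["lone2"] <- randSeq(1500)
  v <- suppressMessages(clusterVOTUs(seqs))
  tab <- votuTable(v)
  members <- unlist(as.list(tab$members), use.names = FALSE)
  expect_setequal(members, names(seqs))        # union = input
  expect_false(anyDuplicated(members) > 0)     # disjoint
  # representative is the longest member of its cluster
  for (i in seq_len(nrow(tab))) {
    mem <- tab$members[[i]]
    expect_equal(nchar(seqs[[as.character(tab$representative[i])]]),
                 max(nchar(seqs[mem])))
  }
  # every member meets the thresholds against its representative
  for (i in seq_len(nrow(tab))) {
    rep_ <- as.character(tab$representative[i])
    for (m in setdiff(tab$members[[i]], rep_)) {
      sim <- computeAniAf(seqs[[rep_]], seqs[[m]])
      expect_gte(sim$ani_pct, 95)
      expect_gte(sim$af_smaller, 0.85)
    }
  }
})

test_that("clone detection evaluates only within-vOTU pairs at 99.4/0.85", {
  set.seed(34)
  s <- randSeq(5000)
  seqs <- c(a = s,
            b = mutateClone(s, 0.001)$sequence,   # clone of a
            c = mutateClone(s, 0.03)$sequence,    # same vOTU, not a clone
            d = randSeq(5000))                    # other vOTU
  v <- suppressMessages(clusterVOTUs(seqs))
  cl <- suppressMessages(detectClones(v, seqs))
  key <- paste(pmin(cl$uvig_a, cl$uvig_b), pmax(cl$uvig_a, cl$uvig_b))
  expect_true("a b" %in% key)
  expect_false(any(grepl("c", key)))
  expect_false(any(grepl("d", key)))
  # threshold nesting: clone pairs share a vOTU by construction
  membership <- votuMembership(v)
  expect_true(all(membership[cl$uvig_a] == membership[cl$uvig_b]))
})

test_that("singleton vOTUs yield no clone pairs", {
  set.seed(35)
  seqs <- c(x = randSeq(2000), y = randSeq(2000))
  v <- suppressMessages(clusterVOTUs(seqs))
  cl <- suppressMessages(detectClones(v, seqs))
  expect_equal(nrow(cl), 0)
})

test_that("clone-threshold sensitivity and specificity on generated pairs", {
  set.seed(36)
  n <- 40   # scaled-down version of the acceptance check
  sens <- spec <- logical(n)
  for (i in seq_len(n)) {
    s <- randSeq(6000)
    near <- mutateClone(s, 0.002)$sequence
    far <- mutateClone(s, 0.03)$sequence
    rn <- computeAniAf(s, near)
    rf <- computeAniAf(s, far)
    sens[i] <- rn$ani_pct >= 99.4 && rn$af_smaller >= 0.85
    spec[i] <- !(rf$ani_pct >= 99.4 && rf$af_smaller >= 0.85)
  }
  expect_gte(mean(sens), 0.95)
  expect_equal(mean(spec), 1)
})

test_that("precomputed similarity tables drive clustering (FastANI adapter path)", {
  seqs <- c(a = randSeq(2000), b = randSeq(2000), c = randSeq(2000))
  pre <- data.frame(uvig_a = c("a", "a"), uvig_b = c("b", "c"),
                    ani_pct = c(99.9, 80), af_smaller = c(1, 1))
  v <- suppressMessages(clusterVOTUs(seqs, precomputed = pre))
  membership <- votuMembership(v)
  expect_equal(membership[["a"]], membership[["b"]])
  expect_false(membership[["a"]] == membership[["c"]])
})

test_that("FastANI output tables are parsed into the provider format", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("dir/a.fa\tdir/b.fa\t97.5\t85\t100", f)
  tab <- readFastANITable(f)
  expect_equal(tab$uvig_a, "a")
  expect_equal(tab$uvig_b, "b")
  expect_equal(tab$ani_pct, 97.5)
  expect_equal(tab$af_smaller, 0.85)
})
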