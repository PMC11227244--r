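# a tiny hand-built UViGSet: two UViGs sharing one identical gene, plus
# distinctive genes, so catalog clustering and attribution are exercised
tinyQuantFixture <- function() {
  set.seed(51)
  shared <- randSeq(600)
  g_u1 <- randSeq(400)
  g_u2a <- randSeq(500); g_u2b <- randSeq(450)
  u1 <- paste0(shared, g_u1)
  u2 <- paste0(shared, g_u2a, g_u2b)
  anno <- data.frame(
    uvig_id = c("u1", "u2"), sample_id = c("s1", "s2"),
    viral_genes = 3L, host_genes = 0L, hallmark_genes = 1L,
    screen_score = 0.9, completeness_pct = 95, lifestyle = "unknown",
    predicted_host = NA_character_)
  genes <- data.frame(
    gene_id = c("u1.g1", "u1.g2", "u2.g1", "u2.g2", "u2.g3"),
    uvig_id = c("u1", "u1", "u2", "u2", "u2"),
    start = c(0L, 600L, 0L, 600L, 1100L),
    end = c(600L, 1000L, 600L, 1100L, 1550L),
    length_bp = c(600L, 400L, 600L, 500L, 450L))
  makeUViGSet(c(u1 = u1, u2 = u2), anno, genes)
}

test_that("identical genes on different UViGs form one catalog cluster", {
  u <- tinyQuantFixture()
  cat_ <- suppressMessages(buildGeneCatalog(u))
  sizes <- lengths(cat_$members)
  expect_equal(sum(sizes), 5)
  expect_equal(sort(sizes, decreasing = TRUE)[1], 2)  # the shared gene
  shared_cl <- which(sizes == 2)
  expect_setequal(cat_$members[[shared_cl]], c("u1.g1", "u2.g1"))
})

test_that("genes at 90% identity stay in separate clusters", {
  set.seed(52)
  g <- randSeq(600)
  g2 <- mutateClone(g, 0.10)$sequence
  expect_lt(hammingIdentity(g, g2), 95)
  anno <- data.frame(uvig_id = c("a", "b"), sample_id = "s1",
                     viral_genes = 1L, host_genes = 0L, hallmark_genes = 0L,
                     screen_score = 0.9, completeness_pct = 95,
                     lifestyle = "unknown", predicted_host = NA_character_)
  genes <- data.frame(gene_id = c("a.g1", "b.g1"), uvig_id = c("a", "b"),
                      start = 0L, end = 600L, length_bp = 600L)
  u <- makeUViGSet(c(a = g, b = g2), anno, genes)
  cat_ <- suppressMessages(buildGeneCatalog(u))
  expect_equal(nrow(cat_), 2)
})

test_that("CPM normalization matches the worked examples", {
  # sole gene in its sample: RPK 50 -> CPM 1e6
  m <- matrix(c(100), 1, 1, dimnames = list("g1", "s1"))
  cpm <- countsToCPM(m, c(g1 = 2000))
  expect_equal(abundanceValues(cpm)[1, 1], 1e6)
  # two genes with equal RPK -> 500,000 each
  m <- matrix(c(100, 50), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  cpm <- countsToCPM(m, c(g1 = 2000, g2 = 1000))
  expect_equal(unname(abundanceValues(cpm)[, 1]), c(5e5, 5e5))
  # missing length errors with the gene named
  expect_error(countsToCPM(m, c(g1 = 2000)), "g2")
})

test_that("per-sample CPM sums are 1e6 on random count tables", {
  set.seed(53)
  m <- matrix(rpois(200, 40), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  m[, 3] <- 0   # an all-zero sample stays all-zero
  lens <- setNames(sample(300:1500, 20), rownames(m))
  cpm <- abundanceValues(countsToCPM(m, lens))
  cs <- colSums(cpm)
  expect_true(all(abs(cs[-3] - 1e6) <= 1e-6 * 1e6))
  expect_equal(unname(cs[3]), 0)
})

test_that("UViG abundance is the median over catalog genes, zeros included", {
  u <- tinyQuantFixture()
  cat_ <- suppressMessages(buildGeneCatalog(u))
  # craft cluster CPM directly: u2 has 3 genes
  cl_of <- setNames(rep(as.character(cat_$cluster_id), lengths(cat_$members)),
                    unlist(as.list(cat_$members)))
  cpm_m <- matrix(0, nrow(cat_), 2,
                  dimnames = list(as.character(cat_$cluster_id),
                                  c("s1", "s2")))
  cpm_m[cl_of["u2.g1"], "s2"] <- 10
  cpm_m[cl_of["u2.g2"], "s2"] <- 20
  cpm_m[cl_of["u2.g3"], "s2"] <- 30
  cpm_m[cl_of["u1.g1"], "s1"] <- 0
  cpm_m[cl_of["u1.g2"], "s1"] <- 50
  cpm <- AbundanceMatrix(cpm_m, unit = "CPM-derived")
  ua <- uvigAbundance(cpm, cat_, u)
  v <- abundanceValues(ua)
  expect_equal(unname(v["u2", "s2"]), 20)      # odd median
  expect_equal(unname(v["u1", "s1"]), 25)      # even: mean of middle pair
  # zeros included: {0, 50} -> 25, and {0,0,50} -> 0
  cpm_m2 <- cpm_m; cpm_m2[cl_of["u2.g1"], "s2"] <- 0
  cpm_m2[cl_of["u2.g2"], "s2"] <- 0; cpm_m2[cl_of["u2.g3"], "s2"] <- 50
  ua2 <- uvigAbundance(AbundanceMatrix(cpm_m2, unit = "CPM-derived"), cat_, u)
  expect_equal(unname(abundanceValues(ua2)["u2", "s2"]), 0)
  # configurable alternative: zeros excluded
  ua3 <- uvigAbundance(AbundanceMatrix(cpm_m2, unit = "CPM-derived"), cat_, u,
                       includeZeros = FALSE)
  expect_equal(unname(abundanceValues(ua3)["u2", "s2"]), 50)
})

test_that("median aggregation is invariant to gene order", {
  u <- tinyQuantFixture()
  cat_ <- suppressMessages(buildGeneCatalog(u))
  set.seed(54)
  cpm_m <- matrix(runif(nrow(cat_) * 2, 0, 100), nrow(cat_), 2,
                  dimnames = list(as.character(cat_$cluster_id),
                                  c("s1", "s2")))
  ua <- abundanceValues(uvigAbundance(
    AbundanceMatrix(cpm_m, unit = "CPM-derived"), cat_, u))
  perm <- sample(nrow(cpm_m))
  ua_p <- abundanceValues(uvigAbundance(
    AbundanceMatrix(cpm_m[perm, , drop = FALSE], unit = "CPM-derived"),
    cat_, u))
  expect_equal(ua, ua_p)
})

test_that("vOTU abundance sums members and never decreases when adding one", {
  m <- matrix(c(5, 7, 2, 0, 3, 1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ua <- AbundanceMatrix(m, unit = "CPM-derived")
  v1 <- new("VOTUSet", clusters = S4Vectors::DataFrame(
    votu_id = c("v1", "v2"), representative = c("a", "c"),
    members = IRanges::CharacterList(list(c("a", "b"), "c"))))
  av <- abundanceValues(votuAbundance(ua, v1))
  expect_equal(unname(av["v1", ]), c(5 + 7, 0 + 3))
  expect_equal(unname(av["v2", ]), c(2, 1))
  # single-member vOTU row is identical to the UViG row
  expect_equal(unname(av["v2", ]), unname(m["c", ]))
  # aggregation monotonicity
  v2 <- new("VOTUSet", clusters = S4Vectors::DataFrame(
    votu_id = "v1", representative = "a",
    members = IRanges::CharacterList(list(c("a", "b", "c")))))
  av2 <- abundanceValues(votuAbundance(ua, v2))
  expect_true(all(av2["v1", ] >= av["v1", ]))
})
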