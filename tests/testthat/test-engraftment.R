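# Hand-built engraftment scenarios: sequences constructed so clone/vOTU
# relations are known by design, then pushed through the real clustering.
engraftScenario <- function(recipient_tps, baseline_clone = FALSE) {
  set.seed(61)
  donor_seq <- randSeq(5000)
  clone <- mutateClone(donor_seq, 0.001)$sequence
  other <- randSeq(5000)
  ids <- c("DF01_don.u1")
  seqs <- c(donor_seq)
  samples <- c("DF01_don")
  for (tp in recipient_tps) {
    ids <- c(ids, paste0("RF01_", tp, ".u1"))
    seqs <- c(seqs, clone)
    samples <- c(samples, paste0("RF01_", tp))
  }
  if (baseline_clone) {
    ids <- c(ids, "RF01_baseline.u1")
    seqs <- c(seqs, clone)
    samples <- c(samples, "RF01_baseline")
  }
  ids <- c(ids, "RM01_wk6.u9")
  seqs <- c(seqs, other)
  samples <- c(samples, "RM01_wk6")
  anno <- data.frame(uvig_id = ids, sample_id = samples,
                     viral_genes = 2L, host_genes = 0L, hallmark_genes = 1L,
                     screen_score = 0.9, completeness_pct = 95,
                     lifestyle = "temperate", predicted_host = NA_character_)
  uvigs <- makeUViGSet(setNames(seqs, ids), anno)
  votus <- suppressMessages(clusterVOTUs(uvigs))
  clones <- suppressMessages(detectClones(votus, uvigs))
  list(uvigs = uvigs, votus = votus, clones = clones,
       metadata = scenarioMetadata())
}

test_that("a donor clone first seen at week 6 is an engraftment event", {
  sc <- engraftScenario(c("wk6", "wk12"))
  ev <- suppressMessages(detectEngraftment(sc$clones, sc$uvigs, sc$metadata,
                                           sc$votus))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$recipient_subject, "RF01")
  expect_equal(ev$first_detection, "wk6")
  expect_equal(ev$donors, "DF01")
})

test_that("baseline presence of a donor clone disqualifies the event", {
  sc <- engraftScenario(c("wk12"), baseline_clone = TRUE)
  ev <- suppressMessages(detectEngraftment(sc$clones, sc$uvigs, sc$metadata,
                                           sc$votus))
  expect_equal(nrow(ev), 0)
})

test_that("cross-sex clone pairs are excluded with a warning", {
  set.seed(62)
  s <- randSeq(5000)
  cl <- mutateClone(s, 0.001)$sequence
  ids <- c("DF01_don.u1", "RM01_wk6.u1")
  anno <- data.frame(uvig_id = ids, sample_id = c("DF01_don", "RM01_wk6"),
                     viral_genes = 2L, host_genes = 0L, hallmark_genes = 1L,
                     screen_score = 0.9, completeness_pct = 95,
                     lifestyle = "unknown", predicted_host = NA_character_)
  uvigs <- makeUViGSet(setNames(c(s, cl), ids), anno)
  votus <- suppressMessages(clusterVOTUs(uvigs))
  clones <- suppressMessages(detectClones(votus, uvigs))
  expect_gt(nrow(clones), 0)
  expect_warning(
    ev <- suppressMessages(detectEngraftment(clones, uvigs,
                                             scenarioMetadata(), votus)),
    "cross-sex")
  expect_equal(nrow(ev), 0)
})

test_that("multi-donor vOTUs are attributed to every carrying donor", {
  pres <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                 dimnames = list(c("vOTU_0001", "vOTU_0002"),
                                 c("DF01", "DF02")))
  events <- data.frame(votu_id = c("vOTU_0001", "vOTU_0002"),
                       recipient_subject = "RF01", treatment = "FMT",
                       sex = "female", first_detection = "wk6",
                       donors = "", multiple_donors = FALSE, n_evidence = 1L)
  # column-major fixture: vOTU_0001 carried by DF01 only, vOTU_0002 by both
  out <- attributeDonors(events, pres)
  expect_equal(out$donors, c("DF01", "DF01;DF02"))
  expect_equal(out$multiple_donors, c(FALSE, TRUE))
  # an event without any carrying donor is an internal error
  pres0 <- pres; pres0["vOTU_0001", ] <- FALSE
  expect_error(attributeDonors(events, pres0), "internal error")
})

test_that("efficacy arithmetic and the homogeneity test match hand computation", {
  expect_equal(engraftmentEfficacy(63, 100), 0.63)
  expect_equal(engraftmentEfficacy(0, 10), 0)
  expect_true(is.na(engraftmentEfficacy(0, 0)))
  expect_error(engraftmentEfficacy(5, 3))
  # 2x2 engrafted/not by donor table, chi-squared against the direct formula
  tab <- matrix(c(8, 2, 2, 8), 2, 2,
                dimnames = list(c("engrafted", "not"), c("d1", "d2")))
  res <- chisqWithPosthoc(tab)
  expect_equal(res$test$statistic, chisqOracle(tab))
  expect_equal(res$test$statistic, 7.2)
})

test_that("donor efficacy counts shared vOTUs for every carrying donor", {
  pres <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), 3, 2,
                 dimnames = list(paste0("v", 1:3), c("D1", "D2")))
  events <- data.frame(votu_id = c("v1", "v2"), recipient_subject = "R1",
                       treatment = "FMT", sex = "female",
                       first_detection = "wk6", donors = "",
                       multiple_donors = FALSE, n_evidence = 1L)
  eff <- donorEfficacy(events, pres)
  # v1 is carried by both donors -> counted in both numerators
  expect_equal(eff$efficacy$n_engrafted, c(2L, 1L))
  expect_equal(eff$efficacy$n_votus_donor, c(3L, 1L))
  expect_equal(eff$overall$n_engrafted, 2)
  expect_equal(eff$overall$n_donor_votus, 3)
  # sum of per-donor counts >= unique engrafted vOTUs
  expect_gte(sum(eff$efficacy$n_engrafted), eff$overall$n_engrafted)
})

test_that("phageome partition classifies vOTU origins with donor precedence", {
  sc <- engraftScenario(c("wk6", "wk12", "wk26"))
  md <- sc$metadata
  # abundance: donor vOTU present in recipient from wk6; a baseline vOTU
  # conserved through wk26; a novel vOTU at wk12 only
  votus_ids <- as.character(votuTable(sc$votus)$votu_id)
  membership <- votuMembership(sc$votus)
  donor_votu <- unname(membership[["DF01_don.u1"]])
  other_votu <- unname(membership[["RM01_wk6.u9"]])
  m <- matrix(0, 3, nrow(md),
              dimnames = list(c(donor_votu, "vX", "vY"), md$sample_id))
  m[donor_votu, paste0("RF01_", c("wk6", "wk12", "wk26"))] <- 5
  m["vX", paste0("RF01_", c("baseline", "wk6", "wk12", "wk26"))] <- 3
  m["vY", "RF01_wk12"] <- 2
  part <- partitionPhageome(m, sc$clones, sc$uvigs, md, sc$votus)
  p <- part[part$subject == "RF01", ]
  wk12 <- p[p$timepoint == "wk12", ]
  expect_equal(wk12$count[wk12$class == "shared_with_donors"], 1L)
  expect_equal(wk12$count[wk12$class == "conserved_from_baseline"], 1L)
  expect_equal(wk12$count[wk12$class == "novel"], 1L)
  # proportions sum to one whenever any vOTU is present
  sums <- tapply(p$proportion, paste(p$subject, p$timepoint), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # baseline has no novel class
  base <- p[p$timepoint == "baseline", ]
  expect_equal(base$count[base$class == "novel"], 0L)
})

test_that("a missing baseline sample is an error for that subject", {
  sc <- engraftScenario("wk6")
  md <- as.data.frame(sc$metadata)
  md <- md[md$sample_id != "RF01_baseline", ]
  m <- matrix(1, 1, nrow(md),
              dimnames = list("vOTU_0001", md$sample_id))
  expect_error(partitionPhageome(m, sc$clones, sc$uvigs,
                                 validateSampleMetadata(md), sc$votus),
               "baseline")
})
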