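test_that("Shannon diversity matches closed forms and the direct-sum oracle", {
  expect_equal(shannonDiversity(rep(1, 4)), log(4))
  expect_equal(shannonDiversity(c(0, 5, 0)), 0)        # single feature
  expect_true(is.na(shannonDiversity(c(0, 0))))        # undefined
  set.seed(71)
  for (i in 1:20) {
    v <- runif(sample(3:30, 1), 0, 10)
    expect_equal(shannonDiversity(v), shannonOracle(v), tolerance = 1e-12)
  }
  # bounded by log richness, equality iff uniform
  v <- runif(12)
  expect_lte(shannonDiversity(v), log(12))
})

test_that("Bray-Curtis matches its definition and bounds", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 0, 2), c(0, 3, 0)), 1)  # disjoint supports
  expect_equal(brayCurtis(c(1, 1), c(1, 0)), 1 / 3)
  expect_true(is.na(brayCurtis(c(0, 0), c(0, 0))))
  set.seed(72)
  for (i in 1:20) {
    a <- runif(10); b <- runif(10)
    expect_equal(brayCurtis(a, b), brayCurtisOracle(a, b), tolerance = 1e-12)
    expect_equal(brayCurtis(a, b), brayCurtis(b, a))
    expect_gte(brayCurtis(a, b), 0); expect_lte(brayCurtis(a, b), 1)
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  set.seed(73)
  for (i in 1:10) {
    p <- runif(sample(2:20, 1))
    q <- fdrAdjust(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # monotone in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("Pearson test matches exact correlations and the covariance oracle", {
  x <- 1:8
  expect_equal(pearsonTest(x, 2 * x)$estimate, 1)
  expect_equal(pearsonTest(x, -x)$estimate, -1)
  set.seed(74)
  x <- rnorm(8); y <- rnorm(8)
  r <- pearsonTest(x, y)
  expect_equal(r$estimate, pearsonOracle(x, y), tolerance = 1e-12)
  # p from the t distribution with n-2 df
  tval <- r$estimate * sqrt(6 / (1 - r$estimate^2))
  expect_equal(r$p, 2 * pt(-abs(tval), 6), tolerance = 1e-12)
})

test_that("chi-squared with post hoc matches direct arithmetic", {
  tab <- matrix(c(10, 10, 10, 10), 2, 2)
  res <- chisqWithPosthoc(tab)
  expect_equal(res$test$statistic, 0)
  expect_equal(res$test$p, 1)
  tab <- matrix(c(20, 5, 5, 20), 2, 2)
  res <- chisqWithPosthoc(tab)
  expect_equal(res$test$statistic, chisqOracle(tab))
  expect_equal(res$test$statistic, 18)
  # in a 2x2, standardized residuals pair positive with negative in each
  # row and column
  z <- matrix(res$cells$stdres, 2, 2)
  expect_true(all(abs(rowSums(sign(z))) == 0))
  expect_true(all(abs(colSums(sign(z))) == 0))
  expect_true(all(res$cells$q >= res$cells$p))
  # degenerate margin errors
  expect_error(chisqWithPosthoc(matrix(c(0, 0, 3, 4), 2, 2)), "degenerate")
})

test_that("small-table operators agree with direct-formula oracles to 1e-10", {
  set.seed(75)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 15) + 1, 2, 3)
    expect_equal(chisqWithPosthoc(tab)$test$statistic, chisqOracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("LMM contrasts recover an injected arm shift and reject degenerate input", {
  set.seed(76)
  mkdf <- function(shift) {
    subj <- paste0("S", 1:20)
    treat <- rep(c("FMT", "placebo"), each = 10)
    do.call(rbind, lapply(1:20, function(i) {
      re <- rnorm(1, 0, 0.5)
      data.frame(subject = subj[i], treatment = treat[i],
                 timepoint = c("wk6", "wk12", "wk26"),
                 value = rnorm(3, ifelse(treat[i] == "FMT", shift, 0), 1) + re)
    }))
  }
  # injected 2 SD shift is detected at wk6
  ctr <- lmmTimepointContrast(mkdf(2))
  expect_lt(ctr$p[ctr$timepoint == "wk6"], 0.05)
  expect_gt(ctr$estimate[ctr$timepoint == "wk6"], 0)
  # single timepoint is degenerate
  df1 <- mkdf(0); df1 <- df1[df1$timepoint == "wk6", ]
  expect_error(lmmTimepointContrast(df1), "two timepoints")
  # fewer than two subjects per arm is degenerate
  # one placebo subject only (S11 is in the placebo half)
  df2 <- mkdf(0); df2 <- df2[df2$subject %in% c("S1", "S2", "S11"), ]
  expect_error(lmmTimepointContrast(df2), "two subjects")
})

test_that("wilcoxon wrapper uses the exact test for small untied samples", {
  set.seed(77)
  x <- rnorm(8); y <- rnorm(8) + 2
  w <- wilcoxonTest(x, y)
  expect_equal(w$p, wilcox.test(x, y, exact = TRUE)$p.value)
  expect_lt(w$p, 0.05)
})

test_that("variability from week 6 produces per-subject dissimilarities and tests", {
  sim <- simulateCohort(tinySimConfig(seed = 78), sequences = FALSE)
  res <- variabilityFromWk6(truthAbundance(sim), cohortMetadata(sim))
  expect_true(all(res$values$timepoint %in% c("wk12", "wk26")))
  expect_true(all(res$values$bc >= 0 & res$values$bc <= 1))
  # one value per recipient per later timepoint
  md <- as.data.frame(cohortMetadata(sim))
  n_rec <- length(unique(md$subject_id[md$role == "recipient"]))
  expect_equal(nrow(res$values), n_rec * 2)
  expect_true(all(res$tests$q >= res$tests$p))
})

test_that("vOTU stability categories count detection timepoints", {
  md <- scenarioMetadata()
  m <- matrix(0, 2, nrow(md), dimnames = list(c("v1", "v2"), md$sample_id))
  m["v1", "RF01_wk6"] <- 1                     # category 1
  m["v2", paste0("RF01_", c("baseline", "wk6", "wk12", "wk26"))] <- 1  # 4
  res <- votuStability(m, md)
  d <- res$distribution
  expect_equal(d$count[d$category == 1 & d$sex == "female" &
                         d$treatment == "FMT"], 1)
  expect_equal(d$count[d$category == 4 & d$sex == "female" &
                         d$treatment == "FMT"], 1)
})

test_that("lifestyle totals separate temperate and virulent sums", {
  md <- scenarioMetadata()
  m <- matrix(0, 2, nrow(md), dimnames = list(c("v1", "v2"), md$sample_id))
  m["v1", ] <- 2; m["v2", ] <- 5
  ls <- c(v1 = "temperate", v2 = "virulent")
  # only-virulent sample: temperate total 0
  m2 <- m; m2["v1", "RF01_wk6"] <- 0
  res <- suppressWarnings(lifestyleTotals(m2, ls, md))
  tot <- res$totals
  expect_equal(tot$total[tot$sample_id == "RF01_wk6" &
                           tot$lifestyle == "temperate"], 0)
  expect_equal(tot$total[tot$sample_id == "RF01_wk6" &
                           tot$lifestyle == "virulent"], 5)
})
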