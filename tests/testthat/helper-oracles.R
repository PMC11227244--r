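# Independent oracles used against the package's implementations. These are
# deliberately naive direct-formula computations, kept free of any package
# internals.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# percent identity of two equal-length strings (exact ANI oracle for
# substitution-only pairs)
hammingIdentity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y) * 100
}

# direct-sum Shannon entropy
shannonOracle <- function(v) {
  p <- v[v > 0] / sum(v)
  -sum(p * log(p))
}

# direct-formula Bray-Curtis
brayCurtisOracle <- function(a, b) sum(abs(a - b)) / sum(a + b)

# brute-force Pearson r from the covariance formula
pearsonOracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# direct chi-squared statistic sum((O-E)^2/E)
chisqOracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# step-up BH adjustment written out by hand
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# small cohort configuration used by unit tests (fast, not the study-scale
# default)
tinySimConfig <- function(seed = 1L, ...) {
  defaultSimConfig(
    seed = seed, n_donors_per_sex = 2L, donor_richness_range = c(4L, 7L),
    recipient_richness = 4L, n_fmt = 2L, n_placebo = 2L,
    genome_length_range = c(2000L, 4000L), novel_rate_fmt = 1,
    novel_rate_placebo = 1, n_distractors = 1L, n_shared_lineages = 1L,
    mean_depth = 2e4, engraft_prob_intercept = -2.5, ...)
}

# minimal hand-built metadata for engraftment scenarios: one donor and one
# recipient per sex unless overridden
scenarioMetadata <- function() {
  validateSampleMetadata(data.frame(
    sample_id = c("DF01_don", "DM01_don",
                  paste0("RF01_", c("baseline", "wk6", "wk12", "wk26")),
                  paste0("RM01_", c("baseline", "wk6", "wk12", "wk26"))),
    subject_id = c("DF01", "DM01", rep("RF01", 4), rep("RM01", 4)),
    role = c("donor", "donor", rep("recipient", 8)),
    treatment = c("none", "none", rep("FMT", 8)),
    sex = c("female", "male", rep("female", 4), rep("male", 4)),
    timepoint = c("donation", "donation",
                  rep(c("baseline", "wk6", "wk12", "wk26"), 2)),
    donation_round = c(1L, 1L, rep(NA_integer_, 8))))
}
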