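#' @include accessors.R
#' @importFrom stats median setNames p.adjust pnorm
NULL

.abMatrix <- function(x) {
  if (is(x, "AbundanceMatrix")) abundanceValues(x) else as.matrix(x)
}

#' Shannon diversity of abundance profiles
#'
#' Alpha diversity per sample, `H = -sum(p_i * log(p_i))` over features with
#' positive relative abundance, in natural-log units (the convention of the
#' vegan package, to which the computation is delegated). All-zero samples
#' are undefined and reported as `NA`.
#'
#' @param x An [AbundanceMatrix-class] or feature-by-sample matrix (or a
#'   single abundance vector).
#' @param base Logarithm base (default `exp(1)`).
#' @return A named numeric vector of per-sample diversities (or a single
#'   value for a vector input).
#' @export
shannonDiversity <- function(x, base = exp(1)) {
  if (is.null(dim(x)) && !is(x, "AbundanceMatrix")) {
    if (sum(x) <= 0) return(NA_real_)
    return(unname(vegan::diversity(rbind(x), index = "shannon", base = base)))
  }
  m <- .abMatrix(x)
  h <- vegan::diversity(t(m), index = "shannon", base = base)
  h[colSums(m) <= 0] <- NA_real_
  setNames(as.numeric(h), colnames(m))
}

#' Bray-Curtis dissimilarity
#'
#' `BC = sum|a_i - b_i| / sum(a_i + b_i)`: 0 for identical profiles, 1 for
#' disjoint supports. Undefined (NA) when both profiles are all-zero.
#' Delegates to [vegan::vegdist()].
#'
#' @param a,b Abundance vectors over the same features.
#' @return A single dissimilarity in `[0, 1]`, or `NA`.
#' @export
brayCurtis <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sum(a) + sum(b) <= 0) return(NA_real_)
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; `q >= p` elementwise and `q` is
#' monotone in the sorted-p order. Thin wrapper over [stats::p.adjust()] so
#' every adjustment in the package goes through one place.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values.
#' @export
fdrAdjust <- function(p) p.adjust(p, method = "BH")

#' Pearson correlation test
#'
#' Correlation coefficient with a two-sided p-value from the t-distribution
#' on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors.
#' @return A one-row data.frame with `estimate`, `p`, `n`.
#' @export
pearsonTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  data.frame(estimate = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Pearson chi-squared test with standardized-residual post hoc
#'
#' Pearson's chi-squared test (no continuity correction, so the statistic is
#' exactly `sum((O - E)^2 / E)`), followed by a per-cell post hoc analysis on
#' standardized Pearson residuals: each residual gets a two-sided normal
#' p-value and the cell p-values are BH-FDR adjusted across the table.
#'
#' @param tab A contingency table (matrix of counts).
#' @return A list with `test` (one-row data.frame: `statistic`, `df`, `p`)
#'   and `cells` (data.frame: `row`, `col`, `observed`, `expected`,
#'   `stdres`, `p`, `q`).
#' @export
chisqWithPosthoc <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("degenerate margin: a cell has expected count 0", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  z <- ct$stdres
  pc <- 2 * pnorm(-abs(z))
  cells <- data.frame(
    row = rep(rownames(tab) %||% seq_len(nrow(tab)), ncol(tab)),
    col = rep(colnames(tab) %||% seq_len(ncol(tab)), each = nrow(tab)),
    observed = as.vector(tab), expected = as.vector(ct$expected),
    stdres = as.vector(z), p = as.vector(pc))
  cells$q <- fdrAdjust(cells$p)
  list(test = data.frame(statistic = unname(ct$statistic),
                         df = unname(ct$parameter), p = ct$p.value),
       cells = cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilcoxon rank-sum comparison
#'
#' Two-group comparison via [stats::wilcox.test()], exact when both groups
#' have at most 25 observations and no ties, otherwise the normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return One-row data.frame with `statistic`, `p`, `n_x`, `n_y`.
#' @export
wilcoxonTest <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  exact <- max(length(x), length(y)) <= 25 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  data.frame(statistic = unname(wt$statistic), p = wt$p.value,
             n_x = length(x), n_y = length(y))
}

## ---- linear mixed model contrasts -------------------------------------------

#' Per-timepoint treatment contrasts from a linear mixed-effects model
#'
#' Fits `value ~ treatment * timepoint` with a random intercept per subject
#' (REML, via lmerTest) and reports the FMT-minus-placebo contrast at each
#' timepoint present in the data (emmeans, Satterthwaite df). A singular fit
#' falls back to the fixed-effects model with a warning. The returned `q`
#' is BH-adjusted across the returned contrasts; callers pooling a larger
#' family should re-adjust from `p`.
#'
#' @param df Data.frame with columns `subject`, `treatment` (two levels),
#'   `timepoint`, `value`.
#' @return Data.frame with one row per timepoint: `timepoint`, `estimate`
#'   (difference between the first and second treatment level), `se`, `p`,
#'   `q`.
#' @export
lmmTimepointContrast <- function(df) {
  df <- df[is.finite(df$value), , drop = FALSE]
  tps <- intersect(.RECIPIENT_TIMEPOINTS, unique(df$timepoint))
  if (length(tps) < 2)
    stop("need at least two timepoints for a treatment-by-time model",
         call. = FALSE)
  df$timepoint <- factor(df$timepoint, levels = tps)
  df$treatment <- factor(df$treatment)
  if (nlevels(df$treatment) != 2)
    stop("treatment must have exactly two levels", call. = FALSE)
  counts <- table(unique(df[c("subject", "treatment")])$treatment)
  if (any(counts < 2))
    stop("need at least two subjects per arm", call. = FALSE)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      value ~ treatment * timepoint + (1 | subject), data = df,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    warning("singular mixed-model fit; falling back to fixed effects",
            call. = FALSE)
    fit <- stats::lm(value ~ treatment * timepoint, data = df)
  }
  emm <- emmeans::emmeans(fit, ~ treatment | timepoint,
                          lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise"))
  out <- data.frame(timepoint = as.character(ctr$timepoint),
                    estimate = ctr$estimate, se = ctr$SE, p = ctr$p.value)
  out$q <- fdrAdjust(out$p)
  out
}

## ---- longitudinal summaries -------------------------------------------------

.recipientMeta <- function(metadata) {
  md <- as.data.frame(metadata)
  md[md$role == "recipient", , drop = FALSE]
}

#' Phageome variability from week 6
#'
#' Per-subject Bray-Curtis dissimilarity between the week-6 profile and each
#' subsequent timepoint (weeks 12 and 26), compared between treatment arms
#' per sex and timepoint with Wilcoxon rank-sum tests, BH-FDR adjusted
#' within the family of comparisons. Subjects without a week-6 sample are
#' skipped with a warning.
#'
#' @param abund An [AbundanceMatrix-class] or matrix, features x samples.
#' @param metadata Sample metadata (see [readSampleMetadata()]).
#' @return A list with `values` (subject, sex, treatment, timepoint, bc) and
#'   `tests` (sex, timepoint, statistic, p, q).
#' @export
variabilityFromWk6 <- function(abund, metadata) {
  m <- .abMatrix(abund)
  md <- .recipientMeta(metadata)
  rows <- list()
  for (subj in unique(md$subject_id)) {
    sm <- md[md$subject_id == subj, ]
    wk6 <- sm$sample_id[sm$timepoint == "wk6"]
    if (!length(wk6) || !wk6 %in% colnames(m)) {
      warning("subject without week-6 sample skipped: ", subj, call. = FALSE)
      next
    }
    for (tp in c("wk12", "wk26")) {
      sid <- sm$sample_id[sm$timepoint == tp]
      if (!length(sid) || !sid %in% colnames(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, sex = sm$sex[1], treatment = sm$treatment[1],
        timepoint = tp, bc = brayCurtis(m[, wk6], m[, sid]))
    }
  }
  values <- do.call(rbind, rows)
  tests <- list()
  for (sex in unique(values$sex)) {
    for (tp in c("wk12", "wk26")) {
      v <- values[values$sex == sex & values$timepoint == tp, ]
      if (length(unique(v$treatment)) < 2) next
      wt <- wilcoxonTest(v$bc[v$treatment == "FMT"],
                         v$bc[v$treatment == "placebo"])
      tests[[length(tests) + 1L]] <- data.frame(
        sex = sex, timepoint = tp, statistic = wt$statistic, p = wt$p)
    }
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) tests$q <- fdrAdjust(tests$p)
  list(values = values, tests = tests)
}

#' vOTU temporal stability
#'
#' For each recipient, every vOTU detected in the subject is classified by
#' the number of timepoints (1-4) at which it is detected (abundance > 0).
#' The per-sex 2 x 4 treatment-by-category tables are tested with Pearson's
#' chi-squared, with standardized-residual post hoc analysis (BH-FDR across
#' cells).
#'
#' @inheritParams variabilityFromWk6
#' @return A list with `distribution` (sex, treatment, category, count) and
#'   `tests` (a named list per sex, each as in [chisqWithPosthoc()]).
#' @export
votuStability <- function(abund, metadata) {
  m <- .abMatrix(abund)
  md <- .recipientMeta(metadata)
  rows <- list()
  for (subj in unique(md$subject_id)) {
    sm <- md[md$subject_id == subj, ]
    sids <- sm$sample_id[sm$sample_id %in% colnames(m)]
    if (!length(sids)) next
    ntp <- rowSums(m[, sids, drop = FALSE] > 0)
    ntp <- ntp[ntp > 0]
    if (!length(ntp)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sm$sex[1], treatment = sm$treatment[1],
      category = factor(ntp, levels = 1:4))
  }
  df <- do.call(rbind, rows)
  distribution <- as.data.frame(table(sex = df$sex, treatment = df$treatment,
                                      category = df$category,
                                      dnn = c("sex", "treatment", "category")))
  names(distribution)[4] <- "count"
  tests <- list()
  for (sex in unique(df$sex)) {
    tab <- table(df$treatment[df$sex == sex], df$category[df$sex == sex])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) == 2 && ncol(tab) >= 2)
      tests[[sex]] <- chisqWithPosthoc(tab)
  }
  list(distribution = distribution, tests = tests)
}

#' Total abundance of temperate and virulent phages with LMM contrasts
#'
#' Per sample, sums the abundance of vOTUs whose representative UViG is
#' temperate (resp. virulent); unknown lifestyles are excluded. Treatment
#' contrasts of the change from baseline are estimated per sex and lifestyle
#' with [lmmTimepointContrast()], and p-values are BH-FDR adjusted within
#' each sex (across lifestyles and timepoints).
#'
#' @param abund vOTU-by-sample [AbundanceMatrix-class] or matrix.
#' @param lifestyleOfFeature Named character vector mapping each feature
#'   (row of `abund`) to a lifestyle (`temperate` / `virulent` / `unknown`).
#'   For pipeline output use [votuLifestyles()].
#' @param metadata Sample metadata.
#' @return A list with `totals` (sample-level totals per lifestyle) and
#'   `contrasts` (sex, lifestyle, timepoint, estimate, p, q).
#' @export
lifestyleTotals <- function(abund, lifestyleOfFeature, metadata) {
  m <- .abMatrix(abund)
  md <- .recipientMeta(metadata)
  ls <- lifestyleOfFeature[rownames(m)]
  totals <- list()
  for (lf in c("temperate", "virulent")) {
    tot <- colSums(m[which(ls == lf), , drop = FALSE])
    totals[[lf]] <- data.frame(sample_id = colnames(m), lifestyle = lf,
                               total = as.numeric(tot))
  }
  totals <- do.call(rbind, totals)
  rownames(totals) <- NULL
  contrasts <- list()
  for (sex in unique(md$sex)) {
    sexp <- list()
    for (lf in c("temperate", "virulent")) {
      sm <- md[md$sex == sex, ]
      tot <- setNames(totals$total[totals$lifestyle == lf],
                      totals$sample_id[totals$lifestyle == lf])
      base <- sm[sm$timepoint == "baseline", ]
      base_tot <- setNames(tot[base$sample_id], base$subject_id)
      post <- sm[sm$timepoint != "baseline", ]
      df <- data.frame(subject = post$subject_id, treatment = post$treatment,
                       timepoint = post$timepoint,
                       value = tot[post$sample_id] -
                         base_tot[post$subject_id])
      ctr <- tryCatch(lmmTimepointContrast(df), error = function(e) {
        warning("lifestyle contrast skipped (", sex, "/", lf, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(ctr)) next
      ctr$sex <- sex; ctr$lifestyle <- lf
      sexp[[lf]] <- ctr
    }
    if (!length(sexp)) next
    sexdf <- do.call(rbind, sexp)
    sexdf$q <- fdrAdjust(sexdf$p)   # family: all contrasts within a sex
    contrasts[[sex]] <- sexdf
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL
  if (!is.null(contrasts)) {
    rownames(contrasts) <- NULL
    contrasts <- contrasts[, c("sex", "lifestyle", "timepoint",
                               "estimate", "se", "p", "q")]
  }
  list(totals = totals, contrasts = contrasts)
}

#' Lifestyle of each vOTU from its representative UViG
#'
#' @param votus A [VOTUSet-class].
#' @param uvigs The corresponding [UViGSet-class].
#' @return Named character vector votu_id -> lifestyle.
#' @export
votuLifestyles <- function(votus, uvigs) {
  anno <- uvigAnnotations(uvigs)
  reps <- votuRepresentatives(votus)
  setNames(as.character(anno$lifestyle[match(reps, anno$uvig_id)]),
           names(reps))
}

#' Alpha-diversity treatment contrast
#'
#' Shannon diversity per recipient sample; the default response is each
#' subject's change from baseline at weeks 6, 12 and 26, contrasted between
#' arms per sex with [lmmTimepointContrast()] (`response = "raw"` instead
#' models the raw values with baseline as a timepoint).
#'
#' @inheritParams variabilityFromWk6
#' @param response `"change"` (default) or `"raw"`.
#' @return A list with `diversity` (per-sample values) and `contrasts`
#'   (sex, timepoint, estimate, p, q; FDR within sex).
#' @export
diversityContrast <- function(abund, metadata, response = c("change", "raw")) {
  response <- match.arg(response)
  m <- .abMatrix(abund)
  md <- .recipientMeta(metadata)
  h <- shannonDiversity(m)
  contrasts <- list()
  for (sex in unique(md$sex)) {
    sm <- md[md$sex == sex, ]
    if (response == "change") {
      base <- sm[sm$timepoint == "baseline", ]
      base_h <- setNames(h[base$sample_id], base$subject_id)
      post <- sm[sm$timepoint != "baseline", ]
      df <- data.frame(subject = post$subject_id, treatment = post$treatment,
                       timepoint = post$timepoint,
                       value = h[post$sample_id] - base_h[post$subject_id])
    } else {
      df <- data.frame(subject = sm$subject_id, treatment = sm$treatment,
                       timepoint = sm$timepoint, value = h[sm$sample_id])
    }
    ctr <- tryCatch(lmmTimepointContrast(df), error = function(e) {
      warning("diversity contrast skipped (", sex, "): ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(ctr)) next
    ctr$q <- fdrAdjust(ctr$p)
    ctr$sex <- sex
    contrasts[[sex]] <- ctr
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL
  if (!is.null(contrasts)) {
    rownames(contrasts) <- NULL
    contrasts <- contrasts[, c("sex", "timepoint", "estimate", "se",
                               "p", "q")]
  }
  list(diversity = data.frame(sample_id = names(h), shannon = as.numeric(h)),
       contrasts = contrasts)
}

#' Convergence of recipient phageomes toward individual donors
#'
#' Bray-Curtis dissimilarity between every recipient sample and each
#' sex-matched donor profile, modelled per donor with
#' [lmmTimepointContrast()] on the raw dissimilarities (treatment-by-time
#' interaction, subject random intercept). The p-values of all donors and
#' timepoints are collectively BH-FDR adjusted.
#'
#' @inheritParams variabilityFromWk6
#' @return A list with `values` (subject, donor, timepoint, bc, ...) and
#'   `contrasts` (donor, timepoint, estimate, p, q).
#' @export
donorConvergence <- function(abund, metadata) {
  m <- .abMatrix(abund)
  md <- as.data.frame(metadata)
  dm <- md[md$role == "donor", ]
  rm_ <- .recipientMeta(metadata)
  values <- list()
  for (di in seq_len(nrow(dm))) {
    dsid <- dm$sample_id[di]
    if (!dsid %in% colnames(m)) next
    rec <- rm_[rm_$sex == dm$sex[di], ]
    rec <- rec[rec$sample_id %in% colnames(m), ]
    if (!nrow(rec)) next
    bc <- vapply(rec$sample_id,
                 function(s) brayCurtis(m[, dsid], m[, s]), 0)
    values[[length(values) + 1L]] <- data.frame(
      donor = dm$subject_id[di], subject = rec$subject_id,
      treatment = rec$treatment, sex = rec$sex, timepoint = rec$timepoint,
      bc = as.numeric(bc))
  }
  values <- do.call(rbind, values)
  contrasts <- list()
  for (d in unique(values$donor)) {
    v <- values[values$donor == d, ]
    df <- data.frame(subject = v$subject, treatment = v$treatment,
                     timepoint = v$timepoint, value = v$bc)
    ctr <- tryCatch(lmmTimepointContrast(df), error = function(e) NULL)
    if (is.null(ctr)) next
    ctr$donor <- d
    contrasts[[d]] <- ctr
  }
  contrasts <- do.call(rbind, contrasts)
  if (!is.null(contrasts)) {
    contrasts$q <- fdrAdjust(contrasts$p)   # collective family
    rownames(contrasts) <- NULL
    contrasts <- contrasts[, c("donor", "timepoint", "estimate", "se",
                               "p", "q")]
  }
  list(values = values, contrasts = contrasts)
}
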