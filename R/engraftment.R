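#' @include cluster.R stats.R
NULL

.TP_ORDER <- setNames(seq_along(.RECIPIENT_TIMEPOINTS), .RECIPIENT_TIMEPOINTS)

## annotate each side of a clone pair with its sample's metadata
.pairMeta <- function(clones, uvigs, metadata) {
  anno <- as.data.frame(uvigAnnotations(uvigs))
  md <- as.data.frame(metadata)
  sample_of <- setNames(anno$sample_id, anno$uvig_id)
  mrow <- function(sid, field) md[[field]][match(sid, md$sample_id)]
  sa <- sample_of[clones$uvig_a]; sb <- sample_of[clones$uvig_b]
  data.frame(clones,
             subject_a = mrow(sa, "subject_id"), subject_b = mrow(sb, "subject_id"),
             role_a = mrow(sa, "role"), role_b = mrow(sb, "role"),
             sex_a = mrow(sa, "sex"), sex_b = mrow(sb, "sex"),
             treatment_a = mrow(sa, "treatment"), treatment_b = mrow(sb, "treatment"),
             timepoint_a = mrow(sa, "timepoint"), timepoint_b = mrow(sb, "timepoint"))
}

#' Call engraftment events from clone evidence
#'
#' A donor phage is engrafted when a clonal UViG (ANI >= 99.4% over AF >=
#' 0.85, within a vOTU) of a sex-matched donor UViG is identified in a
#' recipient at or after week 6, provided no donor-clone of that vOTU was
#' present in the recipient's baseline sample. Events are keyed by
#' (vOTU, recipient); the first detection is the earliest qualifying
#' timepoint. Placebo recipients are processed identically — their events
#' are a pipeline false-positive control, not a biological claim.
#' Cross-sex donor-recipient clone pairs are excluded with a warning
#' (capsules were administered sex-specifically).
#'
#' @param clones Clone-pair table from [detectClones()].
#' @param uvigs The [UViGSet-class] (for UViG-to-sample assignment).
#' @param metadata Sample metadata.
#' @param votus The [VOTUSet-class] the clones were detected within.
#' @return A data.frame with one row per event: `votu_id`,
#'   `recipient_subject`, `treatment`, `sex`, `first_detection`, `donors`
#'   (";"-separated), `multiple_donors`, `n_evidence`.
#' @export
detectEngraftment <- function(clones, uvigs, metadata, votus) {
  if (!nrow(clones)) {
    .stageLog("engraft", "0 events (no clone pairs)")
    return(data.frame(votu_id = character(), recipient_subject = character(),
                      treatment = character(), sex = character(),
                      first_detection = character(), donors = character(),
                      multiple_donors = logical(), n_evidence = integer()))
  }
  pm <- .pairMeta(clones, uvigs, metadata)
  ## orient donor -> recipient
  dr <- pm[pm$role_a != pm$role_b, , drop = FALSE]
  flip <- dr$role_a == "recipient"
  donor_subj <- ifelse(flip, dr$subject_b, dr$subject_a)
  rec_subj <- ifelse(flip, dr$subject_a, dr$subject_b)
  rec_tp <- ifelse(flip, dr$timepoint_a, dr$timepoint_b)
  rec_treat <- ifelse(flip, dr$treatment_a, dr$treatment_b)
  rec_sex <- ifelse(flip, dr$sex_a, dr$sex_b)
  cross <- dr$sex_a != dr$sex_b
  if (any(cross)) {
    warning(sum(cross), " cross-sex donor-recipient clone pair(s) excluded",
            call. = FALSE)
    dr <- dr[!cross, , drop = FALSE]
    donor_subj <- donor_subj[!cross]; rec_subj <- rec_subj[!cross]
    rec_tp <- rec_tp[!cross]; rec_treat <- rec_treat[!cross]
    rec_sex <- rec_sex[!cross]
  }
  key <- paste(dr$votu_id, rec_subj, sep = "\r")
  ## disqualify (vOTU, recipient) with a donor clone at baseline
  disq <- unique(key[rec_tp == "baseline"])
  post <- rec_tp %in% c("wk6", "wk12", "wk26") & !key %in% disq
  if (!any(post)) {
    .stageLog("engraft", "0 events")
    return(data.frame(votu_id = character(), recipient_subject = character(),
                      treatment = character(), sex = character(),
                      first_detection = character(), donors = character(),
                      multiple_donors = logical(), n_evidence = integer()))
  }
  dpost <- data.frame(votu_id = dr$votu_id[post], recipient = rec_subj[post],
                      treatment = rec_treat[post], sex = rec_sex[post],
                      donor = donor_subj[post], timepoint = rec_tp[post],
                      key = key[post])
  events <- lapply(split(dpost, dpost$key), function(g) {
    donors <- sort(unique(g$donor))
    data.frame(votu_id = g$votu_id[1], recipient_subject = g$recipient[1],
               treatment = g$treatment[1], sex = g$sex[1],
               first_detection =
                 names(.TP_ORDER)[min(.TP_ORDER[g$timepoint])],
               donors = paste(donors, collapse = ";"),
               multiple_donors = length(donors) > 1,
               n_evidence = nrow(g))
  })
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  .stageLog("engraft", nrow(out), " engraftment events (",
            sum(out$treatment == "placebo"), " in placebo recipients)")
  out
}

#' Donor presence of vOTUs
#'
#' Logical vOTU-by-donor matrix: a vOTU is identified in a donor when the
#' donor contributed a member UViG.
#'
#' @param votus A [VOTUSet-class].
#' @param uvigs The [UViGSet-class].
#' @param metadata Sample metadata.
#' @return A logical matrix (vOTUs x donors).
#' @export
donorVotuPresence <- function(votus, uvigs, metadata) {
  anno <- as.data.frame(uvigAnnotations(uvigs))
  md <- as.data.frame(metadata)
  donors <- md$subject_id[md$role == "donor"]
  donors <- unique(donors)
  membership <- votuMembership(votus)
  subj <- md$subject_id[match(anno$sample_id, md$sample_id)]
  votu_of <- membership[anno$uvig_id]
  pres <- matrix(FALSE, nrow(votuTable(votus)), length(donors),
                 dimnames = list(as.character(votuTable(votus)$votu_id),
                                 donors))
  keep <- subj %in% donors & !is.na(votu_of)
  idx <- cbind(votu_of[keep], subj[keep])
  pres[idx] <- TRUE
  pres
}

#' Attribute donors to engraftment events
#'
#' Assigns to each event every donor carrying its vOTU (from the donor
#' presence table); events with more than one carrying donor are tagged as
#' donated by "multiple" donors and the vOTU counts toward every carrying
#' donor's engrafted total. An event whose vOTU has no carrying donor is an
#' internal inconsistency (an event requires donor clone evidence).
#'
#' @param events Events from [detectEngraftment()].
#' @param donorPresence Matrix from [donorVotuPresence()].
#' @return `events` with `donors` / `multiple_donors` recomputed from
#'   presence.
#' @export
attributeDonors <- function(events, donorPresence) {
  if (!nrow(events)) return(events)
  donors <- colnames(donorPresence)
  att <- vapply(as.character(events$votu_id), function(v) {
    d <- donors[donorPresence[v, ]]
    if (!length(d))
      stop("internal error: event vOTU ", v, " has no carrying donor",
           call. = FALSE)
    paste(sort(d), collapse = ";")
  }, "")
  events$donors <- unname(att)
  events$multiple_donors <- lengths(strsplit(events$donors, ";")) > 1
  events
}

#' Engraftment efficacy arithmetic
#'
#' The proportion of donor vOTUs that engrafted relative to the total number
#' of vOTUs identified in the donor.
#'
#' @param nEngrafted,nTotal Engrafted and total vOTU counts.
#' @return `nEngrafted / nTotal` (NA when `nTotal` is 0).
#' @export
engraftmentEfficacy <- function(nEngrafted, nTotal) {
  stopifnot(all(nEngrafted >= 0), all(nTotal >= 0),
            all(nEngrafted <= nTotal))
  ifelse(nTotal > 0, nEngrafted / nTotal, NA_real_)
}

#' Per-donor engraftment efficacy with homogeneity test
#'
#' For each donor: the number of vOTUs identified in the donor, the number
#' of those engrafted in at least one recipient (a vOTU carried by several
#' donors counts toward each carrying donor), and their ratio. Efficacy
#' homogeneity across donors is tested with Pearson's chi-squared on the
#' engrafted/not-engrafted by donor table, with standardized-residual post
#' hoc analysis (BH-FDR across cells).
#'
#' @param events Events from [detectEngraftment()] (donors attributed).
#' @param donorPresence Matrix from [donorVotuPresence()].
#' @return A list with `efficacy` (donor, n_votus_donor, n_engrafted,
#'   efficacy), `overall` (one-row data.frame with unique-vOTU totals), and
#'   `test` / `cells` from [chisqWithPosthoc()] (NULL when degenerate).
#' @export
donorEfficacy <- function(events, donorPresence) {
  donors <- colnames(donorPresence)
  n_votus <- colSums(donorPresence)
  engrafted_votus <- unique(as.character(
    events$votu_id[events$treatment == "FMT"]))
  n_eng <- vapply(donors, function(d)
    sum(donorPresence[engrafted_votus, d, drop = TRUE]), 0L)
  eff <- data.frame(donor = donors, n_votus_donor = as.integer(n_votus),
                    n_engrafted = as.integer(n_eng),
                    efficacy = engraftmentEfficacy(n_eng, n_votus))
  donor_union <- rownames(donorPresence)[rowSums(donorPresence) > 0]
  overall <- data.frame(
    n_donor_votus = length(donor_union),
    n_engrafted = sum(engrafted_votus %in% donor_union),
    efficacy = engraftmentEfficacy(sum(engrafted_votus %in% donor_union),
                                   length(donor_union)))
  tab <- rbind(engrafted = eff$n_engrafted,
               not_engrafted = eff$n_votus_donor - eff$n_engrafted)
  colnames(tab) <- donors
  ht <- tryCatch(chisqWithPosthoc(tab[, eff$n_votus_donor > 0, drop = FALSE]),
                 error = function(e) NULL)
  c(list(efficacy = eff, overall = overall), ht)
}

#' Partition a recipient phageome by vOTU origin
#'
#' Classifies every vOTU identified (abundance > 0) in each recipient sample
#' as (1) shared with the sex-matched donors, (2) conserved from the
#' subject's baseline, or (3) novel. Donor sharing uses clone-level evidence
#' by default (a clone pair links the subject to a sex-matched donor within
#' the vOTU), consistent with the engraftment definition;
#' `donorMatch = "votu"` relaxes to vOTU-level presence in any sex-matched
#' donor. Baseline samples have no novel class. Precedence: a vOTU both
#' donor-shared and present at baseline is labeled shared with donors (it is
#' still not an engraftment event — baseline presence disqualifies there).
#'
#' @param abund vOTU-by-sample [AbundanceMatrix-class] or matrix.
#' @param clones Clone-pair table from [detectClones()].
#' @param uvigs The [UViGSet-class].
#' @param metadata Sample metadata.
#' @param votus The [VOTUSet-class].
#' @param donorMatch `"clone"` (default) or `"votu"`.
#' @return A data.frame with one row per (subject, timepoint, class):
#'   `subject`, `sex`, `treatment`, `timepoint`, `class`, `count`,
#'   `proportion`.
#' @export
partitionPhageome <- function(abund, clones, uvigs, metadata, votus,
                              donorMatch = c("clone", "votu")) {
  donorMatch <- match.arg(donorMatch)
  m <- .abMatrix(abund)
  md <- as.data.frame(metadata)
  rec <- .recipientMeta(metadata)
  membership <- votuMembership(votus)

  ## donor-shared keys
  if (donorMatch == "clone") {
    shared_keys <- character(0)
    if (nrow(clones)) {
      pm <- .pairMeta(clones, uvigs, metadata)
      dr <- pm[pm$role_a != pm$role_b & pm$sex_a == pm$sex_b, , drop = FALSE]
      if (nrow(dr)) {
        rec_subj <- ifelse(dr$role_a == "recipient", dr$subject_a,
                           dr$subject_b)
        shared_keys <- unique(paste(dr$votu_id, rec_subj, sep = "\r"))
      }
    }
    isShared <- function(votu, subj, sex)
      paste(votu, subj, sep = "\r") %in% shared_keys
  } else {
    pres <- donorVotuPresence(votus, uvigs, metadata)
    donor_sex <- setNames(md$sex[match(colnames(pres), md$subject_id)],
                          colnames(pres))
    isShared <- function(votu, subj, sex)
      any(pres[votu, donor_sex[colnames(pres)] == sex])
  }

  out <- list()
  for (subj in unique(rec$subject_id)) {
    sm <- rec[rec$subject_id == subj, ]
    bsid <- sm$sample_id[sm$timepoint == "baseline"]
    if (!length(bsid) || !bsid %in% colnames(m))
      stop("recipient without baseline sample: ", subj, call. = FALSE)
    baseline_votus <- rownames(m)[m[, bsid] > 0]
    for (tp in intersect(.RECIPIENT_TIMEPOINTS, sm$timepoint)) {
      sid <- sm$sample_id[sm$timepoint == tp]
      if (!sid %in% colnames(m)) next
      present <- rownames(m)[m[, sid] > 0]
      if (!length(present)) next
      shared <- vapply(present, isShared, TRUE, subj = subj, sex = sm$sex[1])
      conserved <- !shared & present %in% baseline_votus
      novel <- !shared & !conserved
      if (tp == "baseline") { conserved <- conserved | novel; novel <- rep(FALSE, length(novel)) }
      counts <- c(shared_with_donors = sum(shared),
                  conserved_from_baseline = sum(conserved),
                  novel = sum(novel))
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, sex = sm$sex[1], treatment = sm$treatment[1],
        timepoint = tp, class = names(counts), count = as.integer(counts),
        proportion = as.numeric(counts) / length(present))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
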