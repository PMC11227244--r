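#' @include accessors.R io.R
NULL

#' Default configuration of the synthetic FMT cohort generator
#'
#' The generator emulates a sex-stratified, placebo-controlled FMT trial:
#' 4 donors per sex with differing phageome richness, sex-matched FMT and
#' placebo recipients sampled at baseline and 6, 12 and 26 weeks, clonal
#' transfer of donor phages into FMT recipients only (from week 6 onward),
#' near-threshold non-clone relatives of donor phages at recipient baselines,
#' novel lineages appearing at single later timepoints, and overdispersed
#' gene-level read counts. Genome and cohort sizes are desk-scale so that a
#' full sequence-level run completes in minutes on one CPU.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param ... Named overrides of any default field.
#' @return A list with class `SimConfig`. Fields:
#' \describe{
#'   \item{n_donors_per_sex}{donors per sex (default 4, i.e. 8 donors).}
#'   \item{donor_richness_range}{phage lineages per donor, sampled uniformly.}
#'   \item{recipient_richness}{baseline lineages per recipient.}
#'   \item{n_fmt, n_placebo}{recipients per sex and arm.}
#'   \item{genome_length_range}{UViG length range in bp.}
#'   \item{gene_length_range}{gene length range in bp (non-overlapping genes
#'     tiling at least 70\% of each genome).}
#'   \item{clone_divergence}{substitutions/site of transferred clones
#'     (default 0.001, i.e. ~99.9\% identity, above the 99.4\% clone cut).}
#'   \item{distractor_divergence}{divergence of near-threshold non-clone
#'     baseline relatives (default 0.03: same vOTU, not a clone).}
#'   \item{engraft_prob_slope, engraft_prob_intercept}{logistic link from a
#'     donor's realized Shannon diversity to the per-recipient, per-phage
#'     transfer probability `plogis(intercept + slope * H)`.}
#'   \item{temperate_fraction}{fraction of lineages that are temperate.}
#'   \item{temperate_postfmt_fold}{abundance multiplier (>= 1) applied to
#'     temperate lineages in FMT recipients after baseline.}
#'   \item{count_dispersion}{negative-binomial dispersion of gene counts
#'     (variance = mu + dispersion * mu^2; 0 gives Poisson).}
#'   \item{mean_depth}{expected reads per sample.}
#'   \item{novel_rate_fmt, novel_rate_placebo}{Poisson rate of novel
#'     lineages injected per post-baseline timepoint, per arm.}
#'   \item{n_distractors}{donor-lineage relatives per recipient baseline.}
#'   \item{n_shared_lineages}{lineages seeded into two same-sex donors, to
#'     exercise multi-donor attribution.}
#'   \item{baseline_persistence}{probability a baseline lineage is detected
#'     at each post-baseline timepoint.}
#'   \item{abund_sdlog, timepoint_sdlog}{log-normal spread of lineage base
#'     abundances and of their per-timepoint jitter.}
#' }
#' @export
defaultSimConfig <- function(seed = 1L, ...) {
  config <- list(
    seed = as.integer(seed),
    n_donors_per_sex = 4L,
    donor_richness_range = c(12L, 30L),
    recipient_richness = 12L,
    n_fmt = 10L,
    n_placebo = 10L,
    genome_length_range = c(5000L, 12000L),
    gene_length_range = c(300L, 1500L),
    clone_divergence = 0.001,
    distractor_divergence = 0.03,
    engraft_prob_slope = 1.0,
    engraft_prob_intercept = -5.5,
    temperate_fraction = 0.15,
    temperate_postfmt_fold = 3,
    count_dispersion = 0.5,
    mean_depth = 1e5,
    novel_rate_fmt = 4,
    novel_rate_placebo = 2,
    n_distractors = 4L,
    n_shared_lineages = 2L,
    baseline_persistence = 0.8,
    abund_sdlog = 1,
    timepoint_sdlog = 0.4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown))
    stop("unknown SimConfig fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config[names(dots)] <- dots
  .validateSimConfig(config)
  class(config) <- c("SimConfig", "list")
  config
}

#' @rdname defaultSimConfig
#' @details `nullSimConfig` returns the generator's null: no transfers, equal
#' novel-injection rates in both arms, and no temperate fold change, so any
#' treatment contrast downstream is a false positive. Used for type-I error
#' control checks.
#' @export
nullSimConfig <- function(seed = 1L, ...) {
  defaultSimConfig(seed = seed, engraft_prob_slope = 0,
                   engraft_prob_intercept = -Inf,
                   novel_rate_fmt = 2, novel_rate_placebo = 2,
                   temperate_postfmt_fold = 1, ...)
}

#' @rdname defaultSimConfig
#' @param path Path to a YAML file whose keys are SimConfig fields; missing
#'   fields take their defaults.
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  seed <- if (!is.null(vals$seed)) as.integer(vals$seed) else 1L
  vals$seed <- NULL
  do.call(defaultSimConfig, c(list(seed = seed), vals))
}

.validateSimConfig <- function(config) {
  stopifnot(
    config$temperate_fraction >= 0, config$temperate_fraction <= 1,
    config$temperate_postfmt_fold >= 1,
    config$clone_divergence >= 0, config$clone_divergence <= 0.2,
    config$distractor_divergence >= 0, config$distractor_divergence <= 0.2,
    config$baseline_persistence >= 0, config$baseline_persistence <= 1,
    diff(config$donor_richness_range) >= 0,
    diff(config$genome_length_range) >= 0,
    config$n_distractors <= config$recipient_richness)
  invisible(config)
}

#' Simulate one phage genome with gene coordinates and screening annotations
#'
#' Draws a uniform-random nucleotide sequence, tiles it with non-overlapping
#' genes (tiling at least 70\% of the genome), and draws annotation fields
#' guaranteed to pass the contig screen (>= 1 viral gene, <= 4 host genes,
#' HVR <= 0.386, completeness >= 90). Uses the current RNG state.
#'
#' @param length Genome length in bp (>= 1000).
#' @param geneLengthRange Gene length range in bp.
#' @return A list with `sequence` (character), `genes` (data.frame of
#'   0-based half-open `start`, `end`, `length_bp`), and `anno` (list of
#'   `viral_genes`, `host_genes`, `hallmark_genes`, `screen_score`,
#'   `completeness_pct`).
#' @export
simulateGenome <- function(length, geneLengthRange = c(300L, 1500L)) {
  if (length < 1000)
    stop("genome length < 1000 bp: too short to tile genes", call. = FALSE)
  sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
  lo <- geneLengthRange[1]; hi <- geneLengthRange[2]
  starts <- ends <- integer(0)
  pos <- 0L
  while (length - pos >= lo) {
    glen <- min(sample(lo:hi, 1L), length - pos)
    starts <- c(starts, pos)
    ends <- c(ends, pos + glen)
    pos <- pos + glen + sample(0:60, 1L)
  }
  genes <- data.frame(start = as.integer(starts), end = as.integer(ends),
                      length_bp = as.integer(ends - starts))
  viral <- sample(3:12, 1L)
  host <- sample(0:min(.FP_HOST_GENES_MAX, floor(.FP_HVR_MAX * viral)), 1L)
  anno <- list(viral_genes = viral, host_genes = host,
               hallmark_genes = stats::rpois(1L, 2),
               screen_score = stats::runif(1L, 0.5, 1),
               completeness_pct = stats::runif(1L, 90, 100))
  list(sequence = sequence, genes = genes, anno = anno)
}

#' Mutate a sequence into a clone at a given divergence
#'
#' Applies point substitutions placed uniformly at the stated per-site rate
#' (substitution-only: length is preserved, so alignment-free Hamming
#' identity is an exact oracle for ANI on simulated pairs).
#'
#' @param parent Nucleotide string.
#' @param divergence Per-site substitution rate in `[0, 0.2]`.
#' @return A list with `sequence` and `substitutions` (the realized count).
#' @export
mutateClone <- function(parent, divergence) {
  stopifnot(divergence >= 0, divergence <= 0.2)
  n <- nchar(parent)
  k <- stats::rbinom(1L, n, divergence)
  if (k == 0) return(list(sequence = parent, substitutions = 0L))
  pos <- sample.int(n, k)
  chars <- strsplit(parent, "", fixed = TRUE)[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  chars[pos] <- vapply(chars[pos], function(b) sample(alt[[b]], 1L), "")
  list(sequence = paste(chars, collapse = ""), substitutions = k)
}

## ---- cohort simulation ------------------------------------------------------

## carriage variant codes: r = donor reference copy, c = transferred clone,
## d = near-threshold distractor relative, o = recipient-own baseline
## lineage, n = novel lineage at a single later timepoint
.VARIANT_DIVERGENCE <- function(type, config) {
  switch(type, r = 0, o = 0, n = 0,
         c = config$clone_divergence,
         d = config$distractor_divergence)
}

#' Simulate a synthetic FMT cohort with ground truth
#'
#' Generates a full sex-stratified FMT cohort: donor and recipient sample
#' metadata, phage lineages with true relative abundances at every timepoint,
#' clonal transfers of donor phages into FMT recipients only (appearing from
#' week 6 onward), near-threshold distractor relatives at recipient
#' baselines, novel lineages at single later timepoints, and — when
#' `sequences = TRUE` — genome sequences, per-sample UViGs with annotations
#' and gene coordinates, and overdispersed gene-level read counts.
#'
#' @param config A configuration from [defaultSimConfig()].
#' @param sequences If `FALSE`, stop at design level (metadata, truth
#'   abundance, transfer tables); an order of magnitude faster, used for
#'   statistical calibration over many replicates.
#' @return A [CohortSim-class].
#' @export
simulateCohort <- function(config = defaultSimConfig(), sequences = TRUE) {
  .validateSimConfig(config)
  set.seed(config$seed)
  tps_post <- c("wk6", "wk12", "wk26")

  ## subjects and samples
  donors <- list(); recipients <- list(); meta <- list()
  for (sex in .SEXES) {
    tag <- if (sex == "female") "F" else "M"
    d_ids <- sprintf("D%s%02d", tag, seq_len(config$n_donors_per_sex))
    r_ids <- sprintf("R%s%02d", tag, seq_len(config$n_fmt + config$n_placebo))
    treat <- rep(c("FMT", "placebo"), c(config$n_fmt, config$n_placebo))
    donors[[sex]] <- d_ids
    recipients[[sex]] <- data.frame(subject_id = r_ids, treatment = treat)
    meta[[sex]] <- rbind(
      data.frame(sample_id = paste0(d_ids, "_don"), subject_id = d_ids,
                 role = "donor", treatment = "none", sex = sex,
                 timepoint = "donation", donation_round = 1L),
      data.frame(sample_id = paste0(rep(r_ids, each = 4), "_",
                                    rep(.RECIPIENT_TIMEPOINTS, length(r_ids))),
                 subject_id = rep(r_ids, each = 4), role = "recipient",
                 treatment = rep(treat, each = 4), sex = sex,
                 timepoint = rep(.RECIPIENT_TIMEPOINTS, length(r_ids)),
                 donation_round = NA_integer_))
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  ## donor lineage pools (with a few lineages seeded into two same-sex
  ## donors to exercise multi-donor attribution)
  lineage_counter <- 0L
  newLineage <- function(n) {
    ids <- sprintf("L%05d", lineage_counter + seq_len(n))
    lineage_counter <<- lineage_counter + n
    ids
  }
  drawLifestyle <- function(n) {
    tf <- config$temperate_fraction
    sample(.LIFESTYLES, n, replace = TRUE,
           prob = c(tf, (1 - tf) * 0.85, (1 - tf) * 0.15))
  }
  lifestyles <- character(0)
  donor_pool <- list()
  for (sex in .SEXES) {
    for (d in donors[[sex]]) {
      r <- sample(seq(config$donor_richness_range[1],
                      config$donor_richness_range[2]), 1L)
      donor_pool[[d]] <- newLineage(r)
    }
    if (config$n_shared_lineages > 0 && length(donors[[sex]]) >= 2) {
      for (i in seq_len(config$n_shared_lineages)) {
        pair <- sample(donors[[sex]], 2L)
        l <- sample(donor_pool[[pair[1]]], 1L)
        if (!l %in% donor_pool[[pair[2]]])
          donor_pool[[pair[2]]] <- c(donor_pool[[pair[2]]], l)
      }
    }
  }
  all_donor_lineages <- unique(unlist(donor_pool, use.names = FALSE))
  lifestyles <- c(lifestyles,
                  setNames(drawLifestyle(length(all_donor_lineages)),
                           all_donor_lineages))

  ## donor profiles; a donor's realized Shannon diversity drives the
  ## per-recipient transfer probability of each of its phages
  donor_ids <- unlist(donors, use.names = FALSE)
  donorShannon <- setNames(numeric(length(donor_ids)), donor_ids)
  base_abund <- new.env(parent = emptyenv())   # "subject\rlineage" -> base
  for (d in donor_ids) {
    a <- stats::rlnorm(length(donor_pool[[d]]), 0, config$abund_sdlog)
    w <- a / sum(a)
    donorShannon[d] <- -sum(w * log(w))
    for (i in seq_along(donor_pool[[d]]))
      assign(paste(d, donor_pool[[d]][i], sep = "\r"), a[i],
             envir = base_abund)
  }

  ## transfers (FMT recipients only, sex-matched)
  transfers <- list()
  for (sex in .SEXES) {
    rec <- recipients[[sex]]
    for (ri in which(rec$treatment == "FMT")) {
      subj <- rec$subject_id[ri]
      for (d in donors[[sex]]) {
        p <- stats::plogis(config$engraft_prob_intercept +
                           config$engraft_prob_slope * donorShannon[[d]])
        hit <- stats::runif(length(donor_pool[[d]])) < p
        if (any(hit))
          transfers[[length(transfers) + 1L]] <-
            data.frame(donor_id = d, lineage_id = donor_pool[[d]][hit],
                       recipient_id = subj, transfer_time = "wk6")
      }
    }
  }
  transfers <- if (length(transfers)) do.call(rbind, transfers)
    else data.frame(donor_id = character(), lineage_id = character(),
                    recipient_id = character(), transfer_time = character())
  rownames(transfers) <- NULL

  ## carriage: one row per (subject, lineage, variant type) with the
  ## timepoints the lineage is present at
  carr_subject <- carr_lineage <- carr_type <- character(0)
  carr_tps <- list()
  addCarriage <- function(subject, lineage, type, tps) {
    carr_subject <<- c(carr_subject, subject)
    carr_lineage <<- c(carr_lineage, lineage)
    carr_type <<- c(carr_type, type)
    carr_tps[[length(carr_tps) + 1L]] <<- tps
  }
  for (sex in .SEXES)
    for (d in donors[[sex]])
      for (l in donor_pool[[d]]) addCarriage(d, l, "r", "donation")

  for (sex in .SEXES) {
    sex_lineages <- unique(unlist(donor_pool[donors[[sex]]],
                                  use.names = FALSE))
    rec <- recipients[[sex]]
    for (ri in seq_len(nrow(rec))) {
      subj <- rec$subject_id[ri]
      novel_rate <- if (rec$treatment[ri] == "FMT") config$novel_rate_fmt
                    else config$novel_rate_placebo
      n_dist <- min(config$n_distractors, length(sex_lineages))
      dist_l <- sample(sex_lineages, n_dist)
      own_l <- newLineage(config$recipient_richness - n_dist)
      lifestyles[own_l] <- drawLifestyle(length(own_l))
      for (l in c(dist_l, own_l)) {
        tps <- c("baseline",
                 tps_post[stats::runif(3) < config$baseline_persistence])
        addCarriage(subj, l, if (l %in% dist_l) "d" else "o", tps)
      }
      for (l in unique(transfers$lineage_id[transfers$recipient_id == subj]))
        addCarriage(subj, l, "c", tps_post)
      for (tp in tps_post) {
        k <- stats::rpois(1L, novel_rate)
        if (k > 0) {
          nov <- newLineage(k)
          lifestyles[nov] <- drawLifestyle(k)
          for (l in nov) addCarriage(subj, l, "n", tp)
        }
      }
    }
  }
  ## base abundance for recipient carriages (donors already assigned)
  for (ci in seq_along(carr_subject)) {
    key <- paste(carr_subject[ci], carr_lineage[ci], sep = "\r")
    if (is.null(base_abund[[key]]))
      assign(key, stats::rlnorm(1, 0, config$abund_sdlog), envir = base_abund)
  }

  ## truth abundance: per-sample lineage loads normalized to a relative
  ## profile, then the temperate fold applied multiplicatively to temperate
  ## lineages in FMT recipients post-baseline WITHOUT renormalizing: the
  ## fold models a true biological increase of temperate load that leaves
  ## other lineages untouched. The compositional squeeze belongs to the
  ## measurement layer (read counts and CPM renormalize per sample).
  all_lineages <- sprintf("L%05d", seq_len(lineage_counter))
  abund <- matrix(0, length(all_lineages), nrow(metadata),
                  dimnames = list(all_lineages, metadata$sample_id))
  sample_of <- setNames(metadata$sample_id,
                        paste(metadata$subject_id, metadata$timepoint))
  treat_of_sample <- setNames(metadata$treatment, metadata$sample_id)
  for (ci in seq_along(carr_subject)) {
    base <- base_abund[[paste(carr_subject[ci], carr_lineage[ci], sep = "\r")]]
    for (tp in carr_tps[[ci]]) {
      sid <- sample_of[[paste(carr_subject[ci], tp)]]
      a <- base * stats::rlnorm(1, 0, config$timepoint_sdlog)
      abund[carr_lineage[ci], sid] <- abund[carr_lineage[ci], sid] + a
    }
  }
  cs <- colSums(abund)
  abund <- sweep(abund, 2, ifelse(cs > 0, cs, 1), "/")
  if (config$temperate_postfmt_fold != 1) {
    temperate <- names(lifestyles)[lifestyles == "temperate"]
    temperate <- intersect(temperate, all_lineages)
    post_fmt <- metadata$sample_id[metadata$treatment == "FMT" &
                                   metadata$timepoint %in% tps_post]
    abund[temperate, post_fmt] <-
      abund[temperate, post_fmt] * config$temperate_postfmt_fold
  }

  truth <- new("SimTruth",
    clonePairs = S4Vectors::DataFrame(uvig_a = character(),
                                      uvig_b = character(),
                                      true_divergence = numeric()),
    transfers = S4Vectors::DataFrame(transfers),
    lineageOfUvig = character(0),
    lifestyleOfLineage = lifestyles[all_lineages],
    donorShannon = donorShannon)

  metaDF <- validateSampleMetadata(metadata)
  if (!sequences)
    return(new("CohortSim", uvigs = .emptyUViGSet(), metadata = metaDF,
               counts = matrix(0, 0, 0), truthAbundance = abund,
               truth = truth, config = unclass(config)))

  carriage <- list(subject = carr_subject, lineage = carr_lineage,
                   type = carr_type, tps = carr_tps)
  .materializeSequences(config, metaDF, carriage, abund, truth, lifestyles)
}

.emptyUViGSet <- function() {
  makeUViGSet(Biostrings::DNAStringSet(),
              data.frame(uvig_id = character(), sample_id = character(),
                         viral_genes = integer(), host_genes = integer(),
                         hallmark_genes = integer(), screen_score = numeric(),
                         completeness_pct = numeric(), lifestyle = character(),
                         predicted_host = character()))
}

## Reference genome per lineage; one variant sequence per carriage row
## (donor reference = the lineage reference; transferred clones and
## distractors are substitution-mutated copies); one UViG per (sample,
## carriage row); gene counts; clone-pair ground truth.
.materializeSequences <- function(config, metadata, carriage, abund, truth,
                                  lifestyles) {
  lineages_used <- unique(carriage$lineage)
  glr <- config$genome_length_range
  ref <- vector("list", length(lineages_used))
  names(ref) <- lineages_used
  for (l in lineages_used)
    ref[[l]] <- simulateGenome(sample(seq(glr[1], glr[2]), 1L),
                               config$gene_length_range)

  n_carr <- length(carriage$subject)
  var_seq <- character(n_carr)
  var_sub <- integer(n_carr)
  for (ci in seq_len(n_carr)) {
    div <- .VARIANT_DIVERGENCE(carriage$type[ci], config)
    if (div == 0) {
      var_seq[ci] <- ref[[carriage$lineage[ci]]]$sequence
      var_sub[ci] <- 0L
    } else {
      m <- mutateClone(ref[[carriage$lineage[ci]]]$sequence, div)
      var_seq[ci] <- m$sequence
      var_sub[ci] <- m$substitutions
    }
  }

  ## one UViG per (carriage row, timepoint present)
  sample_of <- setNames(metadata$sample_id,
                        paste(metadata$subject_id, metadata$timepoint))
  n_uvig <- sum(lengths(carriage$tps))
  uvig_id <- uvig_sample <- uvig_lineage <- character(n_uvig)
  uvig_carr <- integer(n_uvig)
  k <- 0L
  for (ci in seq_len(n_carr)) {
    for (tp in carriage$tps[[ci]]) {
      k <- k + 1L
      sid <- sample_of[[paste(carriage$subject[ci], tp)]]
      uvig_id[k] <- paste(sid, carriage$lineage[ci], carriage$type[ci],
                          sep = ".")
      uvig_sample[k] <- sid
      uvig_lineage[k] <- carriage$lineage[ci]
      uvig_carr[k] <- ci
    }
  }
  ref_anno <- lapply(ref, `[[`, "anno")
  la <- function(field) vapply(ref_anno[uvig_lineage], `[[`, 0, field)
  anno <- data.frame(
    uvig_id = uvig_id, sample_id = uvig_sample,
    viral_genes = as.integer(la("viral_genes")),
    host_genes = as.integer(la("host_genes")),
    hallmark_genes = as.integer(la("hallmark_genes")),
    screen_score = round(la("screen_score"), 4),
    completeness_pct = round(la("completeness_pct"), 2),
    lifestyle = unname(lifestyles[uvig_lineage]),
    predicted_host = NA_character_)

  gene_per_uvig <- lapply(seq_len(n_uvig), function(k) {
    g <- ref[[uvig_lineage[k]]]$genes
    data.frame(gene_id = sprintf("%s.g%02d", uvig_id[k], seq_len(nrow(g))),
               uvig_id = uvig_id[k], start = g$start, end = g$end,
               length_bp = g$length_bp)
  })
  genes <- do.call(rbind, gene_per_uvig)
  rownames(genes) <- NULL

  sequences <- Biostrings::DNAStringSet(setNames(var_seq[uvig_carr], uvig_id))
  uvigs <- makeUViGSet(sequences, anno, genes)

  names(uvig_lineage) <- uvig_id
  truth@lineageOfUvig <- uvig_lineage
  truth@clonePairs <- S4Vectors::DataFrame(.truthClonePairs(
    uvig_id, uvig_lineage, uvig_carr, var_sub,
    vapply(ref, function(r) nchar(r$sequence), 0),
    max_div = 1 - .CLONE_ANI_MIN / 100))

  counts <- simulateGeneCounts(genes, anno, uvig_lineage, abund, config)

  new("CohortSim", uvigs = uvigs, metadata = metadata, counts = counts,
      truthAbundance = abund, truth = truth, config = unclass(config))
}

## True clone pairs: same-lineage UViG pairs whose summed realized
## substitution load keeps pairwise identity at or above the clone
## threshold. Same-variant pairs (the same strain observed at two
## timepoints) are identical; distractor variants fall outside the
## threshold by construction.
.truthClonePairs <- function(uvig_id, uvig_lineage, uvig_carr, var_sub,
                             ref_len, max_div) {
  out <- list()
  for (l in unique(uvig_lineage)) {
    idx <- which(uvig_lineage == l)
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2)
    same <- uvig_carr[pr[1, ]] == uvig_carr[pr[2, ]]
    div <- ifelse(same, 0,
                  (var_sub[uvig_carr[pr[1, ]]] + var_sub[uvig_carr[pr[2, ]]]) /
                    ref_len[[l]])
    keep <- div <= max_div
    if (any(keep))
      out[[l]] <- data.frame(uvig_a = uvig_id[pr[1, keep]],
                             uvig_b = uvig_id[pr[2, keep]],
                             true_divergence = div[keep])
  }
  if (!length(out))
    return(data.frame(uvig_a = character(), uvig_b = character(),
                      true_divergence = numeric()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Simulate overdispersed gene-level read counts
#'
#' For each sample, the expected count of a gene on a UViG assembled from
#' that sample is proportional to the lineage's true relative abundance times
#' the gene length, scaled so the sample's expected total is `mean_depth`;
#' counts are negative-binomial with the configured dispersion (Poisson when
#' dispersion is 0). Genes of lineages absent from a sample have count 0.
#'
#' @param genes Gene table (`gene_id`, `uvig_id`, `length_bp`).
#' @param anno UViG annotation table (`uvig_id`, `sample_id`).
#' @param lineageOfUvig Named character vector uvig_id -> lineage.
#' @param abundance Lineage-by-sample relative abundance matrix.
#' @param config A [defaultSimConfig()] list.
#' @return A gene-by-sample numeric matrix of counts.
#' @export
simulateGeneCounts <- function(genes, anno, lineageOfUvig, abundance, config) {
  samples <- colnames(abundance)
  counts <- matrix(0, nrow(genes), length(samples),
                   dimnames = list(genes$gene_id, samples))
  gene_sample <- anno$sample_id[match(genes$uvig_id, anno$uvig_id)]
  gene_lineage <- unname(lineageOfUvig[genes$uvig_id])
  size <- if (config$count_dispersion > 0) 1 / config$count_dispersion else Inf
  for (s in samples) {
    idx <- which(gene_sample == s)
    if (!length(idx)) next
    w <- abundance[cbind(gene_lineage[idx], s)] * genes$length_bp[idx]
    if (sum(w) <= 0) next
    mu <- config$mean_depth * w / sum(w)
    counts[idx, s] <- if (is.finite(size))
      stats::rnbinom(length(mu), size = size, mu = mu)
    else stats::rpois(length(mu), mu)
  }
  counts
}

#' Write a simulated cohort to a directory
#'
#' Emits `genomes.fasta`, `annotations.tsv`, `metadata.tsv`, `genes.tsv`,
#' `gene_counts.tsv` and ground-truth tables under `truth/`. With a fixed
#' config seed the outputs are byte-identical across runs.
#'
#' @param sim A [CohortSim-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  writeFasta(uvigSequences(cohortUvigs(sim)), file.path(dir, "genomes.fasta"))
  writeAnnotations(cohortUvigs(sim), file.path(dir, "annotations.tsv"))
  writeGeneTable(cohortUvigs(sim), file.path(dir, "genes.tsv"))
  writeSampleMetadata(cohortMetadata(sim), file.path(dir, "metadata.tsv"))
  writeCountsTable(cohortCounts(sim), file.path(dir, "gene_counts.tsv"))
  .writeTSV(as.data.frame(truthTransfers(sim)),
            file.path(dir, "truth", "transfers.tsv"))
  .writeTSV(as.data.frame(truthClonePairs(sim)),
            file.path(dir, "truth", "clone_pairs.tsv"))
  lin <- cohortTruth(sim)@lineageOfUvig
  .writeTSV(data.frame(uvig_id = names(lin), lineage_id = unname(lin)),
            file.path(dir, "truth", "lineages.tsv"))
  invisible(dir)
}
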