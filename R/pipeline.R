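#' @include engraftment.R abundance.R screen.R simulate.R
NULL

#' Run the full phageome pipeline on a simulated or provided cohort
#'
#' Orchestrates simulate -> screen -> cluster -> quantify -> engraft -> stats
#' as one reproducible run. Inputs are either a simulated cohort (default) or
#' a directory of input tables (`genomes.fasta`, `annotations.tsv`,
#' `metadata.tsv`, `genes.tsv`, `gene_counts.tsv`). Every stage logs its
#' input/output record counts so the screening funnel (contigs -> putative
#' viral -> post-false-positive -> high-quality vOTUs) is auditable, and the
#' effective configuration is written into the run directory.
#'
#' @param outDir Run directory (created; existing files are overwritten).
#' @param simConfig A [defaultSimConfig()] configuration (used when
#'   `inputDir` is NULL).
#' @param inputDir Optional directory of input tables; when given, the
#'   simulator is not run and ground-truth-based summaries are omitted.
#' @param donorMatch Donor-sharing rule for the phageome partition
#'   (`"clone"` or `"votu"`, see [partitionPhageome()]).
#' @param includeZeros,attribution Gene-median options, see
#'   [uvigAbundance()].
#' @param assign Centroid assignment rule, see [clusterVOTUs()].
#' @return Invisibly, a list with every stage result (`sim`, `screen`,
#'   `votus`, `hqVotus`, `clones`, `catalog`, `votuAbundance`, `events`,
#'   `efficacy`, `partition`, `variability`, `stability`, `lifestyle`,
#'   `diversity`, `convergence`, `diversityEfficacy`, `funnel`).
#' @export
runPhageomePipeline <- function(outDir, simConfig = defaultSimConfig(),
                                inputDir = NULL,
                                donorMatch = c("clone", "votu"),
                                includeZeros = TRUE,
                                attribution = c("all", "centroid"),
                                assign = c("first", "best")) {
  donorMatch <- match.arg(donorMatch)
  attribution <- match.arg(attribution)
  assign <- match.arg(assign)
  dir.create(file.path(outDir, "stats"), recursive = TRUE,
             showWarnings = FALSE)

  ## ---- inputs ----
  sim <- NULL
  if (is.null(inputDir)) {
    .stageLog("simulate", "generating synthetic cohort (seed ",
              simConfig$seed, ")")
    sim <- simulateCohort(simConfig, sequences = TRUE)
    uvigs <- cohortUvigs(sim)
    metadata <- cohortMetadata(sim)
    counts <- cohortCounts(sim)
  } else {
    paths <- file.path(inputDir, c("genomes.fasta", "annotations.tsv",
                                   "metadata.tsv", "genes.tsv",
                                   "gene_counts.tsv"))
    missing_in <- paths[!file.exists(paths)]
    if (length(missing_in))
      stop("missing input file(s): ", paste(missing_in, collapse = ", "),
           call. = FALSE)
    seqs <- readFasta(paths[1])
    genes <- readGeneTable(paths[4])
    uvigs <- readAnnotations(paths[2], seqs, genes)
    metadata <- readSampleMetadata(paths[3])
    counts <- readCountsTable(paths[5])
  }
  n_contigs <- length(uvigSequences(uvigs))

  ## ---- screen ----
  screen <- screenUViGs(uvigs)
  retained <- makeUViGSet(
    uvigSequences(uvigs)[screen$retained],
    as.data.frame(uvigAnnotations(uvigs))[screen$retained, , drop = FALSE],
    {
      g <- as.data.frame(geneTable(uvigs))
      g[g$uvig_id %in% screen$uvig_id[screen$retained], , drop = FALSE]
    })
  .writeTSV(screen, file.path(outDir, "screen_decisions.tsv"))

  ## ---- cluster ----
  votus <- clusterVOTUs(retained, assign = assign)
  ## high-quality filter at the vOTU-representative level
  anno <- as.data.frame(uvigAnnotations(retained))
  comp <- setNames(anno$completeness_pct, anno$uvig_id)
  cl <- votuTable(votus)
  hq <- comp[as.character(cl$representative)] >= .HQ_COMPLETENESS_MIN
  hqVotus <- new("VOTUSet", clusters = cl[hq, , drop = FALSE])
  .stageLog("hq-filter", nrow(cl), " vOTUs -> ", sum(hq),
            " with high-quality representative")
  votu_long <- data.frame(
    votu_id = rep(as.character(cl$votu_id), lengths(cl$members)),
    representative = rep(as.character(cl$representative),
                         lengths(cl$members)),
    member = unlist(as.list(cl$members), use.names = FALSE),
    high_quality = rep(hq, lengths(cl$members)))
  .writeTSV(votu_long, file.path(outDir, "votus.tsv"))

  ## ---- clones (within high-quality vOTUs) ----
  hq_uvig <- unlist(as.list(hqVotus@clusters$members), use.names = FALSE)
  clones <- detectClones(hqVotus, retained)
  .writeTSV(clones, file.path(outDir, "clones.tsv"))

  ## ---- quantify ----
  hq_set <- makeUViGSet(
    uvigSequences(retained)[hq_uvig],
    anno[match(hq_uvig, anno$uvig_id), , drop = FALSE],
    {
      g <- as.data.frame(geneTable(retained))
      g[g$uvig_id %in% hq_uvig, , drop = FALSE]
    })
  catalog <- buildGeneCatalog(hq_set)
  ccounts <- catalogCounts(counts, catalog)
  cpm <- countsToCPM(ccounts, catalog)
  uvAb <- uvigAbundance(cpm, catalog, hq_set, includeZeros = includeZeros,
                        attribution = attribution)
  vAb <- votuAbundance(uvAb, hqVotus)
  .writeTSV(data.frame(votu_id = rownames(abundanceValues(vAb)),
                       as.data.frame(abundanceValues(vAb)),
                       check.names = FALSE),
            file.path(outDir, "votu_abundance.tsv"))

  ## ---- engraftment ----
  events <- detectEngraftment(clones, retained, metadata, hqVotus)
  presence <- donorVotuPresence(hqVotus, retained, metadata)
  if (nrow(events)) events <- attributeDonors(events, presence)
  eff <- donorEfficacy(events, presence)
  .writeTSV(events, file.path(outDir, "events.tsv"))
  .writeTSV(eff$efficacy, file.path(outDir, "efficacy.tsv"))

  ## ---- partition & longitudinal statistics ----
  partition <- partitionPhageome(vAb, clones, retained, metadata, hqVotus,
                                 donorMatch = donorMatch)
  .writeTSV(partition, file.path(outDir, "partition.tsv"))
  variability <- variabilityFromWk6(vAb, metadata)
  stability <- votuStability(vAb, metadata)
  lifestyle <- lifestyleTotals(vAb, votuLifestyles(hqVotus, retained),
                               metadata)
  diversity <- diversityContrast(vAb, metadata)
  convergence <- donorConvergence(vAb, metadata)

  ## diversity-efficacy correlation across donors
  md <- as.data.frame(metadata)
  donor_samples <- md[md$role == "donor", ]
  h_donor <- shannonDiversity(vAb)[donor_samples$sample_id]
  names(h_donor) <- donor_samples$subject_id
  de <- merge(data.frame(donor = names(h_donor),
                         shannon = as.numeric(h_donor)),
              eff$efficacy, by = "donor")
  de <- de[is.finite(de$shannon) & is.finite(de$efficacy), ]
  diversityEfficacy <- list(
    values = de,
    test = if (nrow(de) >= 3) pearsonTest(de$shannon, de$efficacy) else NULL)

  .writeTSV(variability$values, file.path(outDir, "stats", "variability.tsv"))
  if (!is.null(variability$tests))
    .writeTSV(variability$tests,
              file.path(outDir, "stats", "variability_tests.tsv"))
  .writeTSV(stability$distribution,
            file.path(outDir, "stats", "stability.tsv"))
  .writeTSV(lifestyle$totals, file.path(outDir, "stats", "lifestyle_totals.tsv"))
  if (!is.null(lifestyle$contrasts))
    .writeTSV(lifestyle$contrasts,
              file.path(outDir, "stats", "lifestyle_contrasts.tsv"))
  if (!is.null(diversity$contrasts))
    .writeTSV(diversity$contrasts,
              file.path(outDir, "stats", "diversity_contrasts.tsv"))
  .writeTSV(convergence$values, file.path(outDir, "stats", "convergence.tsv"))
  if (!is.null(convergence$contrasts))
    .writeTSV(convergence$contrasts,
              file.path(outDir, "stats", "convergence_contrasts.tsv"))
  .writeTSV(de, file.path(outDir, "stats", "diversity_efficacy.tsv"))

  ## ---- funnel and summary ----
  funnel <- data.frame(
    stage = c("contigs", "putative_viral", "post_false_positive",
              "votus", "hq_votus"),
    count = c(n_contigs, sum(screen$included), sum(screen$retained),
              nrow(cl), sum(hq)))
  .writeTSV(funnel, file.path(outDir, "funnel.tsv"))

  summary_rows <- rbind(
    data.frame(metric = "overall_efficacy", group = "all",
               value = eff$overall$efficacy),
    data.frame(metric = "n_engrafted_unique_votus", group = "all",
               value = eff$overall$n_engrafted),
    data.frame(metric = "n_events", group = "all",
               value = sum(events$treatment == "FMT")),
    data.frame(metric = "n_placebo_events", group = "all",
               value = sum(events$treatment == "placebo")),
    data.frame(metric = "donor_efficacy", group = eff$efficacy$donor,
               value = eff$efficacy$efficacy),
    stats::aggregate(proportion ~ treatment + timepoint + class,
                     data = partition, FUN = mean) |>
      (\(a) data.frame(metric = paste0("partition_", a$class),
                       group = paste(a$treatment, a$timepoint, sep = ":"),
                       value = a$proportion))())
  .writeTSV(summary_rows, file.path(outDir, "summary.tsv"))

  effective <- list(
    seed = simConfig$seed, donor_match = donorMatch,
    include_zeros = includeZeros, attribution = attribution,
    assign = assign,
    thresholds = list(
      screen_score_min = .SCREEN_SCORE_MIN,
      hallmark_min = .SCREEN_HALLMARK_MIN,
      fp_host_genes = .FP_HOST_GENES_MAX, fp_hvr = .FP_HVR_MAX,
      hq_completeness = .HQ_COMPLETENESS_MIN,
      votu_ani = .VOTU_ANI_MIN, votu_af = .VOTU_AF_MIN,
      clone_ani = .CLONE_ANI_MIN, clone_af = .CLONE_AF_MIN),
    sim = if (is.null(inputDir)) unclass(simConfig) else NULL,
    input_dir = inputDir)
  yaml::write_yaml(effective, file.path(outDir, "config.yaml"))

  invisible(list(sim = sim, uvigs = uvigs, retained = retained,
                 screen = screen, votus = votus, hqVotus = hqVotus,
                 clones = clones, catalog = catalog, cpm = cpm,
                 uvigAbund = uvAb, votuAbund = vAb, events = events,
                 presence = presence, efficacy = eff, partition = partition,
                 variability = variability, stability = stability,
                 lifestyle = lifestyle, diversity = diversity,
                 convergence = convergence,
                 diversityEfficacy = diversityEfficacy, funnel = funnel))
}

#' Compare called engraftment events to simulator ground truth
#'
#' Maps each true transfer (donor, lineage, recipient) to the vOTU(s) its
#' UViGs cluster into and checks whether a called event matches; conversely
#' checks every called FMT event against the truth. Placebo events are
#' always false positives (the generator never transfers into placebo).
#'
#' @param events Events from [detectEngraftment()].
#' @param sim The [CohortSim-class] the pipeline ran on.
#' @param votus The [VOTUSet-class] used for event calling.
#' @return One-row data.frame: `recall`, `precision`, `n_truth`,
#'   `n_called_fmt`, `n_called_placebo`.
#' @export
evaluateEngraftment <- function(events, sim, votus) {
  truth <- as.data.frame(truthTransfers(sim))
  lineage_of <- cohortTruth(sim)@lineageOfUvig
  membership <- votuMembership(votus)
  ## lineage -> set of vOTUs containing its UViGs
  lin_votu <- split(unname(membership[names(lineage_of)]),
                    unname(lineage_of))
  lin_votu <- lapply(lin_votu, function(v) unique(v[!is.na(v)]))
  truth_keys <- unique(unlist(lapply(seq_len(nrow(truth)), function(i) {
    v <- lin_votu[[truth$lineage_id[i]]]
    if (is.null(v) || !length(v)) return(character(0))
    paste(v, truth$recipient_id[i], sep = "\r")
  })))
  fmt <- events[events$treatment == "FMT", , drop = FALSE]
  called_keys <- paste(fmt$votu_id, fmt$recipient_subject, sep = "\r")
  truth_pairs <- unique(truth[, c("lineage_id", "recipient_id")])
  hit <- vapply(seq_len(nrow(truth_pairs)), function(i) {
    v <- lin_votu[[truth_pairs$lineage_id[i]]]
    length(v) && any(paste(v, truth_pairs$recipient_id[i], sep = "\r") %in%
                       called_keys)
  }, TRUE)
  data.frame(
    recall = if (nrow(truth_pairs)) mean(hit) else NA_real_,
    precision = if (length(called_keys)) mean(called_keys %in% truth_keys)
                else NA_real_,
    n_truth = nrow(truth_pairs),
    n_called_fmt = nrow(fmt),
    n_called_placebo = sum(events$treatment == "placebo"))
}

#' Summarize a completed run as report tables (and plots)
#'
#' Reads the output tables of [runPhageomePipeline()] from a run directory
#' and writes five report tables mirroring the headline analyses (per-donor
#' efficacy, donor convergence, phageome partition, stability categories,
#' lifestyle totals) under `report/`, plus simple plots when ggplot2 is
#' available. An incomplete run produces an error listing the missing stage
#' outputs.
#'
#' @param runDir A directory produced by [runPhageomePipeline()].
#' @return Invisibly, the list of report tables.
#' @export
pipelineReport <- function(runDir) {
  need <- c("efficacy.tsv", "stats/convergence.tsv", "partition.tsv",
            "stats/stability.tsv", "stats/lifestyle_totals.tsv")
  missing_out <- need[!file.exists(file.path(runDir, need))]
  if (length(missing_out))
    stop("incomplete run; missing stage outputs: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  rep_dir <- file.path(runDir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  tables <- list(
    efficacy = .readTSV(file.path(runDir, "efficacy.tsv")),
    convergence = .readTSV(file.path(runDir, "stats", "convergence.tsv")),
    partition = .readTSV(file.path(runDir, "partition.tsv")),
    stability = .readTSV(file.path(runDir, "stats", "stability.tsv")),
    lifestyle = .readTSV(file.path(runDir, "stats", "lifestyle_totals.tsv")))
  ## panel-style aggregates
  part <- tables$partition
  part_tab <- stats::aggregate(proportion ~ treatment + timepoint + class,
                               data = part, FUN = mean)
  tables$partition_summary <- part_tab
  for (nm in names(tables))
    .writeTSV(tables[[nm]], file.path(rep_dir, paste0(nm, ".tsv")))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    g <- ggplot2::ggplot(part_tab,
           ggplot2::aes(x = timepoint, y = proportion, fill = class)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~treatment) +
      ggplot2::labs(title = "Phageome partition by vOTU origin")
    ggplot2::ggsave(file.path(rep_dir, "partition.pdf"), g,
                    width = 7, height = 4)
    e <- tables$efficacy
    g2 <- ggplot2::ggplot(e, ggplot2::aes(x = donor, y = efficacy)) +
      ggplot2::geom_col() +
      ggplot2::labs(title = "Donor engraftment efficacy")
    ggplot2::ggsave(file.path(rep_dir, "efficacy.pdf"), g2,
                    width = 6, height = 4)
  }
  invisible(tables)
}
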