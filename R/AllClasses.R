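#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet width
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Controlled vocabularies used throughout the package. Timepoint order is
## total for recipients; "donation" is the donor sampling timepoint.
.ROLES       <- c("donor", "recipient")
.TREATMENTS  <- c("FMT", "placebo", "none")
.SEXES       <- c("female", "male")
.TIMEPOINTS  <- c("baseline", "wk6", "wk12", "wk26", "donation")
.RECIPIENT_TIMEPOINTS <- c("baseline", "wk6", "wk12", "wk26")
.LIFESTYLES  <- c("temperate", "virulent", "unknown")

## Thresholds from the screening and clustering rules. Comparators follow the
## printed rules exactly: host > 4 and HVR > 0.386 flag false positives
## (boundaries not flagged); score >= 0.95 and completeness >= 90 include.
.SCREEN_SCORE_MIN    <- 0.95
.SCREEN_HALLMARK_MIN <- 3
.FP_HOST_GENES_MAX   <- 4
.FP_HVR_MAX          <- 0.386
.HQ_COMPLETENESS_MIN <- 90
.VOTU_ANI_MIN        <- 95
.VOTU_AF_MIN         <- 0.85
.CLONE_ANI_MIN       <- 99.4
.CLONE_AF_MIN        <- 0.85

#' Required columns of a UViG annotation table
#' @keywords internal
.ANNOTATION_COLUMNS <- c("uvig_id", "sample_id", "viral_genes", "host_genes",
                         "hallmark_genes", "screen_score", "completeness_pct",
                         "lifestyle", "predicted_host")

#' A set of uncultivated virus genomes (UViGs)
#'
#' Couples UViG nucleotide sequences with the per-contig annotation fields
#' consumed by the screening rules (viral/host/hallmark gene counts, screening
#' score, completeness, lifestyle, predicted host) and, optionally, the gene
#' coordinate table used to build the gene catalog. Annotation rows are
#' parallel to the sequences; gene coordinates are 0-based half-open.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by `uvig_id`.
#' @slot anno A [S4Vectors::DataFrame] with one row per UViG (columns
#'   `uvig_id`, `sample_id`, `viral_genes`, `host_genes`, `hallmark_genes`,
#'   `screen_score`, `completeness_pct`, `lifestyle`, `predicted_host`).
#' @slot genes A [S4Vectors::DataFrame] with columns `gene_id`, `uvig_id`,
#'   `start`, `end`, `length_bp` (0-based half-open coordinates).
#'
#' @export
setClass("UViGSet",
  slots = c(sequences = "DNAStringSet", anno = "DataFrame", genes = "DataFrame"))

setValidity("UViGSet", function(object) {
  msg <- character()
  anno <- object@anno
  if (!all(.ANNOTATION_COLUMNS %in% colnames(anno)))
    return(paste("annotation table must have columns:",
                 paste(.ANNOTATION_COLUMNS, collapse = ", ")))
  if (length(object@sequences) != nrow(anno))
    msg <- c(msg, "number of sequences and annotation rows differ")
  else {
    if (!identical(as.character(names(object@sequences) %||% character(0)),
                   as.character(anno$uvig_id)))
      msg <- c(msg, "sequence names do not match anno$uvig_id")
    if (anyDuplicated(anno$uvig_id))
      msg <- c(msg, "duplicated uvig_id")
    counts <- cbind(anno$viral_genes, anno$host_genes, anno$hallmark_genes)
    if (any(counts < 0))
      msg <- c(msg, "gene counts must be nonnegative")
    if (any(anno$completeness_pct < 0 | anno$completeness_pct > 100))
      msg <- c(msg, "completeness_pct must lie in [0, 100]")
    if (any(anno$screen_score < 0 | anno$screen_score > 1))
      msg <- c(msg, "screen_score must lie in [0, 1]")
    if (!all(anno$lifestyle %in% .LIFESTYLES))
      msg <- c(msg, paste("lifestyle must be one of:",
                          paste(.LIFESTYLES, collapse = ", ")))
  }
  g <- object@genes
  if (nrow(g)) {
    if (!all(c("gene_id", "uvig_id", "start", "end", "length_bp") %in%
             colnames(g)))
      msg <- c(msg, "gene table must have gene_id, uvig_id, start, end, length_bp")
    else {
      if (!all(g$uvig_id %in% anno$uvig_id))
        msg <- c(msg, "gene table references unknown uvig_id")
      if (any(g$start < 0) || any(g$start >= g$end))
        msg <- c(msg, "gene coordinates must satisfy 0 <= start < end")
      if (any(g$length_bp != g$end - g$start))
        msg <- c(msg, "gene length_bp must equal end - start")
      lens <- setNames(Biostrings::width(object@sequences),
                       names(object@sequences))
      if (any(g$end > lens[as.character(g$uvig_id)]))
        msg <- c(msg, "gene end exceeds parent UViG length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A vOTU clustering of UViGs
#'
#' A partition of UViGs into viral operational taxonomic units. Each cluster
#' carries its representative (the longest member, ties broken
#' lexicographically by id); every member meets ANI >= 95% and AF >= 0.85
#' against the representative.
#'
#' @slot clusters A [S4Vectors::DataFrame] with columns `votu_id`,
#'   `representative` and `members` (a CharacterList).
#'
#' @export
setClass("VOTUSet", slots = c(clusters = "DataFrame"))

setValidity("VOTUSet", function(object) {
  cl <- object@clusters
  if (!all(c("votu_id", "representative", "members") %in% colnames(cl)))
    return("clusters must have columns votu_id, representative, members")
  mem <- cl$members
  repin <- mapply(function(r, m) r %in% m, cl$representative, as.list(mem))
  if (!all(repin)) return("representative must be a member of its cluster")
  all_members <- unlist(as.list(mem), use.names = FALSE)
  if (anyDuplicated(all_members))
    return("clusters must be disjoint (a UViG appears in two vOTUs)")
  if (anyDuplicated(cl$votu_id)) return("duplicated votu_id")
  TRUE
})

#' A feature-by-sample abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay of
#' nonnegative values, tagged with its unit (`count`, `RPK`, `CPM`, or
#' `CPM-derived`). At unit `CPM` the gene-level column sums equal 1e6 for
#' every sample with any nonzero entry.
#'
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  unit <- S4Vectors::metadata(object)$unit
  if (is.null(unit) ||
      !unit %in% c("count", "RPK", "CPM", "CPM-derived"))
    return("metadata(object)$unit must be count, RPK, CPM or CPM-derived")
  m <- SummarizedExperiment::assay(object)
  if (any(m < 0)) return("abundance values must be nonnegative")
  if (identical(unit, "CPM")) {
    cs <- colSums(m)
    bad <- cs > 0 & abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad))
      return("CPM columns with nonzero entries must sum to 1e6")
  }
  TRUE
})

#' Ground truth emitted by the cohort simulator
#'
#' @slot clonePairs DataFrame of simulated clone pairs
#'   (`uvig_a`, `uvig_b`, `true_divergence`); symmetric, stored once per
#'   unordered pair.
#' @slot transfers DataFrame of true donor-to-recipient transfers
#'   (`donor_id`, `lineage_id`, `recipient_id`, `transfer_time`).
#' @slot lineageOfUvig Named character vector mapping uvig_id to lineage id.
#' @slot lifestyleOfLineage Named character vector mapping lineage id to
#'   lifestyle.
#' @slot donorShannon Named numeric vector of the realized Shannon diversity
#'   of each donor's true lineage profile.
#'
#' @export
setClass("SimTruth",
  slots = c(clonePairs = "DataFrame", transfers = "DataFrame",
            lineageOfUvig = "character", lifestyleOfLineage = "character",
            donorShannon = "numeric"))

setValidity("SimTruth", function(object) {
  tr <- object@transfers
  if (nrow(tr) &&
      !all(c("donor_id", "lineage_id", "recipient_id", "transfer_time") %in%
           colnames(tr)))
    return("transfers must have donor_id, lineage_id, recipient_id, transfer_time")
  TRUE
})

#' A simulated FMT cohort
#'
#' The full output of [simulateCohort()]: UViG sequences and annotations,
#' sample metadata, gene-level counts, the design-level truth abundance of
#' each lineage in each sample, and the [SimTruth] ground-truth tables.
#' When the cohort is simulated at design level only (`sequences = FALSE`)
#' the `uvigs` slot holds an empty set and `counts` is a 0-row matrix.
#'
#' @slot uvigs A [UViGSet].
#' @slot metadata DataFrame of sample records.
#' @slot counts gene-by-sample integer matrix of simulated read counts.
#' @slot truthAbundance lineage-by-sample matrix of true relative abundances.
#' @slot truth A [SimTruth].
#' @slot config The [SimConfig][defaultSimConfig] list used.
#'
#' @export
setClass("CohortSim",
  slots = c(uvigs = "UViGSet", metadata = "DataFrame", counts = "matrix",
            truthAbundance = "matrix", truth = "SimTruth", config = "list"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "UViGSet", function(object) {
  cat("UViGSet with", length(object@sequences), "UViGs,",
      nrow(object@genes), "genes\n")
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat("  length range:", min(w), "-", max(w), "bp\n")
    cat("  samples:", length(unique(object@anno$sample_id)), "\n")
  }
})

setMethod("show", "VOTUSet", function(object) {
  sizes <- lengths(object@clusters$members)
  cat("VOTUSet with", nrow(object@clusters), "vOTUs covering",
      sum(sizes), "UViGs\n")
  if (length(sizes))
    cat("  cluster sizes: median", stats::median(sizes), ", max", max(sizes), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@transfers), "transfers,",
      nrow(object@clonePairs), "clone pairs,",
      length(unique(object@lineageOfUvig)), "lineages\n")
})

setMethod("show", "CohortSim", function(object) {
  cat("CohortSim:", nrow(object@metadata), "samples,",
      length(object@uvigs@sequences), "UViGs,",
      nrow(object@truthAbundance), "true lineages\n")
  show(object@truth)
})
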