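#' @include AllClasses.R
NULL

#' Accessors for phagetrack classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x An object of the documented class.
#' @return `uvigSequences`: a DNAStringSet. `uvigAnnotations`, `geneTable`,
#'   `votuTable`, `truthTransfers`, `truthClonePairs`: a DataFrame.
#'   `votuMembership`: a named character vector mapping each UViG to its
#'   vOTU. `votuRepresentatives`: a named character vector mapping each vOTU
#'   to its representative UViG. `abundanceUnit`: a length-1 character.
#'   `truthAbundance`, `cohortCounts`: a matrix. `cohortMetadata`: a
#'   DataFrame. `cohortUvigs`: a [UViGSet].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("uvigSequences", function(x) standardGeneric("uvigSequences"))
#' @rdname accessors
#' @export
setMethod("uvigSequences", "UViGSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("uvigAnnotations", function(x) standardGeneric("uvigAnnotations"))
#' @rdname accessors
#' @export
setMethod("uvigAnnotations", "UViGSet", function(x) x@anno)

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setMethod("geneTable", "UViGSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("votuTable", function(x) standardGeneric("votuTable"))
#' @rdname accessors
#' @export
setMethod("votuTable", "VOTUSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("votuMembership", function(x) standardGeneric("votuMembership"))
#' @rdname accessors
#' @export
setMethod("votuMembership", "VOTUSet", function(x) {
  cl <- x@clusters
  members <- as.list(cl$members)
  out <- rep(as.character(cl$votu_id), lengths(members))
  names(out) <- unlist(members, use.names = FALSE)
  out
})

#' @rdname accessors
#' @export
setGeneric("votuRepresentatives", function(x) standardGeneric("votuRepresentatives"))
#' @rdname accessors
#' @export
setMethod("votuRepresentatives", "VOTUSet", function(x) {
  setNames(as.character(x@clusters$representative),
           as.character(x@clusters$votu_id))
})

#' @rdname accessors
#' @export
setGeneric("abundanceUnit", function(x) standardGeneric("abundanceUnit"))
#' @rdname accessors
#' @export
setMethod("abundanceUnit", "AbundanceMatrix", function(x)
  S4Vectors::metadata(x)$unit)

#' @rdname accessors
#' @export
setGeneric("truthTransfers", function(x) standardGeneric("truthTransfers"))
#' @rdname accessors
#' @export
setMethod("truthTransfers", "SimTruth", function(x) x@transfers)
#' @rdname accessors
#' @export
setMethod("truthTransfers", "CohortSim", function(x) x@truth@transfers)

#' @rdname accessors
#' @export
setGeneric("truthClonePairs", function(x) standardGeneric("truthClonePairs"))
#' @rdname accessors
#' @export
setMethod("truthClonePairs", "SimTruth", function(x) x@clonePairs)
#' @rdname accessors
#' @export
setMethod("truthClonePairs", "CohortSim", function(x) x@truth@clonePairs)

#' @rdname accessors
#' @export
setGeneric("truthAbundance", function(x) standardGeneric("truthAbundance"))
#' @rdname accessors
#' @export
setMethod("truthAbundance", "CohortSim", function(x) x@truthAbundance)

#' @rdname accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))
#' @rdname accessors
#' @export
setMethod("cohortMetadata", "CohortSim", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("cohortCounts", function(x) standardGeneric("cohortCounts"))
#' @rdname accessors
#' @export
setMethod("cohortCounts", "CohortSim", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("cohortUvigs", function(x) standardGeneric("cohortUvigs"))
#' @rdname accessors
#' @export
setMethod("cohortUvigs", "CohortSim", function(x) x@uvigs)

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setMethod("cohortTruth", "CohortSim", function(x) x@truth)

#' Construct an AbundanceMatrix
#'
#' @param values Nonnegative numeric matrix (features x samples).
#' @param unit One of `"count"`, `"RPK"`, `"CPM"`, `"CPM-derived"`.
#' @return An [AbundanceMatrix-class].
#' @export
AbundanceMatrix <- function(values, unit) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values))
  S4Vectors::metadata(se)$unit <- unit
  new("AbundanceMatrix", se)
}

#' @rdname AbundanceMatrix
#' @param x An AbundanceMatrix.
#' @export
abundanceValues <- function(x) SummarizedExperiment::assay(x, "abundance")

## stage logging: every pipeline stage reports input/output record counts so
## the screening/clustering funnel is auditable.
.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
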