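#' @include AllClasses.R
NULL

## Canonical table dialect: tab-delimited, header row, UTF-8, "." for missing.
## All coordinates in internal tables are 0-based half-open.

.readTSV <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

.writeTSV <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write FASTA files
#'
#' `readFasta` returns sequences upper-cased and named by the first
#' whitespace-delimited token of each header, preserving file order. A
#' malformed file produces an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (empty for an empty file).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(Biostrings::DNAStringSet())
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA: line ", nonblank[1],
         " does not start a record ('>')", call. = FALSE)
  bad <- grep("[^ACGTNacgtn>[:space:]]",
              sub("^>.*$", "", lines))
  if (length(bad))
    stop("malformed FASTA: line ", bad[1],
         " contains non-nucleotide characters", call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- vapply(strsplit(names(x), "[[:space:]]+"), `[`, "", 1L)
  x
}

#' @rdname readFasta
#' @param sequences A named DNAStringSet or named character vector.
#' @export
writeFasta <- function(sequences, path) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path, width = 80L)
  invisible(path)
}

.checkEnum <- function(values, allowed, column, allow_na = FALSE) {
  ok <- values %in% allowed | (allow_na & is.na(values))
  if (!all(ok)) {
    row <- which(!ok)[1]
    stop(sprintf("invalid value '%s' in column '%s' (row %d); expected one of: %s",
                 values[row], column, row, paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read trial sample metadata
#'
#' Reads a tab-delimited metadata table with columns `sample_id`,
#' `subject_id`, `role` (donor/recipient), `treatment` (FMT/placebo/none),
#' `sex` (female/male), `timepoint` (baseline/wk6/wk12/wk26/donation) and
#' optional `donation_round`. Enums are validated; donors must carry
#' `treatment = none` and `timepoint = donation`; recipients must have at
#' most one record per (subject, timepoint).
#'
#' @param path Path to the TSV file.
#' @return A [S4Vectors::DataFrame] of sample records.
#' @export
readSampleMetadata <- function(path) {
  df <- .readTSV(path)
  validateSampleMetadata(df)
}

#' @rdname readSampleMetadata
#' @param df A data.frame of sample records (e.g. from a simulator run).
#' @export
validateSampleMetadata <- function(df) {
  req <- c("sample_id", "subject_id", "role", "treatment", "sex", "timepoint")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  .checkEnum(df$role, .ROLES, "role")
  .checkEnum(df$treatment, .TREATMENTS, "treatment")
  .checkEnum(df$sex, .SEXES, "sex")
  .checkEnum(df$timepoint, .TIMEPOINTS, "timepoint")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  don <- df$role == "donor"
  if (any(df$treatment[don] != "none"))
    stop("donor rows must have treatment = none", call. = FALSE)
  if (any(df$timepoint[don] != "donation"))
    stop("donor rows must have timepoint = donation", call. = FALSE)
  rec <- df[!don, , drop = FALSE]
  if (any(rec$timepoint == "donation"))
    stop("recipient rows must not use timepoint = donation", call. = FALSE)
  key <- paste(rec$subject_id, rec$timepoint)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("recipient has multiple records for (subject, timepoint): ", dup,
         call. = FALSE)
  }
  if (is.null(df$donation_round)) df$donation_round <- NA_integer_
  S4Vectors::DataFrame(df)
}

#' Read a UViG annotation table and join it to sequences
#'
#' Every annotation row must have a sequence of the same `uvig_id`; the
#' joined records must satisfy the UViG invariants (nonnegative gene counts,
#' completeness and score in range, known lifestyle).
#'
#' @param path Path to the annotation TSV (columns `uvig_id`, `sample_id`,
#'   `viral_genes`, `host_genes`, `hallmark_genes`, `screen_score`,
#'   `completeness_pct`, `lifestyle`, `predicted_host`).
#' @param sequences A named DNAStringSet (e.g. from [readFasta()]).
#' @param genes Optional gene coordinate table (see [readGeneTable()]).
#' @return A [UViGSet-class].
#' @export
readAnnotations <- function(path, sequences, genes = NULL) {
  df <- .readTSV(path)
  makeUViGSet(sequences, df, genes)
}

#' @rdname readAnnotations
#' @param anno A data.frame of annotation rows.
#' @export
makeUViGSet <- function(sequences, anno, genes = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  missing_cols <- setdiff(.ANNOTATION_COLUMNS, colnames(anno))
  if (length(missing_cols))
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  absent <- setdiff(anno$uvig_id, names(sequences))
  if (length(absent))
    stop("no sequence for uvig_id: ", paste(utils::head(absent, 5),
                                            collapse = ", "), call. = FALSE)
  sequences <- if (nrow(anno)) sequences[as.character(anno$uvig_id)]
               else Biostrings::DNAStringSet()
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), uvig_id = character(),
                        start = integer(), end = integer(),
                        length_bp = integer())
  if (!is.null(anno$predicted_host))
    anno$predicted_host <- as.character(anno$predicted_host)
  new("UViGSet", sequences = sequences, anno = S4Vectors::DataFrame(anno),
      genes = S4Vectors::DataFrame(genes))
}

#' Read a gene coordinate table
#'
#' Columns `gene_id`, `uvig_id`, `start`, `end`, `length_bp`; coordinates are
#' 0-based half-open, so `length_bp == end - start`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of gene records.
#' @export
readGeneTable <- function(path) {
  df <- .readTSV(path)
  req <- c("gene_id", "uvig_id", "start", "end", "length_bp")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop("gene table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(df$length_bp != df$end - df$start)
  if (length(bad))
    stop("gene table row ", bad[1],
         ": length_bp does not equal end - start", call. = FALSE)
  df
}

#' Read and write gene-by-sample count tables
#'
#' The first column is `gene_id`; remaining columns are samples. Values are
#' nonnegative counts.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with genes as rows and samples as columns.
#' @export
readCountsTable <- function(path) {
  df <- .readTSV(path)
  if (colnames(df)[1] != "gene_id")
    stop("counts table must have gene_id as its first column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0))
    stop("counts must be nonnegative and complete", call. = FALSE)
  m
}

#' @rdname readCountsTable
#' @param m A gene-by-sample matrix with rownames.
#' @export
writeCountsTable <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  .writeTSV(df, path)
}

#' Write the tables of a simulated or assembled cohort
#'
#' Convenience writers mirroring the readers, used by the pipeline to
#' materialize a run directory. All use the canonical tab-delimited dialect.
#'
#' @param x Object to write.
#' @param path Destination file.
#' @name writers
NULL

#' @rdname writers
#' @export
writeSampleMetadata <- function(x, path) .writeTSV(as.data.frame(x), path)

#' @rdname writers
#' @export
writeAnnotations <- function(x, path) {
  if (is(x, "UViGSet")) x <- uvigAnnotations(x)
  .writeTSV(as.data.frame(x), path)
}

#' @rdname writers
#' @export
writeGeneTable <- function(x, path) {
  if (is(x, "UViGSet")) x <- geneTable(x)
  .writeTSV(as.data.frame(x), path)
}

#' Read a FastANI output table as a pairwise-similarity provider
#'
#' Adapter for parity runs against FastANI: accepts the standard five-column
#' FastANI output (query, reference, ANI, mapped fragments, total fragments)
#' and returns a data.frame with columns `uvig_a`, `uvig_b`, `ani_pct`,
#' `af_smaller` (mapped/total fragments). Paths are reduced to basenames
#' without extension.
#'
#' @param path Path to a FastANI output file (tab-delimited, no header).
#' @return A data.frame usable with [clusterVOTUs()] via `precomputed`.
#' @export
readFastANITable <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5)
    stop("FastANI table must have 5 columns", call. = FALSE)
  strip <- function(p) sub("\\.[^.]*$", "", basename(p))
  data.frame(uvig_a = strip(df[[1]]), uvig_b = strip(df[[2]]),
             ani_pct = df[[3]], af_smaller = df[[4]] / df[[5]])
}
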