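#' @include accessors.R
NULL

## Contig screening decision rules. A contig is a putative viral contig if it
## has at least one viral gene, or no host genes, or a screening score of at
## least 0.95, or at least three hallmark genes. An included contig is a
## false positive if it has more than 4 host genes or a host-to-viral gene
## ratio (HVR) above 0.386; boundary values (host = 4, HVR = 0.386) are not
## flagged. High-quality filtering keeps completeness >= 90%.

#' Putative-viral inclusion rule
#'
#' A contig is included when `viral_genes >= 1` OR `host_genes == 0` OR
#' `screen_score >= 0.95` OR `hallmark_genes >= 3`. All comparators are
#' applied exactly as printed (score and hallmark boundaries inclusive).
#'
#' @param anno A data.frame/DataFrame of annotation rows (or a
#'   [UViGSet-class]).
#' @return A data.frame with `uvig_id`, logical `included`, and a `reasons`
#'   string listing every satisfied clause (";"-separated, "" if excluded).
#' @export
classifyPutativeViral <- function(anno) {
  if (is(anno, "UViGSet")) anno <- uvigAnnotations(anno)
  anno <- as.data.frame(anno)
  clauses <- cbind(
    viral_gene  = anno$viral_genes >= 1,
    no_host     = anno$host_genes == 0,
    score       = anno$screen_score >= .SCREEN_SCORE_MIN,
    hallmark    = anno$hallmark_genes >= .SCREEN_HALLMARK_MIN)
  reasons <- apply(clauses, 1, function(r)
    paste(colnames(clauses)[r], collapse = ";"))
  data.frame(uvig_id = anno$uvig_id,
             included = rowSums(clauses) > 0,
             reasons = reasons)
}

#' False-positive removal rule
#'
#' Among included contigs, a contig is flagged as a false positive when
#' `host_genes > 4` or HVR `> 0.386`, where HVR is `host_genes/viral_genes`
#' (defined as `+Inf` when `viral_genes == 0` and `host_genes > 0`, and 0
#' when both are 0). Boundary values are not flagged.
#'
#' @inheritParams classifyPutativeViral
#' @return A data.frame with `uvig_id`, numeric `hvr`, logical
#'   `false_positive`, and a `reasons` string.
#' @export
flagFalsePositive <- function(anno) {
  if (is(anno, "UViGSet")) anno <- uvigAnnotations(anno)
  anno <- as.data.frame(anno)
  hvr <- ifelse(anno$viral_genes > 0, anno$host_genes / anno$viral_genes,
                ifelse(anno$host_genes > 0, Inf, 0))
  host_rule <- anno$host_genes > .FP_HOST_GENES_MAX
  hvr_rule <- hvr > .FP_HVR_MAX
  reasons <- apply(cbind(host_gt_4 = host_rule, hvr_gt_0.386 = hvr_rule), 1,
                   function(r) paste(c("host_gt_4", "hvr_gt_0.386")[r],
                                     collapse = ";"))
  data.frame(uvig_id = anno$uvig_id, hvr = hvr,
             false_positive = host_rule | hvr_rule, reasons = reasons)
}

#' High-quality completeness filter
#'
#' Retains records with completeness >= 90% (boundary inclusive), preserving
#' input order. Applied downstream to vOTU representatives by default, and
#' available here as a UViG-level pre-filter.
#'
#' @param x A [UViGSet-class] or a data.frame with `completeness_pct`.
#' @return An object of the same kind containing only the retained records.
#' @export
filterHighQuality <- function(x) {
  if (is(x, "UViGSet")) {
    keep <- uvigAnnotations(x)$completeness_pct >= .HQ_COMPLETENESS_MIN
    anno <- as.data.frame(uvigAnnotations(x))[keep, , drop = FALSE]
    genes <- as.data.frame(geneTable(x))
    genes <- genes[genes$uvig_id %in% anno$uvig_id, , drop = FALSE]
    return(makeUViGSet(uvigSequences(x)[keep], anno, genes))
  }
  x[x$completeness_pct >= .HQ_COMPLETENESS_MIN, , drop = FALSE]
}

#' Composed contig screen
#'
#' Applies inclusion, false-positive removal and (optionally) the
#' completeness pre-filter, returning one decision per contig. Exactly one of
#' excluded / false positive / retained holds for every record, so class
#' counts sum to the input count (the funnel is logged per stage).
#'
#' @param x A [UViGSet-class] or annotation data.frame.
#' @param applyCompleteness If `TRUE`, also require completeness >= 90% at
#'   the UViG level. Default `FALSE`: the completeness rule is applied to
#'   vOTU representatives downstream, as in the published workflow.
#' @return A data.frame with columns `uvig_id`, `included`,
#'   `false_positive`, `high_quality`, `hvr`, `retained`, `reasons`.
#' @export
screenUViGs <- function(x, applyCompleteness = FALSE) {
  anno <- if (is(x, "UViGSet")) as.data.frame(uvigAnnotations(x)) else x
  inc <- classifyPutativeViral(anno)
  fp <- flagFalsePositive(anno)
  ## only included contigs are evaluated for false positives
  false_positive <- inc$included & fp$false_positive
  high_quality <- inc$included & !false_positive &
    anno$completeness_pct >= .HQ_COMPLETENESS_MIN
  retained <- inc$included & !false_positive
  if (applyCompleteness) retained <- retained & high_quality
  reasons <- ifelse(inc$included,
                    ifelse(false_positive, paste0("FP:", fp$reasons),
                           paste0("include:", inc$reasons)),
                    "excluded")
  out <- data.frame(uvig_id = anno$uvig_id, included = inc$included,
                    false_positive = false_positive,
                    high_quality = high_quality, hvr = fp$hvr,
                    retained = retained, reasons = reasons)
  .stageLog("screen", nrow(out), " contigs: ", sum(!out$included),
            " excluded, ", sum(out$false_positive), " false positives, ",
            sum(out$retained), " retained")
  out
}
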