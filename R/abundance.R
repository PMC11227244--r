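#' @include cluster.R
NULL

#' Build a non-redundant gene catalog
#'
#' Extracts each UViG's gene sequences (0-based half-open coordinates) and
#' clusters them greedily at 95% identity over 85% alignment fraction of the
#' shorter gene (the same kernel as vOTU clustering, with the fragment length
#' shortened to `min(gene length, 300)` bp). Cluster centroids are the
#' longest members.
#'
#' @param uvigs A [UViGSet-class] with a gene table.
#' @param aniMin,afMin Clustering thresholds (defaults 95 and 0.85).
#' @param fragmentLen Fragment cap for gene-scale comparison (default 300).
#' @return A [S4Vectors::DataFrame] with columns `cluster_id`,
#'   `centroid_gene`, `centroid_length` and `members` (CharacterList).
#' @export
buildGeneCatalog <- function(uvigs, aniMin = 95, afMin = 0.85,
                             fragmentLen = 300L) {
  genes <- as.data.frame(geneTable(uvigs))
  if (!nrow(genes)) stop("UViGSet has no gene table", call. = FALSE)
  seqs <- as.character(uvigSequences(uvigs))
  gseq <- substr(seqs[genes$uvig_id], genes$start + 1L, genes$end)
  names(gseq) <- genes$gene_id
  res <- .greedyCluster(genes$gene_id, gseq, aniMin, afMin, fragmentLen)
  nC <- length(res$centroids)
  members <- split(genes$gene_id, res$membership)
  members <- members[as.character(seq_len(nC))]
  centroid <- genes$gene_id[res$centroids]
  out <- S4Vectors::DataFrame(
    cluster_id = sprintf("GC_%05d", seq_len(nC)),
    centroid_gene = centroid,
    centroid_length = genes$length_bp[res$centroids],
    members = IRanges::CharacterList(unname(members)))
  .stageLog("catalog", nrow(genes), " genes -> ", nC, " gene clusters")
  out
}

#' Aggregate gene-copy counts to catalog-cluster counts
#'
#' Sums counts over the member genes of each catalog cluster, as if all
#' member reads had been mapped to the cluster centroid.
#'
#' @param counts Gene-by-sample count matrix (rows named by gene_id).
#' @param catalog A gene catalog from [buildGeneCatalog()].
#' @return A cluster-by-sample count matrix (rows named by `cluster_id`).
#' @export
catalogCounts <- function(counts, catalog) {
  members <- as.list(catalog$members)
  cluster_of <- setNames(rep(catalog$cluster_id, lengths(members)),
                         unlist(members, use.names = FALSE))
  genes <- intersect(rownames(counts), names(cluster_of))
  m <- rowsum(counts[genes, , drop = FALSE], group = cluster_of[genes])
  m[as.character(catalog$cluster_id[catalog$cluster_id %in% rownames(m)]), ,
    drop = FALSE]
}

#' Convert counts to RPK and CPM
#'
#' RPK (reads per kilobase) divides each count by the feature length in kb;
#' CPM (copies per million) rescales each sample's RPK column to sum to one
#' million. Samples with all-zero counts remain all-zero.
#'
#' @param counts Feature-by-sample count matrix.
#' @param lengths Named numeric vector of feature lengths in bp (or a gene
#'   catalog, whose centroid lengths are used).
#' @return An [AbundanceMatrix-class] with unit `"CPM"`.
#' @export
countsToCPM <- function(counts, lengths) {
  if (is(lengths, "DataFrame") && "centroid_length" %in% colnames(lengths))
    lengths <- setNames(lengths$centroid_length, lengths$cluster_id)
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stop("no length for feature: ", missing_len[1], call. = FALSE)
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("feature lengths must be positive", call. = FALSE)
  rpk <- counts / (len / 1000)
  tot <- colSums(rpk)
  cpm <- sweep(rpk, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  cpm[, tot == 0] <- 0
  AbundanceMatrix(cpm, unit = "CPM")
}

#' UViG abundance as the median CPM of its genes
#'
#' A UViG's abundance in a sample is the median CPM over all its catalog
#' genes, zeros included by default (excluding zero-count genes would make
#' presence/absence circular; set `includeZeros = FALSE` for the alternative
#' reading, where a UViG with all-zero genes still gets 0). By default a gene
#' cluster's CPM is attributed to every UViG contributing a member gene;
#' `attribution = "centroid"` restricts to the cluster's centroid owner, in
#' which case UViGs without any centroid gene get 0 with a warning.
#'
#' @param cpm An [AbundanceMatrix-class] of catalog-cluster CPM values.
#' @param catalog A gene catalog from [buildGeneCatalog()].
#' @param uvigs The [UViGSet-class] the catalog was built from.
#' @param includeZeros Include zero-CPM genes in the median (default TRUE).
#' @param attribution `"all"` (default) or `"centroid"`.
#' @return An [AbundanceMatrix-class] (unit `"CPM-derived"`), UViG x sample.
#' @export
uvigAbundance <- function(cpm, catalog, uvigs, includeZeros = TRUE,
                          attribution = c("all", "centroid")) {
  attribution <- match.arg(attribution)
  m <- abundanceValues(cpm)
  genes <- as.data.frame(geneTable(uvigs))
  members <- as.list(catalog$members)
  cluster_of <- setNames(rep(as.character(catalog$cluster_id),
                             lengths(members)),
                         unlist(members, use.names = FALSE))
  if (attribution == "centroid") {
    keep_genes <- as.character(catalog$centroid_gene)
    genes <- genes[genes$gene_id %in% keep_genes, , drop = FALSE]
  }
  uvig_ids <- as.character(uvigAnnotations(uvigs)$uvig_id)
  out <- matrix(0, length(uvig_ids), ncol(m),
                dimnames = list(uvig_ids, colnames(m)))
  gene_rows <- split(cluster_of[genes$gene_id], genes$uvig_id)
  for (u in uvig_ids) {
    cl <- gene_rows[[u]]
    if (is.null(cl) || !length(cl)) {
      warning("UViG with no catalog genes: ", u, " (abundance set to 0)",
              call. = FALSE)
      next
    }
    sub <- m[cl, , drop = FALSE]
    if (!includeZeros) {
      out[u, ] <- apply(sub, 2, function(v) {
        v <- v[v > 0]
        if (length(v)) stats::median(v) else 0
      })
    } else {
      out[u, ] <- apply(sub, 2, stats::median)
    }
  }
  AbundanceMatrix(out, unit = "CPM-derived")
}

#' vOTU abundance as the sum over member UViGs
#'
#' Sums the abundance of all UViGs clustering into each vOTU, per sample. A
#' vOTU is "identified" in a sample when its value is strictly positive.
#'
#' @param uvigAbund An [AbundanceMatrix-class], UViG x sample.
#' @param votus A [VOTUSet-class] (a partition of the UViGs).
#' @return An [AbundanceMatrix-class] (unit `"CPM-derived"`), vOTU x sample.
#' @export
votuAbundance <- function(uvigAbund, votus) {
  m <- abundanceValues(uvigAbund)
  membership <- votuMembership(votus)
  uvig_ids <- intersect(rownames(m), names(membership))
  s <- rowsum(m[uvig_ids, , drop = FALSE], group = membership[uvig_ids])
  ord <- intersect(as.character(votuTable(votus)$votu_id), rownames(s))
  AbundanceMatrix(s[ord, , drop = FALSE], unit = "CPM-derived")
}
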