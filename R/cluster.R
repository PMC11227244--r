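#' @include ani.R accessors.R
NULL

## Greedy centroid clustering shared by vOTU construction and the gene
## catalog. Records are visited in length-descending order (ties broken
## lexicographically by id); each record joins the first (or best, if
## `assign = "best"`) existing centroid meeting the ANI/AF thresholds, or
## founds a new cluster. Centroid candidates are prescreened with a
## value-sampled k-mer sketch; the decision itself always uses the full
## fragment ANI/AF computation (or the supplied precomputed table).
.greedyCluster <- function(ids, seqs, aniMin, afMin, fragmentLen,
                           minFragIdentity = 80,
                           assign = c("first", "best"),
                           precomputed = NULL, seedK = 16L) {
  assign <- match.arg(assign)
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  lens <- nchar(seqs)
  ord <- order(-lens, ids)
  useq <- unique(seqs)
  uidx <- match(seqs, useq)
  lookup <- .similarityProvider(useq, fragmentLen, minFragIdentity,
                                precomputed = precomputed,
                                ids = if (is.null(precomputed)) NULL else ids)
  ## precomputed tables are keyed by record id, not sequence, so disable the
  ## sequence-level dedupe in that mode
  if (!is.null(precomputed)) {
    uidx <- seq_along(seqs)
    lookup <- .similarityProvider(seqs, fragmentLen, minFragIdentity,
                                  precomputed = precomputed, ids = ids)
  }
  sketchOf <- vector("list", length(useq))
  sketch <- new.env(parent = emptyenv(), hash = TRUE)
  centroids <- integer(0)          # record index of each centroid
  membership <- integer(length(ids))
  for (i in ord) {
    ui <- uidx[i]
    if (is.null(precomputed) && is.null(sketchOf[[ui]]))
      sketchOf[[ui]] <- .sketchKmers(.kmerCodes(.encodeSeq(seqs[i]), seedK))
    ## candidate centroids sharing sketch k-mers, in founding order
    if (is.null(precomputed)) {
      hits <- integer(0)
      for (code in sketchOf[[ui]]) {
        v <- sketch[[as.character(code)]]
        if (!is.null(v)) hits <- c(hits, v)
      }
      cand <- sort(unique(hits))
    } else {
      cand <- seq_along(centroids)
    }
    bestC <- 0L; bestAni <- -1
    for (cidx in cand) {
      sim <- lookup(ui, uidx[centroids[cidx]])
      if (sim["ani_pct"] >= aniMin && sim["af_smaller"] >= afMin) {
        if (assign == "first") { bestC <- cidx; break }
        if (sim["ani_pct"] > bestAni) { bestC <- cidx; bestAni <- sim["ani_pct"] }
      }
    }
    if (bestC > 0L) {
      membership[i] <- bestC
    } else {
      centroids <- c(centroids, i)
      cidx <- length(centroids)
      membership[i] <- cidx
      if (is.null(precomputed)) {
        for (code in sketchOf[[ui]]) {
          key <- as.character(code)
          sketch[[key]] <- c(sketch[[key]], cidx)
        }
      }
    }
  }
  list(membership = membership, centroids = centroids)
}

#' Cluster UViGs into vOTUs
#'
#' Greedy centroid clustering of UViGs into viral operational taxonomic units
#' at the MIUViG thresholds: ANI >= 95% over AF >= 0.85 of the smaller
#' sequence. Records are processed in length-descending order so each
#' cluster's representative is its longest member (ties broken
#' lexicographically by id); by default a record joins the first qualifying
#' centroid (`assign = "best"` joins the highest-ANI qualifying centroid).
#'
#' @param x A [UViGSet-class], or a named character vector / DNAStringSet of
#'   sequences.
#' @param aniMin,afMin Cluster admission thresholds (defaults 95 and 0.85).
#' @param fragmentLen,minFragIdentity Passed to the fragment ANI estimator
#'   (see [computeAniAf()]).
#' @param assign Centroid assignment rule, `"first"` (default) or `"best"`.
#' @param precomputed Optional externally computed pairwise table with
#'   columns `uvig_a`, `uvig_b`, `ani_pct`, `af_smaller`
#'   (see [readFastANITable()]); pairs absent from the table are treated as
#'   ANI 0.
#' @return A [VOTUSet-class].
#' @export
clusterVOTUs <- function(x, aniMin = .VOTU_ANI_MIN, afMin = .VOTU_AF_MIN,
                         fragmentLen = 1000L, minFragIdentity = 80,
                         assign = c("first", "best"), precomputed = NULL) {
  seqs <- if (is(x, "UViGSet")) as.character(uvigSequences(x))
          else setNames(as.character(x), names(x))
  if (!length(seqs)) stop("no sequences to cluster", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by uvig_id", call. = FALSE)
  if (is.null(precomputed) && min(nchar(seqs)) < fragmentLen)
    stop("sequence shorter than fragment_len (", fragmentLen,
         "); use a smaller fragment_len", call. = FALSE)
  res <- .greedyCluster(ids, seqs, aniMin, afMin, fragmentLen,
                        minFragIdentity, assign, precomputed)
  nC <- length(res$centroids)
  votu_ids <- sprintf("vOTU_%04d", seq_len(nC))
  members <- split(ids, res$membership)
  members <- members[as.character(seq_len(nC))]
  cl <- S4Vectors::DataFrame(
    votu_id = votu_ids,
    representative = ids[res$centroids],
    members = IRanges::CharacterList(unname(members)))
  .stageLog("cluster", length(ids), " UViGs -> ", nC, " vOTUs")
  new("VOTUSet", clusters = cl)
}

#' Detect clone pairs within vOTUs
#'
#' Two UViGs of the same vOTU are clones when ANI >= 99.4% over AF >= 0.85.
#' Only within-vOTU pairs are evaluated (the clone threshold nests inside the
#' vOTU threshold); the clone relation is symmetric and is not forced to be
#' transitive.
#'
#' @param votus A [VOTUSet-class].
#' @param x The same sequences the clustering was computed from (a
#'   [UViGSet-class] or named character vector / DNAStringSet).
#' @inheritParams clusterVOTUs
#' @return A data.frame of clone pairs with columns `uvig_a`, `uvig_b`,
#'   `ani_pct`, `af_smaller`, `votu_id` (one row per unordered pair).
#' @export
detectClones <- function(votus, x, aniMin = .CLONE_ANI_MIN,
                         afMin = .CLONE_AF_MIN, fragmentLen = 1000L,
                         minFragIdentity = 80, precomputed = NULL) {
  seqs <- if (is(x, "UViGSet")) as.character(uvigSequences(x))
          else setNames(as.character(x), names(x))
  ids <- names(seqs)
  cl <- votuTable(votus)
  useq <- unique(seqs)
  uidx <- setNames(match(seqs, useq), ids)
  lookup <- .similarityProvider(useq, fragmentLen, minFragIdentity)
  if (!is.null(precomputed)) {
    uidx <- setNames(seq_along(seqs), ids)
    lookup <- .similarityProvider(seqs, fragmentLen, minFragIdentity,
                                  precomputed = precomputed, ids = ids)
  }
  out <- vector("list", nrow(cl))
  for (r in seq_len(nrow(cl))) {
    mem <- sort(cl$members[[r]])
    if (length(mem) < 2) next
    pairs <- utils::combn(mem, 2)
    keep <- logical(ncol(pairs))
    ani <- af <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      sim <- lookup(uidx[[pairs[1, p]]], uidx[[pairs[2, p]]])
      ani[p] <- sim["ani_pct"]; af[p] <- sim["af_smaller"]
      keep[p] <- sim["ani_pct"] >= aniMin && sim["af_smaller"] >= afMin
    }
    if (any(keep))
      out[[r]] <- data.frame(uvig_a = pairs[1, keep], uvig_b = pairs[2, keep],
                             ani_pct = ani[keep], af_smaller = af[keep],
                             votu_id = cl$votu_id[r])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(uvig_a = character(), uvig_b = character(),
                      ani_pct = numeric(), af_smaller = numeric(),
                      votu_id = character())
  .stageLog("clones", nrow(out), " clone pairs detected")
  out
}
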