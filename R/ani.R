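#' @include AllClasses.R
NULL

## Fragment-based ANI/AF estimator.
##
## The shorter sequence of a pair is tiled into non-overlapping fragments of
## `fragmentLen` bp (trailing partial fragments are dropped). Each fragment is
## placed on the longer sequence by exact k-mer seeding followed by gapless
## extension: candidate offsets are collected from exact seed matches, and the
## candidate with the highest Hamming identity over the full fragment wins.
## Fragments reaching `minFragIdentity` percent identity are "mapped".
## ANI is the mean identity of mapped fragments; AF is the fraction of
## fragments mapped. Gapless placement assumes collinear, substitution-
## dominated divergence, which holds for clone/vOTU discrimination of
## same-lineage contigs; for indel-rich comparisons use an external ANI table
## via [readFastANITable()].

.BASE_CODE <- {
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
}

## integer encoding of a nucleotide string (NA for ambiguity codes)
.encodeSeq <- function(s) .BASE_CODE[utf8ToInt(s) + 1L]

## rolling k-mer codes as doubles (exact up to 4^k <= 2^53); NA where the
## window contains an ambiguous base
.kmerCodes <- function(b, k) {
  n <- length(b)
  if (n < k) return(numeric(0))
  m <- embed(as.numeric(b), k)   # row i = b[i+k-1], ..., b[i]
  as.numeric(m %*% 4^(0:(k - 1)))
}

#' Pairwise ANI and alignment fraction of two sequences
#'
#' Estimates average nucleotide identity (ANI) and alignment fraction (AF)
#' between two nucleotide sequences with a fragment-mapping estimator. AF is
#' computed relative to the shorter sequence: the fraction of its
#' full-length fragments that map to the longer sequence. If no fragment
#' maps, ANI and AF are both 0 (not missing), so thresholds evaluate false.
#'
#' @param seqA,seqB Nucleotide strings (or length-1 DNAStringSet /
#'   DNAString).
#' @param fragmentLen Fragment size in bp (default 1000).
#' @param minFragIdentity Percent identity required for a fragment to count
#'   as mapped (default 80).
#' @param seedK Seed k-mer length used to place fragments.
#' @param seedStep Spacing between seeds inside a fragment.
#' @return A one-row data.frame with `ani_pct` (0-100), `af_smaller` (0-1),
#'   `n_fragments` and `n_mapped`.
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
#' computeAniAf(s, s)
#' @export
computeAniAf <- function(seqA, seqB, fragmentLen = 1000L,
                         minFragIdentity = 80, seedK = 16L, seedStep = 64L) {
  a <- as.character(seqA)[1]
  b <- as.character(seqB)[1]
  if (min(nchar(a), nchar(b)) < fragmentLen)
    stop("sequence shorter than fragment_len (", fragmentLen,
         "); use a smaller fragment_len", call. = FALSE)
  if (nchar(a) <= nchar(b)) {
    short <- .encodeSeq(a); long <- .encodeSeq(b)
  } else {
    short <- .encodeSeq(b); long <- .encodeSeq(a)
  }
  .aniCore(short, long, fragmentLen, minFragIdentity, seedK, seedStep)
}

## core on integer-encoded vectors; short is the shorter sequence
.aniCore <- function(short, long, fragmentLen, minFragIdentity,
                     seedK = 16L, seedStep = 64L) {
  nFrag <- length(short) %/% fragmentLen
  longCodes <- .kmerCodes(long, seedK)
  shortCodes <- .kmerCodes(short, seedK)
  seedOffsets <- seq.int(1L, fragmentLen - seedK + 1L, by = seedStep)
  identities <- numeric(0)
  nMapped <- 0L
  longLen <- length(long)
  for (f in seq_len(nFrag)) {
    s <- (f - 1L) * fragmentLen + 1L
    frag <- short[s:(s + fragmentLen - 1L)]
    ## candidate placements from exact seed matches
    cand <- integer(0)
    for (off in seedOffsets) {
      code <- shortCodes[s + off - 1L]
      if (is.na(code)) next
      hits <- which(longCodes == code)
      if (length(hits)) cand <- c(cand, hits - off + 1L)
    }
    cand <- cand[cand >= 1L & cand + fragmentLen - 1L <= longLen]
    if (!length(cand)) next
    tab <- sort(table(cand), decreasing = TRUE)
    cand <- as.integer(names(tab))[seq_len(min(8L, length(tab)))]
    best <- 0
    for (o in cand) {
      idn <- sum(frag == long[o:(o + fragmentLen - 1L)], na.rm = TRUE) /
        fragmentLen * 100
      if (idn > best) best <- idn
    }
    if (best >= minFragIdentity) {
      nMapped <- nMapped + 1L
      identities <- c(identities, best)
    }
  }
  data.frame(
    ani_pct = if (nMapped) mean(identities) else 0,
    af_smaller = if (nFrag) nMapped / nFrag else 0,
    n_fragments = nFrag, n_mapped = nMapped)
}

## Value-sampled k-mer sketch used to prescreen candidate centroids during
## greedy clustering: the same k-mer is sampled in every sequence containing
## it, so related sequences share sketch entries while unrelated random
## sequences share essentially none. Purely an accelerator; final membership
## is always decided by the full ANI/AF computation.
.sketchKmers <- function(codes, mod = 101, keep = 6) {
  codes <- codes[!is.na(codes)]
  unique(codes[codes %% mod < keep])
}

## A memoising pairwise-similarity provider over a fixed set of sequences.
## `lookup(i, j)` returns the computeAniAf row for sequences i and j, caching
## by unordered index pair so duplicated sequences cost one computation.
.similarityProvider <- function(seqs, fragmentLen = 1000L,
                                minFragIdentity = 80, precomputed = NULL,
                                ids = NULL) {
  enc <- lapply(seqs, .encodeSeq)
  lens <- nchar(seqs)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  pre <- NULL
  if (!is.null(precomputed)) {
    stopifnot(!is.null(ids))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    pre <- new.env(parent = emptyenv(), hash = TRUE)
    for (r in seq_len(nrow(precomputed))) {
      k <- key(precomputed$uvig_a[r], precomputed$uvig_b[r])
      assign(k, c(precomputed$ani_pct[r], precomputed$af_smaller[r]), envir = pre)
    }
  }
  function(i, j) {
    k <- if (i < j) paste0(i, ",", j) else paste0(j, ",", i)
    hit <- cache[[k]]
    if (!is.null(hit)) return(hit)
    if (!is.null(pre)) {
      pk <- paste(pmin(ids[i], ids[j]), pmax(ids[i], ids[j]), sep = "\r")
      v <- pre[[pk]]
      res <- if (is.null(v)) c(ani_pct = 0, af_smaller = 0)
             else c(ani_pct = v[1], af_smaller = v[2])
    } else {
      fl <- min(fragmentLen, lens[i], lens[j])
      if (i == j || identical(seqs[i], seqs[j])) {
        res <- c(ani_pct = 100, af_smaller = 1)
      } else {
        r <- if (lens[i] <= lens[j])
          .aniCore(enc[[i]], enc[[j]], fl, minFragIdentity)
        else
          .aniCore(enc[[j]], enc[[i]], fl, minFragIdentity)
        res <- c(ani_pct = r$ani_pct, af_smaller = r$af_smaller)
      }
    }
    cache[[k]] <- res
    res
  }
}
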