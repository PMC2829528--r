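#' @include AllClasses.R pairwise.R
NULL

newCorrespondence <- function(index, consensusCoords, coords) {
  storage.mode(index) <- "integer"
  new("Correspondence", index = index,
      consensusCoords = caCoords(consensusCoords), coords = lapply(coords, caCoords))
}

#' Merge pairwise alignments center-star style
#'
#' Combines K pairwise alignments that all share the consensus as their fixed
#' sequence into one correspondence matrix. Consensus positions give shared
#' columns ("once a gap, always a gap" for consensus positions); residues the
#' proteins insert between consecutive consensus positions share insertion
#' columns at that slot, left-aligned — the slot gets as many columns as the
#' longest insertion run among the proteins, and each protein fills its run
#' from the left. The consensus has a gap in every insertion column. The
#' merge leaves the (consensus, protein) pairwise distance of every protein
#' unchanged: projecting the result back to rows (0, j) and dropping
#' mutual-gap columns reproduces the input pairwise alignment exactly.
#'
#' @param consensus consensus coordinates (n0 x 3 matrix or
#'   [CaStructure-class]).
#' @param pairAlignments list of K [PairAlignment-class] objects, each with
#'   the consensus as its fixed sequence (ungapped fixed length must equal
#'   n0).
#' @param coords list of K protein coordinate matrices (in the frame each
#'   alignment was computed in).
#' @return A [Correspondence-class] with K+1 rows.
#' @export
mergeCenterStar <- function(consensus, pairAlignments, coords) {
  consensus <- caCoords(consensus)
  n0 <- nrow(consensus)
  K <- length(pairAlignments)
  stopifnot(K >= 1L, length(coords) == K)
  matchOf <- matrix(NA_integer_, K, n0)   # protein residue matched to cons pos
  insertions <- vector("list", K)         # per protein: list over slots 0..n0
  for (j in seq_len(K)) {
    pa <- pairAlignments[[j]]
    if (pa@nFixed != n0)
      stop(sprintf(
        "pair alignment %d has consensus length %d, expected %d",
        j, pa@nFixed, n0))
    ins <- vector("list", n0 + 1L)
    slot <- 0L
    for (c in seq_along(pa@fixedIdx)) {
      fi <- pa@fixedIdx[c]; mi <- pa@movingIdx[c]
      if (is.na(fi)) {
        ins[[slot + 1L]] <- c(ins[[slot + 1L]], mi)
      } else {
        slot <- fi
        matchOf[j, fi] <- mi
      }
    }
    insertions[[j]] <- ins
  }
  slotWidth <- vapply(0:n0, function(s) {
    max(vapply(insertions, function(ins) length(ins[[s + 1L]]), integer(1)))
  }, integer(1))
  L <- n0 + sum(slotWidth)
  idx <- matrix(NA_integer_, K + 1L, L)
  col <- 0L
  for (s in 0:n0) {
    if (s > 0L) {
      col <- col + 1L
      idx[1L, col] <- s
      idx[seq_len(K) + 1L, col] <- matchOf[, s]
    }
    w <- slotWidth[s + 1L]
    if (w > 0L) {
      for (j in seq_len(K)) {
        run <- insertions[[j]][[s + 1L]]
        if (length(run))
          idx[j + 1L, col + seq_along(run)] <- run
      }
      col <- col + w
    }
  }
  newCorrespondence(idx, consensus, coords)
}

#' Remove all-gap columns from a correspondence
#'
#' Columns in which every row (consensus included) holds a gap contribute
#' nothing to the SC-distance (aligning two gaps costs zero), so they are
#' dropped; the relative order of the remaining columns is preserved. The
#' operation is idempotent.
#'
#' @param H a [Correspondence-class].
#' @return The stripped [Correspondence-class].
#' @export
stripAllGapColumns <- function(H) {
  keep <- colSums(!is.na(H@index)) > 0L
  if (all(keep)) return(H)
  newCorrespondence(H@index[, keep, drop = FALSE], H@consensusCoords,
                    H@coords)
}

#' Sum-of-Consensus distance
#'
#' The total distance of the K proteins to the consensus: for every protein
#' row, each column contributes the squared Euclidean distance between the
#' consensus triple and the protein triple when both are present, the gap
#' cost (see [gapCostSq()]) when exactly one is a gap, and zero when both are
#' gaps. Coordinates are taken as stored in the correspondence (the current
#' frame); the consensus itself is never transformed.
#'
#' @param H a [Correspondence-class].
#' @param params an [AlignParams-class].
#' @return SC-distance in squared Angstrom.
#' @export
scDistance <- function(H, params = alignParams()) {
  g <- gapCostSq(params)
  cIdx <- H@index[1L, ]
  K <- nrow(H@index) - 1L
  total <- 0
  for (j in seq_len(K)) {
    pIdx <- H@index[j + 1L, ]
    match <- !is.na(cIdx) & !is.na(pIdx)
    if (any(match))
      total <- total +
        sum(rowSqDist(H@consensusCoords[cIdx[match], , drop = FALSE],
                      H@coords[[j]][pIdx[match], , drop = FALSE]))
    total <- total + g * sum(is.na(cIdx) != is.na(pIdx))
  }
  total
}

# Project the merged correspondence back onto the (consensus, protein j)
# pair, dropping mutual-gap columns. Returns a PairAlignment whose cost is
# recomputed in the stored frame. This is the defining contract of the
# center-star merge.
projectPair <- function(H, j, params = alignParams()) {
  cIdx <- H@index[1L, ]
  pIdx <- H@index[j + 1L, ]
  keep <- !(is.na(cIdx) & is.na(pIdx))
  al <- newPairAlignment(cIdx[keep], pIdx[keep], 0,
                         nrow(H@consensusCoords), nrow(H@coords[[j]]))
  al@cost <- pairAlignmentCost(al, H@consensusCoords, H@coords[[j]], params)
  al
}
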