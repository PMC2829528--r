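#' @include AllClasses.R multialign.R
NULL

#' Optimal consensus choice for one alignment column
#'
#' For a column with point set \eqn{p_i, i \in I_n} (proteins with a residue
#' there) and \eqn{|I_g|} protein gaps, the optimal consensus entry is either
#' the arithmetic centroid \eqn{x} of the points or a gap. Among all
#' coordinate triples the centroid minimises the summed squared distance
#' ("spread"), so the choice reduces to comparing the centroid against the
#' gap option, whose cost is \eqn{|I_n|\rho^2}. Under the default
#' \code{"strict"} rule the triple is chosen iff
#' \eqn{\sum_i \|x - p_i\|^2 + |I_g|\rho^2 \le |I_n|\rho^2}, counting the
#' \eqn{|I_g|\rho^2} a consensus triple incurs against protein gaps, so the
#' update is an exact SC-distance minimiser. The \code{"literal"} rule drops
#' the \eqn{|I_g|\rho^2} term and compares the spread alone against
#' \eqn{|I_n|\rho^2} (the two-case comparison as commonly printed); the two
#' rules coincide on gap-free columns. Ties pick the triple.
#'
#' @param points numeric matrix (one row per non-gap protein triple in the
#'   column); may have zero rows only if \code{nGaps} covers all proteins.
#' @param nGaps number of proteins with a gap in the column.
#' @param params an [AlignParams-class] (\code{consensusRule} selects the
#'   rule).
#' @return List with \code{value} (numeric length-3 centroid, or \code{NULL}
#'   for a gap), \code{gap} (logical), \code{support} (\eqn{|I_n|}) and
#'   \code{spread} (summed squared distance to the centroid).
#' @examples
#' consensusColumn(rbind(c(0, 0, 0), c(2, 0, 0)), 0, alignParams())
#' @export
consensusColumn <- function(points, nGaps = 0L, params = alignParams()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) {
    if (nGaps < 1L) stop("empty column")
    return(list(value = NULL, gap = TRUE, support = 0L, spread = 0))
  }
  g <- gapCostSq(params)
  x <- colMeans(points)
  spread <- sum(rowSqDist(points, matrix(x, n, 3L, byrow = TRUE)))
  tripleCost <- if (params@consensusRule == "strict") spread + nGaps * g
                else spread
  if (tripleCost <= n * g)
    list(value = as.numeric(x), gap = FALSE, support = n, spread = spread)
  else
    list(value = NULL, gap = TRUE, support = n, spread = spread)
}

#' Recompute the consensus row of a correspondence
#'
#' Applies [consensusColumn()] to every column of the correspondence,
#' replacing the consensus row by per-column centroids or gaps. The update
#' never increases the SC-distance relative to the previous consensus under
#' the default \code{"strict"} rule (each column is optimised independently);
#' the \code{"literal"} rule can re-admit a triple whose gap charges exceed
#' its savings. Columns whose consensus becomes a gap while every
#' protein is also gapped turn into all-gap columns; strip them afterwards
#' with [stripAllGapColumns()].
#'
#' @param H a [Correspondence-class] (protein coordinates in the current
#'   frame).
#' @param params an [AlignParams-class].
#' @return The updated [Correspondence-class].
#' @export
updateConsensus <- function(H, params = alignParams()) {
  idx <- H@index
  K <- nrow(idx) - 1L
  L <- ncol(idx)
  consRow <- integer(L)
  triples <- vector("list", L)
  nCons <- 0L
  for (c in seq_len(L)) {
    pIdx <- idx[seq_len(K) + 1L, c]
    inSet <- which(!is.na(pIdx))
    pts <- if (length(inSet))
      do.call(rbind, lapply(inSet, function(j) H@coords[[j]][pIdx[j], ]))
    else matrix(numeric(0), 0L, 3L)
    cc <- consensusColumn(pts, K - length(inSet), params)
    if (cc$gap) {
      consRow[c] <- NA_integer_
    } else {
      nCons <- nCons + 1L
      consRow[c] <- nCons
      triples[[nCons]] <- cc$value
    }
  }
  idx[1L, ] <- consRow
  cons <- if (nCons)
    do.call(rbind, triples[seq_len(nCons)]) else matrix(numeric(0), 0L, 3L)
  newCorrespondence(idx, cons, H@coords)
}
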