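#' @import methods
NULL

#' Alpha-carbon backbone structure
#'
#' A protein backbone reduced to its ordered C-alpha trace: one coordinate
#' triple (in Angstrom) per residue, in backbone order, together with the
#' three-letter residue names and the residue numbers from the source file.
#'
#' @slot id character label for the structure (typically file base name plus
#'   chain).
#' @slot resid character vector of three-letter residue codes.
#' @slot resno integer vector of residue numbers as found in the source.
#' @slot coords numeric matrix with one row per residue and columns x, y, z.
#'
#' @seealso [caStructure()], [readStructure()]
#' @export
setClass("CaStructure",
  representation(id = "character", resid = "character",
                 resno = "integer", coords = "matrix"))

setValidity("CaStructure", function(object) {
  n <- nrow(object@coords)
  if (n < 1L) return("structure must contain at least one residue")
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (!is.numeric(object@coords) || !all(is.finite(object@coords)))
    return("coords must be finite numeric")
  if (length(object@resid) != n || length(object@resno) != n)
    return("resid/resno length must match number of residues")
  if (length(object@id) != 1L) return("id must be a single string")
  TRUE
})

#' Construct a CaStructure
#'
#' @param coords numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param id structure label.
#' @param resid three-letter residue codes (recycled "UNK" if omitted).
#' @param resno residue numbers (defaults to 1..n).
#' @return A [CaStructure-class] object.
#' @examples
#' s <- caStructure(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE))
#' length(s)
#' @export
caStructure <- function(coords, id = "structure", resid = NULL, resno = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(resid)) resid <- rep("UNK", n)
  if (is.null(resno)) resno <- seq_len(n)
  new("CaStructure", id = as.character(id), resid = as.character(resid),
      resno = as.integer(resno), coords = coords)
}

#' Rigid-body transform
#'
#' A rotation plus translation acting on row-vector coordinates as
#' \eqn{G = (H - e t) R}: the translation is subtracted first, then the
#' rotation matrix is applied on the right. Gaps are unaffected by a
#' transform.
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 translation vector (Angstrom).
#' @seealso [rigidTransform()], [applyTransform()], [composeTransforms()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (R'R = I within 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det +1 within 1e-8)")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return A [RigidTransform-class] object.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname RigidTransform-class
#' @export
identityTransform <- function() rigidTransform()

#' Pairwise structural alignment
#'
#' A global alignment of two C-alpha traces, stored as two parallel index
#' vectors: column c pairs residue \code{fixedIdx[c]} of the fixed structure
#' with residue \code{movingIdx[c]} of the moving structure; \code{NA} marks a
#' gap. Every residue of both structures appears exactly once, indices are
#' strictly increasing, and no column is gap-gap. \code{cost} is the alignment
#' cost in squared Angstrom: the sum of squared match distances plus the gap
#' cost for every gap column.
#'
#' @slot fixedIdx integer vector with NA gaps (indices into the fixed trace).
#' @slot movingIdx integer vector with NA gaps (indices into the moving trace).
#' @slot cost numeric scalar, squared-Angstrom alignment cost.
#' @slot nFixed,nMoving lengths of the two traces.
#' @seealso [dpAlign()], [pairwiseStructureAlign()]
#' @export
setClass("PairAlignment",
  representation(fixedIdx = "integer", movingIdx = "integer",
                 cost = "numeric", nFixed = "integer", nMoving = "integer"))

setValidity("PairAlignment", function(object) {
  f <- object@fixedIdx; m <- object@movingIdx
  if (length(f) != length(m)) return("index vectors must have equal length")
  if (any(is.na(f) & is.na(m))) return("gap-gap columns are not allowed")
  ff <- f[!is.na(f)]; mm <- m[!is.na(m)]
  if (!identical(ff, seq_len(object@nFixed)))
    return("fixed indices must cover 1..nFixed in order")
  if (!identical(mm, seq_len(object@nMoving)))
    return("moving indices must cover 1..nMoving in order")
  if (length(object@cost) != 1L || !is.finite(object@cost))
    return("cost must be a finite scalar")
  TRUE
})

#' Alignment parameters
#'
#' Tunable parameters shared by the pairwise aligner, the merge step and the
#' consensus update.
#'
#' @slot gapPenalty gap penalty value; its meaning depends on
#'   \code{gapMode}. With the default \code{"squared"} mode the value is the
#'   per-gap-column cost in squared Angstrom (default 16, i.e. a gap costs as
#'   much as a 4 Angstrom mismatch); with \code{"linear"} the value is the
#'   gap distance \eqn{\rho} in Angstrom and every gap column costs
#'   \eqn{\rho^2}.
#' @slot gapMode "squared" or "linear" (see above).
#' @slot eta outer-loop convergence threshold on the change in SC-distance
#'   (default 1e-4).
#' @slot etaMode "relative" (default) or "absolute" convergence test.
#' @slot innerTol absolute tolerance in squared Angstrom for the inner
#'   refinement loops (default 1e-6).
#' @slot maxOuter,maxInnerPair,maxInnerRefine iteration caps.
#' @slot consensusRule "strict" (default) decides triple-vs-gap by comparing
#'   the centroid spread plus the \eqn{|I_g|\rho^2} cost a consensus triple
#'   incurs against protein gaps with the gap option's \eqn{|I_n|\rho^2},
#'   making the update an exact SC minimiser and the outer loop provably
#'   non-increasing; "literal" drops the \eqn{|I_g|\rho^2} term (the
#'   two-case comparison as commonly printed), which can re-admit consensus
#'   positions with little support.
#' @slot coreCutoff strict-core distance cutoff in Angstrom (default 4.0).
#' @seealso [alignParams()]
#' @export
setClass("AlignParams",
  representation(gapPenalty = "numeric", gapMode = "character",
                 eta = "numeric", etaMode = "character",
                 innerTol = "numeric", maxOuter = "integer",
                 maxInnerPair = "integer", maxInnerRefine = "integer",
                 consensusRule = "character", coreCutoff = "numeric"))

setValidity("AlignParams", function(object) {
  if (object@gapPenalty <= 0) return("gapPenalty must be positive")
  if (!object@gapMode %in% c("squared", "linear"))
    return("gapMode must be 'squared' or 'linear'")
  if (object@eta <= 0 || object@eta >= 1) return("eta must be in (0, 1)")
  if (!object@etaMode %in% c("relative", "absolute"))
    return("etaMode must be 'relative' or 'absolute'")
  if (object@innerTol <= 0) return("innerTol must be positive")
  if (!object@consensusRule %in% c("literal", "strict"))
    return("consensusRule must be 'literal' or 'strict'")
  if (object@coreCutoff <= 0) return("coreCutoff must be positive")
  TRUE
})

#' Construct alignment parameters
#'
#' @param gapPenalty gap penalty (default 16; see [AlignParams-class]).
#' @param gapMode "squared" (default) or "linear".
#' @param eta outer convergence threshold (default 1e-4).
#' @param etaMode "relative" or "absolute".
#' @param innerTol inner-loop tolerance in squared Angstrom.
#' @param maxOuter,maxInnerPair,maxInnerRefine iteration caps.
#' @param consensusRule "strict" or "literal" consensus update rule.
#' @param coreCutoff strict-core cutoff in Angstrom.
#' @return An [AlignParams-class] object.
#' @examples
#' p <- alignParams()
#' gapCostSq(p)
#' @export
alignParams <- function(gapPenalty = 16, gapMode = c("squared", "linear"),
                        eta = 1e-4, etaMode = c("relative", "absolute"),
                        innerTol = 1e-6, maxOuter = 100L, maxInnerPair = 50L,
                        maxInnerRefine = 100L,
                        consensusRule = c("strict", "literal"),
                        coreCutoff = 4.0) {
  new("AlignParams", gapPenalty = gapPenalty,
      gapMode = match.arg(gapMode), eta = eta, etaMode = match.arg(etaMode),
      innerTol = innerTol, maxOuter = as.integer(maxOuter),
      maxInnerPair = as.integer(maxInnerPair),
      maxInnerRefine = as.integer(maxInnerRefine),
      consensusRule = match.arg(consensusRule), coreCutoff = coreCutoff)
}

#' Per-gap-column cost in squared Angstrom
#'
#' @param params an [AlignParams-class] object.
#' @return The cost charged for every gap column: \code{gapPenalty} itself in
#'   \code{"squared"} mode, \code{gapPenalty^2} in \code{"linear"} mode.
#' @export
gapCostSq <- function(params) {
  if (params@gapMode == "squared") params@gapPenalty else params@gapPenalty^2
}

#' Multiple-alignment correspondence matrix
#'
#' The gapped correspondence of K proteins and the consensus pseudo-structure:
#' an integer matrix of K+1 rows (row 1 is the consensus) by L columns, where
#' entry (i, c) is the residue index of row i placed in column c, or \code{NA}
#' for a gap. Reading the non-NA entries of any row left to right gives
#' exactly 1..l_i, so removing the gaps from a row reproduces that structure's
#' residue sequence in order. Coordinates travel with the object:
#' \code{consensusCoords} holds the consensus triples (one row per non-gap
#' consensus position) and \code{coords} the K protein coordinate matrices in
#' the frame the correspondence is evaluated in.
#'
#' @slot index integer (K+1) x L matrix with NA gaps; row 1 = consensus.
#' @slot consensusCoords numeric matrix of consensus coordinate triples.
#' @slot coords list of K numeric l_i x 3 matrices.
#' @seealso [mergeCenterStar()], [scDistance()], [stripAllGapColumns()]
#' @export
setClass("Correspondence",
  representation(index = "matrix", consensusCoords = "matrix",
                 coords = "list"))

setValidity("Correspondence", function(object) {
  idx <- object@index
  K <- nrow(idx) - 1L
  if (K < 1L) return("correspondence needs at least one protein row")
  if (length(object@coords) != K)
    return("coords list length must equal the number of protein rows")
  cons <- idx[1L, ]
  cc <- cons[!is.na(cons)]
  if (!identical(as.integer(cc), seq_len(nrow(object@consensusCoords))))
    return("consensus row must cover its coordinates 1..n0 in order")
  for (j in seq_len(K)) {
    r <- idx[j + 1L, ]
    rr <- r[!is.na(r)]
    if (!identical(as.integer(rr), seq_len(nrow(object@coords[[j]]))))
      return(sprintf("row %d must cover residues 1..l in order", j))
    if (ncol(object@coords[[j]]) != 3L)
      return("protein coordinates must be n x 3")
  }
  lens <- c(nrow(object@consensusCoords),
            vapply(object@coords, nrow, integer(1)))
  if (ncol(idx) < max(lens))
    return("width must be at least the longest ungapped row")
  TRUE
})

#' Result of a multiple structure alignment
#'
#' Everything [mapsci()] produces: the final correspondence (with transformed
#' coordinates and consensus), the per-protein rigid transforms mapping each
#' input structure into the consensus frame, the trace of SC-distance values
#' across outer iterations, and bookkeeping about the run.
#'
#' @slot structures list of the input [CaStructure-class] objects.
#' @slot correspondence final [Correspondence-class]; protein coordinates are
#'   in the consensus frame.
#' @slot transforms list of K [RigidTransform-class] objects (original
#'   coordinates to consensus frame).
#' @slot scTrace numeric vector of SC-distance values, one per outer
#'   iteration (non-increasing).
#' @slot iterations number of outer iterations performed.
#' @slot initialIndex index of the structure used as initial consensus.
#' @slot strategy initial-consensus strategy name.
#' @slot params the [AlignParams-class] used.
#' @seealso [mapsci()], [strictCore()], [coreReport()]
#' @export
setClass("MapsciAlignment",
  representation(structures = "list", correspondence = "Correspondence",
                 transforms = "list", scTrace = "numeric",
                 iterations = "integer", initialIndex = "integer",
                 strategy = "character", params = "AlignParams"))

setValidity("MapsciAlignment", function(object) {
  K <- length(object@structures)
  if (length(object@transforms) != K)
    return("one transform per input structure required")
  if (nrow(object@correspondence@index) != K + 1L)
    return("correspondence must have K+1 rows")
  TRUE
})
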