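#' @include AllClasses.R geometry.R
NULL

# Recompute a PairAlignment's cost from coordinates (used by tests and by the
# validity story: the stored cost must equal the per-column sum).
pairAlignmentCost <- function(alignment, fixed, moving, params) {
  fixed <- caCoords(fixed); moving <- caCoords(moving)
  f <- alignment@fixedIdx; m <- alignment@movingIdx
  match <- !is.na(f) & !is.na(m)
  sum(rowSqDist(fixed[f[match], , drop = FALSE],
                moving[m[match], , drop = FALSE])) +
    sum(!match) * gapCostSq(params)
}

newPairAlignment <- function(fixedIdx, movingIdx, cost, nFixed, nMoving) {
  new("PairAlignment", fixedIdx = as.integer(fixedIdx),
      movingIdx = as.integer(movingIdx), cost = as.numeric(cost),
      nFixed = as.integer(nFixed), nMoving = as.integer(nMoving))
}

#' Dynamic-programming alignment of two traces in a common frame
#'
#' Global (Needleman-Wunsch-style) alignment of two C-alpha traces that are
#' already in a common coordinate frame, minimising the sum of squared match
#' distances plus a constant cost per gap column (see [gapCostSq()]). No
#' superposition happens inside this function.
#'
#' @param fixed,moving [CaStructure-class] objects or n x 3 coordinate
#'   matrices; \code{fixed} is typically the consensus.
#' @param params an [AlignParams-class].
#' @return A [PairAlignment-class] with the optimal cost and a deterministic
#'   traceback (match preferred over gap-in-moving over gap-in-fixed on
#'   ties).
#' @examples
#' a <- matrix(c(0, 0, 0), 1, 3)
#' b <- matrix(c(10, 0, 0), 1, 3)
#' alignmentCost(dpAlign(a, b, alignParams()))  # 32: two gaps beat one match
#' @export
dpAlign <- function(fixed, moving, params = alignParams()) {
  fixed <- caCoords(fixed); moving <- caCoords(moving)
  if (nrow(fixed) < 1L || nrow(moving) < 1L) stop("empty input trace")
  res <- dp_align_cpp(fixed, moving, gapCostSq(params))
  newPairAlignment(res$fixedIdx, res$movingIdx, res$cost,
                   nrow(fixed), nrow(moving))
}

# Gapless seed windows for the bootstrap aligner: N-terminal, C-terminal and
# centered windows of length w = min(n, m, 40).
seedWindows <- function(n, m, wmax = 40L) {
  w <- min(n, m, wmax)
  list(nterm    = list(fi = seq_len(w), mi = seq_len(w)),
       cterm    = list(fi = n - w + seq_len(w), mi = m - w + seq_len(w)),
       centered = list(fi = floor((n - w) / 2) + seq_len(w),
                       mi = floor((m - w) / 2) + seq_len(w)))
}

#' Pairwise structure alignment by iterated superposition and DP
#'
#' Self-contained bootstrap aligner for two structures in arbitrary frames.
#' Three gapless seed correspondences (N-terminal, C-terminal and centered
#' windows of up to 40 residues) are each superposed and scored by a DP
#' alignment in the resulting frame; the cheapest seed initialises an
#' iteration that alternates optimal superposition on the current match
#' columns with a fresh DP alignment in the new frame, until the cost change
#' drops below \code{innerTol} or \code{maxInnerPair} iterations. The cost
#' sequence is non-increasing: each superposition is optimal for the current
#' matches and each DP is optimal for the current frame.
#'
#' @param P,Q [CaStructure-class] objects or coordinate matrices with at
#'   least 3 residues each; P is the fixed structure, Q is moved.
#' @param params an [AlignParams-class].
#' @return List with elements \code{alignment} (a [PairAlignment-class], in
#'   the final frame) and \code{transform} (the [RigidTransform-class]
#'   mapping Q into P's frame).
#' @export
pairwiseStructureAlign <- function(P, Q, params = alignParams()) {
  P <- caCoords(P); Q <- caCoords(Q)
  if (nrow(P) < 3L || nrow(Q) < 3L)
    stop("pairwise structure alignment needs at least 3 residues per input")
  best <- NULL
  for (sw in seedWindows(nrow(P), nrow(Q))) {
    tf <- superpose(P[sw$fi, , drop = FALSE],
                    Q[sw$mi, , drop = FALSE])$transform
    al <- dpAlign(P, applyTransform(Q, tf), params)
    if (is.null(best) || al@cost < best$alignment@cost)
      best <- list(alignment = al, transform = tf)
  }
  refinePairAlignment(P, Q, best$alignment, best$transform, params)
}

# Inner refinement shared with the driver: alternate superposition on match
# columns with DP realignment until the cost stabilises.
refinePairAlignment <- function(P, Q, alignment, transform, params) {
  cost <- alignment@cost
  for (it in seq_len(params@maxInnerPair)) {
    f <- alignment@fixedIdx; m <- alignment@movingIdx
    match <- !is.na(f) & !is.na(m)
    if (!any(match)) break
    tf <- superpose(P[f[match], , drop = FALSE],
                    Q[m[match], , drop = FALSE])$transform
    al <- dpAlign(P, applyTransform(Q, tf), params)
    if (al@cost <= cost) {
      alignment <- al
      transform <- tf
    }
    if (cost - al@cost < params@innerTol) break
    cost <- al@cost
  }
  list(alignment = alignment, transform = transform)
}
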