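#' @include AllClasses.R geometry.R pairwise.R multialign.R consensus.R coremetrics.R
NULL

# identity pairwise alignment of a structure against itself
identityAlignment <- function(n) newPairAlignment(seq_len(n), seq_len(n), 0, n, n)

# Initial correspondence for candidate center c: pairwise-align every
# structure to it and merge, carrying the pairwise-transformed coordinates so
# the initial core can be measured.
initialCorrespondence <- function(coordsList, center, params) {
  K <- length(coordsList)
  cons <- coordsList[[center]]
  pairs <- vector("list", K)
  moved <- vector("list", K)
  for (j in seq_len(K)) {
    if (j == center) {
      pairs[[j]] <- identityAlignment(nrow(cons))
      moved[[j]] <- cons
    } else {
      pa <- pairwiseStructureAlign(cons, coordsList[[j]], params)
      pairs[[j]] <- pa$alignment
      moved[[j]] <- applyTransform(coordsList[[j]], pa$transform)
    }
  }
  mergeCenterStar(cons, pairs, moved)
}

#' Choose the initial consensus structure
#'
#' Four strategies: \code{"median"} picks the protein of (lower) median
#' length; \code{"center"} the protein minimising the sum of pairwise
#' structure-alignment costs to all others; \code{"minmax"} the protein with
#' the smallest maximum pairwise cost; \code{"maxcore"} the protein whose
#' initial correspondence (all structures pairwise-aligned to it and merged)
#' yields the largest strict core. Ties break to the lowest index.
#'
#' @param structures list of at least two [CaStructure-class] objects (or
#'   coordinate matrices).
#' @param strategy one of "maxcore" (default), "median", "center", "minmax".
#' @param params an [AlignParams-class]; \code{coreCutoff} feeds the maxcore
#'   strategy.
#' @return Integer index of the chosen structure.
#' @export
selectInitialConsensus <- function(structures,
                                   strategy = c("maxcore", "median",
                                                "center", "minmax"),
                                   params = alignParams()) {
  strategy <- match.arg(strategy)
  K <- length(structures)
  if (K < 2L) stop("need at least two structures")
  coordsList <- lapply(structures, caCoords)
  if (strategy == "median") {
    lens <- vapply(coordsList, nrow, integer(1))
    target <- sort(lens)[floor((K + 1L) / 2L)]
    return(which(lens == target)[1L])
  }
  if (strategy %in% c("center", "minmax")) {
    D <- matrix(0, K, K)
    for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
      cost <- pairwiseStructureAlign(coordsList[[a]], coordsList[[b]],
                                     params)$alignment@cost
      D[a, b] <- D[b, a] <- cost
    }
    score <- if (strategy == "center") rowSums(D)
             else apply(D + diag(-Inf, K), 1L, max)
    return(which.min(score))
  }
  # maxcore
  sizes <- vapply(seq_len(K), function(c) {
    H <- initialCorrespondence(coordsList, c, params)
    length(coreColumnsOfCorrespondence(H, params@coreCutoff))
  }, integer(1))
  which.max(sizes)
}

#' Interleaved optimal transforms and consensus for a fixed correspondence
#'
#' For a given correspondence the combined objective (the SC-distance over
#' transforms and consensus) is minimised by alternating two closed-form
#' half-steps: (a) for each protein, the optimal rigid superposition of its
#' match columns onto the current consensus (mismatch columns drop out, since
#' a transform does not affect gap costs), and (b) the per-column consensus
#' update of [updateConsensus()]. The objective is non-increasing at every
#' half-step; iteration stops when the change drops below \code{innerTol} or
#' after \code{maxInnerRefine} rounds.
#'
#' @param H a [Correspondence-class] whose protein coordinates are in their
#'   original (input) frames; the returned transforms map those originals
#'   into the consensus frame.
#' @param params an [AlignParams-class].
#' @return List with \code{transforms} (K [RigidTransform-class] objects),
#'   \code{correspondence} (the [Correspondence-class] with transformed
#'   coordinates and updated consensus) and \code{sc} (the final objective in
#'   squared Angstrom).
#' @export
optimalTransformsAndConsensus <- function(H, params = alignParams()) {
  idx <- H@index
  cons <- H@consensusCoords
  orig <- H@coords
  K <- length(orig)
  transforms <- lapply(seq_len(K), function(i) identityTransform())
  prevS <- Inf
  Ht <- H
  for (it in seq_len(params@maxInnerRefine)) {
    moved <- vector("list", K)
    cI <- idx[1L, ]
    for (j in seq_len(K)) {
      pI <- idx[j + 1L, ]
      match <- !is.na(cI) & !is.na(pI)
      if (any(match))
        transforms[[j]] <- superpose(
          cons[cI[match], , drop = FALSE],
          orig[[j]][pI[match], , drop = FALSE])$transform
      moved[[j]] <- applyTransform(orig[[j]], transforms[[j]])
    }
    Ht <- updateConsensus(newCorrespondence(idx, cons, moved), params)
    S <- scDistance(Ht, params)
    idx <- Ht@index
    cons <- Ht@consensusCoords
    if (is.finite(prevS) && prevS - S < params@innerTol) { prevS <- S; break }
    prevS <- S
  }
  list(transforms = transforms, correspondence = Ht, sc = prevS)
}

#' Multiple structure alignment with consensus identification
#'
#' The main driver. An initial consensus is chosen from the input set
#' ([selectInitialConsensus()]); then the loop repeats: align every protein
#' to the current consensus (a full pairwise structure alignment on the first
#' pass, a coordinate-frame DP realignment afterwards), merge the pairwise
#' alignments center-star style, compute optimal rigid transforms and the
#' updated consensus by interleaved closed-form steps, strip all-gap columns,
#' and record the SC-distance — until its relative change falls below
#' \code{eta}. Every step is individually non-increasing in SC-distance, so
#' the trace converges.
#'
#' @param structures list of K >= 2 [CaStructure-class] objects (or
#'   coordinate matrices), each with at least 3 residues.
#' @param strategy initial-consensus strategy (default "maxcore"); see
#'   [selectInitialConsensus()].
#' @param params an [AlignParams-class].
#' @return A [MapsciAlignment-class].
#' @examples
#' fam <- makeFamily(familySpec(templateLength = 30, K = 3, seed = 7))
#' res <- mapsci(fam$structures)
#' utils::tail(scTrace(res), 1)   # final SC-distance, ~0 for a rigid family
#' @export
mapsci <- function(structures, strategy = c("maxcore", "median", "center",
                                            "minmax"),
                   params = alignParams()) {
  strategy <- match.arg(strategy)
  K <- length(structures)
  if (K < 2L) stop("need at least two structures")
  structures <- lapply(structures, function(s)
    if (is(s, "CaStructure")) s else caStructure(s))
  orig <- lapply(structures, caCoords)
  lens <- vapply(orig, nrow, integer(1))
  if (any(lens < 3L)) stop("every structure needs at least 3 residues")
  idx0 <- selectInitialConsensus(structures, strategy, params)
  cons <- orig[[idx0]]
  cur <- orig
  transforms <- lapply(seq_len(K), function(i) identityTransform())
  trace <- numeric(0)
  scPrev <- Inf
  H <- NULL
  for (outer in seq_len(params@maxOuter)) {
    pairs <- vector("list", K)
    for (j in seq_len(K)) {
      pairs[[j]] <- if (outer == 1L)
        pairwiseStructureAlign(cons, orig[[j]], params)$alignment
      else dpAlign(cons, cur[[j]], params)
    }
    Hm <- mergeCenterStar(cons, pairs, orig)
    step <- optimalTransformsAndConsensus(Hm, params)
    H <- stripAllGapColumns(step$correspondence)
    sc <- step$sc
    trace <- c(trace, sc)
    transforms <- step$transforms
    cur <- lapply(seq_len(K), function(j)
      applyTransform(orig[[j]], transforms[[j]]))
    cons <- H@consensusCoords
    if (nrow(cons) == 0L) break   # degenerate: consensus vanished
    conv <- if (params@etaMode == "relative")
      (scPrev - sc) / max(scPrev, 1e-12) < params@eta
    else scPrev - sc < params@eta
    if (is.finite(scPrev) && conv) break
    scPrev <- sc
  }
  new("MapsciAlignment", structures = structures, correspondence = H,
      transforms = transforms, scTrace = trace,
      iterations = as.integer(length(trace)), initialIndex = as.integer(idx0),
      strategy = strategy, params = params)
}
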