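#' @include AllClasses.R multialign.R
NULL

# Column indices of the strict core for a correspondence whose protein
# coordinates are already in a common frame. A column qualifies iff no
# protein has a gap there and the K triples are mutually within `cutoff`
# ("pairs" reference) or each within `cutoff` of the consensus triple
# ("consensus" reference; columns where the consensus is a gap are excluded).
coreColumnsOfCorrespondence <- function(H, cutoff = 4.0,
                                        reference = c("pairs", "consensus")) {
  reference <- match.arg(reference)
  idx <- H@index
  K <- nrow(idx) - 1L
  full <- colSums(!is.na(idx[seq_len(K) + 1L, , drop = FALSE])) == K
  if (reference == "consensus") full <- full & !is.na(idx[1L, ])
  out <- integer(0)
  for (c in which(full)) {
    pts <- do.call(rbind, lapply(seq_len(K), function(j)
      H@coords[[j]][idx[j + 1L, c], ]))
    ok <- if (reference == "pairs") {
      K < 2L || max(stats::dist(pts)) <= cutoff
    } else {
      x <- H@consensusCoords[idx[1L, c], ]
      all(sqrt(rowSqDist(pts, matrix(x, K, 3L, byrow = TRUE))) <= cutoff)
    }
    if (ok) out <- c(out, c)
  }
  out
}

#' Strict core of a multiple structure alignment
#'
#' The strict core is the set of alignment columns with 100 percent
#' conservation (no protein has a gap) in which the K superposed triples lie
#' within \code{cutoff} Angstrom of each other in the final frames. The
#' default reads "within ... of each other" as the all-pairs rule; the
#' \code{"consensus"} reference instead requires each triple to be within
#' \code{cutoff} of the consensus triple (a sensitivity-check variant).
#'
#' @param x a [MapsciAlignment-class] or a [Correspondence-class] with
#'   coordinates in a common frame.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @param reference "pairs" (default) or "consensus".
#' @return Integer vector of core column indices (possibly empty: no core).
#' @export
setGeneric("strictCore", function(x, cutoff = 4.0,
                                  reference = c("pairs", "consensus"))
  standardGeneric("strictCore"))

#' @rdname strictCore
setMethod("strictCore", "Correspondence", function(x, cutoff, reference)
  coreColumnsOfCorrespondence(x, cutoff, match.arg(reference)))

#' @rdname strictCore
setMethod("strictCore", "MapsciAlignment", function(x, cutoff, reference)
  coreColumnsOfCorrespondence(x@correspondence, cutoff,
                              match.arg(reference)))

#' Core RMSD of a multiple structure alignment
#'
#' RMSD over the strict-core columns in the final superposed frames, with no
#' re-superposition. The default is the average over all K(K-1)/2 structure
#' pairs of the pairwise RMSD across core columns; the \code{"consensus"}
#' reference averages each structure's RMSD to the consensus instead.
#'
#' @param x a [MapsciAlignment-class] or [Correspondence-class].
#' @param core integer vector of core column indices (from [strictCore()]).
#' @param reference "pairs" (default) or "consensus".
#' @return RMSD in Angstrom, or \code{NA_real_} when the core is empty (no
#'   core was found; distinct from an RMSD of 0).
#' @export
coreRmsd <- function(x, core, reference = c("pairs", "consensus")) {
  reference <- match.arg(reference)
  H <- if (is(x, "MapsciAlignment")) x@correspondence else x
  if (length(core) == 0L) return(NA_real_)
  idx <- H@index
  K <- nrow(idx) - 1L
  mats <- lapply(seq_len(K), function(j)
    H@coords[[j]][idx[j + 1L, core], , drop = FALSE])
  if (reference == "pairs") {
    if (K < 2L) return(0)
    vals <- c()
    for (a in seq_len(K - 1L)) for (b in (a + 1L):K)
      vals <- c(vals, rmsdCoords(mats[[a]], mats[[b]]))
    mean(vals)
  } else {
    cIdx <- idx[1L, core]
    if (anyNA(cIdx)) stop("consensus has a gap in a core column")
    cons <- H@consensusCoords[cIdx, , drop = FALSE]
    mean(vapply(mats, function(m) rmsdCoords(cons, m), numeric(1)))
  }
}

#' Summary report of strict core and core RMSD
#'
#' @param x a [MapsciAlignment-class].
#' @param cutoff strict-core cutoff in Angstrom (default 4.0).
#' @param reference "pairs" (default) or "consensus".
#' @return List with \code{core_columns}, \code{core_size},
#'   \code{core_percent} (relative to the shortest input protein) and
#'   \code{core_rmsd} (\code{NA} when no core).
#' @export
coreReport <- function(x, cutoff = 4.0, reference = c("pairs", "consensus")) {
  reference <- match.arg(reference)
  core <- strictCore(x, cutoff, reference)
  minLen <- min(vapply(x@structures, length, integer(1)))
  list(core_columns = core, core_size = length(core),
       core_percent = 100 * length(core) / minLen,
       core_rmsd = coreRmsd(x, core, reference))
}
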