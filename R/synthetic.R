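#' @include AllClasses.R geometry.R
NULL

aaThree <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

#' Random protein-like backbone
#'
#' A self-avoiding-ish random walk with the consecutive C-alpha distance
#' fixed at 3.8 Angstrom: each step perturbs the previous direction
#' (persistence keeps the chain locally straight, jitter emulates bond-angle
#' variation), and proposals landing within 3 Angstrom of an earlier atom are
#' resampled with growing randomness. Deterministic for a given seed; residue
#' names are drawn from the 20 standard amino acids.
#'
#' @param length number of residues (>= 1).
#' @param seed integer seed; all randomness is local to the call.
#' @param id structure label.
#' @return A [CaStructure-class].
#' @examples
#' b <- randomBackbone(10, seed = 1)
#' range(sqrt(rowSums(diff(caCoords(b))^2)))   # all 3.8
#' @export
randomBackbone <- function(length, seed = 1L, id = "synthetic") {
  stopifnot(length >= 1L)
  withSeed(seed, {
    coords <- matrix(0, length, 3L)
    if (length > 1L) {
      dir <- c(1, 0, 0)
      for (i in 2:length) {
        jitter <- 0.6
        for (try in seq_len(30L)) {
          prop <- dir + jitter * stats::rnorm(3L)
          prop <- prop / sqrt(sum(prop^2))
          pt <- coords[i - 1L, ] + 3.8 * prop
          prev <- coords[seq_len(i - 2L), , drop = FALSE]
          if (nrow(prev) == 0L ||
              min(rowSqDist(prev, matrix(pt, nrow(prev), 3L,
                                         byrow = TRUE))) > 9)
            break
          jitter <- jitter * 1.4
        }
        coords[i, ] <- pt
        dir <- prop
      }
    }
    caStructure(coords, id = id,
                resid = sample(aaThree, length, replace = TRUE))
  })
}

#' Specification of a synthetic structure family
#'
#' @param templateLength template length in residues (>= 5).
#' @param K family size (>= 2).
#' @param noiseSigma per-coordinate iid Gaussian noise standard deviation in
#'   Angstrom (default 0: exact rigid copies).
#' @param indelRate per-residue probability of starting a deletion run
#'   (default 0; must be < 0.5).
#' @param maxIndelLen maximum deletion run length in residues.
#' @param seed integer seed driving all of the family's randomness.
#' @return A validated list of class \code{"FamilySpec"}.
#' @seealso [makeFamily()]
#' @export
familySpec <- function(templateLength = 60L, K = 4L, noiseSigma = 0,
                       indelRate = 0, maxIndelLen = 5L, seed = 1L) {
  stopifnot(templateLength >= 5L, K >= 2L, noiseSigma >= 0,
            indelRate >= 0, indelRate < 0.5, maxIndelLen >= 1L)
  structure(list(templateLength = as.integer(templateLength),
                 K = as.integer(K), noiseSigma = noiseSigma,
                 indelRate = indelRate, maxIndelLen = as.integer(maxIndelLen),
                 seed = as.integer(seed)),
            class = "FamilySpec")
}

#' Generate a structure family with known ground truth
#'
#' Builds a template backbone, then derives K family members by (i) deleting
#' runs of residues (each template position starts a deletion of length
#' 1..\code{maxIndelLen} with probability \code{indelRate}; an insertion in
#' one member is equivalent to a deletion in all the others relative to an
#' extended template, so deletions alone span the indel patterns that
#' matter), (ii) adding iid Gaussian coordinate noise, and (iii) applying a
#' random rigid motion. The true residue-to-template-column map and the true
#' motions are recorded, so alignment output can be scored against ground
#' truth.
#'
#' @param spec a [familySpec()].
#' @return List with \code{structures} (K [CaStructure-class] objects),
#'   \code{template} (the template [CaStructure-class]), \code{columns}
#'   (per-structure integer vectors: template column of each residue),
#'   \code{transforms} (the true [RigidTransform-class] mapping each
#'   structure back onto the template frame), \code{nDeleted} (total deleted
#'   residues) and \code{spec}.
#' @examples
#' fam <- makeFamily(familySpec(templateLength = 40, K = 3, seed = 2))
#' superpose(caCoords(fam$structures[[1]]),
#'           caCoords(fam$structures[[2]]))$residual   # ~0: rigid copies
#' @export
makeFamily <- function(spec = familySpec()) {
  stopifnot(inherits(spec, "FamilySpec"))
  template <- randomBackbone(spec$templateLength, seed = spec$seed,
                             id = "template")
  tcoords <- caCoords(template)
  withSeed(spec$seed + 1L, {
    structures <- vector("list", spec$K)
    columns <- vector("list", spec$K)
    transforms <- vector("list", spec$K)
    nDeleted <- 0L
    for (k in seq_len(spec$K)) {
      keep <- rep(TRUE, spec$templateLength)
      if (spec$indelRate > 0) {
        i <- 1L
        while (i <= spec$templateLength) {
          if (stats::runif(1L) < spec$indelRate) {
            len <- sample.int(spec$maxIndelLen, 1L)
            keep[i:min(i + len - 1L, spec$templateLength)] <- FALSE
            i <- i + len
          } else i <- i + 1L
        }
        if (sum(keep) < 3L) keep[] <- TRUE   # degenerate draw: keep all
      }
      nDeleted <- nDeleted + sum(!keep)
      cols <- which(keep)
      X <- tcoords[cols, , drop = FALSE]
      if (spec$noiseSigma > 0)
        X <- X + matrix(stats::rnorm(length(X), sd = spec$noiseSigma),
                        nrow(X), 3L)
      Q <- randomRotation()
      shift <- stats::runif(3L, -20, 20)
      obs <- X %*% Q + matrix(shift, nrow(X), 3L, byrow = TRUE)
      structures[[k]] <- caStructure(obs, id = sprintf("member%02d", k),
                                     resid = residueNames(template)[cols],
                                     resno = cols)
      columns[[k]] <- cols
      # inverse motion: (obs - e shift) Q^T restores the template frame
      transforms[[k]] <- rigidTransform(rotation = t(Q), translation = shift)
    }
    list(structures = structures, template = template, columns = columns,
         transforms = transforms, nDeleted = nDeleted, spec = spec)
  })
}

#' Fraction of ground-truth correspondences recovered
#'
#' For every pair of family members and every template column where both
#' retain a residue, the truth pairs those two residues; the score is the
#' fraction of such pairs that the final correspondence places in the same
#' alignment column.
#'
#' @param result a [MapsciAlignment-class] computed on \code{family$structures}
#'   (in the same order).
#' @param family output of [makeFamily()].
#' @return Fraction in \[0, 1\].
#' @export
correspondenceRecovery <- function(result, family) {
  idx <- correspondenceMatrix(result)
  K <- length(family$structures)
  L <- ncol(idx)
  # columnOf[[k]][r] = alignment column holding residue r of member k
  columnOf <- lapply(seq_len(K), function(k) {
    v <- idx[k + 1L, ]
    out <- integer(max(v, na.rm = TRUE))
    out[v[!is.na(v)]] <- which(!is.na(v))
    out
  })
  hits <- 0L; total <- 0L
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    common <- intersect(family$columns[[a]], family$columns[[b]])
    if (!length(common)) next
    ra <- match(common, family$columns[[a]])
    rb <- match(common, family$columns[[b]])
    total <- total + length(common)
    hits <- hits + sum(columnOf[[a]][ra] == columnOf[[b]][rb])
  }
  if (total == 0L) return(NA_real_)
  hits / total
}
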