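#' @include AllClasses.R
NULL

#' Extract C-alpha coordinates
#'
#' @param x a [CaStructure-class] or a plain numeric matrix.
#' @return Numeric n x 3 matrix of coordinates (Angstrom).
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname caCoords
setMethod("caCoords", "CaStructure", function(x) x@coords)

#' @rdname caCoords
setMethod("caCoords", "matrix", function(x) {
  stopifnot(ncol(x) == 3L)
  storage.mode(x) <- "double"
  x
})

#' @describeIn CaStructure-class number of residues.
#' @param x a CaStructure.
#' @export
setMethod("length", "CaStructure", function(x) nrow(x@coords))

#' @describeIn CaStructure-class structure label.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname CaStructure-class
setMethod("structureId", "CaStructure", function(x) x@id)

#' @describeIn CaStructure-class three-letter residue codes.
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))

#' @rdname CaStructure-class
setMethod("residueNames", "CaStructure", function(x) x@resid)

#' @describeIn CaStructure-class residue numbers from the source file.
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname CaStructure-class
setMethod("residueNumbers", "CaStructure", function(x) x@resno)

#' @describeIn RigidTransform-class the 3 x 3 rotation matrix.
#' @param x a RigidTransform.
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' @rdname RigidTransform-class
setMethod("rotationMatrix", "RigidTransform", function(x) x@rotation)

#' @describeIn RigidTransform-class the translation 3-vector.
#' @export
setGeneric("translationVector",
           function(x) standardGeneric("translationVector"))

#' @rdname RigidTransform-class
setMethod("translationVector", "RigidTransform", function(x) x@translation)

#' Alignment cost in squared Angstrom
#'
#' @param x a [PairAlignment-class].
#' @return Numeric scalar.
#' @export
setGeneric("alignmentCost", function(x) standardGeneric("alignmentCost"))

#' @rdname alignmentCost
setMethod("alignmentCost", "PairAlignment", function(x) x@cost)

#' Alignment columns as a two-column index matrix
#'
#' @param x a [PairAlignment-class].
#' @return Integer L x 2 matrix (columns \code{fixed}, \code{moving}) with NA
#'   marking gaps.
#' @export
setGeneric("alignmentColumns", function(x) standardGeneric("alignmentColumns"))

#' @rdname alignmentColumns
setMethod("alignmentColumns", "PairAlignment", function(x)
  cbind(fixed = x@fixedIdx, moving = x@movingIdx))

#' Consensus coordinate triples
#'
#' @param x a [Correspondence-class] or [MapsciAlignment-class].
#' @return Numeric matrix, one row per non-gap consensus position.
#' @export
setGeneric("consensusCoords", function(x) standardGeneric("consensusCoords"))

#' @rdname consensusCoords
setMethod("consensusCoords", "Correspondence", function(x) x@consensusCoords)

#' @rdname consensusCoords
setMethod("consensusCoords", "MapsciAlignment",
          function(x) x@correspondence@consensusCoords)

#' Correspondence index matrix
#'
#' @param x a [Correspondence-class] or [MapsciAlignment-class].
#' @return Integer (K+1) x L matrix with NA gaps; row 1 is the consensus.
#' @export
setGeneric("correspondenceMatrix",
           function(x) standardGeneric("correspondenceMatrix"))

#' @rdname correspondenceMatrix
setMethod("correspondenceMatrix", "Correspondence", function(x) x@index)

#' @rdname correspondenceMatrix
setMethod("correspondenceMatrix", "MapsciAlignment",
          function(x) x@correspondence@index)

#' Aligned (current-frame) protein coordinates
#'
#' @param x a [Correspondence-class] or [MapsciAlignment-class].
#' @return List of K numeric l_i x 3 matrices.
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))

#' @rdname alignedCoords
setMethod("alignedCoords", "Correspondence", function(x) x@coords)

#' @rdname alignedCoords
setMethod("alignedCoords", "MapsciAlignment",
          function(x) x@correspondence@coords)

#' @describeIn MapsciAlignment-class final correspondence.
#' @param x a MapsciAlignment.
#' @export
setGeneric("correspondence", function(x) standardGeneric("correspondence"))

#' @rdname MapsciAlignment-class
setMethod("correspondence", "MapsciAlignment", function(x) x@correspondence)

#' @describeIn MapsciAlignment-class per-structure rigid transforms into the
#'   consensus frame.
#' @export
setGeneric("transforms", function(x) standardGeneric("transforms"))

#' @rdname MapsciAlignment-class
setMethod("transforms", "MapsciAlignment", function(x) x@transforms)

#' @describeIn MapsciAlignment-class SC-distance trace across outer
#'   iterations (squared Angstrom).
#' @export
setGeneric("scTrace", function(x) standardGeneric("scTrace"))

#' @rdname MapsciAlignment-class
setMethod("scTrace", "MapsciAlignment", function(x) x@scTrace)

#' @describeIn MapsciAlignment-class number of outer iterations run.
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))

#' @rdname MapsciAlignment-class
setMethod("nIterations", "MapsciAlignment", function(x) x@iterations)

#' @describeIn MapsciAlignment-class index of the initial consensus protein.
#' @export
setGeneric("initialConsensusIndex",
           function(x) standardGeneric("initialConsensusIndex"))

#' @rdname MapsciAlignment-class
setMethod("initialConsensusIndex", "MapsciAlignment",
          function(x) x@initialIndex)

setMethod("show", "CaStructure", function(object) {
  cat("CaStructure", sQuote(object@id), "with", length(object),
      "residues\n")
  cat("  first residue:", object@resid[1L], object@resno[1L],
      sprintf("at (%.3f, %.3f, %.3f)\n", object@coords[1L, 1L],
              object@coords[1L, 2L], object@coords[1L, 3L]))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", sprintf("(%.3f, %.3f, %.3f)\n",
      object@translation[1L], object@translation[2L],
      object@translation[3L]))
})

setMethod("show", "PairAlignment", function(object) {
  nm <- sum(!is.na(object@fixedIdx) & !is.na(object@movingIdx))
  cat("PairAlignment:", length(object@fixedIdx), "columns (", nm,
      "matches,", length(object@fixedIdx) - nm, "gaps ), cost",
      sprintf("%.4f A^2\n", object@cost))
})

setMethod("show", "Correspondence", function(object) {
  K <- nrow(object@index) - 1L
  cat("Correspondence:", K, "proteins x", ncol(object@index),
      "columns;", nrow(object@consensusCoords), "consensus positions\n")
})

setMethod("show", "MapsciAlignment", function(object) {
  K <- length(object@structures)
  cat("MapsciAlignment of", K, "structures\n")
  cat("  strategy:", object@strategy, "(initial consensus:",
      structureId(object@structures[[object@initialIndex]]), ")\n")
  cat("  outer iterations:", object@iterations, "\n")
  cat("  SC-distance:", sprintf("%.6g", utils::tail(object@scTrace, 1L)),
      "A^2\n")
  cat("  correspondence width:", ncol(object@correspondence@index),
      "columns,", nrow(object@correspondence@consensusCoords),
      "consensus positions\n")
})
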