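#' @include AllClasses.R
NULL

# All geometry works on row-vector coordinates with the shared transform
# convention G = (H - e t) R: subtract the translation, then right-multiply
# by the rotation.

#' Apply a rigid transform to coordinates
#'
#' @param x numeric n x 3 matrix or [CaStructure-class].
#' @param transform a [RigidTransform-class].
#' @return Object of the same class with transformed coordinates
#'   \eqn{(x - e t) R}.
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  sweep(x, 2L, transform@translation) %*% transform@rotation
})

#' @rdname applyTransform
setMethod("applyTransform", "CaStructure", function(x, transform) {
  initialize(x, coords = applyTransform(x@coords, transform))
})

#' Compose two rigid transforms
#'
#' Returns the single transform equivalent to applying \code{first} and then
#' \code{second} under the row-vector convention \eqn{G = (H - e t) R}.
#'
#' @param first,second [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(first, second) {
  # ((P - e t0) R0 - e t1) R1 = (P - e (t0 + t1 R0^T)) (R0 R1)
  rigidTransform(rotation = first@rotation %*% second@rotation,
                 translation = first@translation +
                   as.numeric(second@translation %*% t(first@rotation)))
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return The transform mapping the image back onto the original frame.
#' @export
invertTransform <- function(transform) {
  R <- transform@rotation
  rigidTransform(rotation = t(R),
                 translation = -as.numeric(transform@translation %*% R))
}

#' Optimal translation for matched point sets
#'
#' For matched coordinate sets A (reference) and B (moving) and a given
#' rotation R, the translation minimising \eqn{\|A - (B - e t) R\|_F^2} is the
#' one matching the centroids of the two sets:
#' \eqn{t = \bar b - \bar a R^T}.
#'
#' @param A,B numeric n x 3 matrices with equal row counts (mismatches
#'   against gaps removed beforehand).
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @return Numeric length-3 translation vector.
#' @export
optimalTranslation <- function(A, B, rotation = diag(3)) {
  A <- caCoords(A); B <- caCoords(B)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 1L)
  as.numeric(colMeans(B) - colMeans(A) %*% t(rotation))
}

#' Optimal rotation for matched point sets (Kabsch/SVD)
#'
#' Centers both sets, takes the SVD \eqn{U \Sigma V^T} of the 3 x 3
#' cross-covariance of the centered sets, and returns
#' \eqn{R = U\,\mathrm{diag}(1, 1, d)\,V^T} with \eqn{d = \det(UV^T)}, so the
#' result is always a proper rotation even when the unconstrained optimum
#' would be a reflection.
#'
#' @param A,B numeric n x 3 matrices with equal row counts.
#' @return 3 x 3 rotation matrix R minimising \eqn{\|A_c - B_c R\|_F^2} over
#'   proper rotations.
#' @export
optimalRotation <- function(A, B) {
  A <- caCoords(A); B <- caCoords(B)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 1L)
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  M <- crossprod(Bc, Ac)   # maximise trace(R^T M) over rotations
  if (max(abs(M)) < .Machine$double.eps * 10) {
    warning("degenerate (all-zero) cross-covariance; returning identity")
    return(diag(3))
  }
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Optimal rigid superposition of matched point sets
#'
#' Closed-form least-squares superposition: center both sets, recover the
#' Kabsch rotation, then the centroid-matching translation. The residual is
#' the summed squared distance after the transform is applied to B.
#'
#' @param A,B numeric n x 3 matrices with equal row counts; n >= 3 gives a
#'   well-determined rotation (n of 1 or 2 is allowed but the rotation is
#'   then not unique; the residual is still optimal).
#' @return List with elements \code{transform} (a
#'   [RigidTransform-class]) and \code{residual} (squared Angstrom).
#' @examples
#' A <- matrix(rnorm(12), 4, 3)
#' superpose(A, A)$residual   # 0
#' @export
superpose <- function(A, B) {
  A <- caCoords(A); B <- caCoords(B)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 1L)
  R <- suppressWarnings(optimalRotation(A, B))
  t <- optimalTranslation(A, B, R)
  tf <- rigidTransform(rotation = R, translation = t)
  list(transform = tf, residual = sum((A - applyTransform(B, tf))^2))
}

#' Root-mean-square deviation over matched positions
#'
#' @param A,B numeric n x 3 matrices with equal row counts (n >= 1). No
#'   superposition is performed; coordinates are compared as given.
#' @return RMSD in Angstrom.
#' @examples
#' rmsdCoords(matrix(0, 1, 3), matrix(c(3, 0, 0), 1, 3))  # 3
#' @export
rmsdCoords <- function(A, B) {
  A <- caCoords(A); B <- caCoords(B)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 1L)
  sqrt(mean(rowSums((A - B)^2)))
}

#' Uniformly random proper rotation
#'
#' Draws from the Haar measure on SO(3) via QR decomposition of a Gaussian
#' matrix with sign correction. Used by the synthetic-family generator and as
#' a brute-force probe of superposition optimality.
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3L, 3L))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}
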