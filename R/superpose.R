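# Rigid-body superposition (Kabsch) and RMSD under a fixed correspondence.
# Convention throughout: the transform maps frame-of-B coordinates into the
# frame of A, y = R x + t.

.asCoordMatrix <- function(x) {
  m <- if (is(x, "LigandInstance") || is(x, "ProteinChain")) coords(x)
       else as.matrix(x)
  if (ncol(m) != 3L) stop("coordinates must have three columns")
  storage.mode(m) <- "double"
  m
}

.mappedPairs <- function(mapping) {
  if (is(mapping, "AtomMapping")) mapping@pairs
  else matrix(as.integer(mapping), ncol = 2)
}

.checkMapped <- function(coordsA, coordsB, pairs) {
  if (max(pairs[, 1L]) > nrow(coordsA) || max(pairs[, 2L]) > nrow(coordsB))
    stop("mapping references atoms missing from the coordinate sets")
}

.isCollinear <- function(m, tol = 1e-8) {
  if (nrow(m) < 3L) return(TRUE)
  c0 <- sweep(m, 2, colMeans(m))
  s <- svd(c0, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param x coordinate matrix (n x 3) in the frame of B.
#' @return coordinates in the frame of A (`y = R x + t`).
#' @export
applyTransform <- function(transform, x) {
  m <- .asCoordMatrix(x)
  sweep(m %*% t(transform@rotation), 2, transform@translation, `+`)
}

#' Compose two rigid transforms
#'
#' `composeTransforms(f, g)` returns the transform equivalent to applying
#' `g` first and then `f`.
#'
#' @param f,g [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(f, g) {
  RigidTransform(f@rotation %*% g@rotation,
                 as.numeric(f@rotation %*% g@translation) + f@translation)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse transform (A frame back to B frame).
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

# lean Kabsch kernel: no validation, no S4 construction; used on hot paths
.kabschCore <- function(a, b, needTransform = FALSE) {
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- a - rep(ca, each = nrow(a))
  bc <- b - rep(cb, each = nrow(b))
  sv <- svd(crossprod(bc, ac))
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((ac - bc %*% t(R))^2)))
  if (needTransform)
    list(rmsd = rmsd, R = R, t = ca - as.numeric(R %*% cb))
  else rmsd
}

#' Optimal rigid superposition of mapped atoms (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of the
#' mapped B atoms onto the mapped A atoms.  Reflections are excluded by
#' correcting the sign of the smallest singular direction, so mirror-image
#' point sets score poorly rather than perfectly.
#'
#' @param coordsA,coordsB coordinate matrices (or `LigandInstance`s).
#' @param mapping an [AtomMapping-class] or a two-column index matrix; at
#'   least 3 pairs, not all collinear.
#' @return A [SuperpositionResult-class] with the optimal
#'   [RigidTransform-class] (B to A) and the minimised RMSD.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' kabsch(a, a, cbind(1:5, 1:5))  # rmsd 0, identity rotation
#' @export
kabsch <- function(coordsA, coordsB, mapping) {
  A <- .asCoordMatrix(coordsA); B <- .asCoordMatrix(coordsB)
  p <- .mappedPairs(mapping)
  if (nrow(p) < 3L) stop("at least 3 mapped atom pairs are required")
  .checkMapped(A, B, p)
  a <- A[p[, 1L], , drop = FALSE]
  b <- B[p[, 2L], , drop = FALSE]
  if (.isCollinear(a) || .isCollinear(b))
    stop("mapped atoms are collinear; superposition is under-determined")
  k <- .kabschCore(a, b, needTransform = TRUE)
  new("SuperpositionResult", transform = RigidTransform(k$R, k$t),
      rmsd = k$rmsd)
}

#' RMSD under a given (fixed) transform
#'
#' Applies the transform to the B coordinates and measures the RMSD over the
#' mapped pairs, with no re-fitting.  This is the RMSD' of a binding-site
#' alignment: the ligand deviation induced by the aligner's superposition.
#'
#' @inheritParams kabsch
#' @param transform a [RigidTransform-class] carrying B into A's frame.
#' @return RMSD in Angstrom.
#' @export
rmsdUnderTransform <- function(coordsA, coordsB, mapping, transform) {
  A <- .asCoordMatrix(coordsA); B <- .asCoordMatrix(coordsB)
  p <- .mappedPairs(mapping)
  if (nrow(p) < 1L) stop("mapping must contain at least one pair")
  .checkMapped(A, B, p)
  a <- A[p[, 1L], , drop = FALSE]
  b <- applyTransform(transform, B)[p[, 2L], , drop = FALSE]
  sqrt(mean(rowSums((a - b)^2)))
}

# ---- JSON serialisation ------------------------------------------------

#' Serialise a RigidTransform to JSON
#'
#' @param transform a [RigidTransform-class].
#' @return A JSON string recording rotation, translation and the frame
#'   convention.
#' @export
transformToJSON <- function(transform) {
  as.character(jsonlite::toJSON(list(
    rotation = unname(lapply(seq_len(3), function(i)
      unname(transform@rotation[i, ]))),
    translation = unname(transform@translation),
    convention = "y=Rx+t, B->A"
  ), auto_unbox = TRUE, digits = NA))
}

#' Deserialise a RigidTransform from JSON
#'
#' @param json a JSON string produced by [transformToJSON()].
#' @return A [RigidTransform-class].
#' @export
transformFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  R <- if (is.matrix(x$rotation)) x$rotation
       else matrix(unlist(x$rotation), 3, 3, byrow = TRUE)
  RigidTransform(R, as.numeric(x$translation))
}
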