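#' Rigid (Kabsch) alignment of one cap to a reference
#'
#' Finds the proper rotation and translation minimising the root mean squared
#' deviation between corresponding points of `cap` and `reference`, using the
#' closed-form SVD solution. Correspondence is positional (the layouts are
#' fixed per cap design); a subset of points may drive the fit while the
#' transform is applied to all points. Reflections are excluded by sign
#' correction of the smallest singular vector, so the returned rotation always
#' has determinant +1.
#'
#' @param cap Cap to align.
#' @param reference Cap or template with the same layout.
#' @param point_subset Indices (or logical mask) of the correspondence points
#'   driving the fit; default all points.
#' @return A list with `transform` (list of `rotation` 3x3, `translation`
#'   length-3, applying as `R x + t`), `aligned` (the transformed cap), and
#'   `distances` (per-point 3D distance from the aligned cap to the
#'   reference, cm).
#' @export
kabsch_align <- function(cap, reference, point_subset = NULL) {
  stopifnot(inherits(cap, "cap"))
  ref_pts <- template_points(reference)
  P <- cap$points
  if (nrow(P) != nrow(ref_pts))
    stop_fnirsdot("cap and reference must have identical point counts",
                  "layout_mismatch")
  idx <- if (is.null(point_subset)) seq_len(nrow(P)) else {
    if (is.logical(point_subset)) which(point_subset) else as.integer(point_subset)
  }
  X <- P[idx, , drop = FALSE]
  Y <- ref_pts[idx, , drop = FALSE]
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  # < 3 non-collinear points leave the rotation underdetermined
  if (nrow(Xc) < 3L || qr(Xc)$rank < 2L || qr(Yc)$rank < 2L)
    stop_fnirsdot("need at least 3 non-collinear correspondence points",
                  "underdetermined")
  H <- crossprod(Xc, Yc)              # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cy - R %*% cx)
  aligned_pts <- sweep(P %*% t(R), 2, tr, `+`)
  aligned <- cap
  aligned$points <- aligned_pts
  dimnames(aligned$points) <- dimnames(P)
  dist <- sqrt(rowSums((aligned_pts - ref_pts)^2))
  list(transform = list(rotation = R, translation = tr),
       aligned = aligned, distances = dist)
}

# Points matrix of a cap or template (both store $points).
template_points <- function(x) {
  if (is.matrix(x)) x else x$points
}

#' Root mean squared deviation between two corresponded point sets
#' @param a,b n x 3 matrices, or caps/templates.
#' @export
rmsd <- function(a, b) {
  a <- template_points(a); b <- template_points(b)
  sqrt(mean(rowSums((a - b)^2)))
}
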