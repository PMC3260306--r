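# Least-squares rigid-body superposition (Kabsch, SVD-based) and RMSD.
# The geometric kernel used by the spin angle and the steering potential.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `reference`. Reflections are excluded by the standard determinant
#' sign correction, so the result is always a proper rotation (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices with equal n >= 3; the
#'   reference points must not be collinear.
#' @return an object of class `rigid_transform`: a list with `rotation`
#'   (3 x 3, applied as `x %*% t(rotation)`), `translation` (length-3) and
#'   `rmsd`, the minimized value in Angstrom.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  .assert_coords(mobile, "mobile coordinates")
  .assert_coords(reference, "reference coordinates")
  if (nrow(mobile) != nrow(reference))
    .fail(sprintf("point counts differ (%d vs %d)", nrow(mobile),
                  nrow(reference)), "shape")
  if (nrow(mobile) < 3)
    .fail("at least 3 points are required", "shape")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  # collinear (or coincident) point sets leave the rotation underdetermined
  sv <- svd(Y)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    .fail("degenerate geometry: reference points are (near-)collinear",
          "conditioning")
  H <- crossprod(X, Y)               # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Xt <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xt - Y)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(rc - R %*% mc),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param tf a `rigid_transform` from [superpose()].
#' @param x n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(tf, x) {
  stopifnot(inherits(tf, "rigid_transform"))
  sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Rotation angle of a rigid transform
#'
#' @param tf a `rigid_transform`.
#' @return rotation angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(tf) {
  tr <- sum(diag(tf$rotation))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Minimized RMSD between two coordinate sets
#'
#' Best-fit RMSD of `mobile` onto `reference`; equals
#' `superpose(mobile, reference)$rmsd` and is never negative.
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_to <- function(mobile, reference) superpose(mobile, reference)$rmsd

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rotation %.2f deg, |t| = %.3f A, rmsd = %.4f A\n",
              rotation_angle(x), .vnorm(x$translation), x$rmsd))
  invisible(x)
}
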