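# The reference-overlap spin angle between the TMD dimer and the NBD dimer.
#
# The reference structure's TMD dimer is least-squares overlapped onto the
# TMD C-alphas of a frame, and its NBD dimer onto the NBD C-alphas. The two
# lines connecting the transformed reference subunit mass centers (half 1 to
# half 2, for TMD and NBD respectively) then reflect the relative arrangement
# of the two dimers in that frame; the spin angle is the angle between these
# lines, by default after projecting both onto the membrane plane (the plane
# normal to the quasi-C2 axis, taken as z for pre-oriented input).

.angle_between <- function(a, b, normal) {
  cr <- .cross3(a, b)
  ang <- atan2(.vnorm(cr), sum(a * b)) * 180 / pi
  signed <- atan2(sum(normal * cr), sum(a * b)) * 180 / pi
  list(angle = ang %% 180, signed = signed)
}

.project_plane <- function(v, normal) {
  n <- normal / .vnorm(normal)
  v - sum(v * n) * n
}

# Internal worker shared by spin_angle() and spin_angle_series().
.spin_angle_one <- function(frame, ref_coords, map, projection, normal) {
  out <- list()
  lines <- list()
  for (reg in c("TMD", "NBD")) {
    in_reg <- map$region == reg
    if (!any(in_reg))
      .fail(sprintf("homodimer map labels no %s residues", reg), "config")
    fit <- superpose(ref_coords[in_reg, , drop = FALSE],
                     frame[in_reg, , drop = FALSE])
    moved <- apply_transform(fit, ref_coords[in_reg, , drop = FALSE])
    half <- map$half[in_reg]
    if (!all(c(1, 2) %in% half))
      .fail(sprintf("%s region does not span both halves", reg), "config")
    c1 <- colMeans(moved[half == 1, , drop = FALSE])
    c2 <- colMeans(moved[half == 2, , drop = FALSE])
    if (.vnorm(c2 - c1) < 1e-9)
      .fail(sprintf("%s subunit mass centers coincide", reg), "conditioning")
    lines[[reg]] <- rbind(c1, c2)
  }
  v_tmd <- lines$TMD[2, ] - lines$TMD[1, ]
  v_nbd <- lines$NBD[2, ] - lines$NBD[1, ]
  if (projection == "membrane-plane") {
    v_tmd <- .project_plane(v_tmd, normal)
    v_nbd <- .project_plane(v_nbd, normal)
    if (.vnorm(v_tmd) < 1e-9 || .vnorm(v_nbd) < 1e-9)
      .fail("a center-connecting line is parallel to the membrane normal",
            "conditioning")
  }
  ang <- .angle_between(v_tmd, v_nbd, normal)
  structure(list(angle = ang$angle, signed_angle = ang$signed,
                 tmd_line = lines$TMD, nbd_line = lines$NBD,
                 normal = normal / .vnorm(normal), projection = projection),
            class = "spin_angle_result")
}

#' Spin angle between the TMD and NBD dimers
#'
#' @param frame either a [structure3d()] or an n x 3 coordinate matrix over
#'   the mapped C-alpha residues in homodimer-map row order (see
#'   [map_calpha_coords()]).
#' @param reference a [structure3d()] providing the reference dimer geometry.
#' @param map a `homodimer_map` labelling both TMD and NBD residues.
#' @param projection `"membrane-plane"` (default) projects both
#'   center-connecting lines onto the plane perpendicular to `normal` before
#'   measuring the angle; `"none"` measures the 3D angle.
#' @param normal membrane normal; defaults to the z axis of the (pre-oriented)
#'   input.
#' @return an object of class `spin_angle_result`: `angle` in degrees in
#'   \[0, 180), a `signed_angle` variant oriented by `normal`, the two stored
#'   mass-center lines and the projection settings.
#' @export
spin_angle <- function(frame, reference, map,
                       projection = c("membrane-plane", "none"),
                       normal = c(0, 0, 1)) {
  projection <- match.arg(projection)
  stopifnot(inherits(map, "homodimer_map"))
  ref_coords <- map_calpha_coords(reference, map)
  if (inherits(frame, "structure3d")) frame <- map_calpha_coords(frame, map)
  frame <- as.matrix(frame)
  if (nrow(frame) != nrow(map))
    .fail("frame does not cover the mapped residues", "shape")
  .spin_angle_one(frame, ref_coords, map, projection, normal)
}

#' @export
print.spin_angle_result <- function(x, ...) {
  cat(sprintf("spin angle: %.2f deg (signed %.2f), projection = %s\n",
              x$angle, x$signed_angle, x$projection))
  invisible(x)
}

# Match trajectory selection rows to homodimer-map rows (C-alphas only).
.traj_map_index <- function(traj, map) {
  sel <- traj$selection
  ins <- sel$insert %||% rep("", nrow(sel))
  skey <- paste(sel$chain, sel$resno, ins, sel$elety)
  idx <- match(paste(map$chain, map$resno, map$insert, "CA"), skey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    .fail(sprintf("trajectory selection lacks C-alpha of mapped residue %s %d",
                  map$chain[bad], map$resno[bad]), "config")
  }
  idx
}

#' Spin-angle time series over a trajectory
#'
#' @param traj a `ca_trajectory` whose selection covers the mapped C-alphas.
#' @inheritParams spin_angle
#' @return data.frame with one row per frame: `label`, `angle` (degrees in
#'   \[0, 180)) and `signed_angle` (continuous across frames, oriented by the
#'   normal).
#' @export
spin_angle_series <- function(traj, reference, map,
                              projection = c("membrane-plane", "none"),
                              normal = c(0, 0, 1)) {
  projection <- match.arg(projection)
  stopifnot(inherits(traj, "ca_trajectory"), inherits(map, "homodimer_map"))
  nf <- n_frames(traj)
  if (nf == 0)
    return(data.frame(label = numeric(0), angle = numeric(0),
                      signed_angle = numeric(0)))
  ref_coords <- map_calpha_coords(reference, map)
  idx <- .traj_map_index(traj, map)
  res <- vapply(seq_len(nf), function(i) {
    r <- .spin_angle_one(get_frame(traj, i)[idx, , drop = FALSE],
                         ref_coords, map, projection, normal)
    c(r$angle, r$signed_angle)
  }, numeric(2))
  data.frame(label = traj$labels, angle = res[1, ], signed_angle = res[2, ])
}
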