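# Pore-radius profiling of the translocation pathway (maximal inscribed
# sphere per membrane slice, HOLE-style), layer radii, d_pair / delta-d_pair
# metrics and minimal inter-residue contact distances.

# Objective for one slice: the clearance of a probe sphere centered at the
# in-plane point (cx, cy) on the slice plane z = z0, against all atoms.
# f = min_a ( |center - atom_a| - vdw_a ); maximizing f over (cx, cy) gives
# the radius of the largest sphere inscribable at this slice.
.slice_clearance <- function(cx, cy, z0, axyz, radii) {
  d <- sqrt((axyz[, 1] - cx)^2 + (axyz[, 2] - cy)^2 + (axyz[, 3] - z0)^2)
  min(d - radii)
}

# Derivative-free in-plane maximization: multi-start (previous-slice center
# plus 4 jittered starts) axial pattern search with step halving down to
# `tol` Angstrom.
.optimize_slice <- function(z0, axyz, radii, start, init_step = 1.0,
                            jitter = 0.5, tol = 0.01, max_radius = 10) {
  starts <- rbind(start,
                  start + c(jitter, 0), start - c(jitter, 0),
                  start + c(0, jitter), start - c(0, jitter))
  best <- c(NA, NA); best_f <- -Inf
  for (si in seq_len(nrow(starts))) {
    c0 <- starts[si, ]
    f0 <- .slice_clearance(c0[1], c0[2], z0, axyz, radii)
    step <- init_step
    while (step >= tol) {
      moved <- FALSE
      for (dxy in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
        cand <- c0 + dxy
        fc <- .slice_clearance(cand[1], cand[2], z0, axyz, radii)
        if (fc > f0) { c0 <- cand; f0 <- fc; moved <- TRUE }
      }
      if (!moved) step <- step / 2
      if (f0 >= max_radius) break   # escaped the protein; cap applies
    }
    if (f0 > best_f) { best_f <- f0; best <- c0 }
  }
  list(center = best, clearance = best_f)
}

#' Pore radius profile along the channel axis
#'
#' For every slice of the z grid the largest inscribed sphere is found whose
#' center is constrained to the slice plane: the radius is
#' `max over centers of min over atoms (distance - vdW radius)`, maximized by
#' a multi-start derivative-free search seeded from the previous slice's
#' center. Radii are clamped to be non-negative and capped at `max_radius`
#' (slices with no nearby atoms, or where the probe escapes the protein, are
#' reported at the cap with `capped = TRUE`, not as errors).
#'
#' @param x a [structure3d()] or an n x 3 coordinate matrix (then `radii`
#'   must be given).
#' @param radii per-atom van der Waals radii when `x` is a bare matrix.
#' @param axis channel axis (membrane normal); default z. Coordinates are
#'   rotated internally so the profile is always taken along z.
#' @param zlim Angstrom interval to profile; defaults to the atom z range.
#' @param step slice spacing in Angstrom.
#' @param seed_point starting probe center; defaults to the atom centroid.
#' @param max_radius escape cap in Angstrom (default 10).
#' @param tol in-plane search resolution (default 0.01 A).
#' @param lining_tol atoms within this clearance of the optimum are reported
#'   as lining the pore at that slice (default 0.1 A).
#' @return data.frame of class `pore_profile` with columns `z`, `radius`,
#'   `cx`, `cy`, `capped`; attribute `lining` lists per-slice lining residues.
#' @export
pore_profile <- function(x, radii = NULL, axis = c(0, 0, 1), zlim = NULL,
                         step = 1, seed_point = NULL, max_radius = 10,
                         tol = 0.01, lining_tol = 0.1) {
  if (inherits(x, "structure3d")) {
    axyz <- x$xyz
    radii <- radii %||% x$atoms$radius
    res_chain <- x$atoms$chain; res_no <- x$atoms$resno
  } else {
    axyz <- as.matrix(x)
    if (is.null(radii)) .fail("radii required for bare coordinates", "config")
    res_chain <- rep("", nrow(axyz)); res_no <- seq_len(nrow(axyz))
  }
  .assert_coords(axyz, "atom coordinates")
  if (length(radii) != nrow(axyz))
    .fail("radius count differs from atom count", "shape")
  if (!is.numeric(step) || step <= 0) .fail("step must be positive", "config")
  axis <- axis / .vnorm(axis)
  if (max(abs(axis - c(0, 0, 1))) > 1e-12) {
    # rotate so that the requested axis becomes z
    v <- .cross3(axis, c(0, 0, 1))
    if (.vnorm(v) < 1e-12) R <- diag(c(1, -1, -1))  # axis = -z
    else R <- .rot_about(v, acos(max(-1, min(1, axis[3]))))
    axyz <- axyz %*% t(R)
    if (!is.null(seed_point)) seed_point <- as.numeric(R %*% seed_point)
  }
  zlim <- zlim %||% range(axyz[, 3])
  zgrid <- seq(zlim[1], zlim[2], by = step)
  if (length(zgrid) == 0) .fail("empty z grid", "config")
  center <- if (!is.null(seed_point)) seed_point[1:2] else
    colMeans(axyz)[1:2]
  out <- data.frame(z = zgrid, radius = NA_real_, cx = NA_real_,
                    cy = NA_real_, capped = FALSE)
  lining <- vector("list", length(zgrid))
  reach <- max(radii) + max_radius + 2 * step
  for (k in seq_along(zgrid)) {
    z0 <- zgrid[k]
    near <- abs(axyz[, 3] - z0) < reach
    if (!any(near)) {
      out$radius[k] <- max_radius; out$capped[k] <- TRUE
      out$cx[k] <- center[1]; out$cy[k] <- center[2]
      next
    }
    opt <- .optimize_slice(z0, axyz[near, , drop = FALSE], radii[near],
                           center, tol = tol, max_radius = max_radius)
    center <- opt$center                     # seed for the next slice
    capped <- opt$clearance >= max_radius
    out$radius[k] <- min(max(opt$clearance, 0), max_radius)
    out$cx[k] <- opt$center[1]; out$cy[k] <- opt$center[2]
    out$capped[k] <- capped
    if (!capped) {
      d <- sqrt((axyz[near, 1] - opt$center[1])^2 +
                (axyz[near, 2] - opt$center[2])^2 +
                (axyz[near, 3] - z0)^2) - radii[near]
      hit <- which(d <= opt$clearance + lining_tol)
      lin <- unique(data.frame(chain = res_chain[near][hit],
                               resno = res_no[near][hit],
                               stringsAsFactors = FALSE))
      lining[[k]] <- lin[order(lin$chain, lin$resno), , drop = FALSE]
    }
  }
  structure(out, class = c("pore_profile", "data.frame"),
            lining = lining, step = step, max_radius = max_radius)
}

#' Define a channel layer
#'
#' A layer is a z slab of the channel, either given explicitly by its center
#' or anchored at a residue: the window is then centered at the mean z of the
#' two partner C-alpha atoms of that residue in a reference frame.
#'
#' @param name display name (e.g. `"I164 layer"`).
#' @param center explicit window center in Angstrom (optional).
#' @param anchor_resno,anchor_chain anchor residue when `center` is absent.
#' @param half_width window half-width in Angstrom (default 2).
#' @return an object of class `layer_definition`.
#' @export
layer_definition <- function(name, center = NULL, anchor_resno = NULL,
                             anchor_chain = NULL, half_width = 2) {
  if (is.null(center) && is.null(anchor_resno))
    .fail("a layer needs either a center or an anchor residue", "config")
  if (half_width <= 0) .fail("window half-width must be positive", "config")
  structure(list(name = name, center = center, anchor_resno = anchor_resno,
                 anchor_chain = anchor_chain, half_width = half_width),
            class = "layer_definition")
}

.layer_window <- function(layer, map = NULL, reference = NULL) {
  center <- layer$center
  if (is.null(center)) {
    if (is.null(map) || is.null(reference))
      .fail(sprintf("layer '%s' is residue-anchored; a map and reference are required",
                    layer$name), "config")
    row <- which(map$resno == layer$anchor_resno &
                 (is.null(layer$anchor_chain) |
                    map$chain == (layer$anchor_chain %||% map$chain)))
    if (length(row) == 0)
      .fail(sprintf("anchor residue %s not in map", layer$anchor_resno),
            "config")
    r1 <- row[1]
    pidx <- .map_partner_index(map)
    coords <- map_calpha_coords(reference, map)
    center <- mean(coords[c(r1, pidx[r1]), 3])
  }
  c(center - layer$half_width, center + layer$half_width)
}

#' Layer radius along a trajectory
#'
#' Per frame, the minimum pore-profile radius within the layer's z window.
#'
#' @param traj a `ca_trajectory` (radii taken from the selection).
#' @param layer a [layer_definition()].
#' @param map,reference needed to resolve residue-anchored layers.
#' @param step slice spacing within the window (default 0.5 A).
#' @param ... further arguments passed to [pore_profile()].
#' @return data.frame with columns `label` and `radius` (Angstrom).
#' @export
layer_radius_series <- function(traj, layer, map = NULL, reference = NULL,
                                step = 0.5, ...) {
  stopifnot(inherits(traj, "ca_trajectory"),
            inherits(layer, "layer_definition"))
  win <- .layer_window(layer, map, reference)
  radii <- traj$selection$radius
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    zr <- range(fr[, 3])
    if (win[2] < zr[1] || win[1] > zr[2])
      .fail(sprintf("layer '%s' window [%g, %g] lies outside the profiled z range [%g, %g]",
                    layer$name, win[1], win[2], zr[1], zr[2]), "config")
    prof <- pore_profile(fr, radii = radii, zlim = win, step = step, ...)
    min(prof$radius)
  }, numeric(1))
  data.frame(label = traj$labels, radius = vals)
}

#' Distance between symmetry-equivalent C-alpha atoms along a trajectory
#'
#' d_pair of a residue is the Euclidean distance between its C-alpha and the
#' C-alpha of its symmetry partner in the opposite half; no superposition is
#' involved.
#'
#' @param traj a `ca_trajectory`.
#' @param resno residue number.
#' @param chain chain of the residue.
#' @param map a `homodimer_map`.
#' @return data.frame of class `dpair_series` with columns `label`, `d_pair`.
#' @export
dpair_series <- function(traj, resno, chain, map) {
  stopifnot(inherits(traj, "ca_trajectory"), inherits(map, "homodimer_map"))
  row <- which(map$chain == chain & map$resno == resno)
  if (length(row) == 0)
    .fail(sprintf("residue %s %d is not in the homodimer map", chain, resno),
          "config")
  row <- row[1]
  prow <- .map_partner_index(map)[row]
  sel <- traj$selection
  ins <- sel$insert %||% rep("", nrow(sel))
  skey <- paste(sel$chain, sel$resno, ins, sel$elety)
  idx <- match(paste(map$chain[c(row, prow)], map$resno[c(row, prow)],
                     map$insert[c(row, prow)], "CA"), skey)
  if (anyNA(idx))
    .fail(sprintf("trajectory lacks C-alpha atoms of residue %s %d or its partner",
                  chain, resno), "config")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    .vnorm(fr[idx[1], ] - fr[idx[2], ])
  }, numeric(1))
  structure(data.frame(label = traj$labels, d_pair = vals),
            class = c("dpair_series", "data.frame"),
            residue = sprintf("%s %d", chain, resno))
}

.dpair_static <- function(s, map, chain, resno, pidx) {
  row <- which(map$chain == chain & map$resno == resno)
  if (length(row) == 0) return(NA_real_)
  row <- row[1]
  coords <- tryCatch(map_calpha_coords(s, map), error = function(e) NULL)
  if (is.null(coords)) return(NA_real_)
  .vnorm(coords[row, ] - coords[pidx[row], ])
}

#' d_pair differences between two end-state structures
#'
#' Per residue, `|d_pair(sB) - d_pair(sA)|`. Residues absent from either
#' structure are reported as missing (`NA`), not as errors.
#'
#' @param sA,sB two [structure3d()] end states.
#' @param map a `homodimer_map` valid for both.
#' @param residues data.frame with columns `chain` and `resno`; defaults to
#'   all half-1 residues of the map.
#' @return data.frame with `chain`, `resno`, `d_pair_A`, `d_pair_B`, `delta`;
#'   attribute `missing` lists residues lacking coordinates.
#' @export
delta_dpair <- function(sA, sB, map, residues = NULL) {
  stopifnot(inherits(map, "homodimer_map"))
  if (is.null(residues))
    residues <- unique(map[map$half == 1, c("chain", "resno")])
  pidx <- .map_partner_index(map)
  cA <- map_calpha_coords(sA, map)
  cB <- map_calpha_coords(sB, map)
  key <- paste(map$chain, map$resno)
  row <- match(paste(residues$chain, residues$resno), key)
  dp <- function(coords, r) {
    if (is.na(r)) return(NA_real_)
    .vnorm(coords[r, ] - coords[pidx[r], ])
  }
  dA <- vapply(row, function(r) dp(cA, r), numeric(1))
  dB <- vapply(row, function(r) dp(cB, r), numeric(1))
  out <- data.frame(chain = residues$chain, resno = residues$resno,
                    d_pair_A = dA, d_pair_B = dB, delta = abs(dB - dA),
                    stringsAsFactors = FALSE)
  structure(out, missing = out[is.na(out$delta), c("chain", "resno")])
}

#' Minimal heavy-atom distance between two residues along a trajectory
#'
#' Per frame, the minimum over all heavy-atom pairs (one atom from each
#' residue) of the interatomic distance. Hydrogens are excluded.
#'
#' @param traj a trajectory whose selection carries the residues' heavy atoms
#'   (an all-atom trajectory for sidechain contacts).
#' @param chain_a,resno_a,chain_b,resno_b the two residues.
#' @return data.frame with columns `label` and `distance` (Angstrom).
#' @export
min_residue_distance_series <- function(traj, chain_a, resno_a,
                                        chain_b, resno_b) {
  stopifnot(inherits(traj, "ca_trajectory"))
  sel <- traj$selection
  elesy <- .element_from_name(sel$elety)
  heavy <- toupper(elesy) != "H"
  ia <- which(sel$chain == chain_a & sel$resno == resno_a & heavy)
  ib <- which(sel$chain == chain_b & sel$resno == resno_b & heavy)
  if (length(ia) == 0 || length(ib) == 0)
    .fail("selection lacks the residues' heavy atoms; provide an all-atom trajectory",
          "config")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    A <- fr[ia, , drop = FALSE]; B <- fr[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  data.frame(label = traj$labels, distance = vals)
}
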