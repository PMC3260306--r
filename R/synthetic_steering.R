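# Synthetic-data generator: a coarse-grained elastic-network toy homodimer
# evolved under a targeted-MD steering potential. Produces labelled
# trajectories (schedule tracking, injected asymmetry, constructed gate
# motions) with known ground truth for every analysis module.
#
# The two-gate-channel preset emulates, qualitatively, an ABC-importer TMD
# channel: stacked bead rings form a pore that is wide at the periplasmic
# (high-z) end and narrow at the cytoplasmic (low-z) end in state O, and the
# reverse in state I. The two gate rings additionally twist azimuthally
# between the end states, so that a near-straight steered path passes through
# a genuinely double-occluded intermediate — the qualitative signature the
# analysis stack must be able to detect. Two further chains play the role of
# the NBD dimer; between the end states the NBD dimer spins by 8 degrees
# about z and separates slightly. Both end states are exactly two-fold
# symmetric about z by construction.

.toy_rings <- 6L
.toy_ring_z <- c(0, 5, 10, 15, 20, 25)
.toy_radii_O <- c(3, 5, 7, 7, 5.5, 6)
.toy_radii_I <- c(6, 5, 7, 7, 5.5, 3)
.toy_gate_twist <- 120 * pi / 180   # azimuthal gate twist between end states
.toy_nbd_center <- c(7, 0, -6)
.toy_nbd_ball <- 3.5
.toy_nbd_spin <- 8 * pi / 180       # NBD dimer spin between end states
.toy_nbd_shift <- 1.5               # NBD radial separation increase in I

# Half-ring bead angles for one chain: p beads centered on +x.
.half_ring_angles <- function(p) (-90 + 180 * (seq_len(p) - 0.5) / p) * pi / 180

# Deterministic ball of n beads (spherical spiral), centered at origin.
.bead_ball <- function(n, radius) {
  m <- seq_len(n)
  h <- if (n > 1) -1 + 2 * (m - 1) / (n - 1) else 0
  theta <- acos(pmax(-1, pmin(1, h)))
  phi <- m * pi * (3 - sqrt(5))
  r <- radius * (m / n)^(1 / 3)
  cbind(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi),
        r * cos(theta))
}

.rz <- function(theta) .rot_about(c(0, 0, 1), theta)

# Connectivity of a cutoff graph by breadth-first search.
.connected <- function(xyz, cutoff) {
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz)) < cutoff
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(dm[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Build a coarse-grained toy homodimer
#'
#' Constructs a four-chain bead model: chains A and B (TMD role) form the
#' channel, chains C and D (NBD role) sit below it. Both end states are
#' exactly related by a 180-degree rotation about z between halves, so
#' C_asymm is zero to machine precision in either state. The
#' `two-gate-channel` preset gives state O a wide high-z aperture and a
#' narrow low-z aperture and state I the reverse; `generic` keeps a uniform
#' cylinder and only moves the NBD dimer.
#'
#' @param beads_per_chain beads per chain (>= 10).
#' @param preset `"two-gate-channel"` (default) or `"generic"`.
#' @param cutoff elastic-network contact cutoff in Angstrom.
#' @param seed integer seed for the (small) deterministic bead jitter.
#' @return an object of class `toy_homodimer` holding the atom table, both
#'   end-state coordinate sets, the contact cutoff and the homodimer map.
#' @export
build_toy_homodimer <- function(beads_per_chain = 30,
                                preset = c("two-gate-channel", "generic"),
                                cutoff = 7, seed = 1) {
  preset <- match.arg(preset)
  n <- as.integer(beads_per_chain)
  if (n < 10) .fail("beads_per_chain must be at least 10", "config")
  sizes <- rep(n %/% .toy_rings, .toy_rings)
  if (n %% .toy_rings > 0)
    sizes[seq_len(n %% .toy_rings)] <- sizes[seq_len(n %% .toy_rings)] + 1
  r_O <- .toy_radii_O; r_I <- .toy_radii_I
  if (preset == "generic") { r_O <- rep(6, .toy_rings); r_I <- r_O }
  twist <- if (preset == "two-gate-channel") .toy_gate_twist else 0
  chainA <- function(radii, gate_twist) {
    do.call(rbind, lapply(seq_len(.toy_rings), function(k) {
      th <- .half_ring_angles(sizes[k]) +
        if (k %in% c(1L, .toy_rings)) gate_twist else 0
      cbind(radii[k] * cos(th), radii[k] * sin(th), .toy_ring_z[k])
    }))
  }
  A_O <- chainA(r_O, 0)
  A_I <- chainA(r_I, twist)
  # NBD-role chain C: rigid bead ball, identical internal geometry in both
  # states; the dimer spins and separates between states.
  ball <- .with_seed(seed, .bead_ball(n, .toy_nbd_ball) +
                       matrix(stats::rnorm(3 * n, sd = 0.2), n, 3))
  C_O <- sweep(ball, 2, .toy_nbd_center, `+`)
  shift_dir <- c(.toy_nbd_center[1:2] / .vnorm(.toy_nbd_center[1:2]), 0)
  C_I <- sweep(C_O, 2, .toy_nbd_shift * shift_dir, `+`) %*% t(.rz(.toy_nbd_spin))
  flip <- .rz(pi)
  state <- function(A, C) rbind(A, A %*% t(flip), C, C %*% t(flip))
  xyz_O <- state(A_O, C_O)
  xyz_I <- state(A_I, C_I)
  atoms <- data.frame(chain = rep(c("A", "B", "C", "D"), each = n),
                      resno = rep(seq_len(n), 4),
                      insert = "", resid = "GLY", elety = "CA", elesy = "C",
                      radius = 1.7, stringsAsFactors = FALSE)
  for (st in list(O = xyz_O, I = xyz_I))
    if (!.connected(st, cutoff))
      .fail(sprintf("contact cutoff %g A leaves the network disconnected",
                    cutoff), "connectivity")
  s <- structure3d(atoms, xyz_O)
  map <- suppressMessages(build_homodimer_map(
    s, half1 = c("A", "C"), half2 = c("B", "D"),
    regions = c(A = "TMD", B = "TMD", C = "NBD", D = "NBD")))
  structure(list(atoms = atoms, state_O = xyz_O, state_I = xyz_I,
                 cutoff = cutoff, map = map, preset = preset,
                 beads_per_chain = n, seed = as.integer(seed)),
            class = "toy_homodimer")
}

#' @export
print.toy_homodimer <- function(x, ...) {
  cat(sprintf("toy_homodimer: %d beads (%d per chain), preset '%s', cutoff %g A\n",
              nrow(x$atoms), x$beads_per_chain, x$preset, x$cutoff))
  invisible(x)
}

#' View a toy end state as a structure
#'
#' @param dimer a `toy_homodimer`.
#' @param state `"O"` or `"I"`.
#' @return a [structure3d()].
#' @export
toy_structure <- function(dimer, state = c("O", "I")) {
  state <- match.arg(state)
  structure3d(dimer$atoms,
              if (state == "O") dimer$state_O else dimer$state_I)
}

#' Targeted-MD steering schedule
#'
#' Holds the preset target r.m.s.d.* profile (linear and non-increasing from
#' `initial` to `final` over `steps` steps), the force constant `k` and the
#' targeted atom count `n_atoms`.
#'
#' @param initial,final r.m.s.d.* at step 0 and at the last step (Angstrom);
#'   must be non-increasing.
#' @param steps number of integration steps (>= 1).
#' @param k force constant, in kcal/mol/A^2 by convention (default 5550;
#'   zero gives an unsteered run).
#' @param n_atoms number of targeted atoms N (>= 3).
#' @return an object of class `steering_schedule`.
#' @export
steering_schedule <- function(initial, final = 0, steps, k = 5550, n_atoms) {
  if (final > initial) .fail("r.m.s.d.* must be non-increasing", "config")
  if (k < 0) .fail("force constant k must be non-negative", "config")
  if (n_atoms < 3) .fail("at least 3 targeted atoms are required", "config")
  if (steps < 1) .fail("steps must be >= 1", "config")
  structure(list(initial = initial, final = final, steps = as.integer(steps),
                 k = k, n_atoms = as.integer(n_atoms)),
            class = "steering_schedule")
}

#' Preset r.m.s.d.* at a schedule step
#'
#' @param schedule a [steering_schedule()].
#' @param step step index in `0:steps`.
#' @return r.m.s.d.* in Angstrom.
#' @export
rmsd_star <- function(schedule, step) {
  stopifnot(inherits(schedule, "steering_schedule"))
  if (any(step < 0 | step > schedule$steps))
    .fail(sprintf("step outside schedule range 0..%d", schedule$steps),
          "range")
  schedule$initial + (schedule$final - schedule$initial) *
    step / schedule$steps
}

#' Targeted-MD steering energy and forces
#'
#' The steering potential is `E = k/(2N) * (rmsd(t) - rmsd*(t))^2`, with
#' `rmsd(t)` the best-fit RMSD of the frame onto the target. Forces are the
#' negative gradient with respect to the bead positions, computed after
#' rotating the target into the frame (the gradient through the optimal
#' rotation vanishes at the optimum, so this matches finite differences).
#' Forces sum to zero and vanish when `rmsd(t) = rmsd*(t)`.
#'
#' @param frame,target n x 3 coordinate matrices with n equal to the
#'   schedule's targeted atom count.
#' @param schedule a [steering_schedule()].
#' @param step step index in `0:steps`.
#' @return list with `energy`, `forces` (n x 3), `rmsd` and `rmsd_star`.
#' @export
steering_energy <- function(frame, target, schedule, step) {
  stopifnot(inherits(schedule, "steering_schedule"))
  frame <- as.matrix(frame); target <- as.matrix(target)
  .assert_coords(frame, "frame"); .assert_coords(target, "target")
  if (nrow(frame) != nrow(target) || nrow(frame) != schedule$n_atoms)
    .fail("frame, target and schedule N are inconsistent", "shape")
  rs <- rmsd_star(schedule, step)
  fit <- superpose(target, frame)
  y <- apply_transform(fit, target)
  r <- fit$rmsd
  N <- schedule$n_atoms; k <- schedule$k
  energy <- k / (2 * N) * (r - rs)^2
  forces <- if (r < 1e-12) matrix(0, N, 3) else
    -(k / N) * (r - rs) * (frame - y) / (N * r)
  list(energy = energy, forces = forces, rmsd = r, rmsd_star = rs)
}

# Elastic-network edges (and rest lengths) of a coordinate set.
.network_edges <- function(xyz, cutoff) {
  dm <- as.matrix(stats::dist(xyz))
  dm[lower.tri(dm, diag = TRUE)] <- Inf
  hit <- which(dm < cutoff, arr.ind = TRUE)
  list(i = hit[, 1], j = hit[, 2], L0 = dm[hit])
}

.network_forces <- function(xyz, edges, spring_k) {
  dvec <- xyz[edges$i, , drop = FALSE] - xyz[edges$j, , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  coef <- -spring_k * (len - edges$L0) / pmax(len, 1e-12)
  fi <- dvec * coef
  F <- matrix(0, nrow(xyz), 3)
  agg <- rowsum(rbind(fi, -fi), group = c(edges$i, edges$j))
  F[as.integer(rownames(agg)), ] <- agg
  F
}

#' Run a steered toy transition
#'
#' Evolves the toy homodimer from one end state toward the other by
#' overdamped (position) Langevin dynamics on elastic-network plus steering
#' forces. The elastic network (rest lengths from the start state, single
#' cutoff) provides local structure; the targeted-MD potential pulls the
#' best-fit RMSD to the target down the preset schedule. Same seed and
#' settings give a bitwise-identical trajectory; with `k = 0` in the schedule
#' the steering term contributes exactly zero force and the run is bitwise
#' identical to an unsteered one.
#'
#' @param dimer a [build_toy_homodimer()] object.
#' @param from_state start state, `"O"` or `"I"`.
#' @param target_state target state; defaults to the other end state. Setting
#'   it equal to `from_state` (with a zero schedule) gives a null-steering
#'   run that fluctuates about the start.
#' @param schedule a [steering_schedule()]; default: linear from the best-fit
#'   inter-state RMSD to 0 over 1500 steps with k = 5550. An initial r.m.s.d.*
#'   above the inter-state RMSD is clamped with a warning.
#' @param temperature dimensionless temperature factor (thermal noise
#'   variance scale; default 5e-4).
#' @param friction friction coefficient (1/time, reduced units).
#' @param dt integration step (reduced units).
#' @param spring_k elastic-network spring constant (energy/A^2).
#' @param seed integer seed.
#' @param save_every save a frame every this many steps (frame 0 and the
#'   final step are always saved).
#' @return an object of class `steered_trajectory` (also a `ca_trajectory`):
#'   frames over the bead selection, labels = step indices, plus a
#'   `diagnostics` data.frame (`step`, `rmsd`, `rmsd_star`, `energy`), the
#'   schedule and the seed.
#' @export
run_steered <- function(dimer, from_state = c("O", "I"), schedule = NULL,
                        target_state = NULL, temperature = 5e-4,
                        friction = 1, dt = 0.2, spring_k = 0.0025, seed = 1,
                        save_every = 15) {
  stopifnot(inherits(dimer, "toy_homodimer"))
  from_state <- match.arg(from_state)
  target_state <- match.arg(target_state %||% setdiff(c("O", "I"), from_state),
                            c("O", "I"))
  x <- if (from_state == "O") dimer$state_O else dimer$state_I
  target <- if (target_state == "O") dimer$state_O else dimer$state_I
  n <- nrow(x)
  r0 <- rmsd_to(x, target)
  if (is.null(schedule))
    schedule <- steering_schedule(r0, 0, steps = 1500, k = 5550, n_atoms = n)
  if (schedule$n_atoms != n)
    .fail("schedule targeted-atom count differs from bead count", "config")
  if (schedule$initial > r0 + 1e-9) {
    warning(sprintf(
      "initial r.m.s.d.* (%.3f A) exceeds the inter-state best-fit RMSD (%.3f A); clamping",
      schedule$initial, r0))
    schedule <- steering_schedule(r0, min(schedule$final, r0),
                                  schedule$steps, schedule$k, n)
  }
  edges <- .network_edges(x, dimer$cutoff)
  sigma <- sqrt(2 * temperature * dt / friction)
  saved <- list(); diag_rows <- list()
  record <- function(step, st) {
    saved[[length(saved) + 1]] <<- x
    diag_rows[[length(diag_rows) + 1]] <<-
      data.frame(step = step, rmsd = st$rmsd, rmsd_star = st$rmsd_star,
                 energy = st$energy)
  }
  .with_seed(seed, {
    st0 <- steering_energy(x, target, schedule, 0)
    record(0L, st0)
    labels <- 0L
    for (t in seq_len(schedule$steps)) {
      st <- steering_energy(x, target, schedule, t)
      if (st$rmsd > 2 * max(r0, 0.5))
        .fail(sprintf(
          "steered run diverged at step %d (rmsd %.2f A); reduce dt or increase friction",
          t, st$rmsd), "instability")
      F <- .network_forces(x, edges, spring_k) + st$forces
      noise <- matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
      x <- x + (dt / friction) * F + noise
      if (t %% save_every == 0 || t == schedule$steps) {
        record(t, steering_energy(x, target, schedule, t))
        labels <- c(labels, t)
      }
    }
    sel <- data.frame(chain = dimer$atoms$chain, resno = dimer$atoms$resno,
                      insert = dimer$atoms$insert, resid = dimer$atoms$resid,
                      elety = dimer$atoms$elety, radius = dimer$atoms$radius,
                      stringsAsFactors = FALSE)
    traj <- trajectory(saved, sel, labels = labels)
    traj$diagnostics <- do.call(rbind, diag_rows)
    traj$schedule <- schedule
    traj$from_state <- from_state
    traj$target_state <- target_state
    traj$seed <- as.integer(seed)
    class(traj) <- c("steered_trajectory", class(traj))
    traj
  })
}

#' @export
print.steered_trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "steered_trajectory: %s -> %s, %d frames, final rmsd %.3f A (rmsd* %.3f A)\n",
    x$from_state, x$target_state %||% setdiff(c("O", "I"), x$from_state),
    n_frames(x),
    d$rmsd[nrow(d)], d$rmsd_star[nrow(d)]))
  invisible(x)
}

#' Inject a known asymmetric perturbation
#'
#' Displaces the named residues of one half along reproducible random
#' directions (one unit direction per residue, derived from the seed):
#' either a static offset applied to every frame, or an offset growing
#' linearly from zero to `amplitude` across frames. All other coordinates are
#' untouched; amplitude 0 returns the input unchanged.
#'
#' @param x a `ca_trajectory` or a [structure3d()].
#' @param map a `homodimer_map`.
#' @param residues residue numbers to perturb.
#' @param half which half (1 or 2) the residues belong to.
#' @param amplitude displacement in Angstrom (>= 0).
#' @param mode `"static"` or `"growing"`.
#' @param seed integer seed for the displacement directions.
#' @return a perturbed copy of `x`, same class.
#' @export
inject_asymmetry <- function(x, map, residues, half, amplitude,
                             mode = c("static", "growing"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "homodimer_map"))
  if (amplitude < 0) .fail("amplitude must be non-negative", "config")
  rows <- map[map$half == half & map$resno %in% residues, , drop = FALSE]
  missing <- setdiff(residues, rows$resno)
  if (length(missing) > 0)
    .fail(sprintf("residue(s) %s not found in half %d of the map",
                  paste(missing, collapse = ","), half), "config")
  dirs <- .with_seed(seed, {
    m <- matrix(stats::rnorm(3 * nrow(rows)), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  sel_atoms <- if (inherits(x, "ca_trajectory")) x$selection else x$atoms
  akey <- paste(sel_atoms$chain, sel_atoms$resno)
  tgt <- match(paste(rows$chain, rows$resno), akey)
  if (anyNA(tgt))
    .fail("perturbed residue absent from the coordinate set", "consistency")
  if (inherits(x, "ca_trajectory")) {
    nf <- n_frames(x)
    for (f in seq_len(nf)) {
      scale <- if (mode == "growing" && nf > 1) (f - 1) / (nf - 1) else 1
      x$coords[tgt, , f] <- x$coords[tgt, , f] + amplitude * scale * dirs
    }
  } else {
    x$xyz[tgt, ] <- x$xyz[tgt, ] + amplitude * dirs
  }
  x
}
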