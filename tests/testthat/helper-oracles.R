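# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package code paths.

# Horn quaternion characteristic-polynomial RMSD: the largest eigenvalue of
# the 4x4 key matrix gives the optimal superposition score. Independent of
# the SVD-based Kabsch implementation.
quat_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(X, Y)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(X)
  sqrt(max(0, (sum(X^2) + sum(Y^2) - 2 * lam) / n))
}

# Brute-force O(n^2) residue-pair scan under a strict cutoff.
brute_pairs <- function(coords, d0) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d < d0) out[[length(out) + 1]] <- c(i, j, d)
  }
  do.call(rbind, out)
}

# Exhaustive in-plane grid search for the maximal inscribed sphere radius of
# one slice (independent of the pattern-search optimizer).
grid_slice_radius <- function(z0, xyz, radii, xlim, ylim, step = 0.05) {
  gx <- seq(xlim[1], xlim[2], by = step)
  gy <- seq(ylim[1], ylim[2], by = step)
  best <- -Inf
  for (cx in gx) {
    dx2 <- (xyz[, 1] - cx)^2 + (xyz[, 3] - z0)^2
    for (cy in gy) {
      f <- min(sqrt(dx2 + (xyz[, 2] - cy)^2) - radii)
      if (f > best) best <- f
    }
  }
  best
}

# Random proper rotation + translation.
rand_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- dimergate:::.rot_about(ax, runif(1, 0, 2 * pi))
  list(R = R, t = rnorm(3, sd = 10))
}
apply_rigid <- function(xyz, rt) sweep(xyz %*% t(rt$R), 2, rt$t, `+`)

# Minimal in-memory structure: one CA bead per residue at the given coords.
make_ca_structure <- function(chains, resnos, coords, radius = 1.7) {
  atoms <- data.frame(chain = chains, resno = resnos, insert = "",
                      resid = "GLY", elety = "CA", elesy = "C",
                      radius = radius, stringsAsFactors = FALSE)
  structure3d(atoms, coords)
}

# Exactly C2-symmetric two-chain structure: chain B is chain A rotated 180
# degrees about z.
make_symmetric_pair <- function(coordsA, chainA = "A", chainB = "B") {
  flip <- dimergate:::.rz(pi)
  n <- nrow(coordsA)
  make_ca_structure(rep(c(chainA, chainB), each = n),
                    rep(seq_len(n), 2),
                    rbind(coordsA, coordsA %*% t(flip)))
}

# 11-bead collinear chain pair: exactly 10 nearest-neighbour pairs per half
# at 7 A spacing (cutoff 8 A selects only (i, i+1)).
make_chain11 <- function() {
  xs <- 30 + 7 * (0:10)
  make_symmetric_pair(cbind(xs, 1, 0))
}

# Selection metadata matching homodimer-map row order, for building
# trajectories directly from map-ordered coordinate frames.
map_sel <- function(map) {
  data.frame(chain = map$chain, resno = map$resno, insert = map$insert,
             resid = "GLY", elety = "CA", radius = 1.7,
             stringsAsFactors = FALSE)
}

# Map for a symmetric pair structure (both chains TMD by default).
pair_map <- function(s, regions = c(A = "TMD", B = "TMD")) {
  suppressMessages(build_homodimer_map(s, "A", "B", regions))
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = paste0("dimergate_", class, "_error"))
}
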