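# Pore profiling, layer radii, d_pair metrics and contact distances.

ring_coords <- function(n, radius, z, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(th), radius * sin(th), z)
}

test_that("an analytic ring gives pore radius ring - vdW", {
  xyz <- ring_coords(12, 6, 0)
  prof <- pore_profile(xyz, radii = rep(1.7, 12), zlim = c(0, 0), step = 1)
  expect_equal(prof$radius[1], 4.3, tolerance = 0.05)
  expect_equal(c(prof$cx[1], prof$cy[1]), c(0, 0), tolerance = 0.05)
})

test_that("a stacked-ring cylinder has a flat profile", {
  xyz <- do.call(rbind, lapply(0:10, function(z) ring_coords(12, 6, z)))
  prof <- pore_profile(xyz, radii = rep(1.7, nrow(xyz)), zlim = c(0, 10),
                       step = 1)
  expect_lt(diff(range(prof$radius)), 0.05)
  expect_equal(mean(prof$radius), 4.3, tolerance = 0.05)
})

test_that("slice radii match an exhaustive 0.05 A grid search", {
  set.seed(51)
  # random cloud with a guaranteed channel: atoms kept >= 2.5 A from the axis
  pts <- matrix(runif(900, -8, 8), ncol = 3)
  pts[, 3] <- pts[, 3] * 0.5 + 2
  keep <- sqrt(pts[, 1]^2 + pts[, 2]^2) > 2.5
  xyz <- pts[keep, , drop = FALSE]
  radii <- rep(1.2, nrow(xyz))
  prof <- pore_profile(xyz, radii = radii, zlim = c(1, 3), step = 1,
                       seed_point = c(0, 0, 0), max_radius = 10)
  for (k in seq_along(prof$z)) {
    g <- grid_slice_radius(prof$z[k], xyz, radii, c(-3, 3), c(-3, 3),
                           step = 0.05)
    expect_equal(prof$radius[k], max(0, min(g, 10)), tolerance = 0.05)
  }
})

test_that("removing an atom never shrinks the optimal slice radius", {
  set.seed(52)
  xyz <- ring_coords(10, 5, 0) + matrix(rnorm(30, sd = 0.2), 10, 3)
  radii <- rep(1.5, 10)
  r_all <- pore_profile(xyz, radii = radii, zlim = c(0, 0), step = 1)$radius
  for (drop in 1:10) {
    r_less <- pore_profile(xyz[-drop, ], radii = radii[-drop],
                           zlim = c(0, 0), step = 1)$radius
    expect_gte(r_less, r_all - 0.05)
  }
})

test_that("the profile is invariant when structure and axis rotate together", {
  set.seed(53)
  xyz <- do.call(rbind, lapply(0:5, function(z) ring_coords(10, 5.5, z)))
  radii <- rep(1.7, nrow(xyz))
  p0 <- pore_profile(xyz, radii = radii, zlim = c(1, 4), step = 1)
  for (rep in 1:4) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- dimergate:::.rot_about(ax, runif(1, 0, 2 * pi))
    p1 <- pore_profile(xyz %*% t(R), radii = radii,
                       axis = as.numeric(R %*% c(0, 0, 1)),
                       zlim = c(1, 4), step = 1)
    expect_equal(p1$radius, p0$radius, tolerance = 0.05)
  }
})

test_that("empty slices are capped and flagged, not fatal", {
  xyz <- ring_coords(12, 6, 0)
  prof <- pore_profile(xyz, radii = rep(1.7, 12), zlim = c(0, 40), step = 40)
  expect_true(prof$capped[2])
  expect_equal(prof$radius[2], 10)
})

test_that("layer radius series tracks a closing gate", {
  sel <- data.frame(chain = "A", resno = 1:12, insert = "", resid = "GLY",
                    elety = "CA", radius = 1.7, stringsAsFactors = FALSE)
  static <- lapply(1:4, function(k) ring_coords(12, 6, 0))
  tr_static <- trajectory(static, sel)
  layer <- layer_definition("gate", center = 0, half_width = 1)
  ser0 <- layer_radius_series(tr_static, layer, step = 0.5)
  expect_lt(diff(range(ser0$radius)), 1e-9)
  # ring shrinking 6 -> 3 A across frames: series decreases by 3 A
  shrink <- lapply(seq(6, 3, length.out = 7), function(r)
    ring_coords(12, r, 0))
  ser <- layer_radius_series(trajectory(shrink, sel), layer, step = 0.5)
  expect_true(all(diff(ser$radius) < 0))
  expect_equal(ser$radius[1] - ser$radius[7], 3, tolerance = 0.1)
  # window outside the profiled range is a configuration error
  far <- layer_definition("far", center = 100, half_width = 1)
  expect_error_class(layer_radius_series(tr_static, far, step = 0.5),
                     "config")
})

test_that("d_pair series equals the raw inter-partner distance", {
  # symmetric structure: beads at in-plane distance 10 A either side
  s <- make_symmetric_pair(cbind(10, 0.0, 1:12))
  map <- pair_map(s)
  sel <- s$atoms[s$atoms$elety == "CA", ]
  base <- map_calpha_coords(s, map)
  ser <- dpair_series(trajectory(list(base), sel), 5, "A", map)
  expect_equal(ser$d_pair, 20, tolerance = 1e-9)
  # translating half 2 by +1 A per frame along the separation direction
  frames <- lapply(0:4, function(k) {
    fr <- base
    fr[map$half == 2, 1] <- fr[map$half == 2, 1] - k
    fr
  })
  ser2 <- dpair_series(trajectory(frames, sel), 5, "A", map)
  expect_equal(diff(ser2$d_pair), rep(1, 4), tolerance = 1e-9)
  # brute-force recomputation from raw coordinates
  row <- which(map$chain == "A" & map$resno == 5)
  prow <- which(map$chain == "B" & map$resno == 5)
  for (k in 1:5)
    expect_equal(ser2$d_pair[k],
                 sqrt(sum((frames[[k]][row, ] - frames[[k]][prow, ])^2)),
                 tolerance = 1e-12)
  expect_error_class(dpair_series(trajectory(list(base), sel), 99, "A", map),
                     "config")
})

test_that("delta d_pair is zero for identical states and exact when built", {
  set.seed(54)
  n <- 14
  coords <- cbind(8 + runif(n, 0, 2), 0, 1:n)  # y = 0: d_pair = 2x exactly
  sA <- make_symmetric_pair(coords)
  map <- pair_map(sA)
  dd0 <- delta_dpair(sA, sA, map)
  expect_true(all(dd0$delta == 0))
  # push residue 7 of both halves outward so its d_pair grows by exactly 13 A
  cB <- coords
  cB[7, 1] <- cB[7, 1] + 6.5
  sB <- make_symmetric_pair(cB)
  dd <- delta_dpair(sA, sB, map)
  expect_equal(dd$delta[dd$resno == 7], 13, tolerance = 1e-9)
  expect_true(all(dd$delta[dd$resno != 7] < 1e-9))
  # random end states match per-residue brute force
  cC <- coords + matrix(rnorm(3 * n, sd = 0.5), n, 3)
  sC <- make_symmetric_pair(cC)
  dd2 <- delta_dpair(sA, sC, map)
  for (r in 1:n) {
    dA <- sqrt(sum((coords[r, ] - c(-coords[r, 1], -coords[r, 2],
                                    coords[r, 3]))^2))
    dC <- sqrt(sum((cC[r, ] - c(-cC[r, 1], -cC[r, 2], cC[r, 3]))^2))
    expect_equal(dd2$delta[dd2$resno == r], abs(dC - dA), tolerance = 1e-9)
  }
})

test_that("minimal inter-residue distances scan all heavy-atom pairs", {
  atoms <- data.frame(chain = rep(c("A", "B"), c(4, 3)),
                      resno = rep(c(90, 150), c(4, 3)),
                      insert = "", resid = "LEU",
                      elety = c("CA", "CB", "CG", "HD1", "CA", "CB", "CG"),
                      radius = 1.7, stringsAsFactors = FALSE)
  set.seed(55)
  base <- rbind(matrix(rnorm(12), 4, 3),
                matrix(rnorm(9), 3, 3) + 5)
  frames <- lapply(0:3, function(k) {
    fr <- base; fr[5:7, ] <- fr[5:7, ] + k; fr
  })
  tr <- trajectory(frames, atoms)
  ser <- min_residue_distance_series(tr, "A", 90, "B", 150)
  expect_true(all(diff(ser$distance) > 0))
  # brute force over heavy atoms only (the hydrogen is excluded)
  for (k in 1:4) {
    fr <- frames[[k]]
    d <- Inf
    for (i in 1:3) for (j in 5:7)   # atoms 1:3 heavy in residue A
      d <- min(d, sqrt(sum((fr[i, ] - fr[j, ])^2)))
    expect_equal(ser$distance[k], d, tolerance = 1e-12)
  }
  # two single-atom residues at a known separation
  at2 <- data.frame(chain = c("A", "B"), resno = c(1, 2), insert = "",
                    resid = "GLY", elety = "CA", radius = 1.7,
                    stringsAsFactors = FALSE)
  tr2 <- trajectory(list(rbind(c(0, 0, 0), c(4.2, 0, 0))), at2)
  expect_equal(min_residue_distance_series(tr2, "A", 1, "B", 2)$distance,
               4.2, tolerance = 1e-12)
  expect_error_class(min_residue_distance_series(tr2, "A", 9, "B", 2),
                     "config")
})
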