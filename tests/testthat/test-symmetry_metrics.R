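# Residue-pair selection, C_asymm, A_ij and ARP classification.

test_that("collinear beads at 0/5/10 A with d0 = 8 give pairs (1,2),(2,3)", {
  xs <- 30 + c(0, 5, 10)
  s <- make_symmetric_pair(cbind(xs, 0, 0))
  map <- pair_map(s)
  prs <- select_pairs(s, map, d0 = 8)
  half1 <- prs[prs$chain_i == "A" & prs$chain_j == "A", ]
  expect_equal(nrow(half1), 2)
  expect_equal(sort(paste(half1$resno_i, half1$resno_j)), c("1 2", "2 3"))
  # same two pairs mirrored in the other half under dedup = "none"
  expect_equal(attr(prs, "n_pair"), 4)
  prs1 <- select_pairs(s, map, d0 = 8, dedup = "symmetric")
  expect_equal(attr(prs1, "n_pair"), 2)
})

test_that("pair selection matches a brute-force all-against-all scan", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 25
    coords <- cbind(25 + cumsum(runif(n, 2, 6)), rnorm(n, sd = 3),
                    rnorm(n, sd = 3))
    s <- make_symmetric_pair(coords)
    map <- pair_map(s)
    prs <- select_pairs(s, map, d0 = 8)
    bf <- brute_pairs(map_calpha_coords(s, map), 8)
    expect_equal(attr(prs, "n_pair"), nrow(bf))
    got <- sort(paste(prs$i, prs$j))
    expect_identical(got, sort(paste(bf[, 1], bf[, 2])))
    expect_equal(sort(prs$d_ref), sort(bf[, 3]), tolerance = 1e-12)
  }
})

test_that("strict cutoff: a pair exactly at d0 is not selected", {
  s <- make_symmetric_pair(cbind(30 + c(0, 8), 0, 0))
  prs <- select_pairs(s, pair_map(s), d0 = 8)
  expect_equal(attr(prs, "n_pair"), 0)
})

test_that("an exactly symmetric dimer has zero C_asymm under both forms", {
  s <- make_chain11()
  prs <- select_pairs(s, pair_map(s), d0 = 8)
  expect_lt(casymm(s, prs, "mean-abs"), 1e-9)
  expect_lt(casymm(s, prs, "rms"), 1e-9)
})

test_that("one perturbed pair among 10 gives mean-absolute C_asymm 0.1 A", {
  s <- make_chain11()
  map <- pair_map(s)
  prs <- select_pairs(s, map, d0 = 8, dedup = "symmetric")
  expect_equal(attr(prs, "n_pair"), 10)
  # move chain A bead 1 by +1 A along x: only pair (1,2) changes, by 1.0 A
  s$xyz[1, 1] <- s$xyz[1, 1] + 1
  expect_equal(casymm(s, prs, "mean-abs"), 0.1, tolerance = 1e-9)
  expect_equal(casymm(s, prs, "rms"), sqrt(1 / 10), tolerance = 1e-9)
})

test_that("C_asymm is invariant under rigid motion and half swap", {
  set.seed(42)
  n <- 20
  coords <- cbind(25 + cumsum(runif(n, 2, 5)), rnorm(n, 2), rnorm(n, 2))
  s <- make_symmetric_pair(coords)
  s$xyz <- s$xyz + matrix(rnorm(length(s$xyz), sd = 0.4), ncol = 3)
  map <- pair_map(s)
  prs <- select_pairs(s, map, d0 = 8)
  v0 <- casymm(s, prs)
  for (rep in 1:6) {
    rt <- rand_rigid()
    expect_equal(casymm(apply_rigid(map_calpha_coords(s, map), rt), prs),
                 v0, tolerance = 1e-9)
  }
  # swapping the halves of the map leaves C_asymm unchanged
  map_sw <- suppressMessages(build_homodimer_map(s, "B", "A",
                                                 c(A = "TMD", B = "TMD")))
  prs_sw <- select_pairs(s, map_sw, d0 = 8)
  expect_equal(casymm(s, prs_sw), v0, tolerance = 1e-9)
})

test_that("mean-absolute C_asymm never exceeds the RMS form", {
  set.seed(43)
  n <- 15
  for (rep in 1:10) {
    coords <- cbind(25 + cumsum(runif(n, 2, 5)), rnorm(n, 2), rnorm(n, 2))
    s <- make_symmetric_pair(coords)
    s$xyz <- s$xyz + matrix(rnorm(length(s$xyz), sd = 0.5), ncol = 3)
    prs <- select_pairs(s, pair_map(s), d0 = 9)
    expect_lte(casymm(s, prs, "mean-abs"), casymm(s, prs, "rms") + 1e-12)
  }
})

test_that("the A_ij closed form holds for a two-frame trajectory", {
  s <- make_chain11()
  map <- pair_map(s)
  prs <- select_pairs(s, map, d0 = 8, dedup = "symmetric")
  f_sym <- map_calpha_coords(s, map)
  f_pert <- f_sym
  f_pert[1, 1] <- f_pert[1, 1] + 1    # pair (1,2): |delta| = 1.0 A
  sel <- s$atoms[s$atoms$elety == "CA", ]
  tr <- trajectory(list(f_pert, f_sym), sel)
  a <- aij(tr, prs)
  i <- which(prs$resno_i == 1 & prs$resno_j == 2 & prs$chain_i == "A")
  expect_equal(a[i], sqrt(0.5), tolerance = 1e-9)
  expect_equal(sum(a > 1e-9), 1)
  # single-frame trajectory reduces to the static per-pair deltas
  tr1 <- trajectory(list(f_pert), sel)
  expect_equal(aij(tr1, prs), aij(f_pert, prs), tolerance = 1e-12)
  expect_error_class(aij(trajectory(list(), sel), prs), "empty_input")
})

test_that("A_ij matches an independent per-pair loop on random frames", {
  set.seed(44)
  n <- 15
  coords <- cbind(25 + cumsum(runif(n, 2, 5)), rnorm(n, 2), rnorm(n, 2))
  s <- make_symmetric_pair(coords)
  map <- pair_map(s)
  prs <- select_pairs(s, map, d0 = 9)
  base <- map_calpha_coords(s, map)
  frames <- lapply(1:5, function(k) base + matrix(rnorm(length(base), sd = 0.3),
                                                  ncol = 3))
  sel <- s$atoms[s$atoms$elety == "CA", ]
  a <- aij(trajectory(frames, sel), prs)
  pidx <- dimergate:::.map_partner_index(map)
  for (p in seq_len(nrow(prs))) {
    dd <- vapply(frames, function(fr) {
      dij <- sqrt(sum((fr[prs$i[p], ] - fr[prs$j[p], ])^2))
      dpp <- sqrt(sum((fr[prs$pi[p], ] - fr[prs$pj[p], ])^2))
      abs(dij - dpp)
    }, numeric(1))
    expect_equal(a[p], sqrt(mean(dd^2)), tolerance = 1e-12)
  }
})

test_that("casymm_series on constructed trajectories behaves as built", {
  s <- make_chain11()
  map <- pair_map(s)
  prs <- select_pairs(s, map, d0 = 8)
  base <- map_calpha_coords(s, map)
  sel <- s$atoms[s$atoms$elety == "CA", ]
  # constant symmetric trajectory -> all zeros
  ser0 <- casymm_series(trajectory(list(base, base, base), sel), prs)
  expect_true(all(ser0$casymm < 1e-12))
  # linearly growing displacement of one half-1 residue -> non-decreasing
  frames <- lapply(0:6, function(k) {
    fr <- base; fr[1, 1] <- fr[1, 1] + 0.2 * k; fr
  })
  ser <- casymm_series(trajectory(frames, sel), prs)
  expect_true(all(diff(ser$casymm) > -1e-12))
  # single-frame series equals the static value
  ser1 <- casymm_series(trajectory(list(frames[[4]]), sel), prs)
  expect_equal(ser1$casymm, casymm(frames[[4]], prs), tolerance = 1e-12)
})

test_that("ARP classification: nulls, tiers, regions and validation", {
  s <- make_chain11()
  prs <- select_pairs(s, pair_map(s), d0 = 8)
  a0 <- aij(map_calpha_coords(s, pair_map(s)), prs)
  arp0 <- classify_arps(a0, prs)
  expect_equal(arp0$n_arp, 0)
  expect_true(all(arp0$region_counts == 0))
  a <- rep(c(0.3, 0.7, 1.5, 2.5), length.out = nrow(prs))
  arp <- classify_arps(a, prs, threshold = 0.8, tiers = c(0.5, 1, 2))
  expect_equal(arp$n_arp, sum(a > 0.8))
  expect_equal(sum(arp$region_counts), arp$n_arp)
  expect_equal(unname(arp$tier_counts),
               c(sum(a >= 0.5 & a < 1), sum(a >= 1 & a < 2), sum(a >= 2)))
  expect_error_class(classify_arps(a, prs, tiers = c(1, 0.5)), "config")
  expect_error_class(classify_arps(a, prs, threshold = -1), "config")
})

test_that("injected asymmetry is recovered at the injection site", {
  d <- build_toy_homodimer(seed = 2)
  sO <- toy_structure(d, "O")
  prs <- select_pairs(sO, d$map, d0 = 8)
  pert <- inject_asymmetry(sO, d$map, 10:12, half = 1, amplitude = 2,
                           seed = 9)
  a <- aij(map_calpha_coords(pert, d$map), prs)
  arp <- classify_arps(a, prs, threshold = 0.8)
  expect_gt(arp$n_arp, 0)
  # neighborhood: injected rows, anything within d0 of them, and partners
  map <- d$map
  coords <- map_calpha_coords(sO, map)
  inj <- which(map$half == 1 & map$resno %in% 10:12)
  dm <- as.matrix(dist(coords))
  near <- which(apply(dm[, inj, drop = FALSE] < 8, 1, any))
  pidx <- dimergate:::.map_partner_index(map)
  neigh <- unique(c(inj, near, pidx[c(inj, near)]))
  flagged <- which(a > 0.8)
  ok <- vapply(flagged, function(r)
    any(c(prs$i[r], prs$j[r], prs$pi[r], prs$pj[r]) %in% neigh), TRUE)
  expect_true(all(ok))
  # the strongest pair involves an injected residue directly
  top <- which.max(a)
  expect_true(any(c(prs$i[top], prs$j[top], prs$pi[top], prs$pj[top]) %in% inj))
})

test_that("ARP count is non-decreasing in injection amplitude", {
  d <- build_toy_homodimer(seed = 6)
  sO <- toy_structure(d, "O")
  prs <- select_pairs(sO, d$map, d0 = 8)
  counts <- vapply(c(0, 0.5, 1, 2, 3), function(amp) {
    p <- inject_asymmetry(sO, d$map, 14:16, half = 1, amplitude = amp,
                          seed = 13)
    classify_arps(aij(map_calpha_coords(p, d$map), prs), prs, 0.8)$n_arp
  }, numeric(1))
  expect_equal(counts[1], 0)
  expect_true(all(diff(counts) >= 0))
})
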