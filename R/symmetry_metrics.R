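# Homodimer symmetry-breaking statistics: residue-pair selection under a
# distance cutoff, the asymmetry coefficient C_asymm, per-pair A_ij scores
# and classification of asymmetric residue pairs (ARPs).
#
# All statistics are built from internal C-alpha distances only, so they are
# superposition-free and invariant under global rigid motions.

.pair_region_classes <- c("within-TMD", "within-NBD", "TMD-NBD",
                          "TMD-TMD'", "NBD-NBD'")

.classify_pair_region <- function(h_i, h_j, r_i, r_j) {
  same_half <- h_i == h_j
  ifelse(same_half & r_i == "TMD" & r_j == "TMD", "within-TMD",
  ifelse(same_half & r_i == "NBD" & r_j == "NBD", "within-NBD",
  ifelse(!same_half & r_i == "TMD" & r_j == "TMD", "TMD-TMD'",
  ifelse(!same_half & r_i == "NBD" & r_j == "NBD", "NBD-NBD'",
         "TMD-NBD"))))
}

#' Select symmetry residue pairs within a distance cutoff
#'
#' A residue pair (i, j) is selected when the C-alpha separation d_ij in the
#' selecting structure is strictly less than `d0` and both residues (hence
#' both partners) are present in the homodimer map. Each pair carries a
#' region class (within-TMD, within-NBD, TMD-NBD interface, or the
#' cross-dimer TMD-TMD' / NBD-NBD' interfaces) and the row indices of its
#' partner pair. Pairs are selected once, from the given structure, and held
#' fixed along trajectories.
#'
#' @param s a [structure3d()] (typically the initial/reference structure).
#' @param map a `homodimer_map` covering the C-alpha selection.
#' @param d0 cutoff in Angstrom (default 8).
#' @param dedup `"none"` (default) keeps a pair and its symmetry partner as
#'   distinct entries whenever both satisfy the cutoff; `"symmetric"` counts
#'   each symmetry-equivalent pair once.
#' @return data.frame of class `symmetry_pairs`: map row indices `i`, `j` and
#'   partner indices `pi`, `pj`, residue identities, reference distance
#'   `d_ref` and `region`. Attributes: `d0`, `dedup`, `n_pair`, `map`.
#' @export
select_pairs <- function(s, map, d0 = 8, dedup = c("none", "symmetric")) {
  dedup <- match.arg(dedup)
  stopifnot(inherits(map, "homodimer_map"))
  if (nrow(map) == 0) .fail("homodimer map is empty", "config")
  if (!is.numeric(d0) || d0 <= 0) .fail("d0 must be positive", "config")
  coords <- map_calpha_coords(s, map)
  pidx <- .map_partner_index(map)
  dm <- as.matrix(stats::dist(coords))
  dm[lower.tri(dm, diag = TRUE)] <- Inf
  hit <- which(dm < d0, arr.ind = TRUE)
  i <- hit[, 1]; j <- hit[, 2]
  pi_ <- pidx[i]; pj <- pidx[j]
  region <- .classify_pair_region(map$half[i], map$half[j],
                                  map$region[i], map$region[j])
  pairs <- data.frame(i = i, j = j, pi = pi_, pj = pj,
                      chain_i = map$chain[i], resno_i = map$resno[i],
                      chain_j = map$chain[j], resno_j = map$resno[j],
                      d_ref = dm[hit], region = region,
                      stringsAsFactors = FALSE)
  ord <- order(pairs$i, pairs$j)
  pairs <- pairs[ord, , drop = FALSE]
  if (dedup == "symmetric") {
    nmap <- nrow(map)
    key <- pmin(pairs$i, pairs$j) * (nmap + 1) + pmax(pairs$i, pairs$j)
    pkey <- pmin(pairs$pi, pairs$pj) * (nmap + 1) + pmax(pairs$pi, pairs$pj)
    # keep the lexicographically smaller member of each symmetry-equivalent
    # duo; self-symmetric pairs and pairs whose partner missed the cutoff
    # are always kept
    drop <- key > pkey & pkey %in% key
    pairs <- pairs[!drop, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(pairs, class = c("symmetry_pairs", "data.frame"),
            d0 = d0, dedup = dedup, n_pair = nrow(pairs), map = map)
}

#' @export
print.symmetry_pairs <- function(x, ...) {
  cat(sprintf("symmetry_pairs: N_pair = %d (d0 = %g A, dedup = %s)\n",
              attr(x, "n_pair"), attr(x, "d0"), attr(x, "dedup")))
  print(table(x$region))
  invisible(x)
}

# Frame coordinates in map order from whatever the caller handed us.
.pairs_frame <- function(frame, pairs) {
  map <- attr(pairs, "map")
  if (inherits(frame, "structure3d")) frame <- map_calpha_coords(frame, map)
  frame <- as.matrix(frame)
  if (nrow(frame) != nrow(map))
    .fail("frame does not cover the mapped residues", "consistency")
  if (!all(is.finite(frame)))
    .fail("frame contains missing residue coordinates", "consistency")
  frame
}

# |d_ij - d_i'j'| per pair for one frame.
.pair_deltas <- function(frame, pairs) {
  d_ij <- sqrt(rowSums((frame[pairs$i, , drop = FALSE] -
                        frame[pairs$j, , drop = FALSE])^2))
  d_pp <- sqrt(rowSums((frame[pairs$pi, , drop = FALSE] -
                        frame[pairs$pj, , drop = FALSE])^2))
  abs(d_ij - d_pp)
}

#' Asymmetry coefficient of one frame
#'
#' Aggregates |d_ij - d_i'j'| over the selected residue pairs, where the
#' primed pair is the symmetry counterpart in the opposite half of the
#' protein. Zero for an exactly symmetric structure. Both natural
#' aggregations are provided: the mean of absolute differences (default) and
#' the root mean square.
#'
#' @param frame a [structure3d()] or an n x 3 matrix over the mapped residues
#'   in map order.
#' @param pairs a `symmetry_pairs` set from [select_pairs()].
#' @param form aggregation form, `"mean-abs"` or `"rms"`.
#' @return C_asymm in Angstrom (non-negative scalar).
#' @export
casymm <- function(frame, pairs, form = c("mean-abs", "rms")) {
  form <- match.arg(form)
  stopifnot(inherits(pairs, "symmetry_pairs"))
  deltas <- .pair_deltas(.pairs_frame(frame, pairs), pairs)
  if (form == "mean-abs") mean(deltas) else sqrt(mean(deltas^2))
}

#' Asymmetry coefficient along a trajectory
#'
#' @param traj a `ca_trajectory` covering the mapped C-alphas.
#' @inheritParams casymm
#' @return data.frame of class `asymmetry_series` with columns `label` and
#'   `casymm` (Angstrom); attribute `form` records the aggregation.
#' @export
casymm_series <- function(traj, pairs, form = c("mean-abs", "rms")) {
  form <- match.arg(form)
  stopifnot(inherits(traj, "ca_trajectory"), inherits(pairs, "symmetry_pairs"))
  map <- attr(pairs, "map")
  idx <- .traj_map_index(traj, map)
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    casymm(get_frame(traj, f)[idx, , drop = FALSE], pairs, form), numeric(1))
  structure(data.frame(label = traj$labels, casymm = vals),
            class = c("asymmetry_series", "data.frame"), form = form)
}

#' Per-pair asymmetry score A_ij along a trajectory
#'
#' A_ij is the quadratic mean of |d_ij - d_i'j'| over the frames of the
#' trajectory; for a single-frame input it reduces to |d_ij - d_i'j'| of that
#' frame, so static structures and trajectories share one code path.
#'
#' @param traj a `ca_trajectory` (or a single [structure3d()] / coordinate
#'   matrix, treated as a one-frame trajectory).
#' @param pairs a `symmetry_pairs` set.
#' @return numeric vector of A_ij values (Angstrom), aligned with the rows of
#'   `pairs`.
#' @export
aij <- function(traj, pairs) {
  stopifnot(inherits(pairs, "symmetry_pairs"))
  if (!inherits(traj, "ca_trajectory")) {
    frame <- .pairs_frame(traj, pairs)
    return(.pair_deltas(frame, pairs))
  }
  nf <- n_frames(traj)
  if (nf == 0) .fail("trajectory has no frames", "empty_input")
  idx <- .traj_map_index(traj, attr(pairs, "map"))
  acc <- numeric(nrow(pairs))
  for (f in seq_len(nf))
    acc <- acc + .pair_deltas(get_frame(traj, f)[idx, , drop = FALSE], pairs)^2
  sqrt(acc / nf)
}

#' Classify asymmetric residue pairs (ARPs)
#'
#' Pairs with A_ij strictly above `threshold` are flagged as ARPs; counts are
#' attributed to the pair region classes, and a display histogram over the
#' tier edges (defaults 0.5 / 1.0 / 2.0 A, last tier open-ended) is reported.
#'
#' @param aij_values numeric vector from [aij()], aligned with `pairs`.
#' @param pairs the `symmetry_pairs` the values were computed over.
#' @param threshold ARP selection threshold in Angstrom (default 0.8).
#' @param tiers ascending tier edges for the display histogram.
#' @return an object of class `arp_table`: the per-pair table (sorted by
#'   A_ij descending), the threshold, per-region ARP counts, tier counts and
#'   the total ARP count.
#' @export
classify_arps <- function(aij_values, pairs, threshold = 0.8,
                          tiers = c(0.5, 1.0, 2.0)) {
  stopifnot(inherits(pairs, "symmetry_pairs"))
  if (!is.numeric(threshold) || threshold <= 0)
    .fail("threshold must be positive", "config")
  if (is.unsorted(tiers, strictly = TRUE))
    .fail("tier edges must be strictly ascending", "config")
  if (length(aij_values) != nrow(pairs))
    .fail("A_ij vector length differs from pair count", "shape")
  if (any(aij_values < 0)) .fail("A_ij values must be non-negative",
                                 "consistency")
  is_arp <- aij_values > threshold
  tab <- data.frame(pairs[, c("chain_i", "resno_i", "chain_j", "resno_j",
                              "region")],
                    a_ij = aij_values, is_arp = is_arp,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$a_ij), , drop = FALSE]
  rownames(tab) <- NULL
  region_counts <- vapply(.pair_region_classes, function(rc)
    sum(is_arp & pairs$region == rc), integer(1))
  edges <- c(tiers, Inf)
  tier_counts <- vapply(seq_along(tiers), function(k)
    sum(aij_values >= edges[k] & aij_values < edges[k + 1]), integer(1))
  names(tier_counts) <- paste0("[", tiers, ",",
                               c(tiers[-1], "Inf"), ")")
  structure(list(table = tab, threshold = threshold, tiers = tiers,
                 region_counts = region_counts, tier_counts = tier_counts,
                 n_arp = sum(is_arp)),
            class = "arp_table")
}

#' @export
print.arp_table <- function(x, ...) {
  cat(sprintf("arp_table: %d ARPs of %d pairs (A_ij > %g A)\n",
              x$n_arp, nrow(x$table), x$threshold))
  print(x$region_counts)
  invisible(x)
}
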