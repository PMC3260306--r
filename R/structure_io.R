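# Structure and trajectory I/O, atom selections and the homodimer partner map.
#
# PDB reading is delegated to bio3d; the package adds van der Waals radius
# assignment, altloc/insertion policy, multi-model writing (which bio3d does
# not provide) and the partner mapping between symmetry-equivalent residues
# that every symmetry statistic depends on.

# Per-element van der Waals radii (Angstrom). HOLE-style profiling only needs
# heavy-atom radii; unknown elements fall back to the carbon value.
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_default <- 1.70

#' Van der Waals radius lookup
#'
#' Maps element symbols to van der Waals radii in Angstrom. The bundled table
#' covers C, N, O, S, H and P; anything else receives the default (1.70 A).
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param table optional named numeric vector overriding or extending the
#'   bundled radii.
#' @param default radius used for elements absent from the table.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, table = NULL, default = .vdw_default) {
  tab <- .vdw_table
  if (!is.null(table)) tab[names(table)] <- table
  r <- unname(tab[toupper(trimws(element))])
  r[is.na(r)] <- default
  r
}

# Guess the element symbol from a PDB atom name when columns 77-78 are blank.
.element_from_name <- function(elety) {
  nm <- gsub("[0-9']", "", trimws(elety))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(trimws(elety)) == 4 & substr(elety, 1, 1) != " ",
         two, one)
}

#' Construct a structure from atom metadata and coordinates
#'
#' Low-level constructor used by the readers and by the synthetic-data
#' generator. `atoms` must contain columns `chain`, `resno`, `resid`, `elety`;
#' `insert`, `elesy` and `radius` are filled in when absent.
#'
#' @param atoms data.frame of per-atom metadata.
#' @param xyz n x 3 numeric matrix of coordinates in Angstrom.
#' @param model model index this coordinate set came from.
#' @param nmodels number of models in the source.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz, model = 1L, nmodels = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("chain", "resno", "resid", "elety"))
    if (is.null(atoms[[col]]))
      .fail(sprintf("atoms table lacks required column '%s'", col), "config")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)))
    atoms$elesy <- .element_from_name(atoms$elety)
  atoms$elesy[is.na(atoms$elesy) | trimws(atoms$elesy) == ""] <-
    .element_from_name(atoms$elety[is.na(atoms$elesy) | trimws(atoms$elesy) == ""])
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$elesy)
  xyz <- as.matrix(xyz)
  .assert_coords(xyz)
  if (nrow(xyz) != nrow(atoms))
    .fail("coordinate and atom counts differ", "shape")
  if (any(atoms$radius <= 0))
    .fail("van der Waals radii must be positive", "consistency")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    .fail(sprintf("duplicate atom record: %s", key[duplicated(key)][1]),
          "consistency")
  structure(list(atoms = atoms, xyz = xyz,
                 model = as.integer(model), nmodels = as.integer(nmodels)),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d chain(s) [%s], model %d of %d\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ","),
              x$model, x$nmodels))
  invisible(x)
}

# Shared low-level reader: validates ATOM/HETATM records (naming the offending
# line), parses via bio3d, applies the altloc policy (keep blank or 'A'),
# assigns radii. Returns atoms table plus a list of per-model coordinate sets.
.read_pdb_all <- function(path, radius_table = NULL) {
  if (!file.exists(path))
    .fail(sprintf("file not found: %s", path), "format")
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    .fail(sprintf("%s: no ATOM/HETATM records", path), "format")
  for (i in which(rec)) {
    ln <- lines[i]
    bad <- nchar(ln) < 54 ||
      anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                          substr(ln, 39, 46),
                                          substr(ln, 47, 54)))))
    if (bad)
      .fail(sprintf("%s: unparseable coordinate record at line %d", path, i),
            "format")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) .fail(sprintf("%s: %s", path, conditionMessage(e)),
                              "format"))
  at <- pdb$atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmodels <- nrow(xyz)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid,
                      elety = at$elety,
                      elesy = if (is.null(at$elesy)) NA_character_ else at$elesy,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  miss <- is.na(atoms$elesy) | trimws(atoms$elesy) == ""
  atoms$elesy[miss] <- .element_from_name(atoms$elety[miss])
  atoms$elesy <- trimws(atoms$elesy)
  atoms$radius <- vdw_radius(atoms$elesy, table = radius_table)
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                          3 * which(keep)))
  models <- lapply(seq_len(nmodels), function(m) {
    matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
  })
  list(atoms = atoms, models = models, nmodels = nmodels)
}

#' Read a structure from a PDB file
#'
#' Reads one coordinate set (model) from a PDB file. Atoms with alternate
#' location indicator other than blank or 'A' are dropped; insertion-coded
#' residues are kept as distinct residues; van der Waals radii are assigned
#' from the bundled element table (see [vdw_radius()]).
#'
#' @param path path to a PDB file (single- or multi-model).
#' @param model 1-based model index to extract.
#' @param radius_table optional named numeric vector overriding element radii.
#' @return a [structure3d()] object.
#' @export
read_structure <- function(path, model = 1L, radius_table = NULL) {
  raw <- .read_pdb_all(path, radius_table)
  model <- as.integer(model)
  if (model < 1L || model > raw$nmodels)
    .fail(sprintf("%s: model %d requested but file holds %d model(s)",
                  path, model, raw$nmodels), "range")
  xyz <- raw$models[[model]]
  if (!all(is.finite(xyz)))
    .fail(sprintf("%s: non-finite coordinates in model %d", path, model),
          "consistency")
  structure3d(raw$atoms, xyz, model = model, nmodels = raw$nmodels)
}

# Fixed-width PDB ATOM line. Short atom names get the conventional leading
# space so that " CA " lands in columns 13-16.
.pdb_atom_line <- function(serial, elety, resid, chain, resno, insert,
                           x, y, z, elesy) {
  nm <- ifelse(nchar(elety) < 4, paste0(" ", elety), elety)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, resid, substr(chain, 1, 1), resno %% 10000,
          substr(paste0(insert, " "), 1, 1), x, y, z, 1, 0,
          toupper(substr(paste0(elesy, " "), 1, 2)))
}

.write_pdb_models <- function(atoms, frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  n <- nrow(atoms)
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    writeLines(.pdb_atom_line(seq_len(n), atoms$elety, atoms$resid,
                              atoms$chain, atoms$resno, atoms$insert,
                              xyz[, 1], xyz[, 2], xyz[, 3], atoms$elesy), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure to a PDB file
#'
#' @param s a [structure3d()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  .write_pdb_models(s$atoms, list(s$xyz), path)
}

#' Select C-alpha atoms
#'
#' Returns the C-alpha atoms of the named chains in (chain, residue number,
#' insertion code) order, with chains ordered as given. Residues that lack a
#' C-alpha atom are skipped and reported in the `skipped` attribute (and via
#' a message).
#'
#' @param s a [structure3d()] object.
#' @param chains character vector of chain identifiers (non-empty).
#' @param label optional label stored on the selection.
#' @return data.frame of class `atom_selection` with columns `index` (row in
#'   `s$atoms`), `chain`, `resno`, `insert`, `resid`, `elety`, `radius`.
#' @export
select_calpha <- function(s, chains, label = NULL) {
  stopifnot(inherits(s, "structure3d"))
  if (length(chains) == 0)
    .fail("no chains given", "config")
  at <- s$atoms
  in_chain <- at$chain %in% chains
  is_ca <- at$elety == "CA" & in_chain
  # residues present in the chains but lacking a C-alpha
  res_key <- paste(at$chain, at$resno, at$insert)
  have_ca <- unique(res_key[is_ca])
  skipped <- unique(at[in_chain & !(res_key %in% have_ca),
                       c("chain", "resno", "insert", "resid")])
  idx <- which(is_ca)
  if (length(idx) == 0)
    .fail(sprintf("no C-alpha atoms found in chain(s) %s",
                  paste(chains, collapse = ",")), "empty_selection")
  ord <- order(match(at$chain[idx], chains), at$resno[idx], at$insert[idx])
  idx <- idx[ord]
  sel <- data.frame(index = idx, at[idx, c("chain", "resno", "insert",
                                           "resid", "elety", "radius")],
                    stringsAsFactors = FALSE)
  rownames(sel) <- NULL
  if (nrow(skipped) > 0)
    message(sprintf("select_calpha: %d residue(s) lack a C-alpha and were skipped",
                    nrow(skipped)))
  structure(sel, class = c("atom_selection", "data.frame"),
            label = label %||% paste0("CA:", paste(chains, collapse = ",")),
            skipped = skipped)
}

#' Coordinates of a selection within a structure
#'
#' @param s a [structure3d()] object the selection was built on (or one with
#'   an identical atom table, e.g. another model of the same file).
#' @param sel an `atom_selection`.
#' @return n x 3 matrix of coordinates.
#' @export
selection_coords <- function(s, sel) {
  stopifnot(inherits(s, "structure3d"), inherits(sel, "atom_selection"))
  s$xyz[sel$index, , drop = FALSE]
}

#' Build the homodimer partner map
#'
#' Pairs every residue of half 1 with the same-numbered residue of the
#' corresponding half-2 chain and labels each residue with its region (TMD or
#' NBD) and half. Residues without a same-numbered counterpart in the paired
#' chain are excluded from the map and reported via the `excluded` attribute.
#' The partner relation is an involution by construction.
#'
#' @param s a [structure3d()] object.
#' @param half1,half2 ordered chain vectors of equal length; `half1[i]` is
#'   paired with `half2[i]`.
#' @param regions named character vector mapping each chain to `"TMD"` or
#'   `"NBD"`; paired chains must share a region label.
#' @return data.frame of class `homodimer_map` with columns `chain`, `resno`,
#'   `insert`, `half`, `region`, `partner_chain`, `partner_resno`.
#' @export
build_homodimer_map <- function(s, half1, half2, regions) {
  stopifnot(inherits(s, "structure3d"))
  if (length(half1) != length(half2))
    .fail("half1 and half2 chain lists differ in length", "config")
  regions <- unlist(regions)
  need <- setdiff(c(half1, half2), names(regions))
  if (length(need) > 0)
    .fail(sprintf("no region label for chain(s): %s",
                  paste(need, collapse = ",")), "config")
  if (!all(regions[c(half1, half2)] %in% c("TMD", "NBD")))
    .fail("region labels must be 'TMD' or 'NBD'", "config")
  at <- s$atoms
  rows <- list()
  excluded <- list()
  for (i in seq_along(half1)) {
    c1 <- half1[i]; c2 <- half2[i]
    if (regions[c1] != regions[c2])
      .fail(sprintf("paired chains %s and %s have different region labels",
                    c1, c2), "config")
    ca1 <- at[at$elety == "CA" & at$chain == c1, c("resno", "insert")]
    ca2 <- at[at$elety == "CA" & at$chain == c2, c("resno", "insert")]
    k1 <- paste(ca1$resno, ca1$insert)
    k2 <- paste(ca2$resno, ca2$insert)
    common <- intersect(k1, k2)
    drop1 <- ca1[!(k1 %in% common), , drop = FALSE]
    drop2 <- ca2[!(k2 %in% common), , drop = FALSE]
    if (nrow(drop1) > 0) excluded[[paste0(c1)]] <- cbind(chain = c1, drop1)
    if (nrow(drop2) > 0) excluded[[paste0(c2)]] <- cbind(chain = c2, drop2)
    keep1 <- ca1[k1 %in% common, , drop = FALSE]
    keep1 <- keep1[order(keep1$resno, keep1$insert), , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      chain = c1, resno = keep1$resno, insert = keep1$insert,
      half = 1L, region = unname(regions[c1]),
      partner_chain = c2, partner_resno = keep1$resno,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      chain = c2, resno = keep1$resno, insert = keep1$insert,
      half = 2L, region = unname(regions[c2]),
      partner_chain = c1, partner_resno = keep1$resno,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  map <- map[order(map$half, match(map$chain, c(half1, half2)),
                   map$resno, map$insert), ]
  rownames(map) <- NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(chain = character(), resno = integer(), insert = character())
  rownames(excluded) <- NULL
  if (nrow(excluded) > 0)
    message(sprintf("build_homodimer_map: %d residue(s) have no counterpart and were excluded",
                    nrow(excluded)))
  structure(map, class = c("homodimer_map", "data.frame"),
            excluded = excluded)
}

# Row index of each map residue's partner within the map itself.
.map_partner_index <- function(map) {
  key <- paste(map$chain, map$resno, map$insert)
  pkey <- paste(map$partner_chain, map$partner_resno, map$insert)
  idx <- match(pkey, key)
  if (anyNA(idx))
    .fail("homodimer map is not a bijection (missing partner rows)",
          "consistency")
  idx
}

#' C-alpha coordinates in homodimer-map order
#'
#' Extracts the C-alpha coordinate of every mapped residue from a structure,
#' in map row order. This is the canonical frame layout used by the symmetry
#' statistics.
#'
#' @param s a [structure3d()] object.
#' @param map a `homodimer_map`.
#' @return n x 3 matrix, one row per map row.
#' @export
map_calpha_coords <- function(s, map) {
  stopifnot(inherits(s, "structure3d"), inherits(map, "homodimer_map"))
  at <- s$atoms
  akey <- paste(at$chain, at$resno, at$insert, at$elety)
  idx <- match(paste(map$chain, map$resno, map$insert, "CA"), akey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    .fail(sprintf("structure lacks C-alpha for mapped residue %s %d",
                  map$chain[bad], map$resno[bad]), "consistency")
  }
  s$xyz[idx, , drop = FALSE]
}

#' Construct a trajectory from coordinate frames
#'
#' @param frames list of n x 3 coordinate matrices over a fixed atom order.
#' @param selection an `atom_selection` (or atoms data.frame) describing that
#'   order.
#' @param labels strictly increasing numeric frame labels; defaults to
#'   `0:(nframes-1)`.
#' @return an object of class `ca_trajectory`.
#' @export
trajectory <- function(frames, selection, labels = NULL) {
  if (length(frames) > 0) {
    n <- nrow(frames[[1]])
    for (f in frames) {
      .assert_coords(f, "frame coordinates")
      if (nrow(f) != n) .fail("frames differ in atom count", "consistency")
    }
  }
  labels <- labels %||% (seq_along(frames) - 1)
  if (length(labels) != length(frames))
    .fail("label count differs from frame count", "consistency")
  if (length(labels) > 1 && any(diff(labels) <= 0))
    .fail("frame labels must be strictly increasing", "consistency")
  sel <- as.data.frame(selection, stringsAsFactors = FALSE)
  coords <- if (length(frames) > 0)
    array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  else array(numeric(0), dim = c(0, 3, 0))
  structure(list(selection = sel, coords = coords, labels = labels),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf("ca_trajectory: %d frame(s) x %d atoms, labels [%s..%s]\n",
              n_frames(x), nrow(x$selection),
              if (n_frames(x)) x$labels[1] else "-",
              if (n_frames(x)) x$labels[n_frames(x)] else "-"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `ca_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj a `ca_trajectory`.
#' @param i 1-based frame index.
#' @return n x 3 coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1 || i > nf)
    .fail(sprintf("frame %d outside 1..%d", i, nf), "range")
  traj$coords[, , i, drop = FALSE][, , 1]
}

#' View one trajectory frame as a structure
#' @param traj a `ca_trajectory`.
#' @param i 1-based frame index.
#' @return a [structure3d()] built from the trajectory's selection metadata.
#' @export
frame_structure <- function(traj, i) {
  sel <- traj$selection
  at <- data.frame(chain = sel$chain, resno = sel$resno,
                   insert = sel$insert %||% "", resid = sel$resid,
                   elety = sel$elety, radius = sel$radius,
                   stringsAsFactors = FALSE)
  structure3d(at, get_frame(traj, i))
}

#' Read a trajectory from a multi-model PDB file
#'
#' Produces one frame per model, restricted to `selection` and in selection
#' order; frame labels are the 0-based model indices. Every model must contain
#' all selected atoms.
#'
#' @param path multi-model PDB file.
#' @param selection an `atom_selection` built on a structure read from the
#'   same file (atoms are matched by chain, residue number, insertion code and
#'   atom name).
#' @return a `ca_trajectory`.
#' @export
read_trajectory <- function(path, selection) {
  stopifnot(inherits(selection, "atom_selection"))
  raw <- tryCatch(.read_pdb_all(path),
                  error = function(e) {
                    if (inherits(e, "dimergate_format_error")) stop(e)
                    .fail(sprintf("%s: models are inconsistent (%s)", path,
                                  conditionMessage(e)), "consistency")
                  })
  akey <- paste(raw$atoms$chain, raw$atoms$resno, raw$atoms$insert,
                raw$atoms$elety)
  skey <- paste(selection$chain, selection$resno, selection$insert,
                selection$elety)
  idx <- match(skey, akey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    .fail(sprintf("%s: selected atom %s %d %s absent from file", path,
                  selection$chain[bad], selection$resno[bad],
                  selection$elety[bad]), "consistency")
  }
  frames <- lapply(seq_len(raw$nmodels), function(m) {
    fr <- raw$models[[m]][idx, , drop = FALSE]
    if (!all(is.finite(fr))) {
      bad <- which(!is.finite(rowSums(fr)))[1]
      .fail(sprintf("%s: model %d lacks coordinates for atom %s %d %s", path,
                    m, selection$chain[bad], selection$resno[bad],
                    selection$elety[bad]), "consistency")
    }
    fr
  })
  trajectory(frames, selection, labels = seq_len(raw$nmodels) - 1)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `ca_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ca_trajectory"))
  sel <- traj$selection
  at <- data.frame(chain = sel$chain, resno = sel$resno,
                   insert = sel$insert %||% "", resid = sel$resid,
                   elety = sel$elety,
                   elesy = .element_from_name(sel$elety),
                   stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames(traj)), function(i) get_frame(traj, i))
  .write_pdb_models(at, frames, path)
}
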