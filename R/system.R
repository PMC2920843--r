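#' Molecular system container
#'
#' A parameterized system bundles an atom table (one row per atom, in file
#' order), optional coordinates, bonded topology, and named atom selections.
#' All positions are in Angstrom, charges in elementary charge units, masses
#' in amu, energies in kcal/mol.
#'
#' @param atoms A tibble with one row per atom. Recognised columns: `serial`,
#'   `name`, `element`, `resname`, `resid`, `chain`, `icode`, `is_water`,
#'   `mass`, `mm_charge`, `parse_charge`, `lj_epsilon`, `lj_rmin_half`,
#'   `radius_pb`, `radius_sasa`. Missing parameter columns are filled with
#'   `NA` and populated later by [assign_parameters()].
#' @param coords Optional numeric matrix (n_atoms x 3) of coordinates.
#' @param bonds Optional two-column integer matrix of bonded atom pairs
#'   (1-based indices).
#' @param dihedrals Optional tibble of proper torsions with columns
#'   `i, j, k, l` (1-based atom indices), `k_dih` (kcal/mol), `n`
#'   (periodicity) and `delta` (phase, degrees).
#' @param selections Named list of integer index vectors; the roles
#'   `receptor`, `ligand` and `water` must be pairwise disjoint.
#' @param box Optional numeric length-3 vector of periodic box edges
#'   (Angstrom).
#'
#' @return An object of class `mm_system`.
#' @export
new_system <- function(atoms, coords = NULL, bonds = NULL, dihedrals = NULL,
                       selections = list(), box = NULL) {
  atoms <- as_tibble(atoms)
  needed <- c("mass", "mm_charge", "parse_charge", "lj_epsilon",
              "lj_rmin_half", "radius_pb", "radius_sasa")
  for (col in needed) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms[["element"]])) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms[["chain"]])) atoms$chain <- ""
  if (is.null(atoms[["icode"]])) atoms$icode <- ""
  if (is.null(atoms[["serial"]])) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms[["is_water"]])) {
    atoms$is_water <- atoms$resname %in% water_residue_names()
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(ncol(coords) == 3)
    if (nrow(coords) != nrow(atoms)) {
      abort("coordinate row count does not match the atom count")
    }
  }
  if (!is.null(dihedrals)) {
    dihedrals <- as_tibble(dihedrals)
    if (nrow(dihedrals) > 0 &&
        max(dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l) > nrow(atoms)) {
      abort("dihedral atom index exceeds the atom count")
    }
  }
  check_role_disjoint(selections)
  structure(
    list(atoms = atoms, coords = coords, bonds = bonds,
         dihedrals = dihedrals, selections = selections, box = box),
    class = "mm_system"
  )
}

check_role_disjoint <- function(selections) {
  roles <- intersect(names(selections), c("receptor", "ligand", "water"))
  if (length(roles) > 1) {
    for (a in seq_along(roles)) {
      for (b in seq_along(roles)) {
        if (a < b &&
            length(intersect(selections[[roles[a]]],
                             selections[[roles[b]]])) > 0) {
          abort(sprintf("role selections '%s' and '%s' overlap",
                        roles[a], roles[b]))
        }
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.mm_system <- function(x, ...) {
  nw <- length(unique(paste(x$atoms$resid, x$atoms$chain)[x$atoms$is_water]))
  cat(sprintf("<mm_system> %d atoms, %d residues (%d water)\n",
              nrow(x$atoms),
              length(unique(residue_key(x$atoms))), nw))
  if (!is.null(x$coords)) cat("  coordinates attached\n")
  if (length(x$selections)) {
    cat("  selections:", paste(sprintf("%s[%d]", names(x$selections),
                                       lengths(x$selections)),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of atoms in a system
#' @param system An `mm_system`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resid, atoms$icode, sep = ":")
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  el <- substr(nm, 1, 1)
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")] <-
    two[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")]
  # hydrogens named like 1H, 2H
  el[grepl("^[0-9]*H", toupper(trimws(name)))] <- "H"
  toupper(el)
}

#' Residue names recognised as water
#'
#' @param extra Additional residue names to accept.
#' @return Character vector of residue-name patterns.
#' @export
water_residue_names <- function(extra = character()) {
  c("HOH", "WAT", "TIP3", "TIP4", "TIP", "SPC", "SOL", extra)
}

#' Attach role selections to a system
#'
#' Roles drive the MM-PBSA bookkeeping: `receptor` and `ligand` index sets
#' define the interaction terms, `water` the solvent analyses. Role sets must
#' be pairwise disjoint.
#'
#' @param system An `mm_system`.
#' @param receptor,ligand,water Integer atom index vectors (1-based). When
#'   `water` is `NULL` and the atom table flags waters, those atoms are used.
#' @export
set_roles <- function(system, receptor = NULL, ligand = NULL, water = NULL) {
  if (is.null(water) && any(system$atoms$is_water)) {
    water <- which(system$atoms$is_water)
  }
  sel <- system$selections
  if (!is.null(receptor)) sel$receptor <- as.integer(receptor)
  if (!is.null(ligand)) sel$ligand <- as.integer(ligand)
  if (!is.null(water)) sel$water <- as.integer(water)
  check_role_disjoint(sel)
  system$selections <- sel
  system
}

#' Trajectory container
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom), or a list
#'   of `n_atoms x 3` matrices.
#' @param frame_interval Time between stored frames, ps. Must be positive.
#' @param box Optional per-frame box edges: length-3 vector (constant box) or
#'   `n_frames x 3` matrix.
#' @param source Free-text provenance string.
#' @return An object of class `mm_trajectory`.
#' @export
new_trajectory <- function(coords, frame_interval = 1, box = NULL,
                           source = "memory") {
  if (is.list(coords)) {
    nf <- length(coords)
    na <- nrow(coords[[1]])
    arr <- array(0, dim = c(na, 3, nf))
    for (f in seq_len(nf)) {
      if (!identical(dim(coords[[f]]), dim(coords[[1]]))) {
        abort("all frames must have the same atom count")
      }
      arr[, , f] <- coords[[f]]
    }
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (frame_interval <= 0) abort("frame_interval must be positive (ps)")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = dim(coords)[3],
                                         ncol = 3, byrow = TRUE)
  }
  structure(list(coords = coords, frame_interval = frame_interval,
                 box = box, source = source),
            class = "mm_trajectory")
}

#' @export
print.mm_trajectory <- function(x, ...) {
  cat(sprintf("<mm_trajectory> %d frames x %d atoms, %.3g ps interval (%s)\n",
              n_frames(x), dim(x$coords)[1], x$frame_interval, x$source))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An `mm_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param trajectory An `mm_trajectory`.
#' @param i Frame number (1-based).
#' @export
frame_coords <- function(trajectory, i) {
  if (i < 1 || i > n_frames(trajectory)) abort("frame index out of range")
  trajectory$coords[, , i, drop = TRUE]
}

frame_box <- function(trajectory, i) {
  if (is.null(trajectory$box)) NULL else trajectory$box[i, ]
}
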