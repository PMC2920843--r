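#' Pairwise nonbonded energy between two atom groups
#'
#' CHARMM-form electrostatics and Lennard-Jones:
#' `elec = sum 332.0637 q_i q_j / (dielectric * r_ij)` and
#' `vdw = sum eps_ij ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with
#' `Rmin_ij = Rmin_half_i + Rmin_half_j`, `eps_ij = sqrt(eps_i eps_j)`.
#' No cutoff. Atom pairs closer than 1e-4 Angstrom raise a near-singularity
#' error naming the pair.
#'
#' @param system Parameterized `mm_system`.
#' @param frame Coordinate matrix (n_atoms x 3).
#' @param groupA,groupB Disjoint 1-based atom index vectors.
#' @param dielectric Relative dielectric for the Coulomb term.
#' @param box Optional periodic box edges for minimum-image distances.
#' @param by_residue When `TRUE`, also return residue-pair energy matrices
#'   (rows: residues of `groupA`; columns: residues of `groupB`).
#' @return An `energy_breakdown` list with `vdw`, `elec`, `torsion` (zero
#'   here) and `total`; with `by_residue`, matrices `elec_by_residue` and
#'   `vdw_by_residue` with residue-key dimnames.
#' @export
pairwise_nonbonded <- function(system, frame, groupA, groupB, dielectric = 2,
                               box = NULL, by_residue = FALSE) {
  if (length(intersect(groupA, groupB)) > 0) {
    abort("groupA and groupB must be disjoint")
  }
  if (length(groupA) == 0 || length(groupB) == 0) {
    abort("empty atom selection")
  }
  a <- system$atoms
  check_params(a, c(groupA, groupB))
  ga <- gb <- NULL; nga <- ngb <- 0L
  if (by_residue) {
    keys <- residue_key(a)
    ka <- factor(keys[groupA], levels = unique(keys[groupA]))
    kb <- factor(keys[groupB], levels = unique(keys[groupB]))
    ga <- as.integer(ka); gb <- as.integer(kb)
    nga <- nlevels(ka); ngb <- nlevels(kb)
  }
  res <- cpp_group_energy(frame, as.integer(groupA), as.integer(groupB),
                          a$mm_charge, a$lj_epsilon, a$lj_rmin_half,
                          dielectric, box, ga, gb, nga, ngb)
  out <- energy_breakdown(vdw = res$vdw, elec = res$elec, torsion = 0,
                          context = "pairwise_nonbonded")
  if (by_residue) {
    dimnames(res$elec_by_group) <- dimnames(res$vdw_by_group) <-
      list(levels(ka), levels(kb))
    out$elec_by_residue <- res$elec_by_group
    out$vdw_by_residue <- res$vdw_by_group
  }
  out
}

energy_breakdown <- function(vdw, elec, torsion = 0, context = "") {
  structure(list(vdw = vdw, elec = elec, torsion = torsion,
                 total = vdw + elec + torsion, context = context),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> %s\n  vdw %.4f  elec %.4f  torsion %.4f  total %.4f kcal/mol\n",
              x$context, x$vdw, x$elec, x$torsion, x$total))
  invisible(x)
}

check_params <- function(atoms, idx) {
  bad <- idx[is.na(atoms$mm_charge[idx]) | is.na(atoms$lj_epsilon[idx]) |
               is.na(atoms$lj_rmin_half[idx])]
  if (length(bad) > 0) {
    abort(sprintf("atoms without assigned parameters in selection (e.g. %s:%s)",
                  atoms$resname[bad[1]], atoms$name[bad[1]]))
  }
  invisible(TRUE)
}

#' Proper-torsion angle of four atoms
#'
#' @param frame Coordinate matrix.
#' @param i,j,k,l Atom indices defining the dihedral.
#' @return Angle in radians in (-pi, pi].
#' @export
dihedral_angle <- function(frame, i, j, k, l) {
  b1 <- frame[j, ] - frame[i, ]
  b2 <- frame[k, ] - frame[j, ]
  b3 <- frame[l, ] - frame[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    abort("undefined dihedral geometry: colinear atoms")
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsional energy of the dihedrals internal to a selection
#'
#' `sum k (1 + cos(n phi - delta))` over all proper torsions whose four
#' atoms lie inside `selection`.
#'
#' @param system An `mm_system` with a dihedral table.
#' @param frame Coordinate matrix.
#' @param selection Atom index vector.
#' @return Energy in kcal/mol.
#' @export
torsion_energy <- function(system, frame, selection) {
  d <- system$dihedrals
  if (is.null(d) || nrow(d) == 0) return(0)
  inside <- d$i %in% selection & d$j %in% selection &
    d$k %in% selection & d$l %in% selection
  d <- d[inside, ]
  if (nrow(d) == 0) return(0)
  e <- 0
  for (r in seq_len(nrow(d))) {
    phi <- dihedral_angle(frame, d$i[r], d$j[r], d$k[r], d$l[r])
    e <- e + d$k_dih[r] * (1 + cos(d$n[r] * phi - d$delta[r] * pi / 180))
  }
  e
}

#' Receptor-ligand interaction energy over a trajectory
#'
#' One van der Waals + electrostatic breakdown per frame, waters always
#' excluded from both groups. The solute-solute dielectric defaults to 2.
#'
#' @param system Parameterized `mm_system` with roles.
#' @param trajectory An `mm_trajectory`.
#' @param receptor,ligand Atom index vectors; default to the role
#'   selections.
#' @param dielectric Relative dielectric.
#' @return Tibble with columns `frame`, `time`, `vdw`, `elec`, `total`.
#' @export
interaction_energy <- function(system, trajectory, receptor = NULL,
                               ligand = NULL, dielectric = 2) {
  receptor <- receptor %||% system$selections$receptor
  ligand <- ligand %||% system$selections$ligand
  if (length(receptor) == 0 || length(ligand) == 0) {
    abort("empty receptor or ligand selection")
  }
  w <- which(system$atoms$is_water)
  receptor <- setdiff(receptor, w)
  ligand <- setdiff(ligand, w)
  a <- system$atoms
  check_params(a, c(receptor, ligand))
  nf <- n_frames(trajectory)
  vdw <- elec <- numeric(nf)
  for (f in seq_len(nf)) {
    res <- cpp_group_energy(frame_coords(trajectory, f),
                            as.integer(receptor), as.integer(ligand),
                            a$mm_charge, a$lj_epsilon, a$lj_rmin_half,
                            dielectric, NULL, NULL, NULL, 0L, 0L)
    vdw[f] <- res$vdw; elec[f] <- res$elec
  }
  tibble(frame = seq_len(nf),
         time = seq_len(nf) * trajectory$frame_interval,
         vdw = vdw, elec = elec, total = vdw + elec)
}

#' Intra-ligand internal energy (elec + vdw + torsion) per frame
#'
#' Bonded (1-2) and 1-3 pairs are excluded; 1-4 pairs are scaled by
#' `scale14` (default 1, i.e. full interaction).
#'
#' @inheritParams interaction_energy
#' @param ligand Atom index vector (defaults to the ligand role).
#' @param scale14 1-4 nonbonded scale factor.
#' @return Tibble with `frame`, `vdw`, `elec`, `torsion`, `total`.
#' @export
internal_energy <- function(system, trajectory, ligand = NULL,
                            dielectric = 2, scale14 = 1) {
  ligand <- ligand %||% system$selections$ligand
  if (length(ligand) < 2) abort("ligand selection needs at least 2 atoms")
  a <- system$atoms
  check_params(a, ligand)
  pl <- nonbonded_pairlist(system, ligand, scale14)
  nf <- n_frames(trajectory)
  vdw <- elec <- tor <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(trajectory, f)
    res <- cpp_pairlist_energy(co, pl$i, pl$j, pl$scale,
                               a$mm_charge, a$lj_epsilon, a$lj_rmin_half,
                               dielectric)
    vdw[f] <- res$vdw; elec[f] <- res$elec
    tor[f] <- torsion_energy(system, co, ligand)
  }
  tibble(frame = seq_len(nf), vdw = vdw, elec = elec, torsion = tor,
         total = vdw + elec + tor)
}

# All unique pairs within `idx` with exclusion-aware scale factors derived
# from the bond graph: 1-2 and 1-3 scale 0, 1-4 scale `scale14`, rest 1.
nonbonded_pairlist <- function(system, idx, scale14 = 1) {
  n <- length(idx)
  pos <- match(seq_len(n_atoms(system)), idx)
  adj <- vector("list", n)
  if (!is.null(system$bonds)) {
    for (r in seq_len(nrow(system$bonds))) {
      i <- pos[system$bonds[r, 1]]; j <- pos[system$bonds[r, 2]]
      if (!is.na(i) && !is.na(j)) {
        adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  # graph distances up to 3 bonds
  dist_class <- function(i) {
    d <- rep(Inf, n); d[i] <- 0
    frontier <- i
    for (step in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[nxt] == Inf]
      if (length(nxt) == 0) break
      d[nxt] <- step
      frontier <- nxt
    }
    d
  }
  pi_ <- pj_ <- integer(0); sc <- numeric(0)
  for (i in seq_len(n - 1)) {
    d <- dist_class(i)
    for (j in (i + 1):n) {
      s <- if (d[j] <= 2) 0 else if (d[j] == 3) scale14 else 1
      pi_ <- c(pi_, idx[i]); pj_ <- c(pj_, idx[j]); sc <- c(sc, s)
    }
  }
  list(i = pi_, j = pj_, scale = sc)
}

#' Ligand deformation penalty
#'
#' Difference of the mean intra-ligand internal energy between the bound and
#' unbound ensembles, with the standard error propagated in quadrature from
#' the 20-block standard errors of each series.
#'
#' @param bound,unbound Per-frame internal-energy series (numeric vectors or
#'   tibbles from [internal_energy()], in which case the `total` column is
#'   used).
#' @param n_blocks Blocks for the standard error (default 20).
#' @return List with `value` and `sem` (kcal/mol).
#' @export
deformation_penalty <- function(bound, unbound, n_blocks = 20) {
  bv <- if (is.data.frame(bound)) bound$total else as.numeric(bound)
  uv <- if (is.data.frame(unbound)) unbound$total else as.numeric(unbound)
  if (length(bv) == 0 || length(uv) == 0) abort("empty energy series")
  sem <- function(x) if (length(x) >= n_blocks) block_sem(x, n_blocks) else NA_real_
  list(value = mean(bv) - mean(uv),
       sem = sqrt(sem(bv)^2 + sem(uv)^2))
}

#' Interaction energy of one water with the rest of the system
#'
#' Full (unhalved) Coulomb + Lennard-Jones interaction of the chosen water
#' molecule with every other atom, with minimum-image distances when a box
#' is present. The explicit-solvent dielectric defaults to 1.
#'
#' @param system Parameterized `mm_system`.
#' @param frame Coordinate matrix.
#' @param water Either a water residue id (matched among water atoms) or a
#'   vector of atom indices.
#' @param dielectric Relative dielectric (default 1).
#' @param box Optional periodic box edges (defaults to the system box).
#' @return Energy in kcal/mol (0 for an isolated water).
#' @export
water_environment_energy <- function(system, frame, water, dielectric = 1,
                                     box = system$box) {
  a <- system$atoms
  watoms <- if (length(water) > 1) as.integer(water) else
    which(a$is_water & a$resid == water)
  if (length(watoms) == 0) abort("water selection matched no atoms")
  rest <- setdiff(seq_len(nrow(a)), watoms)
  if (length(rest) == 0) return(0)
  check_params(a, c(watoms, rest))
  res <- cpp_group_energy(frame, watoms, as.integer(rest),
                          a$mm_charge, a$lj_epsilon, a$lj_rmin_half,
                          dielectric, box, NULL, NULL, 0L, 0L)
  res$vdw + res$elec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
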