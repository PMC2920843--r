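#' Generate a toy receptor-ligand complex with checkable energetics
#'
#' Builds a rigid receptor of ~20 charged Lennard-Jones sites and a small
#' peptide-like ligand of `n_ligand_residues` residues. Each ligand residue
#' carries mainchain atoms (N, CA, C, O) and a two-atom sidechain (CB, CG)
#' with one proper sidechain torsion (N-CA-CB-CG), so the
#' mainchain/sidechain partition and torsional terms are all exercised. All
#' force-field constants are recorded on the system, so every energy is
#' reproducible by a brute-force double loop.
#'
#' Bound frames are Gaussian jitter of the ligand about the docked pose
#' (receptor held rigid); unbound frames jitter the ligand about a relaxed
#' pose with rotated sidechain torsions, giving a non-zero deformation
#' penalty.
#'
#' @param n_ligand_residues Number of ligand residues (2 to 6).
#' @param seed RNG seed; the generator is deterministic under it.
#' @param n_frames Frames per trajectory.
#' @param jitter Per-atom Gaussian jitter, Angstrom.
#' @return List with `system` (roles set), `bound` and `unbound`
#'   trajectories.
#' @export
gen_toy_complex <- function(n_ligand_residues = 3, seed = 1, n_frames = 30,
                            jitter = 0.08) {
  if (n_ligand_residues < 2 || n_ligand_residues > 6) {
    abort("n_ligand_residues must be between 2 and 6")
  }
  set.seed(seed)
  n_rec <- 20
  # receptor: blob of parameterized sites left of the interface plane
  rec_xyz <- matrix(rnorm(3 * n_rec, sd = 2.6), ncol = 3)
  rec_xyz[, 1] <- pmin(rec_xyz[, 1] - 6, -2.5)
  rec_atoms <- tibble(
    name = sprintf("R%d", seq_len(n_rec)), element = "C",
    resname = "REC", resid = rep(1:4, each = 5), chain = "A",
    mass = 12.011,
    mm_charge = round(runif(n_rec, -0.4, 0.4), 3),
    parse_charge = round(runif(n_rec, -0.4, 0.4), 3),
    lj_epsilon = round(runif(n_rec, 0.05, 0.2), 4),
    lj_rmin_half = round(runif(n_rec, 1.6, 2.0), 3),
    radius_pb = 1.8, radius_sasa = 1.8, is_water = FALSE
  )

  lig_atoms <- list(); lig_xyz <- list(); bonds <- list(); dihedrals <- list()
  names_res <- c("N", "CA", "C", "O", "CB", "CG")
  elem_res <- c("N", "C", "C", "O", "C", "C")
  q_res <- c(-0.35, 0.10, 0.45, -0.45, 0.05, 0.20)
  offset <- 0
  for (r in seq_len(n_ligand_residues)) {
    base <- c(2.0, (r - (n_ligand_residues + 1) / 2) * 3.9, 0)
    local <- rbind(
      N  = c(0.0, -1.45, 0.0),
      CA = c(0.5, -0.2,  0.3),
      C  = c(0.0,  1.05, 0.0),
      O  = c(-0.9, 1.6, -0.6),
      CB = c(1.9, -0.2,  0.6),
      CG = c(2.7,  0.0,  1.8)
    )
    lig_xyz[[r]] <- sweep(local, 2, base, "+")
    lig_atoms[[r]] <- tibble(
      name = names_res, element = elem_res, resname = "GLX",
      resid = 10 + r, chain = "B", mass = c(14.007, 12.011, 12.011,
                                            15.999, 12.011, 12.011),
      mm_charge = q_res + round(runif(6, -0.05, 0.05), 3),
      parse_charge = q_res, lj_epsilon = c(0.2, 0.1, 0.11, 0.12, 0.1, 0.08),
      lj_rmin_half = c(1.85, 2.0, 2.0, 1.7, 2.0, 2.0),
      radius_pb = c(1.5, 1.7, 1.7, 1.4, 1.7, 1.7),
      radius_sasa = c(1.55, 1.7, 1.7, 1.52, 1.7, 1.7), is_water = FALSE
    )
    b <- n_rec + offset
    bonds[[length(bonds) + 1]] <-
      rbind(c(b + 1, b + 2), c(b + 2, b + 3), c(b + 3, b + 4),
            c(b + 2, b + 5), c(b + 5, b + 6))
    if (r > 1) bonds[[length(bonds) + 1]] <- rbind(c(b - 3, b + 1))
    dihedrals[[r]] <- tibble(
      i = b + 1, j = b + 2, k = b + 5, l = b + 6,
      k_dih = round(runif(1, 0.3, 1.0), 3),
      n = sample(1:3, 1), delta = 0
    )
    offset <- offset + 6
  }
  atoms <- dplyr::bind_rows(c(list(rec_atoms), lig_atoms))
  docked <- rbind(rec_xyz, do.call(rbind, lig_xyz))
  system <- new_system(atoms, coords = docked,
                       bonds = do.call(rbind, bonds),
                       dihedrals = dplyr::bind_rows(dihedrals))
  system <- set_roles(system, receptor = seq_len(n_rec),
                      ligand = n_rec + seq_len(6 * n_ligand_residues))

  # relaxed (unbound) pose: shift away and swing each sidechain
  relaxed <- docked
  lig_idx <- system$selections$ligand
  relaxed[lig_idx, 1] <- relaxed[lig_idx, 1] + 30
  for (r in seq_len(n_ligand_residues)) {
    cb <- n_rec + (r - 1) * 6 + 5
    cg <- cb + 1
    ca <- n_rec + (r - 1) * 6 + 2
    axis <- relaxed[cb, ] - relaxed[ca, ]
    axis <- axis / sqrt(sum(axis^2))
    ang <- 35 * pi / 180
    v <- relaxed[cg, ] - relaxed[cb, ]
    cross <- c(axis[2] * v[3] - axis[3] * v[2],
               axis[3] * v[1] - axis[1] * v[3],
               axis[1] * v[2] - axis[2] * v[1])
    relaxed[cg, ] <- relaxed[cb, ] + v * cos(ang) + cross * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang))
  }

  jitter_traj <- function(pose) {
    arr <- array(0, dim = c(nrow(pose), 3, n_frames))
    for (f in seq_len(n_frames)) {
      d <- matrix(0, nrow(pose), 3)
      d[lig_idx, ] <- matrix(rnorm(3 * length(lig_idx), sd = jitter),
                             ncol = 3)
      arr[, , f] <- pose + d
    }
    arr
  }
  bound <- new_trajectory(jitter_traj(docked), frame_interval = 10,
                          source = "gen_toy_complex bound")
  unbound <- new_trajectory(jitter_traj(relaxed), frame_interval = 10,
                            source = "gen_toy_complex unbound")
  list(system = system, bound = bound, unbound = unbound)
}

#' Hydrogen-bond census fixture with known ground truth
#'
#' A hand-built receptor/ligand/water arrangement containing exactly one
#' direct receptor-ligand hydrogen bond and exactly one bridging water
#' (hydrogen-bonded to both sides) under the default criteria.
#'
#' @param variant `"default"` (1 direct, 1 bridged), `"no_bridge"` (bridge
#'   water removed), or `"stretched"` (direct donor-acceptor distance pushed
#'   past the cutoff).
#' @return List with `system` (roles set, coordinates attached) and `truth`,
#'   the expected `c(direct, bridged)` counts.
#' @export
gen_hbond_fixture <- function(variant = c("default", "no_bridge",
                                          "stretched")) {
  variant <- match.arg(variant)
  direct_nz <- if (variant == "stretched") 4.1 else 2.9
  atoms <- tibble(
    name    = c("C", "O", "N", "HN", "N", "H", "C", "O",
                "OH2", "H1", "H2"),
    element = c("C", "O", "N", "H", "N", "H", "C", "O", "O", "H", "H"),
    resname = c(rep("REC", 4), rep("LIG", 4), rep("TIP3", 3)),
    resid   = c(rep(1, 4), rep(2, 4), rep(3, 3)),
    chain   = c(rep("A", 4), rep("B", 4), rep("W", 3))
  )
  xyz <- rbind(
    c(0, 0, -1.23),            # REC C
    c(0, 0, 0),                # REC O   (acceptor of the direct bond)
    c(6, 0, 0),                # REC N   (donor to the bridge water)
    c(6, 0, 1.0),              # REC HN
    c(0, 0, direct_nz),        # LIG N   (direct donor)
    c(0, 0, direct_nz - 1.0),  # LIG H
    c(6, 0, 7.03),             # LIG C
    c(6, 0, 5.8),              # LIG O   (acceptor from the bridge water)
    c(6, 0, 2.9),              # WAT O
    c(6, 0, 2.9 + 0.9572),     # WAT H1 (donates to LIG O)
    c(6 + 0.9266, 0, 2.9 - 0.2396) # WAT H2 (points away)
  )
  bonds <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10), c(9, 11))
  if (variant == "no_bridge") {
    keep <- 1:8
    atoms <- atoms[keep, ]
    xyz <- xyz[keep, , drop = FALSE]
    bonds <- bonds[1:4, , drop = FALSE]
  }
  system <- new_system(atoms, coords = xyz, bonds = bonds)
  nr <- nrow(atoms)
  system <- set_roles(system, receptor = 1:4, ligand = 5:8,
                      water = if (nr > 8) 9:11 else integer(0))
  truth <- switch(variant,
    default = c(direct = 1, bridged = 1),
    no_bridge = c(direct = 1, bridged = 0),
    stretched = c(direct = 0, bridged = 1))
  list(system = system, truth = truth)
}
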