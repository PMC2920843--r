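#' Monte Carlo water box generator
#'
#' Samples equilibrium configurations of rigid 3-site (TIP3P-parameter)
#' waters in a cubic periodic box by single-molecule translation/rotation
#' Metropolis moves with molecule-based minimum image and a nonbonded cutoff.
#' The box edge follows from the water count and the target mass density.
#' Snapshots are decorrelated: successive stored configurations are separated
#' by at least `5 * n_waters` attempted and `n_waters` accepted moves.
#'
#' @param n_waters Number of waters (>= 8).
#' @param density Mass density, g/cm^3.
#' @param temperature Temperature, K.
#' @param n_snapshots Configurations to store.
#' @param n_equil_moves Attempted moves discarded as equilibration.
#' @param seed Optional RNG seed (the sampler uses R's RNG stream).
#' @param cutoff Nonbonded cutoff on the O-O distance, Angstrom.
#' @param dtrans,drot Maximum translation (Angstrom) and rotation (rad) per
#'   move.
#' @return List with `system` (parameterized `mm_system`), `trajectory`
#'   (`mm_trajectory` with the periodic box), `box_edge` (Angstrom),
#'   `acceptance` (fraction of accepted moves, logged), and
#'   `snapshot_energy` (total pair energy per stored configuration,
#'   kcal/mol, at the sampling cutoff).
#' @export
gen_water_box <- function(n_waters = 216, density = 0.997, temperature = 300,
                          n_snapshots = 200, n_equil_moves = 200000,
                          seed = NULL, cutoff = 8.5, dtrans = 0.15,
                          drot = 0.3) {
  if (density <= 0) abort("density must be positive (g/cm^3)")
  if (n_waters < 8) abort("need at least 8 waters")
  if (!is.null(seed)) set.seed(seed)
  L <- water_box_edge(n_waters, density)
  if (cutoff > L / 2) cutoff <- L / 2

  geom <- water_geometry()
  # loose cubic lattice start with random orientations
  nside <- ceiling(n_waters^(1 / 3))
  cell <- L / nside
  coords <- matrix(0, 3 * n_waters, 3)
  m <- 0
  for (i in seq_len(nside)) for (j in seq_len(nside)) for (k in seq_len(nside)) {
    if (m >= n_waters) next
    m <- m + 1
    o <- (c(i, j, k) - 0.5) * cell
    rot <- quat_to_matrix(rand_quaternion(1)[1, ])
    w <- geom %*% t(rot)
    coords[(3 * m - 2):(3 * m), ] <- sweep(w, 2, o, "+")
  }

  pars <- tip3p_parameters()
  site <- pars[pars$resname == "TIP3" & pars$name %in% c("OH2", "H1"), ]
  site_q <- c(site$mm_charge[site$name == "OH2"][1],
              rep(site$mm_charge[site$name == "H1"][1], 2))
  site_eps <- c(site$lj_epsilon[site$name == "OH2"][1],
                rep(site$lj_epsilon[site$name == "H1"][1], 2))
  site_rminh <- c(site$lj_rmin_half[site$name == "OH2"][1],
                  rep(site$lj_rmin_half[site$name == "H1"][1], 2))

  res <- cpp_mc_water(coords, L, temperature, cutoff,
                      as.integer(n_equil_moves), as.integer(n_snapshots),
                      as.integer(5 * n_waters), as.integer(n_waters),
                      dtrans, drot, site_q, site_eps, site_rminh)

  atoms <- tibble(
    name = rep(c("OH2", "H1", "H2"), n_waters),
    element = rep(c("O", "H", "H"), n_waters),
    resname = "TIP3",
    resid = rep(seq_len(n_waters), each = 3),
    chain = "W"
  )
  system <- new_system(atoms, coords = res$frames[, , 1], box = rep(L, 3))
  system <- assign_parameters(system, pars)
  system <- set_roles(system)
  traj <- new_trajectory(res$frames, frame_interval = 10,
                         box = rep(L, 3), source = "gen_water_box")
  list(system = system, trajectory = traj, box_edge = L,
       acceptance = res$acceptance, snapshot_energy = res$snapshot_energy)
}

#' Cubic box edge for a given water count and density
#' @param n_waters Water count.
#' @param density g/cm^3.
#' @return Edge length in Angstrom.
#' @export
water_box_edge <- function(n_waters, density) {
  m_water <- 18.0154            # g/mol
  n_av <- 6.02214076e23
  v_cm3 <- n_waters * m_water / (n_av * density)
  (v_cm3 * 1e24)^(1 / 3)
}
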