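# Shared fixtures built in code.

born_ion_system <- function(q = 1, radius = 2, at = c(0.05, -0.03, 0.08)) {
  atoms <- tibble::tibble(
    name = "X", element = "C", resname = "ION", resid = 1, chain = "A",
    mass = 12, mm_charge = q, parse_charge = q, lj_epsilon = 0.1,
    lj_rmin_half = radius, radius_pb = radius, radius_sasa = 1.9,
    is_water = FALSE)
  new_system(atoms, coords = matrix(at, 1))
}

two_site_system <- function(q = c(1, -1), r = 3.320637,
                            eps = c(0, 0), rminh = c(1, 1)) {
  atoms <- tibble::tibble(
    name = c("A", "B"), element = "C", resname = "TST", resid = c(1, 2),
    chain = "A", mass = 12, mm_charge = q, parse_charge = q,
    lj_epsilon = eps, lj_rmin_half = rminh, radius_pb = 1.5,
    radius_sasa = 1.5, is_water = FALSE)
  new_system(atoms, coords = rbind(c(0, 0, 0), c(r, 0, 0)))
}

water_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.736   6.822  -4.147  1.00  0.00           C",
    "HETATM    4  O   HOH A   2       2.000   1.000   0.000  1.00  0.00           O",
    "HETATM    5  H1  HOH A   2       2.900   1.200   0.000  1.00  0.00           H",
    "HETATM    6  H2  HOH A   2       1.600   1.900   0.100  1.00  0.00           H",
    "HETATM    7  O   HOH A   3       8.000   1.000   0.000  1.00  0.00           O",
    "HETATM    8  H1  HOH A   3       8.900   1.200   0.000  1.00  0.00           H",
    "HETATM    9  H2  HOH A   3       7.600   1.900   0.100  1.00  0.00           H")
}

# Trajectory of a 3-atom group fluctuating along known internal modes
# (orthogonal to the mass-weighted rigid-body space), plus the frequencies
# (cm^-1) implied by the chosen mode variances.
internal_mode_fixture <- function(n_frames = 10000, sds = c(0.25, 0.15, 0.08),
                                  temperature = 298, seed = 31) {
  set.seed(seed)
  x0 <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(0.8, 1.4, 0))
  masses <- c(12, 16, 14)
  mw <- rep(sqrt(masses), each = 3)
  rb <- matrix(0, 9, 6)
  for (d in 1:3) rb[seq(d, 9, 3), d] <- sqrt(masses)
  ctr <- colSums(x0 * masses) / sum(masses)
  xc <- sweep(x0, 2, ctr)
  axes <- diag(3)
  for (d in 1:3) {
    v <- t(sapply(1:3, function(i) {
      c(axes[d, 2] * xc[i, 3] - axes[d, 3] * xc[i, 2],
        axes[d, 3] * xc[i, 1] - axes[d, 1] * xc[i, 3],
        axes[d, 1] * xc[i, 2] - axes[d, 2] * xc[i, 1])
    }))
    rb[, 3 + d] <- as.vector(t(v)) * mw
  }
  internal <- qr.Q(qr(rb), complete = TRUE)[, 7:9]
  coefs <- sweep(matrix(rnorm(n_frames * 3), n_frames), 2, sds, "*")
  frames <- array(0, dim = c(3, 3, n_frames))
  for (f in seq_len(n_frames)) {
    disp <- matrix((internal %*% coefs[f, ]) / mw, ncol = 3, byrow = TRUE)
    frames[, , f] <- x0 + disp
  }
  atoms <- tibble::tibble(
    name = c("C1", "O1", "N1"), element = c("C", "O", "N"),
    resname = "TST", resid = 1, chain = "A", mass = masses)
  kbt_j <- 1.380649e-23 * temperature
  lam_si <- sds^2 * 1.66053906660e-27 * 1e-20
  list(system = new_system(atoms, coords = x0),
       trajectory = new_trajectory(frames, 1),
       expected_frequencies = sort(sqrt(kbt_j / lam_si) /
                                     (2 * pi * 2.99792458e10)))
}

# Brute-force nonbonded double loop (independent of the package kernels).
brute_nonbonded <- function(system, co, ia, ib, dielectric) {
  a <- system$atoms
  elec <- 0; vdw <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((co[i, ] - co[j, ])^2))
    elec <- elec + 332.0637 * a$mm_charge[i] * a$mm_charge[j] / (dielectric * r)
    eij <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    if (eij > 0) {
      rm <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
      vdw <- vdw + eij * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  list(elec = elec, vdw = vdw)
}

random_rotation <- function() quat_to_matrix(rand_quaternion(1)[1, ])
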