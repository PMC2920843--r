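test_that("Coulomb term reproduces the closed form", {
  # +1e and -1e at 3.320637 A with dielectric 2: 332.0637/(2*3.320637) = 50
  sys <- two_site_system(q = c(1, -1), r = 3.320637)
  e <- pairwise_nonbonded(sys, sys$coords, 1, 2, dielectric = 2)
  expect_equal(e$elec, -50, tolerance = 1e-9)
  expect_equal(e$vdw, 0)
})

test_that("LJ minimum sits at -eps_ij for touching identical atoms", {
  sys <- two_site_system(q = c(0, 0), r = 2, eps = c(0.1, 0.1),
                         rminh = c(1, 1))
  e <- pairwise_nonbonded(sys, sys$coords, 1, 2, dielectric = 1)
  expect_equal(e$vdw, -0.1, tolerance = 1e-12)
})

test_that("near-singular contacts and overlapping groups error", {
  sys <- two_site_system(r = 1e-6)
  expect_error(pairwise_nonbonded(sys, sys$coords, 1, 2), "near-singular")
  sys2 <- two_site_system()
  expect_error(pairwise_nonbonded(sys2, sys2$coords, 1:2, 2), "disjoint")
})

test_that("nonbonded energy is symmetric, decomposable and rigid-invariant", {
  tc <- gen_toy_complex(3, seed = 8, n_frames = 1)
  co <- frame_coords(tc$bound, 1)
  rec <- tc$system$selections$receptor
  lig <- tc$system$selections$ligand
  ab <- pairwise_nonbonded(tc$system, co, rec, lig)
  ba <- pairwise_nonbonded(tc$system, co, lig, rec)
  expect_equal(ab$elec, ba$elec, tolerance = 1e-13)
  expect_equal(ab$vdw, ba$vdw, tolerance = 1e-13)
  # union decomposition over disjoint halves of the receptor
  h1 <- rec[1:10]; h2 <- rec[11:20]
  e1 <- pairwise_nonbonded(tc$system, co, h1, lig)
  e2 <- pairwise_nonbonded(tc$system, co, h2, lig)
  expect_equal(e1$elec + e2$elec, ab$elec, tolerance = 1e-12)
  expect_equal(e1$vdw + e2$vdw, ab$vdw, tolerance = 1e-12)
  # global rotation + translation
  set.seed(1)
  rot <- random_rotation()
  co2 <- sweep(co %*% t(rot), 2, c(5, -3, 2), "+")
  e3 <- pairwise_nonbonded(tc$system, co2, rec, lig)
  expect_equal(e3$elec, ab$elec, tolerance = 1e-9)
  expect_equal(e3$vdw, ab$vdw, tolerance = 1e-9)
})

test_that("electrostatics are linear in 1/dielectric, vdw unchanged", {
  tc <- gen_toy_complex(2, seed = 9, n_frames = 1)
  co <- frame_coords(tc$bound, 1)
  rec <- tc$system$selections$receptor
  lig <- tc$system$selections$ligand
  e1 <- pairwise_nonbonded(tc$system, co, rec, lig, dielectric = 2)
  e2 <- pairwise_nonbonded(tc$system, co, rec, lig, dielectric = 4)
  expect_equal(e2$elec, e1$elec / 2, tolerance = 1e-12)
  expect_identical(e2$vdw, e1$vdw)
})

test_that("torsion energy follows k(1 + cos(n phi - delta))", {
  # explicit 4-atom geometries with known dihedral angles
  make_sys <- function(phi_deg, k_dih, n_per, delta = 0) {
    phi <- phi_deg * pi / 180
    co <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1.5),
                c(cos(phi), sin(phi), 1.5))
    atoms <- tibble::tibble(name = paste0("C", 1:4), element = "C",
                            resname = "TOR", resid = 1, chain = "A",
                            mass = 12)
    dih <- tibble::tibble(i = 1, j = 2, k = 3, l = 4, k_dih = 0,
                          n = 0, delta = delta)
    dih$k_dih <- k_dih
    dih$n <- n_per
    new_system(atoms, coords = co, dihedrals = dih)
  }
  s <- make_sys(180, 1, 1)
  expect_equal(abs(dihedral_angle(s$coords, 1, 2, 3, 4)), pi,
               tolerance = 1e-9)
  expect_equal(torsion_energy(s, s$coords, 1:4), 0, tolerance = 1e-9)
  s <- make_sys(0, 1, 1)
  expect_equal(torsion_energy(s, s$coords, 1:4), 2, tolerance = 1e-9)
  # k = 0.5, n = 3 at phi = 60 degrees: 0.5 (1 + cos 180) = 0,
  # confirmed by the independent geometric dihedral above
  s <- make_sys(60, 0.5, 3)
  expect_equal(abs(dihedral_angle(s$coords, 1, 2, 3, 4)), pi / 3,
               tolerance = 1e-9)
  expect_equal(torsion_energy(s, s$coords, 1:4), 0, tolerance = 1e-9)
  # colinear geometry errors
  bad <- s
  bad$coords <- rbind(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1.5), c(0, 0, 2.5))
  expect_error(torsion_energy(bad, bad$coords, 1:4), "colinear")
})

test_that("interaction energy decays to zero at large separation", {
  tc <- gen_toy_complex(2, seed = 10, n_frames = 1)
  # neutralize each group so the monopole term does not linger
  a <- tc$system$atoms
  rec <- tc$system$selections$receptor
  lig <- tc$system$selections$ligand
  a$mm_charge[rec] <- a$mm_charge[rec] - mean(a$mm_charge[rec])
  a$mm_charge[lig] <- a$mm_charge[lig] - mean(a$mm_charge[lig])
  tc$system$atoms <- a
  co <- frame_coords(tc$bound, 1)
  co[lig, 1] <- co[lig, 1] + 500
  t1 <- new_trajectory(array(co, dim = c(nrow(co), 3, 1)), 1)
  e <- interaction_energy(tc$system, t1)
  expect_lt(abs(e$elec), 1e-3)
  expect_lt(abs(e$vdw), 1e-3)
})

test_that("internal energy respects exclusions and matches brute force", {
  # bonded two-atom ligand contributes nothing
  atoms <- tibble::tibble(name = c("A", "B"), element = "C", resname = "DI",
                          resid = 1, chain = "A", mass = 12, mm_charge = 0.3,
                          parse_charge = 0.3, lj_epsilon = 0.1,
                          lj_rmin_half = 1.8, radius_pb = 1.8,
                          radius_sasa = 1.8, is_water = FALSE)
  di <- new_system(atoms, coords = rbind(c(0, 0, 0), c(1.5, 0, 0)),
                   bonds = rbind(c(1, 2)))
  tr <- new_trajectory(array(di$coords, dim = c(2, 3, 2)), 1)
  e <- internal_energy(di, tr, ligand = 1:2)
  expect_equal(e$total, c(0, 0))

  tc <- gen_toy_complex(2, seed = 12, n_frames = 3)
  lig <- tc$system$selections$ligand
  got <- internal_energy(tc$system, tc$bound, scale14 = 0.5)
  co <- frame_coords(tc$bound, 2)
  pl <- hydrobind:::nonbonded_pairlist(tc$system, lig, 0.5)
  a <- tc$system$atoms
  want <- 0
  for (p in seq_along(pl$i)) {
    if (pl$scale[p] == 0) next
    i <- pl$i[p]; j <- pl$j[p]
    r <- sqrt(sum((co[i, ] - co[j, ])^2))
    want <- want + pl$scale[p] *
      (332.0637 * a$mm_charge[i] * a$mm_charge[j] / (2 * r) +
         sqrt(a$lj_epsilon[i] * a$lj_epsilon[j]) *
         (((a$lj_rmin_half[i] + a$lj_rmin_half[j]) / r)^12 -
            2 * ((a$lj_rmin_half[i] + a$lj_rmin_half[j]) / r)^6))
  }
  want <- want + torsion_energy(tc$system, co, lig)
  expect_equal(got$total[2], want, tolerance = 1e-8)

  # rigid ligand: constant series
  still <- new_trajectory(array(frame_coords(tc$bound, 1),
                                dim = c(n_atoms(tc$system), 3, 4)), 1)
  es <- internal_energy(tc$system, still)
  expect_equal(var(es$total), 0)
})

test_that("deformation penalty is a difference of means", {
  x <- c(1, 2, 3, 4)
  expect_equal(deformation_penalty(x, x, n_blocks = 2)$value, 0)
  expect_equal(deformation_penalty(x + 3, x, n_blocks = 2)$value, 3)
})

test_that("water environment energy matches an explicit dimer sum", {
  geom <- water_geometry()
  w2 <- sweep(geom %*% t(random_rotation()), 2, c(3.1, 0.4, -0.2), "+")
  atoms <- tibble::tibble(
    name = rep(c("OH2", "H1", "H2"), 2), element = rep(c("O", "H", "H"), 2),
    resname = "TIP3", resid = rep(1:2, each = 3), chain = "W")
  sys <- new_system(atoms, coords = rbind(geom, w2))
  sys <- assign_parameters(sys, tip3p_parameters())
  got <- water_environment_energy(sys, sys$coords, water = 1)
  # 9 Coulomb terms + all LJ site pairs, by hand
  a <- sys$atoms
  want <- 0
  for (i in 1:3) for (j in 4:6) {
    r <- sqrt(sum((sys$coords[i, ] - sys$coords[j, ])^2))
    want <- want + 332.0637 * a$mm_charge[i] * a$mm_charge[j] / r
    eij <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    rm <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    want <- want + eij * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(got, want, tolerance = 1e-10)
  # isolated single water
  solo <- new_system(atoms[1:3, ], coords = geom)
  solo <- assign_parameters(solo, tip3p_parameters())
  expect_equal(water_environment_energy(solo, solo$coords, 1), 0)
})
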