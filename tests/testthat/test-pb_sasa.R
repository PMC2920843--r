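pb_fast <- list(dimension = 49, margin = 15, final_spacing = 0.5, levels = 2)

test_that("charge spreading conserves total charge and maps place eps", {
  sys <- born_ion_system(q = 1, radius = 2, at = c(0, 0, 0))
  n <- 41L; h <- 0.5
  maps <- hydrobind:::cpp_pb_maps(sys$coords, 1, 2, n, h, c(0, 0, 0),
                                  2, 80, 0, 2, 1.4)
  expect_equal(sum(maps$rho), 1, tolerance = 1e-12)
  mid <- (n + 1) / 2
  idx <- function(i, j, k) i + n * (j - 1) + n^2 * (k - 1)
  expect_gt(maps$level[idx(mid, mid, mid)], 0)       # centre inside
  expect_equal(maps$epsx[idx(mid, mid, mid)], 2)
  far <- idx(mid + 16, mid, mid)                     # 8 A out
  expect_lt(maps$level[far], 0)
  expect_equal(maps$epsx[far], 80)
})

test_that("molecular surface closes the reentrant gap between two atoms", {
  # two radius-1.6 atoms 4.0 A apart: the midpoint is outside both vdW
  # spheres but a 1.4 A probe cannot pass between them
  co <- rbind(c(-2, 0, 0), c(2, 0, 0))
  n <- 61L; h <- 0.25
  maps <- hydrobind:::cpp_pb_maps(co, c(0, 0), c(1.6, 1.6), n, h,
                                  c(0, 0, 0), 2, 80, 0, 2, 1.4)
  idx <- function(i, j, k) i + n * (j - 1) + n^2 * (k - 1)
  mid <- (n + 1) / 2
  # dense-sample oracle: no probe centre on the SAS-complement can reach
  # the midpoint within 1.4 A
  grid <- as.matrix(expand.grid(x = seq(-6, 6, 0.1), y = seq(-6, 6, 0.1),
                                z = 0))
  da <- pmin(sqrt((grid[, 1] + 2)^2 + grid[, 2]^2) - 3.0,
             sqrt((grid[, 1] - 2)^2 + grid[, 2]^2) - 3.0)
  outside_sas <- grid[da >= 0, ]
  mind <- min(sqrt(outside_sas[, 1]^2 + outside_sas[, 2]^2))
  expect_gt(mind, 1.4)  # oracle: midpoint is inside the molecular surface
  expect_gt(maps$level[idx(mid, mid, mid)], 0)
  # a point 3 A above the axis is solvent in both views
  up <- idx(mid, mid + 3 / h, mid)
  expect_lt(maps$level[up], 0)
})

test_that("PB solver reproduces the Born ion within 3%", {
  sys <- born_ion_system()
  res <- pb_solvation(sys, sys$coords, eps_in = 1, eps_out = 80,
                      ionic_strength = 0, dimension = 65, margin = 20,
                      final_spacing = 0.35, levels = 3)
  born <- -332.0637 / (2 * 2) * (1 - 1 / 80)
  expect_lt(abs(res$energy - born) / abs(born), 0.03)
  expect_lt(res$residual, 1e-6)
})

test_that("all-zero charges give zero solvation energy", {
  sys <- born_ion_system(q = 0)
  res <- do.call(pb_solvation, c(list(sys, sys$coords, eps_in = 1,
                                      ionic_strength = 0), pb_fast))
  expect_equal(res$energy, 0)
})

test_that("distant Born ions decompose additively", {
  # closed-form oracle: on a shared grid, the pair energy is the sum of the
  # single-ion energies plus the analytic screening change of their
  # Coulomb interaction, q1 q2 (1/eps_out - 1/eps_in) * 332.0637 / r
  atoms <- dplyr::bind_rows(born_ion_system()$atoms,
                            born_ion_system()$atoms)
  atoms$resid <- c(1, 2)
  sys <- new_system(atoms, coords = rbind(c(-30, 0, 0), c(30, 0, 0)))
  args <- list(eps_in = 1, eps_out = 80, ionic_strength = 0,
               dimension = 97, margin = 15, final_spacing = 0.72,
               levels = 3, center = c(0, 0, 0), extent = 64)
  pair <- do.call(pb_solvation, c(list(sys, sys$coords), args))$energy
  s1 <- born_ion_system(at = c(-30, 0, 0))
  s2 <- born_ion_system(at = c(30, 0, 0))
  e1 <- do.call(pb_solvation, c(list(s1, s1$coords), args))$energy
  e2 <- do.call(pb_solvation, c(list(s2, s2$coords), args))$energy
  cross <- 332.0637 / 60 * (1 / 80 - 1)
  expect_lt(abs(pair - (e1 + e2 + cross)) / abs(pair), 0.01)
})

test_that("PB energy magnitude converges monotonically with refinement", {
  sys <- born_ion_system()
  es <- vapply(c(0.55, 0.42, 0.3), function(hf) {
    pb_solvation(sys, sys$coords, eps_in = 1, eps_out = 80,
                 ionic_strength = 0, dimension = 49, margin = 12,
                 final_spacing = hf, levels = 2)$energy
  }, numeric(1))
  born <- -332.0637 / 4 * (1 - 1 / 80)
  errs <- abs(es - born)
  expect_true(all(diff(errs) < 0))
})

test_that("PB energy is robust to sub-grid translations", {
  sys1 <- born_ion_system(at = c(0, 0, 0))
  sys2 <- born_ion_system(at = c(0.21, -0.13, 0.17))
  args <- list(eps_in = 1, eps_out = 80, ionic_strength = 0,
               dimension = 49, margin = 12, final_spacing = 0.45,
               levels = 2, center = c(0, 0, 0), extent = 4)
  e1 <- do.call(pb_solvation, c(list(sys1, sys1$coords), args))$energy
  e2 <- do.call(pb_solvation, c(list(sys2, sys2$coords), args))$energy
  expect_lt(abs(e1 - e2) / abs(e1), 0.01)
})

test_that("the PB binding term is the three-way difference", {
  expect_equal(pb_binding_term(-100, -70, -40), 10)
  expect_error(pb_binding_term(1:3, 1:2, 1:3), "mismatch")
  # uncharged ligand removed from the geometry as well: dG_PB -> 0
  tc <- gen_toy_complex(2, seed = 3, n_frames = 1)
  co <- frame_coords(tc$bound, 1)
  rec <- tc$system$selections$receptor
  g_rec <- do.call(pb_solvation, c(list(tc$system, co, atoms = rec),
                                   pb_fast))$energy
  d <- pb_binding_term(g_rec, g_rec, 0)
  expect_equal(d, 0)
})

test_that("delta_g_pb decays as the partners separate", {
  tc <- gen_toy_complex(2, seed = 3, n_frames = 1)
  co <- frame_coords(tc$bound, 1)
  lig <- tc$system$selections$ligand
  near <- do.call(delta_g_pb, c(list(tc$system, co), pb_fast))
  co2 <- co; co2[lig, 1] <- co2[lig, 1] + 40
  far <- do.call(delta_g_pb, c(list(tc$system, co2), pb_fast))
  expect_lt(abs(far$delta), abs(near$delta) * 0.5 + 0.05)
})

test_that("SASA of a lone atom matches the sphere area within 0.5%", {
  sys <- born_ion_system()
  s <- sasa(sys, sys$coords, atoms = 1, n_points = 960)
  exact <- 4 * pi * (1.9 + 1.4)^2
  expect_lt(abs(s$total - exact) / exact, 0.005)
})

test_that("SASA is additive when atoms are disjoint and zero when buried", {
  atoms <- dplyr::bind_rows(born_ion_system()$atoms, born_ion_system()$atoms)
  atoms$resid <- c(1, 2)
  sys <- new_system(atoms, coords = rbind(c(0, 0, 0), c(100, 0, 0)))
  s <- sasa(sys, sys$coords)
  lone <- 4 * pi * (1.9 + 1.4)^2
  expect_equal(s$total, 2 * s$per_atom[[1]])
  expect_lt(abs(s$total - 2 * lone) / (2 * lone), 0.005)
  # cage of 26 neighbours buries the central atom
  shell <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 2.2
  shell <- shell[rowSums(shell^2) > 0, ]
  atoms2 <- born_ion_system()$atoms[rep(1, nrow(shell) + 1), ]
  atoms2$resid <- seq_len(nrow(shell) + 1)
  sys2 <- new_system(atoms2, coords = rbind(c(0, 0, 0), shell))
  s2 <- sasa(sys2, sys2$coords)
  expect_equal(s2$per_atom[["1"]], 0)
})

test_that("SASA decreases monotonically as two atoms approach", {
  areas <- vapply(c(8, 6, 4, 2.5, 1.5), function(d) {
    atoms <- dplyr::bind_rows(born_ion_system()$atoms,
                              born_ion_system()$atoms)
    atoms$resid <- c(1, 2)
    sys <- new_system(atoms, coords = rbind(c(0, 0, 0), c(d, 0, 0)))
    sasa(sys, sys$coords)$total
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("the nonpolar term is linear with the documented constants", {
  expect_equal(delta_g_sa(-1000), -4.50)
  expect_equal(delta_g_sa(0), 0.92)
  expect_equal(delta_g_sa(-100, include_constant = FALSE), -0.542)
})
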