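test_that("water box edge follows from count and density", {
  # (n M_w / (N_A rho))^(1/3), independent arithmetic
  expect_equal(water_box_edge(216, 0.997),
               (216 * 18.0154 / (6.02214076e23 * 0.997) * 1e24)^(1 / 3))
  expect_equal(water_box_edge(216, 0.997), 18.64, tolerance = 1e-3)
  expect_error(gen_water_box(216, density = -1), "density")
  expect_error(gen_water_box(4), "at least 8")
})

test_that("water box sampler is deterministic under seed", {
  a <- gen_water_box(8, density = 0.3, temperature = 300, n_snapshots = 3,
                     n_equil_moves = 2000, seed = 9)
  b <- gen_water_box(8, density = 0.3, temperature = 300, n_snapshots = 3,
                     n_equil_moves = 2000, seed = 9)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$snapshot_energy, b$snapshot_energy)
})

test_that("near-infinite temperature at low density approaches ideal gas", {
  hot <- gen_water_box(8, density = 0.02, temperature = 1e6,
                       n_snapshots = 20, n_equil_moves = 5000, seed = 2)
  expect_gt(hot$acceptance, 0.95)
  expect_lt(mean(abs(hot$snapshot_energy)) / 8, 0.6)
})

test_that("water box configurations Boltzmann-reweight across temperatures", {
  cold <- gen_water_box(8, density = 0.8, temperature = 280,
                        n_snapshots = 150, n_equil_moves = 40000, seed = 4)
  warm <- gen_water_box(8, density = 0.8, temperature = 340,
                        n_snapshots = 150, n_equil_moves = 40000, seed = 5)
  e_c <- cold$snapshot_energy
  e_w <- warm$snapshot_energy
  beta <- function(t) 1 / (0.0019872041 * t)
  w <- exp(-(beta(340) - beta(280)) * (e_c - mean(e_c)))
  reweighted <- sum(e_c * w) / sum(w)
  spread <- sd(e_w) + sd(e_c)
  expect_lt(abs(reweighted - mean(e_w)), 3 * spread)
})

test_that("tethered waters reproduce occupancy within a binomial 99% CI", {
  tw <- gen_tethered_waters(tethered_site(c(0, 0, 0), 0.3, 0, 0.5),
                            n_frames = 2000, seed = 11)
  ox <- which(tw$system$atoms$name == "OH2")
  occ <- mean(vapply(seq_len(2000), function(f) {
    sqrt(sum(frame_coords(tw$trajectory, f)[ox, ]^2)) <= 1.0
  }, logical(1)))
  ci <- qnorm(0.995) * sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(occ - 0.5), ci)
})

test_that("tethered generator analytic entropies match independent quadrature", {
  tw <- gen_tethered_waters(tethered_site(c(0, 0, 0), 0.3, 0, 1),
                            n_frames = 5, seed = 1, bulk_density = 0.0334,
                            temperature = 300)
  # closed-form Gaussian value cross-checked by numerical quadrature of
  # -k <ln(rho/rho_bulk)> over the radial distribution
  sg <- 0.3; kT <- 0.0019872041 * 300
  integrand <- function(r) {
    lnrho <- -1.5 * log(2 * pi * sg^2) - r^2 / (2 * sg^2)
    (lnrho - log(0.0334)) * 4 * pi * r^2 *
      exp(-r^2 / (2 * sg^2)) / (2 * pi * sg^2)^1.5
  }
  quad <- kT * integrate(integrand, 0, 3)$value
  expect_equal(tw$truth$minus_TdS_trans, quad, tolerance = 1e-6)
  expect_equal(tw$truth$minus_TdS_trans, 1.64, tolerance = 0.02)
  expect_equal(tw$truth$minus_TdS_orient, 0)
})

test_that("tethered sites too close together are rejected", {
  expect_error(gen_tethered_waters(list(tethered_site(c(0, 0, 0)),
                                        tethered_site(c(3, 0, 0))),
                                   n_frames = 10),
               "overlapping")
  expect_error(tethered_site(c(0, 0, 0), translational_sigma = 0),
               "sigma")
  expect_error(tethered_site(c(0, 0, 0), occupancy_prob = 1.4),
               "occupancy_prob")
})

test_that("toy complex energies equal the brute-force double loop", {
  tc <- gen_toy_complex(3, seed = 5, n_frames = 2)
  co <- frame_coords(tc$bound, 1)
  got <- pairwise_nonbonded(tc$system, co, tc$system$selections$receptor,
                            tc$system$selections$ligand, dielectric = 2)
  want <- brute_nonbonded(tc$system, co, tc$system$selections$receptor,
                          tc$system$selections$ligand, 2)
  expect_equal(got$elec, want$elec, tolerance = 1e-8)
  expect_equal(got$vdw, want$vdw, tolerance = 1e-8)
})

test_that("toy complex generator is deterministic and bounds its input", {
  a <- gen_toy_complex(2, seed = 3, n_frames = 3)
  b <- gen_toy_complex(2, seed = 3, n_frames = 3)
  expect_identical(a$system$atoms, b$system$atoms)
  expect_identical(a$bound$coords, b$bound$coords)
  expect_error(gen_toy_complex(1), "between 2 and 6")
  expect_error(gen_toy_complex(7), "between 2 and 6")
})

test_that("identical bound/unbound ensembles give zero deformation", {
  tc <- gen_toy_complex(2, seed = 6, n_frames = 6)
  same <- internal_energy(tc$system, tc$bound)
  expect_equal(deformation_penalty(same, same, n_blocks = 3)$value, 0)
})

test_that("hydrogen-bond fixture variants match their ground truth", {
  for (v in c("default", "no_bridge", "stretched")) {
    fx <- gen_hbond_fixture(v)
    cen <- interface_hbond_census(fx$system)
    expect_equal(c(direct = cen$direct, bridged = cen$bridged), fx$truth)
  }
})
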