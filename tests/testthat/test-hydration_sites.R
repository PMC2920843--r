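pool_oxygens <- function(tw) {
  ox <- which(tw$system$atoms$name == "OH2")
  nf <- n_frames(tw$trajectory)
  pos <- do.call(rbind, lapply(seq_len(nf), function(f) {
    frame_coords(tw$trajectory, f)[ox, , drop = FALSE]
  }))
  pos[pos[, 1] < 1e3, , drop = FALSE]  # drop parked (unoccupied) waters
}

test_that("clustering finds tethered sites at their centres", {
  tw <- gen_tethered_waters(list(tethered_site(c(0, 0, 0), 0.3),
                                 tethered_site(c(8, 0, 0), 0.3)),
                            n_frames = 300, seed = 31)
  cl <- cluster_hydration_sites(pool_oxygens(tw), n_frames = 300)
  expect_equal(nrow(cl), 2)
  d1 <- min(sqrt(cl$x^2 + cl$y^2 + cl$z^2))
  d2 <- min(sqrt((cl$x - 8)^2 + cl$y^2 + cl$z^2))
  expect_lt(d1, 0.2)
  expect_lt(d2, 0.2)
})

test_that("dilute uniform samples below the threshold give no sites", {
  set.seed(32)
  pos <- matrix(runif(3 * 60, 0, 30), ncol = 3)
  cl <- suppressWarnings(cluster_hydration_sites(pos, n_frames = 1000))
  expect_equal(nrow(cl), 0)
})

test_that("greedy clustering equals an exhaustive brute-force search", {
  set.seed(33)
  pos <- rbind(matrix(rnorm(3 * 12, sd = 0.4), ncol = 3),
               sweep(matrix(rnorm(3 * 10, sd = 0.4), ncol = 3), 2,
                     c(5, 0, 0), "+"),
               matrix(runif(3 * 8, -8, 8), ncol = 3))
  got <- suppressWarnings(
    cluster_hydration_sites(pos, n_frames = 30, min_occupancy = 0.2))
  # independent brute-force greedy
  brute <- list()
  active <- rep(TRUE, nrow(pos))
  repeat {
    idx <- which(active)
    if (!length(idx)) break
    counts <- sapply(idx, function(i) {
      sum(sqrt(rowSums(sweep(pos[idx, , drop = FALSE], 2, pos[i, ])^2)) <= 1)
    })
    if (max(counts) < 0.2 * 30) break
    cand <- idx[counts == max(counts)]
    cand <- cand[order(pos[cand, 1], pos[cand, 2], pos[cand, 3])][1]
    brute[[length(brute) + 1]] <- pos[cand, ]
    active[idx[sqrt(rowSums(sweep(pos[idx, , drop = FALSE], 2,
                                  pos[cand, ])^2)) <= 2.4]] <- FALSE
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(got), nrow(brute))
  expect_equal(unname(as.matrix(got[, c("x", "y", "z")])), unname(brute))
})

test_that("clustering is invariant to sample order", {
  tw <- gen_tethered_waters(list(tethered_site(c(0, 0, 0), 0.4),
                                 tethered_site(c(7, 0, 0), 0.4)),
                            n_frames = 200, seed = 34)
  pos <- pool_oxygens(tw)
  set.seed(1)
  perm <- sample(nrow(pos))
  a <- cluster_hydration_sites(pos, 200)
  b <- cluster_hydration_sites(pos[perm, ], 200)
  expect_equal(a[, c("x", "y", "z")], b[, c("x", "y", "z")])
})

test_that("site characterization obeys its exact identities", {
  tw <- gen_tethered_waters(tethered_site(c(0, 0, 0), 0.3,
                                          orientational_concentration = 4,
                                          occupancy_prob = 0.5),
                            n_frames = 400, seed = 35)
  ch <- suppressWarnings(
    characterize_site(c(0, 0, 0), tw$trajectory, tw$system,
                      bulk_ref = -18.5))
  expect_identical(ch$dG, ch$dH + ch$mTdS)
  expect_identical(ch$weighted_dH, ch$occupancy * ch$dH)
  expect_identical(ch$weighted_mTdS, ch$occupancy * ch$mTdS)
  expect_identical(ch$weighted_dG, ch$occupancy * ch$dG)
  # occupancy within the binomial 99% CI of 0.5
  ci <- qnorm(0.995) * sqrt(0.25 / 400)
  expect_lt(abs(ch$occupancy - 0.5), ci + 1e-9)
  # isolated tethered waters have zero environment energy, so dH = -bulk
  expect_equal(ch$dH, 18.5, tolerance = 1e-9)
})

test_that("fully occupied sites report occupancy 1 and fail when empty", {
  tw <- gen_tethered_waters(tethered_site(c(0, 0, 0), 0.15), n_frames = 120,
                            seed = 36)
  ch <- suppressWarnings(characterize_site(c(0, 0, 0), tw$trajectory,
                                           tw$system, bulk_ref = -18.5))
  expect_equal(ch$occupancy, 1.0)
  expect_error(suppressWarnings(
    characterize_site(c(50, 0, 0), tw$trajectory, tw$system, -18.5)),
    "zero occupancy")
})

test_that("probe-site analysis reports occupancy and relative enthalpy", {
  tw <- gen_tethered_waters(tethered_site(c(0, 0, 0), 0.3), n_frames = 100,
                            seed = 37)
  pr <- probe_site_analysis(c(0, 0, 0), tw$trajectory, tw$system,
                            bulk_ref = -18.5)
  expect_equal(pr$occupancy, 1.0)
  expect_equal(pr$enthalpy, 18.5, tolerance = 1e-9)  # isolated waters
  far <- probe_site_analysis(c(50, 0, 0), tw$trajectory, tw$system, -18.5)
  expect_equal(far$occupancy, 0)
  expect_true(is.na(far$enthalpy))
})

test_that("bulk reference vanishes for isolated waters and is reproducible", {
  geom <- water_geometry()
  atoms <- tibble::tibble(
    name = rep(c("OH2", "H1", "H2"), 2), element = rep(c("O", "H", "H"), 2),
    resname = "TIP3", resid = rep(1:2, each = 3), chain = "W")
  co <- rbind(geom, sweep(geom, 2, c(100, 0, 0), "+"))
  sys <- assign_parameters(new_system(atoms, coords = co),
                           tip3p_parameters())
  tr <- new_trajectory(array(co, dim = c(6, 3, 2)), 1)
  br <- bulk_reference(sys, tr)
  expect_lt(abs(br$value), 1e-3)
  # determinism under seed for the sampler-backed path
  a <- gen_water_box(8, density = 0.5, n_snapshots = 5,
                     n_equil_moves = 3000, seed = 8)
  b <- gen_water_box(8, density = 0.5, n_snapshots = 5,
                     n_equil_moves = 3000, seed = 8)
  expect_identical(bulk_reference(a$system, a$trajectory)$value,
                   bulk_reference(b$system, b$trajectory)$value)
})

test_that("site comparison reproduces the displaced and stabilized rules", {
  # displaced: binding gains the negated apo excess values
  apo <- tibble::tibble(x = 0, y = 0, z = 0,
                        dH = -0.95, mTdS = 1.29, dG = 0.34)
  none <- apo[0, ]
  cmp <- compare_states(apo, none, matrix(c(0.5, 0, 0), 1))
  expect_equal(cmp$classification[1], "displaced")
  expect_equal(cmp[1, c("ddH", "dTdS", "ddG")],
               tibble::tibble(ddH = 0.95, dTdS = -1.29, ddG = -0.34))
  # stabilized: bound minus apo
  apo2 <- tibble::tibble(x = 0, y = 0, z = 0,
                         dH = -1.13, mTdS = 2.94, dG = 1.81)
  bound2 <- tibble::tibble(x = 0.3, y = 0, z = 0,
                           dH = -7.80, mTdS = 5.11, dG = -2.69)
  cmp2 <- compare_states(apo2, bound2, matrix(c(0.2, 0, 0), 1))
  expect_equal(cmp2$classification[1], "stabilized")
  expect_equal(cmp2$ddG[1], -4.50)
  expect_equal(cmp2$ddH[1] + cmp2$dTdS[1], cmp2$ddG[1], tolerance = 1e-12)
  # no bound sites, no overlap: unchanged with zero contribution
  cmp3 <- compare_states(apo, none, matrix(c(50, 0, 0), 1))
  expect_equal(cmp3$classification[1], "unchanged")
  expect_equal(cmp3$ddG[1], 0)
})

test_that("site aggregation reproduces reference residue totals", {
  t3 <- tibble::tibble(
    residue = c("Leu 1", "Leu 1", "Leu 1", "Leu 2", "Leu 2", "Leu 2",
                "Cys 3", "Cys 3", "Ser 4", "Asn 7", "Asn 7"),
    dH = c(1.57, -0.05, 1.22, 0.31, -2.50, 1.50, 2.01, -0.58, 0.80, 1.22,
           0.91),
    mTdS = c(0.85, 0.85, 0.73, 0.81, 2.46, 1.03, 0.85, 1.73, 2.76, 0.86,
             0.92),
    dG = c(2.42, 0.80, 1.95, 1.12, -0.04, 2.53, 2.86, 1.15, 3.56, 2.08,
           1.83))
  agg <- aggregate_sites(t3, group = "residue")
  total <- agg[agg$group == "Total", ]
  expect_equal(total$dH, 6.41, tolerance = 1e-9)
  expect_equal(total$mTdS, 13.85, tolerance = 1e-9)
  expect_equal(total$dG, 20.26, tolerance = 1e-9)
  expect_equal(agg$dG[agg$group == "Ser 4"], 3.56)
  # single row aggregates to itself
  one <- aggregate_sites(t3[9, ], group = "residue")
  expect_equal(one$dG[one$group == "Total"], 3.56)
})

test_that("compared-site sums reproduce the reference binding changes", {
  t4 <- tibble::tibble(
    ddH = c(-6.67, -6.24, -8.37, -3.72, -5.02, 0.95, 2.62),
    dTdS = c(2.17, 3.08, 2.27, 1.95, 2.13, -1.29, -1.82),
    ddG = c(-4.50, -3.16, -6.10, -1.77, -1.79, -0.34, 0.80))
  agg <- aggregate_sites(t4, values = c("ddH", "dTdS", "ddG"))
  expect_equal(agg$ddH, -26.45, tolerance = 1e-9)
  expect_equal(agg$dTdS, 8.49, tolerance = 1e-9)
  expect_equal(agg$ddG, -16.86, tolerance = 1e-9)
})
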