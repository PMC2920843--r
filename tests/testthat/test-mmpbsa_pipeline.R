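test_that("block SEM follows the 20-block rule", {
  expect_equal(block_sem(rep(3.7, 100)), 0)
  # known block means: series is the block index repeated
  x <- rep(1:20, each = 5)
  expect_equal(block_sem(x, 20), sd(1:20) / sqrt(20))
  expect_equal(block_sem(2 * x, 20), 2 * block_sem(x, 20))
  expect_error(block_sem(1:10, 20), "shorter")
  expect_error(block_sem(1:10, 1), "at least 2")
  # n_blocks = length reduces to sd of the points / sqrt(n)
  y <- c(1.2, -0.3, 2.2, 0.7)
  expect_equal(block_sem(y, 4), sd(y) / 2)
})

test_that("snapshot counting follows floor(duration / stride)", {
  tc <- gen_toy_complex(2, seed = 2, n_frames = 40)  # 400 ps at 10 ps
  mm <- run_mmpbsa(tc$system, tc$bound, tc$unbound, stride = 100,
                   pb = FALSE, sasa_term = FALSE, n_blocks = 2)
  expect_equal(mm$n_snapshots, 4)
  expect_error(run_mmpbsa(tc$system, tc$bound, tc$unbound, stride = 5000),
               "stride")
})

test_that("free energy assembly reproduces the reference arithmetic", {
  # phosphopeptide column: dH -32.7 with -TdS 13.7 gives -19.0
  t1 <- assemble_binding_free_energy(c(dH = -32.7), 13.7)
  expect_equal(t1$value[t1$term == "dG"], -19.0)
  # peptide column: -21.9 + 9.2 = -12.7
  t2 <- assemble_binding_free_energy(c(dH = -21.9), 9.2)
  expect_equal(t2$value[t2$term == "dG"], -12.7)
  # all-zero components give zero
  t0 <- assemble_binding_free_energy(
    c(vdw = 0, elec = 0, deformation = 0, desolvation = 0, sasa = 0), 0)
  expect_equal(t0$value[t0$term == "dG"], 0)
  expect_error(assemble_binding_free_energy(c(vdw = -41.3, elec = -187.5), 13.7),
               "desolvation")
  # ddG from unrounded values
  td <- assemble_binding_free_energy(c(dH = -32.65), 13.72, reference = t2)
  expect_equal(td$delta_vs_reference[td$term == "dG"],
               (-32.65 + 13.72) - (-12.7))
})

test_that("Eq-1 assembly is exact arithmetic before rounding", {
  set.seed(4)
  for (i in 1:20) {
    comp <- rnorm(5)
    names(comp) <- c("vdw", "elec", "deformation", "desolvation", "sasa")
    mtds <- rnorm(1)
    tb <- assemble_binding_free_energy(comp, mtds)
    v <- setNames(tb$value, tb$term)
    expect_lt(abs(v[["dG"]] - v[["dH"]] - mtds), 1e-12)
    expect_identical(v[["dH"]], sum(comp))
  }
})

test_that("cross-residue intramolecular pairs split half and half", {
  # two one-atom 'residues' with a single interacting pair of energy E
  atoms <- tibble::tibble(name = c("CB", "CB"), element = "C",
                          resname = "GLX", resid = c(1, 2), chain = "B",
                          mass = 12, mm_charge = c(1, 1), parse_charge = 1,
                          lj_epsilon = 0, lj_rmin_half = 1.8,
                          radius_pb = 1.8, radius_sasa = 1.8,
                          is_water = FALSE)
  r <- 332.0637 / (2 * 2.0)  # distance at which E = 2.0 with dielectric 2
  sys <- new_system(atoms, coords = rbind(c(0, 0, 0), c(r, 0, 0)))
  pl <- hydrobind:::nonbonded_pairlist(sys, 1:2, 1)
  e <- hydrobind:::intra_group_energy(sys, sys$coords, 1:2,
                                      c(1L, 2L), pl, 2)
  expect_equal(e, c(1.0, 1.0), tolerance = 1e-12)
})

test_that("per-residue interaction columns sum to the whole-ligand values", {
  tc <- gen_toy_complex(3, seed = 13, n_frames = 6)
  mm <- run_mmpbsa(tc$system, tc$bound, tc$unbound, n_blocks = 3,
                   pb = FALSE, sasa_term = FALSE)
  pr <- per_residue_decomposition(tc$system, tc$bound, tc$unbound,
                                  n_blocks = 3, pb = FALSE,
                                  sasa_term = FALSE)
  v <- setNames(mm$table$value, mm$table$term)
  expect_equal(sum(pr$vdw), v[["vdw"]], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(pr$elec), v[["elec"]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sum(pr$deformation), v[["deformation"]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sum(pr$percent), 100, tolerance = 1e-9)
})

test_that("reference per-residue rows give the phosphothreonine share", {
  rows <- tibble::tibble(
    residue = c("Mainchain", "Leu 1", "Leu 2", "Cys 3", "Ser 4", "pThr 5",
                "Pro 6", "Asn 7"),
    vdw = c(-20.5, -4.3, -2.8, -0.5, -4.2, -2.5, -2.0, -4.5),
    elec = c(-22.3, 0.1, 0.2, 0.1, 0, -162.0, 3.1, -6.7),
    deformation = c(-2.3, -1.0, -0.8, -0.9, -2.5, -0.7, -1.8, 0.6),
    desolvation = c(37.1, 1.5, 3.1, 2.7, 6.5, 157.8, -1.3, 11.0),
    sasa = c(-1.9, -0.2, -0.2, -0.2, -0.1, -0.4, 0.0, -0.1))
  tab <- residue_contribution_table(rows)
  expect_equal(tab$percent[tab$residue == "pThr 5"], 34.1, tolerance = 0.05)
  expect_gt(tab$percent[tab$residue == "pThr 5"], 30)
  expect_gt(sum(tab$percent[tab$residue %in% c("pThr 5", "Mainchain")]), 75)
  expect_equal(sum(tab$percent), 100, tolerance = 0.5)
})

test_that("single-frame pipeline equals the static calculation", {
  tc <- gen_toy_complex(2, seed = 14, n_frames = 2)
  cb <- frame_coords(tc$bound, 1)
  cu <- frame_coords(tc$unbound, 1)
  one_b <- new_trajectory(array(cb, dim = c(nrow(cb), 3, 1)), 1)
  one_u <- new_trajectory(array(cu, dim = c(nrow(cu), 3, 1)), 1)
  dyn <- run_mmpbsa(tc$system, one_b, one_u, pb = FALSE, n_blocks = 2)
  sta <- static_mmpbsa(tc$system, cb, cu, pb = FALSE, n_blocks = 2)
  expect_equal(sta$table$value, dyn$table$value, tolerance = 1e-12)
  # identical frames give zero deformation
  same <- static_mmpbsa(tc$system, cb, cb, pb = FALSE, n_blocks = 2)
  expect_equal(same$table$value[same$table$term == "deformation"], 0)
})

test_that("pipeline dH matches brute-force composition without PB/SASA", {
  tc <- gen_toy_complex(2, seed = 15, n_frames = 5)
  mm <- run_mmpbsa(tc$system, tc$bound, tc$unbound, pb = FALSE,
                   sasa_term = FALSE, n_blocks = 2)
  rec <- tc$system$selections$receptor
  lig <- tc$system$selections$ligand
  inter <- sapply(1:5, function(f) {
    bf <- brute_nonbonded(tc$system, frame_coords(tc$bound, f), rec, lig, 2)
    bf$elec + bf$vdw
  })
  defo <- mean(internal_energy(tc$system, tc$bound)$total) -
    mean(internal_energy(tc$system, tc$unbound)$total)
  v <- setNames(mm$table$value, mm$table$term)
  expect_equal(v[["dH"]], mean(inter) + defo, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("tidiers expose the result tables", {
  tc <- gen_toy_complex(2, seed = 16, n_frames = 4)
  mm <- run_mmpbsa(tc$system, tc$bound, tc$unbound, pb = FALSE,
                   sasa_term = FALSE, n_blocks = 2)
  expect_identical(tidy(mm), mm$table)
  g <- glance(mm)
  expect_equal(g$n_snapshots, 4)
})
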