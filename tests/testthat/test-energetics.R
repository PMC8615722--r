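test_that("pair_vdw: LJ identities and brute-force agreement", {
  # two atoms at rmin -> -sqrt(eps_i eps_j)
  s <- mk_system(rbind(c(0, 0, 0), c(3.8, 0, 0)), epsilon = c(0.2, 0.3),
                 rmin_half = 1.9, group = c("receptor", "ligand"))
  expect_equal(pair_vdw(s, 1, 1, 2), -sqrt(0.2 * 0.3), tolerance = 1e-12)

  # eps = 0 on one side -> 0
  s0 <- mk_system(rbind(c(0, 0, 0), c(2, 0, 0)), epsilon = c(0, 0.3),
                  group = c("receptor", "ligand"))
  expect_identical(pair_vdw(s0, 1, 1, 2), 0)

  # random 5-atom system vs naive double loop
  rs <- rand_system(5, seed = 21)
  a <- group_mask(rs, "receptor"); b <- group_mask(rs, "ligand")
  expect_equal(pair_vdw(rs, 1, a, b), brute_lj(rs, 1, a, b), tolerance = 1e-10)

  expect_error(pair_vdw(rs, 1, a, a[1]), "disjoint")
})

test_that("pair_coulomb: closed form, neutrality, brute force", {
  s <- mk_system(rbind(c(0, 0, 0), c(3.320637, 0, 0)), charge = c(1, -1),
                 epsilon = 0, group = c("receptor", "ligand"))
  expect_equal(pair_coulomb(s, 1, 1, 2), -100, tolerance = 0.01)

  sn <- mk_system(rbind(c(0, 0, 0), c(2, 0, 0)), charge = 0,
                  group = c("receptor", "ligand"))
  expect_identical(pair_coulomb(sn, 1, 1, 2), 0)

  rs <- rand_system(6, seed = 22)
  a <- group_mask(rs, "receptor"); b <- group_mask(rs, "ligand")
  expect_equal(pair_coulomb(rs, 1, a, b), brute_coulomb(rs, 1, a, b),
               tolerance = 1e-10)
})

test_that("gb_energy: Born ion, null dielectric, asymptotics, invariance", {
  ion <- mk_system(rbind(c(0, 0, 0)), charge = 1, born_radius = 2)
  born <- -0.5 * KE * (1 - 1 / 80) * 1 / 2
  expect_equal(gb_energy(ion, 1, 1, eps_solvent = 80, offset = 0),
               born, tolerance = 0.05)

  # eps = 1 -> exactly 0
  expect_identical(gb_energy(ion, 1, 1, eps_solvent = 1, offset = 0), 0)

  # two distant ions -> two Born self terms (cross screening ~ 1/r)
  far <- mk_system(rbind(c(0, 0, 0), c(5000, 0, 0)), charge = 1,
                   born_radius = 2, group = c("receptor", "ligand"))
  expect_equal(gb_energy(far, 1, 1:2, offset = 0), 2 * born,
               tolerance = abs(2 * born) * 0.001)

  # rigid rotation + translation invariance
  rs <- rand_system(8, seed = 23)
  rs2 <- transform_system(rs, rotation_z(0.83), c(3, -2, 7))
  expect_equal(gb_energy(rs, 1), gb_energy(rs2, 1), tolerance = 1e-8)
})

test_that("sasa: sphere area, burial, monotonicity, refined-grid agreement", {
  one <- mk_system(rbind(c(0, 0, 0)), rmin_half = 1.5)
  expect_equal(sasa(one, 1, 1), 4 * pi * 2.9^2,
               tolerance = 4 * pi * 2.9^2 * 0.005)

  # fully buried atom contributes nothing: the two-atom total is exactly the
  # engulfing sphere's area (atom 1's 1.9 A sphere lies inside atom 2's 4.9 A)
  cage <- mk_system(rbind(c(0, 0, 0), c(2, 0, 0)), rmin_half = c(0.5, 3.5))
  expect_equal(sasa(cage, 1, 1:2), 4 * pi * 4.9^2, tolerance = 1e-6)

  # SASA of a two-sphere system decreases monotonically on approach
  areas <- vapply(seq(6, 2, by = -0.5), function(d) {
    s <- mk_system(rbind(c(0, 0, 0), c(d, 0, 0)), rmin_half = 1.5)
    sasa(s, 1, 1:2)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))

  # overlapping equal spheres: 960 points within 1% of a 10x-dense reference
  ov <- mk_system(rbind(c(0, 0, 0), c(2.5, 0, 0)), rmin_half = 1.5)
  a1 <- sasa(ov, 1, 1:2, n_points = 960)
  a2 <- sasa(ov, 1, 1:2, n_points = 9600)
  expect_lt(abs(a1 - a2) / a2, 0.01)

  expect_error(sasa(one, 1, 1, n_points = 8), "12")
})

test_that("nonpolar_energy is gamma * area + beta", {
  expect_identical(nonpolar_energy(0, beta = 1.5), 1.5)
  expect_equal(nonpolar_energy(105.68, gamma = 0.005, beta = 0), 0.5284)
  expect_identical(nonpolar_energy(250, gamma = 0), 0)
  expect_error(nonpolar_energy(-1), ">= 0")
})

test_that("gas_phase_interaction is the cross vdW + Coulomb sum", {
  rs <- rand_system(8, seed = 24)
  a <- group_mask(rs, "receptor"); b <- group_mask(rs, "ligand")
  expect_equal(gas_phase_interaction(rs, 1),
               pair_vdw(rs, 1, a, b) + pair_coulomb(rs, 1, a, b),
               tolerance = 1e-12)

  # ligand with zero charges and epsilon -> 0
  s0 <- mk_system(rbind(c(0, 0, 0), c(3, 0, 0)), charge = c(1, 0),
                  epsilon = c(0.2, 0), group = c("receptor", "ligand"))
  expect_identical(gas_phase_interaction(s0, 1), 0)
})

test_that("interaction-energy series feeds the IE estimator cleanly", {
  sys <- demo_complex(n_frames = 120, seed = 31)
  ser <- interaction_energy_series(sys)
  expect_true(all(is.finite(ser$values)))
  res <- ie_entropy(ser)
  expect_true(is.finite(res$minus_t_delta_s))
  expect_gte(res$minus_t_delta_s, 0)
})
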