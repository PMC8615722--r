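test_that("gen_energy_series: degenerate, deterministic, and law of large numbers", {
  # sigma = 0 -> constant at the mean
  s0 <- gen_energy_series(series_spec(n_points = 100, mean = -60, sigma = 0))
  expect_true(all(s0$values == -60))

  # same seed -> bit-identical
  sp <- series_spec(n_points = 1000, mean = -60, sigma = 2,
                    autocorrelation_time = 5, outlier_fraction = 0.01,
                    seed = 42)
  expect_identical(gen_energy_series(sp)$values, gen_energy_series(sp)$values)

  # white noise at n = 1e6: sample mean and SD within 0.01 of spec
  big <- gen_energy_series(series_spec(n_points = 1e6, mean = -60, sigma = 2,
                                       seed = 5))
  expect_lt(abs(mean(big$values) + 60), 0.01)
  expect_lt(abs(sd(big$values) - 2), 0.01)
})

test_that("gen_energy_series: AR(1), regimes and outliers behave as specified", {
  # AR(1) lag-1 autocorrelation ~ exp(-dt/tau)
  tau <- 5
  s <- gen_energy_series(series_spec(n_points = 2e5, sigma = 1,
                                     autocorrelation_time = tau, seed = 3))
  x <- s$values
  rho <- cor(x[-1], x[-length(x)])
  expect_lt(abs(rho - exp(-1 / tau)), 0.02)

  # regime segments: realized SDs order like the specified sigmas
  sp <- series_spec(n_points = 3e4, sigma = 1, regime_changes = list(
    list(start_index = 1, mean = -60, sigma = 3),
    list(start_index = 10001, mean = -60, sigma = 0.5),
    list(start_index = 20001, mean = -60, sigma = 1.5)), seed = 8)
  v <- gen_energy_series(sp)$values
  sds <- c(sd(v[1:10000]), sd(v[10001:20000]), sd(v[20001:30000]))
  expect_identical(order(sds), order(c(3, 0.5, 1.5)))

  # injected outliers are at least outlier_scale * sigma from the mean
  spo <- series_spec(n_points = 1e4, mean = -60, sigma = 1,
                     outlier_fraction = 0.01, outlier_scale = 8, seed = 2)
  vo <- gen_energy_series(spo)$values
  expect_equal(sum(abs(vo + 60) >= 8 * 1), 100)
})

test_that("gen_toy_complex realizes contacts exactly and deterministically", {
  # on_fraction = 1: donor-acceptor distance at the 2.7 A target in all frames
  sys <- demo_complex(n_frames = 10, seed = 1, on_hb = 1.0)
  hb <- hbond_occupancy(sys, "A:2:NZ", "R:2:OP2")
  expect_true(all(abs(hb$distance - 2.7) < 0.1))
  expect_equal(hb$occupancy, 100)

  # on_fraction = 0.621 at n = 1000 -> exactly 621 satisfying frames
  sys2 <- gen_toy_complex(complex_spec(
    n_protein_chains = 2, residues_per_chain = 2, n_rna_nucleotides = 3,
    contact_pairs = list(list(type = "hbond", donor = "A:2:NZ",
                              acceptor = "R:2:OP2", target_distance = 2.7,
                              on_fraction = 0.621)),
    n_frames = 1000, jitter_sigma = 0.05, seed = 7))
  hb2 <- hbond_occupancy(sys2, "A:2:NZ", "R:2:OP2")
  expect_equal(sum(hb2$satisfied), 621)

  # determinism
  spc <- complex_spec(n_protein_chains = 2, residues_per_chain = 2,
                      n_rna_nucleotides = 2, n_frames = 4, seed = 5)
  expect_identical(gen_toy_complex(spc)$coords, gen_toy_complex(spc)$coords)

  # infeasible geometry: target inside the hard-sphere core
  expect_error(gen_toy_complex(complex_spec(
    n_protein_chains = 1, residues_per_chain = 2, n_rna_nucleotides = 2,
    contact_pairs = list(list(type = "hbond", donor = "A:1:NZ",
                              acceptor = "R:1:OP2", target_distance = 1.0,
                              on_fraction = 1)), n_frames = 2)),
    "hard spheres")
})

test_that("two disjoint contacts are realized independently", {
  sys <- gen_toy_complex(complex_spec(
    n_protein_chains = 3, residues_per_chain = 3, n_rna_nucleotides = 5,
    contact_pairs = list(
      list(type = "hbond", donor = "A:2:NZ", acceptor = "R:1:OP2",
           target_distance = 2.7, on_fraction = 0.6),
      list(type = "hbond", donor = "B:2:NZ", acceptor = "R:5:OP2",
           target_distance = 2.7, on_fraction = 0.5)),
    n_frames = 2000, jitter_sigma = 0.05, seed = 13))
  h1 <- hbond_occupancy(sys, "A:2:NZ", "R:1:OP2")$satisfied
  h2 <- hbond_occupancy(sys, "B:2:NZ", "R:5:OP2")$satisfied
  expect_equal(sum(h1), 1200)
  expect_equal(sum(h2), 1000)
  joint <- mean(h1 & h2)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(joint - 0.6 * 0.5), 4 * se)
})

test_that("gen_fep_samples matches the Gaussian sampler's closed forms", {
  # equal end states: perturbation energies are identically zero
  d0 <- gen_fep_samples(2, 2, n_per_window = 50, seed = 1)
  for (w in d0$windows) expect_equal(w$v_lambda_next, w$v_lambda)

  # equipartition: Var(x) = kT/k_lambda, recovered from <V> = k Var(x) / 2
  d <- gen_fep_samples(1.5, 1.5, n_per_window = 1e5, seed = 2)
  kT <- KB * 300
  for (i in c(1, 5, 10)) {
    vbar <- mean(d$windows[[i]]$v_lambda)
    expect_lt(abs(2 * vbar / 1.5 - kT / 1.5) / (kT / 1.5), 0.02)
  }

  # determinism
  a <- gen_fep_samples(1, 2, n_per_window = 100, seed = 9)
  b <- gen_fep_samples(1, 2, n_per_window = 100, seed = 9)
  expect_identical(a$windows, b$windows)
})
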