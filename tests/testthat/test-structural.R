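test_that("rmsd_series: superposition identities and brute-force agreement", {
  rs <- rand_system(10, seed = 51)
  base <- matrix(rs$coords[1, , ], ncol = 3)
  frames <- array(0, c(3, 10, 3))
  frames[1, , ] <- base
  frames[2, , ] <- base %*% t(rotation_z(0.9)) + 2      # rigid motion
  set.seed(52)
  frames[3, , ] <- base + matrix(rnorm(30, sd = 0.4), 10, 3)
  sys <- mk_system(base, frames = frames)

  r <- rmsd_series(sys, reference = 1)
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_equal(r[2], 0, tolerance = 1e-6)

  # brute-force rotation grid can never beat Kabsch, and approaches it
  P <- scale(matrix(frames[3, , ], ncol = 3), scale = FALSE)
  Q <- scale(base, scale = FALSE)
  gr <- seq(0, 2 * pi, length.out = 25)[-25]
  best <- Inf
  for (a in gr) for (b in seq(0, pi, length.out = 13)) for (cc in gr) {
    Rz <- rotation_z(a)
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    R <- Rz %*% Ry %*% rotation_z(cc)
    best <- min(best, sqrt(mean(rowSums((P %*% R - Q)^2))))
  }
  expect_gte(best + 1e-9, r[3])
  expect_lt(best - r[3], 0.05)

  expect_error(rmsd_series(mk_system(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(2, 0, 0)))), "degenerate")
})

test_that("rmsf_coords: static zeros and the Gaussian displacement oracle", {
  rs <- rand_system(8, seed = 53)
  static <- mk_system(matrix(rs$coords[1, , ], ncol = 3),
                      frames = array(rep(rs$coords[1, , ], each = 4),
                                     c(4, 8, 3)))
  expect_true(all(rmsf_coords(static) < 1e-10))

  # one atom jittered isotropically with sd sigma -> RMSF ~ sigma * sqrt(3).
  # Tolerance allows for the 6 rigid DOF the alignment absorbs (~2/N per
  # axis downward bias) on top of Monte-Carlo error.
  set.seed(54)
  N <- 50; nf <- 3000; sigma <- 0.5
  base <- matrix(runif(3 * N, 0, 15), N, 3)
  frames <- array(rep(base, each = nf), c(nf, N, 3))
  frames[, 1, ] <- frames[, 1, ] + matrix(rnorm(3 * nf, sd = sigma), nf, 3)
  sys <- mk_system(base, frames = frames)
  rf <- rmsf_coords(sys)
  expect_lt(abs(rf[1] - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.08)
  expect_true(all(rf[-1] < 0.06))
})

test_that("hbond_occupancy counts satisfying frames and averages all frames", {
  sys <- demo_complex(n_frames = 10, seed = 55, on_hb = 0.9)
  hb <- hbond_occupancy(sys, "A:2:NZ", "R:2:OP2")
  expect_equal(hb$occupancy, 90)
  # never satisfiable criterion
  hb0 <- hbond_occupancy(sys, "A:2:NZ", "R:2:OP2", max_distance = 0)
  expect_equal(hb0$occupancy, 0)
  # mean distance includes the non-satisfying (displaced) frames
  expect_gt(hb$mean_distance, 2.7)
  expect_error(hbond_occupancy(sys, "A:2:QQ", "R:2:OP2"), "matches no atoms")
})

test_that("distance_series: constants, centroids, histogram conservation", {
  base <- rbind(c(0, 0, 0), c(3.7, 0, 0))
  sys <- mk_system(base, frames = array(rep(base, each = 5), c(5, 2, 3)),
                   group = c("receptor", "ligand"))
  d <- distance_series(sys, 1, 2, mode = "min_atom_pair")
  expect_true(all(abs(d$distance - 3.7) < 1e-12))
  expect_equal(sum(d$histogram$count), 5)

  # centroid of a symmetric ring is its center
  ring <- t(vapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3), 0),
                   numeric(3)))
  sys2 <- mk_system(rbind(c(10, 0, 0), ring),
                    group = c("receptor", rep("ligand", 6)))
  d2 <- distance_series(sys2, 1, 2:7, mode = "centroid")
  expect_equal(d2$distance, 10, tolerance = 1e-12)
  # permutation invariance in atom order
  d3 <- distance_series(sys2, 1, c(5, 3, 7, 2, 6, 4), mode = "centroid")
  expect_equal(d3$distance, d2$distance)

  # global translation invariance
  sys3 <- transform_system(sys2, diag(3), c(5, -1, 3))
  expect_equal(distance_series(sys3, 1, 2:7, mode = "centroid")$distance,
               d2$distance, tolerance = 1e-10)
})

test_that("lowest_energy_frame is the brute-force argmin", {
  expect_equal(lowest_energy_frame(c(5, 4, 3, 2, 1)), 5)
  expect_equal(lowest_energy_frame(c(3, 1, 2, 1)), 2)  # tie -> earliest
  set.seed(56)
  x <- rnorm(500)
  expect_equal(lowest_energy_frame(x), which(x == min(x))[1])
  expect_error(lowest_energy_frame(numeric(0)), "empty")
})
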