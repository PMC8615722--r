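# Small in-code fixtures and brute-force oracles shared across tests.

# single/multi-frame point system with recycled parameters
mk_system <- function(coords, charge = 0, rmin_half = 1.9, epsilon = 0.1,
                      born_radius = 1.7, group = "receptor",
                      frames = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  atoms <- data.frame(
    atom_id = seq_len(n), name = paste0("X", seq_len(n)), element = "C",
    chain = "A", resi = seq_len(n), resn = "TOY",
    charge = rep_len(charge, n), rmin_half = rep_len(rmin_half, n),
    epsilon = rep_len(epsilon, n), born_radius = rep_len(born_radius, n),
    group = rep_len(group, n), stringsAsFactors = FALSE)
  if (is.null(frames)) frames <- array(coords, c(1, n, 3))
  toy_system(atoms, frames)
}

# random system split into receptor/ligand halves, for brute-force checks
rand_system <- function(n, seed, spread = 6) {
  set.seed(seed)
  mk_system(matrix(runif(3 * n, 0, spread), n, 3),
            charge = round(runif(n, -1, 1), 2),
            rmin_half = runif(n, 1.2, 2.0), epsilon = runif(n, 0.05, 0.3),
            born_radius = runif(n, 1.3, 2.0),
            group = rep(c("receptor", "ligand"), length.out = n))
}

# naive double-loop oracles
brute_lj <- function(system, frame, a, b) {
  xyz <- matrix(system$coords[frame, , ], ncol = 3)
  at <- system$atoms
  e <- 0
  for (i in a) for (j in b) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rmin <- at$rmin_half[i] + at$rmin_half[j]
    eps <- sqrt(at$epsilon[i] * at$epsilon[j])
    e <- e + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  e
}

brute_coulomb <- function(system, frame, a, b) {
  xyz <- matrix(system$coords[frame, , ], ncol = 3)
  at <- system$atoms
  e <- 0
  for (i in a) for (j in b)
    e <- e + iebind::KE * at$charge[i] * at$charge[j] /
      sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  e
}

# all-pairs LJ within one mask (for the complex-minus-parts identity)
brute_lj_within <- function(system, frame, mask) {
  if (length(mask) < 2) return(0)
  pairs <- utils::combn(mask, 2)
  sum(vapply(seq_len(ncol(pairs)), function(k)
    brute_lj(system, frame, pairs[1, k], pairs[2, k]), numeric(1)))
}

# rigidly rotate + translate every frame of a system
transform_system <- function(system, R = diag(3), t = c(0, 0, 0)) {
  out <- system
  for (f in seq_len(n_frames(system))) {
    xyz <- matrix(system$coords[f, , ], ncol = 3)
    out$coords[f, , ] <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  }
  out
}

rotation_z <- function(theta)
  rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))

# a quick two-contact toy complex used by several files
demo_complex <- function(n_frames = 50, seed = 4, on_hb = 1.0) {
  gen_toy_complex(complex_spec(
    n_protein_chains = 3, residues_per_chain = 3, n_rna_nucleotides = 4,
    contact_pairs = list(
      list(type = "hbond", donor = "A:2:NZ", acceptor = "R:2:OP2",
           target_distance = 2.7, on_fraction = on_hb)),
    n_frames = n_frames, jitter_sigma = 0.05, seed = seed))
}
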