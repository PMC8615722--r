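# Molecular-mechanics and implicit-solvent energy terms for a single frame:
# Lennard-Jones 12-6 and Coulomb cross sums, generalized-Born (OBC-II) polar
# solvation, and Shrake-Rupley SASA with the gamma*SASA + beta non-polar term.
# Everything is a full pair sum (no cutoff): end-state rescoring convention.

# cross-distance matrix between atom sets (rows a, cols b)
cross_dist <- function(xyz, a, b) {
  pa <- xyz[a, , drop = FALSE]
  pb <- xyz[b, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(pmax(d2, 0))
}

check_masks <- function(mask_a, mask_b) {
  if (length(intersect(mask_a, mask_b))) stop("masks must be disjoint")
  if (!length(mask_a) || !length(mask_b)) stop("masks must be non-empty")
}

# per-pair LJ matrix (rows mask_a, cols mask_b), kcal/mol
vdw_matrix <- function(system, frame, mask_a, mask_b) {
  xyz <- frame_coords(system, frame)
  at <- system$atoms
  r <- cross_dist(xyz, mask_a, mask_b)
  eps <- sqrt(outer(at$epsilon[mask_a], at$epsilon[mask_b]))
  if (any(r < 1e-9 & eps > 0)) stop("coincident atoms across masks (LJ singularity)")
  rmin <- outer(at$rmin_half[mask_a], at$rmin_half[mask_b], "+")
  sr6 <- ifelse(eps > 0, (rmin / pmax(r, 1e-9))^6, 0)
  eps * (sr6^2 - 2 * sr6)
}

# per-pair Coulomb matrix, kcal/mol
coulomb_matrix <- function(system, frame, mask_a, mask_b) {
  xyz <- frame_coords(system, frame)
  at <- system$atoms
  r <- cross_dist(xyz, mask_a, mask_b)
  qq <- outer(at$charge[mask_a], at$charge[mask_b])
  if (any(r < 1e-9 & qq != 0)) stop("coincident atoms across masks (Coulomb singularity)")
  ifelse(qq != 0, KE * qq / pmax(r, 1e-9), 0)
}

#' Lennard-Jones 12-6 cross interaction
#'
#' Full pair sum over `mask_a` x `mask_b` with Lorentz-Berthelot-style
#' combination: `rmin_ij = rmin_half_i + rmin_half_j`,
#' `eps_ij = sqrt(eps_i eps_j)`; energy
#' `eps_ij ((rmin/r)^12 - 2 (rmin/r)^6)`. No cutoff.
#'
#' @param system a `ToySystem`.
#' @param frame frame index.
#' @param mask_a,mask_b disjoint integer atom-index sets.
#' @return Energy, kcal/mol.
#' @export
pair_vdw <- function(system, frame, mask_a, mask_b) {
  check_masks(mask_a, mask_b)
  sum(vdw_matrix(system, frame, mask_a, mask_b))
}

#' Coulomb cross interaction
#'
#' `sum k_e q_i q_j / r_ij` over cross pairs, `k_e = 332.0637`
#' kcal A/(mol e^2), vacuum dielectric 1, no cutoff.
#'
#' @inheritParams pair_vdw
#' @return Energy, kcal/mol.
#' @export
pair_coulomb <- function(system, frame, mask_a, mask_b) {
  check_masks(mask_a, mask_b)
  sum(coulomb_matrix(system, frame, mask_a, mask_b))
}

# OBC-II effective Born radii from the HCT pairwise-descreening integral with
# the tanh rescaling (alpha = 1.0, beta = 0.8, gamma = 4.85).
effective_born_radii <- function(xyz, radii, offset = 0.09, scale = 0.8,
                                 alpha = 1.0, beta = 0.8, gamma = 4.85) {
  n <- nrow(xyz)
  rho <- radii - offset
  if (any(rho <= 0)) stop("born_radius must exceed the dielectric offset")
  if (n == 1L) return(rho)
  r <- cross_dist(xyz, seq_len(n), seq_len(n))
  sr <- scale * rho                       # scaled descreening radii (by column j)
  srm <- matrix(sr, n, n, byrow = TRUE)
  rhom <- matrix(rho, n, n)               # rho_i by row
  L <- pmax(rhom, abs(r - srm))
  U <- r + srm
  diag(r) <- 1                            # avoid 0/0 on the diagonal; masked out
  term <- (1 / L - 1 / U) +
    0.25 * (r - srm^2 / r) * (1 / U^2 - 1 / L^2) +
    (0.5 / r) * log(L / U)
  inside <- rhom < (srm - r)              # atom i buried inside scaled j
  term <- term + ifelse(inside, 2 * (1 / rhom - 1 / L), 0)
  excl <- diag(n) == 1 | (rhom >= U)      # self pairs and fully engulfed j
  term[excl] <- 0
  psi <- 0.5 * rho * rowSums(term)
  inv <- 1 / rho - tanh(alpha * psi - beta * psi^2 + gamma * psi^3) / radii
  if (any(inv <= 0)) stop("non-positive inverse effective Born radius")
  1 / inv
}

# full pairwise GB energy matrix (including diagonal self terms); total is
# sum of all entries. Entry (i, j), i != j, carries half of the ordered-pair
# double sum so the matrix sums to the standard still-water GB energy.
gb_matrix <- function(xyz, q, radii, eps_solvent, offset, scale) {
  tau <- 1 - 1 / eps_solvent
  if (tau == 0) return(matrix(0, nrow(xyz), nrow(xyz)))
  reff <- effective_born_radii(xyz, radii, offset = offset, scale = scale)
  n <- nrow(xyz)
  r <- cross_dist(xyz, seq_len(n), seq_len(n))
  rr <- outer(reff, reff)
  f <- sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
  -0.5 * KE * tau * outer(q, q) / f
}

#' Generalized-Born polar solvation energy (OBC-II)
#'
#' `dG_gb = -1/2 k_e (1 - 1/eps) sum_ij q_i q_j / f_ij` with
#' `f_ij = sqrt(r_ij^2 + R_i R_j exp(-r_ij^2 / (4 R_i R_j)))`, including the
#' i = j Born self terms. Effective radii `R_i` come from the OBC-II
#' pairwise-descreening recipe (tanh correction, alpha 1.0, beta 0.8,
#' gamma 4.85) applied to the intrinsic `born_radius` column minus the
#' dielectric `offset`.
#'
#' @inheritParams pair_vdw
#' @param mask atom-index set.
#' @param eps_solvent exterior dielectric (80 for water); interior is 1.
#' @param offset dielectric offset subtracted from intrinsic radii, A.
#' @param scale HCT descreening scale factor.
#' @return Energy, kcal/mol (0 exactly when `eps_solvent = 1`).
#' @export
gb_energy <- function(system, frame, mask = seq_len(n_atoms(system)),
                      eps_solvent = 80, offset = 0.09, scale = 0.8) {
  xyz <- frame_coords(system, frame)[mask, , drop = FALSE]
  at <- system$atoms
  sum(gb_matrix(xyz, at$charge[mask], at$born_radius[mask],
                eps_solvent, offset, scale))
}

# deterministic golden-spiral unit sphere points
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# per-atom solvent-accessible surface areas, A^2
sasa_per_atom <- function(system, frame, mask, probe = 1.4, n_points = 960) {
  if (probe < 0) stop("probe must be >= 0")
  if (n_points < 12) stop("n_points must be >= 12")
  xyz <- frame_coords(system, frame)[mask, , drop = FALSE]
  rad <- system$atoms$rmin_half[mask] + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d <- cross_dist(xyz, seq_len(n), seq_len(n))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    p <- xyz[rep(i, n_points), , drop = FALSE] + rad[i] * pts
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rad[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  areas
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA over the mask atoms with atomic radius `rmin_half + probe`
#' and a deterministic golden-spiral quadrature of `n_points` per atom.
#'
#' @inheritParams gb_energy
#' @param probe probe radius, A (1.4 = water).
#' @param n_points quadrature points per atom (>= 12).
#' @return Area, A^2.
#' @export
sasa <- function(system, frame, mask = seq_len(n_atoms(system)),
                 probe = 1.4, n_points = 960) {
  sum(sasa_per_atom(system, frame, mask, probe = probe, n_points = n_points))
}

#' Non-polar solvation energy from SASA
#'
#' The empirical surface term `gamma * SASA + beta`. The study's values are
#' `gamma = 0.005` kcal/(mol A^2) and `beta = 0` kcal/mol.
#'
#' @param area SASA, A^2 (>= 0).
#' @param gamma surface tension coefficient, kcal/(mol A^2).
#' @param beta offset, kcal/mol.
#' @return Energy, kcal/mol.
#' @export
nonpolar_energy <- function(area, gamma = 0.005, beta = 0) {
  if (any(area < 0)) stop("area must be >= 0")
  gamma * area + beta
}

#' Gas-phase interaction energy across the binding partition
#'
#' `pair_vdw + pair_coulomb` between the receptor and ligand atom sets. This
#' is the E_int whose fluctuations feed the interaction-entropy estimator.
#'
#' @inheritParams pair_vdw
#' @return Energy, kcal/mol.
#' @export
gas_phase_interaction <- function(system, frame) {
  rec <- group_mask(system, "receptor")
  lig <- group_mask(system, "ligand")
  pair_vdw(system, frame, rec, lig) + pair_coulomb(system, frame, rec, lig)
}

#' Gas-phase interaction-energy series over all frames
#'
#' Convenience wrapper evaluating [gas_phase_interaction()] on every frame;
#' times are `dt * (frame - 1)` ps.
#'
#' @param system a `ToySystem`.
#' @param dt frame spacing, ps.
#' @return An [energy_series()].
#' @export
interaction_energy_series <- function(system, dt = 1) {
  vals <- vapply(seq_len(n_frames(system)), function(f)
    gas_phase_interaction(system, f), numeric(1))
  energy_series(dt * (seq_along(vals) - 1), vals, label = "E_int")
}
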