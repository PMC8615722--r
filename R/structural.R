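# Trajectory-level geometric analyses: Kabsch-superposed RMSD, per-atom
# coordinate RMSF, hydrogen-bond occupancy, group-distance series/histograms
# and lowest-energy frame selection.

# optimal rotation (Kabsch, SVD with reflection fix) of P onto Q; both centered
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

center <- function(M) sweep(M, 2, colMeans(M))

check_mask_rank <- function(M) {
  sv <- svd(center(M), nu = 0, nv = 0)$d
  if (length(M[, 1]) < 3 || sv[2] < 1e-8)
    stop("alignment mask is degenerate (fewer than 3 non-collinear atoms)")
}

#' RMSD series after optimal superposition
#'
#' Per-frame root-mean-square deviation of the mask atoms from a reference
#' frame, after Kabsch alignment of the mask.
#'
#' @param system a `ToySystem`.
#' @param reference reference frame index.
#' @param mask atom indices (>= 3, non-collinear).
#' @return Numeric vector, A, one value per frame.
#' @export
rmsd_series <- function(system, reference = 1,
                        mask = seq_len(n_atoms(system))) {
  Q0 <- frame_coords(system, reference)[mask, , drop = FALSE]
  check_mask_rank(Q0)
  Q <- center(Q0)
  vapply(seq_len(n_frames(system)), function(f) {
    P <- center(frame_coords(system, f)[mask, , drop = FALSE])
    R <- kabsch_rotation(P, Q)
    sqrt(mean(rowSums((P %*% R - Q)^2)))
  }, numeric(1))
}

#' Per-atom coordinate RMSF
#'
#' Aligns every frame's mask onto the first frame (Kabsch), computes the mean
#' structure, and returns each atom's root-mean-square deviation about it.
#'
#' @inheritParams rmsd_series
#' @return Numeric vector, A, one value per mask atom.
#' @export
rmsf_coords <- function(system, mask = seq_len(n_atoms(system))) {
  nf <- n_frames(system)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  Q0 <- frame_coords(system, 1)[mask, , drop = FALSE]
  check_mask_rank(Q0)
  Q <- center(Q0)
  aligned <- lapply(seq_len(nf), function(f) {
    P <- center(frame_coords(system, f)[mask, , drop = FALSE])
    P %*% kabsch_rotation(P, Q)
  })
  M <- Reduce(`+`, aligned) / nf
  sq <- Reduce(`+`, lapply(aligned, function(A) rowSums((A - M)^2))) / nf
  sqrt(sq)
}

#' Hydrogen-bond occupancy, distance and angle
#'
#' A frame satisfies the bond when the donor-acceptor heavy-atom distance is
#' at most `max_distance` and the donor-H...acceptor angle (at the hydrogen)
#' is at least `min_angle`. Occupancy is the percentage of satisfying frames;
#' the reported mean distance and angle are averaged over ALL frames, so a
#' never-formed pair still gets a (large) characteristic distance.
#'
#' @param system a `ToySystem`.
#' @param donor,acceptor selectors (see [select_atoms()]) resolving to the
#'   donor and acceptor heavy atoms; the donor's hydrogen is located
#'   automatically within its residue.
#' @param max_distance A (default 3.5).
#' @param min_angle degrees (default 135).
#' @return List with `occupancy` (%), `mean_distance` (A), `mean_angle`
#'   (deg), and the per-frame `distance`/`angle`/`satisfied` vectors.
#' @export
hbond_occupancy <- function(system, donor, acceptor, max_distance = 3.5,
                            min_angle = 135) {
  if (max_distance < 0 || min_angle < 0 || min_angle > 180)
    stop("invalid hydrogen-bond criterion")
  d_idx <- select_atoms(system, donor)[1]
  a_idx <- select_atoms(system, acceptor)[1]
  h_idx <- find_donor_hydrogen(system, d_idx)
  nf <- n_frames(system)
  dist <- ang <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(system, f)
    dvec <- xyz[a_idx, ] - xyz[d_idx, ]
    dist[f] <- sqrt(sum(dvec^2))
    v1 <- xyz[d_idx, ] - xyz[h_idx, ]
    v2 <- xyz[a_idx, ] - xyz[h_idx, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang[f] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  sat <- dist <= max_distance & ang >= min_angle
  list(occupancy = 100 * mean(sat), mean_distance = mean(dist),
       mean_angle = mean(ang), distance = dist, angle = ang, satisfied = sat)
}

#' Group-distance series and histogram
#'
#' Per-frame distance between two atom groups: `"centroid"` mode uses
#' unweighted centroids (e.g. alkyl to base-ring center of a CH-pi contact),
#' `"min_atom_pair"` the minimum cross-pair distance (e.g. charged group to
#' phosphate for a salt bridge).
#'
#' @param system a `ToySystem`.
#' @param group_a,group_b selectors (see [select_atoms()]).
#' @param mode `"centroid"` or `"min_atom_pair"`.
#' @param bin_width histogram bin width, A.
#' @return List with `distance` (per frame, A), `mean` and `histogram`
#'   (data.frame: mid, count, density).
#' @export
distance_series <- function(system, group_a, group_b,
                            mode = c("centroid", "min_atom_pair"),
                            bin_width = 0.2) {
  mode <- match.arg(mode)
  ga <- select_atoms(system, group_a)
  gb <- select_atoms(system, group_b)
  d <- vapply(seq_len(n_frames(system)), function(f) {
    xyz <- frame_coords(system, f)
    if (mode == "centroid") {
      sqrt(sum((colMeans(xyz[ga, , drop = FALSE]) -
                  colMeans(xyz[gb, , drop = FALSE]))^2))
    } else {
      min(cross_dist(xyz, ga, gb))
    }
  }, numeric(1))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(distance = d, mean = mean(d),
       histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density))
}

#' Lowest-energy frame
#'
#' Index of the minimum of a per-frame enthalpy series; ties go to the
#' earliest frame.
#'
#' @param dh_series numeric per-frame dH, kcal/mol.
#' @return 1-based frame index.
#' @export
lowest_energy_frame <- function(dh_series) {
  if (!length(dh_series)) stop("empty enthalpy series")
  which.min(dh_series)
}
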