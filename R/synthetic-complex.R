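# Synthetic protein-RNA toy complexes: a ring of identical protein chains
# (hexamer-like) with a short single-stranded RNA-like chain docked above the
# ring face, plus per-atom parameters. Contact pairs (hydrogen bonds, salt
# bridges, CH-pi contacts) are imposed geometrically in an exact, seeded
# subset of frames so that downstream occupancy/distance analyses have known
# ground truth.

# placeholder residue templates: local offsets from the residue anchor (A)
PROTEIN_TEMPLATE <- data.frame(
  name = c("N", "H", "CA", "CB", "NZ", "HZ", "C", "O"),
  element = c("N", "H", "C", "C", "N", "H", "C", "O"),
  dx = c(-1.2, -1.2, 0.0, 0.0, 0.0, 0.0, 1.2, 1.4),
  dy = c(0.5, 1.5, 0.0, -0.8, -1.6, -1.6, 0.5, 1.7),
  dz = c(0.0, 0.0, 0.0, 1.4, 2.9, 3.9, 0.0, 0.0),
  charge = c(-0.4, 0.3, 0.1, 0.0, 1.0, 0.4, 0.5, -0.5),
  stringsAsFactors = FALSE)

RNA_TEMPLATE <- local({
  ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- (0:5) * pi / 3
  data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C1'", ring_names),
    element = c("P", "O", "O", "O", "C", "N", "C", "N", "C", "C", "C"),
    dx = c(-1.5, -2.4, -1.0, -0.5, 0.0, 1.4 * cos(ang)),
    dy = c(1.8, 2.5, 2.6, 1.0, 1.2, 1.4 * sin(ang)),
    dz = c(0.5, 1.2, -0.5, 1.0, -0.8, rep(0, 6)),
    charge = c(1.2, -0.8, -0.8, -0.5, 0.1, -0.5, 0.2, -0.5, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE)
})

# element -> (rmin_half A, epsilon kcal/mol, intrinsic Born radius A)
ELEMENT_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "P"),
  rmin_half = c(0.6, 1.908, 1.824, 1.661, 2.1),
  epsilon = c(0.0157, 0.086, 0.17, 0.21, 0.2),
  born_radius = c(1.2, 1.7, 1.55, 1.5, 1.85),
  stringsAsFactors = FALSE)

#' Specification of a synthetic protein-RNA toy complex
#'
#' @param n_protein_chains number of identical protein chains arranged on a
#'   ring (6 emulates an Sm-like hexamer).
#' @param residues_per_chain residues per protein chain.
#' @param n_rna_nucleotides length of the single-stranded RNA-like ligand
#'   (7 matches an A-rich heptamer).
#' @param contact_pairs list of intended interactions. Each entry is a list
#'   with `type` (`"hbond"`, `"salt_bridge"` or `"ch_pi"`), selectors
#'   (`donor`/`acceptor` for hbond, `group_a` receptor-side and `group_b`
#'   ligand-side otherwise; see [select_atoms()]), `target_distance` (A) and
#'   `on_fraction` (proportion of frames in which the geometry holds).
#' @param n_frames number of trajectory frames.
#' @param jitter_sigma per-axis Gaussian coordinate jitter, A.
#' @param seed RNG seed.
#' @return A list of class `ComplexSpec`.
#' @export
complex_spec <- function(n_protein_chains = 6, residues_per_chain = 8,
                         n_rna_nucleotides = 7, contact_pairs = list(),
                         n_frames = 10, jitter_sigma = 0.08, seed = 1) {
  if (n_protein_chains < 1 || residues_per_chain < 1 || n_rna_nucleotides < 1)
    stop("chain/residue counts must be >= 1")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  for (cp in contact_pairs) {
    if (!cp$type %in% c("hbond", "salt_bridge", "ch_pi"))
      stopf("unknown contact type '%s'", cp$type)
    if (is.null(cp$target_distance) || cp$target_distance <= 0)
      stop("contact target_distance must be > 0")
    of <- cp$on_fraction %||% 1
    if (of < 0 || of > 1) stop("on_fraction must be in [0, 1]")
  }
  structure(list(n_protein_chains = n_protein_chains,
                 residues_per_chain = residues_per_chain,
                 n_rna_nucleotides = n_rna_nucleotides,
                 contact_pairs = contact_pairs, n_frames = n_frames,
                 jitter_sigma = jitter_sigma, seed = seed),
            class = "ComplexSpec")
}

# base (frame-independent) coordinates + atom table
build_base_complex <- function(spec) {
  rows <- list()
  xyz <- list()
  ring_radius <- 8 + 1.2 * spec$residues_per_chain
  for (c_i in seq_len(spec$n_protein_chains)) {
    chain <- LETTERS[c_i]
    theta0 <- 2 * pi * (c_i - 1) / spec$n_protein_chains
    for (r_i in seq_len(spec$residues_per_chain)) {
      phi <- theta0 + (r_i - (spec$residues_per_chain + 1) / 2) * 3.8 / ring_radius
      anchor <- c(ring_radius * cos(phi), ring_radius * sin(phi), 0)
      t <- PROTEIN_TEMPLATE
      rows[[length(rows) + 1L]] <- data.frame(
        name = t$name, element = t$element, chain = chain, resi = r_i,
        resn = "TOY", charge = t$charge, group = "receptor",
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- cbind(anchor[1] + t$dx, anchor[2] + t$dy,
                                       anchor[3] + t$dz)
    }
  }
  for (k in seq_len(spec$n_rna_nucleotides)) {
    center <- c(3.9 * (k - (spec$n_rna_nucleotides + 1) / 2), 0, 7)
    t <- RNA_TEMPLATE
    rows[[length(rows) + 1L]] <- data.frame(
      name = t$name, element = t$element, chain = "R", resi = k,
      resn = "ADE", charge = t$charge, group = "ligand",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- cbind(center[1] + t$dx, center[2] + t$dy,
                                     center[3] + t$dz)
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  pi_ <- match(atoms$element, ELEMENT_PARAMS$element)
  atoms$rmin_half <- ELEMENT_PARAMS$rmin_half[pi_]
  atoms$epsilon <- ELEMENT_PARAMS$epsilon[pi_]
  atoms$born_radius <- ELEMENT_PARAMS$born_radius[pi_]
  list(atoms = atoms, base = do.call(rbind, xyz))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction vector")
  v / n
}

#' Generate a synthetic protein-RNA toy complex trajectory
#'
#' Builds the base geometry, jitters every atom per frame, then enforces each
#' requested contact: in exactly `round(on_fraction * n_frames)` frames
#' (seeded draw) the ligand-side atoms are placed so the contact geometry
#' holds at `target_distance` exactly (hydrogen bonds additionally collinear,
#' i.e. donor-H-acceptor angle 180 deg); in the remaining frames they are
#' displaced to `target_distance + 6` A along the same direction, which
#' defeats any conventional distance cutoff. Only ligand (RNA) atoms are
#' moved, mirroring a rigid receptor. Deterministic under the spec seed.
#'
#' @param spec a [complex_spec()].
#' @return A [toy_system()]; attribute `"contact_frames"` records, per
#'   contact, the 1-based frame indices in which it is realized.
#' @export
gen_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "ComplexSpec"))
  bb <- build_base_complex(spec)
  nf <- spec$n_frames
  na <- nrow(bb$atoms)
  sys0 <- toy_system(bb$atoms, array(rep(bb$base, each = 1), c(1, na, 3)))

  # resolve contacts and check hard-sphere feasibility on the defining pair
  contacts <- lapply(spec$contact_pairs, function(cp) {
    if (cp$type == "hbond") {
      d_idx <- select_atoms(sys0, cp$donor)[1]
      a_idx <- select_atoms(sys0, cp$acceptor)[1]
      lig <- sys0$atoms$group == "ligand"
      if (lig[a_idx] == lig[d_idx])
        stop("hbond contact must span the receptor/ligand partition")
      pair <- c(d_idx, a_idx)
      list(type = "hbond", donor = d_idx, acceptor = a_idx,
           h = if (!lig[d_idx]) find_donor_hydrogen(sys0, d_idx) else NA_integer_,
           donor_on_ligand = lig[d_idx], pair = pair,
           target = cp$target_distance, on_fraction = cp$on_fraction %||% 1)
    } else {
      ga <- select_atoms(sys0, cp$group_a)
      gb <- select_atoms(sys0, cp$group_b)
      if (any(sys0$atoms$group[ga] == "ligand") ||
          any(sys0$atoms$group[gb] != "ligand"))
        stop("group_a must be receptor-side and group_b ligand-side")
      # defining pair: closest cross pair in base geometry
      d2 <- outer(seq_along(ga), seq_along(gb), function(i, j)
        rowSums((bb$base[ga[i], , drop = FALSE] - bb$base[gb[j], , drop = FALSE])^2))
      w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      list(type = cp$type, group_a = ga, group_b = gb,
           pair = c(ga[w[1]], gb[w[2]]), target = cp$target_distance,
           on_fraction = cp$on_fraction %||% 1)
    }
  })
  for (ct in contacts) {
    core <- 0.75 * sum(sys0$atoms$rmin_half[ct$pair])
    if (ct$target < core)
      stopf("contact target %.2f A overlaps hard spheres (core %.2f A)",
            ct$target, core)
  }

  with_seed(spec$seed, {
    on_sets <- lapply(contacts, function(ct) {
      n_on <- round(ct$on_fraction * nf)
      if (n_on > 0) sort(sample.int(nf, n_on)) else integer(0)
    })
    coords <- array(0, c(nf, na, 3))
    for (f in seq_len(nf)) {
      xyz <- bb$base + matrix(stats::rnorm(3 * na, sd = spec$jitter_sigma), na, 3)
      for (k in seq_along(contacts)) {
        ct <- contacts[[k]]
        on <- f %in% on_sets[[k]]
        dist <- if (on) ct$target else ct$target + 6
        if (ct$type == "hbond") {
          if (!ct$donor_on_ligand) {
            d <- xyz[ct$donor, ]; h <- xyz[ct$h, ]
            u <- unit(h - d)
            xyz[ct$acceptor, ] <- d + dist * u
          } else {
            a <- xyz[ct$acceptor, ]
            u <- unit(bb$base[ct$donor, ] - a)
            xyz[ct$donor, ] <- a + dist * u
            hd <- find_donor_hydrogen(sys0, ct$donor)
            xyz[hd, ] <- xyz[ct$donor, ] - u  # 1 A, collinear with acceptor
          }
        } else {
          a_star <- xyz[ct$pair[1], ]; b_star <- xyz[ct$pair[2], ]
          if (ct$type == "ch_pi") {
            # realize as centroid-centroid distance
            ca <- colMeans(xyz[ct$group_a, , drop = FALSE])
            cb <- colMeans(xyz[ct$group_b, , drop = FALSE])
            u <- unit(cb - ca)
            shift <- (ca + dist * u) - cb
          } else {
            u <- unit(b_star - a_star)
            shift <- (a_star + dist * u) - b_star
          }
          xyz[ct$group_b, ] <- xyz[ct$group_b, , drop = FALSE] +
            matrix(shift, length(ct$group_b), 3, byrow = TRUE)
        }
      }
      coords[f, , ] <- xyz
    }
    out <- toy_system(bb$atoms, coords)
    attr(out, "contact_frames") <- on_sets
    out
  })
}
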