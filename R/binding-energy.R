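# MM/GBSA enthalpy under the single-trajectory protocol: receptor and ligand
# energies are evaluated on the complex frames themselves, so bonded/internal
# terms cancel and the gas-phase deltas reduce to cross-partition pair sums.

gb_default <- list(eps_solvent = 80, offset = 0.09, scale = 0.8)
sasa_default <- list(probe = 1.4, n_points = 960)
np_default <- list(gamma = 0.005, beta = 0)

residue_key <- function(atoms, idx = seq_len(nrow(atoms))) {
  paste(atoms$chain[idx], atoms$resi[idx], sep = ":")
}

#' Per-frame MM/GBSA enthalpy decomposition
#'
#' Computes, for one complex frame, the four binding-enthalpy terms
#' `dE_vdw`, `dE_ele`, `dG_gb`, `dG_np` as complex-minus-parts differences
#' (the gas-phase terms reduce exactly to cross-partition pair sums), plus a
#' per-atom split: cross pair energies half to each partner atom, GB
#' self/cross terms by atom ownership, non-polar by per-atom SASA difference.
#'
#' @param system a `ToySystem`.
#' @param frame frame index.
#' @param gb,sasa_opts,np option lists overriding the defaults
#'   (`eps_solvent = 80, offset = 0.09, scale = 0.8`; `probe = 1.4,
#'   n_points = 960`; `gamma = 0.005, beta = 0`).
#' @return List with `totals` (named: vdw, ele, gb, np, dh) and `per_atom`
#'   (matrix n_atoms x 4).
#' @export
frame_enthalpy <- function(system, frame, gb = list(), sasa_opts = list(),
                           np = list()) {
  gb <- utils::modifyList(gb_default, gb)
  so <- utils::modifyList(sasa_default, sasa_opts)
  np <- utils::modifyList(np_default, np)
  rec <- group_mask(system, "receptor")
  lig <- group_mask(system, "ligand")
  na <- n_atoms(system)
  at <- system$atoms
  xyz <- frame_coords(system, frame)

  vm <- vdw_matrix(system, frame, rec, lig)
  cm <- coulomb_matrix(system, frame, rec, lig)
  pa <- matrix(0, na, 4, dimnames = list(NULL, c("vdw", "ele", "gb", "np")))
  pa[rec, "vdw"] <- 0.5 * rowSums(vm); pa[lig, "vdw"] <- 0.5 * colSums(vm)
  pa[rec, "ele"] <- 0.5 * rowSums(cm); pa[lig, "ele"] <- 0.5 * colSums(cm)

  gbm_all <- gb_matrix(xyz, at$charge, at$born_radius,
                       gb$eps_solvent, gb$offset, gb$scale)
  gb_atom <- rowSums(gbm_all)
  for (m in list(rec, lig)) {
    sub <- gb_matrix(xyz[m, , drop = FALSE], at$charge[m], at$born_radius[m],
                     gb$eps_solvent, gb$offset, gb$scale)
    gb_atom[m] <- gb_atom[m] - rowSums(sub)
  }
  pa[, "gb"] <- gb_atom

  s_all <- sasa_per_atom(system, frame, seq_len(na), so$probe, so$n_points)
  s_atom <- s_all
  for (m in list(rec, lig))
    s_atom[m] <- s_atom[m] - sasa_per_atom(system, frame, m, so$probe, so$n_points)
  # beta enters the complex and each part once: net -beta, spread over no atom
  pa[, "np"] <- np$gamma * s_atom
  np_total <- sum(pa[, "np"]) - np$beta

  totals <- c(vdw = sum(vm), ele = sum(cm), gb = sum(gb_atom), np = np_total)
  totals["dh"] <- sum(totals)
  list(totals = totals, per_atom = pa)
}

#' Per-frame enthalpy series and summary over an analysis window
#'
#' Applies [frame_enthalpy()] to each requested frame (stride 1) and
#' aggregates: term means, mean dH and its standard error over frames.
#'
#' @inheritParams frame_enthalpy
#' @param frames frame indices (default: all).
#' @return List of class `EnthalpySummary` with `per_frame` (data.frame:
#'   frame, vdw, ele, gb, np, dh), `term_means`, `mean_dh`, `sem_dh`,
#'   `n_frames`, and `per_atom_mean` (matrix, for the residue decomposition).
#' @export
enthalpy_series <- function(system, frames = seq_len(n_frames(system)),
                            gb = list(), sasa_opts = list(), np = list()) {
  if (!length(frames)) stop("empty frame window")
  acc <- NULL
  rows <- matrix(0, length(frames), 5,
                 dimnames = list(NULL, c("vdw", "ele", "gb", "np", "dh")))
  for (k in seq_along(frames)) {
    fe <- frame_enthalpy(system, frames[k], gb = gb, sasa_opts = sasa_opts,
                         np = np)
    rows[k, ] <- fe$totals[colnames(rows)]
    acc <- if (is.null(acc)) fe$per_atom else acc + fe$per_atom
  }
  per_frame <- data.frame(frame = frames, rows)
  dh <- per_frame$dh
  structure(list(per_frame = per_frame,
                 term_means = colMeans(rows[, 1:4, drop = FALSE]),
                 mean_dh = mean(dh),
                 sem_dh = if (length(dh) > 1) stats::sd(dh) / sqrt(length(dh)) else 0,
                 n_frames = length(frames),
                 per_atom_mean = acc / length(frames)),
            class = "EnthalpySummary")
}

#' @export
print.EnthalpySummary <- function(x, ...) {
  cat(sprintf("MM/GBSA enthalpy over %d frames: dH = %.2f +/- %.2f kcal/mol\n",
              x$n_frames, x$mean_dh, x$sem_dh))
  cat(sprintf("  vdw %.2f  ele %.2f  gb %.2f  np %.2f\n",
              x$term_means["vdw"], x$term_means["ele"], x$term_means["gb"],
              x$term_means["np"]))
  invisible(x)
}

#' Per-residue decomposition of the binding enthalpy
#'
#' Mean per-residue contribution over the analysis window, split into vdW,
#' electrostatic, GB, non-polar, the conventional `ele + gb` grouping, and
#' the total. Pairwise terms are split half to each partner residue, so the
#' vdW / ele columns sum over all residues (both partners) to the
#' corresponding totals.
#'
#' @inheritParams enthalpy_series
#' @param summary optionally, a precomputed [enthalpy_series()] result.
#' @return data.frame with columns `chain`, `resi`, `resn`, `vdw`, `ele`,
#'   `gb`, `np`, `ele_plus_gb`, `total`, one row per residue.
#' @export
per_residue_decomposition <- function(system,
                                      frames = seq_len(n_frames(system)),
                                      gb = list(), sasa_opts = list(),
                                      np = list(), summary = NULL) {
  if (is.null(summary))
    summary <- enthalpy_series(system, frames, gb = gb,
                               sasa_opts = sasa_opts, np = np)
  at <- system$atoms
  key <- residue_key(at)
  agg <- rowsum(summary$per_atom_mean, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chain = at$chain[first], resi = at$resi[first],
                    resn = at$resn[first],
                    agg[match(key[first], rownames(agg)), , drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$ele_plus_gb <- out$ele + out$gb
  out$total <- out$vdw + out$ele + out$gb + out$np
  out
}

#' Key residues by enthalpy contribution
#'
#' Residues whose mean total contribution is at least as favorable as
#' `threshold` (a negative number, e.g. -2.5 kcal/mol), sorted most
#' favorable first.
#'
#' @param per_residue output of [per_residue_decomposition()].
#' @param threshold kcal/mol, must be < 0.
#' @return Subset of `per_residue`, ordered ascending by `total`.
#' @export
key_residues <- function(per_residue, threshold = -2.5) {
  if (threshold >= 0) stop("threshold must be < 0")
  hit <- per_residue[per_residue$total <= threshold, , drop = FALSE]
  hit[order(hit$total), , drop = FALSE]
}
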