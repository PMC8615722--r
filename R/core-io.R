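#' Toy molecular system container
#'
#' A `ToySystem` bundles an atom table (identity, force-field-like parameters
#' and receptor/ligand partition) with one or more coordinate frames, the way a
#' topology plus trajectory pair would in a real MD workflow. It is the input
#' to every energetic and structural analysis in the package.
#'
#' @param atoms data.frame with columns `atom_id`, `name`, `element`, `chain`,
#'   `resi` (1-based, per chain), `resn`, `charge` (e), `rmin_half` (A),
#'   `epsilon` (kcal/mol), `born_radius` (A), `group` (`"receptor"` or
#'   `"ligand"`).
#' @param coords numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param temperature simulation temperature, K.
#'
#' @return An object of class `ToySystem`.
#' @export
toy_system <- function(atoms, coords, temperature = 300) {
  req <- c("atom_id", "name", "element", "chain", "resi", "resn",
           "charge", "rmin_half", "epsilon", "born_radius", "group")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stopf("atoms table missing columns: %s", paste(miss, collapse = ", "))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[1] < 1L) stop("at least one frame is required")
  if (dim(coords)[2] != nrow(atoms))
    stopf("coords has %d atoms but atom table has %d", dim(coords)[2], nrow(atoms))
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(atoms$born_radius <= 0)) stop("born_radius must be > 0 for every atom")
  if (any(atoms$epsilon < 0)) stop("epsilon must be >= 0")
  if (!all(atoms$group %in% c("receptor", "ligand")))
    stop("group must be 'receptor' or 'ligand' for every atom")
  key <- paste(atoms$chain, atoms$resi, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate atom key (chain, resi, name): %s", key[anyDuplicated(key)])
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 coords = coords, temperature = temperature),
            class = "ToySystem")
}

#' @export
print.ToySystem <- function(x, ...) {
  cat(sprintf("ToySystem: %d atoms (%d receptor, %d ligand), %d frame(s), T = %g K\n",
              nrow(x$atoms), sum(x$atoms$group == "receptor"),
              sum(x$atoms$group == "ligand"), n_frames(x), x$temperature))
  invisible(x)
}

#' @rdname toy_system
#' @param system a `ToySystem`.
#' @export
n_frames <- function(system) dim(system$coords)[1]

#' @rdname toy_system
#' @export
n_atoms <- function(system) dim(system$coords)[2]

# n_atoms x 3 coordinate matrix of one frame
frame_coords <- function(system, frame) {
  nf <- n_frames(system)
  if (frame < 1L || frame > nf) stopf("frame %d out of range 1..%d", frame, nf)
  matrix(system$coords[frame, , ], ncol = 3L)
}

# Atom indices of one side of the binding partition
group_mask <- function(system, group = c("receptor", "ligand")) {
  which(system$atoms$group == match.arg(group))
}

#' Interaction-energy time series
#'
#' Holds a gas-phase interaction-energy trace E_int(t): times in ps (strictly
#' increasing) and energies in kcal/mol. This is the object the
#' interaction-entropy machinery ([scan_windows()], [filter_outliers()],
#' [ie_entropy()]) consumes.
#'
#' @param times numeric, ps, strictly increasing.
#' @param values numeric, kcal/mol, finite.
#' @param label optional text label.
#' @return An object of class `EnergySeries`.
#' @export
energy_series <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (length(times) < 2L) stop("an energy series needs at least 2 points")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("times and values must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "EnergySeries")
}

#' @export
print.EnergySeries <- function(x, ...) {
  cat(sprintf("EnergySeries '%s': %d points, t = [%g, %g] ps, mean %.3f kcal/mol\n",
              x$label, length(x$times), x$times[1], x$times[length(x$times)],
              mean(x$values)))
  invisible(x)
}

#' @export
length.EnergySeries <- function(x) length(x$times)

# ---- file input helpers -----------------------------------------------------

# Accept a file path or raw text; return character vector of lines.
as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x)
  else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read a multi-model PDB plus parameter table into a ToySystem
#'
#' Frames are taken from `MODEL`/`ENDMDL` records (a model-less file is a
#' single frame). Per-atom parameters and the receptor/ligand partition come
#' from a delimited table with header
#' `chain,resi,resn,atom,charge,rmin_half,epsilon,born_radius,group`, matched
#' to PDB atoms by (chain, residue index, atom name). Altloc and insertion
#' codes are rejected.
#'
#' @param pdb file path or PDB text.
#' @param params file path or delimited text of the parameter table.
#' @param temperature K, stored on the system.
#' @return A [toy_system()].
#' @export
read_models <- function(pdb, params, temperature = 300) {
  lines <- as_lines(pdb)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grepl("^MODEL", lines)
  fld <- function(l, a, b) trimws(substr(l, a, b))
  parse_atoms <- function(ls) {
    altloc <- substr(ls, 17, 17)
    icode <- substr(ls, 27, 27)
    if (any(altloc != " ")) stop("altloc records are not supported")
    if (any(icode != " ")) stop("insertion codes are not supported")
    data.frame(
      name = fld(ls, 13, 16), resn = fld(ls, 18, 20), chain = fld(ls, 22, 22),
      resi = as.integer(fld(ls, 23, 26)),
      x = as.numeric(fld(ls, 31, 38)), y = as.numeric(fld(ls, 39, 46)),
      z = as.numeric(fld(ls, 47, 54)), element = fld(ls, 77, 78),
      stringsAsFactors = FALSE)
  }
  if (any(model_starts)) {
    # split atom lines by model blocks
    model_id <- cumsum(model_starts)
    blocks <- split(lines[atom_lines], model_id[atom_lines])
  } else {
    blocks <- list(lines[atom_lines])
  }
  if (!length(blocks) || !length(blocks[[1]])) stop("no ATOM records found")
  frames <- lapply(blocks, parse_atoms)
  n0 <- nrow(frames[[1]])
  for (k in seq_along(frames)) if (nrow(frames[[k]]) != n0)
    stopf("model %d has %d atoms but model 1 has %d", k, nrow(frames[[k]]), n0)

  ptab <- utils::read.csv(text = paste(as_lines(params), collapse = "\n"),
                          stringsAsFactors = FALSE)
  preq <- c("chain", "resi", "resn", "atom", "charge", "rmin_half",
            "epsilon", "born_radius", "group")
  miss <- setdiff(preq, names(ptab))
  if (length(miss)) stopf("parameter table missing columns: %s",
                          paste(miss, collapse = ", "))
  a1 <- frames[[1]]
  key_pdb <- paste(a1$chain, a1$resi, a1$name, sep = "|")
  key_par <- paste(ptab$chain, ptab$resi, ptab$atom, sep = "|")
  idx <- match(key_pdb, key_par)
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    stopf("no parameter row for atom chain %s, residue %d, atom %s",
          a1$chain[k], a1$resi[k], a1$name[k])
  }
  atoms <- data.frame(
    atom_id = seq_len(n0), name = a1$name, element = a1$element,
    chain = a1$chain, resi = a1$resi, resn = a1$resn,
    charge = ptab$charge[idx], rmin_half = ptab$rmin_half[idx],
    epsilon = ptab$epsilon[idx], born_radius = ptab$born_radius[idx],
    group = ptab$group[idx], stringsAsFactors = FALSE)
  coords <- array(0, c(length(frames), n0, 3L))
  for (k in seq_along(frames)) {
    fk <- frames[[k]]
    if (!identical(paste(fk$chain, fk$resi, fk$name, sep = "|"), key_pdb))
      stopf("model %d atom order differs from model 1", k)
    coords[k, , ] <- cbind(fk$x, fk$y, fk$z)
  }
  toy_system(atoms, coords, temperature = temperature)
}

#' Write a ToySystem as multi-model PDB plus parameter table
#'
#' Inverse of [read_models()]: coordinates at the PDB's native `%8.3f`
#' precision, parameters at full precision.
#'
#' @param system a `ToySystem`.
#' @param pdb_path,params_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_models <- function(system, pdb_path, params_path) {
  at <- system$atoms
  con <- file(pdb_path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(system))) {
    xyz <- frame_coords(system, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    recs <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$atom_id, at$name, at$resn, at$chain, at$resi,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  ptab <- data.frame(chain = at$chain, resi = at$resi, resn = at$resn,
                     atom = at$name, charge = at$charge,
                     rmin_half = at$rmin_half, epsilon = at$epsilon,
                     born_radius = at$born_radius, group = at$group)
  utils::write.csv(ptab, params_path, row.names = FALSE, quote = FALSE)
  invisible(c(pdb_path, params_path))
}

#' Read an interaction-energy time series from delimited text
#'
#' Two numeric columns (time in ps, energy in kcal/mol), comma / tab /
#' whitespace separated, optional header. Non-monotone times and non-finite
#' rows are hard errors.
#'
#' @param x file path or text.
#' @param label label stored on the series.
#' @return An [energy_series()].
#' @export
read_energy_series <- function(x, label = "") {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty energy-series input")
  toks <- strsplit(trimws(lines), "[,\t ]+")
  first <- suppressWarnings(as.numeric(toks[[1]][1]))
  if (is.na(first)) { toks <- toks[-1] }  # header
  if (length(toks) < 2L) stop("an energy series needs at least 2 rows")
  bad_ncol <- vapply(toks, length, 1L) < 2L
  if (any(bad_ncol)) stopf("row %d does not have two columns", which(bad_ncol)[1])
  tv <- suppressWarnings(vapply(toks, function(t) as.numeric(t[1:2]), numeric(2)))
  if (any(!is.finite(tv))) stopf("non-finite value at row %d",
                                 which(colSums(!is.finite(tv)) > 0)[1])
  if (any(diff(tv[1, ]) <= 0)) stop("times must be strictly increasing")
  energy_series(tv[1, ], tv[2, ], label = label)
}

#' Write an energy series as CSV
#'
#' Full `%.17g` precision so that write-read-write round-trips are
#' byte-identical.
#'
#' @param series an `EnergySeries`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_energy_series <- function(series, path) {
  writeLines(c("time,energy",
               sprintf("%.17g,%.17g", series$times, series$values)), path)
  invisible(path)
}

#' Assemble a per-trajectory free-energy result table
#'
#' One row per (system, trajectory) with dH, -TdS and their sum dG (kcal/mol)
#' plus standard errors. The dG column is validated against dH + (-TdS) at one
#' printed ulp (0.1 kcal/mol): two independently rounded addends can shift a
#' printed sum by exactly that much.
#'
#' @param rows data.frame with columns `system`, `trajectory`, `dh`, `se_dh`,
#'   `minus_tds`, and optionally `dg` (recomputed when absent).
#' @return data.frame of class `ResultTable`.
#' @export
result_table <- function(rows) {
  req <- c("system", "trajectory", "dh", "se_dh", "minus_tds")
  miss <- setdiff(req, names(rows))
  if (length(miss)) stopf("result rows missing columns: %s", paste(miss, collapse = ", "))
  if (is.null(rows$dg)) rows$dg <- rows$dh + rows$minus_tds
  bad <- abs(rows$dg - (rows$dh + rows$minus_tds)) > 0.1 + 1e-9
  if (any(bad))
    stopf("row %d: dG inconsistent with dH + (-TdS) beyond 0.1 kcal/mol", which(bad)[1])
  class(rows) <- c("ResultTable", "data.frame")
  rows
}
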