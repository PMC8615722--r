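# Atom selection by compact text expression "chain:resi:what", where `what`
# is an atom name, a '+'-joined list of names, or a named group. Named groups
# map to the placeholder chemistry of the synthetic complexes.

NAMED_GROUPS <- list(
  charged_group = c("NZ"),
  phosphate = c("P", "OP1", "OP2"),
  ring = c("N1", "C2", "N3", "C4", "C5", "C6"),
  alkyl = c("CB")
)

#' Resolve an atom selector against a system
#'
#' Selectors have the form `"chain:resi:what"` — e.g. `"A:3:NZ"`,
#' `"R:2:phosphate"`, `"A:5:CB+CA"`. `what` is an atom name, several names
#' joined by `+`, or one of the named groups `charged_group` (NZ),
#' `phosphate` (P, OP1, OP2), `ring` (six-membered base ring) and
#' `alkyl` (CB).
#'
#' @param system a `ToySystem`.
#' @param selector selector string, or an integer vector of atom indices
#'   (passed through).
#' @return Integer atom indices.
#' @export
select_atoms <- function(system, selector) {
  if (is.numeric(selector)) {
    idx <- as.integer(selector)
    if (any(idx < 1L | idx > n_atoms(system))) stop("atom index out of range")
    return(idx)
  }
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stopf("selector '%s' is not of the form chain:resi:atoms", selector)
  chain <- parts[1]
  resi <- as.integer(parts[2])
  names_req <- strsplit(parts[3], "+", fixed = TRUE)[[1]]
  if (length(names_req) == 1L && names_req %in% names(NAMED_GROUPS))
    names_req <- NAMED_GROUPS[[names_req]]
  at <- system$atoms
  idx <- which(at$chain == chain & at$resi == resi & at$name %in% names_req)
  if (!length(idx)) stopf("selector '%s' matches no atoms", selector)
  idx
}

# Hydrogen attached to a donor heavy atom: same chain+residue, element H,
# nearest in the first frame, within 1.5 A.
find_donor_hydrogen <- function(system, donor_idx) {
  at <- system$atoms
  cand <- which(at$chain == at$chain[donor_idx] & at$resi == at$resi[donor_idx] &
                  toupper(at$element) == "H")
  if (!length(cand)) stopf("donor atom %s has no attached hydrogen",
                           at$name[donor_idx])
  xyz <- frame_coords(system, 1)
  d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                       matrix(xyz[donor_idx, ], length(cand), 3, byrow = TRUE))^2))
  h <- cand[which.min(d)]
  if (min(d) > 1.5) stopf("nearest hydrogen to donor %s is %.2f A away",
                          at$name[donor_idx], min(d))
  h
}
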