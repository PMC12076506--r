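# Hydrogen-bond donor/acceptor feature typing.
#
# The feature chemistry mirrors the default donor/acceptor definitions of
# the standard cheminformatics toolkit feature factory; the definitions are
# shipped as a versioned data file (inst/extdata/feature_definitions.json)
# so results stay stable across toolkit versions. The matcher itself is a
# rule-based typer over the package's bond-matrix graphs:
#
#   donor:    N or O (or S) carrying at least one hydrogen (explicit or
#             implicit).
#   acceptor: O with no hydrogens (ether/carbonyl/carboxylate oxygens);
#             O-H whose heavy neighbour has no double bond to O/N/P/S
#             (hydroxyl but not carboxylic-acid OH);
#             trivalent N not adjacent (by a single bond) to an atom
#             double-bonded to O/N/P/S (amide/amidine nitrogens excluded)
#             and, if aromatic, carrying no hydrogen (pyridine yes,
#             pyrrole no); thioether S.

.FEATURE_FAMILIES <- c("donor", "acceptor")

atom_is_aromatic <- function(mol) {
  apply(mol$bonds == BOND_AROMATIC, 1, any)
}

# Does atom i have a neighbour (via single/aromatic bond) that is itself
# double-bonded to an electronegative atom (O/N/P/S)? Used to exclude
# amide-type nitrogens and acid hydroxyls from the acceptor set.
.adjacent_to_pi_acceptor_sink <- function(mol, i) {
  for (j in bonded_neighbors(mol, i)) {
    if (mol$bonds[i, j] != 1L) next
    dbl <- setdiff(which(mol$bonds[j, ] == 2L), i)
    if (any(mol$atom_types[dbl] %in% c("O", "N", "P", "S"))) return(TRUE)
  }
  FALSE
}

#' Type hydrogen-bond donor and acceptor atoms
#'
#' @param mol a `Molecule3D`.
#' @return data.frame with columns `atom` (index), `family`
#'   ("donor"/"acceptor"); an atom can appear under both families.
#' @export
feature_atoms <- function(mol) {
  hc <- hydrogen_count(mol)
  arom <- atom_is_aromatic(mol)
  bos <- bond_order_sum(mol)
  rows <- list()
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$atom_types[i]
    if (!(el %in% c("N", "O", "S"))) next
    if (hc[i] >= 1L && el %in% c("N", "O") ||
        (el == "S" && hc[i] == 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(atom = i, family = "donor")
    }
    acc <- FALSE
    if (el == "O") {
      if (hc[i] == 0L) acc <- TRUE
      else acc <- !.adjacent_to_pi_acceptor_sink(mol, i)
    } else if (el == "N") {
      v3 <- (bos[i] + hc[i]) <= 3 + 1e-9
      if (v3 && !.adjacent_to_pi_acceptor_sink(mol, i)) {
        acc <- !(arom[i] && hc[i] >= 1L)
      }
    } else if (el == "S") {
      if (hc[i] == 0L) acc <- bos[i] <= 2 + 1e-9 || arom[i]
      else if (hc[i] == 1L) acc <- !.adjacent_to_pi_acceptor_sink(mol, i)
    }
    if (acc) rows[[length(rows) + 1L]] <- data.frame(atom = i,
                                                     family = "acceptor")
  }
  if (length(rows) == 0L)
    return(data.frame(atom = integer(0), family = character(0)))
  do.call(rbind, rows)
}

#' A pharmacophore point
#'
#' @param position numeric 3-vector (Angstrom).
#' @param family feature family, one of the registered vocabulary
#'   ("donor", "acceptor").
#' @param source_atom_index optional index of the reference-ligand atom the
#'   point was derived from.
#' @return an object of class `PharmacophorePoint`.
#' @export
pharmacophore_point <- function(position, family,
                                source_atom_index = NA_integer_) {
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position)))
    stop("position must be a finite 3-vector")
  if (!family %in% .FEATURE_FAMILIES)
    stop("unknown feature family: ", family)
  structure(list(position = position, family = family,
                 source_atom_index = as.integer(source_atom_index)),
            class = "PharmacophorePoint")
}

#' Extract donor/acceptor pharmacophores from a reference ligand
#'
#' One point is produced per matched feature atom, positioned at that
#' atom's coordinates.
#'
#' @param ref a `Molecule3D` with 3D coordinates.
#' @param families character subset of `c("donor", "acceptor")`.
#' @return list of `PharmacophorePoint`.
#' @export
extract_pharmacophores <- function(ref, families = c("donor", "acceptor")) {
  bad <- setdiff(families, .FEATURE_FAMILIES)
  if (length(bad) > 0L)
    stop("unknown feature family requested: ", paste(bad, collapse = ", "))
  fa <- feature_atoms(ref)
  fa <- fa[fa$family %in% families, , drop = FALSE]
  lapply(seq_len(nrow(fa)), function(k) {
    i <- fa$atom[k]
    pharmacophore_point(ref$positions[i, ], fa$family[k],
                        source_atom_index = i)
  })
}
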