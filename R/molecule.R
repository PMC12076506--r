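#' @importFrom stats rnorm runif setNames
#' @importFrom utils head modifyList
NULL

# Bond-order codes used throughout: 0 none, 1 single, 2 double, 3 triple,
# 4 aromatic. Matches the V2000 bond block convention.
BOND_NONE <- 0L
BOND_AROMATIC <- 4L

.ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Default valences used for implicit-hydrogen assignment on neutral atoms.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Construct a 3D molecule
#'
#' A `Molecule3D` is the package's container for a posed small molecule:
#' element symbols, Cartesian coordinates in Angstrom, and a symmetric
#' bond-order matrix (0 none, 1 single, 2 double, 3 triple, 4 aromatic).
#'
#' @param atom_types character vector of element symbols, length N.
#' @param positions numeric N x 3 matrix of coordinates (Angstrom).
#' @param bonds integer N x N symmetric matrix of bond codes; defaults to
#'   no bonds.
#' @param name molecule name (free text).
#' @return an object of class `Molecule3D`.
#' @export
molecule3d <- function(atom_types, positions, bonds = NULL, name = "") {
  atom_types <- as.character(atom_types)
  n <- length(atom_types)
  if (n < 1L) stop("Molecule3D needs at least one atom")
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L || nrow(positions) != n)
    stop("positions must be a numeric N x 3 matrix matching atom_types")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.null(bonds)) bonds <- matrix(0L, n, n)
  bonds <- matrix(as.integer(bonds), n, n)
  if (nrow(bonds) != n || ncol(bonds) != n)
    stop("bonds must be an N x N matrix")
  if (!isTRUE(all(bonds == t(bonds)))) stop("bond matrix must be symmetric")
  if (any(diag(bonds) != 0L)) stop("bond matrix must have zero diagonal")
  if (any(bonds < 0L | bonds > 4L)) stop("bond codes must be in 0..4")
  dimnames(positions) <- NULL
  structure(
    list(atom_types = atom_types, positions = positions, bonds = bonds,
         name = as.character(name)[1]),
    class = "Molecule3D"
  )
}

#' @export
print.Molecule3D <- function(x, ...) {
  nb <- sum(x$bonds[upper.tri(x$bonds)] > 0L)
  cat(sprintf("Molecule3D '%s': %d atoms (%s), %d bonds\n",
              x$name, n_atoms(x),
              paste(names(sort(table(x$atom_types), decreasing = TRUE)),
                    sort(table(x$atom_types), decreasing = TRUE),
                    sep = "", collapse = " "),
              nb))
  invisible(x)
}

#' Number of atoms
#' @param mol a `Molecule3D`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$atom_types)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a `Molecule3D`.
#' @return integer vector of atom indices.
#' @export
heavy_atoms <- function(mol) which(mol$atom_types != "H")

# Effective bond-order sum per atom; aromatic bonds count 1.5.
bond_order_sum <- function(mol) {
  b <- mol$bonds
  ord <- matrix(0, nrow(b), ncol(b))
  ord[b == 1L] <- 1; ord[b == 2L] <- 2; ord[b == 3L] <- 3
  ord[b == BOND_AROMATIC] <- 1.5
  rowSums(ord)
}

#' Hydrogen counts per atom (explicit plus implicit)
#'
#' Implicit hydrogens are assigned from default valences of neutral atoms
#' (C 4, N 3, O 2, S 2, ...) minus the bond-order sum, with aromatic bonds
#' counted 1.5. Explicit hydrogens present in the structure are counted from
#' the bond matrix and suppress implicit ones.
#'
#' @param mol a `Molecule3D`.
#' @return integer vector, length N: total hydrogens attached to each atom
#'   (entries for hydrogen atoms themselves are 0).
#' @export
hydrogen_count <- function(mol) {
  n <- n_atoms(mol)
  is_h <- mol$atom_types == "H"
  expl <- vapply(seq_len(n), function(i) {
    sum(mol$bonds[i, ] > 0L & is_h)
  }, integer(1))
  bos <- bond_order_sum(mol)
  val <- .DEFAULT_VALENCE[mol$atom_types]
  val[is.na(val)] <- 0
  impl <- pmax(0, round(val - bos))
  out <- expl + ifelse(expl > 0L, 0L, as.integer(impl))
  out[is_h] <- 0L
  out
}

# Heavy-atom degree (bonded heavy neighbours).
heavy_degree <- function(mol) {
  hv <- mol$atom_types != "H"
  vapply(seq_len(n_atoms(mol)), function(i) sum(mol$bonds[i, ] > 0L & hv),
         integer(1))
}

# Neighbour indices of atom i.
bonded_neighbors <- function(mol, i) which(mol$bonds[i, ] > 0L)

# igraph over all atoms; edges carry the bond code.
molecule_graph <- function(mol) {
  b <- mol$bonds
  idx <- which(upper.tri(b) & b > 0L, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(idx)),
                           attr = list(order = b[idx]))
  }
  g
}

#' Extract the largest connected fragment
#'
#' Generated molecules can be disconnected; evaluation keeps the connected
#' component with the most heavy atoms. Ties are broken deterministically in
#' favour of the component containing the smallest original atom index.
#'
#' @param mol a `Molecule3D`, possibly disconnected.
#' @return a `Molecule3D` restricted to the winning component (atom order
#'   preserved; positions and bonds carried over).
#' @export
largest_fragment <- function(mol) {
  g <- molecule_graph(mol)
  comp <- igraph::components(g)$membership
  hv <- mol$atom_types != "H"
  sizes <- vapply(seq_len(max(comp)), function(k) sum(hv & comp == k),
                  integer(1))
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k) min(which(comp == k)), integer(1))
    best <- best[which.min(firsts)]
  }
  keep <- which(comp == best)
  subset_molecule(mol, keep)
}

# Restrict a molecule to a subset of atom indices (order preserved).
subset_molecule <- function(mol, keep) {
  molecule3d(mol$atom_types[keep], mol$positions[keep, , drop = FALSE],
             mol$bonds[keep, keep, drop = FALSE], name = mol$name)
}

#' Construct a protein pocket context
#'
#' Heavy-atom positions of the pocket plus the two parameters of the clash
#' model: the surface smoothing scale sigma of the soft-minimum distance
#' field, and the clash distance threshold below which atoms are penalized.
#'
#' @param atom_positions numeric P x 3 matrix (Angstrom), heavy atoms only.
#' @param residue_labels character vector length P identifying each atom's
#'   residue (chain/resid/resno/insertion collapsed into one label).
#' @param atom_names optional PDB atom names (length P).
#' @param elements optional element symbols (length P).
#' @param sigma surface smoothing scale in Angstrom (> 0).
#' @param clash_threshold clash distance threshold in Angstrom (>= 0).
#' @return an object of class `ProteinContext`.
#' @export
protein_context <- function(atom_positions, residue_labels = NULL,
                            atom_names = NULL, elements = NULL,
                            sigma = 1.0, clash_threshold = 2.0) {
  atom_positions <- as.matrix(atom_positions)
  p <- nrow(atom_positions)
  if (p < 1L) stop("empty protein context: no atoms")
  if (ncol(atom_positions) != 3L || !all(is.finite(atom_positions)))
    stop("atom_positions must be a finite P x 3 matrix")
  if (is.null(residue_labels)) residue_labels <- paste0("RES", seq_len(p))
  if (length(residue_labels) != p) stop("residue_labels length mismatch")
  if (!is.null(atom_names) && length(atom_names) != p)
    stop("atom_names length mismatch")
  if (!is.null(elements) && length(elements) != p)
    stop("elements length mismatch")
  if (!(sigma > 0)) stop("sigma must be > 0")
  if (clash_threshold < 0) stop("clash_threshold must be >= 0")
  dimnames(atom_positions) <- NULL
  structure(
    list(atom_positions = atom_positions,
         residue_labels = as.character(residue_labels),
         atom_names = if (is.null(atom_names)) rep(NA_character_, p)
                      else as.character(atom_names),
         elements = if (is.null(elements)) rep(NA_character_, p)
                    else as.character(elements),
         sigma = sigma, clash_threshold = clash_threshold),
    class = "ProteinContext"
  )
}

#' @export
print.ProteinContext <- function(x, ...) {
  cat(sprintf(
    "ProteinContext: %d heavy atoms, %d residues, sigma=%.2f A, d_clash=%.2f A\n",
    nrow(x$atom_positions), length(unique(x$residue_labels)),
    x$sigma, x$clash_threshold))
  invisible(x)
}
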