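# Hashed circular (Morgan-style) fingerprints over the package's
# bond-matrix graphs: per-atom invariants are iteratively combined with
# sorted (bond-order, neighbour-identifier) pairs up to the configured
# radius and folded into a fixed number of bits. Bit values are not
# interchangeable with any external toolkit's; all fingerprint-based
# metrics in the package use these bits on both sides of a comparison.

.FP_MOD <- 2147483647

.hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + (as.double(x) %% .FP_MOD)) %% .FP_MOD
  h
}

# Circular identifiers of every heavy atom at radii 0..radius.
circular_identifiers <- function(mol, radius = 2L) {
  hv <- heavy_atoms(mol)
  sub <- subset_molecule(mol, hv)  # hydrogens become implicit
  n <- n_atoms(sub)
  hc <- hydrogen_count(sub)
  deg <- heavy_degree(sub)
  arom <- atom_is_aromatic(sub)
  elem <- match(sub$atom_types, .ELEMENTS, nomatch = 99L)
  ids <- vapply(seq_len(n), function(i) {
    .hash_ints(c(elem[i], deg[i], hc[i], as.integer(arom[i])))
  }, numeric(1))
  all_ids <- ids
  nbrs <- lapply(seq_len(n), function(i) which(sub$bonds[i, ] > 0L))
  # an atom stops emitting identifiers once its covered environment no
  # longer grows (fully explored neighbourhood)
  env <- lapply(seq_len(n), function(i) i)
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      new_env <- lapply(seq_len(n), function(i) {
        sort(unique(c(env[[i]], unlist(env[nbrs[[i]]]))))
      })
      grown <- vapply(seq_len(n), function(i) {
        length(new_env[[i]]) > length(env[[i]])
      }, logical(1))
      new_ids <- vapply(seq_len(n), function(i) {
        js <- nbrs[[i]]
        if (length(js) == 0L) return(ids[i])
        pairs <- cbind(sub$bonds[i, js], ids[js])
        ord <- order(pairs[, 1], pairs[, 2])
        .hash_ints(c(r, ids[i], as.vector(t(pairs[ord, , drop = FALSE]))))
      }, numeric(1))
      all_ids <- c(all_ids, new_ids[grown])
      ids <- new_ids
      env <- new_env
      if (!any(grown)) break
    }
  }
  all_ids
}

#' Hashed circular fingerprint
#'
#' @param mol a `Molecule3D`.
#' @param radius neighbourhood radius (default 2).
#' @param bits fingerprint length, a power of two (default 2048).
#' @return sorted integer vector of set bit positions in 1..bits.
#' @export
morgan_bits <- function(mol, radius = 2L, bits = 2048L) {
  if (bitwAnd(bits, bits - 1L) != 0L) stop("bits must be a power of two")
  ids <- circular_identifiers(mol, radius)
  sort(unique(as.integer(ids %% bits) + 1L))
}

#' Tanimoto similarity of two bit sets
#'
#' @param a,b integer vectors of set bit positions.
#' @return similarity in [0, 1]; two empty sets count as identical (1).
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Molecular diversity of a set
#'
#' One minus the average pairwise Tanimoto similarity of circular
#' fingerprints (radius 2, 2048 bits by default).
#'
#' @param mols list of `Molecule3D` (at least 2).
#' @param radius,bits fingerprint parameters.
#' @return diversity in [0, 1].
#' @export
diversity <- function(mols, radius = 2L, bits = 2048L) {
  if (length(mols) < 2L)
    stop("undefined metric: diversity needs at least 2 molecules")
  fps <- lapply(mols, morgan_bits, radius = radius, bits = bits)
  n <- length(fps)
  sims <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) sims <- c(sims, tanimoto(fps[[i]], fps[[j]]))
  }
  1 - mean(sims)
}
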