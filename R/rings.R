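# Light-weight ring perception on the heavy-atom graph: for every
# non-bridge bond, the smallest cycle through it (shortest alternative
# path between its endpoints); rings are the deduplicated vertex sets.
# Sufficient for ring counts, macrocycle detection and the aromatic-ring
# approximation used by the drug-likeness descriptors.

molecule_rings <- function(mol) {
  hv <- heavy_atoms(mol)
  sub <- subset_molecule(mol, hv)
  g <- molecule_graph(sub)
  if (igraph::ecount(g) == 0L) return(list(rings = list(), map = hv))
  br <- igraph::bridges(g)
  nonbridge <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  rings <- list()
  seen <- character(0)
  for (e in nonbridge) {
    ends <- igraph::ends(g, e)
    g2 <- igraph::delete_edges(g, e)
    sp <- igraph::shortest_paths(g2, from = ends[1], to = ends[2])$vpath[[1]]
    if (length(sp) == 0L) next
    ring <- sort(as.integer(sp))
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- as.integer(sp)
    }
  }
  list(rings = rings, map = hv)
}

# Ring atoms listed in path order (indices into the heavy-atom submolecule).
ring_sizes <- function(mol) {
  vapply(molecule_rings(mol)$rings, length, integer(1))
}

# A bond (heavy submolecule indices) is in a ring iff it is not a bridge.
ring_bond_matrix <- function(sub) {
  g <- molecule_graph(sub)
  n <- n_atoms(sub)
  inring <- matrix(FALSE, n, n)
  if (igraph::ecount(g) == 0L) return(inring)
  br <- as.integer(igraph::bridges(g))
  for (e in seq_len(igraph::ecount(g))) {
    if (e %in% br) next
    ends <- igraph::ends(g, e)
    inring[ends[1], ends[2]] <- TRUE
    inring[ends[2], ends[1]] <- TRUE
  }
  inring
}

# Aromatic-ring count: rings of size 5 or 6 whose bonds are all flagged
# aromatic, or (kekulized input) in which every ring atom either has a
# double bond to a ring neighbour or is a lone-pair heteroatom (N/O/S).
count_aromatic_rings <- function(mol) {
  hv <- heavy_atoms(mol)
  sub <- subset_molecule(mol, hv)
  rr <- molecule_rings(mol)$rings
  n_arom <- 0L
  for (ring in rr) {
    k <- length(ring)
    if (k < 5L || k > 6L) next
    ring_cyc <- c(ring, ring[1])
    orders <- vapply(seq_len(k), function(i) {
      sub$bonds[ring_cyc[i], ring_cyc[i + 1L]]
    }, integer(1))
    if (all(orders == BOND_AROMATIC)) {
      n_arom <- n_arom + 1L
      next
    }
    ok <- vapply(ring, function(a) {
      any(sub$bonds[a, ] == 2L) ||
        sub$atom_types[a] %in% c("N", "O", "S")
    }, logical(1))
    if (all(ok)) n_arom <- n_arom + 1L
  }
  n_arom
}
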