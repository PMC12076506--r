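# Shared fixtures and independent oracles, all built in code.

mk_mol <- function(types, pos, bonds = list(), name = "fixture") {
  n <- length(types)
  b <- matrix(0L, n, n)
  for (e in bonds) {
    b[e[1], e[2]] <- as.integer(e[3])
    b[e[2], e[1]] <- as.integer(e[3])
  }
  molecule3d(types, pos, b, name = name)
}

mol_ethane <- function() {
  mk_mol(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
         list(c(1, 2, 1)), "ethane")
}

mol_methanol <- function() {
  mk_mol(c("C", "O"), rbind(c(0, 0, 0), c(1.43, 0, 0)),
         list(c(1, 2, 1)), "methanol")
}

# N-methylacetamide heavy atoms: CH3-NH-C(=O)-CH3
mol_nma <- function() {
  mk_mol(c("C", "N", "C", "C", "O"),
         rbind(c(-2.4, 0.3, 0), c(-1.2, -0.4, 0), c(0, 0.3, 0),
               c(1.3, -0.4, 0), c(0, 1.55, 0)),
         list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(3, 5, 2)), "nma")
}

mol_benzene <- function(aromatic = TRUE) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  pos <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  orders <- if (aromatic) rep(4L, 6) else c(1L, 2L, 1L, 2L, 1L, 2L)
  bonds <- lapply(1:6, function(i) c(i, i %% 6 + 1, orders[i]))
  mk_mol(rep("C", 6), pos, bonds, "benzene")
}

mol_quinone <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  pos <- rbind(cbind(1.4 * cos(ang), 1.4 * sin(ang), 0),
               c(2.6 * cos(ang[1]), 2.6 * sin(ang[1]), 0),
               c(2.6 * cos(ang[4]), 2.6 * sin(ang[4]), 0))
  mk_mol(c(rep("C", 6), "O", "O"), pos,
         list(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 1), c(5, 6, 2),
              c(6, 1, 1), c(1, 7, 2), c(4, 8, 2)), "quinone")
}

mol_ethanol <- function() {
  mk_mol(c("C", "C", "O"),
         rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.3, 0)),
         list(c(1, 2, 1), c(2, 3, 1)), "ethanol")
}

# random rigid transform (proper rotation + translation)
rand_rigid <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(Q = Q, u = rnorm(3, sd = 3))
}

transform_points <- function(X, tr) {
  sweep(X %*% t(tr$Q), 2, tr$u, "+")
}

transform_molecule <- function(mol, tr) {
  mol$positions <- transform_points(mol$positions, tr)
  mol
}

transform_context <- function(ctx, tr) {
  ctx$atom_positions <- transform_points(ctx$atom_positions, tr)
  ctx
}

transform_spec <- function(spec, tr) {
  spec$points <- lapply(spec$points, function(p) {
    p$position <- as.numeric(transform_points(matrix(p$position, 1, 3), tr))
    p
  })
  spec
}

# --- independent oracles -------------------------------------------------

# connected components by union-find on the bond matrix
components_unionfind <- function(mol) {
  n <- n_atoms(mol)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mol$bonds[i, j] > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# brute-force satisfaction over all (atom, point) pairs
satisfaction_bf <- function(mol, spec) {
  fa <- feature_atoms(mol)
  ok <- vapply(seq_along(spec$points), function(k) {
    p <- spec$points[[k]]
    cand <- fa$atom[fa$family == p$family]
    if (length(cand) == 0L) return(FALSE)
    any(vapply(cand, function(i) {
      sqrt(sum((mol$positions[i, ] - p$position)^2)) <= spec$tau
    }, logical(1)))
  }, logical(1))
  all(ok)
}

# brute-force all-pairs geometric hydrogen-bond scan
detect_hbonds_bf <- function(lig, ctx, config = metric_config()) {
  fa <- feature_atoms(lig)
  el <- ctx$elements
  nm <- ifelse(is.na(ctx$atom_names), "", ctx$atom_names)
  pdon <- which(el == "N" | (el == "O" & nm %in% c("OG", "OG1", "OH")))
  pacc <- which(el == "O")
  n_bond <- 0L
  keys <- character(0)
  for (i in fa$atom[fa$family == "donor"]) {
    for (j in pacc) {
      d <- sqrt(sum((lig$positions[i, ] - ctx$atom_positions[j, ])^2))
      if (d > config$hbond_dist_max) next
      hpos <- phoregen:::.donor_hydrogens(lig, i)
      angs <- apply(hpos, 1, function(h) {
        u <- lig$positions[i, ] - h
        v <- ctx$atom_positions[j, ] - h
        acos(min(1, max(-1, sum(u * v) /
                          sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      })
      if (max(angs) >= config$hbond_angle_min) {
        n_bond <- n_bond + 1L
        keys <- c(keys, paste(ctx$residue_labels[j], "donor"))
      }
    }
  }
  for (i in fa$atom[fa$family == "acceptor"]) {
    for (j in pdon) {
      d <- sqrt(sum((lig$positions[i, ] - ctx$atom_positions[j, ])^2))
      if (d <= config$hbond_dist_max) {
        n_bond <- n_bond + 1L
        keys <- c(keys, paste(ctx$residue_labels[j], "acceptor"))
      }
    }
  }
  list(n = n_bond, keys = keys)
}

corpus_molecules <- function() {
  path <- system.file("extdata", "sa_corpus_synthetic.sdf",
                      package = "phoregen")
  mols <- suppressWarnings(read_ligands(path))
  names(mols) <- vapply(mols, function(m) m$name, character(1))
  mols
}

# small random molecule (tree) for property-style loops
random_tree_molecule <- function(seed, n = 8) {
  set.seed(seed)
  types <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  pos <- matrix(rnorm(n * 3, sd = 2), n, 3)
  bonds <- lapply(2:n, function(i) c(sample(i - 1, 1), i, 1))
  mk_mol(types, pos, bonds, sprintf("rand%d", seed))
}

point_matrix_of <- function(spec) {
  t(vapply(spec$points, function(p) p$position, numeric(3)))
}
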