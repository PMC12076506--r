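# Synthetic pocket/ligand fixture generator: a convex spherical-shell
# pocket with an opening, a tree-bonded heavy-atom template ligand centred
# inside it with at least one hydroxyl oxygen and one amine nitrogen, and
# the schedule + toy denoiser wired up. Deterministic per seed.

#' Build a synthetic protein-ligand toy complex
#'
#' The template is a random tree-bonded heavy-atom molecule (vocabulary C,
#' N, O; all single bonds; bond length 1.4 A) centred in a pocket of
#' protein pseudo-atoms sampled on a spherical shell with a polar opening.
#' Two leaves of the tree carry an O (hydroxyl: donor + acceptor) and an N
#' (amine: donor + acceptor), so donor and acceptor pharmacophores are
#' always extractable. Construction guarantees that every template atom's
#' smoothed surface distance exceeds the clash threshold.
#'
#' @param seed integer seed; the system is byte-identical per seed.
#' @param n_atoms template heavy-atom count (>= 4).
#' @param pocket_radius shell radius in Angstrom (> 3).
#' @param n_pocket_atoms number of pocket pseudo-atoms.
#' @param sigma,clash_threshold clash-model parameters of the pocket.
#' @return an object of class `ToySystem`: list with `template`
#'   (`Molecule3D`), `pocket` (`ProteinContext`), `pharm_subset` (indices
#'   of the donor/acceptor template atoms), `sched` (`ScheduleSpec`) and
#'   `denoiser` (toy denoiser bound to the template).
#' @export
make_toy_complex <- function(seed = 1L, n_atoms = 12L, pocket_radius = 8,
                             n_pocket_atoms = 150L, sigma = 1.0,
                             clash_threshold = 2.0) {
  if (n_atoms < 4L) stop("n_atoms must be >= 4")
  if (pocket_radius <= 3) stop("pocket_radius must be > 3 A")
  # the soft-min surface sits below the true wall distance by up to about
  # sigma * log(P); leave that much extra clearance for the template
  r_inner <- pocket_radius - clash_threshold -
    sigma * log(n_pocket_atoms) * 0.5
  if (r_inner <= 1) stop("pocket too tight for a template ligand")
  set.seed(derive_seed(seed, 0L, 0L, 0L, 7L))
  for (trial in seq_len(100L)) {
    pos <- build_tree_template(n_atoms, r_inner)
    if (is.null(pos)) next
    # centre at the origin; re-check containment
    pts <- pos$positions
    pts <- t(t(pts) - colMeans(pts))
    if (max(sqrt(rowSums(pts^2))) > r_inner) next
    deg <- tabulate(unlist(pos$edges), nbins = n_atoms)
    leaves <- which(deg == 1L)
    if (length(leaves) < 2L) next
    types <- rep("C", n_atoms)
    n_leaf <- leaves[1]; o_leaf <- leaves[2]
    types[n_leaf] <- "N"; types[o_leaf] <- "O"
    bonds <- matrix(0L, n_atoms, n_atoms)
    for (e in pos$edges) {
      bonds[e[1], e[2]] <- 1L; bonds[e[2], e[1]] <- 1L
    }
    template <- molecule3d(types, pts, bonds, name = "toy_template")
    # pocket shell with a polar opening (cap half-angle 35 degrees)
    dirs <- matrix(rnorm(n_pocket_atoms * 6), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dirs <- dirs[acos(pmin(1, pmax(-1, dirs[, 3]))) > 35 * pi / 180, ,
                 drop = FALSE]
    if (nrow(dirs) < n_pocket_atoms) next
    dirs <- dirs[seq_len(n_pocket_atoms), , drop = FALSE]
    shell <- pocket_radius * dirs
    res_no <- (seq_len(n_pocket_atoms) - 1L) %/% 3L + 1L
    ctx <- protein_context(
      shell,
      residue_labels = paste0("A:GLY:", res_no),
      atom_names = rep(c("N", "CA", "O"), length.out = n_pocket_atoms),
      elements = rep(c("N", "C", "O"), length.out = n_pocket_atoms),
      sigma = sigma, clash_threshold = clash_threshold)
    if (min(protein_surface(template$positions, ctx)) <= clash_threshold)
      next
    sched <- make_schedule(50L)
    return(structure(list(
      template = template, pocket = ctx,
      pharm_subset = c(n_leaf, o_leaf),
      sched = sched,
      denoiser = toy_denoiser(template, sched)
    ), class = "ToySystem"))
  }
  stop("toy-complex generation error: infeasible geometry after 100 tries")
}

# Random tree: atom i attaches to an eligible parent at bond length 1.4 A;
# degree capped at 2 for the first four atoms (so masked slots stay
# donor/acceptor-capable after type clamping) and 3 elsewhere. Returns NULL
# on rejection.
build_tree_template <- function(n_atoms, r_max) {
  positions <- matrix(0, n_atoms, 3)
  edges <- list()
  deg <- integer(n_atoms)
  cap <- ifelse(seq_len(n_atoms) <= 4L, 2L, 3L)
  for (i in seq(2L, n_atoms)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      parents <- which(deg[seq_len(i - 1L)] < cap[seq_len(i - 1L)])
      if (length(parents) == 0L) return(NULL)
      p <- parents[sample.int(length(parents), 1L)]
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- positions[p, ] + 1.4 * u
      if (sqrt(sum(cand^2)) > r_max) next
      d <- sqrt(rowSums((positions[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3, byrow = TRUE))^2))
      d[p] <- Inf
      if (any(d < 1.2)) next
      positions[i, ] <- cand
      edges[[length(edges) + 1L]] <- c(p, i)
      deg[p] <- deg[p] + 1L; deg[i] <- deg[i] + 1L
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  list(positions = positions, edges = edges)
}

#' @export
print.ToySystem <- function(x, ...) {
  cat("ToySystem:\n  ")
  print(x$template)
  cat("  ")
  print(x$pocket)
  invisible(x)
}

#' Constraint spec from a toy system's pharmacophore atoms
#'
#' Builds donor/acceptor points at the template's labelled N and O atoms,
#' with the corresponding fixed atom types, bound to the first slots.
#'
#' @param sys a `ToySystem`.
#' @param tau satisfaction threshold in Angstrom.
#' @return a `ConstraintSpec` over `n_atoms(sys$template)` slots.
#' @export
toy_constraints <- function(sys, tau = 1.0) {
  tm <- sys$template
  idx <- sys$pharm_subset
  fams <- ifelse(tm$atom_types[idx] == "N", "donor", "acceptor")
  pts <- lapply(seq_along(idx), function(k) {
    pharmacophore_point(tm$positions[idx[k], ], fams[k],
                        source_atom_index = idx[k])
  })
  build_constraints(pts, fixed_types = tm$atom_types[idx], tau = tau,
                    slots = n_atoms(tm))
}

#' Write toy-complex fixture files
#'
#' Emits `template.sdf`, `pocket.pdb` and `pharm.json` into a directory for
#' command-line-level integration tests.
#'
#' @param sys a `ToySystem`.
#' @param dir output directory (created if absent).
#' @param tau satisfaction threshold written into `pharm.json`.
#' @return character vector of the three file paths, invisibly.
#' @export
write_toy_fixtures <- function(sys, dir, tau = 1.0) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sdf <- file.path(dir, "template.sdf")
  pdb <- file.path(dir, "pocket.pdb")
  pj <- file.path(dir, "pharm.json")
  write_sdf(sys$template, sdf)
  write_protein(sys$pocket, pdb)
  write_pharm_json(toy_constraints(sys, tau = tau), pj)
  invisible(c(sdf, pdb, pj))
}
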