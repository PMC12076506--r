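# Shape-and-color 3D similarity: poses are compared in place (no
# realignment). Shape similarity is a Gaussian-overlap volume Tanimoto
# over heavy atoms; color similarity is the same overlap restricted to
# pharmacophore feature points of matching family.

.gauss_overlap <- function(A, B, sigma) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(0)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sum(exp(-pmax(d2, 0) / (4 * sigma^2)))
}

.overlap_tanimoto <- function(A, B, sigma) {
  vab <- .gauss_overlap(A, B, sigma)
  vaa <- .gauss_overlap(A, A, sigma)
  vbb <- .gauss_overlap(B, B, sigma)
  den <- vaa + vbb - vab
  if (den <= 0) return(NA_real_)
  vab / den
}

#' Shape-and-color similarity of two posed conformers
#'
#' Mean (by default; weights configurable) of a volumetric shape-overlap
#' Tanimoto over heavy-atom Gaussians and a pharmacophoric feature-overlap
#' ("color") Tanimoto in which only same-family feature pairs contribute
#' cross terms. Both components lie in [0, 1]; identical poses score 1.
#' When neither molecule carries any donor/acceptor feature the score
#' reduces to the shape component.
#'
#' @param gen,ref `Molecule3D` objects with 3D coordinates, compared in
#'   their given frames.
#' @param sigma Gaussian width per heavy atom in Angstrom (default 1.2,
#'   about a carbon van der Waals radius over sqrt 2).
#' @param weights length-2 numeric `c(shape, color)` mixing weights.
#' @return similarity in [0, 1].
#' @export
shape_color_similarity <- function(gen, ref, sigma = 1.2,
                                   weights = c(shape = 0.5, color = 0.5)) {
  A <- gen$positions[heavy_atoms(gen), , drop = FALSE]
  B <- ref$positions[heavy_atoms(ref), , drop = FALSE]
  shape <- .overlap_tanimoto(A, B, sigma)
  fg <- feature_atoms(gen)
  fr <- feature_atoms(ref)
  if (nrow(fg) == 0L && nrow(fr) == 0L) return(shape)
  fam <- union(fg$family, fr$family)
  vab <- vaa <- vbb <- 0
  for (f in fam) {
    Af <- gen$positions[fg$atom[fg$family == f], , drop = FALSE]
    Bf <- ref$positions[fr$atom[fr$family == f], , drop = FALSE]
    vab <- vab + .gauss_overlap(Af, Bf, sigma)
    vaa <- vaa + .gauss_overlap(Af, Af, sigma)
    vbb <- vbb + .gauss_overlap(Bf, Bf, sigma)
  }
  color <- if (vaa + vbb - vab <= 0) 0 else vab / (vaa + vbb - vab)
  w <- weights / sum(weights)
  unname(w[1] * shape + w[2] * color)
}

#' Select the top-k molecules by shape-and-color similarity
#'
#' Stable descending selection: ties keep input order. Downstream metrics
#' are conventionally reported as the best value within this subset.
#'
#' @param mols list of `Molecule3D`.
#' @param ref reference `Molecule3D`.
#' @param k subset size (>= 1); if larger than `length(mols)` all
#'   molecules are returned with a warning.
#' @param ... passed to [shape_color_similarity()].
#' @return list with `mols` (ordered subset), `scores` (their similarity
#'   scores, descending) and `index` (positions in the input list).
#' @export
topk_by_sc <- function(mols, ref, k, ...) {
  if (k < 1L) stop("k must be >= 1")
  scores <- vapply(mols, shape_color_similarity, numeric(1), ref = ref, ...)
  if (k > length(mols)) {
    warning("k exceeds number of molecules; returning all")
    k <- length(mols)
  }
  ord <- order(-scores)  # stable: ties keep input order
  sel <- ord[seq_len(k)]
  list(mols = mols[sel], scores = scores[sel], index = sel)
}

#' Normalize a docking score by molecular size
#'
#' Docking scores correlate with atom count; dividing by the square root
#' of the number of atoms deflates the size bias.
#'
#' @param score docking score (kcal/mol).
#' @param n_atoms atom count (>= 1).
#' @return normalized score.
#' @export
normalized_score <- function(score, n_atoms) {
  if (any(n_atoms <= 0)) stop("domain error: n_atoms must be >= 1")
  score / sqrt(n_atoms)
}
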