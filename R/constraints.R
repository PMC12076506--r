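# Constraint specification: pharmacophore points bound to masked atom
# slots, optional fixed atom types, and the satisfaction threshold tau.
# Masked slot k is permanently bound to point k for the whole trajectory.

#' Build a constraint specification
#'
#' Binds pharmacophore points to the first `length(points)` atom slots of a
#' generated molecule. Slot binding is by index and never reassigned during
#' sampling, so generation is permutation-free.
#'
#' @param points list of `PharmacophorePoint`.
#' @param fixed_types optional character vector of element symbols, aligned
#'   to `points`; these types are clamped on the masked slots at every
#'   reverse-diffusion step. Use `NA` entries to leave a slot's type free.
#' @param tau satisfaction distance threshold in Angstrom (> 0); a point is
#'   fulfilled when an atom of matching family lies within `tau`.
#' @param slots total number of atom slots of the generated molecule.
#' @return an object of class `ConstraintSpec` with fields `points`,
#'   `mask` (binary vector over slots), `fixed_atom_types`, `tau`.
#' @export
build_constraints <- function(points, fixed_types = NULL, tau = 1.0,
                              slots) {
  m <- length(points)
  if (m > slots)
    stop(sprintf("capacity error: %d points but only %d atom slots",
                 m, slots))
  if (!(tau > 0)) stop("tau must be > 0")
  for (p in points) {
    if (!inherits(p, "PharmacophorePoint"))
      stop("points must be PharmacophorePoint objects")
  }
  if (!is.null(fixed_types)) {
    if (length(fixed_types) != m)
      stop("fixed_types must align with points")
  }
  mask <- c(rep(1L, m), rep(0L, slots - m))
  structure(list(points = points, mask = mask,
                 fixed_atom_types = fixed_types, tau = tau),
            class = "ConstraintSpec")
}

#' @export
print.ConstraintSpec <- function(x, ...) {
  fams <- vapply(x$points, function(p) p$family, character(1))
  cat(sprintf("ConstraintSpec: %d points (%s), %d slots, tau = %.2f A\n",
              length(x$points),
              if (length(fams)) paste(fams, collapse = ",") else "-",
              length(x$mask), x$tau))
  invisible(x)
}

n_points <- function(spec) length(spec$points)

point_matrix <- function(spec) {
  if (n_points(spec) == 0L) return(matrix(numeric(0), 0, 3))
  t(vapply(spec$points, function(p) p$position, numeric(3)))
}

#' Test pharmacophore satisfaction of a posed molecule
#'
#' A point is satisfied when some atom of `mol` lies within `spec$tau` of
#' the point and that atom carries the point's feature family (typed on
#' `mol` itself by the same donor/acceptor definitions used for
#' extraction). The overall verdict requires every point to be satisfied.
#'
#' @param mol a `Molecule3D`.
#' @param spec a `ConstraintSpec`.
#' @param strict if TRUE, only the masked slot bound to each point may
#'   satisfy it (slot k for point k); default FALSE accepts any atom.
#' @return list with `satisfied` (logical), and `report`: a data.frame with
#'   one row per point (`family`, `nearest_match_dist`, `satisfied`).
#' @export
satisfaction <- function(mol, spec, strict = FALSE) {
  m <- n_points(spec)
  if (m == 0L) {
    return(list(satisfied = TRUE,
                report = data.frame(family = character(0),
                                    nearest_match_dist = numeric(0),
                                    satisfied = logical(0))))
  }
  fa <- feature_atoms(mol)
  pm <- point_matrix(spec)
  rows <- lapply(seq_len(m), function(k) {
    fam <- spec$points[[k]]$family
    cand <- fa$atom[fa$family == fam]
    if (strict) cand <- intersect(cand, k)
    if (length(cand) == 0L) {
      return(data.frame(family = fam, nearest_match_dist = Inf,
                        satisfied = FALSE))
    }
    d <- sqrt(colSums((t(mol$positions[cand, , drop = FALSE]) - pm[k, ])^2))
    data.frame(family = fam, nearest_match_dist = min(d),
               satisfied = min(d) <= spec$tau)
  })
  report <- do.call(rbind, rows)
  list(satisfied = all(report$satisfied), report = report)
}

#' Write a pharmacophore specification to JSON
#'
#' Schema:
#' \preformatted{
#' {"points":[{"xyz":[x,y,z],"family":"donor|acceptor",
#'             "fixed_element":"N"}], "tau":1.0}
#' }
#'
#' @param spec a `ConstraintSpec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pharm_json <- function(spec, path) {
  pts <- lapply(seq_len(n_points(spec)), function(k) {
    p <- spec$points[[k]]
    out <- list(xyz = p$position, family = p$family)
    ft <- spec$fixed_atom_types
    if (!is.null(ft) && !is.na(ft[k])) out$fixed_element <- ft[k]
    out
  })
  jsonlite::write_json(list(points = pts, tau = spec$tau), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore specification from JSON
#'
#' Strictly validates the schema documented in [write_pharm_json()].
#'
#' @param path path to a pharmacophore JSON file.
#' @param slots number of atom slots for the constraint spec.
#' @return a `ConstraintSpec`.
#' @export
read_pharm_json <- function(path, slots) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path)
  if (!is.list(x) || is.null(x$points))
    stop("pharmacophore JSON error: missing 'points'")
  tau <- if (is.null(x$tau)) 1.0 else as.numeric(x$tau)
  pts <- list()
  fixed <- character(0)
  for (p in x$points) {
    if (is.null(p$xyz) || length(p$xyz) != 3L)
      stop("pharmacophore JSON error: each point needs a 3-element 'xyz'")
    if (is.null(p$family))
      stop("pharmacophore JSON error: each point needs a 'family'")
    fam <- as.character(p$family)
    if (!fam %in% .FEATURE_FAMILIES)
      stop("pharmacophore JSON error: unknown family '", fam, "'")
    pts[[length(pts) + 1L]] <-
      pharmacophore_point(unlist(p$xyz), fam)
    fixed <- c(fixed,
               if (is.null(p$fixed_element)) NA_character_
               else as.character(p$fixed_element))
  }
  if (all(is.na(fixed))) fixed <- NULL
  build_constraints(pts, fixed_types = fixed, tau = tau, slots = slots)
}
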