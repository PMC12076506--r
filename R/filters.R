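# Structural-alert filtering with pattern graphs matched by subgraph
# isomorphism (igraph LAD with per-atom candidate domains), and the
# success-rate metric built on the filters and the drug-likeness scores.
#
# Catalogs ship as JSON pattern-graph files under inst/extdata/filters/:
# each pattern lists atoms (allowed elements, min/max attached hydrogens)
# and bonds [i, j, order] with order 0 matching any bond and 4 aromatic.

load_catalog <- function(name) {
  key <- paste0("catalog_", tolower(name))
  if (!is.null(.phoregen_cache[[key]])) return(.phoregen_cache[[key]])
  path <- system.file("extdata", "filters",
                      paste0(tolower(name), ".json"), package = "phoregen")
  if (path == "") stop("config error: unknown catalog '", name, "'")
  cat_ <- jsonlite::read_json(path)
  .phoregen_cache[[key]] <- cat_
  cat_
}

# Does one pattern match anywhere in the (heavy-atom) molecule?
match_pattern <- function(mol, pattern) {
  hv <- heavy_atoms(mol)
  sub <- subset_molecule(mol, hv)
  n <- n_atoms(sub)
  atoms <- pattern$atoms
  np <- length(atoms)
  if (np > n) return(FALSE)
  hc <- hydrogen_count(sub)
  deg <- heavy_degree(sub)
  bonds <- do.call(rbind, lapply(pattern$bonds, function(b) unlist(b)))
  pdeg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = np)
  domains <- lapply(seq_len(np), function(k) {
    a <- atoms[[k]]
    ok <- sub$atom_types %in% unlist(a$elem)
    if (!is.null(a$minH)) ok <- ok & hc >= a$minH
    if (!is.null(a$maxH)) ok <- ok & hc <= a$maxH
    ok <- ok & deg >= pdeg[k]
    which(ok)
  })
  if (any(vapply(domains, length, integer(1)) == 0L)) return(FALSE)
  pg <- igraph::make_empty_graph(n = np, directed = FALSE)
  pg <- igraph::add_edges(pg, as.vector(t(bonds[, 1:2, drop = FALSE])))
  tg <- molecule_graph(sub)
  maps <- igraph::subgraph_isomorphisms(pg, tg, method = "lad",
                                        induced = FALSE, domains = domains)
  if (length(maps) == 0L) return(FALSE)
  nonring <- if (is.null(pattern$nonring_bonds)) NULL
             else do.call(rbind, lapply(pattern$nonring_bonds, unlist))
  inring <- if (is.null(nonring)) NULL else ring_bond_matrix(sub)
  for (m in maps) {
    idx <- as.integer(m)
    ok <- TRUE
    for (r in seq_len(nrow(bonds))) {
      o <- bonds[r, 3]
      have <- sub$bonds[idx[bonds[r, 1]], idx[bonds[r, 2]]]
      if (o != 0L && have != o) { ok <- FALSE; break }
    }
    if (ok && !is.null(nonring)) {
      for (r in seq_len(nrow(nonring))) {
        if (inring[idx[nonring[r, 1]], idx[nonring[r, 2]]]) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Screen a molecule against structural-alert catalogs
#'
#' @param mol a `Molecule3D`.
#' @param catalogs character subset of `c("NIH", "PAINS", "Brenk")`; an
#'   empty set passes trivially.
#' @return list with `pass` (TRUE iff no catalog pattern matches) and
#'   `hits` (character vector of matched pattern names, prefixed with the
#'   catalog).
#' @export
structural_filters <- function(mol, catalogs = c("NIH", "PAINS", "Brenk")) {
  hits <- character(0)
  for (cname in catalogs) {
    cat_ <- load_catalog(cname)
    for (p in cat_$patterns) {
      if (match_pattern(mol, p)) {
        hits <- c(hits, paste0(cat_$catalog, ":", p$name))
      }
    }
  }
  list(pass = length(hits) == 0L, hits = hits)
}

#' Number of structural-alert hits (Brenk catalog)
#'
#' Used as the ALERTS descriptor of the drug-likeness estimate.
#'
#' @param mol a `Molecule3D`.
#' @return integer count of matched alert patterns.
#' @export
alert_count <- function(mol) {
  length(structural_filters(mol, "Brenk")$hits)
}

#' Per-pocket success rate
#'
#' The fraction of generated molecules per pocket that are flagged valid
#' by the validity adapter, pass the NIH structural filter, and reach the
#' QED and normalized-SA thresholds (set from the minimum values of the
#' reference test set). Pockets with no passing molecule are counted
#' separately.
#'
#' @param mols_per_pocket named list: pocket id -> list of `Molecule3D`.
#' @param qed_min,sa_min inclusion thresholds (defaults 0.19 / 0.33).
#' @param validity_flags optional named list of logical vectors aligned
#'   with `mols_per_pocket`; NULL means offline mode with all molecules
#'   assumed valid.
#' @return list with `rate` (named numeric per pocket), `n_empty_pockets`
#'   and `passed` (named list of logical vectors).
#' @export
success_rate <- function(mols_per_pocket, qed_min = 0.19, sa_min = 0.33,
                         validity_flags = NULL) {
  rates <- numeric(0)
  passed <- list()
  n_empty <- 0L
  for (pk in names(mols_per_pocket)) {
    mols <- mols_per_pocket[[pk]]
    vf <- if (is.null(validity_flags)) rep(TRUE, length(mols))
          else validity_flags[[pk]]
    ok <- vapply(seq_along(mols), function(i) {
      if (!isTRUE(vf[i])) return(FALSE)
      if (!structural_filters(mols[[i]], "NIH")$pass) return(FALSE)
      if (qed(mols[[i]]) < qed_min) return(FALSE)
      sa_score_normalized(mols[[i]]) >= sa_min
    }, logical(1))
    rates[pk] <- if (length(mols) == 0L) 0 else mean(ok)
    passed[[pk]] <- ok
    if (!any(ok)) n_empty <- n_empty + 1L
  }
  list(rate = rates, n_empty_pockets = n_empty, passed = passed)
}
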