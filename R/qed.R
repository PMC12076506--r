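# Quantitative estimate of drug-likeness: weighted geometric mean of
# asymmetric-double-sigmoid desirability functions over eight standard
# properties. The published ADS parameterization and weights ship as
# inst/extdata/qed_ads_params.json. Bulk descriptors (MW, logP, TPSA)
# come from OpenBabel via ChemmineOB; counting descriptors (HBA, HBD,
# rotatable bonds, aromatic rings, alerts) are computed on the package's
# own graphs so they stay consistent with the feature typer.

qed_params <- function() {
  if (!is.null(.phoregen_cache$qed_params))
    return(.phoregen_cache$qed_params)
  path <- system.file("extdata", "qed_ads_params.json",
                      package = "phoregen")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .phoregen_cache$qed_params <- x
  x
}

# Asymmetric double sigmoid desirability, normalized by its maximum.
ads <- function(x, p) {
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]
  dmax <- p[7]
  val <- a + b / (1 + exp(-(x - c + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - c - d / 2) / f)))
  val / dmax
}

.ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007,
                  O = 15.999, F = 18.998, P = 30.974, S = 32.06,
                  Cl = 35.45, Br = 79.904, I = 126.904)

#' Drug-likeness descriptors of a molecule
#'
#' @param mol a `Molecule3D`.
#' @return named numeric vector with `MW`, `ALOGP`, `HBA`, `HBD`, `PSA`,
#'   `ROTB`, `AROM`, `ALERTS`.
#' @export
qed_descriptors <- function(mol) {
  ob <- .propOB_safe(mol)
  fa <- feature_atoms(mol)
  hc <- hydrogen_count(mol)
  hbd <- sum(hc[unique(fa$atom[fa$family == "donor"])])
  hba <- length(unique(fa$atom[fa$family == "acceptor"]))
  c(MW = ob$MW, ALOGP = ob$logP, HBA = hba, HBD = hbd, PSA = ob$TPSA,
    ROTB = rotatable_bonds(mol), AROM = count_aromatic_rings(mol),
    ALERTS = alert_count(mol))
}

.propOB_safe <- function(mol) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for MW/logP/TPSA descriptors")
  sdf <- molecule3d_to_sdfobj(mol)
  s <- methods::new("SDFset", SDF = list(sdf), ID = "CMP1")
  p <- ChemmineR::propOB(s)
  list(MW = p$MW[1], logP = p$logP[1], TPSA = p$TPSA[1])
}

#' Count rotatable bonds
#'
#' Single non-ring bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds.
#'
#' @param mol a `Molecule3D`.
#' @return integer count.
#' @export
rotatable_bonds <- function(mol) {
  hv <- heavy_atoms(mol)
  sub <- subset_molecule(mol, hv)
  n <- n_atoms(sub)
  if (n < 2L) return(0L)
  deg <- heavy_degree(sub)
  inring <- ring_bond_matrix(sub)
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (sub$bonds[i, j] != 1L) next
      if (inring[i, j]) next
      if (deg[i] < 2L || deg[j] < 2L) next
      # amide: C(=O)-N
      amide <- function(a, b) {
        sub$atom_types[a] == "C" && sub$atom_types[b] == "N" &&
          any(sub$bonds[a, ] == 2L & sub$atom_types == "O")
      }
      if (amide(i, j) || amide(j, i)) next
      cnt <- cnt + 1L
    }
  }
  cnt
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of the eight property desirabilities under the
#' published parameterization.
#'
#' @param mol a `Molecule3D`.
#' @return QED value in [0, 1].
#' @export
qed <- function(mol) {
  qed_from_descriptors(qed_descriptors(mol))
}

#' QED from precomputed descriptor values
#'
#' @param desc named numeric vector as returned by [qed_descriptors()].
#' @return QED value in [0, 1].
#' @export
qed_from_descriptors <- function(desc) {
  pp <- qed_params()
  props <- names(pp$weights)
  d <- vapply(props, function(nm) {
    max(ads(desc[[nm]], pp$params[[nm]]), 1e-10)
  }, numeric(1))
  w <- unlist(pp$weights)
  unname(exp(sum(w * log(d)) / sum(w)))
}
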