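# Geometric hydrogen-bond detection between a posed ligand and the
# protein pocket, and the interaction-similarity metric built on it.

#' Metric configuration
#'
#' @param hbond_dist_max donor-acceptor heavy-atom distance cutoff in
#'   Angstrom (default 3.5).
#' @param hbond_angle_min minimum donor angle D-H...A in degrees
#'   (default 120).
#' @param fp_radius,fp_bits circular-fingerprint parameters (2 / 2048).
#' @param qed_threshold,sa_threshold success-rate thresholds for QED and
#'   normalized SA (defaults 0.19 / 0.33, the minimum values of the
#'   benchmark test set).
#' @param sc_weights shape/color mixing weights.
#' @return an object of class `MetricConfig`.
#' @export
metric_config <- function(hbond_dist_max = 3.5, hbond_angle_min = 120,
                          fp_radius = 2L, fp_bits = 2048L,
                          qed_threshold = 0.19, sa_threshold = 0.33,
                          sc_weights = c(shape = 0.5, color = 0.5)) {
  if (hbond_dist_max <= 0) stop("hbond_dist_max must be > 0")
  if (hbond_angle_min < 0 || hbond_angle_min > 180)
    stop("hbond_angle_min must be in [0, 180]")
  if (bitwAnd(fp_bits, fp_bits - 1L) != 0L)
    stop("fp_bits must be a power of two")
  structure(list(hbond_dist_max = hbond_dist_max,
                 hbond_angle_min = hbond_angle_min,
                 fp_radius = as.integer(fp_radius),
                 fp_bits = as.integer(fp_bits),
                 qed_threshold = qed_threshold,
                 sa_threshold = sa_threshold,
                 sc_weights = sc_weights),
            class = "MetricConfig")
}

# Hydrogen positions on a donor atom: explicit hydrogens if bonded,
# otherwise one idealized hydrogen placed 1.0 A anti to the mean heavy-
# neighbour direction (arbitrary +x for an isolated atom). Deterministic.
.donor_hydrogens <- function(mol, i) {
  nb <- bonded_neighbors(mol, i)
  hs <- nb[mol$atom_types[nb] == "H"]
  if (length(hs) > 0L) return(mol$positions[hs, , drop = FALSE])
  heavy <- nb[mol$atom_types[nb] != "H"]
  d <- mol$positions[i, ]
  if (length(heavy) == 0L) {
    dir <- c(1, 0, 0)
  } else {
    u <- t(mol$positions[heavy, , drop = FALSE]) - d
    u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
    s <- -rowSums(u)
    if (sqrt(sum(s^2)) < 1e-6) {
      # symmetric environment: any direction orthogonal to the first bond
      v <- u[, 1]
      dir <- c(-v[2], v[1], 0)
      if (sqrt(sum(dir^2)) < 1e-6) dir <- c(0, 1, 0)
      dir <- dir / sqrt(sum(dir^2))
    } else {
      dir <- s / sqrt(sum(s^2))
    }
  }
  matrix(d + dir, 1, 3)
}

.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Protein-side feature typing from element symbols and PDB atom names:
# nitrogens donate, oxygens accept, and Ser/Thr/Tyr hydroxyl oxygens
# (OG/OG1/OH) also donate.
protein_feature_atoms <- function(ctx) {
  el <- ctx$elements
  nm <- ifelse(is.na(ctx$atom_names), "", ctx$atom_names)
  donors <- which(el == "N" | (el == "O" & nm %in% c("OG", "OG1", "OH")))
  acceptors <- which(el == "O")
  list(donors = donors, acceptors = acceptors)
}

#' Detect ligand-protein hydrogen bonds
#'
#' Donor-acceptor heavy-atom pairs within the distance cutoff, in both
#' directions (ligand donor to protein acceptor and protein donor to
#' ligand acceptor). On the ligand-donor side the D-H...A angle must reach
#' the configured minimum, with hydrogens taken as present or placed
#' anti to the donor's heavy neighbours when absent; protein donors carry
#' no hydrogens (heavy atoms only), so only the distance criterion applies
#' on that side.
#'
#' @param lig a `Molecule3D`.
#' @param ctx a `ProteinContext` with element/atom-name annotations.
#' @param config a `MetricConfig`.
#' @return data.frame with one row per bond: `protein_residue`,
#'   `protein_atom`, `ligand_atom`, `ligand_role` ("donor"/"acceptor"),
#'   `distance`, and donor/acceptor coordinates `d_x..d_z`, `a_x..a_z`.
#' @export
detect_hbonds <- function(lig, ctx, config = metric_config()) {
  fa <- feature_atoms(lig)
  pf <- protein_feature_atoms(ctx)
  out <- list()
  add <- function(res, patom, latom, role, dpos, apos) {
    out[[length(out) + 1L]] <<- data.frame(
      protein_residue = res, protein_atom = patom, ligand_atom = latom,
      ligand_role = role, distance = sqrt(sum((dpos - apos)^2)),
      d_x = dpos[1], d_y = dpos[2], d_z = dpos[3],
      a_x = apos[1], a_y = apos[2], a_z = apos[3])
  }
  for (i in fa$atom[fa$family == "donor"]) {
    dpos <- lig$positions[i, ]
    for (j in pf$acceptors) {
      apos <- ctx$atom_positions[j, ]
      if (sqrt(sum((dpos - apos)^2)) > config$hbond_dist_max) next
      hpos <- .donor_hydrogens(lig, i)
      ang <- apply(hpos, 1, function(h) .angle_deg(dpos, h, apos))
      if (max(ang) >= config$hbond_angle_min) {
        add(ctx$residue_labels[j], j, i, "donor", dpos, apos)
      }
    }
  }
  for (i in fa$atom[fa$family == "acceptor"]) {
    apos <- lig$positions[i, ]
    for (j in pf$donors) {
      dpos <- ctx$atom_positions[j, ]
      if (sqrt(sum((dpos - apos)^2)) > config$hbond_dist_max) next
      add(ctx$residue_labels[j], j, i, "acceptor", dpos, apos)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_residue = character(0),
                      protein_atom = integer(0), ligand_atom = integer(0),
                      ligand_role = character(0), distance = numeric(0),
                      d_x = numeric(0), d_y = numeric(0), d_z = numeric(0),
                      a_x = numeric(0), a_y = numeric(0), a_z = numeric(0)))
  }
  do.call(rbind, out)
}

#' Fraction of reference hydrogen bonds reproduced by a generated ligand
#'
#' A reference bond counts as shared when the generated ligand forms a
#' bond to the same protein residue with the same ligand role; bonds are
#' matched with multiplicity and the score is capped at 1.
#'
#' @param gen,ref `Molecule3D` poses.
#' @param ctx a `ProteinContext`.
#' @param config a `MetricConfig`.
#' @return similarity in [0, 1].
#' @export
interaction_similarity <- function(gen, ref, ctx,
                                   config = metric_config()) {
  rb <- detect_hbonds(ref, ctx, config)
  if (nrow(rb) == 0L)
    stop("undefined metric: reference ligand forms no hydrogen bonds")
  gb <- detect_hbonds(gen, ctx, config)
  if (nrow(gb) == 0L) return(0)
  rkey <- paste(rb$protein_residue, rb$ligand_role)
  gkey <- paste(gb$protein_residue, gb$ligand_role)
  rt <- table(rkey)
  gt <- table(gkey)
  shared <- sum(vapply(names(rt), function(k) {
    min(rt[[k]], if (k %in% names(gt)) gt[[k]] else 0L)
  }, numeric(1)))
  min(1, shared / nrow(rb))
}
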