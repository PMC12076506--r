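# PDB input via bio3d. The protein context keeps heavy atoms only; waters
# (HOH/WAT/H2O/DOD residues) are dropped by default, matching the practice
# of excluding crystallographic waters from generation and evaluation.

.WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SPC")

#' Read a protein pocket from a PDB file
#'
#' ATOM and HETATM records are read with bio3d; hydrogens are discarded,
#' alternate locations other than 'A'/blank are dropped, and water residues
#' are removed by default. Residue labels keep chain, residue name, residue
#' number and insertion code.
#'
#' @param path path to a PDB file.
#' @param drop_waters remove water residues (default TRUE).
#' @param sigma surface smoothing scale in Angstrom for the clash model.
#' @param clash_threshold clash distance threshold in Angstrom.
#' @return a `ProteinContext`.
#' @export
read_protein <- function(path, drop_waters = TRUE, sigma = 1.0,
                         clash_threshold = 2.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("PDB format error: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  elem <- at$elesy
  # fall back to the first letter(s) of the atom name when the element
  # column is absent (common in minimal files)
  guess <- sub("^[0-9]*", "", at$elety)
  guess <- ifelse(substr(guess, 1, 2) %in% c("CL", "BR", "Cl", "Br"),
                  substr(guess, 1, 2), substr(guess, 1, 1))
  elem <- ifelse(is.na(elem) | elem == "", guess, elem)
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))
  keep <- elem != "H" & elem != "D"
  alt <- at$alt
  keep <- keep & (is.na(alt) | alt %in% c("", "A"))
  if (drop_waters) keep <- keep & !(toupper(at$resid) %in% .WATER_RESIDUES)
  if (!any(keep)) stop("empty protein context after filtering: ", path)
  at <- at[keep, , drop = FALSE]
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  labels <- paste0(at$chain, ":", at$resid, ":", at$resno, ins)
  protein_context(
    atom_positions = cbind(at$x, at$y, at$z),
    residue_labels = labels,
    atom_names = trimws(at$elety),
    elements = elem[keep],
    sigma = sigma, clash_threshold = clash_threshold
  )
}

#' Write a protein context to a PDB file
#'
#' Used by the fixture generator; atoms are written as HETATM-free ATOM
#' records with their stored names and residue labels.
#'
#' @param ctx a `ProteinContext`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein <- function(ctx, path) {
  p <- nrow(ctx$atom_positions)
  parts <- strsplit(ctx$residue_labels, ":", fixed = TRUE)
  chain <- vapply(parts, function(x) if (length(x) >= 1) x[1] else "A",
                  character(1))
  resid <- vapply(parts, function(x) if (length(x) >= 2) x[2] else "UNK",
                  character(1))
  resno <- vapply(parts, function(x) {
    if (length(x) >= 3) as.integer(sub("[A-Za-z]$", "", x[3])) else 1L
  }, integer(1))
  elety <- ifelse(is.na(ctx$atom_names), "CA", ctx$atom_names)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(ctx$atom_positions)),
                   resno = resno, resid = resid, chain = chain,
                   elety = elety,
                   elesy = ifelse(is.na(ctx$elements), "C", ctx$elements))
  invisible(path)
}
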