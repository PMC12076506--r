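# SDF input/output. Reading and writing of V2000 records goes through
# ChemmineR; a compact V3000 CTAB reader covers read-only V3000 support.
# Single-atom records are handled by a plain V2000 text path because
# ChemmineR's validator rejects one-atom molecules.

element_from_rowname <- function(rn) sub("_\\d+$", "", rn)

sdfobj_to_molecule3d <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  types <- element_from_rowname(rownames(ab))
  pos <- unname(ab[, 1:3, drop = FALSE])
  bonds <- matrix(0L, n, n)
  if (!is.null(bb) && nrow(bb) > 0L) {
    for (k in seq_len(nrow(bb))) {
      i <- as.integer(bb[k, 1]); j <- as.integer(bb[k, 2])
      o <- as.integer(bb[k, 3])
      bonds[i, j] <- o; bonds[j, i] <- o
    }
  }
  nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
  molecule3d(types, pos, bonds, name = if (is.na(nm)) "" else nm)
}

# Minimal V3000 CTAB reader (ATOM/BOND blocks of the first record).
read_sdf_v3000 <- function(lines) {
  grab <- function(tag) {
    i0 <- grep(sprintf("BEGIN %s", tag), lines, fixed = TRUE)[1]
    i1 <- grep(sprintf("END %s", tag), lines, fixed = TRUE)[1]
    if (is.na(i0) || is.na(i1) || i1 <= i0 + 1L) return(character(0))
    lines[(i0 + 1L):(i1 - 1L)]
  }
  atoms <- grab("ATOM")
  if (length(atoms) == 0L) stop("SDF format error: empty V3000 ATOM block")
  parse_row <- function(l) {
    toks <- strsplit(sub("^M  V30 ", "", l), "\\s+")[[1]]
    toks[toks != ""]
  }
  arows <- lapply(atoms, parse_row)
  idx <- vapply(arows, function(x) as.integer(x[1]), integer(1))
  types <- vapply(arows, function(x) x[2], character(1))
  pos <- t(vapply(arows, function(x) as.numeric(x[3:5]), numeric(3)))
  ord <- order(idx)
  types <- types[ord]; pos <- pos[ord, , drop = FALSE]
  n <- length(types)
  bonds <- matrix(0L, n, n)
  for (l in grab("BOND")) {
    x <- parse_row(l)
    o <- as.integer(x[2]); i <- match(as.integer(x[3]), idx[ord])
    j <- match(as.integer(x[4]), idx[ord])
    bonds[i, j] <- o; bonds[j, i] <- o
  }
  nm <- if (length(lines) >= 1L) trimws(lines[1]) else ""
  molecule3d(types, pos, bonds, name = nm)
}

# Plain V2000 text reader for records ChemmineR rejects (N == 1).
read_sdf_v2000_tiny <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stop("SDF format error: bad counts line")
  at <- lines[5:(4 + na)]
  types <- trimws(substr(at, 32, 34))
  pos <- cbind(as.numeric(substr(at, 1, 10)),
               as.numeric(substr(at, 11, 20)),
               as.numeric(substr(at, 21, 30)))
  bonds <- matrix(0L, na, na)
  if (nb > 0L) {
    bt <- lines[(5 + na):(4 + na + nb)]
    for (l in bt) {
      i <- as.integer(substr(l, 1, 3)); j <- as.integer(substr(l, 4, 6))
      o <- as.integer(substr(l, 7, 9))
      bonds[i, j] <- o; bonds[j, i] <- o
    }
  }
  molecule3d(types, pos, bonds, name = trimws(lines[1]))
}

first_record_lines <- function(lines) {
  end <- grep("^\\$\\$\\$\\$", lines)[1]
  if (is.na(end)) lines else lines[seq_len(end - 1L)]
}

#' Read the first ligand record from an SDF file
#'
#' Reads V2000 (via ChemmineR) or V3000 records; hydrogens are kept as
#' present in the file. Records whose coordinates are all-zero in z are
#' flagged with a warning as 2D-only.
#'
#' @param path path to an SDF/MOL file.
#' @return a `Molecule3D` (first record of the file).
#' @export
read_ligand <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0L || all(trimws(lines) == ""))
    stop("SDF format error: empty file")
  rec <- first_record_lines(lines)
  if (length(rec) < 4L) stop("SDF format error: truncated record")
  mol <- if (grepl("V3000", rec[4])) {
    read_sdf_v3000(rec)
  } else {
    na <- suppressWarnings(as.integer(substr(rec[4], 1, 3)))
    if (is.na(na)) stop("SDF format error: bad counts line")
    if (na == 1L) {
      read_sdf_v2000_tiny(rec)
    } else {
      s <- tryCatch(
        suppressWarnings(ChemmineR::read.SDFset(path)),
        error = function(e) stop("SDF format error: ", conditionMessage(e)))
      if (length(s) < 1L || !ChemmineR::validSDF(s)[1])
        stop("SDF format error: unparsable record in ", path)
      sdfobj_to_molecule3d(s[[1]])
    }
  }
  if (all(abs(mol$positions[, 3]) < 1e-9) && n_atoms(mol) > 2L)
    warning("ligand appears to have 2D-only coordinates (all z = 0)")
  mol
}

#' Read every record of a multi-record SDF file
#'
#' @param path path to an SDF file.
#' @return list of `Molecule3D`, one per parseable record.
#' @export
read_ligands <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                error = function(e) stop("SDF format error: ",
                                         conditionMessage(e)))
  ok <- ChemmineR::validSDF(s)
  lapply(which(ok), function(i) sdfobj_to_molecule3d(s[[i]]))
}

molecule3d_to_sdfobj <- function(mol) {
  n <- n_atoms(mol)
  # V2000 atom lines are fixed-width %10.4f columns; higher precision
  # shifts the element field and breaks downstream parsers
  ab <- cbind(round(mol$positions, 4), matrix(0, n, 12))
  rownames(ab) <- paste(mol$atom_types, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  idx <- which(upper.tri(mol$bonds) & mol$bonds > 0L, arr.ind = TRUE)
  nb <- nrow(idx)
  bb <- cbind(idx[, 1], idx[, 2], mol$bonds[idx], matrix(0, nb, 4))
  colnames(bb) <- paste0("C", 1:7)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  methods::new("SDF",
               header = c(Molecule_Name = mol$name, Source = "  phoregen",
                          Comment = "", Counts_Line = counts),
               atomblock = ab, bondblock = bb, datablock = character(0))
}

write_sdf_tiny <- function(mol, con) {
  lines <- c(mol$name, "  phoregen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n_atoms(mol), 0L),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     mol$positions[, 1], mol$positions[, 2],
                     mol$positions[, 3], mol$atom_types),
             "M  END", "$$$$")
  writeLines(lines, con)
}

#' Write molecules to an SDF file (V2000)
#'
#' @param mols a `Molecule3D` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "Molecule3D")) mols <- list(mols)
  if (length(mols) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  tiny <- vapply(mols, function(m) n_atoms(m) < 2L, logical(1))
  if (any(tiny)) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (m in mols) {
      if (n_atoms(m) < 2L) write_sdf_tiny(m, con)
      else {
        tmp <- tempfile(fileext = ".sdf")
        write_sdf(list(m), tmp)
        writeLines(readLines(tmp, warn = FALSE), con)
        unlink(tmp)
      }
    }
    return(invisible(path))
  }
  sdfs <- lapply(mols, molecule3d_to_sdfobj)
  s <- methods::new("SDFset", SDF = sdfs,
                    ID = paste0("CMP", seq_along(sdfs)))
  ChemmineR::write.SDF(s, path)
  invisible(path)
}
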