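# Synthetic-accessibility score: fragment-frequency contributions plus
# complexity penalties, normalized so that high values mean easy to make.
#
# The fragment-frequency table is built at first use from a shipped
# synthetic corpus (inst/extdata/sa_corpus_synthetic.sdf, ~50 common
# drug-like and fragment molecules); it is a small stand-in for the
# historic million-compound frequency tables, so absolute values are
# calibrated to this corpus while orderings (simple alkane vs decorated
# macrocycle) behave as expected. Fragment contribution for identifier i:
#   c_i = clip(2 * log10(count_i / gmean(count)), -4, 4),
# unknown fragments scoring -4.

.phoregen_cache <- new.env(parent = emptyenv())

sa_fragment_table <- function() {
  if (!is.null(.phoregen_cache$sa_table)) return(.phoregen_cache$sa_table)
  path <- system.file("extdata", "sa_corpus_synthetic.sdf",
                      package = "phoregen")
  if (path == "") stop("synthetic SA corpus not found")
  mols <- suppressWarnings(read_ligands(path))
  ids <- unlist(lapply(mols, circular_identifiers, radius = 2L))
  counts <- table(ids)
  g <- exp(mean(log(as.numeric(counts))))
  contrib <- pmin(4, pmax(-4, 2 * log10(as.numeric(counts) / g)))
  tab <- setNames(contrib, names(counts))
  .phoregen_cache$sa_table <- tab
  tab
}

#' Normalized synthetic-accessibility score
#'
#' Fragment-contribution score (mean contribution over all circular
#' fragment instances of radius 0..2) minus complexity penalties for
#' molecular size and macrocycles, plus a symmetry bonus for repetitive
#' molecules; mapped from the raw 1..10 synthetic-accessibility scale to
#' [0, 1] as `(10 - raw) / 9` so that high values denote compounds that
#' are simpler to synthesize.
#'
#' @param mol a `Molecule3D`.
#' @return normalized SA in [0, 1].
#' @export
sa_score_normalized <- function(mol) {
  (10 - sa_score_raw(mol)) / 9
}

#' Raw synthetic-accessibility score (1 hard, 10 easy reversed)
#'
#' @param mol a `Molecule3D`.
#' @return raw score in [1, 10]; low is easy to synthesize.
#' @export
sa_score_raw <- function(mol) {
  tab <- sa_fragment_table()
  ids <- circular_identifiers(mol, radius = 2L)
  key <- as.character(ids)
  contrib <- tab[key]
  contrib[is.na(contrib)] <- -4
  score1 <- mean(contrib)
  n_heavy <- length(heavy_atoms(mol))
  size_penalty <- n_heavy^1.005 - n_heavy
  macro_penalty <- if (any(ring_sizes(mol) > 8L)) log10(2) else 0
  n_unique <- length(unique(key))
  sym_bonus <- if (n_heavy > n_unique) log(n_heavy / n_unique) * 0.5 else 0
  raw <- score1 - size_penalty - macro_penalty + sym_bonus
  sa <- 11 - (raw + 5) / 7.5 * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  min(10, max(1, sa))
}
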