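test_that("hydrogen bonds obey the distance and donor-angle criteria", {
  # ligand N-H donor with an explicit hydrogen pointing +x
  lig <- mk_mol(c("N", "C", "H"),
                rbind(c(0, 0, 0), c(-1.4, 0, 0), c(1.0, 0, 0)),
                list(c(1, 2, 1), c(1, 3, 1)))
  acc_at <- function(pos) {
    protein_context(matrix(pos, 1, 3), residue_labels = "A:ASP:7",
                    atom_names = "OD1", elements = "O")
  }
  # 2.9 A, ~175 degrees: one bond
  hb <- detect_hbonds(lig, acc_at(c(2.9, 0.1, 0)))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$ligand_role, "donor")
  expect_equal(hb$protein_residue, "A:ASP:7")
  # same geometry at 5 A: beyond cutoff
  expect_equal(nrow(detect_hbonds(lig, acc_at(c(5, 0.17, 0)))), 0L)
  # 2.9 A but 90-degree donor angle: rejected
  expect_equal(nrow(detect_hbonds(lig, acc_at(c(1.0, 2.9, 0)))), 0L)
  # protein-donor to ligand-acceptor direction: distance criterion
  lig2 <- mol_methanol()
  don <- protein_context(matrix(c(2.43, 3.0, 0), 1, 3),
                         residue_labels = "A:LYS:3",
                         atom_names = "NZ", elements = "N")
  hb2 <- detect_hbonds(lig2, don)
  expect_equal(nrow(hb2), 1L)
  expect_equal(hb2$ligand_role, "acceptor")
})

test_that("detect_hbonds agrees with a brute-force all-pairs scan", {
  for (seed in 1:20) {
    lig <- random_tree_molecule(seed, n = 7)
    set.seed(seed + 500)
    P <- 12L
    ctx <- protein_context(
      matrix(rnorm(P * 3, sd = 3.5), P, 3),
      residue_labels = paste0("A:GLY:", rep(1:4, each = 3)),
      atom_names = sample(c("N", "O", "CA", "OG"), P, replace = TRUE),
      elements = sample(c("N", "O", "C"), P, replace = TRUE))
    got <- detect_hbonds(lig, ctx)
    bf <- detect_hbonds_bf(lig, ctx)
    expect_equal(nrow(got), bf$n)
    expect_setequal(paste(got$protein_residue, got$ligand_role), bf$keys)
  }
})

test_that("interaction similarity is the shared fraction of reference bonds", {
  # reference ligand with two donors and two acceptors hitting four
  # residues
  ref <- mk_mol(c("N", "C", "N", "O", "C", "O"),
                rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0),
                      c(1.4, 1.4, 0), c(1.4, -1.4, 0), c(1.4, -2.8, 0)),
                list(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1), c(2, 5, 1),
                     c(5, 6, 1)))
  ctx <- protein_context(
    rbind(c(-2.9, 0, 0), c(5.7, 0, 0), c(1.4, 4.2, 0), c(1.4, -5.6, 0)),
    residue_labels = c("A:ASP:1", "A:GLU:2", "A:LYS:3", "A:SER:4"),
    atom_names = c("OD1", "OE1", "NZ", "O"),
    elements = c("O", "O", "N", "O"))
  rb <- detect_hbonds(ref, ctx)
  expect_equal(nrow(rb), 4L)
  # identity: every bond reproduced
  expect_equal(interaction_similarity(ref, ref, ctx), 1.0)
  # an alkane reproduces nothing
  alk <- mk_mol(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                list(c(1, 2, 1)))
  expect_equal(interaction_similarity(alk, ref, ctx), 0.0)
  # half the reference bonds reproduced -> 0.5 (brute-force matched)
  half <- mk_mol(c("N", "C", "O"),
                 rbind(c(0, 0, 0), c(1.4, 0, 0), c(1.4, 1.4, 0)),
                 list(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(interaction_similarity(half, ref, ctx), 0.5)
  # undefined when the reference makes no bonds
  ctx_far <- protein_context(matrix(c(50, 50, 50), 1, 3),
                             residue_labels = "A:GLY:9",
                             atom_names = "O", elements = "O")
  expect_error(interaction_similarity(ref, ref, ctx_far),
               "undefined metric")
})

test_that("shape-and-color similarity is 1 on self and decays with distance", {
  mols <- corpus_molecules()
  asp <- mols[["aspirin"]]
  expect_gte(shape_color_similarity(asp, asp), 0.99)
  far <- asp; far$positions <- far$positions + 50
  expect_lte(shape_color_similarity(far, asp), 0.05)
  near <- asp; near$positions <- near$positions + c(1, 0, 0)
  s1 <- shape_color_similarity(near, asp)
  expect_lt(s1, shape_color_similarity(asp, asp))
  # monotone decay with translation
  mid <- asp; mid$positions <- mid$positions + c(2, 0, 0)
  expect_lt(shape_color_similarity(mid, asp), s1)
  # featureless pair: score reduces to shape, so distant alkanes ~ 0
  eth <- mols[["ethane"]]
  eth2 <- eth; eth2$positions <- eth2$positions + 50
  expect_lte(shape_color_similarity(eth2, eth), 0.05)
})

test_that("top-k by shape-and-color matches a full-sort oracle", {
  mols <- corpus_molecules()
  ref <- mols[["aspirin"]]
  cand <- list(mols[["ibuprofen"]], mols[["paracetamol"]],
               mols[["benzene"]], mols[["caffeine"]],
               mols[["benzoic_acid"]])
  scores <- vapply(cand, shape_color_similarity, numeric(1), ref = ref)
  t3 <- topk_by_sc(cand, ref, 3L)
  expect_identical(t3$index, order(-scores)[1:3])
  expect_equal(t3$scores, sort(scores, decreasing = TRUE)[1:3])
  t1 <- topk_by_sc(cand, ref, 1L)
  expect_identical(t1$index, which.max(scores))
  # ties keep input order
  same <- list(cand[[1]], cand[[1]], cand[[1]])
  expect_identical(topk_by_sc(same, ref, 2L)$index, c(1L, 2L))
  expect_warning(t_all <- topk_by_sc(cand, ref, 10L), "returning all")
  expect_length(t_all$mols, 5L)
})

test_that("synthetic-accessibility score behaves and is order-invariant", {
  mols <- corpus_molecules()
  eth <- mols[["ethane"]]
  sa_eth <- sa_score_normalized(eth)
  expect_gte(sa_eth, 0.6)
  expect_lte(sa_eth, 1)
  # a heteroatom-decorated macrocycle is harder than ethane
  nn <- 12
  ang <- seq(0, 2 * pi, length.out = nn + 1)[1:nn]
  bonds <- lapply(1:nn, function(i) c(i, i %% nn + 1, 1))
  mac <- mk_mol(c(rep("C", 9), "N", "O", "S"),
                cbind(3 * cos(ang), 3 * sin(ang), 0), bonds)
  expect_lt(sa_score_normalized(mac), sa_eth)
  # identical molecule in a different atom order scores identically
  set.seed(3)
  perm <- sample(nn)
  mac2 <- mk_mol(mac$atom_types[perm], mac$positions[perm, ],
                 list(), "perm")
  mac2$bonds <- mac$bonds[perm, perm]
  expect_equal(sa_score_normalized(mac2), sa_score_normalized(mac))
  # all corpus molecules stay in [0, 1]
  sas <- vapply(mols, sa_score_normalized, numeric(1))
  expect_true(all(sas >= 0 & sas <= 1))
})

test_that("diversity matches hand-enumerated pair averages", {
  mols <- corpus_molecules()
  eth <- mols[["ethane"]]
  expect_equal(diversity(list(eth, eth, eth)), 0)
  # disjoint bit sets -> 1 (ethane vs a nitrogen chain shares no
  # environment)
  nch <- mk_mol(c("N", "N", "N"),
                rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)),
                list(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(tanimoto(morgan_bits(eth), morgan_bits(nch)), 0)
  expect_equal(diversity(list(eth, nch)), 1)
  # three molecules with pairwise similarities {1, s, s}
  s <- tanimoto(morgan_bits(eth), morgan_bits(nch))
  expect_equal(diversity(list(eth, eth, nch)), 1 - (1 + 2 * s) / 3)
  expect_error(diversity(list(eth)), "at least 2")
})

test_that("fingerprints are invariant to atom order", {
  mols <- corpus_molecules()
  for (nm in c("aspirin", "caffeine", "ibuprofen")) {
    m <- mols[[nm]]
    set.seed(7)
    perm <- sample(n_atoms(m))
    m2 <- mk_mol(m$atom_types[perm], m$positions[perm, ], list(), "perm")
    m2$bonds <- m$bonds[perm, perm]
    expect_identical(morgan_bits(m), morgan_bits(m2))
  }
})

test_that("docking-score normalization divides by sqrt of atom count", {
  expect_identical(normalized_score(-12.0, 16L), -3.0)
  expect_identical(normalized_score(0, 7L), 0)
  expect_identical(normalized_score(-7.5, 25L), -1.5)
  expect_error(normalized_score(-5, 0L), "domain error")
})

test_that("QED reproduces the published desirability evaluation", {
  # expected value computed with the reference implementation of the
  # published desirability functions on the same descriptor vector
  # (MW 180.157, ALOGP 1.31, HBA 3, HBD 1, PSA 63.6, ROTB 3, AROM 1,
  # ALERTS 0) and frozen here
  desc <- c(MW = 180.157, ALOGP = 1.31, HBA = 3, HBD = 1, PSA = 63.6,
            ROTB = 3, AROM = 1, ALERTS = 0)
  expect_equal(qed_from_descriptors(desc), 0.7621823003, tolerance = 1e-9)
  # full pipeline on real molecules stays in [0, 1] and is order-invariant
  mols <- corpus_molecules()
  q <- qed(mols[["aspirin"]])
  expect_gt(q, 0); expect_lt(q, 1)
  m <- mols[["paracetamol"]]
  set.seed(11)
  perm <- sample(n_atoms(m))
  m2 <- mk_mol(m$atom_types[perm], m$positions[perm, ], list(), "perm")
  m2$bonds <- m$bonds[perm, perm]
  expect_equal(qed(m2), qed(m), tolerance = 1e-9)
})

test_that("rotatable bonds and aromatic rings count correctly", {
  mols <- corpus_molecules()
  expect_equal(rotatable_bonds(mols[["butane"]]), 1L)
  expect_equal(rotatable_bonds(mols[["octane"]]), 5L)
  expect_equal(rotatable_bonds(mols[["benzene"]]), 0L)
  # amide bond is not rotatable
  expect_equal(rotatable_bonds(mols[["n_methylacetamide"]]), 0L)
  expect_equal(count_aromatic_rings(mols[["benzene"]]), 1L)
  expect_equal(count_aromatic_rings(mols[["pyridine"]]), 1L)
  expect_equal(count_aromatic_rings(mols[["furan"]]), 1L)
  expect_equal(count_aromatic_rings(mols[["cyclohexane"]]), 0L)
  expect_equal(count_aromatic_rings(mols[["tetrahydrofuran"]]), 0L)
  expect_equal(count_aromatic_rings(mols[["caffeine"]]), 2L)
})
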