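test_that("a rigid molecule yields exactly one conformer", {
  cs <- enumerate_conformers(mol_benzene())
  expect_length(cs$coords, 1)
  expect_equal(cs$strain, 0)
})

test_that("butane torsion scan matches the brute-force minima count", {
  cs <- enumerate_conformers(mol_butane(), torsion_increment = 120)
  oracle <- oracle_butane_minima()
  # the dense scan finds anti plus the two mirror-related gauche minima;
  # gauche forms are NOT RMSD duplicates (mirror conformations cannot be
  # superposed by a proper rotation), so all survive dedupe
  expect_length(cs$coords, length(oracle$angles))
  expect_length(cs$coords, 3)
  # two distinct energy levels: anti below the (degenerate) gauche pair
  lev <- sort(unique(round(cs$strain, 3)))
  expect_length(lev, 2)
  expect_equal(lev[1], 0)
  expect_equal(sort(round(cs$strain, 2)),
               sort(round(oracle$energies - min(oracle$energies), 2)))
  # gauche pair really is mirror-related: equal energy, nonzero mutual RMSD
  gg <- which(cs$strain > 1e-6)
  expect_gt(conf_rmsd(cs$mol, cs$coords[[gg[1]]], cs$coords[[gg[2]]]), 0.15)
})

test_that("stated caps and dedupe invariants hold", {
  cs <- enumerate_conformers(mol_butane(), torsion_increment = 30)
  expect_lte(length(cs$coords), 250)
  if (length(cs$coords) > 1) {
    prs <- utils::combn(length(cs$coords), 2)
    for (k in seq_len(ncol(prs)))
      expect_gte(conf_rmsd(cs$mol, cs$coords[[prs[1, k]]],
                           cs$coords[[prs[2, k]]]), 0.15)
  }
  # a 30-degree grid collapses to the same three minima after minimization
  expect_length(cs$coords, 3)
  # hard cap respected
  cs2 <- enumerate_conformers(mol_butane(), torsion_increment = 120, max_conf = 2)
  expect_length(cs2$coords, 2)
})

test_that("shrinking the strain window never increases the conformer count", {
  counts <- vapply(c(4, 0.9, 0.3, 0.05), function(w)
    length(enumerate_conformers(mol_butane(), torsion_increment = 120,
                                strain_window = w)$coords), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[[4]], 1)  # only the global minimum survives a tight window
})

test_that("enumeration is invariant to atom-order permutation", {
  m <- mol_butane()
  perm <- c(4, 3, 2, 1)  # reverse the chain
  m2 <- new_molecule("butane_rev", m$atoms$elem[perm], m$coords[perm, ],
                     data.frame(i = c(4, 3, 2), j = c(3, 2, 1), order = 1L),
                     nh = m$atoms$nh[perm])
  cs1 <- enumerate_conformers(m, torsion_increment = 120)
  cs2 <- enumerate_conformers(m2, torsion_increment = 120)
  expect_equal(length(cs1$coords), length(cs2$coords))
  expect_equal(sort(round(cs1$strain, 4)), sort(round(cs2$strain, 4)))
})

test_that("the minimizer contract is honoured by pluggable implementations", {
  m <- mol_butane()
  ref <- m$coords + 0.5
  cs <- enumerate_conformers(m, torsion_increment = 120,
                             minimizer = harmonic_minimizer(ref))
  # a harmonic well collapses every grid point to the reference geometry
  expect_length(cs$coords, 1)
  expect_equal(cs$coords[[1]], ref)
  expect_error(enumerate_conformers(
    new_molecule("nan", "C", matrix(NaN, 1, 3)), torsion_increment = 120),
    "finite|geometry")
})

test_that("rotatable-bond detection excludes rings and terminal bonds", {
  expect_equal(nrow(rotatable_bonds(mol_benzene())), 0)
  expect_equal(nrow(rotatable_bonds(mol_butane())), 1)
  expect_equal(nrow(rotatable_bonds(mol_alkane(6))), 3)
  # phenol C-O is terminal on the oxygen side: not rotatable
  expect_equal(nrow(rotatable_bonds(mol_phenol())), 0)
})
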