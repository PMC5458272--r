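toy_hyp <- function() {
  tc <- make_toy_complex()
  list(tc = tc,
       hyp = build_hypothesis(tc$structure, tc$anchor,
                              essential_residues = tc$declared$essential_residues))
}

test_that("the builder derives the documented feature set from the toy interface", {
  th <- toy_hyp()
  hyp <- th$hyp
  expect_length(hyp$features, th$tc$declared$n_features)
  expect_equal(ph_n_points(hyp), th$tc$declared$n_points)
  kinds <- vapply(hyp$features, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "aromatic"), 2)
  expect_equal(sum(kinds == "donor"), 3)
  expect_equal(sum(kinds == "acceptor"), 1)
  # every feature carries a projection (the "points = 2 x features" layout)
  expect_true(all(vapply(hyp$features, function(f) !is.null(f$proj), logical(1))))
  expect_gt(nrow(hyp$exclusions), 0)
})

test_that("a toy Tyr-Gly-Tyr anchor yields the hand-enumerated feature count", {
  contacts <- data.frame(
    resno = c(1, 3, 3),
    type = c("aromatic", "aromatic", "donor_bb"),
    partner_resname = c("LEU", "VAL", "GLU"),
    partner_resno = c(50, 51, 52))
  tc <- make_toy_complex(toy_complex_spec(anchor_seq = "YGY", start_resno = 1,
                                          contacts = contacts))
  hyp <- build_hypothesis(tc$structure, tc$anchor, essential_residues = c(1, 3))
  # manual enumeration: two rings (always annotated) + one paired backbone N-H
  expect_length(hyp$features, 3)
  expect_setequal(vapply(hyp$features, `[[`, character(1), "kind"),
                  c("aromatic", "aromatic", "donor"))
})

test_that("an anchor without any receptor-paired group raises an empty-hypothesis error", {
  lines <- c(
    "ATOM      1  N   ALA P   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA P   1       1.400   0.400   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA P   1       2.500   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA P   1       2.500   1.230   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA P   1       1.400   0.400   1.500  1.00  0.00           C",
    "ATOM      6  CA  GLY R  50      50.000  50.000  50.000  1.00  0.00           C")
  st <- read_structure(lines)
  expect_error(build_hypothesis(st, residue_selection("P", 1)),
               "empty hypothesis")
})

test_that("the hypothesis matches its own feature points exactly in absolute mode", {
  th <- toy_hyp()
  res <- ph_match(th$hyp, hypothesis_points(th$hyp), mode = "absolute")
  expect_true(res$matched)
  expect_equal(res$n_matched, length(th$hyp$features))
  expect_equal(res$feature_rmsd, 0, tolerance = 1e-9)
})

test_that("align mode tolerates rigid motion, absolute mode rejects it", {
  th <- toy_hyp()
  lib <- make_library(library_spec(n_actives = 1, n_decoys = 0, seed = 5), th$hyp)
  m <- lib$mols[[1]]
  expect_true(ph_match(th$hyp, m, mode = "absolute")$matched)
  m5 <- ppiscreen:::transform_mol(m, diag(3), c(5, 0, 0))
  expect_false(ph_match(th$hyp, m5, mode = "absolute")$matched)
  expect_true(ph_match(th$hyp, m5, mode = "align")$matched)
})

test_that("align-mode verdict is invariant under rigid transforms of the conformer", {
  th <- toy_hyp()
  lib <- make_library(library_spec(n_actives = 2, n_decoys = 2, seed = 8), th$hyp)
  set.seed(11)
  for (m in lib$mols) {
    base <- ph_match(th$hyp, m, mode = "align")$matched
    for (rep in 1:2) {
      mt <- ppiscreen:::transform_mol(m, ppiscreen:::random_rotation(),
                                      stats::rnorm(3, 0, 6))
      expect_equal(ph_match(th$hyp, mt, mode = "align")$matched, base)
    }
  }
})

test_that("a conformer missing an essential feature never matches", {
  th <- toy_hyp()
  lib <- make_library(library_spec(n_actives = 1, n_decoys = 0, seed = 13), th$hyp)
  m <- lib$mols[[1]]
  # drop the ring realizing the Tyr8 aromatic essential (atoms 1-6 by construction)
  keep <- setdiff(seq_len(nrow(m$atoms)), 1:6)
  bonds <- m$bonds[m$bonds$i %in% keep & m$bonds$j %in% keep, ]
  bonds$i <- match(bonds$i, keep)
  bonds$j <- match(bonds$j, keep)
  m2 <- new_molecule("noring", m$atoms$elem[keep], m$coords[keep, ], bonds,
                     nh = m$atoms$nh[keep])
  expect_false(ph_match(th$hyp, m2, mode = "absolute")$matched)
  expect_false(ph_match(th$hyp, m2, mode = "align")$matched)
  # the exhaustive oracle agrees
  expect_null(oracle_match_absolute(th$hyp, annotate_ligand(m2)))
})

test_that("matcher agrees with the exhaustive-correspondence oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_match_instance(seed)
    got <- ph_match(inst$hyp, inst$points, mode = "absolute")
    want <- oracle_match_absolute(inst$hyp, inst$points)
    expect_equal(got$matched, !is.null(want), info = paste("seed", seed))
    if (got$matched) {
      expect_equal(got$n_matched, want$n, info = paste("seed", seed))
      expect_equal(got$feature_rmsd, want$rmsd, tolerance = 1e-9,
                   info = paste("seed", seed))
    }
  }
})

test_that("removing a non-essential feature never unmatches; exclusions never create matches", {
  th <- toy_hyp()
  lib <- make_library(library_spec(n_actives = 2, n_decoys = 2, seed = 21), th$hyp)
  for (m in lib$mols) {
    before <- ph_match(th$hyp, m, mode = "align")$matched
    hyp2 <- th$hyp
    ess <- vapply(hyp2$features, `[[`, logical(1), "essential")
    hyp2$features <- hyp2$features[-(which(!ess)[1])]
    after <- ph_match(hyp2, m, mode = "align")$matched
    if (before) expect_true(after)
    # adding an exclusion sphere can only destroy matches
    hyp3 <- th$hyp
    hyp3$exclusions <- rbind(hyp3$exclusions,
                             data.frame(x = 0, y = 0, z = 0, r = 2))
    if (!before) expect_false(ph_match(hyp3, m, mode = "align")$matched)
  }
})

test_that("hypotheses serialize through versioned JSON losslessly", {
  th <- toy_hyp()
  tf <- tempfile(fileext = ".json")
  ph_write_json(th$hyp, tf)
  back <- ph_read_json(tf)
  expect_length(back$features, length(th$hyp$features))
  for (k in seq_along(back$features)) {
    expect_equal(back$features[[k]]$center, th$hyp$features[[k]]$center)
    expect_equal(back$features[[k]]$proj, th$hyp$features[[k]]$proj)
    expect_equal(back$features[[k]]$kind, th$hyp$features[[k]]$kind)
    expect_equal(back$features[[k]]$essential, th$hyp$features[[k]]$essential)
  }
  expect_equal(back$exclusions, th$hyp$exclusions)
  expect_equal(back$min_match, th$hyp$min_match)
  # self-match still exact after the round trip
  expect_true(ph_match(back, hypothesis_points(back), mode = "absolute")$matched)
  expect_error(ph_read_json(tempfile()), ".")
})
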