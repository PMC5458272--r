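screen_fixture <- function(n_act = 4, n_dec = 4, seed = 2) {
  tc <- make_toy_complex()
  hyp <- build_hypothesis(tc$structure, tc$anchor,
                          essential_residues = tc$declared$essential_residues)
  lib <- make_library(library_spec(n_actives = n_act, n_decoys = n_dec,
                                   seed = seed), hyp)
  list(hyp = hyp, lib = lib)
}

test_that("pharmacophore screen separates engineered actives from feature-free decoys", {
  fx <- screen_fixture()
  surv <- ph_screen(fx$lib$mols, fx$hyp)
  expect_setequal(surv, fx$lib$labels$id[fx$lib$labels$active])
  # per-compound independence: survivors of a union = union of survivors
  a <- fx$lib$mols[1:4]
  b <- fx$lib$mols[5:8]
  expect_setequal(ph_screen(c(a, b), fx$hyp),
                  union(ph_screen(a, fx$hyp),
                        tryCatch(ph_screen(b, fx$hyp), error = function(e) character())))
  expect_error(ph_screen(list(), fx$hyp), "empty")
})

test_that("z-score selection follows the strict two-sigma rule", {
  expect_warning(sel <- zscore_select(stats::setNames(rep(5, 10), letters[1:10])),
                 "variance")
  expect_length(sel, 0)
  set.seed(3)
  sc <- stats::setNames(rnorm(500, 5.89, 0.93), sprintf("c%03d", 1:500))
  sel <- zscore_select(sc)
  expect_setequal(sel, names(sc)[sc > mean(sc) + 2 * sd(sc)])
  # affine invariance: adding a constant changes nothing
  expect_setequal(zscore_select(sc + 3), sel)
  expect_error(zscore_select(c(a = 1)), "at least 2")
})

test_that("pose RMSD is exact for translations and a metric on fixed mappings", {
  m <- mol_butane()
  p0 <- docked_pose(m, m$coords, "e1", 5)
  for (d in c(0.5, 2, 7)) {
    pd <- docked_pose(m, m$coords + matrix(c(d, 0, 0), 4, 3, byrow = TRUE), "e2", 5)
    expect_equal(pose_rmsd(p0, pd), d, tolerance = 1e-12)
  }
  expect_equal(pose_rmsd(p0, p0), 0)
  # triangle inequality on a few random pose triples
  set.seed(14)
  ps <- lapply(1:3, function(i)
    docked_pose(m, m$coords + matrix(rnorm(12, 0, 1), 4, 3), "e", 5))
  ab <- pose_rmsd(ps[[1]], ps[[2]])
  bc <- pose_rmsd(ps[[2]], ps[[3]])
  ac <- pose_rmsd(ps[[1]], ps[[3]])
  expect_lte(ac, ab + bc + 1e-12)
  expect_error(pose_rmsd(p0, docked_pose(mol_benzene(), mol_benzene()$coords, "x", 1)),
               "different compounds")
})

test_that("symmetry-aware RMSD nulls topologically equivalent flips", {
  b <- mol_benzene()
  R <- ppiscreen:::rotation_about_axis(c(0, 0, 1), 60)
  p1 <- docked_pose(b, b$coords, "e1", 5)
  p2 <- docked_pose(b, b$coords %*% t(R), "e2", 5)
  expect_gt(pose_rmsd(p1, p2, symmetry_aware = FALSE), 1)
  expect_equal(pose_rmsd(p1, p2, symmetry_aware = TRUE), 0, tolerance = 1e-9)
  # symmetry-aware never exceeds naive
  set.seed(6)
  for (rep in 1:5) {
    pj <- docked_pose(b, b$coords + matrix(rnorm(18, 0, 0.6), 6, 3), "e", 5)
    expect_lte(pose_rmsd(p1, pj, TRUE), pose_rmsd(p1, pj, FALSE) + 1e-12)
  }
})

test_that("consensus filter demands pose agreement plus the absolute refilter", {
  fx <- screen_fixture(n_act = 2, n_dec = 1, seed = 4)
  m <- fx$lib$mols[[1]]
  same <- lapply(c("dovis", "vina", "moldock"), function(e)
    docked_pose(m, m$coords, e, 5))
  res <- consensus_filter(same, fx$hyp)
  expect_true(res$pass)
  # one engine jittered far away fails
  moved <- same
  moved[[3]] <- docked_pose(m, m$coords + matrix(c(5, 0, 0), nrow(m$coords), 3,
                                                 byrow = TRUE), "moldock", 5)
  expect_false(consensus_filter(moved, fx$hyp)$pass)
  # missing engine fails with a recorded reason
  res2 <- consensus_filter(same[1:1], fx$hyp)
  expect_false(res2$pass)
  expect_match(res2$reason, "missing engine")
  # a decoy with perfectly agreeing poses still fails the refilter
  d <- fx$lib$mols[[which(!fx$lib$labels$active)[1] ]]
  dp <- lapply(c("dovis", "vina"), function(e) docked_pose(d, d$coords, e, 5))
  res3 <- consensus_filter(dp, fx$hyp)
  expect_false(res3$pass)
  expect_match(res3$reason, "pharmacophore")
})

test_that("mock docking consensus recovers the generator's ground truth", {
  fx <- screen_fixture(n_act = 6, n_dec = 0, seed = 9)
  ids <- names(fx$lib$mols)
  md <- make_mock_docking(fx$lib$mols,
                          mock_engine_spec(inconsistent_ids = ids[5:6], seed = 3))
  cf <- consensus_filter(md$poses, fx$hyp)
  expect_setequal(cf$compound[cf$pass],
                  md$truth$compound[md$truth$consistent])
})

test_that("clustering equals connected components and picks the most potent representative", {
  fx <- screen_fixture(n_act = 5, n_dec = 5, seed = 12)
  mols <- fx$lib$mols
  scores <- stats::setNames(seq_along(mols) + 4, names(mols))
  sim <- tanimoto_matrix(mols)
  df <- cluster_and_pick(mols, scores, similarity_threshold = 0.7, sim = sim)
  memb <- oracle_components(sim, 0.7)
  # same partition (up to label renaming)
  got <- df$cluster[match(names(mols), df$compound)]
  expect_equal(length(unique(got)), length(unique(memb)))
  expect_true(all(tapply(memb, got, function(v) length(unique(v))) == 1))
  # per cluster, the highest score is flagged
  for (cl in unique(df$cluster)) {
    sub <- df[df$cluster == cl, ]
    expect_equal(sub$compound[sub$representative],
                 sub$compound[order(-sub$score, sub$compound)][1])
  }
  # identical molecules collapse to one representative with the higher score
  dup <- list(mol_benzene("m1"), mol_benzene("m2"))
  df2 <- cluster_and_pick(dup, c(m1 = 5, m2 = 7))
  expect_equal(length(unique(df2$cluster)), 1)
  expect_equal(df2$compound[df2$representative], "m2")
  # all-dissimilar set: everyone represents itself
  mix <- list(mol_benzene("b"), mol_alkane(7, "a7"))
  df3 <- cluster_and_pick(mix, c(b = 5, a7 = 6))
  expect_equal(sum(df3$representative), 2)
})
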