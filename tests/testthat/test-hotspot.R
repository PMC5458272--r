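test_that("column entropies match the closed form on a small toy alignment", {
  # five distinct sequences (duplicates would be collapsed before scoring)
  ali <- rbind(c("A", "Y", "S"),
               c("A", "Y", "T"),
               c("A", "Y", "N"),
               c("G", "Y", "D"),
               c("G", "Y", "S"))
  prof <- conservation_profile(ali)
  hand <- function(p) -sum(p * log(p))
  expect_equal(prof$entropy[1], hand(c(3, 2) / 5))
  expect_equal(prof$entropy[2], 0)
  expect_equal(prof$entropy[3], hand(c(2, 1, 1, 1) / 5))
})

test_that("invariant columns score 9 and a maximally variable column scores 0", {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ali <- cbind(rep("Y", 20), aa20, rep("S", 20))
  ali[1:10, 3] <- "T"   # middle-ground column
  prof <- conservation_profile(ali)
  expect_equal(prof$score[1], 9L)
  expect_equal(prof$score[2], 0L)
  expect_true(prof$score[3] > 0 && prof$score[3] < 9)
})

test_that("conservation is invariant under row permutation and duplication", {
  ali <- make_anchor_msa(n_seqs = 10, seed = 3)
  base <- conservation_profile(ali)$score
  expect_equal(conservation_profile(ali[sample(nrow(ali)), ])$score, base)
  expect_equal(conservation_profile(rbind(ali, ali[4, ]))$score, base)
})

test_that("degenerate alignments are rejected", {
  expect_error(conservation_profile(matrix("A", 1, 5)), "at least 2")
  ragged <- list(ali = rbind(c("A", "Y", "S"), c("A", "Y", NA)))
  expect_error(conservation_profile(ragged), "ragged")
})

test_that("alanine-scan contact counts equal brute-force enumeration", {
  tc <- make_toy_complex()
  ala <- alanine_scan(tc$structure, tc$anchor)
  for (k in seq_len(nrow(ala))) {
    if (ala$resname[k] %in% c("ALA", "GLY")) next
    expect_equal(ala$n_contacts[k],
                 oracle_sc_contacts(tc$structure, tc$anchor, ala$resno[k], 4.5))
  }
})

test_that("ala/gly and contact-free side chains score exactly zero", {
  tc <- make_toy_complex(toy_complex_spec(anchor_seq = "GYSYA"))
  ala <- alanine_scan(tc$structure, tc$anchor)
  expect_equal(ala$ddg[ala$resname == "GLY"], 0)
  expect_equal(ala$ddg[ala$resname == "ALA"], 0)
  # the toy aspartate side chain points away from the receptor
  tc2 <- make_toy_complex()
  ala2 <- alanine_scan(tc2$structure, tc2$anchor)
  expect_equal(ala2$ddg[ala2$resname == "ASP"], 0)
})

test_that("surrogate ddG is invariant under rigid motion and monotone in cutoff", {
  tc <- make_toy_complex()
  base <- alanine_scan(tc$structure, tc$anchor)
  set.seed(9)
  R <- ppiscreen:::random_rotation()
  st2 <- tc$structure
  xyz <- as.matrix(st2$atoms[, c("x", "y", "z")]) %*% t(R)
  st2$atoms$x <- xyz[, 1] + 4
  st2$atoms$y <- xyz[, 2] - 2
  st2$atoms$z <- xyz[, 3] + 9
  expect_equal(alanine_scan(st2, tc$anchor)$ddg, base$ddg)
  prev <- rep(0L, nrow(base))
  for (cu in c(3.5, 4.5, 6)) {
    cur <- alanine_scan(tc$structure, tc$anchor, contact_cutoff = cu)$n_contacts
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("hot-spot ranking is the intersection of the two filters", {
  tc <- make_toy_complex()
  prof <- conservation_profile(make_anchor_msa(n_seqs = 12, seed = 5))
  ala <- alanine_scan(tc$structure, tc$anchor)
  hs <- rank_hotspots(prof, ala, cons_min = 7, ddg_window = c(2, 4))
  manual <- ala$resno[prof$score[seq_len(nrow(ala))] >= 7 &
                        !is.na(ala$ddg) & ala$ddg >= 2 & ala$ddg <= 4]
  expect_setequal(hs$resno, manual)
  # mirrors the expected pattern: exactly the two tyrosine anchors
  expect_setequal(hs$resno, c(8, 10))
  expect_equal(hs$resname, c("TYR", "TYR"))
  expect_true(all(diff(hs$ddg) <= 0))  # sorted by ddG descending
  # raising the conservation floor above everything empties the list
  expect_equal(nrow(rank_hotspots(prof, ala, cons_min = 10)), 0)
  expect_error(rank_hotspots(prof[0, ], ala), "empty")
})
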