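test_that("a minimal ATOM record parses verbatim", {
  line <- "ATOM      1  CA  GLY A   1      11.104  22.020  -3.143  1.00  0.00           C"
  st <- read_structure(line)
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$name, "CA")
  expect_equal(st$atoms$resname, "GLY")
  expect_equal(st$atoms$resno, 1)
  expect_equal(unlist(st$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(11.104, 22.020, -3.143))
})

test_that("the toy complex round-trips through PDB text at PDB precision", {
  tc <- make_toy_complex()
  expect_equal(nrow(tc$structure$atoms), tc$declared$n_atoms)
  st2 <- read_structure(write_structure(tc$structure))
  expect_equal(st2$atoms$x, tc$structure$atoms$x, tolerance = 1e-9)
  expect_equal(st2$atoms$name, tc$structure$atoms$name)
  expect_equal(st2$atoms$resno, tc$structure$atoms$resno)
})

test_that("malformed and unsupported records fail loudly", {
  bad <- c("ATOM      1  CA  GLY A   1      11.104  xx.020  -3.143  1.00  0.00           C")
  expect_error(read_structure(bad), "line 1")
  expect_error(read_structure("REMARK nothing here"), "no ATOM record")
  ins <- "ATOM      1  CA  GLY A   1A     11.104  22.020  -3.143  1.00  0.00           C"
  expect_error(read_structure(ins), "insertion codes")
})

test_that("altloc resolution keeps the highest occupancy, ties to A", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AGLY A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BGLY A   1       3.000   0.000   0.000  0.50  0.00           C")
  st <- read_structure(lines)
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x[st$atoms$name == "CA"], 1.0)  # higher occupancy wins
  expect_equal(st$atoms$x[st$atoms$name == "CB"], 2.0)  # tie goes to altloc A
})

test_that("HETATM records are flagged and droppable", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O")
  st <- read_structure(lines)
  expect_equal(sum(st$atoms$het), 1)
  expect_equal(nrow(read_structure(lines, drop_het = TRUE)$atoms), 1)
})

test_that("interface atoms equal brute-force enumeration and behave like a metric ball", {
  tc <- make_toy_complex()
  ia <- interface_atoms(tc$structure, tc$anchor, 4.0)
  oracle <- oracle_interface(tc$structure, tc$anchor, 4.0)
  expect_equal(paste(ia$chain, ia$resno, ia$name),
               paste(oracle$chain, oracle$resno, oracle$name))
  # zero cutoff: empty
  expect_equal(nrow(interface_atoms(tc$structure, tc$anchor, 0)), 0)
  # monotone: enlarging the cutoff never removes atoms
  prev <- character()
  for (cu in c(2, 3.5, 4, 5, 7)) {
    cur <- with(interface_atoms(tc$structure, tc$anchor, cu),
                paste(chain, resno, name))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(interface_atoms(tc$structure, tc$anchor, -1), ">= 0")
})

test_that("interface set is invariant under rigid transformation", {
  tc <- make_toy_complex()
  set.seed(4)
  R <- ppiscreen:::random_rotation()
  tv <- c(12, -5, 3)
  st2 <- tc$structure
  xyz <- as.matrix(st2$atoms[, c("x", "y", "z")]) %*% t(R)
  st2$atoms$x <- xyz[, 1] + tv[1]
  st2$atoms$y <- xyz[, 2] + tv[2]
  st2$atoms$z <- xyz[, 3] + tv[3]
  a <- interface_atoms(tc$structure, tc$anchor, 4.0)
  b <- interface_atoms(st2, tc$anchor, 4.0)
  expect_equal(paste(a$chain, a$resno, a$name), paste(b$chain, b$resno, b$name))
})

test_that("selections validate against the structure", {
  tc <- make_toy_complex()
  expect_error(residue_selection("T", integer()), "empty")
  bad <- residue_selection("T", c(7, 99))
  expect_error(interface_atoms(tc$structure, bad, 4), "not present")
})
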