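# ligand_model: small-molecule container, SDF I/O, graph utilities and
# pharmacophore annotation points.

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 5, F = 1, CL = 1,
                      BR = 1, I = 1, H = 1)

#' Construct a small molecule
#'
#' A light container used throughout the screening cascade: element and
#' formal charge per atom, bond list with orders (1, 2, 3, or 4 for
#' aromatic), one 3D geometry, and an implicit-hydrogen count per atom
#' (`nh`) used by the annotation rules when no explicit hydrogens are
#' present.
#'
#' @param name compound identifier (e.g., a library code).
#' @param elem character vector of element symbols.
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param bonds data.frame with columns `i`, `j`, `order`; may have 0 rows.
#' @param charge,nh optional per-atom integer vectors.
#' @export
new_molecule <- function(name, elem, coords, bonds = NULL, charge = 0L, nh = 0L) {
  elem <- toupper(elem)
  n <- length(elem)
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == n)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(), order = integer())
  bonds <- as.data.frame(bonds)
  charge <- rep_len(as.integer(charge), n)
  nh <- rep_len(as.integer(nh), n)
  mol <- structure(list(name = name,
                        atoms = data.frame(elem = elem, charge = charge, nh = nh,
                                           stringsAsFactors = FALSE),
                        bonds = bonds, coords = coords),
                   class = "ppi_mol")
  check_valence(mol)
  mol
}

# Valence sanity check: explicit bond order sum + implicit H must not exceed
# the standard valence (adjusted by formal charge). Aromatic bonds count 1.5.
check_valence <- function(mol) {
  if (!all(mol$bonds$order %in% c(1L, 2L, 3L, 4L)))
    stop("bond orders must be 1, 2, 3 or 4 (aromatic)")
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) > 0 &&
      (max(mol$bonds$i, mol$bonds$j) > n || min(mol$bonds$i, mol$bonds$j) < 1))
    stop("bond indices out of range")
  bo <- rep(0, n)
  for (r in seq_len(nrow(mol$bonds))) {
    o <- if (mol$bonds$order[r] == 4L) 1.5 else mol$bonds$order[r]
    bo[mol$bonds$i[r]] <- bo[mol$bonds$i[r]] + o
    bo[mol$bonds$j[r]] <- bo[mol$bonds$j[r]] + o
  }
  v <- STANDARD_VALENCE[mol$atoms$elem]
  known <- !is.na(v)
  over <- known & (bo + mol$atoms$nh > v + abs(mol$atoms$charge) + 0.51)
  if (any(over))
    stop("valence error at atom(s) ", paste(which(over), collapse = ","),
         " of ", mol$name)
  invisible(TRUE)
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_idx <- function(mol) which(!mol$atoms$elem %in% c("H", "D"))

#' @export
print.ppi_mol <- function(x, ...) {
  cat("ppi_mol", x$name, ":", n_atoms(x), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

# igraph view of the heavy-atom connectivity, element-colored.
mol_graph <- function(mol, heavy_only = TRUE) {
  keep <- if (heavy_only) heavy_idx(mol) else seq_len(n_atoms(mol))
  map <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(b) > 0)
    g <- igraph::add_edges(g, rbind(map[b$i], map[b$j]))
  igraph::E(g)$order <- if (nrow(b) > 0) b$order else integer()
  igraph::V(g)$elem <- mol$atoms$elem[keep]
  g
}

#' Graph automorphisms of the heavy-atom skeleton
#'
#' Element-preserving, bond-order-preserving permutations of the heavy
#' atoms, enumerated with igraph's VF2 machinery. Used for symmetry-aware
#' RMSD. Enumeration is capped; molecules at the sizes handled here stay
#' far below the cap.
#'
#' @param mol a `ppi_mol`
#' @param cap maximum number of automorphisms returned.
#' @return list of integer permutations over the heavy atoms (in
#'   `heavy_idx` order); always contains the identity.
#' @export
mol_automorphisms <- function(mol, cap = 10000) {
  g <- mol_graph(mol)
  col <- as.integer(factor(igraph::V(g)$elem))
  eo <- igraph::E(g)$order
  maps <- igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = col,
                                             vertex.color2 = col,
                                             edge.color1 = eo, edge.color2 = eo)
  if (length(maps) > cap) maps <- maps[seq_len(cap)]
  perms <- lapply(maps, as.integer)
  if (!any(vapply(perms, function(p) all(p == seq_along(p)), logical(1))))
    perms <- c(list(seq_len(igraph::vcount(g))), perms)
  perms
}

# ---- SDF I/O ---------------------------------------------------------------

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a `ppi_mol` or list of them.
#' @param file output path.
#' @param tags optional named list (per molecule, recycled) of SD tags, e.g.
#'   `list(strain = c(0, 1.2))` writes a `> <strain>` field.
#' @export
write_sdf <- function(mols, file, tags = NULL) {
  if (inherits(mols, "ppi_mol")) mols <- list(mols)
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    lines <- c(m$name, "  ppiscreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n_atoms(m), nrow(m$bonds)),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       m$coords[, 1], m$coords[, 2], m$coords[, 3], m$atoms$elem))
    if (nrow(m$bonds) > 0)
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                m$bonds$i, m$bonds$j, m$bonds$order))
    chg <- which(m$atoms$charge != 0)
    if (length(chg))
      lines <- c(lines, sprintf("M  CHG%3d%s", length(chg),
                                paste0(sprintf("%4d%4d", chg, m$atoms$charge[chg]),
                                       collapse = "")))
    lines <- c(lines, "M  END")
    for (tg in names(tags))
      lines <- c(lines, sprintf(">  <%s>", tg), as.character(tags[[tg]][[k]]), "")
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(file)
}

#' Read molecules from an SDF file
#'
#' Parsing goes through [ChemmineR::read.SDFset()]; the result is converted
#' to the package's molecule container. Implicit hydrogen counts are
#' inferred from standard valences minus explicit bond orders.
#'
#' @param file SDF path.
#' @return list of `ppi_mol`.
#' @export
read_sdf <- function(file) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(file))
  lapply(seq_along(sdfs@SDF), function(i) {
    sdf <- sdfs@SDF[[i]]
    ab <- sdf@atomblock
    bb <- sdf@bondblock
    elem <- toupper(gsub("_.*$", "", rownames(ab)))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (nrow(bb) > 0)
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    else data.frame(i = integer(), j = integer(), order = integer())
    nh <- infer_implicit_h(elem, bonds)
    new_molecule(name = sdf@header[["Molecule_Name"]], elem = elem,
                 coords = coords, bonds = bonds, nh = nh)
  })
}

infer_implicit_h <- function(elem, bonds) {
  n <- length(elem)
  bo <- rep(0, n)
  for (r in seq_len(nrow(bonds))) {
    o <- if (bonds$order[r] == 4L) 1.5 else bonds$order[r]
    bo[bonds$i[r]] <- bo[bonds$i[r]] + o
    bo[bonds$j[r]] <- bo[bonds$j[r]] + o
  }
  expl_h <- elem %in% c("H", "D")
  v <- STANDARD_VALENCE[elem]
  nh <- pmax(0L, as.integer(round(ifelse(is.na(v), 0, v) - bo)))
  nh[expl_h] <- 0L
  # molecules carrying explicit hydrogens are taken at face value
  if (any(expl_h)) nh[] <- 0L
  nh
}

# ---- annotation ------------------------------------------------------------

#' Pharmacophore annotation points of a ligand conformer
#'
#' Applies the package's fixed, deterministic pattern set:
#' * aromatic: isolated rings whose bonds are all typed aromatic; one point
#'   at the ring centroid with the two ring normals as projection
#'   directions;
#' * donor: O or N bearing a hydrogen (explicit or implicit); projection
#'   directions along explicit X-H bonds, or isotropic (any direction) when
#'   hydrogens are implicit;
#' * acceptor: O, or N with a free lone pair (charge <= 0, coordination
#'   below 4); projection direction opposed to the mean bond vector;
#' * hydrophobic: connected fragments of three or more apolar carbons
#'   (non-aromatic C with only C/H neighbours); one point at the fragment
#'   centroid.
#'
#' @param mol a `ppi_mol` with 3D coordinates and explicit bond orders.
#' @return list of points, each `list(kind, pos, dirs, atom)`; `dirs` is a
#'   matrix of unit vectors or `NULL` for isotropic points.
#' @export
annotate_ligand <- function(mol) {
  check_valence(mol)
  pts <- list()
  el <- mol$atoms$elem
  xyz <- mol$coords
  nb <- neighbor_list(mol)
  arom_atoms <- integer()

  for (ring in aromatic_rings(mol)) {
    centroid <- colMeans(xyz[ring, , drop = FALSE])
    nrm <- plane_normal(xyz[ring, , drop = FALSE])
    pts[[length(pts) + 1]] <- list(kind = "aromatic", pos = centroid,
                                   dirs = rbind(nrm, -nrm), atom = ring)
    arom_atoms <- c(arom_atoms, ring)
  }

  for (i in seq_len(n_atoms(mol))) {
    if (!el[i] %in% c("N", "O")) next
    h_nbrs <- nb[[i]][el[nb[[i]]] == "H"]
    has_h <- length(h_nbrs) > 0 || mol$atoms$nh[i] > 0
    if (has_h) {
      dirs <- if (length(h_nbrs) > 0)
        t(apply(xyz[h_nbrs, , drop = FALSE], 1, function(h) unitv(h - xyz[i, ])))
      else NULL
      pts[[length(pts) + 1]] <- list(kind = "donor", pos = xyz[i, ],
                                     dirs = dirs, atom = i)
    }
    heavy_nbrs <- nb[[i]][!el[nb[[i]]] %in% c("H", "D")]
    coord_n <- length(nb[[i]]) + mol$atoms$nh[i]
    is_acceptor <- mol$atoms$charge[i] <= 0 &&
      (el[i] == "O" || (el[i] == "N" && coord_n < 4))
    if (is_acceptor) {
      dirs <- if (length(heavy_nbrs) > 0) {
        vsum <- colSums(matrix(apply(xyz[heavy_nbrs, , drop = FALSE], 1,
                                     function(p) unitv(xyz[i, ] - p)), ncol = 3, byrow = TRUE))
        if (vnorm(vsum) > 1e-8) matrix(unitv(vsum), 1) else NULL
      } else NULL
      pts[[length(pts) + 1]] <- list(kind = "acceptor", pos = xyz[i, ],
                                     dirs = dirs, atom = i)
    }
  }

  apolar <- which(el == "C" & !seq_along(el) %in% arom_atoms &
                    vapply(seq_along(el), function(i)
                      all(el[nb[[i]]] %in% c("C", "H")), logical(1)))
  if (length(apolar) > 0) {
    sub <- induced_components(mol, apolar)
    for (comp in sub) {
      if (length(comp) < 3) next
      pts[[length(pts) + 1]] <- list(kind = "hydrophobic",
                                     pos = colMeans(xyz[comp, , drop = FALSE]),
                                     dirs = NULL, atom = comp)
    }
  }
  pts
}

neighbor_list <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# Isolated aromatic rings: connected components of the aromatic-bond
# subgraph that form a single cycle (every vertex degree 2). Fused systems
# are outside the shipped pattern set.
aromatic_rings <- function(mol) {
  b <- mol$bonds[mol$bonds$order == 4L, , drop = FALSE]
  if (nrow(b) == 0) return(list())
  verts <- sort(unique(c(b$i, b$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(b$i, verts), to = match(b$j, verts)),
    directed = FALSE, vertices = data.frame(name = seq_along(verts)))
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::vcount(sub) >= 5 && igraph::vcount(sub) == igraph::ecount(sub) &&
        all(igraph::degree(sub) == 2))
      out[[length(out) + 1]] <- verts[vs]
  }
  out
}

induced_components <- function(mol, atoms) {
  b <- mol$bonds[mol$bonds$i %in% atoms & mol$bonds$j %in% atoms, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
  if (nrow(b) > 0)
    g <- igraph::add_edges(g, rbind(match(b$i, atoms), match(b$j, atoms)))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) atoms[comp$membership == ci])
}

# ---- stock constructors (used by tests and the synthetic generators) -------

ring_coords <- function(center = c(0, 0, 0), radius = 1.39,
                        normal = c(0, 0, 1), n = 6, phase = 0) {
  nrm <- unitv(normal)
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(pracma_cross(nrm, ref))
  e2 <- pracma_cross(nrm, e1)
  t(sapply(seq_len(n), function(k) {
    th <- phase + 2 * pi * (k - 1) / n
    center + radius * (cos(th) * e1 + sin(th) * e2)
  }))
}

#' Stock molecules
#'
#' Small reference molecules used in examples and tests: benzene, phenol
#' (implicit hydroxyl hydrogen), methane, n-butane and unbranched alkanes.
#' @name stock_molecules
#' @export
mol_benzene <- function(name = "benzene", center = c(0, 0, 0), normal = c(0, 0, 1)) {
  new_molecule(name, rep("C", 6), ring_coords(center, normal = normal),
               data.frame(i = 1:6, j = c(2:6, 1), order = 4L))
}

#' @rdname stock_molecules
#' @export
mol_phenol <- function(name = "phenol") {
  rc <- ring_coords()
  o <- rc[1, ] + 1.36 * unitv(rc[1, ])
  new_molecule(name, c(rep("C", 6), "O"), rbind(rc, o),
               data.frame(i = c(1:6, 1), j = c(2:6, 1, 7), order = c(rep(4L, 6), 1L)),
               nh = c(rep(0L, 6), 1L))
}

#' @rdname stock_molecules
#' @export
mol_methane <- function(name = "methane") {
  new_molecule(name, "C", matrix(0, 1, 3), nh = 4L)
}

#' @rdname stock_molecules
#' @export
mol_butane <- function(name = "butane") {
  # anti conformation, idealized sp3 geometry
  coords <- rbind(c(0, 0, 0), c(1.53, 0, 0),
                  c(2.04, 1.44, 0), c(3.57, 1.44, 0))
  new_molecule(name, rep("C", 4), coords,
               data.frame(i = 1:3, j = 2:4, order = 1L),
               nh = c(3L, 2L, 2L, 3L))
}

#' @rdname stock_molecules
#' @export
mol_alkane <- function(n, name = sprintf("alkane%d", n)) {
  stopifnot(n >= 1)
  coords <- t(sapply(seq_len(n), function(i)
    c(1.25 * (i - 1), 0.45 * (i %% 2), 0)))
  bonds <- if (n > 1) data.frame(i = seq_len(n - 1), j = 2:n, order = 1L)
  else NULL
  new_molecule(name, rep("C", n), coords, bonds,
               nh = if (n == 1) 4L else c(3L, rep(2L, max(0, n - 2)), 3L))
}

# rigid transform of a molecule (fresh copy)
transform_mol <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  mol$coords <- apply_rigid(mol$coords, R, t)
  mol
}
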