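# ligand_model: conformer enumeration. The algorithm under contract is
# scan -> minimize -> strain filter -> dedupe -> cap; the energy model is a
# pluggable minimizer so any force field honouring the contract can be
# dropped in. The shipped default is a transparent torsion-plus-sterics
# potential, not a published force field.

#' Non-ring rotatable bonds
#'
#' Single bonds outside rings whose endpoints both carry at least one other
#' heavy neighbour (terminal bonds cannot generate conformers).
#'
#' @param mol a `ppi_mol`
#' @return data.frame with columns `i`, `j`.
#' @export
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(data.frame(i = integer(), j = integer()))
  g <- mol_graph(mol, heavy_only = FALSE)
  bridges <- igraph::bridges(g)
  bridge_pairs <- if (length(bridges) > 0)
    apply(igraph::ends(g, bridges), 1, function(e) paste(sort(as.integer(e)), collapse = "-"))
  else character()
  el <- mol$atoms$elem
  nb <- neighbor_list(mol)
  heavy_deg <- vapply(nb, function(v) sum(!el[v] %in% c("H", "D")), integer(1))
  keep <- b$order == 1L &
    paste(pmin(b$i, b$j), pmax(b$i, b$j), sep = "-") %in% bridge_pairs &
    heavy_deg[b$i] >= 2 & heavy_deg[b$j] >= 2
  out <- b[keep, c("i", "j"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# atoms on the j-side of bond (i, j) once the bond is cut
moving_side <- function(mol, i, j) {
  nb <- neighbor_list(mol)
  seen <- rep(FALSE, n_atoms(mol))
  seen[i] <- TRUE
  stack <- j
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, nb[[v]][!seen[nb[[v]]]])
  }
  setdiff(which(seen), i)
}

# reference atoms a-i-j-b used to measure the torsion of bond (i, j)
torsion_refs <- function(mol, i, j) {
  nb <- neighbor_list(mol)
  el <- mol$atoms$elem
  pick <- function(center, excl) {
    cand <- setdiff(nb[[center]], excl)
    hv <- cand[!el[cand] %in% c("H", "D")]
    if (length(hv)) min(hv) else min(cand)
  }
  c(pick(i, j), i, j, pick(j, i))
}

get_torsion <- function(mol, coords, i, j) {
  r <- torsion_refs(mol, i, j)
  dihedral(coords[r[1], ], coords[r[2], ], coords[r[3], ], coords[r[4], ])
}

set_torsion <- function(mol, coords, i, j, angle) {
  cur <- get_torsion(mol, coords, i, j)
  delta <- angle - cur
  mv <- moving_side(mol, i, j)
  axis <- coords[j, ] - coords[i, ]
  R <- rotation_about_axis(axis, delta)
  pivot <- coords[i, ]
  coords[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2, pivot) %*% t(R), 2, -pivot)
  coords
}

# topological bond-count distances between heavy atoms
topo_dist <- function(mol) {
  g <- mol_graph(mol, heavy_only = FALSE)
  igraph::distances(g)
}

#' Shipped minimizers
#'
#' A minimizer is any `function(mol, coords, max_iter, grad_tol)` returning
#' `list(coords, energy, converged, niter)` with energies in kcal/mol.
#'
#' `torsion_minimizer()` builds the default: a transparent potential with a
#' one-fold plus three-fold cosine term per rotatable bond (minima at the
#' staggered torsions, anti below gauche) and a 12th-power steric repulsion
#' between atom pairs four or more bonds apart, minimized over the
#' rotatable torsions by BFGS.
#'
#' `harmonic_minimizer(ref)` builds a deterministic toy field, harmonic
#' about a fixed reference geometry; it exists to test the contract.
#'
#' @param v1,v3 torsion barrier heights, kcal/mol.
#' @param eps,r0 steric repulsion scale (kcal/mol) and radius (Angstrom).
#' @export
torsion_minimizer <- function(v1 = 0.8, v3 = 2.9, eps = 0.05, r0 = 3.0) {
  force(v1); force(v3); force(eps); force(r0)
  function(mol, coords, max_iter = 200, grad_tol = 0.001) {
    rb <- rotatable_bonds(mol)
    td <- topo_dist(mol)
    far <- which(td >= 4 & upper.tri(td), arr.ind = TRUE)
    energy_at <- function(crd) {
      e <- 0
      for (r in seq_len(nrow(rb))) {
        phi <- get_torsion(mol, crd, rb$i[r], rb$j[r]) * pi / 180
        e <- e + v1 / 2 * (1 + cos(phi)) + v3 / 2 * (1 + cos(3 * phi))
      }
      if (nrow(far) > 0) {
        d <- sqrt(rowSums((crd[far[, 1], , drop = FALSE] -
                             crd[far[, 2], , drop = FALSE])^2))
        e <- e + sum(eps * (r0 / pmax(d, 0.3))^12)
      }
      e
    }
    if (nrow(rb) == 0)
      return(list(coords = coords, energy = energy_at(coords),
                  converged = TRUE, niter = 0L))
    phi0 <- vapply(seq_len(nrow(rb)), function(r)
      get_torsion(mol, coords, rb$i[r], rb$j[r]), numeric(1))
    # grid points can land exactly on torsion maxima, which are stationary
    # (zero gradient) and would pin the optimizer; a small deterministic
    # offset rolls such starts downhill. The search runs in radians so the
    # gradient scale is O(1) for BFGS.
    phi0r <- (phi0 + 0.5) * pi / 180
    obj <- function(phir) {
      crd <- coords
      for (r in seq_len(nrow(rb)))
        crd <- set_torsion(mol, crd, rb$i[r], rb$j[r], phir[r] * 180 / pi)
      energy_at(crd)
    }
    opt <- stats::optim(phi0r, obj, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-12))
    crd <- coords
    for (r in seq_len(nrow(rb)))
      crd <- set_torsion(mol, crd, rb$i[r], rb$j[r], opt$par[r] * 180 / pi)
    gnorm <- max(abs(numeric_grad(obj, opt$par)))
    list(coords = crd, energy = opt$value,
         converged = opt$convergence == 0 && gnorm <= grad_tol,
         niter = as.integer(opt$counts[["function"]]))
  }
}

#' @rdname torsion_minimizer
#' @param ref reference n x 3 geometry of the harmonic well.
#' @param k force constant, kcal/mol/A^2.
#' @export
harmonic_minimizer <- function(ref, k = 5) {
  force(ref); force(k)
  function(mol, coords, max_iter = 200, grad_tol = 0.001) {
    list(coords = ref, energy = 0, converged = TRUE, niter = 1L)
  }
}

numeric_grad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Heavy-atom RMSD between two conformers of one molecule
#'
#' Best-superposition (optimal rotation and translation) RMSD over heavy
#' atoms, minimized over the molecule's graph automorphisms when
#' `symmetry = TRUE` so that atom-order-equivalent geometries compare as
#' duplicates.
#'
#' @param mol a `ppi_mol`
#' @param a,b n x 3 coordinate matrices for the same molecule.
#' @param superpose apply optimal rigid superposition first.
#' @param symmetry minimize over graph automorphisms.
#' @export
conf_rmsd <- function(mol, a, b, superpose = TRUE, symmetry = TRUE) {
  hv <- heavy_idx(mol)
  A <- a[hv, , drop = FALSE]
  B <- b[hv, , drop = FALSE]
  perms <- if (symmetry) mol_automorphisms(mol) else list(seq_along(hv))
  best <- Inf
  for (p in perms) {
    r <- if (superpose) rmsd_fit(A[p, , drop = FALSE], B)
    else rmsd_plain(A[p, , drop = FALSE], B)
    if (r < best) best <- r
  }
  best
}

#' Enumerate low-strain conformers
#'
#' Systematic torsion scan over the non-ring rotatable bonds in fixed
#' increments, each grid point energy-minimized with the supplied
#' minimizer, followed by a strain-energy window, symmetry-aware RMSD
#' duplicate removal (the lower-energy member of a duplicate pair is kept),
#' and an energy-ordered cap on the set size.
#'
#' @param mol a `ppi_mol` with an embeddable 3D geometry.
#' @param torsion_increment scan increment in degrees (default 60).
#' @param max_conf maximum conformers retained (default 250).
#' @param strain_window strain cutoff relative to the set minimum, kcal/mol
#'   (default 4).
#' @param dedupe_rmsd duplicate threshold, heavy-atom best-fit RMSD in
#'   Angstrom (default 0.15).
#' @param minimizer a minimizer honouring the contract of
#'   [torsion_minimizer()].
#' @param max_iter,grad_tol minimizer termination settings (defaults 200
#'   iterations, 0.001 gradient).
#' @return a `conformer_set`: list with `mol`, `coords` (list of matrices),
#'   `energy`, `strain` (kcal/mol, >= 0).
#' @export
enumerate_conformers <- function(mol, torsion_increment = 60, max_conf = 250,
                                 strain_window = 4, dedupe_rmsd = 0.15,
                                 minimizer = torsion_minimizer(),
                                 max_iter = 200, grad_tol = 0.001) {
  stopifnot(torsion_increment > 0, max_conf >= 1)
  if (!all(is.finite(mol$coords))) stop("molecule has no embeddable 3D geometry")
  rb <- rotatable_bonds(mol)
  if (nrow(rb) == 0) {
    m <- minimizer(mol, mol$coords, max_iter, grad_tol)
    return(structure(list(mol = mol, coords = list(m$coords),
                          energy = m$energy, strain = 0),
                     class = "conformer_set"))
  }
  angles <- seq(0, 360 - torsion_increment, by = torsion_increment)
  grid <- as.matrix(expand.grid(rep(list(angles), nrow(rb))))
  if (nrow(grid) > 20000)
    stop("torsion grid too large (", nrow(grid), " points); increase the increment")
  base <- vapply(seq_len(nrow(rb)), function(r)
    get_torsion(mol, mol$coords, rb$i[r], rb$j[r]), numeric(1))
  cands <- vector("list", nrow(grid))
  energies <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    crd <- mol$coords
    for (r in seq_len(nrow(rb)))
      crd <- set_torsion(mol, crd, rb$i[r], rb$j[r], base[r] + grid[gidx, r])
    m <- minimizer(mol, crd, max_iter, grad_tol)
    cands[[gidx]] <- m$coords
    energies[gidx] <- m$energy
  }
  strain <- energies - min(energies)
  keep <- which(strain <= strain_window)
  keep <- keep[order(energies[keep])]
  sel <- integer()
  for (gidx in keep) {
    dup <- FALSE
    for (s in sel) {
      if (conf_rmsd(mol, cands[[gidx]], cands[[s]]) < dedupe_rmsd) {
        dup <- TRUE
        break
      }
    }
    if (!dup) sel <- c(sel, gidx)
    if (length(sel) >= max_conf) break
  }
  structure(list(mol = mol, coords = cands[sel], energy = energies[sel],
                 strain = energies[sel] - min(energies)),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("conformer_set:", length(x$coords), "conformer(s) of", x$mol$name,
      "| strain range", sprintf("%.2f-%.2f kcal/mol", min(x$strain), max(x$strain)), "\n")
  invisible(x)
}

#' Write a conformer set as SDF with strain tags
#' @param cs a `conformer_set`
#' @param file output path
#' @export
write_conformers_sdf <- function(cs, file) {
  mols <- lapply(seq_along(cs$coords), function(i) {
    m <- cs$mol
    m$coords <- cs$coords[[i]]
    m$name <- sprintf("%s_conf%d", m$name, i)
    m
  })
  write_sdf(mols, file, tags = list(strain = sprintf("%.4f", cs$strain)))
}
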