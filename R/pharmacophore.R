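# pharmacophore: protein-based hypothesis construction from an anchor
# peptide, and matching of ligand conformers in aligned or absolute mode.
#
# Feature semantics follow query-sphere conventions: a ligand point matches
# a feature iff its distance to the feature center is at most the feature
# radius (not a sum of radii); directional satisfaction uses projected
# points at a fixed projection length from the source atom.

PH_PROJ_LEN <- 3.0   # Angstrom, projected-point distance for donors/acceptors/normals

RING_ATOMS <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

SC_DONOR_ATOMS <- list(
  TYR = "OH", SER = "OG", THR = "OG1", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1", ASN = "ND2",
  GLN = "NE2", HIS = c("ND1", "NE2")
)

# anchor-side carbonyl-type acceptors: atom -> axis parent
SC_ACCEPTOR_ATOMS <- list(
  ASN = c(OD1 = "CG"), GLN = c(OE1 = "CD"),
  ASP = c(OD1 = "CG", OD2 = "CG"), GLU = c(OE1 = "CD", OE2 = "CD")
)

HYDROXYL_NAMES <- c("OG", "OG1", "OH")

new_feature <- function(kind, center, radius, proj, proj_radius, essential,
                        source, partner) {
  list(kind = kind, center = as.numeric(center), radius = radius,
       proj = if (is.null(proj)) NULL else as.numeric(proj),
       proj_radius = proj_radius, essential = essential,
       source = source, partner = partner)
}

#' Build a protein-based pharmacophore hypothesis from an anchor peptide
#'
#' For each anchor residue the builder emits:
#' * an aromatic feature at each ring centroid, with a normal projection
#'   pointing toward the nearer receptor side;
#' * a donor feature for each N-H or O-H group that has a receptor acceptor
#'   heavy atom within `hbond_cutoff` (backbone N-H directions are checked
#'   against a `donor_cone` half-angle; hydroxyl and amine donors are
#'   orientation-free), projected at the acceptor position;
#' * an acceptor feature for each carbonyl-type oxygen with a receptor
#'   donor inside `hbond_cutoff` and within `acceptor_cone` of the C=O
#'   axis, projected at the donor position.
#'
#' Excluded volumes are one sphere per receptor heavy atom within
#' `exclusion_cutoff` of any anchor atom. Features sourced from
#' `essential_residues` are flagged essential and must all be matched.
#'
#' @param structure a `ppi_structure`
#' @param anchor anchor-peptide `ppi_selection`
#' @param receptor optional receptor `ppi_selection`; defaults to every
#'   non-anchor protein atom.
#' @param exclusion_cutoff Angstrom (default 4, the excluded-volume radius
#'   around the anchor).
#' @param essential_residues residue numbers (anchor chain) whose features
#'   are essential.
#' @param feature_radius,proj_radius query tolerances in Angstrom
#'   (defaults 1.0 and 1.4).
#' @param hbond_cutoff donor/acceptor partner search distance (default 3.5).
#' @param exclusion_radius radius of each excluded-volume sphere (default 1.0).
#' @param min_match minimum number of matched features (default 3).
#' @param donor_cone,acceptor_cone directional half-angles in degrees.
#' @return a `pharmacophore` object.
#' @export
build_hypothesis <- function(structure, anchor, receptor = NULL,
                             exclusion_cutoff = 4.0, essential_residues = integer(),
                             feature_radius = 1.0, proj_radius = 1.4,
                             hbond_cutoff = 3.5, exclusion_radius = 1.0,
                             min_match = 3, donor_cone = 70, acceptor_cone = 90) {
  check_selection(structure, anchor)
  anc <- selection_atoms(structure, anchor)
  rec <- if (is.null(receptor)) {
    a <- structure$atoms
    a[!(a$chain == anchor$chain & a$resno %in% anchor$resnos) & !a$het, , drop = FALSE]
  } else selection_atoms(structure, receptor)
  rec <- rec[!rec$elem %in% c("H", "D"), , drop = FALSE]
  if (nrow(rec) == 0) stop("receptor selection is empty")
  recxyz <- as.matrix(rec[, c("x", "y", "z")])
  rec_acc <- which(rec$elem == "O" | (rec$elem == "N" & !rec$name %in% "N"))
  rec_don <- which((rec$elem == "N" & !(rec$name == "N" & rec$resname == "PRO")) |
                     (rec$elem == "O" & rec$name %in% HYDROXYL_NAMES))

  feats <- list()
  add <- function(f) feats[[length(feats) + 1]] <<- f

  for (rn in anchor$resnos) {
    res <- anc[anc$resno == rn, , drop = FALSE]
    if (nrow(res) == 0) next
    resname <- res$resname[1]
    src <- function(atom) sprintf("%s%d:%s", resname, rn, atom)
    ess <- rn %in% essential_residues
    atom_xyz <- function(nm) {
      r <- res[res$name == nm, , drop = FALSE]
      if (nrow(r) == 0) NULL else as.numeric(r[1, c("x", "y", "z")])
    }

    # aromatic ring centroid + normal projection toward the receptor
    ring_names <- RING_ATOMS[[resname]]
    if (!is.null(ring_names)) {
      rxyz <- as.matrix(res[res$name %in% ring_names, c("x", "y", "z"), drop = FALSE])
      if (nrow(rxyz) >= 5) {
        centroid <- colMeans(rxyz)
        nrm <- plane_normal(rxyz)
        d_plus <- min(cdist(matrix(centroid + PH_PROJ_LEN * nrm, 1), recxyz))
        d_minus <- min(cdist(matrix(centroid - PH_PROJ_LEN * nrm, 1), recxyz))
        if (d_minus < d_plus) nrm <- -nrm
        proj <- centroid + PH_PROJ_LEN * nrm
        near <- nearest_residues(rec, recxyz, proj, radius = 4.0, k = 3)
        add(new_feature("aromatic", centroid, feature_radius, proj, proj_radius,
                        ess, src("ring"), paste(near, collapse = "/")))
      }
    }

    # donors: backbone N-H (directional) and side-chain O-H / N-H (isotropic)
    don_defs <- list()
    if (resname != "PRO") {
      nxyz <- atom_xyz("N")
      if (!is.null(nxyz))
        don_defs[[length(don_defs) + 1]] <- list(atom = "N", pos = nxyz,
                                                 dir = backbone_nh_dir(anc, anchor$chain, rn))
    }
    for (nm in SC_DONOR_ATOMS[[resname]]) {
      p <- atom_xyz(nm)
      if (!is.null(p))
        don_defs[[length(don_defs) + 1]] <- list(atom = nm, pos = p, dir = NULL)
    }
    for (dd in don_defs) {
      cand <- polar_partners(dd$pos, recxyz, rec_acc, hbond_cutoff,
                             dir = dd$dir, cone = donor_cone)
      if (length(cand) == 0) next
      best <- cand[1]
      add(new_feature("donor", dd$pos, feature_radius,
                      recxyz[best, ], proj_radius, ess, src(dd$atom),
                      sprintf("%s%d", rec$resname[best], rec$resno[best])))
    }

    # acceptors: carbonyl-type oxygens with a receptor donor in the C=O fan
    acc_defs <- list()
    oxyz <- atom_xyz("O")
    cxyz <- atom_xyz("C")
    if (!is.null(oxyz))
      acc_defs[[length(acc_defs) + 1]] <-
        list(atom = "O", pos = oxyz,
             axis = if (is.null(cxyz)) NULL else unitv(oxyz - cxyz))
    sca <- SC_ACCEPTOR_ATOMS[[resname]]
    for (nm in names(sca)) {
      p <- atom_xyz(nm)
      parent <- atom_xyz(sca[[nm]])
      if (!is.null(p))
        acc_defs[[length(acc_defs) + 1]] <-
          list(atom = nm, pos = p,
               axis = if (is.null(parent)) NULL else unitv(p - parent))
    }
    for (ad in acc_defs) {
      cand <- polar_partners(ad$pos, recxyz, rec_don, hbond_cutoff,
                             dir = ad$axis, cone = acceptor_cone)
      if (length(cand) == 0) next
      best <- cand[1]
      add(new_feature("acceptor", ad$pos, feature_radius,
                      recxyz[best, ], proj_radius, ess, src(ad$atom),
                      sprintf("%s%d", rec$resname[best], rec$resno[best])))
    }
  }

  if (length(feats) == 0)
    stop("anchor has no annotatable group with a receptor partner: empty hypothesis")
  if (length(essential_residues) > 0 &&
      !any(vapply(feats, `[[`, logical(1), "essential")))
    stop("no feature arises from the requested essential residues")

  ancxyz <- as.matrix(anc[!anc$elem %in% c("H", "D"), c("x", "y", "z"), drop = FALSE])
  D <- cdist(recxyz, ancxyz)
  excl_idx <- which(apply(D, 1, min) <= exclusion_cutoff)
  exclusions <- data.frame(x = recxyz[excl_idx, 1], y = recxyz[excl_idx, 2],
                           z = recxyz[excl_idx, 3], r = exclusion_radius)
  rownames(exclusions) <- NULL
  structure(list(features = feats, exclusions = exclusions,
                 min_match = min_match, proj_len = PH_PROJ_LEN),
            class = "pharmacophore")
}

# Candidate polar partners sorted by distance; directional when dir given.
polar_partners <- function(pos, recxyz, idx, cutoff, dir = NULL, cone = 90) {
  if (length(idx) == 0) return(integer())
  d <- as.vector(cdist(matrix(pos, 1), recxyz[idx, , drop = FALSE]))
  ok <- d <= cutoff & d > 0.1
  if (!is.null(dir)) {
    cosang <- vapply(seq_along(idx), function(k) {
      v <- recxyz[idx[k], ] - pos
      sum(unitv(v) * dir)
    }, numeric(1))
    ok <- ok & cosang >= cos(cone * pi / 180)
  }
  idx[ok][order(d[ok])]
}

# Backbone amide N-H direction: opposite the bisector of N->CA and N->C(prev).
# NULL (isotropic) at a selection N-terminus.
backbone_nh_dir <- function(anc, chain, rn) {
  res <- anc[anc$resno == rn, , drop = FALSE]
  prev <- anc[anc$resno == rn - 1 & anc$name == "C", , drop = FALSE]
  n <- res[res$name == "N", , drop = FALSE]
  ca <- res[res$name == "CA", , drop = FALSE]
  if (nrow(prev) == 0 || nrow(n) == 0 || nrow(ca) == 0) return(NULL)
  np <- as.numeric(n[1, c("x", "y", "z")])
  v <- unitv(as.numeric(ca[1, c("x", "y", "z")]) - np) +
    unitv(as.numeric(prev[1, c("x", "y", "z")]) - np)
  if (vnorm(v) < 1e-8) return(NULL)
  -unitv(v)
}

nearest_residues <- function(rec, recxyz, point, radius = 4.5, k = 3) {
  d <- as.vector(cdist(matrix(point, 1), recxyz))
  ord <- order(d)
  ord <- ord[d[ord] <= radius]
  labs <- unique(sprintf("%s%d", rec$resname[ord], rec$resno[ord]))
  utils::head(labs, k)
}

#' Number of pharmacophore points (features plus projections)
#' @param hyp a `pharmacophore`
#' @export
ph_n_points <- function(hyp) {
  length(hyp$features) +
    sum(vapply(hyp$features, function(f) !is.null(f$proj), logical(1)))
}

#' @export
print.pharmacophore <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, character(1), "kind")
  cat("pharmacophore:", length(x$features), "features /", ph_n_points(x),
      "points (", paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
                        collapse = ", "), ")\n")
  cat("  essential:", sum(vapply(x$features, `[[`, logical(1), "essential")),
      "| exclusion spheres:", nrow(x$exclusions),
      "| min_match:", x$min_match, "\n")
  for (f in x$features)
    cat(sprintf("  - %-10s %s -> %s%s\n", f$kind, f$source, f$partner,
                if (f$essential) " [essential]" else ""))
  invisible(x)
}

#' Ligand-point view of a hypothesis (for self-matching and diagnostics)
#'
#' Each feature becomes a point at its center whose projection direction is
#' the unit vector toward the feature's projection.
#' @param hyp a `pharmacophore`
#' @export
hypothesis_points <- function(hyp) {
  lapply(hyp$features, function(f) {
    dirs <- if (!is.null(f$proj)) matrix(unitv(f$proj - f$center), 1) else NULL
    list(kind = f$kind, pos = f$center, dirs = dirs, atom = NA)
  })
}

# ---- matching --------------------------------------------------------------

kind_compatible <- function(feature_kind, point_kind) {
  feature_kind == point_kind ||
    (feature_kind == "hydrophobic" && point_kind == "aromatic")
}

# Is feature f's projection satisfied by point p (already transformed)?
proj_satisfied <- function(f, p, proj_len) {
  if (is.null(f$proj)) return(TRUE)
  if (is.null(p$dirs)) {
    # orientation-free point: its reachable projected points form the sphere
    # of radius proj_len around the point position
    d <- vnorm(p$pos - f$proj)
    return(abs(d - proj_len) <= f$proj_radius)
  }
  for (r in seq_len(nrow(p$dirs))) {
    projected <- p$pos + proj_len * p$dirs[r, ]
    if (vnorm(projected - f$proj) <= f$proj_radius) return(TRUE)
  }
  FALSE
}

transform_points <- function(points, R, t) {
  lapply(points, function(p) {
    p$pos <- as.vector(R %*% p$pos + t)
    if (!is.null(p$dirs)) p$dirs <- p$dirs %*% t(R)
    p
  })
}

violates_exclusions <- function(hyp, xyz) {
  if (nrow(hyp$exclusions) == 0 || nrow(xyz) == 0) return(FALSE)
  D <- cdist(xyz, as.matrix(hyp$exclusions[, c("x", "y", "z")]))
  any(sweep(D, 2, hyp$exclusions$r, "-") < 0)
}

# candidate matrix: cand[[fi]] = point indices usable for feature fi
match_candidates <- function(hyp, points) {
  lapply(hyp$features, function(f) {
    ok <- vapply(seq_along(points), function(pi) {
      p <- points[[pi]]
      kind_compatible(f$kind, p$kind) &&
        vnorm(p$pos - f$center) <= f$radius &&
        proj_satisfied(f, p, hyp$proj_len)
    }, logical(1))
    which(ok)
  })
}

# Branch-and-bound assignment: maximize matched features with all essential
# features forced; ties broken by lowest feature RMSD.
assign_features <- function(hyp, points, min_match, node_cap = 1e5) {
  nf <- length(hyp$features)
  cand <- match_candidates(hyp, points)
  essential <- vapply(hyp$features, `[[`, logical(1), "essential")
  if (any(essential & vapply(cand, length, integer(1)) == 0))
    return(NULL)
  ord <- order(!essential, vapply(cand, length, integer(1)))
  best <- NULL
  nodes <- 0L
  sqd <- function(fi, pi) sum((points[[pi]]$pos - hyp$features[[fi]]$center)^2)
  rec <- function(k, used, pairs, acc_sq) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) return()
    if (k > nf) {
      n <- nrow(pairs)
      if (n == 0) return()
      rmsd <- sqrt(acc_sq / n)
      if (is.null(best) || n > best$n || (n == best$n && rmsd < best$rmsd))
        best <<- list(n = n, rmsd = rmsd, pairs = pairs)
      return()
    }
    remaining <- nf - k + 1
    if (!is.null(best) && nrow(pairs) + remaining < best$n) return()
    fi <- ord[k]
    for (pi in cand[[fi]]) {
      if (used[pi]) next
      used[pi] <- TRUE
      rec(k + 1, used, rbind(pairs, c(fi, pi)), acc_sq + sqd(fi, pi))
      used[pi] <- FALSE
    }
    if (!essential[fi]) rec(k + 1, used, pairs, acc_sq)
  }
  rec(1, rep(FALSE, length(points)), matrix(integer(), 0, 2), 0)
  if (is.null(best) || best$n < min_match || is.null(best$pairs)) return(NULL)
  if (!all(which(essential) %in% best$pairs[, 1])) return(NULL)
  best
}

empty_match <- function() {
  list(matched = FALSE, n_matched = 0L, correspondence = NULL,
       transform = list(R = diag(3), t = c(0, 0, 0)), feature_rmsd = NA_real_)
}

#' Match a ligand conformer against a pharmacophore hypothesis
#'
#' In `absolute` mode the conformer is tested in place (no rotation or
#' translation), as used for post-docking refiltering of poses that already
#' share the receptor frame. In `align` mode rigid superpositions seeded by
#' triplets of compatible feature/point pairs are searched.
#'
#' A conformer matches iff all essential features are in the
#' correspondence, at least `min_match` features are matched, every matched
#' ligand point lies within its feature's radius, every matched feature's
#' projection is satisfied within the projection radius, and no ligand
#' heavy atom falls inside an exclusion sphere.
#'
#' @param hyp a `pharmacophore`
#' @param conformer a `ppi_mol` (annotated internally), or a point list as
#'   returned by [annotate_ligand()]/[hypothesis_points()].
#' @param mode `"align"` or `"absolute"`.
#' @param min_match override of the hypothesis minimum match count.
#' @param node_cap correspondence-search budget per conformer; when the
#'   budget is exhausted the search degrades to the best correspondence
#'   found so far.
#' @return a match result: list with `matched`, `n_matched`,
#'   `correspondence` (feature/point index pairs), `transform` (identity in
#'   absolute mode), `feature_rmsd`.
#' @export
ph_match <- function(hyp, conformer, mode = c("align", "absolute"),
                     min_match = NULL, node_cap = 1e5) {
  mode <- match.arg(mode)
  if (length(hyp$features) == 0) stop("empty hypothesis")
  if (is.null(min_match)) min_match <- hyp$min_match
  if (inherits(conformer, "ppi_mol")) {
    points <- annotate_ligand(conformer)
    lig_xyz <- conformer$coords[heavy_idx(conformer), , drop = FALSE]
  } else {
    points <- conformer
    lig_xyz <- do.call(rbind, lapply(points, `[[`, "pos"))
  }
  if (length(points) == 0) return(empty_match())

  try_transform <- function(R, t) {
    tp <- transform_points(points, R, t)
    txyz <- sweep(lig_xyz %*% t(R), 2, -t)
    if (violates_exclusions(hyp, txyz)) return(NULL)
    a <- assign_features(hyp, tp, min_match, node_cap)
    if (is.null(a)) return(NULL)
    list(matched = TRUE, n_matched = a$n,
         correspondence = data.frame(feature = a$pairs[, 1], point = a$pairs[, 2]),
         transform = list(R = R, t = t), feature_rmsd = a$rmsd)
  }

  if (mode == "absolute") {
    res <- try_transform(diag(3), c(0, 0, 0))
    return(if (is.null(res)) empty_match() else res)
  }

  # align mode: triplet seeding, essential-first
  nf <- length(hyp$features)
  np <- length(points)
  pair_ok <- matrix(FALSE, nf, np)
  for (fi in seq_len(nf))
    for (pi in seq_len(np))
      pair_ok[fi, pi] <- kind_compatible(hyp$features[[fi]]$kind, points[[pi]]$kind)
  fcent <- do.call(rbind, lapply(hyp$features, `[[`, "center"))
  ppos <- do.call(rbind, lapply(points, `[[`, "pos"))
  essential <- which(vapply(hyp$features, `[[`, logical(1), "essential"))
  ftrip <- utils::combn(nf, min(3, nf), simplify = FALSE)
  ftrip <- ftrip[order(-vapply(ftrip, function(tr) sum(tr %in% essential), numeric(1)))]
  best <- NULL
  seeds_tried <- 0L
  for (tr in ftrip) {
    if (length(tr) < 3) break
    cands <- lapply(tr, function(fi) which(pair_ok[fi, ]))
    if (any(vapply(cands, length, integer(1)) == 0)) next
    for (p1 in cands[[1]]) for (p2 in cands[[2]]) for (p3 in cands[[3]]) {
      ps <- c(p1, p2, p3)
      if (anyDuplicated(ps)) next
      ok <- TRUE
      for (u in 1:2) for (v in (u + 1):3) {
        df <- vnorm(fcent[tr[u], ] - fcent[tr[v], ])
        dp <- vnorm(ppos[ps[u], ] - ppos[ps[v], ])
        if (abs(df - dp) > hyp$features[[tr[u]]]$radius + hyp$features[[tr[v]]]$radius) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      seeds_tried <- seeds_tried + 1L
      if (seeds_tried > node_cap) break
      kb <- kabsch(ppos[ps, , drop = FALSE], fcent[tr, , drop = FALSE])
      res <- try_transform(kb$R, kb$t)
      if (!is.null(res) &&
          (is.null(best) || res$n_matched > best$n_matched ||
           (res$n_matched == best$n_matched && res$feature_rmsd < best$feature_rmsd)))
        best <- res
    }
    if (seeds_tried > node_cap) break
  }
  if (is.null(best)) empty_match() else best
}

# ---- serialization ---------------------------------------------------------

#' Serialize / restore a hypothesis as versioned JSON (units: Angstrom)
#' @param hyp a `pharmacophore`
#' @param file path
#' @export
ph_write_json <- function(hyp, file) {
  obj <- list(
    format = "ppiscreen-pharmacophore",
    version = 1L,
    units = "angstrom",
    proj_len = hyp$proj_len,
    min_match = hyp$min_match,
    features = lapply(hyp$features, function(f) {
      f["proj"] <- list(f$proj)  # keep NULL
      f
    }),
    exclusions = hyp$exclusions
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname ph_write_json
#' @export
ph_read_json <- function(file) {
  if (!file.exists(file)) stop("no such hypothesis file: ", file)
  obj <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "ppiscreen-pharmacophore"))
    stop("not a ppiscreen pharmacophore file")
  feats <- lapply(seq_len(nrow(obj$features)), function(i) {
    row <- obj$features[i, ]
    new_feature(row$kind, unlist(row$center), row$radius,
                if (all(is.na(unlist(row$proj)))) NULL else unlist(row$proj),
                row$proj_radius, row$essential, row$source, row$partner)
  })
  excl <- as.data.frame(obj$exclusions)
  if (nrow(excl) == 0) excl <- data.frame(x = numeric(), y = numeric(),
                                          z = numeric(), r = numeric())
  structure(list(features = feats, exclusions = excl,
                 min_match = obj$min_match, proj_len = obj$proj_len),
            class = "pharmacophore")
}
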