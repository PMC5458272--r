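# synthetic_data: generators for every fixture the cascade needs -- a toy
# receptor-peptide complex, active/decoy ligand libraries, mock docking
# engine output, and noisy sensorgram bundles. All generators are pure
# functions of (spec, seed) and write fixed-format text, so fixture bytes
# are stable across runs. Ground-truth labels are always returned beside
# the fixtures so downstream tests never re-derive truth from the pipeline
# under test.
#
# The default toy complex is a SYNTHETIC geometric stand-in for the
# Aurora-A/TPX2-7-11 interface: a five-residue SYSYD anchor peptide in an
# idealized extended conformation, with receptor partner atoms placed (with
# the published author numbering: Val 206, Glu 170, Leu 178, Val 182,
# Tyr 199, Glu 183) so that the documented interface contacts hold
# geometrically. It is a geometric construct, not a crystal structure:
# internal stereochemistry of the receptor side chains is not modelled.

#' Toy receptor-peptide complex specification
#'
#' @param anchor_seq one-letter anchor sequence, 3-6 residues over
#'   A/G/S/Y/F/D, at least two aromatic (Y/F).
#' @param start_resno author-style residue number of the first anchor
#'   residue (default 7).
#' @param chain_anchor,chain_receptor chain identifiers.
#' @param contacts declared interface contacts: data.frame with columns
#'   `resno`, `type` (aromatic / donor_bb / donor_sc / acceptor_bb),
#'   `partner_resname`, `partner_resno`. Defaults to the Aurora-A/TPX2
#'   analog contact map.
#' @param jitter coordinate noise sd in Angstrom (default 0 = byte-stable
#'   output).
#' @param seed RNG seed used when `jitter > 0`.
#' @export
toy_complex_spec <- function(anchor_seq = "SYSYD", start_resno = 7,
                             chain_anchor = "T", chain_receptor = "A",
                             contacts = default_toy_contacts(),
                             jitter = 0, seed = 1) {
  list(anchor_seq = toupper(anchor_seq), start_resno = start_resno,
       chain_anchor = chain_anchor, chain_receptor = chain_receptor,
       contacts = contacts, jitter = jitter, seed = seed)
}

#' @rdname toy_complex_spec
#' @export
default_toy_contacts <- function() {
  data.frame(
    resno = c(8, 8, 10, 10, 10, 10, 11, 8),
    type = c("aromatic", "donor_sc", "aromatic", "aromatic", "aromatic",
             "donor_bb", "donor_bb", "acceptor_bb"),
    partner_resname = c("VAL", "GLU", "LEU", "VAL", "TYR", "TYR", "GLU", "TYR"),
    partner_resno = c(206, 170, 178, 182, 199, 199, 183, 199),
    stringsAsFactors = FALSE
  )
}

AA1TO3 <- c(A = "ALA", G = "GLY", S = "SER", Y = "TYR", F = "PHE", D = "ASP")

# receptor atom names by role and residue type
PARTNER_ACCEPTOR_ATOM <- c(GLU = "OE1", ASP = "OD1", ASN = "OD1", GLN = "OE1",
                           TYR = "OH", SER = "OG", THR = "OG1")
PARTNER_DONOR_ATOM <- c(TYR = "OH", SER = "OG", THR = "OG1", LYS = "NZ",
                        ARG = "NE", ASN = "ND2", GLN = "NE2")
GROOVE_ATOM <- c(LEU = "CD1", VAL = "CG1", ILE = "CD1", TYR = "CD1",
                 PHE = "CD1", ALA = "CB")

#' Generate a toy receptor-peptide complex
#'
#' Builds the anchor peptide in an idealized extended conformation along x
#' (backbone in the z = 0 plane, aromatic side chains reaching down into
#' the receptor groove at negative z) and places receptor partner atoms to
#' realize every declared contact: hydrophobic probes under each aromatic
#' ring, hydrogen-bond acceptors along declared donor directions, donors in
#' the carbonyl fan of declared acceptors. A receptor hydroxyl shared
#' between a backbone-donor and a backbone-acceptor contact (the Tyr 199
#' arrangement) is placed once, midway.
#'
#' The generated geometry is validated: every declared contact must
#' satisfy the hydrogen-bond distance/cone rules, and no undeclared polar
#' pairing may arise. Specs that cannot host their declared contacts error
#' out.
#'
#' @param spec a [toy_complex_spec()].
#' @return list: `structure` (a `ppi_structure`, re-read from the emitted
#'   text), `pdb` (PDB lines), `anchor` / `receptor` selections, and
#'   `declared` bookkeeping (atom count, expected feature count and
#'   kind/partner table, essential aromatic residues).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  seq1 <- strsplit(spec$anchor_seq, "")[[1]]
  n <- length(seq1)
  if (n < 3 || n > 6) stop("anchor sequence must have 3-6 residues")
  if (!all(seq1 %in% names(AA1TO3)))
    stop("anchor residues must be among ", paste(names(AA1TO3), collapse = ""))
  if (sum(seq1 %in% c("Y", "F")) < 2)
    stop("anchor must contain at least two aromatic residues")
  resnos <- spec$start_resno + seq_len(n) - 1
  ct <- spec$contacts
  if (!all(ct$resno %in% resnos)) stop("contact resno outside the anchor")

  nh_side <- stats::setNames(rep(1, n), resnos)
  o_side <- stats::setNames(rep(1, n), resnos)
  oh_dir <- stats::setNames(rep(1, n), resnos)
  for (r in seq_len(nrow(ct))) {
    rn <- as.character(ct$resno[r])
    if (ct$type[r] == "donor_bb") nh_side[rn] <- -1
    if (ct$type[r] == "acceptor_bb") o_side[rn] <- -1
    if (ct$type[r] == "donor_sc") oh_dir[rn] <- -1
  }

  atoms <- list()
  addat <- function(name, elem, resname, chain, resno, xyz, het = FALSE) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      serial = 0L, name = name, elem = elem, resname = resname, chain = chain,
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
      alt = "", het = het, stringsAsFactors = FALSE)
  }

  # ---- anchor peptide -----------------------------------------------------
  ring_centroids <- list()
  hydroxyls <- list()
  for (k in seq_len(n)) {
    rn <- resnos[k]
    key <- as.character(rn)
    res3 <- AA1TO3[[seq1[k]]]
    x0 <- 3.6 * (k - 1)
    N <- c(x0, 0, 0)
    CA <- c(x0 + 1.25, -nh_side[key] * 0.85, 0)
    C <- c(x0 + 2.45, 0, 0)
    O <- c(x0 + 2.45, o_side[key] * 1.23, 0)
    ch <- spec$chain_anchor
    addat("N", "N", res3, ch, rn, N)
    addat("CA", "C", res3, ch, rn, CA)
    addat("C", "C", res3, ch, rn, C)
    addat("O", "O", res3, ch, rn, O)
    if (res3 == "ALA") addat("CB", "C", res3, ch, rn, CA + c(0, 0, 1.5))
    if (res3 == "SER") {
      # hydroxyl tilted away from the interface plane so it stays unpaired
      addat("CB", "C", res3, ch, rn, CA + c(0, 0.5, 1.5))
      addat("OG", "O", res3, ch, rn, CA + c(0, 1.0, 2.6))
    }
    if (res3 == "ASP") {
      addat("CB", "C", res3, ch, rn, CA + c(0, 0, 1.5))
      CG <- CA + c(0, 0, 2.9)
      addat("CG", "C", res3, ch, rn, CG)
      addat("OD1", "O", res3, ch, rn, CG + c(-1.05, 0, 0.7))
      addat("OD2", "O", res3, ch, rn, CG + c(1.05, 0, 0.7))
    }
    if (res3 %in% c("TYR", "PHE")) {
      addat("CB", "C", res3, ch, rn, CA + c(0, 0, -1.5))
      cen <- c(CA[1], CA[2], -4.3)
      ring_centroids[[key]] <- cen
      a <- c(0, oh_dir[key], 0)   # para axis: CZ/OH direction
      b <- c(1, 0, 0)
      ang <- c(CG = 180, CD1 = 120, CE1 = 60, CZ = 0, CE2 = -60, CD2 = -120) * pi / 180
      for (nm in names(ang))
        addat(nm, "C", res3, ch, rn, cen + 1.39 * (cos(ang[[nm]]) * a + sin(ang[[nm]]) * b))
      if (res3 == "TYR") {
        oh <- cen + 2.75 * a
        addat("OH", "O", res3, ch, rn, oh)
        hydroxyls[[key]] <- list(pos = oh, ca = CA)
      }
    }
  }

  anchor_df <- do.call(rbind, atoms)

  # ---- receptor partners --------------------------------------------------
  bb_N <- function(rn) c(3.6 * (match(rn, resnos) - 1), 0, 0)
  bb_C <- function(rn) c(3.6 * (match(rn, resnos) - 1) + 2.45, 0, 0)
  bb_O <- function(rn) bb_C(rn) + c(0, o_side[as.character(rn)] * 1.23, 0)
  nh_dir_of <- function(rn) {
    d <- backbone_nh_dir(anchor_df, spec$chain_anchor, rn)
    if (is.null(d)) c(0, nh_side[as.character(rn)], 0) else d
  }

  rec <- list()  # per receptor residue: named list of atom positions
  put <- function(resname, resno, atom, pos) {
    key <- paste(resname, resno)
    if (is.null(rec[[key]])) rec[[key]] <<- list(resname = resname, resno = resno)
    if (!is.null(rec[[key]][[atom]]))
      stop("receptor atom placed twice: ", key, " ", atom)
    rec[[key]][[atom]] <<- pos
  }

  # shared hydroxyl: a partner residue appearing in both a donor_bb and an
  # acceptor_bb contact donates to the anchor carbonyl and accepts from the
  # anchor amide with a single O-H group
  pkey <- paste(ct$partner_resname, ct$partner_resno)
  shared <- intersect(pkey[ct$type == "donor_bb"], pkey[ct$type == "acceptor_bb"])
  handled <- rep(FALSE, nrow(ct))
  for (sk in shared) {
    di <- which(pkey == sk & ct$type == "donor_bb")[1]
    ai <- which(pkey == sk & ct$type == "acceptor_bb")[1]
    rn_d <- ct$resno[di]
    rn_a <- ct$resno[ai]
    resname <- ct$partner_resname[di]
    if (!resname %in% c("TYR", "SER", "THR"))
      stop("shared donor/acceptor partner must carry a hydroxyl: ", sk)
    xn <- bb_N(rn_d)[1]
    xo <- bb_O(rn_a)[1]
    pos <- c((xn + xo) / 2 + 0.4 * sign(xn - xo), -2.2, -0.3)
    put(resname, ct$partner_resno[di], PARTNER_DONOR_ATOM[[resname]], pos)
    handled[c(di, ai)] <- TRUE
  }

  for (r in which(!handled)) {
    type <- ct$type[r]
    rn <- ct$resno[r]
    key <- as.character(rn)
    resname <- ct$partner_resname[r]
    prn <- ct$partner_resno[r]
    if (type == "aromatic") {
      cen <- ring_centroids[[key]]
      if (is.null(cen)) stop("aromatic contact on non-aromatic residue ", rn)
      siblings <- which(ct$type == "aromatic" & ct$resno == rn)
      slot <- match(r, siblings)
      offs <- list(c(-1.05, -0.35, -3.1), c(1.05, 0.35, -3.1), c(0.35, -0.65, -3.1))
      atom <- if (!is.na(GROOVE_ATOM[resname])) GROOVE_ATOM[[resname]] else "CB"
      pos <- cen + offs[[if (length(siblings) == 1) 3 else slot]]
      put(resname, prn, atom, pos)
      if (length(siblings) == 1) {  # lone groove partner gets two extra carbons
        put(resname, prn, "CB", pos + c(-0.85, -0.65, -0.7))
        put(resname, prn, "CG2", pos + c(0.85, -0.75, -0.6))
      }
    } else if (type == "donor_sc") {
      h <- hydroxyls[[key]]
      if (is.null(h)) stop("donor_sc contact on residue without hydroxyl: ", rn)
      atom <- if (!is.na(PARTNER_ACCEPTOR_ATOM[resname]))
        PARTNER_ACCEPTOR_ATOM[[resname]] else "O"
      put(resname, prn, atom, h$pos + 2.7 * unitv(h$pos - h$ca))
    } else if (type == "donor_bb") {
      atom <- if (!is.na(PARTNER_ACCEPTOR_ATOM[resname]))
        PARTNER_ACCEPTOR_ATOM[[resname]] else "O"
      put(resname, prn, atom, bb_N(rn) + 2.9 * nh_dir_of(rn))
    } else if (type == "acceptor_bb") {
      atom <- if (!is.na(PARTNER_DONOR_ATOM[resname]))
        PARTNER_DONOR_ATOM[[resname]] else "N"
      put(resname, prn, atom, bb_O(rn) + 2.8 * c(0, o_side[key], 0))
    } else stop("unknown contact type: ", type)
  }

  # backbone stubs per receptor residue, placed well below the interface
  for (key in names(rec)) {
    rr <- rec[[key]]
    keyatoms <- rr[setdiff(names(rr), c("resname", "resno"))]
    cen <- colMeans(do.call(rbind, keyatoms))
    base <- cen + c(0.4, -1.6, -2.8)
    for (nm2 in setdiff(c("N", "CA", "C", "O"), names(rr))) {
      ofs <- switch(nm2, N = c(0, 0, 0), CA = c(1.3, -0.5, -0.4),
                    C = c(2.5, 0, -0.8), O = c(2.5, -1.0, -1.5))
      rec[[key]][[nm2]] <- base + ofs
    }
  }

  for (key in names(rec)) {
    rr <- rec[[key]]
    for (nm2 in setdiff(names(rr), c("resname", "resno")))
      addat(nm2, substr(nm2, 1, 1), rr$resname, spec$chain_receptor,
            rr$resno, rr[[nm2]])
  }

  all_atoms <- do.call(rbind, atoms)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    jit <- matrix(stats::rnorm(3 * nrow(all_atoms), 0, spec$jitter), ncol = 3)
    all_atoms$x <- all_atoms$x + jit[, 1]
    all_atoms$y <- all_atoms$y + jit[, 2]
    all_atoms$z <- all_atoms$z + jit[, 3]
  }
  all_atoms <- all_atoms[order(all_atoms$chain != spec$chain_anchor,
                               all_atoms$chain, all_atoms$resno), , drop = FALSE]
  all_atoms$serial <- seq_len(nrow(all_atoms))
  st <- structure(list(atoms = all_atoms,
                       chains = sort(unique(all_atoms$chain))),
                  class = "ppi_structure")
  anchor <- residue_selection(spec$chain_anchor, resnos, "anchor")
  receptor <- residue_selection(spec$chain_receptor,
                                sort(unique(vapply(rec, `[[`, numeric(1), "resno"))),
                                "receptor")
  validate_toy_contacts(st, anchor, spec, resnos)

  pdb <- write_structure(st)
  st2 <- read_structure(pdb)

  aromatic_res <- resnos[seq1 %in% c("Y", "F")]
  n_feat <- length(aromatic_res) + sum(ct$type != "aromatic")
  declared <- list(
    n_atoms = nrow(all_atoms),
    n_features = n_feat,
    n_points = n_feat * 2,
    essential_residues = aromatic_res,
    contacts = ct
  )
  list(structure = st2, pdb = pdb, anchor = anchor, receptor = receptor,
       declared = declared)
}

# The generated complex must host exactly the declared polar contacts:
# declared ones satisfied, no undeclared donor/acceptor pairing in range.
validate_toy_contacts <- function(st, anchor, spec, resnos) {
  a <- st$atoms
  anc <- a[a$chain == anchor$chain, , drop = FALSE]
  rec <- a[a$chain != anchor$chain, , drop = FALSE]
  recxyz <- as.matrix(rec[, c("x", "y", "z")])
  rec_acc <- which(rec$elem == "O")
  rec_don <- which(rec$elem == "N" | (rec$elem == "O" & rec$name %in% HYDROXYL_NAMES))
  ct <- spec$contacts
  ctkey <- sprintf("%d:%s", ct$resno, ct$type)
  for (rn in resnos) {
    res <- anc[anc$resno == rn, , drop = FALSE]
    key <- as.character(rn)
    # backbone donor
    np <- as.numeric(res[res$name == "N", c("x", "y", "z")])
    hit <- polar_partners(np, recxyz, rec_acc, 3.5,
                          dir = backbone_nh_dir(anc, anchor$chain, rn), cone = 70)
    want <- sprintf("%s:donor_bb", key) %in% ctkey
    if (want != (length(hit) > 0))
      stop("toy complex cannot host declared contacts: backbone donor of ",
           rn, if (want) " finds no partner" else " pairs while undeclared")
    # backbone acceptor
    op <- as.numeric(res[res$name == "O", c("x", "y", "z")])
    cp <- as.numeric(res[res$name == "C", c("x", "y", "z")])
    hit <- polar_partners(op, recxyz, rec_don, 3.5, dir = unitv(op - cp), cone = 90)
    want <- sprintf("%s:acceptor_bb", key) %in% ctkey
    if (want != (length(hit) > 0))
      stop("toy complex cannot host declared contacts: backbone acceptor of ",
           rn, if (want) " finds no partner" else " pairs while undeclared")
    # side-chain hydroxyl donor
    for (nm in intersect(res$name, HYDROXYL_NAMES)) {
      hp <- as.numeric(res[res$name == nm, c("x", "y", "z")])
      hit <- polar_partners(hp, recxyz, rec_acc, 3.5)
      want <- sprintf("%s:donor_sc", key) %in% ctkey
      if (want != (length(hit) > 0))
        stop("toy complex cannot host declared contacts: hydroxyl of ", rn,
             if (want) " finds no partner" else " pairs while undeclared")
    }
  }
  invisible(TRUE)
}

#' Aligned FASTA of anchor-peptide homologs
#'
#' Emulates an alignment of the anchor segment across species: aromatic
#' anchor positions are invariant, the remaining positions vary over
#' chemically similar residues.
#'
#' @param anchor_seq the reference sequence (default "SYSYD").
#' @param n_seqs number of sequences (>= 2).
#' @param seed RNG seed.
#' @param file optional path; when given, an aligned FASTA is written.
#' @return character matrix (sequences x positions).
#' @export
make_anchor_msa <- function(anchor_seq = "SYSYD", n_seqs = 12, seed = 1,
                            file = NULL) {
  stopifnot(n_seqs >= 2)
  seq1 <- strsplit(toupper(anchor_seq), "")[[1]]
  set.seed(seed)
  variable_pool <- list(S = c("S", "T", "A", "N", "G"),
                        A = c("A", "S", "G", "T", "V"),
                        G = c("G", "A", "S", "N", "D"),
                        D = c("D", "E", "N", "S", "Q"),
                        Y = "Y", F = "F")
  ali <- matrix("", n_seqs, length(seq1))
  ali[1, ] <- seq1
  for (i in 2:n_seqs)
    ali[i, ] <- vapply(seq1, function(aa) {
      pool <- variable_pool[[aa]]
      if (length(pool) == 1) pool else sample(pool, 1)
    }, character(1))
  rownames(ali) <- sprintf("homolog_%02d", seq_len(n_seqs))
  if (!is.null(file)) {
    lines <- as.vector(rbind(paste0(">", rownames(ali)),
                             apply(ali, 1, paste0, collapse = "")))
    writeLines(lines, file)
  }
  ali
}

#' Library specification for engineered actives and decoys
#'
#' Actives realize every hypothesis feature with a matching chemical group
#' placed at the feature center plus a uniform-in-sphere jitter strictly
#' smaller than the feature radius; decoys are feature-free alkane chains.
#' Labels are recorded as ground truth.
#'
#' @param n_actives,n_decoys library composition.
#' @param jitter active placement jitter in Angstrom, must be `<` the
#'   smallest feature radius.
#' @param seed RNG seed.
#' @export
library_spec <- function(n_actives = 20, n_decoys = 80, jitter = 0.4, seed = 1) {
  list(n_actives = n_actives, n_decoys = n_decoys, jitter = jitter, seed = seed)
}

#' Generate an active/decoy ligand library against a hypothesis
#'
#' @param spec a [library_spec()].
#' @param hyp the `pharmacophore` the actives must satisfy.
#' @param sdf_file,labels_file optional output paths (SDF and TSV).
#' @return list: `mols` (named list of `ppi_mol`), `labels` (data.frame
#'   id, active).
#' @export
make_library <- function(spec, hyp, sdf_file = NULL, labels_file = NULL) {
  radii <- vapply(hyp$features, `[[`, numeric(1), "radius")
  if (spec$jitter >= min(radii))
    stop("active jitter must be smaller than the smallest feature radius")
  set.seed(spec$seed)
  mols <- list()
  labels <- data.frame(id = character(), active = logical())
  jit <- function() {
    # uniform in the sphere of radius spec$jitter
    repeat {
      v <- stats::runif(3, -spec$jitter, spec$jitter)
      if (vnorm(v) <= spec$jitter) return(v)
    }
  }
  for (k in seq_len(spec$n_actives)) {
    id <- sprintf("ACT%03d", k)
    elem <- character()
    coords <- NULL
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
    nh <- integer()
    for (f in hyp$features) {
      base <- length(elem)
      if (f$kind == "aromatic") {
        nrm <- if (!is.null(f$proj)) unitv(f$proj - f$center) else c(0, 0, 1)
        rc <- ring_coords(f$center + jit(), normal = nrm)
        elem <- c(elem, rep("C", 6))
        coords <- rbind(coords, rc)
        nh <- c(nh, rep(1L, 6))
        bonds <- rbind(bonds, data.frame(i = base + 1:6, j = base + c(2:6, 1),
                                         order = 4L))
      } else if (f$kind == "donor") {
        elem <- c(elem, "O")
        coords <- rbind(coords, matrix(f$center + jit(), 1))
        nh <- c(nh, 2L)
      } else if (f$kind == "acceptor") {
        dirp <- if (!is.null(f$proj)) unitv(f$proj - f$center) else c(0, 0, 1)
        op <- f$center + jit()
        elem <- c(elem, "O", "C")
        coords <- rbind(coords, matrix(op, 1), matrix(op - 1.23 * dirp, 1))
        nh <- c(nh, 0L, 2L)
        bonds <- rbind(bonds, data.frame(i = base + 1, j = base + 2, order = 2L))
      } else if (f$kind == "hydrophobic") {
        p0 <- f$center + jit()
        elem <- c(elem, rep("C", 3))
        coords <- rbind(coords, rbind(p0 + c(-0.8, 0, 0), p0, p0 + c(0.8, 0, 0)))
        nh <- c(nh, c(3L, 2L, 3L))
        bonds <- rbind(bonds, data.frame(i = base + 1:2, j = base + 2:3, order = 1L))
      }
    }
    mols[[id]] <- new_molecule(id, elem, coords, bonds, nh = nh)
    labels <- rbind(labels, data.frame(id = id, active = TRUE))
  }
  for (k in seq_len(spec$n_decoys)) {
    id <- sprintf("DEC%03d", k)
    m <- mol_alkane(sample(4:8, 1), name = id)
    m <- transform_mol(m, random_rotation(), stats::rnorm(3, 0, 8))
    mols[[id]] <- m
    labels <- rbind(labels, data.frame(id = id, active = FALSE))
  }
  if (!is.null(sdf_file)) write_sdf(mols, sdf_file)
  if (!is.null(labels_file))
    utils::write.table(labels, labels_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(mols = mols, labels = labels)
}

#' Mock docking engine specification
#'
#' Per-engine score distributions default to the drug-like screen's
#' printed pKi distribution (mean 5.89, sd 0.93); pose jitter separates
#' "consistent" compounds (sub-Angstrom perturbations, pairwise RMSD well
#' below 2) from "inconsistent" ones (one engine displaced by >= 5).
#'
#' @param engines engine identifiers (three by default).
#' @param score_mean,score_sd pKi distribution per engine (recycled).
#' @param jitter_small,jitter_large translation scales in Angstrom.
#' @param inconsistent_ids compounds whose second engine pose is displaced.
#' @param hit_ids compounds planted as high-scoring true hits.
#' @param hit_boost z-offset of planted hit scores (default 4.5 sd, so
#'   planted hits stay above the realized mean + 2 sd threshold even in
#'   small libraries where they inflate the estimated spread).
#' @param seed RNG seed.
#' @export
mock_engine_spec <- function(engines = c("dovis", "vina", "moldock"),
                             score_mean = 5.89, score_sd = 0.93,
                             jitter_small = 0.12, jitter_large = 6,
                             inconsistent_ids = character(),
                             hit_ids = character(), hit_boost = 4.5, seed = 1) {
  list(engines = engines,
       score_mean = rep_len(score_mean, length(engines)),
       score_sd = rep_len(score_sd, length(engines)),
       jitter_small = jitter_small, jitter_large = jitter_large,
       inconsistent_ids = inconsistent_ids, hit_ids = hit_ids,
       hit_boost = hit_boost, seed = seed)
}

#' Generate mock docking output for a compound set
#'
#' Each engine emits the compound's input pose perturbed by a small random
#' rigid motion; for compounds declared inconsistent, the second engine's
#' pose is displaced by `jitter_large`. Scores are drawn from the
#' configured normal distributions, with planted hits boosted.
#'
#' @param mols named list of `ppi_mol` (poses start from their coordinates,
#'   assumed to be in the receptor frame).
#' @param spec a [mock_engine_spec()].
#' @return list: `poses` (flat list of `docked_pose`), `scores`
#'   (data.frame compound, engine, pki), `truth` (data.frame compound,
#'   consistent, hit).
#' @export
make_mock_docking <- function(mols, spec = mock_engine_spec()) {
  set.seed(spec$seed)
  ids <- vapply(mols, `[[`, character(1), "name")
  poses <- list()
  scores <- NULL
  for (e in seq_along(spec$engines)) {
    eng <- spec$engines[e]
    for (m in mols) {
      ctr <- colMeans(m$coords)
      ax <- stats::rnorm(3)
      R <- rotation_about_axis(ax, stats::rnorm(1, 0, 1.5))
      crd <- sweep(sweep(m$coords, 2, ctr) %*% t(R), 2, -ctr) +
        matrix(stats::rnorm(3, 0, spec$jitter_small / sqrt(3)),
               nrow(m$coords), 3, byrow = TRUE)
      if (e == 2 && m$name %in% spec$inconsistent_ids)
        crd <- crd + matrix(c(spec$jitter_large, 0, 0), nrow(crd), 3, byrow = TRUE)
      sc <- stats::rnorm(1, spec$score_mean[e], spec$score_sd[e])
      if (m$name %in% spec$hit_ids)
        sc <- spec$score_mean[e] + spec$hit_boost * spec$score_sd[e] +
          abs(stats::rnorm(1, 0, 0.1 * spec$score_sd[e]))
      poses[[length(poses) + 1]] <- docked_pose(m, crd, eng, sc)
      scores <- rbind(scores, data.frame(compound = m$name, engine = eng, pki = sc))
    }
  }
  truth <- data.frame(compound = ids,
                      consistent = !ids %in% spec$inconsistent_ids,
                      hit = ids %in% spec$hit_ids)
  list(poses = poses, scores = scores, truth = truth)
}

#' Generate a sensorgram bundle with recorded ground truth
#'
#' Wraps the binding simulators: direct-binding truths (`kind = "kd"`) get
#' a FastStep titration, competition truths (`kind = "ic50"`) get an
#' equilibrium competition series against the activator fragment.
#'
#' @param truth data.frame with columns `compound`, `kind` ("kd"/"ic50"),
#'   `value` (M).
#' @param program an `injection_program` for the direct-binding runs.
#' @param rmax saturation response (RU).
#' @param noise_sd noise in RU.
#' @param seed RNG seed.
#' @param kd_tpx2,tpx2_conc competition assay constants (M).
#' @param inhibitor_concs inhibitor ladder for competition runs (M).
#' @param dir optional output directory for CSV files plus a truth TSV.
#' @return list of per-compound entries (`data`, `kind`, `truth`).
#' @export
make_sensorgrams <- function(truth, program = faststep_program(),
                             rmax = 100, noise_sd = 0, seed = 1,
                             kd_tpx2 = 80e-9, tpx2_conc = 1e-6,
                             inhibitor_concs = c(1, 2, 5, 10, 20, 50, 100) * 1e-6,
                             dir = NULL) {
  out <- list()
  for (k in seq_len(nrow(truth))) {
    cmpd <- truth$compound[k]
    kind <- truth$kind[k]
    val <- truth$value[k]
    sub_seed <- seed + k
    if (kind == "kd") {
      s <- simulate_faststep(kd = val, rmax = rmax, program = program,
                             noise_sd = noise_sd, seed = sub_seed)
      if (!is.null(dir))
        write_sensorgram(s, file.path(dir, paste0(cmpd, "_faststep.csv")))
      out[[cmpd]] <- list(data = s, kind = kind, truth = val)
    } else if (kind == "ic50") {
      ki <- ki_from_ic50(val, kd_tpx2, tpx2_conc)
      d <- simulate_competition(kd_tpx2, tpx2_conc, ki, inhibitor_concs,
                                rmax_tpx2 = rmax, noise_sd = noise_sd,
                                seed = sub_seed)
      if (!is.null(dir))
        utils::write.csv(d, file.path(dir, paste0(cmpd, "_competition.csv")),
                         row.names = FALSE)
      out[[cmpd]] <- list(data = d, kind = kind, truth = val)
    } else stop("unknown truth kind: ", kind)
  }
  if (!is.null(dir))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  out
}
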