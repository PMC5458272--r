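# screening_cascade: pharmacophore screen -> docking adapters -> z-score
# selection -> multi-engine consensus RMSD -> absolute-mode pharmacophore
# refilter -> fingerprint clustering and representative picking.
#
# Docking engines are adapters (compound in, scored poses out); the package
# ships a mock engine in the synthetic-data module. Docking itself is out of
# scope. The adapter configuration defaults record the grid settings used by
# the original campaign (40x40x40 points at 0.375 A spacing; selected box
# 30x15x15 centered at x=185.0, y=190.0, z=11.0; Lamarckian GA population
# 150, 250000 evaluations, 27e3 generations, mutation rate 0.02); they are
# passed through to engines verbatim, never interpreted here.

#' Default docking adapter configuration
#' @export
docking_adapter_defaults <- function() {
  list(grid_points = c(40, 40, 40), grid_spacing = 0.375,
       box = c(30, 15, 15), box_center = c(x = 185.0, y = 190.0, z = 11.0),
       ga_population = 150, ga_evaluations = 250000,
       ga_generations = 27e3, ga_mutation_rate = 0.02)
}

#' Pharmacophore screen of a compound library
#'
#' A compound survives iff any of its conformers matches the hypothesis in
#' align mode. Input is a list of `conformer_set`s (or single `ppi_mol`s,
#' treated as one-conformer sets).
#'
#' @param library named list of `conformer_set` / `ppi_mol`.
#' @param hyp a `pharmacophore`.
#' @return character vector of surviving compound ids.
#' @export
ph_screen <- function(library, hyp) {
  if (length(library) == 0) stop("empty compound library")
  ids <- names(library)
  if (is.null(ids)) ids <- vapply(library, function(x)
    if (inherits(x, "ppi_mol")) x$name else x$mol$name, character(1))
  surv <- vapply(seq_along(library), function(k) {
    entry <- library[[k]]
    confs <- if (inherits(entry, "ppi_mol")) {
      list(entry)
    } else {
      lapply(entry$coords, function(crd) {
        m <- entry$mol
        m$coords <- crd
        m
      })
    }
    for (m in confs) {
      if (ph_match(hyp, m, mode = "align")$matched) return(TRUE)
    }
    FALSE
  }, logical(1))
  ids[surv]
}

#' Select compounds scoring more than two standard deviations above the mean
#'
#' The mean and standard deviation are computed over all supplied scores
#' (predicted pKi); compounds with `score > mean + z * sd` are selected.
#' The strict inequality follows the screen's selection rule.
#'
#' @param scores named numeric vector of predicted pKi values.
#' @param z number of standard deviations (default 2).
#' @return character vector of selected compound ids.
#' @export
zscore_select <- function(scores, z = 2) {
  if (length(scores) < 2) stop("need at least 2 scores")
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  mu <- mean(scores)
  sdv <- stats::sd(scores)
  if (sdv == 0) {
    warning("zero score variance: nothing selected")
    return(character())
  }
  names(scores)[scores > mu + z * sdv]
}

#' Construct a docked pose
#'
#' @param mol the `ppi_mol` the pose belongs to (atom mapping is by index).
#' @param coords pose coordinates, all atoms of `mol`.
#' @param engine engine identifier.
#' @param score predicted pKi.
#' @export
docked_pose <- function(mol, coords, engine, score) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == n_atoms(mol))
  structure(list(compound = mol$name, mol = mol, coords = coords,
                 engine = engine, score = score), class = "docked_pose")
}

#' In-place RMSD between two poses of one compound
#'
#' Heavy atoms only, no superposition (poses share the receptor frame).
#' With `symmetry_aware = TRUE` the RMSD is minimized over the graph
#' automorphisms of the molecule, so topologically equivalent atoms (e.g.,
#' a flipped phenyl ring) do not inflate the value.
#'
#' @param a,b `docked_pose` objects for the same compound.
#' @param symmetry_aware minimize over automorphisms (default TRUE).
#' @export
pose_rmsd <- function(a, b, symmetry_aware = TRUE) {
  if (!identical(a$compound, b$compound))
    stop("poses belong to different compounds")
  hv <- heavy_idx(a$mol)
  if (length(hv) != length(heavy_idx(b$mol)))
    stop("atom mapping mismatch between poses")
  A <- a$coords[hv, , drop = FALSE]
  B <- b$coords[hv, , drop = FALSE]
  perms <- if (symmetry_aware) mol_automorphisms(a$mol) else list(seq_along(hv))
  min(vapply(perms, function(p) rmsd_plain(A[p, , drop = FALSE], B), numeric(1)))
}

#' Three-engine consensus pose filter
#'
#' For each compound, the top-scoring pose of each engine is compared
#' pairwise; a compound passes iff every pairwise pose RMSD is below
#' `threshold` and its reference-engine pose still satisfies the
#' pharmacophore in absolute mode (no translation or rotation allowed).
#'
#' @param poses list of `docked_pose` (any order; grouped internally by
#'   compound and engine).
#' @param hyp a `pharmacophore` for the absolute-mode refilter, or `NULL`
#'   to skip it.
#' @param threshold pairwise RMSD threshold in Angstrom (default 2.0).
#' @param ph_engine which engine's pose is refiltered (default the first
#'   engine seen; the choice is configurable).
#' @return data.frame: compound, n_engines, max_rmsd, ph_ok, pass, reason.
#' @export
consensus_filter <- function(poses, hyp, threshold = 2.0, ph_engine = NULL) {
  if (length(poses) == 0)
    return(data.frame(compound = character(), n_engines = integer(),
                      max_rmsd = numeric(), ph_ok = logical(),
                      pass = logical(), reason = character()))
  comp <- vapply(poses, `[[`, character(1), "compound")
  engines <- unique(vapply(poses, `[[`, character(1), "engine"))
  if (is.null(ph_engine)) ph_engine <- engines[1]
  rows <- lapply(split(seq_along(poses), comp), function(ii) {
    pp <- poses[ii]
    eng <- vapply(pp, `[[`, character(1), "engine")
    top <- lapply(split(seq_along(pp), eng), function(jj) {
      sc <- vapply(pp[jj], `[[`, numeric(1), "score")
      pp[[jj[which.max(sc)]]]   # tie resolves to first pose index
    })
    id <- pp[[1]]$compound
    if (length(top) < 2)
      return(data.frame(compound = id, n_engines = length(top),
                        max_rmsd = NA_real_, ph_ok = NA, pass = FALSE,
                        reason = "missing engine pose"))
    prs <- utils::combn(names(top), 2, simplify = FALSE)
    rmsds <- vapply(prs, function(pr) pose_rmsd(top[[pr[1]]], top[[pr[2]]]),
                    numeric(1))
    agree <- all(rmsds < threshold)
    ph_ok <- if (is.null(hyp)) TRUE else {
      ref <- if (ph_engine %in% names(top)) top[[ph_engine]] else top[[1]]
      m <- ref$mol
      m$coords <- ref$coords
      ph_match(hyp, m, mode = "absolute")$matched
    }
    data.frame(compound = id, n_engines = length(top),
               max_rmsd = max(rmsds), ph_ok = ph_ok,
               pass = agree && isTRUE(ph_ok),
               reason = if (agree && isTRUE(ph_ok)) "" else if (!agree)
                 "pose disagreement" else "pharmacophore refilter")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound), , drop = FALSE]
}

#' Pairwise Tanimoto similarity of a compound set
#'
#' Hashed atom-pair fingerprints via ChemmineR; molecules without bonds
#' (for which no pairs exist) get zero similarity to everything.
#'
#' @param mols named list of `ppi_mol`.
#' @return symmetric similarity matrix with compound ids as dimnames.
#' @export
tanimoto_matrix <- function(mols) {
  ids <- vapply(mols, `[[`, character(1), "name")
  n <- length(mols)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  has_bonds <- vapply(mols, function(m) nrow(m$bonds) > 0, logical(1))
  if (sum(has_bonds) >= 1) {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    write_sdf(mols[has_bonds], tf)
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
    # sdf2ap prints progress chatter straight to the console; swallow it
    utils::capture.output(
      ap <- suppressMessages(suppressWarnings(ChemmineR::sdf2ap(sdfs))))
    kk <- which(has_bonds)
    for (u in seq_along(kk)) for (v in seq_len(u - 1)) {
      s <- tryCatch(ChemmineR::cmp.similarity(ap[u], ap[v]), error = function(e) 0)
      S[kk[u], kk[v]] <- S[kk[v], kk[u]] <- s
    }
  }
  S
}

#' Cluster compounds and pick the most potent representative of each group
#'
#' Single-linkage clustering: compounds are connected when their structural
#' (Tanimoto) similarity is at least `similarity_threshold`; each connected
#' component forms one cluster and its highest-scoring member (ties broken
#' by lexicographic id) is flagged representative.
#'
#' @param mols named list of `ppi_mol`.
#' @param scores named numeric (predicted pKi) covering the compounds.
#' @param similarity_threshold Tanimoto threshold (default 0.7).
#' @param sim optional precomputed similarity matrix.
#' @return data.frame: compound, cluster, score, representative.
#' @export
cluster_and_pick <- function(mols, scores, similarity_threshold = 0.7, sim = NULL) {
  if (length(mols) == 0)
    return(data.frame(compound = character(), cluster = integer(),
                      score = numeric(), representative = logical()))
  ids <- vapply(mols, `[[`, character(1), "name")
  if (is.null(sim)) sim <- tanimoto_matrix(mols)
  adj <- sim >= similarity_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  df <- data.frame(compound = ids, cluster = as.integer(memb),
                   score = as.numeric(scores[ids]))
  df$representative <- FALSE
  for (cl in unique(df$cluster)) {
    sub <- df[df$cluster == cl, ]
    pick <- sub$compound[order(-sub$score, sub$compound)][1]
    df$representative[df$compound == pick] <- TRUE
  }
  df[order(df$cluster, -df$score, df$compound), , drop = FALSE]
}

#' Read / write engine score tables (TSV: compound, engine, pki)
#' @param file path
#' @export
read_score_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_score_table
#' @param scores data.frame with columns compound, engine, pki
#' @export
write_score_table <- function(scores, file) {
  utils::write.table(scores, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
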