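# hotspot: conservation + alanine-scan surrogate scoring of interface
# residues, and hot-spot ranking.
#
# The original analysis used external conservation servers and a computational
# alanine-scanning server; those retrieve homologs automatically and are not
# reproducible, so two transparent column-scoring schemes stand in (Shannon
# entropy and mean pairwise substitution-matrix similarity), preserving the
# "mean of two schemes, normalized to a 0-9 conservation scale" structure.
# The ddG surrogate is contact-count based, not force-field based: it is not
# expected to reproduce server energies, only the ranking of buried,
# conserved side chains.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Per-column conservation profile of an aligned peptide family
#'
#' Two complementary column scores are computed: (A) a Shannon-entropy score
#' over the 20 amino-acid alphabet, and (B) the mean pairwise
#' substitution-matrix (BLOSUM62) similarity as computed by
#' [bio3d::conserv()]. Each is min-max normalized over columns, the two are
#' averaged, and the mean is binned to the conventional 0 (highly variable)
#' to 9 (invariant) conservation scale. An invariant column always scores 9.
#'
#' Duplicate sequences are collapsed before scoring (a copied sequence adds
#' no evolutionary information), which also makes the profile invariant
#' under sequence duplication and row permutation.
#'
#' @param msa an alignment: path to an aligned FASTA file, a bio3d `fasta`
#'   object, or a character matrix (rows = sequences, columns = positions).
#' @return a `conservation_profile`: data.frame with columns `column`,
#'   `score` (0-9), `entropy` (raw column entropy, nats), `similarity`
#'   (raw scheme-B score), `norm_entropy`, `norm_similarity`, `invariant`.
#' @export
conservation_profile <- function(msa) {
  ali <- as_alignment_matrix(msa)
  if (nrow(ali) < 2) stop("alignment must contain at least 2 sequences")
  ali <- unique(ali)
  ncol_ali <- ncol(ali)
  ent <- apply(ali, 2, column_entropy)
  sim <- bio3d::conserv(ali, method = "similarity", sub.matrix = "blosum62")
  inv <- apply(ali, 2, function(col) {
    res <- col[col %in% AA20]
    length(res) == length(col) && length(unique(res)) == 1
  })
  norm_e <- minmax_norm(-ent)   # low entropy = conserved
  norm_s <- minmax_norm(sim)
  # degenerate alignment (all columns identical raw score)
  if (is.null(norm_e)) norm_e <- ifelse(inv, 1, 0.5)
  if (is.null(norm_s)) norm_s <- ifelse(inv, 1, 0.5)
  v <- (norm_e + norm_s) / 2
  score <- pmin(9L, as.integer(floor(v * 10 + 1e-9)))  # equal-width bins, half-up
  score[inv] <- 9L
  out <- data.frame(column = seq_len(ncol_ali), score = score,
                    entropy = ent, similarity = sim,
                    norm_entropy = norm_e, norm_similarity = norm_s,
                    invariant = inv)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

as_alignment_matrix <- function(msa) {
  if (is.matrix(msa)) {
    ali <- toupper(msa)
  } else if (is.list(msa) && !is.null(msa$ali)) {
    ali <- toupper(msa$ali)
  } else if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    ali <- toupper(bio3d::read.fasta(msa)$ali)
  } else {
    stop("msa must be an aligned FASTA path, a bio3d fasta object, or a character matrix")
  }
  if (any(is.na(ali))) stop("ragged alignment: sequences differ in aligned length")
  ali
}

# Shannon entropy of one alignment column over the 20-aa alphabet, in nats.
# Gaps and non-standard letters are excluded from the frequencies.
column_entropy <- function(col) {
  res <- col[col %in% AA20]
  if (length(res) == 0) return(log(20))  # all-gap column: maximally uninformative
  p <- table(res) / length(res)
  -sum(p * log(p))
}

minmax_norm <- function(x) {
  r <- range(x)
  if (diff(r) < 1e-12) return(NULL)
  (x - r[1]) / diff(r)
}

# side-chain atoms beyond C-beta (what an alanine truncation removes)
BACKBONE_PLUS_CB <- c("N", "CA", "C", "O", "CB", "OXT")

#' Alanine-scan surrogate for interface residues
#'
#' For each anchor residue, counts the cross-interface heavy-atom contacts
#' that would be lost if the side chain were truncated past C-beta, and
#' reports a binding free-energy change surrogate `ddg = k * n_contacts`
#' (kJ/mol). Positive values predict that replacement by alanine
#' destabilizes the complex. Ala and Gly score exactly 0.
#'
#' @param structure a `ppi_structure`
#' @param anchor anchor-peptide `ppi_selection`
#' @param contact_cutoff contact distance in Angstrom (default 4.5)
#' @param k kJ/mol per lost contact; the default 0.15 places a fully
#'   buried tyrosine (20-26 lost contacts) in the 3-4 kJ/mol range.
#' @return data.frame with one row per anchor residue: `chain`, `resno`,
#'   `resname`, `n_contacts`, `ddg`, `missing` (side-chain atoms absent).
#' @export
alanine_scan <- function(structure, anchor, contact_cutoff = 4.5, k = 0.15) {
  check_selection(structure, anchor)
  a <- structure$atoms
  rec <- a[!(a$chain == anchor$chain & a$resno %in% anchor$resnos) &
             !a$het & a$elem != "H" & a$elem != "D", , drop = FALSE]
  recxyz <- as.matrix(rec[, c("x", "y", "z")])
  rows <- lapply(anchor$resnos, function(rn) {
    res <- a[a$chain == anchor$chain & a$resno == rn & !a$het, , drop = FALSE]
    resname <- res$resname[1]
    if (resname %in% c("ALA", "GLY"))
      return(data.frame(chain = anchor$chain, resno = rn, resname = resname,
                        n_contacts = 0L, ddg = 0, missing = FALSE))
    sc <- res[!(res$name %in% BACKBONE_PLUS_CB) & res$elem != "H" & res$elem != "D", ,
              drop = FALSE]
    if (nrow(sc) == 0)
      return(data.frame(chain = anchor$chain, resno = rn, resname = resname,
                        n_contacts = NA_integer_, ddg = NA_real_, missing = TRUE))
    D <- cdist(as.matrix(sc[, c("x", "y", "z")]), recxyz)
    n <- sum(D <= contact_cutoff)
    data.frame(chain = anchor$chain, resno = rn, resname = resname,
               n_contacts = n, ddg = k * n, missing = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank interface hot spots
#'
#' A residue is a hot spot when it is both conserved (`score >= cons_min`)
#' and predicted to contribute binding free energy inside `ddg_window`
#' (inclusive). The result is exactly the intersection of the two
#' single-criterion filters, sorted by `ddg` descending.
#'
#' @param profile a `conservation_profile` whose i-th column corresponds to
#'   the i-th anchor residue in `ala`.
#' @param ala result of [alanine_scan()]
#' @param cons_min minimum conservation score (0-9 scale), default 7.
#' @param ddg_window numeric length-2, kJ/mol (default `c(2, 4)`). The
#'   window is configurable because the literature mixes kcal/mol and
#'   kJ/mol for this criterion.
#' @export
rank_hotspots <- function(profile, ala, cons_min = 7, ddg_window = c(2, 4)) {
  if (nrow(profile) == 0 || nrow(ala) == 0) stop("empty inputs")
  if (nrow(profile) < nrow(ala))
    stop("conservation profile does not cover the anchor residues")
  df <- ala
  df$score <- profile$score[seq_len(nrow(ala))]
  keep <- !is.na(df$ddg) & df$score >= cons_min &
    df$ddg >= ddg_window[1] & df$ddg <= ddg_window[2]
  out <- df[keep, , drop = FALSE]
  out <- out[order(-out$ddg, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hot-spot report as TSV
#'
#' Columns: residue, conservation score, ddG surrogate, hotspot flag.
#' @param profile,ala,hotspots as produced by the module's operations
#' @param file output path
#' @export
write_hotspot_report <- function(profile, ala, hotspots, file) {
  df <- ala
  df$cons_score <- profile$score[seq_len(nrow(ala))]
  df$hotspot <- df$resno %in% hotspots$resno
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
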