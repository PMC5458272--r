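# structure_io: PDB complexes, residue selections, interface atom sets.
#
# Parsing is delegated to bio3d::read.pdb; on top of it this module applies
# the policies needed for interface work: first MODEL only, highest-occupancy
# altloc conformer (ties resolved to 'A'), no insertion codes, HETATM records
# retained but flagged so callers can drop them.

#' Read a receptor-peptide complex from PDB text
#'
#' @param pdb Either a path to a PDB file, or PDB-format text (a single
#'   string with newlines, or a character vector of lines).
#' @param drop_het Drop HETATM records (ions, cofactors, waters). They are
#'   retained and flagged by default.
#' @return A `ppi_structure`: list with `atoms` (data.frame: serial, name,
#'   elem, resname, chain, resno, x, y, z, occ, het) and `chains`.
#' @details Coordinates are taken verbatim (author residue numbering, no
#'   renumbering). Malformed coordinate fields raise an error naming the
#'   offending line. Insertion codes are not supported.
#' @export
read_structure <- function(pdb, drop_het = FALSE) {
  lines <- pdb_text_lines(pdb)
  # keep first MODEL only (single-model files have no MODEL records)
  m_start <- grep("^MODEL", lines)
  if (length(m_start) > 1) {
    m_end <- grep("^ENDMDL", lines)[1]
    lines <- lines[seq_len(if (is.na(m_end)) length(lines) else m_end)]
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM record found in PDB input")
  idx <- which(rec)
  # validate fixed-column coordinate fields before handing to the parser
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed ATOM record (truncated) at line ", i, ": ", ln)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(xyz)) || any(!is.finite(xyz)))
      stop("malformed coordinate fields at line ", i, ": ", ln)
    if (substr(ln, 27, 27) != " ")
      stop("insertion codes are not supported (line ", i, ")")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  # rm.alt = FALSE: altloc policy (highest occupancy, ties to 'A') is ours
  pdbobj <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdbobj$atom
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    elem = pdb_element(at),
    resname = at$resid,
    chain = at$chain,
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- resolve_altlocs(atoms)
  if (drop_het) atoms <- atoms[!atoms$het, , drop = FALSE]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates after parsing")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) after altloc resolution: ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = sort(unique(atoms$chain))),
            class = "ppi_structure")
}

pdb_text_lines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb))
    return(readLines(pdb, warn = FALSE))
  if (length(pdb) == 1) return(strsplit(pdb, "\n", fixed = TRUE)[[1]])
  pdb
}

pdb_element <- function(at) {
  e <- toupper(trimws(at$elesy))
  miss <- is.na(e) | e == ""
  # fall back to the first letter of the atom name (column 13-16 convention)
  e[miss] <- toupper(substr(gsub("[0-9]", "", trimws(at$elety[miss])), 1, 1))
  e
}

# Keep the highest-occupancy altloc conformer per (chain, resno, name);
# ties resolve to the alphabetically first altloc id ('A' before 'B').
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    if (length(ii) == 1) return(ii)
    sub <- atoms[ii, ]
    ii[order(-sub$occ, sub$alt)][1]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure as PDB-format text
#'
#' Minimal fixed-format writer (ATOM/HETATM, 3-decimal coordinates) used by
#' the synthetic-data generators; round-trips through [read_structure()]
#' exactly at PDB precision.
#'
#' @param x a `ppi_structure`
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @export
write_structure <- function(x, file = NULL) {
  a <- x$atoms
  fmt_name <- function(n) {
    # atom names of <4 chars start in column 14 by convention
    ifelse(nchar(n) >= 4, substr(n, 1, 4), sprintf(" %-3s", n))
  }
  lines <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$het, "HETATM", "ATOM"), a$serial, fmt_name(a$name),
                   "", a$resname, a$chain, a$resno, "",
                   a$x, a$y, a$z, a$occ, 0, a$elem)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Select residues of one chain by number
#'
#' @param chain single chain identifier.
#' @param resnos ordered integer residue numbers (author numbering).
#' @param role `"anchor"` (the peptide whose interactions template the
#'   pharmacophore) or `"receptor"`.
#' @export
residue_selection <- function(chain, resnos, role = c("anchor", "receptor")) {
  role <- match.arg(role)
  if (length(resnos) == 0) stop("empty residue selection")
  stopifnot(length(chain) == 1)
  structure(list(chain = as.character(chain), resnos = as.integer(resnos),
                 role = role), class = "ppi_selection")
}

# atoms of `structure` belonging to a selection
selection_atoms <- function(structure, sel, heavy_only = FALSE) {
  a <- structure$atoms
  m <- a$chain == sel$chain & a$resno %in% sel$resnos & !a$het
  if (heavy_only) m <- m & a$elem != "H" & a$elem != "D"
  a[m, , drop = FALSE]
}

check_selection <- function(structure, sel) {
  a <- selection_atoms(structure, sel)
  missing <- setdiff(sel$resnos, unique(a$resno))
  if (length(missing))
    stop("selection residues not present in structure: chain ", sel$chain,
         " resno ", paste(missing, collapse = ","))
  invisible(TRUE)
}

#' Receptor heavy atoms at an interface
#'
#' Returns exactly the receptor (non-anchor, non-HETATM) heavy atoms lying
#' within `cutoff` Angstrom of any atom of the anchor selection, ordered by
#' (chain, residue number, atom name). Hydrogens never count, on either side.
#'
#' @param structure a `ppi_structure`
#' @param anchor a `ppi_selection` marking the anchor peptide
#' @param cutoff distance in Angstrom (>= 0)
#' @export
interface_atoms <- function(structure, anchor, cutoff = 4.0) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  check_selection(structure, anchor)
  anc <- selection_atoms(structure, anchor, heavy_only = TRUE)
  if (nrow(anc) == 0) stop("anchor selection is empty")
  a <- structure$atoms
  rec <- a[!(a$chain == anchor$chain & a$resno %in% anchor$resnos) &
             !a$het & a$elem != "H" & a$elem != "D", , drop = FALSE]
  if (nrow(rec) == 0) return(rec)
  D <- cdist(as.matrix(rec[, c("x", "y", "z")]), as.matrix(anc[, c("x", "y", "z")]))
  hit <- apply(D, 1, min) <= cutoff
  out <- rec[hit, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat("ppi_structure:", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s):", paste(x$chains, collapse = " "), "\n")
  cat("  HETATM:", sum(x$atoms$het), "\n")
  invisible(x)
}
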