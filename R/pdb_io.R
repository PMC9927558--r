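#' Parse a PDB file into a two-chain complex
#'
#' Reads `ATOM` records for the two requested chains of a docking model (or a
#' native reference) and returns a validated two-chain complex. `HETATM`
#' records (waters, ions, ligands) are dropped; for atoms with alternate
#' locations only the first-listed altloc is kept; in multi-`MODEL` files only
#' the first model is read (with a warning). Coordinates are kept exactly as
#' printed (angstrom, three decimals).
#'
#' The element of each atom is taken from PDB columns 77-78 when present and
#' otherwise inferred from the atom name (leading digits stripped, first
#' character), so files from docking programs with sloppy element columns
#' still parse.
#'
#' @param text character: PDB file content, either a single string or a vector
#'   of lines.
#' @param receptor_chain,ligand_chain single-character chain identifiers of
#'   the receptor (larger) and ligand (smaller) chain.
#' @param complex_id,model_id identifiers carried through to downstream
#'   tables; default `""`.
#' @return An object of class `chain_complex`: a list with the chain ids and
#'   an `atoms` data frame (element, atom_name, chain_id, residue_seq, icode,
#'   residue_name, x, y, z).
#' @seealso [read_complex()] to read from a file path, [write_pdb()] for the
#'   inverse, [filter_elements()] for the element filter applied before
#'   featurization.
#' @export
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  GLY B   1       4.000   0.000   0.000  1.00  0.00           C"
#' )
#' cc <- parse_complex(pdb, "A", "B")
#' nrow(cc$atoms)
parse_complex <- function(text, receptor_chain, ligand_chain,
                          complex_id = "", model_id = "") {
  stopifnot(is.character(text), nchar(receptor_chain) >= 1,
            nchar(ligand_chain) >= 1)
  if (receptor_chain == ligand_chain)
    grank_stop("receptor and ligand chain must differ", "grank_parse_error")
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else text

  rec <- substr(lines, 1L, 6L)
  ## multi-MODEL: keep the first MODEL block only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1L) {
    warning("multi-MODEL PDB input: using the first MODEL only")
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl)) endmdl[1L] else model_starts[2L]
    lines <- lines[seq_len(stop_at - 1L)]
    rec <- substr(lines, 1L, 6L)
  }
  is_atom <- rec == "ATOM  " | rec == "ATOM"
  idx <- which(is_atom)
  if (!length(idx))
    grank_stop("no ATOM records found in PDB input", "grank_parse_error")
  al <- lines[idx]

  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  rs <- suppressWarnings(as.integer(substr(al, 23L, 26L)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(rs))
  if (length(bad))
    grank_stop(sprintf("unparseable ATOM record at line %d of input",
                       idx[bad[1L]]), "grank_parse_error")

  atoms <- data.frame(
    element      = infer_element(substr(al, 13L, 16L), substr(al, 77L, 78L)),
    atom_name    = trimws(substr(al, 13L, 16L)),
    altloc       = substr(al, 17L, 17L),
    residue_name = trimws(substr(al, 18L, 20L)),
    chain_id     = substr(al, 22L, 22L),
    residue_seq  = rs,
    icode        = trimws(substr(al, 27L, 27L)),
    x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$chain_id %in% c(receptor_chain, ligand_chain), ,
                 drop = FALSE]
  for (ch in c(receptor_chain, ligand_chain)) {
    if (!any(atoms$chain_id == ch))
      grank_stop(sprintf("chain '%s' not found in PDB input", ch),
                 "grank_missing_chain_error")
  }
  ## altloc: keep the first-listed variant of each atom
  akey <- paste(atoms$chain_id, atoms$residue_seq, atoms$icode,
                atoms$atom_name, sep = "\r")
  atoms <- atoms[!duplicated(akey), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  new_chain_complex(complex_id, model_id, receptor_chain, ligand_chain, atoms)
}

#' @rdname parse_complex
#' @param path path to a PDB file.
#' @export
read_complex <- function(path, receptor_chain, ligand_chain,
                         complex_id = "", model_id = "") {
  parse_complex(readLines(path, warn = FALSE), receptor_chain, ligand_chain,
                complex_id = complex_id, model_id = model_id)
}

infer_element <- function(name_field, elem_field) {
  elem <- toupper(trimws(elem_field))
  need <- elem == "" | is.na(elem)
  if (any(need)) {
    nm <- toupper(trimws(name_field[need]))
    nm <- sub("^[0-9]+", "", nm)            # "1HB" -> "HB"
    elem[need] <- substr(nm, 1L, 1L)
  }
  elem
}

new_chain_complex <- function(complex_id, model_id, receptor_chain,
                              ligand_chain, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  if (!all(atoms$chain_id %in% c(receptor_chain, ligand_chain)))
    grank_stop("atoms outside the two declared chains", "grank_parse_error")
  structure(
    list(complex_id = complex_id, model_id = model_id,
         receptor_chain = receptor_chain, ligand_chain = ligand_chain,
         atoms = atoms),
    class = "chain_complex"
  )
}

#' @export
print.chain_complex <- function(x, ...) {
  nr <- sum(x$atoms$chain_id == x$receptor_chain)
  nl <- sum(x$atoms$chain_id == x$ligand_chain)
  cat(sprintf(
    "<chain_complex %s/%s> receptor %s (%d atoms), ligand %s (%d atoms)\n",
    x$complex_id, x$model_id, x$receptor_chain, nr, x$ligand_chain, nl))
  invisible(x)
}

#' Coordinates of a complex as a numeric matrix
#' @param complex a `chain_complex`.
#' @return n x 3 matrix of angstrom coordinates, rows in atom order.
#' @export
complex_coords <- function(complex) {
  as.matrix(complex$atoms[, c("x", "y", "z")])
}

#' Restrict a complex to the five modeled elements
#'
#' Keeps only atoms whose element is one of C, N, O, S, H — the atom types the
#' scoring network encodes — preserving atom order. Idempotent.
#'
#' @param complex a `chain_complex`.
#' @return the filtered `chain_complex`.
#' @export
filter_elements <- function(complex) {
  keep <- complex$atoms$element %in% GRANK_ELEMENTS
  atoms <- complex$atoms[keep, , drop = FALSE]
  for (ch in c(complex$receptor_chain, complex$ligand_chain)) {
    if (!any(atoms$chain_id == ch))
      grank_stop(sprintf(
        "chain '%s' has no C/N/O/S/H atoms after element filtering", ch),
        "grank_empty_chain_error")
  }
  rownames(atoms) <- NULL
  complex$atoms <- atoms
  complex
}

#' Canonical element order of the one-hot atom encoding
#' @export
GRANK_ELEMENTS <- c("C", "N", "O", "S", "H")

#' Write a two-chain complex as PDB text
#'
#' Inverse of [parse_complex()] at PDB precision: coordinates are printed with
#' three decimals, so parse -> write -> parse round-trips exactly for
#' PDB-derived coordinates.
#'
#' @param complex a `chain_complex`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(complex, path = NULL) {
  a <- complex$atoms
  name4 <- ifelse(nchar(a$atom_name) >= 4L, substr(a$atom_name, 1L, 4L),
                  sprintf(" %-3s", a$atom_name))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), name4, a$residue_name, a$chain_id, a$residue_seq,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a batch manifest
#'
#' A manifest is a TSV with columns `complex_id`, `model_id`, `path`,
#' `receptor_chain`, `ligand_chain` mapping docking-model PDB files to
#' complexes; it is the hand-off format between pipeline stages.
#'
#' @param path manifest TSV path.
#' @return data frame with the five columns above.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("complex_id", "model_id", "path", "receptor_chain", "ligand_chain")
  if (!all(need %in% names(m)))
    grank_stop(paste("manifest must have columns:",
                     paste(need, collapse = ", ")), "grank_manifest_error")
  m[, need]
}
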