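#' @name structure_io
#' @title Reading and cleaning protein-small molecule complexes
#'
#' @description
#' Complexes arrive as PDB files.  Before any signature is computed the
#' structure is cleaned the way the training data were curated: water
#' molecules are removed, only the first MODEL of a multi-model file is
#' kept, and alternate locations are collapsed to a single copy per atom.
#' Protein atoms (ATOM records with a standard amino-acid residue name,
#' selenomethionine included) are separated from heteroatom groups; one
#' heteroatom group is later designated as the ligand and all others
#' (cofactors, ions, buffer components) are discarded.
NULL

# 20 canonical amino acids + selenomethionine (MSE, mapped to MET chemistry)
.AA_STANDARD <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL", "MSE")

.WATER_NAMES <- c("HOH", "WAT", "DOD")

.TWO_LETTER_ELEMENTS <- c("SE", "CL", "BR", "ZN", "FE", "MG", "MN", "CA",
                          "NA", "CU", "NI", "CO", "CD", "HG", "SI")

# Element from a PDB atom name when the element column is absent/blank.
# Digits are stripped; known two-letter symbols are recognised first.
.infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1L, 2L)
  ifelse(two %in% .TWO_LETTER_ELEMENTS & !(substr(nm, 1L, 1L) %in% c("C", "N", "O", "S") &
                                             !(two %in% c("CL", "CA", "CD", "CO", "CU", "SE", "SI", "NA", "NI"))),
         two, substr(nm, 1L, 1L))
}

#' Parse a protein-small molecule complex from PDB text
#'
#' Reads fixed-width PDB ATOM/HETATM records (via \pkg{bio3d}), removes all
#' water molecules (residue names HOH, WAT, DOD), keeps only the first
#' MODEL of multi-model files, and resolves alternate locations by keeping
#' the highest-occupancy copy (ties broken in favour of alt-loc \code{"A"},
#' then first occurrence).  Hydrogens are retained but flagged; the
#' signature machinery ignores them in heavy-atom mode.
#'
#' @param pdb_text character: PDB file content, either a single string or a
#'   vector of lines.
#' @param source_id identifier recorded on the returned object (defaults to
#'   \code{"complex"}).
#' @param model_policy \code{"first"} keeps the first MODEL of a
#'   multi-model file; \code{"error"} refuses multi-model input.
#' @return A \code{csm_complex}: list with \code{atoms} (data frame of
#'   retained atom records, columns \code{serial, atom_name, alt_loc,
#'   residue_name, chain_id, residue_seq, x, y, z, occupancy, element,
#'   record_class, is_hydrogen}), \code{source_id}, and cleanup counters.
#' @seealso [select_ligand()], [write_clean_pdb()]
#' @export
parse_complex <- function(pdb_text, source_id = "complex",
                          model_policy = c("first", "error")) {
  model_policy <- match.arg(model_policy)
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text

  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom))
    stop_bindsig("no ATOM/HETATM records found in '%s'", source_id,
                 class = "bindsig_parse_error")

  # validate coordinate fields up front so errors carry a line number
  bad <- which(is_atom)[is.na(vapply(which(is_atom), function(i) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) NA_real_ else 0
  }, numeric(1)))]
  if (length(bad))
    stop_bindsig("unreadable coordinates in '%s' at line %d: '%s'",
                 source_id, bad[1], lines[bad[1]],
                 class = "bindsig_parse_error")

  n_models <- sum(grepl("^MODEL ", lines))
  if (n_models > 1L && model_policy == "error")
    stop_bindsig("'%s' contains %d MODELs (model_policy = \"error\")",
                 source_id, n_models, class = "bindsig_parse_error")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  # rm.alt = FALSE: alternate locations are resolved below by occupancy,
  # not by bio3d's keep-"A" default
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- .infer_element(at$elety[blank])
  elem <- toupper(trimws(elem))

  atoms <- data.frame(
    serial       = at$eleno,
    atom_name    = trimws(at$elety),
    alt_loc      = ifelse(is.na(at$alt), "", at$alt),
    residue_name = trimws(at$resid),
    chain_id     = ifelse(is.na(at$chain), "", at$chain),
    residue_seq  = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy    = ifelse(is.na(at$o), 1, at$o),
    element      = elem,
    record_class = ifelse(at$type == "ATOM" &
                            trimws(at$resid) %in% .AA_STANDARD,
                          "PROTEIN", "HET"),
    is_hydrogen  = elem %in% c("H", "D"),
    stringsAsFactors = FALSE
  )

  n_water <- sum(atoms$residue_name %in% .WATER_NAMES)
  atoms <- atoms[!(atoms$residue_name %in% .WATER_NAMES), , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop_bindsig("'%s' contains only water", source_id,
                 class = "bindsig_parse_error")

  # alternate locations: keep the highest-occupancy copy per atom site;
  # ties go to alt_loc "A", then to the first record seen
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$residue_name,
               atoms$atom_name, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key,
                 -atoms$occupancy,
                 atoms$alt_loc != "A",   # FALSE (i.e. "A") sorts first
                 seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  stopifnot(all(is.finite(atoms$x + atoms$y + atoms$z)))

  structure(list(atoms = atoms,
                 source_id = source_id,
                 n_models_seen = max(1L, n_models),
                 n_waters_removed = n_water),
            class = "csm_complex")
}

#' @export
print.csm_complex <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<csm_complex '%s': %d protein atoms, %d het atoms in %d group(s), %d water(s) removed>\n",
              x$source_id, sum(a$record_class == "PROTEIN"),
              sum(a$record_class == "HET"),
              length(het_groups(x)), x$n_waters_removed))
  invisible(x)
}

#' Protein atoms of a parsed complex
#' @param complex a \code{csm_complex}.
#' @return data frame of atom records with \code{record_class == "PROTEIN"}.
#' @export
protein_atoms <- function(complex) {
  complex$atoms[complex$atoms$record_class == "PROTEIN", , drop = FALSE]
}

#' Heteroatom groups of a parsed complex
#' @param complex a \code{csm_complex}.
#' @return named list of atom data frames, one per (chain, residue name,
#'   residue number) heteroatom group, in file order.
#' @export
het_groups <- function(complex) {
  het <- complex$atoms[complex$atoms$record_class == "HET", , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  key <- paste(het$chain_id, het$residue_name, het$residue_seq, sep = ":")
  split(het, factor(key, levels = unique(key)))
}

#' Designate the ligand among the heteroatom groups
#'
#' All heteroatom groups other than the designated ligand are discarded
#' from downstream computation, mirroring the curation of the training
#' structures (cofactors and ions removed).  Without an explicit
#' \code{ligand_key} the group with the most heavy atoms is chosen; ties
#' are broken by chain then residue number.
#'
#' @param complex a \code{csm_complex}.
#' @param ligand_key optional \code{"chain:resname:resseq"} string naming
#'   the het group to use.
#' @param quiet suppress the selection message.
#' @return A \code{csm_ligand}: list with \code{atoms} (the ligand atom
#'   records) and \code{key}.
#' @export
select_ligand <- function(complex, ligand_key = NULL, quiet = FALSE) {
  groups <- het_groups(complex)
  if (length(groups) == 0L)
    stop_bindsig("no ligand present: '%s' has no heteroatom groups after cleanup",
                 complex$source_id, class = "bindsig_no_ligand")
  if (!is.null(ligand_key)) {
    if (!ligand_key %in% names(groups))
      stop_bindsig("ligand key '%s' not found in '%s'; available: %s",
                   ligand_key, complex$source_id,
                   paste(names(groups), collapse = ", "),
                   class = "bindsig_no_ligand")
    chosen <- ligand_key
  } else {
    heavy <- vapply(groups, function(g) sum(!g$is_hydrogen), integer(1))
    # ties: first by chain then residue_seq (list is already in file order,
    # so order() on the covariates with the max heavy count wins)
    chain <- vapply(groups, function(g) g$chain_id[1], character(1))
    seqno <- vapply(groups, function(g) g$residue_seq[1], numeric(1))
    ord <- order(-heavy, chain, seqno)
    chosen <- names(groups)[ord[1]]
    if (!quiet)
      message(sprintf("select_ligand: chose %s (%d heavy atoms) among {%s}",
                      chosen, heavy[[chosen]],
                      paste(names(groups), collapse = ", ")))
  }
  structure(list(atoms = groups[[chosen]], key = chosen),
            class = "csm_ligand")
}

#' @export
print.csm_ligand <- function(x, ...) {
  cat(sprintf("<csm_ligand %s: %d atoms (%d heavy)>\n", x$key,
              nrow(x$atoms), sum(!x$atoms$is_hydrogen)))
  invisible(x)
}

.format_pdb_line <- function(record, serial, name, alt, resname, chain,
                             resseq, x, y, z, occ, elem) {
  nm <- ifelse(nchar(name) < 4L, paste0(" ", name), name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resname, chain, resseq, x, y, z, occ, 0,
          elem)
}

#' Serialize retained atoms back to PDB text
#'
#' Writes the cleaned atom records of a complex (optionally restricted to
#' the protein plus a designated ligand) as standard fixed-width PDB text.
#' Intended for debugging and for handing a ligand to external chemistry
#' tools; parsing the output again reproduces the same atom records.
#'
#' @param complex a \code{csm_complex}.
#' @param ligand optional \code{csm_ligand}; when given, heteroatoms other
#'   than the ligand are omitted.
#' @param path optional file path; when \code{NULL} the text is returned.
#' @return character vector of PDB lines (invisibly when \code{path} is
#'   given).
#' @export
write_clean_pdb <- function(complex, ligand = NULL, path = NULL) {
  atoms <- complex$atoms
  if (!is.null(ligand)) {
    keep <- atoms$record_class == "PROTEIN"
    key <- paste(atoms$chain_id, atoms$residue_name, atoms$residue_seq,
                 sep = ":")
    atoms <- atoms[keep | key == ligand$key, , drop = FALSE]
  }
  lines <- c(
    sprintf("REMARK 999 bindsig cleaned structure %s", complex$source_id),
    .format_pdb_line(ifelse(atoms$record_class == "PROTEIN", "ATOM", "HETATM"),
                     atoms$serial, atoms$atom_name, "",
                     atoms$residue_name, atoms$chain_id, atoms$residue_seq,
                     atoms$x, atoms$y, atoms$z, atoms$occupancy,
                     atoms$element),
    "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Rigidly transform a parsed complex in memory
#'
#' Applies \code{x -> R x + t} to every atom coordinate at full double
#' precision.  This is the transform used by the geometric-invariance
#' checks: unlike rewriting PDB text (whose coordinate field has three
#' decimals), it preserves pairwise distances to machine precision.
#'
#' @param complex a \code{csm_complex}.
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector (Angstrom).
#' @return the transformed \code{csm_complex}.
#' @export
transform_complex <- function(complex, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  .check_rotation(rotation)
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + rep(translation, each = nrow(xyz))
  complex$atoms$x <- xyz[, 1]
  complex$atoms$y <- xyz[, 2]
  complex$atoms$z <- xyz[, 3]
  complex
}

#' Permute the atom-record order of a parsed complex
#'
#' Signatures must not depend on the order in which atoms appear in the
#' file; this helper reorders the retained records for such checks.
#'
#' @param complex a \code{csm_complex}.
#' @param perm permutation of \code{seq_len(nrow(complex$atoms))}.
#' @return the reordered \code{csm_complex}.
#' @export
permute_atoms <- function(complex, perm) {
  stopifnot(length(perm) == nrow(complex$atoms),
            all(sort(perm) == seq_len(nrow(complex$atoms))))
  complex$atoms <- complex$atoms[perm, , drop = FALSE]
  rownames(complex$atoms) <- NULL
  complex
}

.check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop_bindsig("rotation must be a 3x3 orthonormal matrix with det 1",
                 class = "bindsig_bad_rotation")
  invisible(R)
}
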