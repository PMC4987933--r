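#' @name pharmacophore
#' @title Pharmacophore atom typing
#'
#' @description
#' Graph nodes (heavy atoms) are labelled with eight coarse physicochemical
#' classes: hydrophobic, positively ionisable, negatively ionisable,
#' hydrogen-bond acceptor, hydrogen-bond donor, aromatic, sulfur, and
#' neutral.  An atom may carry several labels (a carboxylate oxygen is both
#' negative and an acceptor); pair counts in the signature are accumulated
#' per class combination.  Protein atoms are typed by a bundled, versioned
#' lookup table over (residue, atom name); ligand atoms are typed from
#' element plus bonded environment.  Typing depends only on chemical
#' identity and connectivity, never on absolute coordinates.
NULL

#' The eight pharmacophore classes, in schema order
#'
#' The ordinal order returned here fixes the feature ordering of every
#' signature; it is identical at training and prediction time.
#'
#' @return character vector of length 8.
#' @export
pharm_types <- function() {
  c("HYDROPHOBIC", "POSITIVE", "NEGATIVE", "H_ACCEPTOR",
    "H_DONOR", "AROMATIC", "SULFUR", "NEUTRAL")
}

#' Load a versioned pharmacophore typing table
#'
#' The table is a plain-text TSV shipped with the package.  Rows with
#' residue \code{"*"} are backbone defaults applied to every amino acid;
#' residue-specific rows override them (proline N, for example, carries no
#' amide hydrogen and is typed neutral).
#'
#' @param version table version tag; \code{"v1"} is the default and
#'   currently only version.
#' @return A \code{csm_typing_table}: environment-free list with
#'   \code{protein} (named list mapping \code{"RES ATOM"} to class sets)
#'   and \code{version}.
#' @export
load_typing_table <- function(version = "v1") {
  path <- system.file("extdata",
                      sprintf("pharmacophore_types_%s.tsv", version),
                      package = "bindsig")
  if (path == "")
    stop_bindsig("no typing table with version '%s'", version,
                 class = "bindsig_bad_table")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  classes <- strsplit(tab$classes, ",", fixed = TRUE)
  bad <- !vapply(classes, function(s) length(s) > 0 && all(s %in% pharm_types()),
                 logical(1))
  if (any(bad))
    stop_bindsig("typing table %s has invalid class sets for: %s", version,
                 paste(tab$atom[bad], collapse = ", "),
                 class = "bindsig_bad_table")

  backbone <- tab$residue == "*"
  entries <- list()
  for (res in .AA_STANDARD) {
    for (i in which(backbone)) {
      if (!(res == "PRO" && tab$atom[i] == "N"))  # residue rows override below
        entries[[paste(res, tab$atom[i])]] <- classes[[i]]
    }
  }
  for (i in which(!backbone))
    entries[[paste(tab$residue[i], tab$atom[i])]] <- classes[[i]]

  structure(list(protein = entries, version = version),
            class = "csm_typing_table")
}

#' Type one protein heavy atom
#'
#' Looks the atom up in the typing table.  Unknown (residue, atom) pairs
#' fall back to element-level rules (C hydrophobic, N donor, O acceptor,
#' S sulfur, anything else neutral) with a warning, so unusual residues
#' never abort a run.
#'
#' @param residue_name 3-letter residue code.
#' @param atom_name PDB atom name (e.g. \code{"NZ"}).
#' @param element element symbol, used only for the fallback.
#' @param table a \code{csm_typing_table} from [load_typing_table()].
#' @return character vector: non-empty set of class names.
#' @export
type_protein_atom <- function(residue_name, atom_name, element,
                              table = load_typing_table()) {
  if (element %in% c("H", "D"))
    stop_bindsig("hydrogen %s/%s passed to protein typing in heavy-atom mode",
                 residue_name, atom_name, class = "bindsig_typing_error")
  hit <- table$protein[[paste(residue_name, atom_name)]]
  if (!is.null(hit)) return(hit)
  warning(sprintf("no typing entry for (%s, %s); falling back to element rule for %s",
                  residue_name, atom_name, element), call. = FALSE)
  .element_fallback(element)
}

.element_fallback <- function(element) {
  switch(element,
         C = "HYDROPHOBIC",
         N = "H_DONOR",
         O = "H_ACCEPTOR",
         S = , SE = "SULFUR",
         "NEUTRAL")
}

# Vectorised table lookup for a protein atom data frame -> list of class sets
.type_protein_atoms <- function(atoms, table) {
  keys <- paste(atoms$residue_name, atoms$atom_name)
  out <- table$protein[keys]
  miss <- vapply(out, is.null, logical(1))
  if (any(miss)) {
    warning(sprintf("%d protein atom(s) missing from typing table (%s); using element fallback",
                    sum(miss), paste(unique(keys[miss]), collapse = ", ")),
            call. = FALSE)
    out[miss] <- lapply(atoms$element[miss], .element_fallback)
  }
  names(out) <- NULL
  out
}

#' Type one ligand heavy atom from its bonded environment
#'
#' Rules, applied on the heavy-atom bond graph (see [perceive_bonds()]):
#' membership in an aromatic ring adds AROMATIC; a carboxylate oxygen
#' (terminal O on a carbon bearing two terminal oxygens) is NEGATIVE and an
#' acceptor; an amine nitrogen with no adjacent carbonyl carbon is POSITIVE
#' and a donor, while amide/aromatic nitrogens are donors/acceptors only;
#' hydroxyl oxygens donate and accept, ether/carbonyl oxygens accept;
#' carbons not otherwise classified are hydrophobic; sulfur (and selenium)
#' is SULFUR; anything left over is NEUTRAL.
#'
#' @param index atom index into the ligand atom table.
#' @param bonds a \code{csm_bond_graph} from [perceive_bonds()].
#' @return character vector: non-empty set of class names.
#' @export
type_ligand_atom <- function(index, bonds) {
  if (index < 1L || index > bonds$n_atoms)
    stop_bindsig("ligand atom index %d outside bond graph (n = %d)",
                 index, bonds$n_atoms, class = "bindsig_typing_error")
  .type_ligand_atoms(bonds)[[index]]
}

# Type all ligand atoms at once; pure function of the bond graph.
.type_ligand_atoms <- function(bonds) {
  elem <- bonds$element
  n <- bonds$n_atoms
  adj <- bonds$adjacency
  deg <- vapply(adj, length, integer(1))
  in_arom <- bonds$aromatic_atoms

  # carbonyl carbon: C with >=1 terminal O neighbour; carboxylate carbon:
  # C with >=2 terminal O neighbours
  terminal_O <- elem == "O" & deg == 1L
  n_term_O <- vapply(seq_len(n), function(i)
    if (elem[i] == "C") sum(terminal_O[adj[[i]]]) else 0L, integer(1))
  carbonyl_C <- n_term_O >= 1L
  carboxylate_C <- n_term_O >= 2L

  lapply(seq_len(n), function(i) {
    cls <- character(0)
    if (in_arom[i]) cls <- c(cls, "AROMATIC")
    e <- elem[i]
    nb <- adj[[i]]
    if (e == "O") {
      if (any(carboxylate_C[nb])) cls <- c(cls, "NEGATIVE", "H_ACCEPTOR")
      else if (deg[i] == 1L && length(nb) && elem[nb[1]] == "C" &&
               !carbonyl_C[nb[1]]) cls <- c(cls, "H_DONOR", "H_ACCEPTOR")
      else if (deg[i] == 1L && length(nb) && elem[nb[1]] != "C")
        cls <- c(cls, "H_DONOR", "H_ACCEPTOR")
      else cls <- c(cls, "H_ACCEPTOR")
    } else if (e == "N") {
      if (in_arom[i]) cls <- c(cls, "H_ACCEPTOR")
      else if (any(carbonyl_C[nb])) cls <- c(cls, "H_DONOR")
      else if (deg[i] <= 3L) cls <- c(cls, "POSITIVE", "H_DONOR")
      else cls <- c(cls, "POSITIVE")
    } else if (e %in% c("S", "SE")) {
      cls <- c(cls, "SULFUR")
    } else if (e == "C") {
      cls <- c(cls, "HYDROPHOBIC")
    } else if (e %in% c("F", "CL", "BR", "I")) {
      cls <- c(cls, "HYDROPHOBIC")
    }
    if (length(cls) == 0L) cls <- "NEUTRAL"
    unique(cls)
  })
}

# Hydroxyl O on an aromatic or carbonyl-free C is donor+acceptor; the
# special-case above keeps phenol OH typed like serine OG.

#' Canonical heavy atoms per amino-acid residue
#'
#' Used by the exhaustiveness checks and by the synthetic generator.
#'
#' @return named list: residue code to character vector of heavy-atom
#'   names (backbone N, CA, C, O included; OXT excluded).
#' @export
residue_heavy_atoms <- function() {
  bb <- c("N", "CA", "C", "O")
  list(
    ALA = c(bb, "CB"),
    ARG = c(bb, "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c(bb, "CB", "CG", "OD1", "ND2"),
    ASP = c(bb, "CB", "CG", "OD1", "OD2"),
    CYS = c(bb, "CB", "SG"),
    GLN = c(bb, "CB", "CG", "CD", "OE1", "NE2"),
    GLU = c(bb, "CB", "CG", "CD", "OE1", "OE2"),
    GLY = bb,
    HIS = c(bb, "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c(bb, "CB", "CG1", "CG2", "CD1"),
    LEU = c(bb, "CB", "CG", "CD1", "CD2"),
    LYS = c(bb, "CB", "CG", "CD", "CE", "NZ"),
    MET = c(bb, "CB", "CG", "SD", "CE"),
    MSE = c(bb, "CB", "CG", "SE", "CE"),
    PHE = c(bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c(bb, "CB", "CG", "CD"),
    SER = c(bb, "CB", "OG"),
    THR = c(bb, "CB", "OG1", "CG2"),
    TRP = c(bb, "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
            "CZ3", "CH2"),
    TYR = c(bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c(bb, "CB", "CG1", "CG2")
  )
}
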