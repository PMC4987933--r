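#' @name ligand_descriptors
#' @title Ligand bond perception and physicochemical descriptors
#'
#' @description
#' HETATM records carry no bonds, so a heavy-atom bond graph is perceived
#' from geometry: two atoms are bonded when their distance does not exceed
#' the sum of their covalent radii plus a tolerance (default 0.45 Angstrom,
#' permissive enough for crystallographic coordinate error).  The graph
#' drives ligand pharmacophore typing and the connectivity-level
#' descriptors (rings, rotatable bonds); the chemistry-heavy descriptors
#' (molecular weight with implicit hydrogens, Crippen-type logP, Ertl-type
#' TPSA, donor/acceptor counts, molar refractivity, fraction Csp3) are
#' computed by Open Babel via \pkg{ChemmineOB} on the same atoms, so the
#' additive-contribution schemes are the field-standard ones.  An explicit
#' SDF sidecar, when available, overrides geometric perception.
NULL

# Covalent radii (Angstrom), Cordero-style consensus values.
.COVALENT_RADII <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39,
  SE = 1.20, ZN = 1.22, FE = 1.32, MG = 1.41, CA = 1.76, "NA" = 1.66,
  K = 2.03, MN = 1.39, CU = 1.32, NI = 1.24, CO = 1.26
)
.radius_of <- function(element) {
  r <- .COVALENT_RADII[element]
  r[is.na(r)] <- 1.2
  unname(r)
}

#' Perceive the heavy-atom bond graph of a ligand
#'
#' @param ligand a \code{csm_ligand} from [select_ligand()].
#' @param bond_tolerance distance slack (Angstrom) added to the covalent
#'   radius sum; default 0.45.
#' @param sdf_text optional character: SDF (V2000) text whose bond block
#'   overrides geometric perception.  Atom order must match the ligand's
#'   heavy atoms.
#' @return A \code{csm_bond_graph}: adjacency list over heavy atoms, edge
#'   list with bond lengths, ring information (cycle count, aromatic-ring
#'   membership) and connected-component count.  A disconnected graph is
#'   kept (some ligands are salts) with a warning.
#' @export
perceive_bonds <- function(ligand, bond_tolerance = 0.45, sdf_text = NULL) {
  atoms <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0L)
    stop_bindsig("ligand %s has no heavy atoms", ligand$key,
                 class = "bindsig_empty_ligand")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  elem <- atoms$element

  if (!is.null(sdf_text)) {
    edges <- .sdf_bond_block(sdf_text, n)
  } else if (n == 1L) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    d <- as.matrix(stats::dist(xyz))
    rsum <- outer(.radius_of(elem), .radius_of(elem), `+`) + bond_tolerance
    hit <- d <= rsum & d > 0.4
    hit[lower.tri(hit, diag = TRUE)] <- FALSE
    edges <- which(hit, arr.ind = TRUE)
    colnames(edges) <- NULL
  }
  lengths <- if (nrow(edges)) sqrt(rowSums((xyz[edges[, 1], , drop = FALSE] -
                                              xyz[edges[, 2], , drop = FALSE])^2))
             else numeric(0)

  adjacency <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adjacency[[i]] <- c(adjacency[[i]], j)
    adjacency[[j]] <- c(adjacency[[j]], i)
  }
  adjacency <- lapply(adjacency, sort)

  comp <- .components(adjacency, n)
  if (comp$n_components > 1L)
    warning(sprintf("ligand %s bond graph has %d connected components (kept)",
                    ligand$key, comp$n_components), call. = FALSE)

  rings <- .small_rings(adjacency, n)           # simple cycles, size 3..6
  ring_count <- nrow(edges) - n + comp$n_components   # cyclomatic number

  deg <- vapply(adjacency, length, integer(1))
  aromatic_rings <- Filter(function(ring) {
    if (!(length(ring) %in% c(5L, 6L))) return(FALSE)
    if (!all(elem[ring] %in% c("C", "N", "O", "S"))) return(FALSE)
    if (any(deg[ring] > 3L)) return(FALSE)
    # aromatic bonds are short (~1.39 A for C-C); saturated rings are not
    len <- vapply(seq_along(ring), function(i) {
      a <- ring[i]; b <- ring[if (i == length(ring)) 1L else i + 1L]
      sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    }, numeric(1))
    mean(len) < 1.45
  }, rings)

  structure(list(n_atoms = n,
                 element = elem,
                 atom_name = atoms$atom_name,
                 adjacency = adjacency,
                 edges = edges,
                 edge_lengths = lengths,
                 n_components = comp$n_components,
                 rings = rings,
                 ring_count = max(0L, ring_count),
                 aromatic_rings = aromatic_rings,
                 aromatic_atoms = seq_len(n) %in% unlist(aromatic_rings)),
            class = "csm_bond_graph")
}

.components <- function(adjacency, n) {
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, adjacency[[v]][comp[adjacency[[v]]] == 0L])
    }
  }
  list(membership = comp, n_components = cur)
}

# Enumerate simple cycles of size 3..6 by bounded DFS from each anchor
# vertex (only paths through vertices > anchor, deduplicated by vertex set).
.small_rings <- function(adjacency, n, max_size = 6L) {
  found <- list(); seen <- character(0)
  walk <- function(anchor, path) {
    v <- path[[length(path)]]
    for (w in adjacency[[v]]) {
      if (w == anchor && length(path) >= 3L) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (w > anchor && !(w %in% path) && length(path) < max_size) {
        walk(anchor, c(path, w))
      }
    }
  }
  for (a in seq_len(n)) walk(a, a)
  found
}

.sdf_bond_block <- function(sdf_text, n_atoms) {
  lines <- if (length(sdf_text) == 1L) strsplit(sdf_text, "\n")[[1]] else sdf_text
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb))
    stop_bindsig("cannot read SDF counts line: '%s'", counts,
                 class = "bindsig_parse_error")
  if (na != n_atoms)
    stop_bindsig("SDF sidecar has %d atoms but ligand has %d heavy atoms",
                 na, n_atoms, class = "bindsig_parse_error")
  bl <- lines[(4 + na + 1):(4 + na + nb)]
  cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)))
}

#' Descriptor names, in schema order
#' @return character vector of the twelve ligand descriptor names.
#' @export
descriptor_names <- function() {
  c("molecular_weight", "heavy_atom_count", "logP_estimate",
    "topological_polar_surface_area", "h_bond_donors", "h_bond_acceptors",
    "rotatable_bonds", "ring_count", "aromatic_ring_count",
    "formal_charge", "fraction_csp3", "molar_refractivity")
}

# Ligand heavy atoms -> OpenBabel perception (implicit H, bond orders,
# aromaticity): additive-scheme properties plus an sp3-carbon SMARTS count.
.ligand_obprops <- function(ligand) {
  atoms <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  pdb <- c(.format_pdb_line("HETATM", seq_len(nrow(atoms)), atoms$atom_name,
                            "", atoms$residue_name, atoms$chain_id,
                            atoms$residue_seq, atoms$x, atoms$y, atoms$z,
                            1, atoms$element),
           "END")
  sdf <- ChemmineOB::convertFormat("PDB", "SDF",
                                   paste(c(pdb, ""), collapse = "\n"))
  out <- ChemmineOB::forEachMol("SDF", sdf, function(m)
    list(props = ChemmineOB::prop_OB(m),
         n_csp3 = as.numeric(ChemmineOB::smartsSearch_OB(
           list(m), "[CX4]", uniqueMatches = TRUE))))
  out[[1]]
}

#' Compute the twelve-descriptor physicochemical block of a ligand
#'
#' Molecular weight (implicit hydrogens included), logP, topological polar
#' surface area, H-bond donor/acceptor counts and molar refractivity come
#' from Open Babel's standard additive schemes on the perceived molecule;
#' heavy-atom count, ring count, aromatic-ring count and rotatable-bond
#' count come from the package's own bond graph; fraction Csp3 and formal
#' charge come from SMARTS matching / the canonical SMILES of the
#' perceived molecule.  Deterministic, and invariant under rigid motion
#' and atom reordering.
#'
#' @param ligand a \code{csm_ligand}.
#' @param bonds a \code{csm_bond_graph}; perceived from geometry when
#'   omitted.
#' @return named numeric vector in [descriptor_names()] order.
#' @export
compute_descriptors <- function(ligand, bonds = perceive_bonds(ligand)) {
  n <- bonds$n_atoms
  if (n == 0L)
    stop_bindsig("empty ligand", class = "bindsig_empty_ligand")

  ob <- .ligand_obprops(ligand)
  props <- ob$props
  num <- function(col) suppressWarnings(as.numeric(props[[col]][1]))

  smi <- as.character(props$cansmi[1])
  formal_charge <- lengths(regmatches(smi, gregexpr("\\+", smi))) -
    lengths(regmatches(smi, gregexpr("-", smi)))

  n_carbon <- sum(bonds$element == "C")
  csp3 <- if (n_carbon == 0L) 0 else ob$n_csp3 / n_carbon

  # rotatable: non-ring bond, both ends non-terminal, and long enough to be
  # a single bond (double/aromatic C-C, C-N, C-O bonds are < ~1.40 A)
  deg <- vapply(bonds$adjacency, length, integer(1))
  ring_edge <- rep(FALSE, nrow(bonds$edges))
  for (ring in bonds$rings) {
    cyc <- cbind(ring, c(ring[-1], ring[1]))
    for (k in seq_len(nrow(bonds$edges))) {
      e <- bonds$edges[k, ]
      if (any((cyc[, 1] == e[1] & cyc[, 2] == e[2]) |
              (cyc[, 1] == e[2] & cyc[, 2] == e[1])))
        ring_edge[k] <- TRUE
    }
  }
  rot <- sum(!ring_edge &
               deg[bonds$edges[, 1]] >= 2L &
               deg[bonds$edges[, 2]] >= 2L &
               bonds$edge_lengths > 1.40)

  out <- c(
    molecular_weight = num("MW"),
    heavy_atom_count = as.numeric(n),
    logP_estimate = num("logP"),
    topological_polar_surface_area = num("TPSA"),
    h_bond_donors = num("HBD"),
    h_bond_acceptors = num("HBA2"),
    rotatable_bonds = as.numeric(rot),
    ring_count = as.numeric(bonds$ring_count),
    aromatic_ring_count = as.numeric(length(bonds$aromatic_rings)),
    formal_charge = as.numeric(formal_charge),
    fraction_csp3 = csp3,
    molar_refractivity = num("MR")
  )
  stopifnot(identical(names(out), descriptor_names()), !anyNA(out))
  out
}
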