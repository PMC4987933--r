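# Hand-built PDB fixtures and independent oracles shared across tests.

pdb_line <- function(record, serial, name, resname, chain, resseq,
                     x, y, z, occ = 1, elem = substr(name, 1, 1),
                     alt = "") {
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resname, chain, resseq, x, y, z, occ, 0,
          elem)
}

# a ligand object without going through a file, for unit-level chemistry
make_ligand <- function(atom, element, x, y, z, resname = "LIG",
                        chain = "L", resseq = 1L) {
  structure(list(
    atoms = data.frame(
      serial = seq_along(atom), atom_name = atom, alt_loc = "",
      residue_name = resname, chain_id = chain, residue_seq = resseq,
      x = x, y = y, z = z, occupancy = 1, element = element,
      record_class = "HET", is_hydrogen = element %in% c("H", "D"),
      stringsAsFactors = FALSE),
    key = paste(chain, resname, resseq, sep = ":")),
    class = "csm_ligand")
}

benzene_ligand <- function() {
  ang <- 2 * pi * (0:5) / 6
  make_ligand(paste0("C", 1:6), rep("C", 6),
              1.39 * cos(ang), 1.39 * sin(ang), rep(0, 6))
}

acetate_ligand <- function() {
  make_ligand(c("C1", "C2", "O1", "O2"), c("C", "C", "O", "O"),
              c(-1.52, 0, 0.63, 0.63), c(0, 0, 1.09, -1.09), rep(0, 4))
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

toy_complex_and_ligand <- function(seed = 1, ...) {
  txt <- generate_toy_complex(toy_spec(seed = seed, ...))
  cplx <- parse_complex(txt, sprintf("toy-seed%d", seed))
  list(complex = cplx,
       ligand = select_ligand(cplx, ligand_key = "L:LIG:1", quiet = TRUE),
       text = txt)
}

# Independent double-loop recount of both cutoff-scan blocks.  Shares the
# typing and pocket definition with the package (those have their own
# tests) but counts pairs with explicit loops, expanding multi-label
# class sets by brute enumeration.
brute_signature_blocks <- function(cplx, lig, cfg = signature_config()) {
  table <- load_typing_table(cfg$typing_table_version)
  pocket <- extract_pocket(cplx, lig, cfg)
  bonds <- perceive_bonds(lig, bond_tolerance = cfg$bond_tolerance)
  latoms <- lig$atoms[!lig$atoms$is_hydrogen, , drop = FALSE]

  pc <- lapply(seq_len(nrow(pocket)), function(i)
    type_protein_atom(pocket$residue_name[i], pocket$atom_name[i],
                      pocket$element[i], table))
  lc <- lapply(seq_len(nrow(latoms)), function(i) type_ligand_atom(i, bonds))

  cps <- class_pairs()
  cuts <- cfg$cutoffs
  ord <- function(cl) match(cl, pharm_types())
  canon <- function(a, b) if (ord(a) <= ord(b)) paste(a, b, sep = ":")
                          else paste(b, a, sep = ":")
  add_pair <- function(block, set_i, set_j, d) {
    if (d > cfg$d_max) return(block)
    combos <- unique(unlist(lapply(set_i, function(a)
      sapply(set_j, function(b) canon(a, b)))))
    for (cp in combos) block[cp, ] <- block[cp, ] + as.integer(d <= cuts)
    block
  }

  pxyz <- as.matrix(pocket[, c("x", "y", "z")])
  lxyz <- as.matrix(latoms[, c("x", "y", "z")])
  blockP <- matrix(0L, length(cps), length(cuts), dimnames = list(cps, NULL))
  np <- nrow(pxyz)
  if (np >= 2) for (i in 1:(np - 1)) for (j in (i + 1):np)
    blockP <- add_pair(blockP, pc[[i]], pc[[j]],
                       sqrt(sum((pxyz[i, ] - pxyz[j, ])^2)))
  blockX <- matrix(0L, length(cps), length(cuts), dimnames = list(cps, NULL))
  for (i in seq_len(np)) for (j in seq_len(nrow(lxyz)))
    blockX <- add_pair(blockX, pc[[i]], lc[[j]],
                       sqrt(sum((pxyz[i, ] - lxyz[j, ])^2)))
  list(pocket = blockP, cross = blockX)
}

# extract the two count blocks of a signature as matrices
signature_blocks <- function(sig, cfg = signature_config()) {
  K <- length(cfg$cutoffs)
  cps <- class_pairs()
  v <- as.numeric(sig)
  list(pocket = matrix(v[1:(36 * K)], nrow = 36, byrow = TRUE,
                       dimnames = list(cps, NULL)),
       cross = matrix(v[(36 * K + 1):(72 * K)], nrow = 36, byrow = TRUE,
                      dimnames = list(cps, NULL)))
}
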