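test_that("waters are removed and protein/het records are classified", {
  txt <- c(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdb_line("HETATM", 2, "O", "HOH", "W", 1, 5, 5, 5),
           "END")
  cplx <- parse_complex(txt, "mini")
  expect_equal(nrow(protein_atoms(cplx)), 1L)
  expect_length(het_groups(cplx), 0L)
  expect_equal(cplx$n_waters_removed, 1L)

  txt2 <- c(pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0),
            pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.5, 0, 0),
            pdb_line("ATOM", 3, "C", "GLY", "A", 1, 2.2, 1.3, 0),
            pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 5, 0, 0),
            pdb_line("HETATM", 5, "C2", "LIG", "L", 1, 6.4, 0, 0),
            pdb_line("HETATM", 6, "O1", "LIG", "L", 1, 7.1, 1.1, 0, elem = "O"),
            pdb_line("HETATM", 7, "N1", "LIG", "L", 1, 7.1, -1.1, 0, elem = "N"))
  cplx2 <- parse_complex(txt2, "mini2")
  expect_equal(nrow(protein_atoms(cplx2)), 3L)
  groups <- het_groups(cplx2)
  expect_length(groups, 1L)
  expect_equal(nrow(groups[["L:LIG:1"]]), 4L)
  # all water dialects go
  for (w in c("HOH", "WAT", "DOD")) {
    tw <- c(txt2, pdb_line("HETATM", 8, "O", w, "W", 2, 9, 9, 9, elem = "O"))
    expect_false(w %in% parse_complex(tw, "w")$atoms$residue_name)
  }
})

test_that("alternate locations keep the highest-occupancy copy", {
  txt <- c(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
                    alt = "A"),
           pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6,
                    alt = "B"),
           pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 1, 1, 1))
  cplx <- parse_complex(txt, "alt")
  ca <- cplx$atoms[cplx$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 9)               # the occ-0.6 B copy survives
  # occupancy tie: alt A wins
  txt2 <- c(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5,
                     alt = "B"),
            pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.5,
                     alt = "A"))
  ca2 <- parse_complex(txt2, "alt2")$atoms
  expect_equal(nrow(ca2), 1L)
  expect_equal(ca2$x, 9)
})

test_that("parse errors name the problem", {
  expect_error(parse_complex(c("REMARK nothing here", "END"), "empty"),
               class = "bindsig_parse_error")
  bad <- pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0)
  substr(bad, 33, 36) <- "abcd"
  expect_error(parse_complex(c("REMARK 1", bad), "badcoord"),
               regexp = "line 2", class = "bindsig_parse_error")
})

test_that("multi-model files keep only the first model", {
  mk <- function(x) pdb_line("ATOM", 1, "CA", "ALA", "A", 1, x, 0, 0)
  txt <- c("MODEL     1", mk(1), "ENDMDL", "MODEL     2", mk(2), "ENDMDL")
  cplx <- parse_complex(txt, "nmr")
  expect_equal(nrow(cplx$atoms), 1L)
  expect_equal(cplx$atoms$x, 1)
  expect_error(parse_complex(txt, "nmr", model_policy = "error"),
               class = "bindsig_parse_error")
})

test_that("ligand auto-selection takes the largest het group", {
  fx <- toy_complex_and_ligand(seed = 5, add_cofactor = TRUE)
  expect_message(lig <- select_ligand(fx$complex), "L:LIG:1")
  expect_equal(lig$key, "L:LIG:1")          # benzene (6) beats sulfate (5)
  expect_equal(sum(!lig$atoms$is_hydrogen), 6L)

  # explicit key: that group; unknown key: error listing candidates
  expect_equal(select_ligand(fx$complex, "L:SO4:2", quiet = TRUE)$key,
               "L:SO4:2")
  expect_error(select_ligand(fx$complex, "X:ABC:9"),
               regexp = "L:LIG:1", class = "bindsig_no_ligand")

  # no het groups at all
  prot_only <- parse_complex(
    grep("^HETATM", fx$text, value = TRUE, invert = TRUE), "apo")
  expect_error(select_ligand(prot_only), class = "bindsig_no_ligand")

  # after selection nothing watery or cofactor-like remains downstream
  resn <- c(protein_atoms(fx$complex)$residue_name, lig$atoms$residue_name)
  expect_false(any(resn %in% c("HOH", "WAT", "DOD", "SO4")))
})

test_that("serialization round-trips and parsing ignores record order", {
  fx <- toy_complex_and_ligand(seed = 9, n_waters = 3)
  out <- write_clean_pdb(fx$complex)
  back <- parse_complex(out, fx$complex$source_id)
  cols <- c("atom_name", "residue_name", "chain_id", "residue_seq",
            "x", "y", "z", "element", "record_class")
  expect_equal(back$atoms[, cols], fx$complex$atoms[, cols])

  atom_lines <- grep("^(ATOM|HETATM)", fx$text, value = TRUE)
  other <- grep("^(ATOM|HETATM)", fx$text, value = TRUE, invert = TRUE)
  set.seed(4)
  shuffled <- parse_complex(c(other, sample(atom_lines)), "shuffled")
  expect_equal(nrow(shuffled$atoms), nrow(fx$complex$atoms))
  expect_equal(sort(shuffled$atoms$serial), sort(fx$complex$atoms$serial))
})

test_that("in-memory transforms preserve structure and guard rotations", {
  fx <- toy_complex_and_ligand(seed = 2)
  set.seed(11)
  R <- random_rotation()
  moved <- transform_complex(fx$complex, R, c(4, -2, 7))
  d0 <- dist(fx$complex$atoms[, c("x", "y", "z")])
  d1 <- dist(moved$atoms[, c("x", "y", "z")])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  expect_error(transform_complex(fx$complex, diag(3) * 2),
               class = "bindsig_bad_rotation")
})
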