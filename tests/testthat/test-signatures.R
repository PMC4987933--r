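cfg_default <- signature_config()

test_that("pocket extraction uses a closed boundary and matches brute force", {
  # one CA exactly at the radius from a single-atom ligand: included
  txt <- c(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 8, 0, 0),
           pdb_line("ATOM", 2, "CA", "ALA", "A", 2, 8.5, 0, 0),
           pdb_line("HETATM", 3, "C1", "LIG", "L", 1, 0, 0, 0))
  cplx <- parse_complex(txt, "edge")
  lig <- select_ligand(cplx, quiet = TRUE)
  pocket <- extract_pocket(cplx, lig, signature_config(pocket_radius = 8))
  expect_equal(pocket$residue_seq, 1L)

  # huge radius: everything
  all_in <- extract_pocket(cplx, lig, signature_config(pocket_radius = 1e4))
  expect_equal(nrow(all_in), 2L)

  # isolated ligand: error naming the observed distance
  expect_error(extract_pocket(cplx, lig, signature_config(pocket_radius = 3)),
               regexp = "isolated", class = "bindsig_empty_pocket")

  # random geometry vs brute-force double loop
  set.seed(17)
  fx <- toy_complex_and_ligand(seed = 17, n_pocket_residues = 10)
  pm <- protein_atoms(fx$complex)
  lm_ <- fx$ligand$atoms
  mind <- apply(as.matrix(pm[, c("x", "y", "z")]), 1, function(p)
    min(sqrt(colSums((t(as.matrix(lm_[, c("x", "y", "z")])) - p)^2))))
  want <- which(mind <= 8)
  got <- extract_pocket(fx$complex, fx$ligand, cfg_default)
  expect_equal(got$serial, pm$serial[want])

  # pocket grows monotonically with radius
  p6 <- extract_pocket(fx$complex, fx$ligand, signature_config(pocket_radius = 6))
  expect_true(all(p6$serial %in% got$serial))
})

test_that("cutoff scan is a cumulative step count per class pair", {
  cfg <- signature_config(d_min = 1, d_max = 10, step = 1)
  one <- data.frame(class_pair = "HYDROPHOBIC:HYDROPHOBIC", distance = 5.0)
  block <- cutoff_scan(one, cfg)
  expect_equal(unname(block["HYDROPHOBIC:HYDROPHOBIC", ]),
               c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_true(all(block[rownames(block) != "HYDROPHOBIC:HYDROPHOBIC", ] == 0L))

  empty <- cutoff_scan(data.frame(class_pair = character(0),
                                  distance = numeric(0)), cfg)
  expect_equal(dim(empty), c(36L, 10L))
  expect_true(all(empty == 0L))

  expect_error(cutoff_scan(data.frame(class_pair = "SULFUR:SULFUR",
                                      distance = -1), cfg),
               class = "bindsig_bad_distance")

  # beyond d_max: counted nowhere
  far <- cutoff_scan(data.frame(class_pair = "SULFUR:SULFUR",
                                distance = 11), cfg)
  expect_true(all(far == 0L))

  # random pairs vs brute-force per-cutoff recount
  set.seed(23)
  pairs <- data.frame(
    class_pair = sample(class_pairs(), 200, replace = TRUE),
    distance = runif(200, 0, 12))
  got <- cutoff_scan(pairs, cfg)
  for (cp in unique(pairs$class_pair)) {
    d <- pairs$distance[pairs$class_pair == cp]
    brute <- vapply(cfg$cutoffs, function(c) sum(d <= c), numeric(1))
    expect_equal(unname(got[cp, ]), as.integer(brute))
  }
})

test_that("signature layout, monotonicity and conservation hold", {
  fx <- toy_complex_and_ligand(seed = 31)
  sig <- build_signature(fx$complex, fx$ligand, cfg_default)
  K <- length(cfg_default$cutoffs)
  expect_length(sig, 36 * K * 2 + 12)
  expect_identical(names(sig), signature_schema(cfg_default))

  blocks <- signature_blocks(sig, cfg_default)
  for (b in blocks) {
    expect_true(all(apply(b, 1, function(r) all(diff(r) >= 0))))
  }
  # conservation: the final cutoff of the brute recount agrees
  brute <- brute_signature_blocks(fx$complex, fx$ligand, cfg_default)
  expect_equal(unname(blocks$pocket[, K]), unname(brute$pocket[, K]))
  expect_equal(unname(blocks$cross[, K]), unname(brute$cross[, K]))
})

test_that("multi-label atoms increment every class combination once", {
  # one ASP OD1 {NEGATIVE,H_ACCEPTOR} against one benzene C {AROMATIC,
  # HYDROPHOBIC}: the cross block gains all four combinations, once each
  txt <- c(pdb_line("ATOM", 1, "OD1", "ASP", "A", 1, 3, 0, 0, elem = "O"),
           pdb_line("HETATM", 2, "C1", "LIG", "L", 1, 0, 0, 0))
  cplx <- parse_complex(txt, "multi")
  lig <- select_ligand(cplx, quiet = TRUE)
  sig <- build_signature(cplx, lig, cfg_default)
  blocks <- signature_blocks(sig, cfg_default)
  K <- length(cfg_default$cutoffs)
  final <- blocks$cross[, K]
  # the lone carbon has no bonds, so it types HYDROPHOBIC only
  expect_equal(unname(final[c("HYDROPHOBIC:NEGATIVE", "HYDROPHOBIC:H_ACCEPTOR")]),
               c(1L, 1L))
  expect_equal(sum(final), 2L)
})

test_that("signatures are invariant to rigid motion and atom order", {
  set.seed(41)
  fx <- toy_complex_and_ligand(seed = 41)
  sig0 <- build_signature(fx$complex, fx$ligand, cfg_default)
  for (rep in 1:3) {
    moved <- transform_complex(fx$complex, random_rotation(),
                               rnorm(3, 0, 20))
    moved <- permute_atoms(moved, sample(nrow(moved$atoms)))
    sig1 <- build_signature(moved, select_ligand(moved, "L:LIG:1",
                                                 quiet = TRUE), cfg_default)
    expect_identical(as.numeric(sig1), as.numeric(sig0))
  }
})

test_that("the signature is geometry-sensitive (scaling changes it)", {
  fx <- toy_complex_and_ligand(seed = 43)
  sig0 <- build_signature(fx$complex, fx$ligand, cfg_default)
  scaled <- fx$complex
  scaled$atoms$x <- scaled$atoms$x * 2
  scaled$atoms$y <- scaled$atoms$y * 2
  scaled$atoms$z <- scaled$atoms$z * 2
  # doubling bond lengths also disconnects the perceived ligand graph,
  # which (correctly) warns; only the geometric change matters here
  sig1 <- suppressWarnings(
    build_signature(scaled, select_ligand(scaled, "L:LIG:1", quiet = TRUE),
                    cfg_default))
  expect_gt(max(abs(as.numeric(sig1) - as.numeric(sig0))), 0)
})

test_that("schema guards and normalization behave", {
  fx <- toy_complex_and_ligand(seed = 47)
  ref <- signature_schema(cfg_default)
  expect_silent_ok <- build_signature(fx$complex, fx$ligand, cfg_default,
                                      reference_schema = ref)
  other <- signature_config(d_max = 20)
  expect_error(build_signature(fx$complex, fx$ligand, other,
                               reference_schema = ref),
               class = "bindsig_schema_mismatch")

  norm <- signature_config(normalize = "PER_PAIRCOUNT")
  sign <- build_signature(fx$complex, fx$ligand, norm)
  expect_true(all(as.numeric(sign)[seq_len(36 * length(norm$cutoffs) * 2)] <= 1))

  expect_error(signature_config(d_min = 5, d_max = 4),
               regexp = "d_max")
  expect_error(signature_config(d_min = 1, d_max = 1.2, step = 1),
               class = "bindsig_bad_config")
})
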