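test_that("toy complexes are well-formed, seeded and parseable", {
  sp <- toy_spec(seed = 77, n_waters = 2, add_cofactor = TRUE)
  txt <- generate_toy_complex(sp)
  expect_identical(txt, generate_toy_complex(sp))        # byte-identical
  expect_true(any(grepl("seed 77", txt)))                # seed recorded

  cplx <- parse_complex(txt, "toy77")
  expect_equal(cplx$n_waters_removed, 2L)
  expect_false(any(cplx$atoms$residue_name %in% c("HOH", "WAT", "DOD")))
  groups <- het_groups(cplx)
  expect_setequal(names(groups), c("L:LIG:1", "L:SO4:2"))
  expect_equal(nrow(groups[["L:LIG:1"]]), 6L)            # benzene

  # no atom loss beyond the waters
  n_atom_lines <- sum(grepl("^(ATOM|HETATM)", txt))
  expect_equal(nrow(cplx$atoms), n_atom_lines - 2L)

  # other templates parse and have the declared sizes
  for (tpl in c("ACETATE", "NEOPENTANE")) {
    t2 <- generate_toy_complex(toy_spec(ligand_template = tpl, seed = 3))
    g <- het_groups(parse_complex(t2, tpl))
    expect_equal(nrow(g[["L:LIG:1"]]),
                 if (tpl == "ACETATE") 4L else 5L)
  }

  expect_error(toy_spec(placement_radius = 1), class = "bindsig_bad_spec")
  expect_error(toy_spec(ligand_template = "XENON"),
               class = "bindsig_bad_spec")
})

test_that("text-level rigid transforms only touch coordinates", {
  txt <- generate_toy_complex(toy_spec(seed = 5))
  expect_identical(rigid_transform(txt), txt)            # identity

  # exact translation: distances unchanged exactly (3-decimal grid shift)
  shifted <- rigid_transform(txt, diag(3), c(10, 0, 0))
  p0 <- parse_complex(txt, "a")$atoms
  p1 <- parse_complex(shifted, "b")$atoms
  expect_equal(as.numeric(dist(p1[, c("x", "y", "z")])),
               as.numeric(dist(p0[, c("x", "y", "z")])), tolerance = 1e-12)
  # non-coordinate bytes untouched
  expect_identical(substr(shifted, 1, 30), substr(txt, 1, 30))
  expect_identical(substr(shifted, 55, 80), substr(txt, 55, 80))

  # rotations through text preserve distances to field precision
  set.seed(6)
  rot <- rigid_transform(txt, random_rotation(), c(1, 2, 3))
  p2 <- parse_complex(rot, "c")$atoms
  expect_equal(as.numeric(dist(p2[, c("x", "y", "z")])),
               as.numeric(dist(p0[, c("x", "y", "z")])), tolerance = 5e-3)

  expect_error(rigid_transform(txt, matrix(rnorm(9), 3, 3)),
               class = "bindsig_bad_rotation")
})

test_that("labeled datasets carry a recoverable declared ground truth", {
  cfg <- signature_config()
  lm0 <- label_model("cross|HYDROPHOBIC:HYDROPHOBIC|8.0", 0.05,
                     intercept = 3, noise_sd = 0)
  ds <- generate_labeled_dataset(n = 12, model = lm0, seed = 4, config = cfg)
  # noiseless single-feature labels correlate perfectly with that feature
  expect_equal(pearson_r(ds$X[, lm0$features], ds$y), 1)
  expect_equal(ds$y, ds$true_signal)

  # weights on a few features are recovered exactly by a linear fit
  lm1 <- default_label_model(noise_sd = 0)
  ds1 <- generate_labeled_dataset(n = 15, model = lm1, seed = 9, config = cfg)
  fit <- lm(ds1$y ~ ds1$X[, lm1$features])
  expect_equal(unname(coef(fit)), c(lm1$intercept, lm1$weights),
               tolerance = 1e-6)

  # label model referencing an unknown feature is rejected
  expect_error(
    generate_labeled_dataset(n = 10, model = label_model("nope", 1)),
    class = "bindsig_bad_spec")
  expect_error(generate_labeled_dataset(n = 5), class = "bindsig_bad_spec")
})

test_that("generator features match the independent brute-force recount", {
  cfg <- signature_config()
  ds <- generate_labeled_dataset(n = 10, seed = 21, config = cfg)
  K <- length(cfg$cutoffs)
  for (i in c(1, 6)) {
    cplx <- parse_complex(ds$pdb_texts[[i]], ds$ids[i])
    lig <- select_ligand(cplx, "L:LIG:1", quiet = TRUE)
    brute <- brute_signature_blocks(cplx, lig, cfg)
    expect_identical(ds$X[i, 1:(36 * K)],
                     setNames(as.numeric(t(brute$pocket)),
                              colnames(ds$X)[1:(36 * K)]))
    expect_identical(ds$X[i, (36 * K + 1):(72 * K)],
                     setNames(as.numeric(t(brute$cross)),
                              colnames(ds$X)[(36 * K + 1):(72 * K)]))
  }
})
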