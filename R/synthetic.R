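#' @name synthetic
#' @title Synthetic toy complexes and labeled datasets
#'
#' @description
#' Every other module is testable offline thanks to a generator of small,
#' well-formed protein-ligand complexes: a ligand template with idealized
#' literature geometry (benzene, acetate or neopentane) sits at the
#' origin, surrounded by a seeded random shell of real residues (ALA,
#' LYS, ASP, PHE, SER) with proper atom names, plus optional waters and a
#' sulfate decoy for cleanup tests.  Labeled datasets attach a known
#' ground truth: pAffinity is a declared linear function of named
#' signature features plus Gaussian noise, so model recovery can be
#' measured against a known answer.  The geometry validates code paths,
#' not chemistry: poses are not energetically meaningful.
NULL

# idealized ligand templates: heavy atoms only, literature bond lengths
.ligand_template <- function(name) {
  switch(name,
    BENZENE = {
      ang <- 2 * pi * (0:5) / 6
      data.frame(atom = paste0("C", 1:6), element = "C",
                 x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0)
    },
    ACETATE = data.frame(
      atom = c("C1", "C2", "O1", "O2"), element = c("C", "C", "O", "O"),
      x = c(-1.52, 0, 0.63, 0.63), y = c(0, 0, 1.09, -1.09), z = 0),
    NEOPENTANE = {
      a <- 1.54 / sqrt(3)
      data.frame(atom = paste0("C", 1:5), element = "C",
                 x = c(0, a, a, -a, -a), y = c(0, a, -a, a, -a),
                 z = c(0, a, -a, -a, a))
    },
    stop_bindsig("unknown ligand template '%s'", name,
                 class = "bindsig_bad_spec"))
}

# minimal residue templates (heavy atoms, CA at origin, ~1.5 A bonds)
.residue_template <- function(res) {
  bb <- data.frame(atom = c("N", "CA", "C", "O"),
                   x = c(-1.20, 0, 1.25, 1.19),
                   y = c(0.85, 0, 0.88, 2.11), z = 0)
  cb <- data.frame(atom = "CB", x = 0, y = -1.20, z = -0.95)
  side <- switch(res,
    ALA = cb,
    SER = rbind(cb, data.frame(atom = "OG", x = 0, y = -2.05, z = 0.18)),
    ASP = rbind(cb,
                data.frame(atom = c("CG", "OD1", "OD2"),
                           x = c(0, 1.09, -1.09),
                           y = c(-2.22, -2.85, -2.85),
                           z = c(0.19, 0.19, 0.19))),
    LYS = rbind(cb,
                data.frame(atom = c("CG", "CD", "CE", "NZ"),
                           x = 0,
                           y = c(-2.45, -3.70, -4.95, -6.15),
                           z = c(-0.07, -0.95, -0.07, -0.92))),
    PHE = {
      cg <- c(0, -2.22, 0.19)
      v <- c(0, -0.6, 0.8); w <- c(1, 0, 0)
      ctr <- cg + 1.39 * v
      ang <- pi / 3 * (0:5)
      ring <- t(vapply(ang, function(t)
        ctr + 1.39 * (cos(t) * -v + sin(t) * w), numeric(3)))
      rbind(cb, data.frame(
        atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
        x = ring[, 1], y = ring[, 2], z = ring[, 3]))
    },
    stop_bindsig("no template for residue '%s'", res,
                 class = "bindsig_bad_spec"))
  out <- rbind(bb, side)
  out$element <- substr(out$atom, 1, 1)
  out$res <- res
  out
}

#' Specification of a synthetic toy complex
#'
#' @param n_pocket_residues number of shell residues (default 8).
#' @param ligand_template \code{"BENZENE"}, \code{"ACETATE"} or
#'   \code{"NEOPENTANE"}.
#' @param placement_radius distance (Angstrom) from the ligand center to
#'   the residue CA shell; must exceed 2 (default 6, a realistic
#'   first-shell contact distance).
#' @param seed integer seed; the generated file is byte-identical for a
#'   given spec.
#' @param n_waters number of decoy waters (default 0).
#' @param add_cofactor add a sulfate decoy het group (default FALSE).
#' @return a \code{csm_toy_spec}.
#' @export
toy_spec <- function(n_pocket_residues = 8L, ligand_template = "BENZENE",
                     placement_radius = 6.0, seed = 1L, n_waters = 0L,
                     add_cofactor = FALSE) {
  if (n_pocket_residues < 1L || placement_radius <= 2)
    stop_bindsig("invalid toy spec (need >= 1 residue and radius > 2 A)",
                 class = "bindsig_bad_spec")
  .ligand_template(ligand_template)  # validates the name
  structure(list(n_pocket_residues = as.integer(n_pocket_residues),
                 ligand_template = ligand_template,
                 placement_radius = placement_radius,
                 seed = as.integer(seed),
                 n_waters = as.integer(n_waters),
                 add_cofactor = isTRUE(add_cofactor)),
            class = "csm_toy_spec")
}

.random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a toy protein-ligand complex as PDB text
#'
#' @param spec a [toy_spec()].
#' @return character vector of PDB lines (REMARK header records the seed
#'   and spec, ATOM records for the shell residues, HETATM records for the
#'   ligand and any decoys).
#' @export
generate_toy_complex <- function(spec = toy_spec()) {
  .with_seed(spec$seed, {
    pool <- c("ALA", "LYS", "ASP", "PHE", "SER")
    resnames <- sample(pool, spec$n_pocket_residues, replace = TRUE)
    lines <- c(
      sprintf("REMARK 999 bindsig toy complex seed %d", spec$seed),
      sprintf("REMARK 999 template %s radius %.2f residues %d",
              spec$ligand_template, spec$placement_radius,
              spec$n_pocket_residues))
    serial <- 0L
    for (i in seq_len(spec$n_pocket_residues)) {
      tmpl <- .residue_template(resnames[i])
      R <- .random_rotation()
      center <- .random_unit() * (spec$placement_radius + runif(1, 0, 2))
      xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(R) +
        rep(center, each = nrow(tmpl))
      for (j in seq_len(nrow(tmpl))) {
        serial <- serial + 1L
        lines <- c(lines, .format_pdb_line("ATOM", serial, tmpl$atom[j], "",
                                           resnames[i], "A", i,
                                           xyz[j, 1], xyz[j, 2], xyz[j, 3],
                                           1, tmpl$element[j]))
      }
    }
    lig <- .ligand_template(spec$ligand_template)
    for (j in seq_len(nrow(lig))) {
      serial <- serial + 1L
      lines <- c(lines, .format_pdb_line("HETATM", serial, lig$atom[j], "",
                                         "LIG", "L", 1L,
                                         lig$x[j], lig$y[j], lig$z[j],
                                         1, lig$element[j]))
    }
    if (spec$add_cofactor) {
      s <- .random_unit() * (2 * spec$placement_radius + 4)
      a <- 1.49 / sqrt(3)
      so4 <- rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a), c(-a, a, -a),
                   c(-a, -a, a)) + rep(s, each = 5)
      nm <- c("S", "O1", "O2", "O3", "O4")
      el <- c("S", "O", "O", "O", "O")
      for (j in 1:5) {
        serial <- serial + 1L
        lines <- c(lines, .format_pdb_line("HETATM", serial, nm[j], "",
                                           "SO4", "L", 2L,
                                           so4[j, 1], so4[j, 2], so4[j, 3],
                                           1, el[j]))
      }
    }
    for (w in seq_len(spec$n_waters)) {
      serial <- serial + 1L
      p <- .random_unit() * (spec$placement_radius + 3 + runif(1, 0, 3))
      lines <- c(lines, .format_pdb_line("HETATM", serial, "O", "", "HOH",
                                         "W", w, p[1], p[2], p[3], 1, "O"))
    }
    c(lines, "END")
  })
}

#' Rigidly transform the coordinates of PDB text
#'
#' Applies \code{x -> R x + t} to every ATOM/HETATM coordinate and
#' rewrites only the coordinate fields; all other bytes are unchanged.
#' Note the PDB coordinate field has three decimals, so round-tripping
#' through text perturbs distances by up to ~2e-3 Angstrom; use
#' [transform_complex()] for exact-precision invariance checks.
#'
#' @param pdb_text character vector of PDB lines (or one string).
#' @param rotation 3x3 orthonormal matrix, det +1 (to 1e-9).
#' @param translation numeric 3-vector.
#' @return character vector of transformed PDB lines.
#' @export
rigid_transform <- function(pdb_text, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  .check_rotation(rotation)
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text))
    strsplit(pdb_text, "\n")[[1]] else pdb_text
  hit <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(hit)) {
    xyz <- as.numeric(c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                        substr(lines[i], 47, 54)))
    new <- as.numeric(rotation %*% xyz + translation)
    substr(lines[i], 31, 54) <- sprintf("%8.3f%8.3f%8.3f",
                                        new[1], new[2], new[3])
  }
  lines
}

#' Declared linear label model over signature features
#'
#' @param features character vector of schema feature names.
#' @param weights numeric weights, one per feature.
#' @param intercept baseline pAffinity (default 2).
#' @param noise_sd Gaussian label noise, pK units (default 0.3).
#' @return a \code{csm_label_model}.
#' @export
label_model <- function(features, weights, intercept = 2, noise_sd = 0.3) {
  stopifnot(length(features) == length(weights), all(is.finite(weights)),
            noise_sd >= 0, is.finite(intercept))
  structure(list(features = features, weights = weights,
                 intercept = intercept, noise_sd = noise_sd),
            class = "csm_label_model")
}

#' Default label model for recovery experiments
#'
#' Weights hydrophobic-contact counts of the cross block at short and
#' medium range, emulating the empirical observation that buried
#' hydrophobic contact area tracks affinity; scaled so synthetic
#' pAffinities span roughly 2-10, like a curated affinity set.
#'
#' @param noise_sd label noise in pK units (default 0.3).
#' @return a \code{csm_label_model}.
#' @export
default_label_model <- function(noise_sd = 0.3) {
  label_model(
    features = c("cross|HYDROPHOBIC:HYDROPHOBIC|6.0",
                 "cross|HYDROPHOBIC:HYDROPHOBIC|10.0",
                 "cross|HYDROPHOBIC:H_ACCEPTOR|8.0"),
    weights = c(0.045, 0.008, 0.02),
    intercept = 2, noise_sd = noise_sd)
}

#' Generate a labeled synthetic dataset
#'
#' Draws \code{n} toy complexes with varied geometry (shell radius and
#' residue count jittered around the spec) and labels each with
#' \code{intercept + weights . features + N(0, noise_sd)}, the features
#' taken from the complex's own signature, so the mapping from structure
#' to label is known exactly.
#'
#' @param n number of complexes (>= 10).
#' @param spec base [toy_spec()]; per-complex seeds are derived from
#'   \code{seed}, and the spec's radius/size are jittered.
#' @param model a [label_model()]; default [default_label_model()].
#' @param seed master seed for geometry variation, per-complex seeds and
#'   label noise.
#' @param config [signature_config()] used for featurization.
#' @return list with \code{ids}, \code{pdb_texts}, \code{X} (signature
#'   matrix), \code{y} (pAffinity), \code{true_signal} (labels before
#'   noise), \code{model}, \code{config}.
#' @export
generate_labeled_dataset <- function(n = 200L, spec = toy_spec(),
                                     model = default_label_model(),
                                     seed = 1L,
                                     config = signature_config()) {
  if (n < 10L)
    stop_bindsig("need n >= 10 synthetic complexes", class = "bindsig_bad_spec")
  schema <- signature_schema(config)
  if (!all(model$features %in% schema))
    stop_bindsig("label model references features outside the schema: %s",
                 paste(setdiff(model$features, schema), collapse = ", "),
                 class = "bindsig_bad_spec")
  draws <- .with_seed(seed, list(
    seeds = sample.int(2147483646L, n),
    radii = spec$placement_radius + runif(n, -1.5, 1.5),
    sizes = pmax(3L, spec$n_pocket_residues +
                   sample(-2:3, n, replace = TRUE)),
    noise = rnorm(n, 0, model$noise_sd)))

  table <- load_typing_table(config$typing_table_version)
  texts <- vector("list", n)
  X <- matrix(NA_real_, n, length(schema), dimnames = list(NULL, schema))
  for (i in seq_len(n)) {
    sp <- toy_spec(n_pocket_residues = draws$sizes[i],
                   ligand_template = spec$ligand_template,
                   placement_radius = draws$radii[i],
                   seed = draws$seeds[i],
                   n_waters = spec$n_waters,
                   add_cofactor = spec$add_cofactor)
    texts[[i]] <- generate_toy_complex(sp)
    cplx <- parse_complex(texts[[i]], source_id = sprintf("toy%04d", i))
    lig <- select_ligand(cplx, ligand_key = "L:LIG:1", quiet = TRUE)
    X[i, ] <- as.numeric(build_signature(cplx, lig, config,
                                         typing_table = table))
  }
  signal <- model$intercept +
    as.numeric(X[, model$features, drop = FALSE] %*% model$weights)
  list(ids = sprintf("toy%04d", seq_len(n)),
       pdb_texts = texts,
       X = X,
       y = signal + draws$noise,
       true_signal = signal,
       model = model,
       config = config)
}
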