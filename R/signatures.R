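#' @name signatures
#' @title Cutoff-scanning structural signatures
#'
#' @description
#' The complex is modelled as a graph whose nodes are heavy atoms labelled
#' with pharmacophore types and whose edges are interatomic distances.  For
#' every unordered pair of the eight types (36 combinations) and every
#' cutoff on a distance grid, the signature records the number of atom
#' pairs at distance less than or equal to the cutoff -- a cumulative
#' distribution of pairwise distances per type pair.  Two blocks are
#' computed: pairs among the binding-pocket atoms (protein heavy atoms
#' within \code{pocket_radius} of any ligand atom) and protein-ligand cross
#' pairs (pocket atom x ligand atom).  The ligand descriptor block is
#' appended, giving one fixed-schema feature vector per complex.
NULL

#' Signature configuration
#'
#' @param pocket_radius pocket inclusion radius in Angstrom (closed
#'   boundary); default 8.
#' @param d_min,d_max,step distance-cutoff grid in Angstrom; default 1.0
#'   to 30.0 in steps of 0.5 (59 cutoffs), the dense short-to-medium-range
#'   scan conventional for cutoff-scanning signatures.
#' @param heavy_atoms_only ignore hydrogens (default TRUE; deposited PDB
#'   files carry them inconsistently).
#' @param normalize \code{"RAW_COUNTS"} (default) keeps cumulative counts;
#'   \code{"PER_PAIRCOUNT"} divides each block by its total number of
#'   counted atom pairs for scale robustness.
#' @param typing_table_version pharmacophore table version (see
#'   [load_typing_table()]).
#' @param bond_tolerance ligand bond-perception slack in Angstrom.
#' @return a \code{csm_signature_config}.
#' @export
signature_config <- function(pocket_radius = 8.0, d_min = 1.0, d_max = 30.0,
                             step = 0.5, heavy_atoms_only = TRUE,
                             normalize = c("RAW_COUNTS", "PER_PAIRCOUNT"),
                             typing_table_version = "v1",
                             bond_tolerance = 0.45) {
  normalize <- match.arg(normalize)
  stopifnot(pocket_radius > 0, d_min > 0, d_max > d_min, step > 0)
  cutoffs <- seq(d_min, d_max, by = step)
  if (length(cutoffs) < 2L)
    stop_bindsig("cutoff grid must have at least 2 points",
                 class = "bindsig_bad_config")
  cfg <- list(pocket_radius = pocket_radius, d_min = d_min, d_max = d_max,
              step = step, cutoffs = cutoffs,
              heavy_atoms_only = heavy_atoms_only, normalize = normalize,
              typing_table_version = typing_table_version,
              bond_tolerance = bond_tolerance)
  cfg$config_hash <- .str_hash(paste(
    "pocket_radius", pocket_radius, "grid", d_min, d_max, step,
    "heavy", heavy_atoms_only, "norm", normalize,
    "table", typing_table_version, "bondtol", bond_tolerance))
  structure(cfg, class = "csm_signature_config")
}

# Polynomial rolling hash (mod 2^31 - 1), hex-encoded; used to bind
# signatures, schemas and models to the configuration that produced them.
.str_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' The 36 unordered pharmacophore class pairs, in schema order
#' @return character vector \code{"CLASSA:CLASSB"} with A before B in the
#'   ordinal order of [pharm_types()].
#' @export
class_pairs <- function() {
  ty <- pharm_types()
  out <- character(0)
  for (i in seq_along(ty))
    for (j in i:length(ty))
      out <- c(out, paste(ty[i], ty[j], sep = ":"))
  out
}

.canonical_pair <- function(a, b) {
  ord <- match(c(a, b), pharm_types())
  if (ord[1] <= ord[2]) paste(a, b, sep = ":") else paste(b, a, sep = ":")
}

# All unique canonical class pairs formed by two class sets.
.expand_class_sets <- function(set_a, set_b) {
  unique(unlist(lapply(set_a, function(a)
    vapply(set_b, function(b) .canonical_pair(a, b), character(1)))))
}

#' Extract the binding-pocket atoms
#'
#' Protein heavy atoms whose minimum distance to any ligand heavy atom is
#' at most \code{pocket_radius} (closed boundary: an atom exactly at the
#' radius is included), returned in file order.
#'
#' @param complex a \code{csm_complex}.
#' @param ligand a \code{csm_ligand}.
#' @param config a \code{csm_signature_config}.
#' @return data frame of pocket atom records.
#' @export
extract_pocket <- function(complex, ligand, config = signature_config()) {
  prot <- protein_atoms(complex)
  if (config$heavy_atoms_only) prot <- prot[!prot$is_hydrogen, , drop = FALSE]
  lig <- ligand$atoms
  if (config$heavy_atoms_only) lig <- lig[!lig$is_hydrogen, , drop = FALSE]
  if (nrow(prot) == 0L)
    stop_bindsig("complex '%s' has no protein atoms", complex$source_id,
                 class = "bindsig_empty_pocket")
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm_ <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rep(1, nrow(lm_))) +
    outer(rep(1, nrow(pm)), rowSums(lm_^2)) - 2 * pm %*% t(lm_)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  keep <- mind <= config$pocket_radius
  if (!any(keep))
    stop_bindsig("ligand appears isolated from protein in '%s' (min distance %.2f A > pocket radius %.2f A)",
                 complex$source_id, min(mind), config$pocket_radius,
                 class = "bindsig_empty_pocket")
  prot[keep, , drop = FALSE]
}

#' Cumulative cutoff scan of labelled atom pairs
#'
#' Given atom pairs annotated with a canonical class pair and a distance,
#' counts for every class pair and every cutoff \code{c} on the grid the
#' pairs with distance \code{<= c}.  Pairs beyond \code{d_max} contribute
#' nowhere; counts are non-decreasing along the grid.
#'
#' @param pairs data frame with columns \code{class_pair} (as produced by
#'   [class_pairs()]) and \code{distance} (Angstrom, non-negative).
#' @param config a \code{csm_signature_config}.
#' @return integer matrix, 36 class pairs x cutoffs, dimnames set.
#' @export
cutoff_scan <- function(pairs, config = signature_config()) {
  cps <- class_pairs()
  cutoffs <- config$cutoffs
  counts <- matrix(0L, nrow = length(cps), ncol = length(cutoffs),
                   dimnames = list(cps, sprintf("%.1f", cutoffs)))
  if (nrow(pairs)) {
    if (any(pairs$distance < 0))
      stop_bindsig("negative pair distance", class = "bindsig_bad_distance")
    if (!all(pairs$class_pair %in% cps))
      stop_bindsig("unknown class pair(s): %s",
                   paste(setdiff(pairs$class_pair, cps), collapse = ", "),
                   class = "bindsig_bad_pair")
    keep <- pairs$distance <= config$d_max
    if (any(keep)) {
      d <- pairs$distance[keep]
      cp <- pairs$class_pair[keep]
      # first grid index whose cutoff is >= distance (ties included: d <= c)
      lo <- findInterval(d, cutoffs)
      at <- ifelse(lo >= 1 & cutoffs[pmax(lo, 1)] == d, lo, lo + 1L)
      inc <- table(factor(cp, levels = cps), factor(at, levels = seq_along(cutoffs)))
      counts <- t(apply(unclass(inc), 1, cumsum))
      dimnames(counts) <- list(cps, sprintf("%.1f", cutoffs))
      storage.mode(counts) <- "integer"
    }
  }
  counts
}

#' Build the full structural signature of a complex
#'
#' Concatenates, in fixed order, the pocket-internal cutoff-scan block
#' (pairs among pocket atoms), the protein-ligand cross block (pocket atom
#' x ligand atom pairs) and the ligand descriptor block.  The schema names
#' every position as \code{block|CLASSA:CLASSB|cutoff} or
#' \code{desc|name}; the configuration hash binds the vector to its
#' configuration so train/predict skew is detectable.
#'
#' @param complex a \code{csm_complex}.
#' @param ligand a \code{csm_ligand}.
#' @param config a \code{csm_signature_config}.
#' @param descriptors optional precomputed [compute_descriptors()] vector.
#' @param typing_table optional preloaded [load_typing_table()].
#' @param reference_schema optional character vector; if the computed
#'   schema differs an error is raised (guards train/predict skew).
#' @return a \code{csm_signature}: named numeric vector with attributes
#'   \code{config_hash}, \code{n_pocket_atoms} and \code{ligand_key}.
#' @export
build_signature <- function(complex, ligand, config = signature_config(),
                            descriptors = NULL, typing_table = NULL,
                            reference_schema = NULL) {
  if (is.null(typing_table))
    typing_table <- load_typing_table(config$typing_table_version)
  pocket <- extract_pocket(complex, ligand, config)
  lig <- ligand$atoms
  if (config$heavy_atoms_only) lig <- lig[!lig$is_hydrogen, , drop = FALSE]

  bonds <- perceive_bonds(ligand, bond_tolerance = config$bond_tolerance)
  if (is.null(descriptors)) descriptors <- compute_descriptors(ligand, bonds)

  pocket_classes <- .type_protein_atoms(pocket, typing_table)
  ligand_classes <- .type_ligand_atoms(bonds)

  pxyz <- as.matrix(pocket[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])

  pocket_block <- cutoff_scan(.internal_pairs(pxyz, pocket_classes), config)
  cross_block <- cutoff_scan(.cross_pairs(pxyz, pocket_classes,
                                          lxyz, ligand_classes), config)

  if (config$normalize == "PER_PAIRCOUNT") {
    np <- nrow(pxyz) * (nrow(pxyz) - 1) / 2
    nc <- nrow(pxyz) * nrow(lxyz)
    pocket_block <- pocket_block / max(1, np)
    cross_block <- cross_block / max(1, nc)
  }

  cuts <- sprintf("%.1f", config$cutoffs)
  schema <- c(
    paste("pocket", rep(class_pairs(), each = length(cuts)), cuts, sep = "|"),
    paste("cross",  rep(class_pairs(), each = length(cuts)), cuts, sep = "|"),
    paste("desc", descriptor_names(), sep = "|"))
  values <- c(as.numeric(t(pocket_block)), as.numeric(t(cross_block)),
              as.numeric(descriptors))
  names(values) <- schema

  if (!is.null(reference_schema) && !identical(schema, reference_schema)) {
    if (length(schema) != length(reference_schema)) {
      stop_bindsig("signature schema mismatch vs reference: %d features vs %d",
                   length(schema), length(reference_schema),
                   class = "bindsig_schema_mismatch")
    }
    diff <- which(schema != reference_schema)[1]
    stop_bindsig("signature schema mismatch vs reference (first difference at position %d: '%s' vs '%s')",
                 diff, schema[diff], reference_schema[diff],
                 class = "bindsig_schema_mismatch")
  }

  structure(values,
            config_hash = config$config_hash,
            n_pocket_atoms = nrow(pocket),
            ligand_key = ligand$key,
            class = "csm_signature")
}

# pairs among one atom set: canonical class pairs x distances
.internal_pairs <- function(xyz, class_sets) {
  n <- nrow(xyz)
  if (n < 2L) return(data.frame(class_pair = character(0), distance = numeric(0)))
  sig <- vapply(class_sets, function(s) paste(sort(s), collapse = ","), character(1))
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  .expand_pairs(sig[idx[, 1]], sig[idx[, 2]], d[upper.tri(d)], class_sets, sig)
}

.cross_pairs <- function(axyz, a_classes, bxyz, b_classes) {
  na <- nrow(axyz); nb <- nrow(bxyz)
  if (na == 0L || nb == 0L)
    return(data.frame(class_pair = character(0), distance = numeric(0)))
  siga <- vapply(a_classes, function(s) paste(sort(s), collapse = ","), character(1))
  sigb <- vapply(b_classes, function(s) paste(sort(s), collapse = ","), character(1))
  d2 <- outer(rowSums(axyz^2), rep(1, nb)) + outer(rep(1, na), rowSums(bxyz^2)) -
    2 * axyz %*% t(bxyz)
  grid <- expand.grid(i = seq_len(na), j = seq_len(nb))
  .expand_pairs(siga[grid$i], sigb[grid$j], sqrt(pmax(as.numeric(d2), 0)),
                c(a_classes, b_classes), c(siga, sigb))
}

# Expand atom pairs (by class-set signature) into one row per canonical
# class pair; a pair of multi-label atoms increments each unique
# combination exactly once.
.expand_pairs <- function(sig_i, sig_j, distances, class_sets, sig_all) {
  set_of <- lapply(split(seq_along(sig_all), sig_all), function(ix)
    class_sets[[ix[1]]])
  key <- paste(pmin(sig_i, sig_j), pmax(sig_i, sig_j), sep = "\r")
  combos <- lapply(split(seq_along(key), key)[unique(key)], function(rows) {
    parts <- strsplit(key[rows[1]], "\r", fixed = TRUE)[[1]]
    list(rows = rows,
         pairs = .expand_class_sets(set_of[[parts[1]]], set_of[[parts[2]]]))
  })
  out_cp <- character(0); out_d <- numeric(0)
  for (cm in combos) {
    out_cp <- c(out_cp, rep(cm$pairs, each = length(cm$rows)))
    out_d <- c(out_d, rep(distances[cm$rows], times = length(cm$pairs)))
  }
  data.frame(class_pair = out_cp, distance = out_d,
             stringsAsFactors = FALSE)
}

#' Schema of a signature under a configuration
#'
#' The ordered feature names a [build_signature()] call will produce,
#' available without any structure (used to declare synthetic label
#' models and to validate stored models).
#'
#' @param config a \code{csm_signature_config}.
#' @return character vector of feature names.
#' @export
signature_schema <- function(config = signature_config()) {
  cuts <- sprintf("%.1f", config$cutoffs)
  c(paste("pocket", rep(class_pairs(), each = length(cuts)), cuts, sep = "|"),
    paste("cross",  rep(class_pairs(), each = length(cuts)), cuts, sep = "|"),
    paste("desc", descriptor_names(), sep = "|"))
}

#' @export
print.csm_signature <- function(x, ...) {
  cat(sprintf("<csm_signature: %d features (config %s), %d pocket atoms, ligand %s>\n",
              length(x), attr(x, "config_hash"),
              attr(x, "n_pocket_atoms"), attr(x, "ligand_key")))
  invisible(x)
}
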