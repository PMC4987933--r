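#' @name dataset
#' @title Affinity index parsing and split protocol
#'
#' @description
#' Training data arrive as a PDBbind-style plain-text index: one line per
#' complex with PDB code, resolution, deposition year, the printed
#' -log(Kd/Ki) value and the raw affinity string (e.g. \code{Kd=50uM}).
#' Only Kd and Ki entries are admitted by default (IC50 depends on assay
#' setup and is excluded from the refined-set protocol); censored
#' affinities (\code{<}, \code{>}, \code{~}) are excluded from training by
#' default because censored labels corrupt regression.  The split protocol
#' is: complexes of the refined set that are not in the core set form the
#' training set, the core set is the blind test; cross-validation folds
#' are a seeded shuffle of the training ids partitioned round-robin.
NULL

.UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9,
                   pM = 1e-12, fM = 1e-15)

#' Convert an affinity string to -log10(molar)
#'
#' @param raw string of the form \code{Kind?value?unit} where Kind is
#'   \code{Kd}, \code{Ki} or \code{IC50}, \code{?} is one of
#'   \code{= < > ~}, and unit is one of M, mM, uM, nM, pM, fM.
#' @return list with \code{p_affinity} (= -log10 of the value in molar),
#'   \code{kind} and \code{qualifier}.
#' @examples
#' affinity_to_plog("Kd=1nM")$p_affinity   # 9
#' affinity_to_plog("Ki=10uM")$p_affinity  # 5
#' @export
affinity_to_plog <- function(raw) {
  m <- regmatches(raw, regexec(
    "^\\s*(Kd|Ki|IC50)\\s*([=<>~])\\s*([0-9.eE+-]+)\\s*(fM|pM|nM|uM|mM|M)\\s*$",
    raw, ignore.case = TRUE))[[1]]
  if (length(m) == 0L)
    stop_bindsig("cannot parse affinity string '%s'", raw,
                 class = "bindsig_affinity_error")
  kind <- c(kd = "Kd", ki = "Ki", ic50 = "IC50")[[tolower(m[2])]]
  value <- suppressWarnings(as.numeric(m[4]))
  unit <- m[5]
  unit <- names(.UNIT_FACTORS)[match(tolower(unit), tolower(names(.UNIT_FACTORS)))]
  if (is.na(value) || is.na(unit))
    stop_bindsig("cannot parse affinity string '%s'", raw,
                 class = "bindsig_affinity_error")
  if (value <= 0)
    stop_bindsig("non-positive affinity value in '%s'", raw,
                 class = "bindsig_affinity_error")
  list(p_affinity = -log10(value * .UNIT_FACTORS[[unit]]),
       kind = kind, qualifier = m[3])
}

#' Format a pAffinity back as a Kd string (round-trip helper)
#' @param p pAffinity value, -log10(molar).
#' @param kind \code{"Kd"} or \code{"Ki"}.
#' @return string such as \code{"Kd=5e-09M"}.
#' @export
plog_to_affinity <- function(p, kind = "Kd") {
  sprintf("%s=%.15gM", kind, 10^(-p))
}

#' Parse a PDBbind-style index file
#'
#' @param index_text character: file content (single string, vector of
#'   lines, or a file path that exists on disk).
#' @param allow_ic50 admit IC50 entries as pseudo-pK (default FALSE).
#' @param include_qualified keep censored (\code{< > ~}) entries (default
#'   FALSE).
#' @return data frame with columns \code{pdb_code} (lowercase),
#'   \code{resolution}, \code{year}, \code{p_affinity},
#'   \code{affinity_kind}, \code{qualifier}, \code{raw_string}.  The
#'   printed -log column is authoritative; a disagreement of more than
#'   0.02 log units with the parsed affinity string raises a data-quality
#'   warning.  Skipped IC50/censored entries are reported via a message.
#' @export
parse_index <- function(index_text, allow_ic50 = FALSE,
                        include_qualified = FALSE) {
  lines <- if (length(index_text) == 1L && !grepl("\n", index_text) &&
               file.exists(index_text)) readLines(index_text)
           else if (length(index_text) == 1L) strsplit(index_text, "\n")[[1]]
           else index_text
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- list(); n_ic50 <- 0L; n_qual <- 0L
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 5L)
      stop_bindsig("malformed index line %d: '%s'", i, lines[i],
                   class = "bindsig_index_error")
    resolution <- suppressWarnings(as.numeric(f[2]))
    year <- suppressWarnings(as.integer(f[3]))
    printed <- suppressWarnings(as.numeric(f[4]))
    if (is.na(printed) || is.na(year))
      stop_bindsig("malformed index line %d: '%s'", i, lines[i],
                   class = "bindsig_index_error")
    aff <- affinity_to_plog(f[5])
    if (aff$kind == "IC50" && !allow_ic50) { n_ic50 <- n_ic50 + 1L; next }
    if (aff$qualifier != "=" && !include_qualified) { n_qual <- n_qual + 1L; next }
    if (abs(printed - aff$p_affinity) > 0.02)
      warning(sprintf("index line %d: printed -log value %.2f disagrees with %s (-log = %.3f)",
                      i, printed, f[5], aff$p_affinity), call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      pdb_code = tolower(f[1]), resolution = resolution, year = year,
      p_affinity = printed, affinity_kind = aff$kind,
      qualifier = aff$qualifier, raw_string = f[5],
      stringsAsFactors = FALSE)
  }
  if (n_ic50 + n_qual > 0L)
    message(sprintf("parse_index: skipped %d IC50 and %d censored entr%s",
                    n_ic50, n_qual, if (n_ic50 + n_qual == 1L) "y" else "ies"))
  if (length(rows) == 0L)
    stop_bindsig("index contains no admissible records",
                 class = "bindsig_index_error")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Refined-minus-core train/test split
#'
#' Training set = refined-set complexes not present in the core set;
#' blind-test set = core-set complexes present in the refined set.  Core
#' ids absent from the records are warned about and dropped from the test
#' set.
#'
#' @param records data frame from [parse_index()] (or anything with a
#'   \code{pdb_code} column).
#' @param core_ids character vector of core-set PDB codes.
#' @return a \code{csm_split}: list with \code{train_ids} and
#'   \code{test_ids} (disjoint).
#' @export
split_train_test <- function(records, core_ids) {
  ids <- tolower(records$pdb_code)
  core_ids <- tolower(core_ids)
  missing <- setdiff(core_ids, ids)
  if (length(missing))
    warning(sprintf("%d core id(s) absent from the index (excluded from test): %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  train <- setdiff(ids, core_ids)
  test <- intersect(core_ids, ids)
  if (length(train) == 0L || length(test) == 0L)
    stop_bindsig("degenerate split: %d train / %d test",
                 length(train), length(test), class = "bindsig_split_error")
  message(sprintf("split_train_test: %d train / %d test", length(train),
                  length(test)))
  structure(list(train_ids = train, test_ids = test), class = "csm_split")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Seeded k-fold partition
#'
#' Ids are shuffled under the seed and dealt round-robin into k folds, so
#' fold sizes differ by at most one and the partition is reproducible.
#'
#' @param ids vector of ids (or indices).
#' @param k number of folds, \code{2 <= k <= length(ids)}.
#' @param seed integer seed.
#' @return list of k id vectors partitioning \code{ids}.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L) {
  n <- length(ids)
  if (k < 2L || k > n)
    stop_bindsig("k = %d invalid for %d ids", k, n,
                 class = "bindsig_fold_error")
  perm <- .with_seed(seed, sample(ids))
  lapply(seq_len(k), function(i) perm[seq(i, n, by = k)])
}
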