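#' @name cli
#' @title Batch prediction and the train/evaluate pipeline
#'
#' @description
#' The command-line surface mirrors a scoring-server workflow: a directory
#' (or archive) of PDB complexes goes in, a tab-separated table of
#' predicted affinities comes out; or an affinity index plus a structure
#' directory goes in and a trained model with cross-validation and
#' blind-test reports comes out.  Per-file failures never abort a batch;
#' they are collected and reported alongside the successes.  The thin
#' executable wrapper lives at \code{system.file("cli", "bindsig",
#' package = "bindsig")}.
NULL

.expand_inputs <- function(inputs) {
  out <- character(0)
  for (p in inputs) {
    if (dir.exists(p)) {
      out <- c(out, list.files(p, pattern = "\\.(pdb|ent)$",
                               full.names = TRUE))
    } else if (grepl("\\.zip$", p)) {
      ex <- file.path(tempfile("bindsig_zip"), "x")
      utils::unzip(p, exdir = ex)
      out <- c(out, list.files(ex, pattern = "\\.(pdb|ent)$",
                               recursive = TRUE, full.names = TRUE))
    } else if (grepl("\\.(tar\\.gz|tgz|tar)$", p)) {
      ex <- file.path(tempfile("bindsig_tar"), "x")
      utils::untar(p, exdir = ex)
      out <- c(out, list.files(ex, pattern = "\\.(pdb|ent)$",
                               recursive = TRUE, full.names = TRUE))
    } else if (file.exists(p)) {
      out <- c(out, p)
    } else {
      stop_bindsig("input '%s' does not exist", p, class = "bindsig_bad_input")
    }
  }
  sort(out)
}

#' Predict affinities for a batch of complexes
#'
#' @param inputs paths: PDB files, directories, or zip/tar archives of
#'   PDB files.
#' @param model a \code{csm_model} or the path of a saved model file.
#' @param config optional [signature_config()]; defaults to the
#'   configuration stored in the model.
#' @param out_tsv optional path; when given, predictions are written as a
#'   UTF-8 tab-separated table with \code{#}-prefixed metadata lines.
#' @param ligand_key optional het-group key forwarded to
#'   [select_ligand()].
#' @return list with \code{predictions} (data frame: \code{complex_id,
#'   predicted_p_affinity, predictive_sd, ligand_key, n_pocket_atoms})
#'   and \code{failures} (data frame: \code{complex_id, reason}).  Errors
#'   only if no complex succeeds.
#' @export
predict_batch <- function(inputs, model, config = NULL, out_tsv = NULL,
                          ligand_key = NULL) {
  if (is.character(model)) model <- load_model(model)
  cfg <- config %||% model$signature_config %||% signature_config()
  files <- .expand_inputs(inputs)
  if (length(files) == 0L)
    stop_bindsig("no PDB files found in the given inputs",
                 class = "bindsig_bad_input")
  table <- load_typing_table(cfg$typing_table_version)

  rows <- list(); fails <- list()
  for (f in files) {
    id <- sub("\\.(pdb|ent)$", "", basename(f))
    res <- tryCatch({
      cplx <- parse_complex(readLines(f, warn = FALSE), source_id = id)
      lig <- select_ligand(cplx, ligand_key = ligand_key, quiet = TRUE)
      sig <- build_signature(cplx, lig, cfg, typing_table = table,
                             reference_schema = model$schema)
      p <- predict(model, sig)
      data.frame(complex_id = id,
                 predicted_p_affinity = p$mean,
                 predictive_sd = p$sd,
                 ligand_key = lig$key,
                 n_pocket_atoms = attr(sig, "n_pocket_atoms"),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error"))
      fails[[length(fails) + 1L]] <- data.frame(complex_id = id,
                                                reason = conditionMessage(res),
                                                stringsAsFactors = FALSE)
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    stop_bindsig("no complex could be processed (%d failure(s); first: %s)",
                 length(fails), fails[[1]]$reason,
                 class = "bindsig_batch_error")
  predictions <- do.call(rbind, rows)
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(complex_id = character(0), reason = character(0))

  if (!is.null(out_tsv)) {
    hdr <- c(sprintf("# bindsig predictions (-log10(Kd|Ki))"),
             sprintf("# signature config %s", cfg$config_hash),
             sprintf("# model schema %s, trained n = %d", model$schema_hash,
                     model$metadata$n))
    body <- c(paste(colnames(predictions), collapse = "\t"),
              apply(predictions, 1, function(r)
                paste(c(r[["complex_id"]],
                        sprintf("%.4f", as.numeric(r[["predicted_p_affinity"]])),
                        sprintf("%.4f", as.numeric(r[["predictive_sd"]])),
                        r[["ligand_key"]], r[["n_pocket_atoms"]]),
                      collapse = "\t")))
    ftr <- if (nrow(failures))
      c("# failures:", sprintf("# %s\t%s", failures$complex_id,
                               failures$reason)) else character(0)
    writeLines(c(hdr, body, ftr), out_tsv, useBytes = TRUE)
  }
  list(predictions = predictions, failures = failures)
}

#' Featurize, split, cross-validate and blind-test in one call
#'
#' @param index_file PDBbind-style index: path or text (see
#'   [parse_index()]).
#' @param core_ids core-set PDB codes: character vector or path of a
#'   one-id-per-line file.
#' @param structures_dir directory containing \code{<pdb_code>.pdb}
#'   files.
#' @param config a [signature_config()].
#' @param gp a [gp_config()].
#' @param k cross-validation folds (default 10).
#' @param seed fold seed.
#' @param out_dir optional directory: writes \code{model.rds},
#'   \code{cv_predictions.tsv} and \code{reports.tsv}.
#' @param max_missing_frac abort when more than this fraction of indexed
#'   structures is absent (default 0.5).
#' @return list with \code{model}, \code{cv} (from [cross_validate()]),
#'   \code{blind_report}, \code{blind_predictions} and \code{split}.
#' @export
run_pipeline <- function(index_file, core_ids, structures_dir,
                         config = signature_config(), gp = gp_config(),
                         k = 10L, seed = 1L, out_dir = NULL,
                         max_missing_frac = 0.5) {
  records <- parse_index(index_file)
  if (length(core_ids) == 1L && file.exists(core_ids))
    core_ids <- readLines(core_ids)
  core_ids <- tolower(trimws(core_ids))
  core_ids <- core_ids[nzchar(core_ids) & !startsWith(core_ids, "#")]

  paths <- file.path(structures_dir, paste0(records$pdb_code, ".pdb"))
  present <- file.exists(paths)
  if (any(!present)) {
    warning(sprintf("missing structure file(s) for: %s",
                    paste(records$pdb_code[!present], collapse = ", ")),
            call. = FALSE)
    if (mean(!present) > max_missing_frac)
      stop_bindsig("%.0f%% of indexed structures are missing (threshold %.0f%%)",
                   100 * mean(!present), 100 * max_missing_frac,
                   class = "bindsig_bad_input")
  }
  records <- records[present, , drop = FALSE]
  paths <- paths[present]

  table <- load_typing_table(config$typing_table_version)
  schema <- signature_schema(config)
  X <- matrix(NA_real_, nrow(records), length(schema),
              dimnames = list(records$pdb_code, schema))
  for (i in seq_len(nrow(records))) {
    cplx <- parse_complex(readLines(paths[i], warn = FALSE),
                          source_id = records$pdb_code[i])
    lig <- select_ligand(cplx, quiet = TRUE)
    X[i, ] <- as.numeric(build_signature(cplx, lig, config,
                                         typing_table = table))
  }
  y <- records$p_affinity

  split <- split_train_test(records, core_ids)
  tr <- match(split$train_ids, records$pdb_code)
  te <- match(split$test_ids, records$pdb_code)

  cv <- cross_validate(X[tr, , drop = FALSE], y[tr], k = k, config = gp,
                       seed = seed)
  fit <- train_model(X[tr, , drop = FALSE], y[tr], config = gp,
                     signature_config = config)
  bp <- predict(fit, X[te, , drop = FALSE])
  blind_report <- evaluation_report(y[te], bp$mean, label = "blind test")
  blind_predictions <- data.frame(pdb_code = records$pdb_code[te],
                                  observed = y[te], predicted = bp$mean,
                                  sd = bp$sd, stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(fit, file.path(out_dir, "model.rds"))
    utils::write.table(cv$predictions,
                       file.path(out_dir, "cv_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep_df <- data.frame(
      split = c(cv$report$label, blind_report$label),
      n = c(cv$report$n, blind_report$n),
      pearson_r = c(cv$report$pearson_r, blind_report$pearson_r),
      spearman_rho = c(cv$report$spearman_rho, blind_report$spearman_rho),
      residual_sd = c(cv$report$residual_sd, blind_report$residual_sd))
    utils::write.table(rep_df, file.path(out_dir, "reports.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(model = fit, cv = cv, blind_report = blind_report,
       blind_predictions = blind_predictions, split = split)
}
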