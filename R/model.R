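#' @name model
#' @title Gaussian-process regression of binding affinity
#'
#' @description
#' An exact Gaussian-process regressor maps signature vectors to
#' pAffinity.  The default kernel is a squared-exponential (RBF) plus
#' white noise; hyperparameters (length scale, signal variance, noise
#' variance) are optimized by maximizing the log marginal likelihood from
#' configurable initializations, with the length scale initialized by the
#' median heuristic over pairwise feature distances.  Features are
#' standardized to zero mean / unit variance on the training data only;
#' the target is left in pK units (already well scaled, typically 2-12).
#' At the training sizes of affinity benchmarks (a few thousand) the
#' O(n^3) exact GP is tractable and no sparse approximation is used.
NULL

#' Gaussian-process configuration
#'
#' @param kernel \code{"RBF_PLUS_WHITE"} (default), \code{"RBF"} (tiny
#'   fixed jitter instead of an optimized noise term) or
#'   \code{"MATERN52"} (Matern 5/2 plus white noise).
#' @param length_scale_init initial length scale; \code{NULL} (default)
#'   uses the median pairwise distance of the standardized features.
#' @param noise_init initial noise standard deviation, pK units.
#' @param normalize_target center/scale the target (default FALSE).
#' @param feature_standardize standardize features (default TRUE).
#' @param seed integer seed recorded in the model metadata.
#' @return a \code{csm_gp_config}.
#' @export
gp_config <- function(kernel = c("RBF_PLUS_WHITE", "RBF", "MATERN52"),
                      length_scale_init = NULL, noise_init = 0.1,
                      normalize_target = FALSE, feature_standardize = TRUE,
                      seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.null(length_scale_init) && length_scale_init <= 0)
    stop_bindsig("length_scale_init must be positive", class = "bindsig_bad_config")
  if (noise_init <= 0)
    stop_bindsig("noise_init must be positive", class = "bindsig_bad_config")
  structure(list(kernel = kernel, length_scale_init = length_scale_init,
                 noise_init = noise_init, normalize_target = normalize_target,
                 feature_standardize = feature_standardize,
                 seed = as.integer(seed)),
            class = "csm_gp_config")
}

.MODEL_FORMAT_VERSION <- 1L

.kernel_matrix <- function(D2, kernel, ls, sf2) {
  if (kernel == "MATERN52") {
    r <- sqrt(pmax(D2, 0)) / ls
    sf2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  } else {
    sf2 * exp(-D2 / (2 * ls^2))
  }
}

.sq_dists <- function(A, B = A) {
  out <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  pmax(out, 0)
}

# negative log marginal likelihood at log-parameters theta
.gp_nlml <- function(theta, D2, yc, kernel, fixed_noise) {
  ls <- exp(theta[1]); sf2 <- exp(theta[2])^2
  sn2 <- if (is.null(fixed_noise)) exp(theta[3])^2 else fixed_noise^2
  n <- length(yc)
  K <- .kernel_matrix(D2, kernel, ls, sf2) + diag(sn2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  as.numeric(0.5 * crossprod(yc, alpha) + sum(log(diag(L))) +
               n / 2 * log(2 * pi))
}

#' Train the affinity regressor
#'
#' @param X numeric matrix (complexes x features) with column names equal
#'   to the signature schema, or a list of \code{csm_signature} vectors
#'   sharing one configuration.
#' @param y numeric vector of pAffinity values, one per row of \code{X}.
#' @param config a [gp_config()].
#' @param signature_config the \code{csm_signature_config} the features
#'   were built under; its hash and typing-table version are stored so
#'   train/predict skew is detectable.
#' @return a \code{csm_model} holding the fitted GP state, feature schema,
#'   standardization parameters and training metadata; usable with
#'   [predict.csm_model()] and round-trippable via [save_model()].
#' @export
train_model <- function(X, y, config = gp_config(),
                        signature_config = NULL) {
  if (is.list(X) && !is.matrix(X)) {
    hashes <- unique(vapply(X, function(s) attr(s, "config_hash") %||% "",
                            character(1)))
    if (length(hashes) > 1L)
      stop_bindsig("signatures built under different configurations: %s",
                   paste(hashes, collapse = ", "),
                   class = "bindsig_schema_mismatch")
    schemas <- unique(vapply(X, function(s) paste(names(s), collapse = "|"),
                             character(1)))
    if (length(schemas) > 1L)
      stop_bindsig("signatures with differing schemas",
                   class = "bindsig_schema_mismatch")
    X <- do.call(rbind, lapply(X, as.numeric)) |>
      `colnames<-`(names(X[[1]]))
  }
  n <- nrow(X)
  if (n != length(y))
    stop_bindsig("X has %d rows but y has %d values", n, length(y),
                 class = "bindsig_bad_input")
  if (n < 5L)
    stop_bindsig("need at least 5 training complexes, got %d", n,
                 class = "bindsig_bad_input")
  if (sd(y) == 0)
    stop_bindsig("degenerate constant target", class = "bindsig_bad_input")
  if (is.null(colnames(X)))
    stop_bindsig("X must carry the feature schema as column names",
                 class = "bindsig_schema_mismatch")

  if (config$feature_standardize) {
    mu <- colMeans(X)
    sigma <- apply(X, 2, sd)
    sigma[sigma == 0] <- 1
  } else {
    mu <- rep(0, ncol(X)); sigma <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, "/")

  if (config$normalize_target) {
    y_mu <- mean(y); y_sd <- sd(y)
  } else {
    y_mu <- mean(y); y_sd <- 1   # target centered, never rescaled unless asked
  }
  yc <- (y - y_mu) / y_sd

  D2 <- .sq_dists(Xs)
  ls0 <- config$length_scale_init %||%
    stats::median(sqrt(D2[upper.tri(D2)][D2[upper.tri(D2)] > 0]))
  if (!is.finite(ls0) || ls0 <= 0) ls0 <- 1
  sf0 <- max(sd(yc), 1e-3)
  fixed_noise <- if (config$kernel == "RBF") 1e-4 else NULL

  theta0 <- c(log(ls0), log(sf0),
              if (is.null(fixed_noise)) log(config$noise_init))
  opt <- stats::optim(theta0, .gp_nlml, D2 = D2, yc = yc,
                      kernel = config$kernel, fixed_noise = fixed_noise,
                      method = "L-BFGS-B",
                      lower = theta0 - 8, upper = theta0 + 8,
                      control = list(maxit = 200))

  ls <- exp(opt$par[1]); sf <- exp(opt$par[2])
  sn <- if (is.null(fixed_noise)) exp(opt$par[3]) else fixed_noise
  K <- .kernel_matrix(D2, config$kernel, ls, sf^2) + diag(sn^2, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))

  structure(list(
    format_version = .MODEL_FORMAT_VERSION,
    kernel = config$kernel,
    length_scale = ls, signal_sd = sf, noise_sd = sn,
    nlml = opt$value,
    X_train = Xs, alpha = alpha, L = L,
    feature_mean = mu, feature_scale = sigma,
    y_mean = y_mu, y_scale = y_sd,
    schema = colnames(X),
    schema_hash = .str_hash(paste(colnames(X), collapse = "|")),
    signature_config = signature_config,
    signature_config_hash = if (!is.null(signature_config))
      signature_config$config_hash else NA_character_,
    typing_table_version = if (!is.null(signature_config))
      signature_config$typing_table_version else NA_character_,
    metadata = list(n = n, trained = format(Sys.time(), "%Y-%m-%d"),
                    package_version = as.character(utils::packageVersion("bindsig")),
                    seed = config$seed)),
    class = "csm_model")
}

#' @export
print.csm_model <- function(x, ...) {
  cat(sprintf("<csm_model: %s GP, n = %d, p = %d, length scale %.3g, signal sd %.3g, noise sd %.3g>\n",
              x$kernel, x$metadata$n, length(x$schema), x$length_scale,
              x$signal_sd, x$noise_sd))
  invisible(x)
}

#' Predict pAffinity for new signatures
#'
#' Returns the GP posterior mean (the \code{-log10(Kd|Ki)} output) and the
#' predictive standard deviation (latent posterior variance plus noise
#' variance).  The schema of \code{newdata} must match the training
#' schema exactly.
#'
#' @param object a \code{csm_model}.
#' @param newdata a \code{csm_signature}, a list of them, or a numeric
#'   matrix with schema column names.
#' @param ... unused.
#' @return data frame with columns \code{mean} and \code{sd}, one row per
#'   complex.
#' @export
predict.csm_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else if (is.list(newdata) && !inherits(newdata, "csm_signature"))
         do.call(rbind, lapply(newdata, as.numeric)) |>
           `colnames<-`(names(newdata[[1]]))
       else matrix(as.numeric(newdata), nrow = 1,
                   dimnames = list(NULL, names(newdata)))
  if (!identical(colnames(X), object$schema)) {
    bad <- which(colnames(X) != object$schema)
    stop_bindsig("schema mismatch at %d position(s), first: %d ('%s' vs '%s')",
                 length(bad), bad[1] %||% ncol(X),
                 (colnames(X)[bad[1]]) %||% "<absent>",
                 object$schema[bad[1]] %||% "<absent>",
                 class = "bindsig_schema_mismatch")
  }
  Xs <- sweep(sweep(X, 2, object$feature_mean), 2, object$feature_scale, "/")
  D2x <- .sq_dists(Xs, object$X_train)
  Kx <- .kernel_matrix(D2x, object$kernel, object$length_scale,
                       object$signal_sd^2)
  mean_c <- as.numeric(Kx %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Kx))
  var_lat <- pmax(object$signal_sd^2 - colSums(v^2), 0)
  data.frame(mean = object$y_mean + object$y_scale * mean_c,
             sd = object$y_scale * sqrt(var_lat + object$noise_sd^2))
}

#' Persist a trained model
#'
#' The model (GP state, schema, standardization and metadata) is written
#' as one RDS archive with an embedded plain-text schema manifest.
#' [load_model()] verifies the format version, the stored schema hash and
#' the availability of the typing-table version before accepting it.
#'
#' @param model a \code{csm_model}.
#' @param path file path to write.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "csm_model"))
  payload <- unclass(model)
  payload$manifest <- c(
    sprintf("format_version\t%d", model$format_version),
    sprintf("schema_hash\t%s", model$schema_hash),
    sprintf("typing_table_version\t%s", model$typing_table_version),
    sprintf("n_features\t%d", length(model$schema)),
    paste0("feature\t", model$schema))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$format_version) ||
      payload$format_version != .MODEL_FORMAT_VERSION)
    stop_bindsig("unsupported model file format (version %s, expected %d)",
                 payload$format_version %||% "<none>", .MODEL_FORMAT_VERSION,
                 class = "bindsig_model_io")
  if (!identical(payload$schema_hash,
                 .str_hash(paste(payload$schema, collapse = "|"))))
    stop_bindsig("model schema hash does not match its schema (corrupt or altered file)",
                 class = "bindsig_model_io")
  ttv <- payload$typing_table_version
  if (!is.na(ttv) &&
      system.file("extdata", sprintf("pharmacophore_types_%s.tsv", ttv),
                  package = "bindsig") == "")
    stop_bindsig("model was trained with typing table '%s', which this installation does not provide",
                 ttv, class = "bindsig_model_io")
  payload$manifest <- NULL
  structure(payload, class = "csm_model")
}

#' k-fold cross-validation of the regressor
#'
#' Builds a seeded fold partition, trains one model per fold on the
#' remaining data and predicts the held-out fold; the assembled
#' out-of-fold predictions cover every complex exactly once and are
#' scored by [evaluation_report()].
#'
#' @param X feature matrix (complexes x features, schema column names).
#' @param y pAffinity vector.
#' @param k number of folds.
#' @param config a [gp_config()].
#' @param seed fold-shuffle seed.
#' @param keep_folds keep the per-fold models (default FALSE).
#' @return list with \code{report} (a \code{csm_evaluation}),
#'   \code{predictions} (data frame \code{index, fold, observed,
#'   predicted, sd}) and optionally \code{fold_models}.
#' @export
cross_validate <- function(X, y, k = 10L, config = gp_config(), seed = 1L,
                           keep_folds = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  folds <- make_folds(seq_len(nrow(X)), k = k, seed = seed)
  # folds of one point are only meaningful as leave-one-out (k == n)
  if (k < nrow(X) && any(lengths(folds) < 2L))
    stop_bindsig("fold with fewer than 2 points (n = %d, k = %d)",
                 nrow(X), k, class = "bindsig_fold_error")
  preds <- vector("list", k)
  models <- if (keep_folds) vector("list", k) else NULL
  for (i in seq_len(k)) {
    hold <- folds[[i]]
    fit <- train_model(X[-hold, , drop = FALSE], y[-hold], config = config)
    p <- predict(fit, X[hold, , drop = FALSE])
    preds[[i]] <- data.frame(index = hold, fold = i,
                             observed = y[hold],
                             predicted = p$mean, sd = p$sd)
    if (keep_folds) models[[i]] <- fit
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$index), ]
  rownames(predictions) <- NULL
  out <- list(report = evaluation_report(predictions$observed,
                                         predictions$predicted,
                                         label = sprintf("%d-fold CV", k)),
              predictions = predictions)
  if (keep_folds) out$fold_models <- models
  out
}
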