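# small dense feature matrices stand in for signatures in these tests;
# the full featurize-train-predict path is covered by test-synthetic and
# test-pipeline
make_xy <- function(n = 20, p = 5, noise = 0.01, seed = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 5 + 1.5 * X[, 1] - 0.8 * X[, 2] + 0.4 * X[, 3] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("training recovers a low-noise linear map and is deterministic", {
  d <- make_xy()
  m <- train_model(d$X, d$y)
  p <- predict(m, d$X)
  expect_lt(max(abs(p$mean - d$y)), 0.05)

  m2 <- train_model(d$X, d$y)
  expect_equal(predict(m2, d$X)$mean, p$mean, tolerance = 1e-10)
})

test_that("posterior mean matches a closed-form linear-algebra oracle", {
  d <- make_xy(n = 15)
  m <- train_model(d$X, d$y)
  # independent route: solve() on the dense kernel system at the fitted
  # hyperparameters
  Xs <- sweep(sweep(d$X, 2, m$feature_mean), 2, m$feature_scale, "/")
  D2 <- as.matrix(dist(Xs))^2
  K <- m$signal_sd^2 * exp(-D2 / (2 * m$length_scale^2)) +
    diag(m$noise_sd^2, nrow(Xs))
  oracle <- m$y_mean + K %*% solve(K, d$y - m$y_mean)  # at train inputs
  # general new-point form on a probe set
  probe <- d$X[c(2, 7, 11), , drop = FALSE]
  Ps <- sweep(sweep(probe, 2, m$feature_mean), 2, m$feature_scale, "/")
  D2x <- outer(rowSums(Ps^2), rep(1, nrow(Xs))) +
    outer(rep(1, nrow(Ps)), rowSums(Xs^2)) - 2 * Ps %*% t(Xs)
  Kx <- m$signal_sd^2 * exp(-D2x / (2 * m$length_scale^2))
  oracle_probe <- m$y_mean + Kx %*% solve(K, d$y - m$y_mean)
  expect_equal(predict(m, probe)$mean, as.numeric(oracle_probe),
               tolerance = 1e-8)
})

test_that("posterior mean agrees with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  d <- make_xy(n = 25, noise = 1)     # noise-dominated data keeps the fitted
  m <- train_model(d$X, d$y)          # noise/signal ratio in kernlab's range
  # same kernel, same hyperparameters, independent solver
  Xs <- sweep(sweep(d$X, 2, m$feature_mean), 2, m$feature_scale, "/")
  sigma <- 1 / (2 * m$length_scale^2)
  yc <- (d$y - m$y_mean) / m$signal_sd^2   # kernlab's rbfdot has unit amplitude
  fit <- kernlab::gausspr(Xs, yc, scaled = FALSE, kernel = "rbfdot",
                          kpar = list(sigma = sigma),
                          var = m$noise_sd^2 / m$signal_sd^2)
  ref <- m$y_mean + m$signal_sd^2 * kernlab::predict(fit, Xs)
  expect_equal(predict(m, d$X)$mean, as.numeric(ref), tolerance = 1e-4)
})

test_that("GP limits behave: interpolation nearby, prior far away", {
  d <- make_xy(n = 15, noise = 0)
  m <- train_model(d$X, d$y, gp_config(kernel = "RBF"))   # tiny fixed jitter
  expect_lt(max(abs(predict(m, d$X)$mean - d$y)), 1e-3)

  mw <- train_model(d$X, d$y)
  far <- matrix(1e6, 1, 5, dimnames = list(NULL, colnames(d$X)))
  pf <- predict(mw, far)
  expect_equal(pf$mean, mw$y_mean, tolerance = 1e-8)
  expect_equal(pf$sd, sqrt(mw$signal_sd^2 + mw$noise_sd^2),
               tolerance = 1e-8)
})

test_that("input contracts are enforced", {
  d <- make_xy()
  expect_error(train_model(d$X[1:4, ], d$y[1:4]), class = "bindsig_bad_input")
  expect_error(train_model(d$X, rep(3, 20)), class = "bindsig_bad_input")
  expect_error(train_model(unname(d$X), d$y),
               class = "bindsig_schema_mismatch")

  m <- train_model(d$X, d$y)
  bad <- d$X
  colnames(bad)[2] <- "other"
  expect_error(predict(m, bad), regexp = "other",
               class = "bindsig_schema_mismatch")
})

test_that("matern kernel trains and differs from RBF", {
  d <- make_xy(n = 25, noise = 0.2, seed = 8)
  m_rbf <- train_model(d$X, d$y)
  m_mat <- train_model(d$X, d$y, gp_config(kernel = "MATERN52"))
  expect_s3_class(m_mat, "csm_model")
  expect_false(isTRUE(all.equal(predict(m_mat, d$X)$mean,
                                predict(m_rbf, d$X)$mean,
                                tolerance = 1e-10)))
})

test_that("models round-trip through disk and refuse tampered files", {
  d <- make_xy()
  m <- train_model(d$X, d$y, signature_config = signature_config())
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, d$X)$mean, predict(m, d$X)$mean,
               tolerance = 1e-12)
  expect_equal(predict(m2, d$X)$sd, predict(m, d$X)$sd, tolerance = 1e-12)

  # altered schema: hash check refuses
  raw <- readRDS(path)
  raw$schema[1] <- "tampered"
  p2 <- tempfile(fileext = ".rds")
  saveRDS(raw, p2)
  expect_error(load_model(p2), class = "bindsig_model_io")

  # unknown typing-table version refused, naming the version
  raw2 <- readRDS(path)
  raw2$typing_table_version <- "v999"
  raw2$schema_hash <- bindsig:::.str_hash(paste(raw2$schema, collapse = "|"))
  p3 <- tempfile(fileext = ".rds")
  saveRDS(raw2, p3)
  expect_error(load_model(p3), regexp = "v999", class = "bindsig_model_io")

  # wrong format version refused
  raw3 <- readRDS(path)
  raw3$format_version <- 99L
  p4 <- tempfile(fileext = ".rds")
  saveRDS(raw3, p4)
  expect_error(load_model(p4), class = "bindsig_model_io")
})

test_that("cross-validation partitions and scores out-of-fold", {
  d <- make_xy(n = 30, noise = 0.05, seed = 12)
  cv <- cross_validate(d$X, d$y, k = 5, seed = 3)
  expect_equal(sort(cv$predictions$index), 1:30)     # each point once
  expect_equal(cv$report$n, 30)
  expect_gt(cv$report$pearson_r, 0.9)                # near-noiseless linear

  # leave-one-out on 10 points: n = 10 out-of-fold predictions
  d10 <- make_xy(n = 10, seed = 13)
  loo <- cross_validate(d10$X, d10$y, k = 10, seed = 1)
  expect_equal(nrow(loo$predictions), 10L)
  expect_equal(sort(loo$predictions$index), 1:10)

  expect_error(cross_validate(d10$X, d10$y, k = 7, seed = 1),
               class = "bindsig_fold_error")
})
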