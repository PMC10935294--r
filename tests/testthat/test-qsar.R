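test_that("noiseless linear data is fitted exactly at full rank", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(2 + X %*% c(1, -2, 0.5))
  m <- fit_pls(X, y, n_components = 3, compute_q2 = FALSE)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(drop(m$intercept + X %*% m$coefficients), y, tolerance = 1e-8)
})

test_that("PLS with n_components = rank(X) equals ordinary least squares", {
  set.seed(2)
  for (i in 1:10) {
    X <- matrix(rnorm(10), 5, 2)
    y <- drop(1 + X %*% rnorm(2) + rnorm(5, 0, 0.5))
    m <- fit_pls(X, y, n_components = 2, compute_q2 = FALSE)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(unname(c(m$intercept, m$coefficients)), ols, tolerance = 1e-8)
  }
})

test_that("a single component matches the closed-form first PLS direction", {
  set.seed(3)
  X <- matrix(rnorm(10), 5, 2)
  y <- drop(X %*% c(2, 1) + rnorm(5, 0, 0.2))
  m <- fit_pls(X, y, n_components = 1, compute_q2 = FALSE)
  # hand oracle in the autoscaled space: w = Xs'ys normalized, t = Xs w,
  # q = t'ys / t't, prediction = q * t back-transformed
  xs <- scale(X); ys <- drop(scale(y))
  w <- drop(crossprod(xs, ys)); w <- w / sqrt(sum(w^2))
  t1 <- drop(xs %*% w)
  q <- sum(t1 * ys) / sum(t1^2)
  yhat_oracle <- mean(y) + q * t1 * sd(y)
  expect_equal(drop(m$intercept + X %*% m$coefficients), yhat_oracle,
               tolerance = 1e-8)
  expect_equal(abs(cosine_similarity(m$weights[, 1], w)), 1, tolerance = 1e-10)
})

test_that("NIPALS X-scores are mutually orthogonal", {
  g <- gen_qsar_dataset(11, n = 60, length = 6, sigma = 0.3)
  m <- fit_pls(g$X, g$log10_ic50, n_components = 4, compute_q2 = FALSE)
  G <- crossprod(m$scores_t)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("r2 is non-decreasing in n_components and q2 never exceeds r2", {
  g <- gen_qsar_dataset(12, n = 50, length = 6, sigma = 0.3)
  r2s <- sapply(1:4, function(a) {
    fit_pls(g$X, g$log10_ic50, n_components = a, compute_q2 = FALSE)$r2
  })
  expect_true(all(diff(r2s) >= -1e-10))
  for (a in c(1, 2, 3)) {
    m <- fit_pls(g$X, g$log10_ic50, n_components = a)
    expect_lte(m$q2, m$r2)
  }
})

test_that("leave-one-out Q2 behaves at the limits", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(1 + X %*% c(1, 2, -1))
  expect_gt(loo_q2(X, y, n_components = 3), 0.999)  # noiseless
  # pure-noise response: Q2 at or below zero in the typical run
  q2s <- replicate(30, {
    yn <- rnorm(20)
    loo_q2(X, yn, n_components = 2)
  })
  expect_lt(median(q2s), 0)
  expect_error(loo_q2(X[1:2, ], y[1:2]), "at least 3")
})

test_that("predictions are invariant to consistent descriptor rescaling", {
  g <- gen_qsar_dataset(13, n = 40, length = 3, sigma = 0.2)
  m1 <- fit_pls(g$X, g$log10_ic50, compute_q2 = FALSE)
  set.seed(5)
  fac <- runif(ncol(g$X), 0.1, 10)
  Xs <- sweep(g$X, 2, fac, "*")
  m2 <- fit_pls(Xs, g$log10_ic50, compute_q2 = FALSE)
  Xnew <- encode_peptides(c("YNL", "TVK", "AAA"))
  expect_equal(predict(m2, sweep(Xnew, 2, fac, "*")),
               predict(m1, Xnew), tolerance = 1e-8)
})

test_that("t,u-score pruning recovers planted gross outliers and only acts when needed", {
  # noiseless data: inner residuals vanish, nothing is excluded
  g0 <- gen_qsar_dataset(14, n = 40, length = 6, sigma = 0)
  m0 <- fit_pls(g0$X, g0$log10_ic50, compute_q2 = FALSE)
  ex0 <- exclude_outliers(m0, g0$X, g0$log10_ic50)
  expect_length(ex0$excluded, 0L)
  # three gross outliers (y shifted by 10 SD) are all caught
  g <- gen_qsar_dataset(15, n = 100, length = 6, sigma = 0.2)
  y <- g$log10_ic50
  planted <- c(10L, 50L, 90L)
  y[planted] <- y[planted] + 10 * 0.2
  m <- fit_pls(g$X, y, compute_q2 = FALSE)
  ex <- exclude_outliers(m, g$X, y)
  expect_true(all(planted %in% ex$excluded))
  expect_identical(ex$model$excluded_indices, ex$excluded)
  # an infinite threshold is the identity
  exinf <- exclude_outliers(m, g$X, y, threshold_sd = Inf)
  expect_length(exinf$excluded, 0L)
  expect_equal(exinf$model$coefficients, m$coefficients)
})

test_that("pruning stops rather than dropping below the minimum sample count", {
  set.seed(6)
  X <- matrix(rnorm(12), 6, 2)
  y <- c(0, 0.1, -0.1, 8, -9, 10)  # mostly 'outliers' by construction
  m <- fit_pls(X, y, n_components = 2, compute_q2 = FALSE)
  expect_warning(exclude_outliers(m, X, y, threshold_sd = 0.5),
                 "too few samples")
})

test_that("fitted coefficients recover the generating beta direction", {
  cos <- sapply(1:5, function(s) {
    g <- gen_qsar_dataset(s, n = 100, length = 6, sigma = 0.05)
    m <- fit_pls(g$X, g$log10_ic50, n_components = 6, compute_q2 = FALSE)
    cosine_similarity(m$coefficients, g$beta)
  })
  expect_true(all(cos > 0.9))
})

test_that("held-out prediction error approaches the noise floor", {
  g <- gen_qsar_dataset(16, n = 200, length = 6, sigma = 0.2)
  m <- fit_pls(g$X[1:150, ], g$log10_ic50[1:150], n_components = 10,
               compute_q2 = FALSE)
  pred <- predict(m, g$X[151:200, ])
  rmse <- sqrt(mean((pred - g$log10_ic50[151:200])^2))
  expect_lt(rmse, 2 * 0.2)
  expect_gt(rmse, 0.5 * 0.2)
})

test_that("peptide-level prediction enforces the length class and inverts the log", {
  g <- gen_qsar_dataset(17, n = 40, length = 3, sigma = 0)
  m <- fit_qsar(g$data, n_components = 15)  # full descriptor rank: exact fit
  # noiseless exact-fit limit: training IC50 recovered
  pr <- predict(m, g$data$peptide[1:5])
  expect_equal(pr$predicted_ic50_uM, g$data$ic50_uM[1:5], tolerance = 1e-4)
  expect_equal(pr$predicted_ic50_uM, 10^pr$predicted_log10_ic50)
  expect_error(predict(m, "ABCDEF"), "length 3")
  # zeroed coefficients predict the flat 10^intercept
  m0 <- m
  m0$coefficients[] <- 0
  m0$intercept <- 0.7
  expect_equal(predict(m0, c("YNL", "TVK"))$predicted_ic50_uM,
               rep(10^0.7, 2))
})

test_that("constant response and short datasets are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10)), "constant")
  expect_error(fit_pls(X[1:3, ], rnorm(3), n_components = 2), "at least")
})

test_that("qsar_dataset enforces the admission filter and length classes", {
  expect_error(qsar_dataset(c("YNL", "TVKA"), c(1, 2)), "one length class")
  expect_error(qsar_dataset("YNL", -1), "positive")
  expect_message(d <- qsar_dataset(c("YNL", "TVK", "AAA"), c(10, 20000, 30)),
                 "admission")
  expect_equal(nrow(d), 2L)
  expect_equal(attr(d, "n_rejected"), 1L)
  expect_equal(attr(d, "length_class"), 3L)
})

test_that("models serialize to JSON and reproduce predictions bit-for-bit", {
  g <- gen_qsar_dataset(18, n = 40, length = 6, sigma = 0.2)
  m <- fit_qsar(g$data)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, tmp)
  m2 <- read_pls_model(tmp)
  peps <- g$data$peptide[1:10]
  expect_identical(predict(m, peps)$predicted_ic50_uM,
                   predict(m2, peps)$predicted_ic50_uM)
  expect_equal(m2$r2, m$r2)
  expect_equal(m2$length_class, m$length_class)
})
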