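test_that("the Pearson VII kernel matches its closed form and is a valid kernel", {
  x <- rnorm(5)
  expect_equal(puk_kernel(x, x), 1)
  expect_equal(puk_kernel(0, 0.5), 0.5)                 # 1 / (1 + 1^2)
  expect_equal(puk_kernel(0, 1, puk_params(omega = 2)),
               (1 + 4 * (sqrt(2) - 1))^-2, tolerance = 1e-12)
  y <- rnorm(5)
  expect_equal(puk_kernel(x, y), puk_kernel(y, x))
  expect_error(puk_kernel(rnorm(3), rnorm(4)), "mismatch")
  # in (0, 1], monotone decreasing in distance
  d <- seq(0, 10, by = 0.25)
  k <- vapply(d, function(dd) puk_kernel(0, dd), numeric(1))
  expect_true(all(k > 0 & k <= 1))
  expect_true(all(diff(k) < 0))
})

test_that("Gram matrices are symmetric, unit-diagonal and PSD", {
  expect_equal(gram_matrix(matrix(rnorm(5), 1)), matrix(1, 1, 1))
  X <- rbind(c(1, 2), c(1, 2), c(3, 4))
  expect_equal(gram_matrix(X)[1, 2], 1)
  set.seed(17)
  for (i in 1:50) {
    G <- gram_matrix(matrix(rnorm(100), 20, 5),
                     puk_params(omega = sample(c(0.5, 1, 2), 1),
                                sigma = runif(1, 0.5, 5)))
    expect_equal(G, t(G))
    expect_equal(unname(diag(G)), rep(1, 20))
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  # cross-gram agrees with elementwise kernel evaluation
  A <- matrix(rnorm(12), 4); B <- matrix(rnorm(6), 2)
  G <- gram_matrix(A, puk_params(sigma = 2), B)
  expect_equal(G[3, 2], puk_kernel(A[3, ], B[2, ], puk_params(sigma = 2)))
})

test_that("SVR training satisfies its optimality conditions", {
  # constant target inside the tube: flat solution, zero duals
  X <- matrix(rnorm(20), 10, 2)
  fit <- train_svr(X, rep(2.5, 10), svr = svr_params(epsilon = 0.01))
  expect_length(fit$dual, 0L)
  expect_equal(fit$bias, 2.5)
  expect_equal(predict(fit, X), rep(2.5, 10))

  # six points on y = x are fit essentially exactly at high cost
  X1 <- matrix(seq(-1, 1, length.out = 6), ncol = 1)
  y1 <- as.numeric(X1)
  fit1 <- train_svr(X1, y1, puk_params(sigma = 2),
                    svr_params(cost = 100, epsilon = 0.001))
  expect_lt(max(abs(predict(fit1, X1) - y1)), 0.05)
  kkt <- check_kkt(fit1)
  expect_true(kkt$box_ok)
  expect_true(kkt$tube_ok)
  expect_true(all(abs(fit1$dual) <= 100 + 1e-6))

  # conflicting duplicated rows: prediction lies between the two targets
  X2 <- matrix(c(0, 0, 5), ncol = 1)
  fit2 <- train_svr(X2, c(-1, 1, 0), svr = svr_params(cost = 10))
  p <- predict(fit2, matrix(0))
  expect_gte(p, -1); expect_lte(p, 1)

  expect_error(train_svr(matrix(c(1, NA), 2), c(1, 2)), "non-finite")
  expect_error(train_svr(matrix(1, 1, 1), 1), "at least 2")
})

test_that("prediction is row-wise and honors the fitted expansion", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(1, -1, 2) + rnorm(20, sd = 0.01)
  fit <- train_svr(X, as.numeric(y), puk_params(sigma = "median",
                                                sigma_scale = 4),
                   svr_params(cost = 50))
  Xn <- matrix(rnorm(15), 5, 3)
  p <- predict(fit, Xn)
  expect_equal(predict(fit, Xn[5:1, ]), p[5:1])
  expect_error(predict(fit, matrix(rnorm(8), 2, 4)), "mismatch")
  # manual kernel expansion reproduces predict()
  K <- gram_matrix(Xn, fit$puk, fit$sv)
  expect_equal(as.numeric(K %*% fit$dual + fit$bias), p)
})

test_that("Q2 metric matches its defining formula", {
  y <- c(1, 2, 3)
  expect_equal(q_squared(y, y, mean(y)), 1)
  expect_equal(q_squared(y, rep(2, 3), 2), 0)
  expect_equal(q_squared(c(1, 2, 3), c(1, 2, 4), 2), 0.5)
  expect_error(q_squared(c(1, 1), c(1, 1), 1), "degenerate")
  expect_error(q_squared(1, 1, 1), "length")
})

test_that("cross-validation recovers noiseless signal and stays honest on noise", {
  set.seed(11)
  X <- matrix(rnorm(120), 40, 3)
  y <- as.numeric(X %*% c(1, -0.5, 0.25))
  q2 <- cross_validate(X, y, puk_params(sigma = "median", sigma_scale = 12),
                       svr_params(cost = 1000), k = 5, seed = 1)
  expect_gte(q2, 0.99)
  # pure-noise responses: no apparent predictivity on average
  q2n <- vapply(1:5, function(s) {
    set.seed(100 + s)
    yn <- rnorm(40)
    as.numeric(cross_validate(X, yn,
                              puk_params(sigma = "median", sigma_scale = 4),
                              svr_params(cost = 10), k = 5, seed = s))
  }, numeric(1))
  expect_lte(mean(q2n), 0.1)
  # leave-one-out runs and is finite
  Xs <- X[1:8, ]; ys <- y[1:8]
  expect_true(is.finite(cross_validate(Xs, ys, k = 8, seed = 1)))
  expect_error(cross_validate(Xs, ys, k = 9), "exceed")
})

test_that("the pcm fit object behaves like a standard R model", {
  syn <- generate_dataset(synth_config(seed = 3, n_compounds = 60,
                                       pairs_per_target = c(20, 18, 30, 8, 22)))
  fit <- pcm(syn$records, syn$protein_block, syn$ligand_block,
             spec = model_spec("P", "L", "blocks_only"),
             puk = synth_puk(), svr = synth_svr(), seed = 5)
  expect_s3_class(fit, "pcm")
  expect_output(print(fit), "Proteochemometric")
  expect_output(print(summary(fit)), "support vectors")
  expect_lte(fit$metrics$r2_train, 1)
  expect_lte(fit$metrics$q2_test, 1)
  # stored predictions match re-prediction of the same pairs
  pairs <- fit$records[, c("compound_id", "target_id")]
  expect_equal(predict(fit, pairs), fit$records$.pred, tolerance = 1e-8)
  # pIC50-scale predictions invert the response scaling
  expect_equal(predict(fit, pairs, type = "pic50"),
               unscale_response(fit$records$.pred, fit$response_scaling))
  expect_equal(length(residuals(fit)), fit$metrics$n_train)
  tr <- fit$records$split == "train"
  expect_equal(unname(fitted(fit) + residuals(fit)),
               fit$records$y_scaled[tr])
  expect_true(all(abs(coef(fit)$dual) <= synth_svr()$cost + 1e-6))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$metrics$n_train, 2L))
  q2cv <- cross_validate(fit, k = 5, seed = 2)
  expect_true(is.finite(q2cv) && q2cv <= 1)
})

test_that("the model grid mirrors the 18-specification layout", {
  syn <- generate_dataset(synth_config(seed = 9, n_compounds = 40,
                                       d_protein = 3, d_ligand = 4,
                                       pairs_per_target = c(12, 12, 16, 6, 14),
                                       beta_protein = c(0.3, -0.25, 0.2),
                                       beta_ligand = c(0.4, -0.3, 0.2, 0)))
  blocks <- list(P = syn$protein_block, L = syn$ligand_block)
  specs <- lapply(c("blocks_only", "blocks_plus_cross", "cross_only"),
                  function(m) model_spec("P", "L", m))
  grid <- pcm_grid(syn$records, blocks, specs, puk = synth_puk(),
                   svr = synth_svr(), seed = 21)
  expect_equal(nrow(grid), 3L)
  expect_equal(grid$D, c(3 + 4, 3 + 4 + 12, 12))
  expect_true(all(c("model", "R2", "Q2_cv", "Q2_test") %in% names(grid)))
})
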