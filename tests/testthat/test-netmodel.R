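make_toy_cube <- function(yi, yk, times = c(0, 10, 20)) {
  cube <- array(1, c(2, 1, length(times)),
                dimnames = list(c("gi", "gk"), "e1", paste0("t", times)))
  cube["gi", 1, ] <- yi
  cube["gk", 1, ] <- yk
  attr(cube, "times") <- times
  cube
}

test_that("design rows encode the dynamical model's terms and steady state", {
  cube <- make_toy_cube(yi = c(1, 2, 2), yk = c(1, 3, 3))
  des <- build_design(cube, "gi", at = "start")
  # interval starting at t = 0: all predictors exactly zero
  expect_true(all(des$X[1, ] == 0))
  # interval starting at t = 10: alpha-term y_k - 1 = 2,
  # beta-term (y_i y_k - 1)/y_i = (2*3 - 1)/2 = 2.5
  expect_equal(unname(des$X[2, "alpha.gk"]), 2)
  expect_equal(unname(des$X[2, "beta.gk"]), 2.5)
  # dependent: finite-difference log rate
  expect_equal(des$y, c(log(2) / 10, 0))

  # constant target and regulator: all rows zero
  flat <- make_toy_cube(yi = c(1, 1, 1), yk = c(1, 1, 1))
  des2 <- build_design(flat, "gi", at = "start")
  expect_true(all(des2$X == 0) && all(des2$y == 0))

  # the modeled rate at the t = 0 state is structurally zero for any
  # coefficients (steady-state constraint, no intercept)
  model <- list(alpha = matrix(rnorm(4), 2, 2,
                               dimnames = list(c("gi", "gk"), c("gi", "gk"))),
                beta = matrix(rnorm(4), 2, 2,
                              dimnames = list(c("gi", "gk"), c("gi", "gk"))))
  state <- c(gi = 1, gk = 1)
  expect_identical(predict_rate(model, state, "gi"), 0)
})

test_that("non-positive expression aborts the design", {
  cube <- make_toy_cube(yi = c(1, 0, 2), yk = c(1, 1, 1))
  expect_error(build_design(cube, "gi"), "positive")
})

test_that("the L1 fit matches closed forms and the brute-force oracle", {
  set.seed(11)
  # orthonormalized 3-predictor design: lambda = 0 equals OLS
  X0 <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  colnames(X0) <- paste0("x", 1:3)
  y0 <- drop(X0 %*% c(1, -2, 0.5)) + rnorm(40, 0, 0.1)
  b_ols <- drop(solve(crossprod(X0), crossprod(X0, y0)))
  b_fit <- fit_gene_lasso(list(X = X0, y = y0), lambda = 0)
  expect_lt(max(abs(b_fit - b_ols)), 1e-8)

  # saturation: a huge penalty zeroes every coefficient
  expect_true(all(fit_gene_lasso(list(X = X0, y = y0), 1e6) == 0))

  # 5-predictor problem: objective within 1e-6 of the coordinate-grid oracle
  X <- matrix(rnorm(40 * 5), 40, 5)
  colnames(X) <- paste0("x", 1:5)
  y <- drop(X %*% c(1.5, 0, -0.8, 0, 0.3)) + rnorm(40, 0, 0.2)
  for (lam in c(0.5, 5, 50)) {
    b_pkg <- fit_gene_lasso(list(X = X, y = y), lam)
    b_orc <- lasso_bruteforce(X, y, lam)
    expect_lt(abs(lasso_objective(X, y, b_pkg, lam) -
                    lasso_objective(X, y, b_orc, lam)), 1e-6)
  }
})

test_that("sparsity is monotone non-increasing along the penalty grid", {
  set.seed(12)
  X <- matrix(rnorm(60 * 8), 60, 8)
  colnames(X) <- paste0("x", 1:8)
  y <- drop(X %*% c(2, -1, 0.5, rep(0, 5))) + rnorm(60, 0, 0.3)
  grid <- exp(seq(log(0.01), log(200), length.out = 12))
  nnz <- vapply(grid, function(l)
    sum(fit_gene_lasso(list(X = X, y = y), l) != 0), numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("BIC selection prefers sparsity on ties and recovers small supports", {
  # grid of length 1 returns that value
  set.seed(13)
  X <- matrix(rnorm(50 * 4), 50, 4)
  colnames(X) <- paste0("x", 1:4)
  y <- drop(X %*% c(1, 0, 0, 0)) + rnorm(50, 0, 0.2)
  des <- list(X = X, y = y)
  expect_equal(select_lambda_bic(des, 0.7)$lambda, 0.7)

  # single true regulator: support of size 1 selected in >= 90% of reps
  hits <- replicate(20, {
    Xr <- matrix(rnorm(100 * 5), 100, 5)
    colnames(Xr) <- paste0("x", 1:5)
    yr <- drop(Xr %*% c(1, 0, 0, 0, 0)) + rnorm(100, 0, 0.3)
    d <- list(X = Xr, y = yr)
    lam <- select_lambda_bic(d, exp(seq(log(0.05), log(100),
                                        length.out = 30)))$lambda
    b <- fit_gene_lasso(d, lam)
    sum(b != 0) == 1 && b[1] != 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cross-validation partitions experiments and silences noise targets", {
  net <- make_cascade_network()
  cube <- simulate_experiments(net, cascade_designs())
  obs <- corrupt_with_noise(cube, noise_spec(0.02, 0, 0, seed = 15))
  des <- build_design(obs, "gD", at = "midpoint")
  grid <- exp(seq(log(1e-4), log(10), length.out = 10))
  cv <- cross_validate(des, grid)
  expect_false(cv$fallback)
  expect_equal(nrow(cv$cv), length(grid))
  expect_true(all(is.finite(cv$cv$mse)))
  # chosen model retains the true regulator of gD
  b <- fit_gene_lasso(des, cv$lambda)
  expect_true(b["alpha.gB"] != 0 || b["beta.gB"] != 0)

  # pure-noise targets are driven to the empty model in most replicates
  zeroed <- replicate(10, {
    Xn <- matrix(rnorm(70 * 6), 70, 6)
    colnames(Xn) <- paste0("x", 1:6)
    dn <- list(X = Xn, y = rnorm(70, 0, 1),
               experiment = rep(paste0("e", 1:7), each = 10))
    cvn <- cross_validate(dn, exp(seq(log(1), log(500), length.out = 12)))
    all(fit_gene_lasso(dn, cvn$lambda) == 0)
  })
  expect_gte(mean(zeroed), 0.8)

  # responsive in < 2 experiments: flagged fallback
  des1 <- des
  keep <- des1$experiment == "expB"
  des1$y[!keep] <- 0
  cv1 <- cross_validate(des1, grid)
  expect_true(cv1$fallback)
})

test_that("network fitting recovers edges, isolates failures and honors the null", {
  bench <- make_benchmark(n_genes = 30, n_regulators = 6, n_exp = 12,
                          sparsity = 0.02, seed = 201)
  model <- suppressWarnings(fit_network(bench$obs))
  auc <- directed_auroc(edge_scores(model), bench$true_edges)
  expect_gt(auc, 0.75)

  # the expression-on-expression baseline is outperformed
  base <- suppressWarnings(baseline_lasso(bench$obs))
  auc_base <- directed_auroc(edge_scores(list(coef = NULL,
                                              alpha = base$coef,
                                              beta = base$coef * 0)),
                             bench$true_edges)
  expect_gt(auc, auc_base)

  # per-target failures are isolated, not fatal
  m2 <- suppressWarnings(
    fit_network(bench$obs, list(targets = c("nonexistent",
                                            bench$net$gene_ids[1:3]))))
  expect_true(is.na(m2$diagnostics$lambda[1]) &&
                !is.na(m2$diagnostics$error[1]))
  expect_true(all(is.na(m2$diagnostics$error[-1])))
})

test_that("fitted rates integrate to log2 trajectories", {
  # single-interval arithmetic: rate 0.1/min over 10 min -> ln y = 1
  cube <- make_toy_cube(yi = c(1, 1, 1), yk = c(1, 3, 3),
                        times = c(0, 10, 20))
  genes <- c("gi", "gk")
  model <- structure(list(
    alpha = matrix(c(0, 0, 0.1, 0), 2, 2, dimnames = list(genes, genes)),
    beta = matrix(0, 2, 2, dimnames = list(genes, genes)),
    config = list(regulators = genes, exclude_self = TRUE,
                  at = "midpoint", exclude_induced = TRUE)),
    class = "network_model")
  # midpoint alpha-term over [0,10] is ((1-1)+(3-1))/2 = 1 -> rate 0.1
  pred <- integrate_predictions(model, cube, targets = "gi")
  expect_equal(unname(pred["gi", 1, 2]), 1 / log(2), tolerance = 1e-12)

  # all-zero coefficients predict identically zero
  model0 <- model
  model0$alpha[] <- 0
  expect_true(all(integrate_predictions(model0, cube) == 0))

  # model-matched zero-noise simulation: integrated predictions track the
  # observed log2 trajectories of responsive targets within 2% RMS
  net <- make_cascade_network()
  cube2 <- simulate_experiments(net, cascade_designs())
  m <- suppressWarnings(fit_network(cube2))
  p <- integrate_predictions(m, cube2, targets = c("gB", "gD"))
  se <- 0; so <- 0
  for (tg in c("gB", "gD")) {
    keep <- attr(cube2, "induced") != tg  # forced rows are not modeled
    obs_l2 <- log2(cube2[tg, keep, ])
    se <- se + sum((p[tg, keep, ] - obs_l2)^2)
    so <- so + sum(obs_l2^2)
  }
  expect_lt(sqrt(se / so), 0.02)
})
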