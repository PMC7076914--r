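test_that("sigmoid evaluation matches its closed-form anchors", {
  expect_equal(eval_sigmoid(0.3, 20, 1.5, 20), 0.75)      # half-max
  expect_equal(eval_sigmoid(0.3, 20, 1.5, 1e5), 1.5)      # asymptote
  # sigma(x) = 0.75 at x = ln 3
  expect_equal(eval_sigmoid(0.25, 15, 2, 15 + 4 * log(3)), 1.5)
})

test_that("impulse evaluation nests the sigmoid and honors its asymptotes", {
  t <- seq(0, 90, by = 1)
  expect_equal(eval_impulse(0.3, 20, 1.5, 50, 1.5, t),
               eval_sigmoid(0.3, 20, 1.5, t))
  expect_equal(eval_impulse(0.3, 10, 2, 40, 0.5, 1e6), 0.5)
  # well-separated transitions: plateau reaches v_inter
  expect_lt(abs(eval_impulse(1, 10, 2, 60, 0, 35) - 2) / 2, 0.01)
  # unimodal between asymptotes
  f <- eval_impulse(0.4, 10, 2, 50, 0, t)
  peak <- which.max(f)
  expect_true(all(diff(f[seq_len(peak)]) >= -1e-9))
  expect_true(all(diff(f[peak:length(f)]) <= 1e-9))
})

test_that("penalized impulse objective at v_final = v_inter equals the sigmoid objective", {
  grid <- c(0, 5, 10, 15, 20, 30, 45, 90)
  y <- eval_sigmoid(0.3, 20, 1.5, grid)
  pr <- kinetic_priors()
  par_s <- c(log(0.3), 20, 1.5)
  par_i <- c(log(0.3), 20, 1.5, log(30), 1.5)  # t_fall = 50, v_final = v_inter
  obj_s <- inducenet:::kin_objective(par_s, grid, y, "sigmoid", pr)
  obj_i <- inducenet:::kin_objective(par_i, grid, y, "impulse", pr)
  # identical data term and f(0) penalty; impulse adds only the v_final prior
  expect_equal(obj_i - obj_s, 1.5^2 / (2 * pr$v_sd^2), tolerance = 1e-9)
})

test_that("noise-free sigmoid parameters are recovered to within 1%", {
  grid <- c(0, 5, 10, 15, 20, 30, 45, 90)
  y <- eval_sigmoid(0.3, 20, 1.5, grid)
  fit <- fit_timecourse(grid, y, "sigmoid", seed = 1)
  expect_lt(abs(fit$slope - 0.3) / 0.3, 0.01)
  expect_lt(abs(fit$t_rise - 20) / 20, 0.01)
  expect_lt(abs(fit$v_inter - 1.5) / 1.5, 0.01)
  expect_true(fit$converged)
})

test_that("an all-zero timecourse fits a null amplitude", {
  grid <- c(0, 5, 10, 15, 20, 30, 45, 90)
  fit <- fit_timecourse(grid, rep(0, 8), "sigmoid", seed = 2)
  expect_lt(abs(fit$v_inter), 0.01)
})

test_that("noisy sigmoid recovery is accurate and improves as noise falls", {
  grid <- c(0, 5, 10, 15, 20, 30, 45, 90)
  run <- function(sd, n = 30) {
    set.seed(100 + round(1000 * sd))
    replicate(n, {
      tr <- runif(1, 5, 40)
      y <- eval_sigmoid(runif(1, 0.1, 0.5), tr,
                        sample(c(-1, 1), 1) * runif(1, 0.5, 3), grid) +
        rnorm(8, 0, sd)
      y[1] <- 0
      fit <- fit_timecourse(grid, y, "sigmoid", seed = sample.int(1e6, 1))
      abs(fit$t_rise - tr)
    })
  }
  err_mid <- median(run(0.1))
  expect_lt(err_mid, 2)
  # recovery degrades monotonically with noise (median absolute error)
  errs <- c(median(run(0.02)), err_mid, median(run(0.3)))
  expect_true(all(diff(errs) > 0))
})

test_that("model selection prefers the sigmoid absent evidence and finds true impulses", {
  grid <- c(0, 5, 10, 15, 20, 30, 45, 90)
  y <- eval_sigmoid(0.3, 20, 1.5, grid)
  sig <- fit_timecourse(grid, y, "sigmoid", seed = 3)
  imp <- fit_timecourse(grid, y, "impulse", seed = 4)
  # force identical likelihoods: zero statistic, sigmoid chosen
  imp2 <- imp
  imp2$loglik <- sig$loglik
  imp2$par <- c(sig$par, log(30), sig$v_inter)
  sel0 <- select_model(sig, imp2)
  expect_equal(sel0$lr_stat, 0)
  expect_equal(sel0$model_class, "sigmoid")

  # strong impulse truth is detected
  set.seed(7)
  yi <- eval_impulse(0.3, 10, 2, 40, 0, grid) + rnorm(8, 0, 0.1)
  yi[1] <- 0
  sig2 <- fit_timecourse(grid, yi, "sigmoid", seed = 5)
  imp3 <- fit_timecourse(grid, yi, "impulse", seed = 6)
  sel <- select_model(sig2, imp3)
  expect_equal(sel$model_class, "impulse")
  expect_gte(sel$lr_stat, 0)
})

test_that("saturation times follow the logistic closed form", {
  fit <- structure(list(slope = 0.25, t_rise = 10, t_fall = 60,
                        model_class = "impulse"), class = "kinetic_fit")
  expect_identical(saturation_time(fit, "rise", 0.5), 10)
  expect_identical(saturation_time(fit, "fall", 0.5), 60)
  # symmetry about t_coef
  expect_equal(saturation_time(fit, "rise", 0.95) - 10,
               10 - saturation_time(fit, "rise", 0.05))
  # numeric inversion oracle: solve logistic(slope (t - t_coef)) = x
  for (x in c(0.05, 0.5, 0.95)) {
    t_num <- uniroot(function(t) plogis(0.25 * (t - 10)) - x,
                     c(-200, 200), tol = 1e-12)$root
    expect_lt(abs(saturation_time(fit, "rise", x) - t_num), 1e-8)
  }
  expect_equal(saturation_time(fit, "rise", 0.95), 10 + log(19) / 0.25)
  expect_error(saturation_time(fit, "rise", 1.2))
})

test_that("response intervals cover each transition's 5-95% window", {
  grid <- c(0, 5, 10, 15, 20, 30, 45, 90)
  sig <- structure(list(model_class = "sigmoid", slope = 0.4, t_rise = 20,
                        v_inter = 1.5, t_fall = NA, v_final = NA,
                        times = grid), class = "kinetic_fit")
  iv <- extract_response_intervals(sig)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$kind, "rise")
  expect_equal((iv$t_start + iv$t_end) / 2, 20)  # centered at t_rise
  expect_equal(iv$t_end - iv$t_start, 2 * log(19) / 0.4)

  imp <- structure(list(model_class = "impulse", slope = 0.5, t_rise = 10,
                        v_inter = 2, t_fall = 50, v_final = 0,
                        times = grid), class = "kinetic_fit")
  iv2 <- extract_response_intervals(imp)
  expect_equal(iv2$kind, c("rise", "fall"))
  expect_equal((iv2$t_start[2] + iv2$t_end[2]) / 2, 50)

  # negative-amplitude sigmoid is a fall; tiny amplitude emits nothing
  neg <- sig; neg$v_inter <- -1
  expect_equal(extract_response_intervals(neg)$kind, "fall")
  tiny <- sig; tiny$v_inter <- 0.05
  expect_equal(nrow(extract_response_intervals(tiny)), 0)
})

test_that("cube-level kinetic fitting tabulates selected timecourses", {
  net <- make_cascade_network()
  cube <- simulate_experiments(net, cascade_designs())
  obs <- corrupt_with_noise(cube, noise_spec(0.02, 0, 0, seed = 5))
  fits <- fit_kinetics(obs, min_signal = 0.5, seed = 42)
  expect_true(all(c("gene", "experiment", "model_class", "slope", "t_rise",
                    "v_inter", "lr_pvalue") %in% names(fits)))
  expect_true(all(fits$slope > 0))
  # the forced induction of gA appears as a fast strong rise
  ga <- fits[fits$gene == "gA" & fits$experiment == "expA", ]
  expect_lt(ga$t_rise, 10)
  expect_gt(ga$v_inter, 4)
  # deterministic under the seed
  fits2 <- fit_kinetics(obs, min_signal = 0.5, seed = 42)
  expect_identical(fits, fits2)
})
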