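# helper: build a one-gene spot table from per-time spot ratio pairs,
# using green = 10 so the C = 2 floor never bites
spots_from_ratios <- function(ratios, times = 5 * (seq_along(ratios) - 1)) {
  do.call(rbind, lapply(seq_along(ratios), function(i) {
    r <- ratios[[i]]
    data.frame(gene = "g1", experiment = "e1", time_min = times[i],
               spot_index = seq_along(r), red = r * 10, green = 10)
  }))
}

test_that("spot aggregation applies the intensity floor and two-spot identities", {
  sp <- data.frame(gene = "g1", experiment = "e1", time_min = 0,
                   spot_index = 1:2, red = c(8, 0), green = c(2, 0))
  agg <- aggregate_spots(sp, C = 2)
  # ratios: max(8,2)/max(2,2) = 4 and max(0,2)/max(0,2) = 1
  expect_equal(agg$rmin, 1)
  expect_equal(agg$rmax, 4)
  expect_equal(agg$rmedian, 2.5)
  expect_equal(agg$rsd, (4 - 1) / sqrt(2))

  sp2 <- spots_from_ratios(list(c(2, 2)))
  agg2 <- aggregate_spots(sp2)
  expect_equal(agg2$rmedian, 2)
  expect_equal(agg2$rsd, 0)
})

test_that("disagreeing spots are repaired by the bracketing geometric mean", {
  sp <- spots_from_ratios(list(c(2, 2), c(10, 2), c(8, 8)))
  agg <- aggregate_spots(sp)
  cube <- obs_to_cube(agg)
  out <- repair_spot_disagreement(cube, agg)
  expect_equal(nrow(out$flags), 1)
  expect_equal(out$flags$time_min, 5)
  expect_equal(out$cube["g1", "e1", 2], sqrt(2 * 8))
  expect_identical(out$cube["g1", "e1", c(1, 3)], cube["g1", "e1", c(1, 3)])

  # ratio 3 between spots is at-or-below the threshold: untouched
  sp2 <- spots_from_ratios(list(c(2, 2), c(3, 1), c(8, 8)))
  agg2 <- aggregate_spots(sp2)
  out2 <- repair_spot_disagreement(obs_to_cube(agg2), agg2)
  expect_equal(nrow(out2$flags), 0)

  # edge position: single-neighbor repair
  sp3 <- spots_from_ratios(list(c(10, 2), c(4, 4), c(8, 8)))
  agg3 <- aggregate_spots(sp3)
  out3 <- repair_spot_disagreement(obs_to_cube(agg3), agg3)
  expect_equal(out3$cube["g1", "e1", 1], 4)
})

test_that("spike outliers are repaired only on a >= 4x reversal", {
  mk <- function(v) {
    cube <- array(v, c(1, 1, length(v)),
                  dimnames = list("g1", "e1", paste0("t", seq_along(v))))
    attr(cube, "times") <- 5 * (seq_along(v) - 1)
    cube
  }
  up_down <- repair_spike_outliers(mk(c(1, 4.5, 1)))
  expect_equal(unname(up_down$cube[1, 1, 2]), 1)
  expect_equal(nrow(up_down$flags), 1)

  down_up <- repair_spike_outliers(mk(c(4, 1, 4)))
  expect_equal(unname(down_up$cube[1, 1, 2]), 4)

  monotone <- repair_spike_outliers(mk(c(1, 4, 16)))
  expect_equal(nrow(monotone$flags), 0)

  small <- repair_spike_outliers(mk(c(1, 2, 1)))
  expect_equal(nrow(small$flags), 0)

  # idempotence: re-running the repair changes nothing
  again <- repair_spike_outliers(up_down$cube)
  expect_identical(again$cube, up_down$cube)
  expect_equal(nrow(again$flags), 0)
})

test_that("crosstalk repair requires both quantile criteria and reuses t0 green", {
  times <- c(0, 5, 10, 15, 20, 30)
  mk_spots <- function(y, green) {
    do.call(rbind, lapply(seq_along(times), function(i) {
      data.frame(gene = "g1", experiment = "e1", time_min = times[i],
                 spot_index = 1:2, red = y[i] * green[1],
                 green = green[i])
    }))
  }
  # inflated green, expression ratio far from 1: both criteria fire
  green <- c(100, rep(1000, 5))
  y <- rep(1.5, 6)
  sp <- mk_spots(y, green)  # red = 150, observed ratio 0.15 for t > 0
  agg <- aggregate_spots(sp)
  cube <- obs_to_cube(agg)
  out <- repair_crosstalk(cube, sp)
  expect_equal(nrow(out$flags), 1)
  expect_equal(unname(out$cube[1, 1, ]), rep(1.5, 6))

  # green constant: untouched
  sp2 <- mk_spots(y, rep(100, 6))
  agg2 <- aggregate_spots(sp2)
  out2 <- repair_crosstalk(obs_to_cube(agg2), sp2)
  expect_equal(nrow(out2$flags), 0)

  # green inflated but red inflated alongside (log-ratio stays small):
  # conjunction fails, untouched
  sp3 <- mk_spots(y, green)
  sp3$red <- y[match(sp3$time_min, times)] * sp3$green
  agg3 <- aggregate_spots(sp3)
  out3 <- repair_crosstalk(obs_to_cube(agg3), sp3)
  expect_equal(nrow(out3$flags), 0)
})

test_that("class-median subtraction removes shared structure and centers output", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:6)
  exps <- sprintf("e%d", 1:5)
  cube <- array(exp(rnorm(6 * 5 * 4, 0, 0.3)), c(6, 5, 4),
                dimnames = list(genes, exps, paste0("t", c(0, 5, 10, 15))))
  cube[, , 1] <- 1
  attr(cube, "times") <- c(0, 5, 10, 15)
  cmap <- setNames(c("ZEV", "ZEV", "ZEV", "GEV", "GEV"), exps)
  out <- subtract_class_median(cube, cmap)
  lg <- log(out$cube)
  for (cl in c("ZEV", "GEV")) {
    med <- apply(lg[, cmap == cl, , drop = FALSE], c(1, 3), median)
    expect_lt(max(abs(med)), 1e-12)
  }

  # identical timecourses within a class vanish entirely
  cube2 <- cube
  cube2[1, cmap == "ZEV", ] <- rep(c(1, 2, 3, 4), each = 3)
  out2 <- subtract_class_median(cube2, cmap)
  expect_lt(max(abs(log(out2$cube[1, cmap == "ZEV", ]))), 1e-12)

  # single-experiment class: warn and skip
  cmap3 <- setNames(c("ZEV", "ZEV", "ZEV", "ZEV", "GEV"), exps)
  expect_warning(out3 <- subtract_class_median(cube, cmap3), "GEV")
  expect_identical(out3$cube[, "e5", ], cube[, "e5", ])
})

test_that("hard-thresholding keeps signal and zeroes noise-consistent courses", {
  # a gene responds in only a minority of experiments, so the robust
  # per-gene noise estimate comes from its invariant majority
  set.seed(41)
  n_genes <- 500
  n_exp <- 5
  times <- c(0, 5, 10, 15, 20, 30, 45, 90)
  sigma <- 0.1
  lg <- array(rnorm(n_genes * n_exp * 7, 0, sigma), c(n_genes, n_exp, 7))
  n_resp <- round(0.05 * n_genes * n_exp)  # 5% of timecourses at 8 sigma
  resp_idx <- cbind(sample.int(n_genes, n_resp, replace = TRUE),
                    sample.int(n_exp, n_resp, replace = TRUE))
  resp_idx <- unique(resp_idx)
  for (r in seq_len(nrow(resp_idx))) {
    lg[resp_idx[r, 1], resp_idx[r, 2], ] <-
      lg[resp_idx[r, 1], resp_idx[r, 2], ] +
      8 * sigma * sample(c(-1, 1), 1)
  }
  cube <- array(1, c(n_genes, n_exp, 8),
                dimnames = list(sprintf("g%04d", 1:n_genes),
                                paste0("e", 1:n_exp), paste0("t", times)))
  cube[, , -1] <- exp(lg)
  attr(cube, "times") <- times
  th <- threshold_noise(cube, fdr_q = 0.05)
  is_resp <- matrix(FALSE, n_genes, n_exp)
  is_resp[resp_idx] <- TRUE
  expect_gte(mean(th$selected[is_resp]), 0.95)
  expect_lte(mean(th$selected[!is_resp]), 2 * 0.05)
  # hard thresholding: output is exactly the input or exactly invariant
  kept <- which(th$selected, arr.ind = TRUE)
  expect_identical(th$cube[cbind(kept, 3)], cube[cbind(kept, 3)])
  dropped <- which(!th$selected, arr.ind = TRUE)
  expect_true(all(th$cube[cbind(dropped, 4)] == 1))

  # an all-flat timecourse is never selected
  expect_false({
    flat <- cube
    flat[2, 1, ] <- 1
    threshold_noise(flat, fdr_q = 0.05)$selected[2, 1]
  })

  # extreme signal is always selected
  expect_true({
    loud <- cube
    loud[3, 1, ] <- exp(c(0, rep(10 * sigma, 6), 0.5 * sigma))
    threshold_noise(loud, fdr_q = 0.05)$selected[3, 1]
  })
})

test_that("the full chain is the identity on clean data with shared stress", {
  net <- generate_network(15, 6, sparsity = 1e-9, seed = 51)
  designs <- lapply(1:6, function(j)
    induction_design(paste0("e", j), net$gene_ids[j],
                     system_class = if (j <= 3) "ZEV" else "GEV"))
  cube <- simulate_experiments(net, designs)
  grid_len <- length(attr(cube, "times"))
  stress <- list(ZEV = c(1, seq(1.1, 1.02, length.out = grid_len - 1)),
                 GEV = c(1, seq(1.15, 1.01, length.out = grid_len - 1)))
  spec <- noise_spec(0, 0, 0, stress_signature = stress, seed = 61)
  obs <- corrupt_with_noise(cube, spec)
  st <- render_spot_table(obs, spec)
  res <- preprocess_spots(st$spots, attr(cube, "class_map"), fdr_q = NA)
  expect_equal(nrow(res$flags), 0)
  expect_lt(max(abs(log(res$cube) - log(cube))), 1e-9)
})
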