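#' Generate a ground-truth regulatory network
#'
#' Draws a sparse directed network over `n_genes` genes in which only the
#' first `n_regulators` genes may have outgoing edges. Each edge carries a
#' linear coefficient (`alpha`) and, optionally, a target-proportional
#' coefficient (`beta`); these are the coefficients of the dynamical model
#' \deqn{d\,\ln y_i/dt = \sum_k \alpha_{ik}(y_k - 1) +
#'       \beta_{ik}(y_i y_k - 1)/y_i,}
#' in units of 1/min per unit ratio-deviation. The diagonal is always zero
#' (no self-edges).
#'
#' @param n_genes number of genes.
#' @param n_regulators number of genes (the first `n_regulators`) allowed to
#'   have outgoing edges; must not exceed `n_genes`.
#' @param sparsity target fraction of nonzero entries of the full
#'   `n_genes x n_genes` coefficient matrix, in (0, 1]. The realized count is
#'   `round(sparsity * n_genes^2)` (capped at the number of admissible
#'   off-diagonal regulator-column cells).
#' @param effect_scale typical coefficient magnitude (1/min); magnitudes are
#'   drawn uniformly in `[0.5, 1.5] * effect_scale` with random sign. The
#'   default 5e-4 gives a few-fold response in direct targets of a ~50-fold
#'   induced regulator over a 90-min timecourse.
#' @param beta_fraction fraction of edges whose weight is placed on the
#'   target-proportional `beta` coefficient instead of `alpha` (default 0:
#'   purely linear ground truth).
#' @param seed integer RNG seed.
#' @return an object of class `true_network`: a list with `gene_ids`,
#'   `regulators`, dense matrices `alpha` and `beta` (target x regulator,
#'   rows/cols named by gene), and the realized `sparsity`.
#' @export
#' @examples
#' net <- generate_network(20, 5, sparsity = 0.02, seed = 1)
#' sum(net$alpha != 0 | net$beta != 0)
generate_network <- function(n_genes, n_regulators, sparsity,
                             effect_scale = 5e-4, beta_fraction = 0,
                             seed = NULL) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (n_regulators > n_genes) stop("n_regulators must not exceed n_genes")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  regulators <- gene_ids[seq_len(n_regulators)]
  alpha <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
  beta <- alpha

  n_edges <- round(sparsity * n_genes^2)
  # admissible cells: regulator columns, off-diagonal
  cells <- which(col(alpha) <= n_regulators & row(alpha) != col(alpha))
  n_edges <- min(n_edges, length(cells))
  with_seed(seed, {
    pick <- sample(cells, n_edges)
    mag <- stats::runif(n_edges, 0.5, 1.5) * effect_scale
    sgn <- sample(c(-1, 1), n_edges, replace = TRUE)
    is_beta <- stats::runif(n_edges) < beta_fraction
    alpha[pick[!is_beta]] <- (mag * sgn)[!is_beta]
    beta[pick[is_beta]] <- (mag * sgn)[is_beta]
  })
  structure(
    list(gene_ids = gene_ids, regulators = regulators,
         alpha = alpha, beta = beta,
         sparsity = n_edges / n_genes^2),
    class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf(
    "true_network: %d genes, %d regulators, %d edges (sparsity %.4f)\n",
    length(x$gene_ids), length(x$regulators),
    sum(x$alpha != 0 | x$beta != 0), x$sparsity))
  invisible(x)
}

#' Describe a single induction experiment
#'
#' An experiment induces one gene from a synthetic promoter: its relative
#' expression is forced along a saturating sigmoid reaching `induction_fold`
#' while every other gene responds through the network. The default sampling
#' grid is 0, 5, 10, 15, 20, 30, 45, 90 min, and the default induction
#' profile saturates within ~10 min at 50-fold.
#'
#' @param experiment_id character identifier.
#' @param induced_gene gene identifier of the induced regulator.
#' @param time_grid_min ascending sampling times in minutes, starting at 0.
#' @param system_class induction system label, `"GEV"` or `"ZEV"`; each class
#'   carries its own background stress signature.
#' @param induction_fold peak fold change of the induced gene (> 1).
#' @param induction_halftime_min half-max time of the induction profile.
#' @param induction_slope_per_min logistic slope of the induction profile;
#'   the default 0.6/min puts 95% saturation ~5 min after half-max.
#' @return an object of class `induction_design`.
#' @export
induction_design <- function(experiment_id, induced_gene,
                             time_grid_min = c(0, 5, 10, 15, 20, 30, 45, 90),
                             system_class = c("ZEV", "GEV"),
                             induction_fold = 50,
                             induction_halftime_min = 5,
                             induction_slope_per_min = 0.6) {
  system_class <- match.arg(system_class)
  stopifnot(time_grid_min[1] == 0, !is.unsorted(time_grid_min, strictly = TRUE))
  if (induction_fold <= 1) stop("induction_fold must exceed 1")
  structure(
    list(experiment_id = experiment_id, induced_gene = induced_gene,
         time_grid_min = time_grid_min, system_class = system_class,
         induction_fold = induction_fold,
         induction_halftime_min = induction_halftime_min,
         induction_slope_per_min = induction_slope_per_min),
    class = "induction_design")
}

#' Forced induction profile of the induced gene
#'
#' Relative expression of the induced gene: a logistic rise anchored so that
#' the profile equals exactly 1 at t = 0 and approaches `fold` as t grows.
#'
#' @param t times (min).
#' @param fold peak fold change.
#' @param halftime half-max time (min).
#' @param slope logistic slope (1/min).
#' @return ratio-scale expression values.
#' @export
induction_profile <- function(t, fold, halftime, slope) {
  s0 <- logistic(-slope * halftime)
  1 + (fold - 1) * (logistic(slope * (t - halftime)) - s0) / (1 - s0)
}

#' Simulate one noise-free induction experiment
#'
#' Integrates the network dynamics in log space with a fixed-step classical
#' Runge-Kutta scheme while the induced gene follows its forced profile, and
#' samples the trajectory at the design's grid. Working in `ln y` guarantees
#' positivity of the ratio-scale values.
#'
#' @param network a `true_network`.
#' @param design an `induction_design`; `design$induced_gene` must be one of
#'   `network$gene_ids`.
#' @param integration_step_min integration step (min), default 0.1; must not
#'   exceed the smallest grid spacing.
#' @param ln_bound divergence guard: integration aborts if any `|ln y|`
#'   exceeds this bound (default 15), naming the offending gene.
#' @return matrix of ratio-scale expression (gene x time), with the time grid
#'   in minutes as an attribute `"times"`. Every gene equals exactly 1 at
#'   t = 0.
#' @export
simulate_induction <- function(network, design, integration_step_min = 0.1,
                               ln_bound = 15) {
  stopifnot(inherits(network, "true_network"),
            inherits(design, "induction_design"))
  gi <- network$gene_ids
  idx <- match(design$induced_gene, gi)
  if (is.na(idx)) stop("induced gene not in network: ", design$induced_gene)
  grid <- design$time_grid_min
  if (integration_step_min > min(diff(grid)))
    stop("integration step exceeds the smallest grid spacing")

  A <- network$alpha
  B <- network$beta
  rsB <- rowSums(B)
  forced <- function(t) induction_profile(
    t, design$induction_fold, design$induction_halftime_min,
    design$induction_slope_per_min)

  # d z_i/dt with z = ln y; beta term expanded:
  # sum_k beta_ik (y_i y_k - 1)/y_i = (B y)_i - rowSums(B)_i / y_i
  deriv <- function(z, t) {
    y <- exp(z)
    y[idx] <- forced(t)
    dz <- drop(A %*% (y - 1)) + drop(B %*% y) - rsB / y
    dz[idx] <- 0
    dz
  }

  n <- length(gi)
  z <- numeric(n)
  out <- matrix(NA_real_, n, length(grid), dimnames = list(gi, NULL))
  out[, 1] <- 1
  h <- integration_step_min
  for (seg in seq_len(length(grid) - 1L)) {
    t0 <- grid[seg]; t1 <- grid[seg + 1L]
    nstep <- ceiling((t1 - t0) / h - 1e-9)
    hh <- (t1 - t0) / nstep
    t <- t0
    for (s in seq_len(nstep)) {
      k1 <- deriv(z, t)
      k2 <- deriv(z + hh / 2 * k1, t + hh / 2)
      k3 <- deriv(z + hh / 2 * k2, t + hh / 2)
      k4 <- deriv(z + hh * k3, t + hh)
      z <- z + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
      if (any(abs(z) > ln_bound)) {
        bad <- gi[which.max(abs(z))]
        stop("integration diverged (|ln y| > ", ln_bound, ") for gene ", bad)
      }
    }
    y <- exp(z)
    y[idx] <- forced(t1)
    out[, seg + 1L] <- y
  }
  attr(out, "times") <- grid
  out
}

#' Measurement-noise and background specification
#'
#' Describes how true expression is corrupted on its way to observed spot
#' intensities: multiplicative log-normal noise with gene- and array-level
#' variance components, a per-class background ("stress") signature shared by
#' all experiments of an induction-system class, duplicate spots with their
#' own noise, and planted artifact events (spot disagreement, transient
#' spikes, channel crosstalk).
#'
#' @param gene_log_sd per-gene noise scale in natural-log units (recycled
#'   over genes).
#' @param array_log_sd per-array (experiment x time) noise scale, natural-log
#'   units.
#' @param spot_log_sd per-spot noise scale, natural-log units.
#' @param stress_signature named list mapping class (`"GEV"`, `"ZEV"`) to a
#'   multiplicative ratio-scale timecourse on the sampling grid (first
#'   element must be 1); `NULL` for no background.
#' @param spot_count spots per gene per array (default 2).
#' @param artifact_rates named numeric: probabilities per eligible position
#'   for `disagreement`, `spike` and `crosstalk` events.
#' @param artifact_counts named integer: exact numbers of events to plant
#'   (takes precedence over `artifact_rates` when non-NULL).
#' @param seed integer RNG seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(gene_log_sd = 0.07, array_log_sd = 0.03,
                       spot_log_sd = 0.02, stress_signature = NULL,
                       spot_count = 2,
                       artifact_rates = c(disagreement = 0, spike = 0,
                                          crosstalk = 0),
                       artifact_counts = NULL, seed = NULL) {
  stopifnot(all(gene_log_sd >= 0), all(array_log_sd >= 0),
            all(spot_log_sd >= 0), spot_count >= 1)
  rates <- c(disagreement = 0, spike = 0, crosstalk = 0)
  rates[names(artifact_rates)] <- artifact_rates
  stopifnot(all(rates >= 0 & rates <= 1))
  if (!is.null(stress_signature))
    stopifnot(all(vapply(stress_signature, function(s) s[1] == 1, logical(1))))
  structure(
    list(gene_log_sd = gene_log_sd, array_log_sd = array_log_sd,
         spot_log_sd = spot_log_sd, stress_signature = stress_signature,
         spot_count = spot_count, artifact_rates = rates,
         artifact_counts = artifact_counts, seed = seed),
    class = "noise_spec")
}

#' Simulate a set of induction experiments into an expression cube
#'
#' Runs [simulate_induction()] for each design and stacks the results into a
#' 3-d array (gene x experiment x time). All designs must share one sampling
#' grid.
#'
#' @param network a `true_network`.
#' @param designs list of `induction_design` objects.
#' @param integration_step_min passed to [simulate_induction()].
#' @return array with dimnames (gene, experiment, time) and attributes
#'   `times` (numeric grid), `class_map` (experiment -> system class) and
#'   `induced` (experiment -> induced gene).
#' @export
simulate_experiments <- function(network, designs,
                                 integration_step_min = 0.1) {
  grids <- lapply(designs, `[[`, "time_grid_min")
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1)
    stop("all designs must share one time grid")
  grid <- grids[[1]]
  ids <- vapply(designs, `[[`, character(1), "experiment_id")
  cube <- array(NA_real_,
                dim = c(length(network$gene_ids), length(designs),
                        length(grid)),
                dimnames = list(network$gene_ids, ids,
                                paste0("t", grid)))
  for (j in seq_along(designs)) {
    cube[, j, ] <- simulate_induction(network, designs[[j]],
                                      integration_step_min)
  }
  attr(cube, "times") <- grid
  attr(cube, "class_map") <- stats::setNames(
    vapply(designs, `[[`, character(1), "system_class"), ids)
  attr(cube, "induced") <- stats::setNames(
    vapply(designs, `[[`, character(1), "induced_gene"), ids)
  cube
}

#' Corrupt a noise-free expression cube with measurement noise
#'
#' Each observation is multiplied by its class's background (stress)
#' signature and by `exp(eps)` with
#' `eps ~ Normal(0, gene_log_sd^2 + array_log_sd^2)` (log-normal noise with
#' gene and array variance components). Each experiment is then renormalized
#' to its own t = 0 value, mirroring the ratio-to-time-zero convention of the
#' measurement, so every timecourse starts at exactly 1.
#'
#' @param cube array from [simulate_experiments()] (or one compatible with
#'   its attributes).
#' @param spec a [noise_spec()].
#' @return cube of the same shape, observed scale.
#' @export
corrupt_with_noise <- function(cube, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  times <- attr(cube, "times")
  class_map <- attr(cube, "class_map")
  d <- dim(cube)
  gene_sd <- rep_len(spec$gene_log_sd, d[1])
  out <- cube
  if (!is.null(spec$stress_signature)) {
    for (j in seq_len(d[2])) {
      s <- spec$stress_signature[[class_map[j]]]
      if (is.null(s)) next
      if (length(s) != d[3]) stop("stress signature grid mismatch")
      out[, j, ] <- sweep(out[, j, , drop = FALSE], 3, s, `*`)
    }
  }
  with_seed(spec$seed, {
    sd_it <- sqrt(outer(gene_sd^2, rep_len(spec$array_log_sd, d[2] * d[3])^2,
                        `+`))
    eps <- array(stats::rnorm(length(out), 0, sd_it), dim = d)
    out <- out * exp(eps)
  })
  # renormalize to t = 0 (ratio-to-time-zero convention)
  out <- out / as.vector(out[, , 1, drop = TRUE])
  attributes(out)[c("dim", "dimnames")] <- attributes(cube)[c("dim", "dimnames")]
  attr(out, "times") <- times
  attr(out, "class_map") <- class_map
  attr(out, "induced") <- attr(cube, "induced")
  out
}

#' Render an expression cube down to two-channel spot intensities
#'
#' Emits `spot_count` red/green intensity pairs per observation whose ratio
#' recovers the cube value up to spot-level log-normal noise, and plants
#' three classes of artifacts at configured rates (or exact counts):
#' \describe{
#'   \item{disagreement}{one spot's red channel is inflated 5x, so the two
#'     spot ratios disagree by more than 4x;}
#'   \item{spike}{all spots' red channels at one interior time are inflated
#'     5x, producing a >= 4x move followed by a >= 4x reversal;}
#'   \item{crosstalk}{the green channel of a whole timecourse is inflated
#'     10x at every t > 0, emulating red-to-green channel leakage.}
#' }
#' Artifacts are never planted on induced genes (their genuine ~50-fold jump
#' would confound the planted patterns), and at most one artifact is planted
#' per (gene, experiment) timecourse so the planted ledger is exact.
#'
#' @param cube observed expression cube.
#' @param spec a [noise_spec()].
#' @param base_intensity green-channel intensity level (arbitrary units).
#' @return list with `spots` (data.frame: gene, experiment, time_min,
#'   spot_index, red, green) and `ledger` (data.frame: type, gene,
#'   experiment, time_min; `time_min` is NA for crosstalk, which affects a
#'   whole timecourse).
#' @export
render_spot_table <- function(cube, spec, base_intensity = 500) {
  stopifnot(inherits(spec, "noise_spec"), spec$spot_count >= 1)
  times <- attr(cube, "times")
  d <- dim(cube)
  genes <- dimnames(cube)[[1]]
  exps <- dimnames(cube)[[2]]
  induced <- attr(cube, "induced")

  long <- expand.grid(gene = genes, experiment = exps, time_min = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$y <- as.vector(cube)

  seed2 <- if (is.null(spec$seed)) NULL else derive_seed(spec$seed, "spots")
  n_spot <- spec$spot_count
  spots <- long[rep(seq_len(nrow(long)), each = n_spot), ]
  spots$spot_index <- rep(seq_len(n_spot), nrow(long))
  ledger <- data.frame(type = character(0), gene = character(0),
                       experiment = character(0), time_min = numeric(0))
  with_seed(seed2, {
    eps <- stats::rnorm(nrow(spots), 0, spec$spot_log_sd)
    spots$green <- base_intensity
    spots$red <- spots$y * base_intensity * exp(eps)

    # eligible timecourses: non-induced genes, one artifact max per course,
    # quiet courses preferred (a spike planted on a genuinely fast-changing
    # course would not match the artifact's defining reversal pattern, so
    # the ledger could not be exact)
    tc <- unique(spots[, c("gene", "experiment")])
    if (!is.null(induced)) tc <- tc[tc$gene != induced[tc$experiment], ]
    quiet <- vapply(seq_len(nrow(tc)), function(r) {
      y <- cube[tc$gene[r], tc$experiment[r], ]
      all(abs(diff(log(y))) < log(1.25))
    }, logical(1))
    tc <- rbind(tc[quiet, ][sample.int(sum(quiet)), ],
                tc[!quiet, ][sample.int(sum(!quiet)), ])

    counts <- spec$artifact_counts
    if (is.null(counts)) {
      # expected events from per-position rates
      n_pos <- nrow(tc) * length(times)
      counts <- c(
        disagreement = stats::rbinom(1, n_pos,
                                     spec$artifact_rates[["disagreement"]]),
        spike = stats::rbinom(1, nrow(tc) * max(length(times) - 2L, 0L),
                              spec$artifact_rates[["spike"]]),
        crosstalk = stats::rbinom(1, nrow(tc),
                                  spec$artifact_rates[["crosstalk"]]))
    }
    counts <- counts[c("disagreement", "spike", "crosstalk")]
    counts[is.na(counts)] <- 0
    if (sum(counts) > nrow(tc))
      stop("more artifacts requested than available timecourses")
    take <- 0L
    key <- function(df) paste(df$gene, df$experiment, sep = "\r")
    spot_key <- key(spots)

    if (counts[["disagreement"]] > 0) {
      pick <- tc[take + seq_len(counts[["disagreement"]]), ]
      take <- take + nrow(pick)
      pick$time_min <- times[sample.int(length(times), nrow(pick),
                                        replace = TRUE)]
      for (r in seq_len(nrow(pick))) {
        sel <- spot_key == key(pick[r, ]) &
          spots$time_min == pick$time_min[r] & spots$spot_index == 1L
        spots$red[sel] <- spots$red[sel] * 5
      }
      ledger <- rbind(ledger, data.frame(type = "disagreement",
                                         pick[, c("gene", "experiment",
                                                  "time_min")]))
    }
    if (counts[["spike"]] > 0) {
      if (length(times) < 3) stop("spike artifacts need >= 3 time points")
      pick <- tc[take + seq_len(counts[["spike"]]), ]
      take <- take + nrow(pick)
      interior <- times[2:(length(times) - 1L)]
      pick$time_min <- interior[sample.int(length(interior), nrow(pick),
                                           replace = TRUE)]
      for (r in seq_len(nrow(pick))) {
        sel <- spot_key == key(pick[r, ]) & spots$time_min == pick$time_min[r]
        spots$red[sel] <- spots$red[sel] * 5
      }
      ledger <- rbind(ledger, data.frame(type = "spike",
                                         pick[, c("gene", "experiment",
                                                  "time_min")]))
    }
    if (counts[["crosstalk"]] > 0) {
      pick <- tc[take + seq_len(counts[["crosstalk"]]), ]
      for (r in seq_len(nrow(pick))) {
        sel <- spot_key == key(pick[r, ]) & spots$time_min > 0
        spots$green[sel] <- spots$green[sel] * 10
      }
      ledger <- rbind(ledger, data.frame(type = "crosstalk",
                                         pick[, c("gene", "experiment")],
                                         time_min = NA_real_))
    }
  })
  spots$y <- NULL
  rownames(spots) <- NULL
  rownames(ledger) <- NULL
  list(spots = spots[, c("gene", "experiment", "time_min", "spot_index",
                         "red", "green")],
       ledger = ledger)
}
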