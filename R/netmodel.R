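#' Build the per-target dynamical regression design
#'
#' For one target gene, rows index (experiment, interval between
#' consecutive observed times). The dependent variable is the
#' finite-difference rate `(ln y[t'] - ln y[t]) / (t' - t)` (1/min). For
#' every candidate regulator k there are two predictors, evaluated at the
#' interval start (or averaged over its endpoints with
#' `at = "midpoint"`): the linear term `y_k - 1` and the
#' target-proportional term `(y_i * y_k - 1) / y_i`. Because every gene
#' equals 1 at t = 0, all predictors of the interval starting at t = 0
#' vanish under `at = "start"`: the pre-induction steady state is encoded
#' structurally and no intercept exists anywhere.
#'
#' @param cube normalized expression cube (ratio scale, y = 1 at t = 0).
#' @param target gene identifier of the modeled target.
#' @param regulators candidate regulator identifiers; defaults to all genes.
#' @param exclude_self drop the target from its own regulator set
#'   (default TRUE).
#' @param at `"start"` or `"midpoint"` evaluation of predictors.
#' @param exclude_induced drop the rows of experiments in which the target
#'   itself is the induced gene (default TRUE, applied when the cube
#'   carries an `induced` attribute). An induced gene's expression is
#'   forced exogenously by the inducer, so its rate of change is not
#'   described by the network model and those rows would only add
#'   unexplainable variance.
#' @return list of class `design_matrix`: `X` (rows x 2K matrix with columns
#'   `alpha.<k>` then `beta.<k>`), `y` (rates), `experiment`, `dt`
#'   (interval widths), `t_start`, `regulators`, `target`, `at`.
#' @export
build_design <- function(cube, target, regulators = NULL,
                         exclude_self = TRUE, at = c("start", "midpoint"),
                         exclude_induced = TRUE) {
  at <- match.arg(at)
  times <- attr(cube, "times")
  genes <- dimnames(cube)[[1]]
  exps <- dimnames(cube)[[2]]
  induced <- attr(cube, "induced")
  if (exclude_induced && !is.null(induced)) {
    exps <- exps[is.na(induced[exps]) | induced[exps] != target]
  }
  regulators <- regulators %||% genes
  if (exclude_self) regulators <- setdiff(regulators, target)
  if (any(cube <= 0)) stop("cube must be strictly positive (log undefined)")
  K <- length(regulators)
  nint <- length(times) - 1L
  nrows <- length(exps) * nint

  X <- matrix(0, nrows, 2L * K,
              dimnames = list(NULL, c(paste0("alpha.", regulators),
                                      paste0("beta.", regulators))))
  y <- numeric(nrows)
  expe <- character(nrows)
  dt <- numeric(nrows)
  t_start <- numeric(nrows)
  row <- 0L
  for (e in exps) {
    yi <- cube[target, e, ]
    Yk <- cube[regulators, e, , drop = FALSE][, 1, ]  # K x T
    if (K == 1) Yk <- matrix(Yk, nrow = 1)
    for (s in seq_len(nint)) {
      row <- row + 1L
      terms_at <- function(ti) {
        a <- Yk[, ti] - 1
        b <- (yi[ti] * Yk[, ti] - 1) / yi[ti]
        c(a, b)
      }
      X[row, ] <- if (at == "start") terms_at(s) else
        (terms_at(s) + terms_at(s + 1L)) / 2
      dt[row] <- times[s + 1L] - times[s]
      y[row] <- (log(yi[s + 1L]) - log(yi[s])) / dt[row]
      expe[row] <- e
      t_start[row] <- times[s]
    }
  }
  structure(list(X = X, y = y, experiment = expe, dt = dt,
                 t_start = t_start, regulators = regulators,
                 target = target, at = at),
            class = "design_matrix")
}

# L1 objective: RSS + lambda * sum(|coef|), no intercept
lasso_objective <- function(X, y, coef, lambda) {
  sum((y - drop(X %*% coef))^2) + lambda * sum(abs(coef))
}

# coefficients at several penalties from a single glmnet path
# (path interpolation; used where per-lambda exactness is not needed)
lasso_path_coefs <- function(X, y, lambdas) {
  n <- length(y)
  keep <- which(colSums(X != 0) > 0)
  B <- matrix(0, ncol(X), length(lambdas),
              dimnames = list(colnames(X), NULL))
  if (length(keep) < 2) {
    for (l in seq_along(lambdas))
      B[, l] <- fit_gene_lasso(list(X = X, y = y), lambdas[l])
    return(B)
  }
  lam_g <- lambdas / (2 * n)
  lam_max <- max(abs(crossprod(X[, keep, drop = FALSE], y))) / n
  path <- sort(unique(c(lam_g, lam_max)), decreasing = TRUE)
  # drop near-duplicates so the solver's warm-start grid is well separated
  sep <- c(TRUE, abs(diff(log(path))) > 1e-8)
  path <- path[sep]
  fit <- glmnet::glmnet(X[, keep, drop = FALSE], y, family = "gaussian",
                        alpha = 1, lambda = path, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  idx <- vapply(lam_g, function(l) which.min(abs(log(path) - log(l))),
                integer(1))
  B[keep, ] <- as.matrix(fit$beta)[, idx, drop = FALSE]
  B
}

#' Fit one target's coefficients by L1-penalized regression
#'
#' Minimizes `sum (y - X b)^2 + lambda * sum |b|` with no intercept (the
#' steady-state constraint leaves no room for one). Uninformative
#' coefficients are shrunk exactly to zero. The heavy lifting is done by
#' glmnet, with the penalty rescaled to this objective's parameterization.
#'
#' @param design a `design_matrix`, or a list with `X` and `y`.
#' @param lambda penalty weight, >= 0.
#' @return named coefficient vector (one entry per design column).
#' @export
fit_gene_lasso <- function(design, lambda) {
  stopifnot(lambda >= 0)
  X <- design$X
  y <- design$y
  n <- length(y)
  keep <- which(colSums(X != 0) > 0)
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (length(keep) == 0) return(coefs)
  Xk <- X[, keep, drop = FALSE]
  if (lambda == 0 || length(keep) == 1) {
    # closed forms: OLS (ridge-stabilized) / single-predictor soft threshold
    if (length(keep) == 1) {
      xx <- sum(Xk^2)
      xy <- sum(Xk * y)
      coefs[keep] <- sign(xy) * max(abs(xy) - lambda / 2, 0) / xx
    } else {
      coefs[keep] <- drop(solve(crossprod(Xk) +
                                  diag(1e-10, ncol(Xk)), crossprod(Xk, y)))
    }
    return(coefs)
  }
  lam_g <- lambda / (2 * n)
  lam_max <- max(abs(crossprod(Xk, y))) / n
  if (lam_g >= lam_max) return(coefs)  # penalty saturates: all-zero solution
  path <- exp(seq(log(lam_max), log(lam_g), length.out = 30))
  path[length(path)] <- lam_g  # exact endpoint, no interpolation needed
  fit <- glmnet::glmnet(Xk, y, family = "gaussian", alpha = 1,
                        lambda = path, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
  # lam_g is the exact last path element, so no refit or interpolation
  b <- as.vector(fit$beta[, length(path)])
  coefs[keep] <- b
  coefs
}

#' Leave-one-experiment-out cross-validation of the penalty weight
#'
#' Whole experiments are held out in turn; for each candidate `lambda` the
#' model is fit on the remaining experiments and the held-out rates are
#' predicted. Experiments partition the rows: each appears in exactly one
#' fold.
#'
#' @param design a `design_matrix`.
#' @param lambda_grid candidate penalties (this objective's scale).
#' @param one_se use the one-standard-error rule instead of the minimum
#'   (default FALSE).
#' @return list with `lambda` (selected), `cv` (data.frame lambda, mse, se)
#'   and `fallback` (TRUE when the target is responsive in < 2 experiments,
#'   in which case the median grid value is returned).
#' @export
cross_validate <- function(design, lambda_grid, one_se = FALSE) {
  exps <- unique(design$experiment)
  responsive <- vapply(exps, function(e) {
    any(abs(design$y[design$experiment == e]) > 1e-8)
  }, logical(1))
  if (sum(responsive) < 2) {
    return(list(lambda = stats::median(lambda_grid), cv = NULL,
                fallback = TRUE))
  }
  err <- matrix(NA_real_, length(exps), length(lambda_grid))
  for (f in seq_along(exps)) {
    hold <- design$experiment == exps[f]
    B <- lasso_path_coefs(design$X[!hold, , drop = FALSE],
                          design$y[!hold], lambda_grid)
    pred <- design$X[hold, , drop = FALSE] %*% B
    err[f, ] <- colMeans((design$y[hold] - pred)^2)
  }
  mse <- colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(nrow(err))
  best <- which.min(mse)
  sel <- best
  if (one_se) {
    ok <- which(mse <= mse[best] + se[best])
    sel <- ok[which.max(lambda_grid[ok])]
  }
  list(lambda = lambda_grid[sel],
       cv = data.frame(lambda = lambda_grid, mse = mse, se = se),
       fallback = FALSE)
}

#' Select the penalty weight by BIC
#'
#' `BIC = n * ln(RSS / n) + df * ln(n)` with `df` the number of nonzero
#' coefficients. Ties are broken toward the largest penalty (the sparsest
#' model).
#'
#' @param design a `design_matrix`.
#' @param lambda_grid candidate penalties.
#' @return list with selected `lambda` and the per-candidate `table`.
#' @export
select_lambda_bic <- function(design, lambda_grid) {
  n <- length(design$y)
  bic <- vapply(lambda_grid, function(l) {
    b <- fit_gene_lasso(design, l)
    rss <- sum((design$y - drop(design$X %*% b))^2)
    n * log(max(rss, 1e-300) / n) + sum(b != 0) * log(n)
  }, numeric(1))
  best <- min(bic)
  sel <- which(bic <= best + 1e-9)
  sel <- sel[which.max(lambda_grid[sel])]
  list(lambda = lambda_grid[sel],
       table = data.frame(lambda = lambda_grid, bic = bic))
}

default_lambda_grid <- function(design, length.out = 20) {
  lam_max <- 2 * max(abs(crossprod(design$X, design$y)), 1e-12)
  exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = length.out))
}

#' Fit the sparse dynamical network model over all targets
#'
#' Loops the per-target L1 regression over every target gene with the
#' chosen penalty rule, recording coefficients and diagnostics. Failures of
#' individual targets are isolated and logged, never aborting the run.
#'
#' @param cube cleaned, thresholded, normalized cube.
#' @param config list of options: `targets`, `regulators` (defaults: all
#'   genes), `lambda_rule` ("bic" or "cv"), `lambda_grid` (default: 20
#'   log-spaced values per target), `one_se`, `interactions` (include the
#'   beta terms; default TRUE), `at` ("midpoint" or "start"; the default
#'   midpoint evaluation averages each predictor over the interval
#'   endpoints, the trapezoid-accurate estimate of its value over the
#'   interval -- start-of-interval evaluation systematically attenuates
#'   the coefficients of fast-growing regulators), `exclude_self`
#'   (default TRUE), `exclude_induced` (default TRUE), and
#'   `permute_experiments` with `permute_seed` (negative control: permute
#'   the dependent variable's experiment labels per target before
#'   fitting, which should destroy edge recovery).
#' @return object of class `network_model`: matrices `alpha`, `beta`
#'   (target x regulator over the union gene set), per-target `lambda`,
#'   `diagnostics` data.frame (target, lambda, nnz, r2, fallback, error),
#'   and the `config`.
#' @export
fit_network <- function(cube, config = list()) {
  genes <- dimnames(cube)[[1]]
  cfg <- utils::modifyList(
    list(targets = genes, regulators = genes, lambda_rule = "bic",
         lambda_grid = NULL, one_se = FALSE, interactions = TRUE,
         at = "midpoint", exclude_self = TRUE, exclude_induced = TRUE,
         permute_experiments = FALSE, permute_seed = NULL),
    config)
  alpha <- matrix(0, length(cfg$targets), length(cfg$regulators),
                  dimnames = list(cfg$targets, cfg$regulators))
  beta <- alpha
  diag_rows <- vector("list", length(cfg$targets))
  lambda <- stats::setNames(rep(NA_real_, length(cfg$targets)), cfg$targets)
  for (i in seq_along(cfg$targets)) {
    tg <- cfg$targets[i]
    res <- tryCatch({
      des <- build_design(cube, tg, cfg$regulators, cfg$exclude_self,
                          cfg$at, cfg$exclude_induced)
      if (cfg$permute_experiments) {
        # negative control: permute the dependent variable's
        # (experiment, interval) labels, decoupling each target's rates
        # from the predictors while leaving the predictors intact
        des$y <- with_seed(derive_seed(cfg$permute_seed %||% 0, tg),
                           sample(des$y))
      }
      if (!cfg$interactions) {
        des$X[, grep("^beta\\.", colnames(des$X))] <- 0
      }
      grid <- cfg$lambda_grid %||% default_lambda_grid(des)
      pick <- if (cfg$lambda_rule == "cv") {
        cross_validate(des, grid, cfg$one_se)
      } else {
        c(select_lambda_bic(des, grid), fallback = FALSE)
      }
      b <- fit_gene_lasso(des, pick$lambda)
      pred <- drop(des$X %*% b)
      tss <- sum((des$y - mean(des$y))^2)
      r2 <- if (tss > 0) 1 - sum((des$y - pred)^2) / tss else NA_real_
      regs <- des$regulators
      alpha[tg, regs] <- b[paste0("alpha.", regs)]
      beta[tg, regs] <- b[paste0("beta.", regs)]
      lambda[tg] <- pick$lambda
      data.frame(target = tg, lambda = pick$lambda, nnz = sum(b != 0),
                 r2 = r2, fallback = isTRUE(pick$fallback),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(target = tg, lambda = NA_real_, nnz = NA_integer_,
                 r2 = NA_real_, fallback = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    diag_rows[[i]] <- res
  }
  structure(list(alpha = alpha, beta = beta, lambda = lambda,
                 diagnostics = do.call(rbind, diag_rows), config = cfg),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  nz <- sum(x$alpha != 0 | x$beta != 0)
  cat(sprintf(
    "network_model: %d targets x %d regulators, %d nonzero edges (%s)\n",
    nrow(x$alpha), ncol(x$alpha), nz, x$config$lambda_rule))
  invisible(x)
}

#' Model-predicted rate of change of a target at an observed state
#'
#' Evaluates the fitted dynamical model at the observed expression state:
#' `sum_k alpha_ik (y_k - 1) + beta_ik (y_i y_k - 1) / y_i`. At t = 0,
#' where every gene equals 1, the predicted rate is structurally zero.
#'
#' @param model a `network_model`.
#' @param state named numeric vector of ratio-scale expression (all genes).
#' @param target target gene.
#' @return predicted d ln y / dt (1/min).
#' @export
predict_rate <- function(model, state, target) {
  regs <- colnames(model$alpha)
  yk <- state[regs]
  yi <- state[[target]]
  sum(model$alpha[target, ] * (yk - 1)) +
    sum(model$beta[target, ] * (yi * yk - 1) / yi)
}

#' Integrate fitted rates into predicted log2 timecourses
#'
#' Predicted rates (teacher-forced: predictors come from the observed cube,
#' using the model's predictor convention) are accumulated across intervals
#' to give predicted `ln y` at the grid times, starting at 0, and converted
#' to log2 fold changes.
#'
#' @param model a `network_model`.
#' @param cube observed normalized cube.
#' @param targets genes to predict (default: the model's targets).
#' @return array (target x experiment x time) of predicted log2 fold
#'   changes, with the cube's `times` attribute.
#' @export
integrate_predictions <- function(model, cube, targets = NULL) {
  targets <- targets %||% rownames(model$alpha)
  times <- attr(cube, "times")
  exps <- dimnames(cube)[[2]]
  out <- array(0, c(length(targets), length(exps), length(times)),
               dimnames = list(targets, exps, dimnames(cube)[[3]]))
  for (tg in targets) {
    des <- build_design(cube, tg, model$config$regulators,
                        model$config$exclude_self, model$config$at,
                        model$config$exclude_induced %||% TRUE)
    b <- c(stats::setNames(model$alpha[tg, ],
                           paste0("alpha.", colnames(model$alpha))),
           stats::setNames(model$beta[tg, ],
                           paste0("beta.", colnames(model$beta))))
    rate <- drop(des$X %*% b[colnames(des$X)])
    for (j in seq_along(exps)) {
      rows <- des$experiment == exps[j]
      if (!any(rows)) next  # e.g. the target's own induction experiment
      out[tg, j, ] <- c(0, cumsum(rate[rows] * des$dt[rows])) / log(2)
    }
  }
  attr(out, "times") <- times
  out
}

#' Baseline: expression-on-expression LASSO with a global penalty
#'
#' The control model against which the dynamical regression is compared:
#' each gene's log2 expression across all observations is fit as a sparse
#' linear combination of all other genes' log2 expression (no dynamics, no
#' intercept), with one penalty shared by all targets chosen to minimize
#' the mean per-target BIC.
#'
#' @param cube normalized cube.
#' @param lambda_grid candidate penalties (default 20 log-spaced values).
#' @return list with `coef` (target x regulator matrix), the chosen global
#'   `lambda`, and the BIC `table`.
#' @export
baseline_lasso <- function(cube, lambda_grid = NULL) {
  genes <- dimnames(cube)[[1]]
  lg2 <- log2(cube)
  d <- dim(lg2)
  flat <- matrix(lg2, d[1], d[2] * d[3])  # gene x observation
  designs <- lapply(genes, function(tg) {
    others <- setdiff(genes, tg)
    list(X = t(flat[match(others, genes), , drop = FALSE]),
         y = flat[match(tg, genes), ], others = others)
  })
  if (is.null(lambda_grid)) {
    lmax <- max(vapply(designs, function(d)
      2 * max(abs(crossprod(d$X, d$y))), numeric(1)))
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 20))
  }
  n <- length(designs[[1]]$y)
  bic <- sapply(designs, function(des) {
    vapply(lambda_grid, function(l) {
      colnames(des$X) <- paste0("x.", des$others)
      b <- fit_gene_lasso(des, l)
      rss <- sum((des$y - drop(des$X %*% b))^2)
      n * log(max(rss, 1e-300) / n) + sum(b != 0) * log(n)
    }, numeric(1))
  })
  lam <- lambda_grid[which.min(rowMeans(bic))]
  coef <- matrix(0, length(genes), length(genes),
                 dimnames = list(genes, genes))
  for (i in seq_along(genes)) {
    des <- designs[[i]]
    colnames(des$X) <- paste0("x.", des$others)
    b <- fit_gene_lasso(des, lam)
    coef[genes[i], des$others] <- b
  }
  list(coef = coef, lambda = lam, table = data.frame(lambda = lambda_grid,
                                                     mean_bic = rowMeans(bic)))
}

#' Score candidate edges by fitted coefficient magnitude
#'
#' @param model a `network_model` (or any list with `alpha`/`beta`
#'   target x regulator matrices).
#' @return data.frame (source = regulator, target, score = |alpha| + |beta|)
#'   for all candidate pairs, source != target.
#' @export
edge_scores <- function(model) {
  sc <- abs(model$alpha) + abs(model$beta)
  df <- data.frame(
    source = rep(colnames(sc), each = nrow(sc)),
    target = rep(rownames(sc), ncol(sc)),
    score = as.vector(sc), stringsAsFactors = FALSE)
  df[df$source != df$target, ]
}
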