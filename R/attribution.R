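#' Interpolate a log2 trajectory at an arbitrary time
#'
#' Linear interpolation between the two closest grid times, used because
#' response-interval endpoints generally fall between observations.
#'
#' @param times grid times.
#' @param log2_values log2 trajectory on the grid.
#' @param t query times (clipped to the grid range).
#' @return interpolated log2 values.
#' @keywords internal
interp_log2 <- function(times, log2_values, t) {
  t <- pmin(pmax(t, min(times)), max(times))
  stats::approx(times, log2_values, xout = t)$y
}

#' Observed and model-predicted fold changes over a response interval
#'
#' `f = log2(y[t_end]) - log2(y[t_start])` for both the observed and the
#' model-predicted trajectory, with both endpoints obtained by linear
#' interpolation between the bracketing grid times. Intervals extending
#' beyond the observed window are clipped and flagged.
#'
#' @param obs_log2 observed log2 trajectory on the grid.
#' @param pred_log2 predicted log2 trajectory on the grid.
#' @param times grid times (min).
#' @param t_start,t_end interval endpoints (min).
#' @return list with `f_observed`, `f_model`, `clipped` (logical), and the
#'   clipped endpoints actually used.
#' @export
interval_fold_changes <- function(obs_log2, pred_log2, times, t_start,
                                  t_end) {
  clipped <- t_start < min(times) || t_end > max(times)
  ts <- max(t_start, min(times))
  te <- min(t_end, max(times))
  list(
    f_observed = interp_log2(times, obs_log2, te) -
      interp_log2(times, obs_log2, ts),
    f_model = interp_log2(times, pred_log2, te) -
      interp_log2(times, pred_log2, ts),
    clipped = clipped, t_start = ts, t_end = te)
}

#' Predictive-value filter for attribution
#'
#' A response is attributed only when the model captures an appreciable
#' fraction of the observed change:
#' `min(f_model, f_observed) / max(f_model, f_observed) > cutoff`.
#' Opposite-signed pairs give a negative ratio and fail; a 0/0 pair is
#' treated as no evidence and fails.
#'
#' @param f_observed observed log2 change over the interval.
#' @param f_model model-predicted log2 change.
#' @param cutoff default 0.2.
#' @return logical.
#' @export
predictive_filter <- function(f_observed, f_model, cutoff = 0.2) {
  hi <- max(f_model, f_observed)
  lo <- min(f_model, f_observed)
  if (hi == 0 && lo == 0) return(FALSE)
  if (hi == 0) return(FALSE)  # both <= 0 with max 0: no positive scale
  (lo / hi) > cutoff
}

#' Per-regulator cumulative model contributions for one timecourse
#'
#' Splits the integrated model prediction for (target, experiment) into
#' per-regulator cumulative log2 contributions at the grid times. By
#' linearity of the model, the contributions sum exactly to the total
#' integrated prediction.
#'
#' @param model a `network_model`.
#' @param cube observed normalized cube.
#' @param target,experiment identifiers.
#' @return matrix (regulator x time) of cumulative log2 contributions,
#'   with attribute `"times"`.
#' @keywords internal
regulator_contributions <- function(model, cube, target, experiment) {
  des <- build_design(cube, target, model$config$regulators,
                      model$config$exclude_self, model$config$at,
                      model$config$exclude_induced %||% TRUE)
  rows <- which(des$experiment == experiment)
  regs <- des$regulators
  times <- attr(cube, "times")
  contrib <- matrix(0, length(regs), length(times),
                    dimnames = list(regs, NULL))
  if (length(rows) == 0) {
    attr(contrib, "times") <- times
    return(contrib)
  }
  for (k in seq_along(regs)) {
    rate_k <- model$alpha[target, regs[k]] *
      des$X[rows, paste0("alpha.", regs[k])] +
      model$beta[target, regs[k]] *
      des$X[rows, paste0("beta.", regs[k])]
    contrib[k, ] <- c(0, cumsum(rate_k * des$dt[rows])) / log(2)
  }
  attr(contrib, "times") <- times
  contrib
}

#' Attribute one response interval to individual regulators
#'
#' Each regulator's marginal change over `[t_start, t_end]` is the
#' difference of its cumulative model contribution at the interval
#' endpoints (linearly interpolated, so partial end intervals are
#' pro-rated). The fractional control is `psi_j = marginal_j /
#' sum_j marginal_j`; regulators with `psi > psi_cutoff` are flagged as
#' attributed drivers. `psi` is signed: a regulator opposing the net change
#' has negative `psi` (an absolute-value variant is available via
#' `use_abs`).
#'
#' @param model a `network_model`.
#' @param cube observed normalized cube.
#' @param target,experiment identifiers.
#' @param interval one-row data.frame (or list) with `kind`, `t_start`,
#'   `t_end` as produced by [extract_response_intervals()].
#' @param psi_cutoff driver threshold on psi (default 0.2).
#' @param filter_cutoff predictive-value cutoff (default 0.2).
#' @param use_abs apply the driver threshold to |psi| instead of signed psi.
#' @return object of class `attribution_record`: list with f_observed,
#'   f_model, per-regulator `marginal` and `psi`, `drivers`,
#'   `passed_predictive_filter`, `degenerate` (zero total marginal),
#'   `unstable` (|total| < 0.1 * sum |marginal|: heavy cancellation), and
#'   `low_confidence` (clipped interval narrower than one grid spacing).
#' @export
attribute_marginal <- function(model, cube, target, experiment, interval,
                               psi_cutoff = 0.2, filter_cutoff = 0.2,
                               use_abs = FALSE) {
  times <- attr(cube, "times")
  contrib <- regulator_contributions(model, cube, target, experiment)
  obs <- log2(cube[target, experiment, ])
  pred <- colSums(contrib)
  fc <- interval_fold_changes(obs, pred, times, interval$t_start,
                              interval$t_end)
  marginal <- apply(contrib, 1, function(cj) {
    interp_log2(times, cj, fc$t_end) - interp_log2(times, cj, fc$t_start)
  })
  total <- sum(marginal)
  degenerate <- total == 0
  psi <- if (degenerate) stats::setNames(rep(NA_real_, length(marginal)),
                                         names(marginal))
         else marginal / total
  crit <- if (use_abs) abs(psi) else psi
  drivers <- names(psi)[!is.na(crit) & crit > psi_cutoff]
  structure(list(
    target = target, experiment = experiment, kind = interval$kind,
    t_start = fc$t_start, t_end = fc$t_end,
    f_observed = fc$f_observed, f_model = fc$f_model,
    marginal = marginal, psi = psi, drivers = drivers,
    passed_predictive_filter = predictive_filter(fc$f_observed, fc$f_model,
                                                 filter_cutoff),
    degenerate = degenerate,
    unstable = !degenerate && abs(total) < 0.1 * sum(abs(marginal)),
    low_confidence = (fc$t_end - fc$t_start) < min(diff(times))),
    class = "attribution_record")
}

#' Attribute every fitted response across a cube
#'
#' Extracts the response intervals of each kinetic fit, computes
#' observed/model fold changes, applies the predictive-value filter, and
#' attributes passing responses to regulators. Two tables are returned: one
#' row per response, and one row per (response, regulator) for responses
#' that passed the filter.
#'
#' @param model a `network_model`.
#' @param cube observed normalized cube.
#' @param fits kinetic fits table from [fit_kinetics()].
#' @param psi_cutoff,filter_cutoff,use_abs see [attribute_marginal()].
#' @return list with `responses` (target, experiment, response index,
#'   kind, t_start, t_end, f_observed, f_model, passed_filter, degenerate,
#'   unstable) and `attributions` (..., regulator, marginal, psi,
#'   driver_flag); `response` enumerates the fit's transitions so repeated
#'   kinds within one timecourse stay distinct.
#' @export
attribute_all <- function(model, cube, fits, psi_cutoff = 0.2,
                          filter_cutoff = 0.2, use_abs = FALSE) {
  resp_rows <- list()
  attr_rows <- list()
  for (r in seq_len(nrow(fits))) {
    fit <- as_kinetic_fit(fits[r, ], attr(cube, "times"))
    ivs <- extract_response_intervals(fit)
    for (z in seq_len(nrow(ivs))) {
      rec <- attribute_marginal(model, cube, fits$gene[r],
                                fits$experiment[r], ivs[z, ],
                                psi_cutoff, filter_cutoff, use_abs)
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        target = rec$target, experiment = rec$experiment, response = z,
        kind = rec$kind, t_start = rec$t_start, t_end = rec$t_end,
        f_observed = rec$f_observed, f_model = rec$f_model,
        passed_filter = rec$passed_predictive_filter,
        degenerate = rec$degenerate, unstable = rec$unstable,
        stringsAsFactors = FALSE)
      if (rec$passed_predictive_filter && !rec$degenerate) {
        nz <- rec$psi != 0
        if (any(nz)) {
          attr_rows[[length(attr_rows) + 1L]] <- data.frame(
            target = rec$target, experiment = rec$experiment,
            response = z, kind = rec$kind, regulator = names(rec$psi)[nz],
            marginal = unname(rec$marginal[nz]), psi = unname(rec$psi[nz]),
            driver_flag = names(rec$psi)[nz] %in% rec$drivers,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(responses = do.call(rbind, resp_rows) %||% data.frame(),
       attributions = do.call(rbind, attr_rows) %||% data.frame())
}

# rebuild a kinetic_fit object from one row of the fits table
as_kinetic_fit <- function(row, times) {
  structure(list(
    model_class = row$model_class, slope = row$slope, t_rise = row$t_rise,
    v_inter = row$v_inter, t_fall = row$t_fall, v_final = row$v_final,
    loglik = row$loglik, converged = row$converged,
    times = times, values = NULL),
    class = "kinetic_fit")
}
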