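#' Aggregate spot-level intensities into per-observation ratio statistics
#'
#' Each spot's expression ratio is computed with an intensity floor,
#' `ratio = max(red, C) / max(green, C)`, and the spots of each
#' (gene, experiment, time) observation are summarized by their minimum,
#' maximum, median and standard deviation. With the usual two spots the
#' median equals the mean and the sd equals `(max - min)/sqrt(2)`.
#'
#' @param spots data.frame with columns gene, experiment, time_min,
#'   spot_index, red, green (intensities >= 0, arbitrary units).
#' @param C intensity floor (default 2, arbitrary units).
#' @return data.frame with one row per (gene, experiment, time_min):
#'   `n_spots`, `rmin`, `rmax`, `rmedian`, `rsd`, `green_median`, plus the
#'   floor `C` as an attribute. Spot-level floored ratios are kept in
#'   attribute `"spot_ratios"` for downstream repairs.
#' @export
aggregate_spots <- function(spots, C = 2) {
  stopifnot(C > 0, all(spots$red >= 0), all(spots$green >= 0))
  ratio <- pmax(spots$red, C) / pmax(spots$green, C)
  key <- interaction(spots$gene, spots$experiment, spots$time_min,
                     drop = TRUE, lex.order = TRUE)
  agg <- function(x, f) as.vector(tapply(x, key, f))
  ord <- order(key)
  stats <- data.frame(
    gene = spots$gene[ord][!duplicated(key[ord])],
    experiment = spots$experiment[ord][!duplicated(key[ord])],
    time_min = spots$time_min[ord][!duplicated(key[ord])],
    n_spots = as.vector(table(key)),
    rmin = agg(ratio, min),
    rmax = agg(ratio, max),
    rmedian = agg(ratio, stats::median),
    rsd = agg(ratio, function(x) if (length(x) > 1) stats::sd(x) else 0),
    green_median = agg(spots$green, stats::median),
    stringsAsFactors = FALSE)
  attr(stats, "C") <- C
  attr(stats, "spot_ratios") <- data.frame(
    gene = spots$gene, experiment = spots$experiment,
    time_min = spots$time_min, spot_index = spots$spot_index,
    ratio = ratio, stringsAsFactors = FALSE)
  stats
}

#' Build a (gene x experiment x time) cube from aggregated observations
#'
#' @param stats output of [aggregate_spots()].
#' @param value column of `stats` to tabulate (default the median ratio).
#' @return 3-d array with dimnames and a `times` attribute; grid positions
#'   with no observation are NA.
#' @export
obs_to_cube <- function(stats, value = "rmedian") {
  genes <- sort(unique(stats$gene))
  exps <- sort(unique(stats$experiment))
  times <- sort(unique(stats$time_min))
  cube <- array(NA_real_, c(length(genes), length(exps), length(times)),
                dimnames = list(genes, exps, paste0("t", times)))
  idx <- cbind(match(stats$gene, genes), match(stats$experiment, exps),
               match(stats$time_min, times))
  cube[idx] <- stats[[value]]
  attr(cube, "times") <- times
  cube
}

geomean <- function(x) exp(mean(log(x)))

#' Repair observations whose duplicate spots disagree
#'
#' Where the ratio between a single observation's spot values exceeds
#' `factor` (max over min of the floored per-spot ratios, strictly greater
#' than 4 by default), the spots cannot be trusted and the observation's
#' value is replaced by the geometric mean of the bracketing time points
#' (the single neighboring time point at either end of the timecourse).
#'
#' @param cube ratio cube from [obs_to_cube()].
#' @param stats aggregated observations from [aggregate_spots()].
#' @param factor disagreement threshold (default 4).
#' @return list with the repaired `cube` and a `flags` data.frame
#'   (type, gene, experiment, time_min). Untouched values are bit-identical
#'   to the input.
#' @export
repair_spot_disagreement <- function(cube, stats, factor = 4) {
  times <- attr(cube, "times")
  bad <- stats[stats$rmax / stats$rmin > factor, , drop = FALSE]
  flags <- data.frame(type = character(0), gene = character(0),
                      experiment = character(0), time_min = numeric(0))
  for (r in seq_len(nrow(bad))) {
    g <- bad$gene[r]; e <- bad$experiment[r]
    ti <- match(bad$time_min[r], times)
    tc <- cube[g, e, ]
    if (length(times) < 2) {  # nothing to interpolate from
      flags <- rbind(flags, data.frame(type = "disagreement_unrepairable",
                                       gene = g, experiment = e,
                                       time_min = bad$time_min[r]))
      next
    }
    nb <- c(if (ti > 1) tc[ti - 1], if (ti < length(times)) tc[ti + 1])
    cube[g, e, ti] <- geomean(nb)
    flags <- rbind(flags, data.frame(type = "disagreement", gene = g,
                                     experiment = e,
                                     time_min = bad$time_min[r]))
  }
  list(cube = cube, flags = flags)
}

#' Repair transient spike outliers
#'
#' An interior observation whose median ratio moves by a factor of at least
#' `factor` relative to the previous time point and then by at least
#' `factor` in the opposite direction at the next time point is treated as a
#' technical spike and replaced by the geometric mean of its bracketing
#' time points. Both up-then-down and down-then-up excursions are repaired.
#'
#' @param cube ratio cube.
#' @param factor spike threshold (default 4, inclusive).
#' @return list with repaired `cube` and `flags` data.frame.
#' @export
repair_spike_outliers <- function(cube, factor = 4) {
  times <- attr(cube, "times")
  d <- dim(cube)
  flags <- data.frame(type = character(0), gene = character(0),
                      experiment = character(0), time_min = numeric(0))
  if (length(times) < 3) return(list(cube = cube, flags = flags))
  for (j in seq_len(d[2])) {
    m <- cube[, j, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = d[1])
    for (ti in 2:(length(times) - 1L)) {
      r1 <- m[, ti] / m[, ti - 1L]
      r2 <- m[, ti + 1L] / m[, ti]
      hit <- which((r1 >= factor & r2 <= 1 / factor) |
                     (r1 <= 1 / factor & r2 >= factor))
      for (g in hit) {
        cube[g, j, ti] <- geomean(c(m[g, ti - 1L], m[g, ti + 1L]))
        flags <- rbind(flags, data.frame(
          type = "spike", gene = dimnames(cube)[[1]][g],
          experiment = dimnames(cube)[[2]][j], time_min = times[ti]))
      }
    }
  }
  list(cube = cube, flags = flags)
}

#' Repair red-to-green channel crosstalk
#'
#' When the red channel is much brighter than the green channel, signal can
#' leak into the green measurement, inflating it after induction. Per
#' timecourse, the green channel ratio relative to t = 0 is computed for all
#' t > 0; a timecourse is flagged when the 30% quantile of that ratio
#' exceeds `green_factor` (8) AND the 30% quantile of the magnitude of the
#' expression log-ratio exceeds a twofold change (|log2 ratio| > 1). Both
#' criteria must hold. Flagged timecourses are repaired by recomputing every
#' spot's ratio with that spot's time-zero green channel (floored at `C`)
#' and re-aggregating.
#'
#' @param cube ratio cube.
#' @param spots raw spot table (gene, experiment, time_min, spot_index,
#'   red, green).
#' @param C intensity floor.
#' @param green_factor green-inflation threshold on the 30% quantile.
#' @param log2_cut log2 magnitude the 30% quantile of the expression
#'   log-ratio must exceed (default 1, i.e. twofold).
#' @param q quantile used for both criteria (default 0.30).
#' @return list with repaired `cube` and `flags` data.frame (`time_min` NA:
#'   the repair applies to the whole timecourse).
#' @export
repair_crosstalk <- function(cube, spots, C = 2, green_factor = 8,
                             log2_cut = 1, q = 0.30) {
  times <- attr(cube, "times")
  genes <- dimnames(cube)[[1]]
  exps <- dimnames(cube)[[2]]
  flags <- data.frame(type = character(0), gene = character(0),
                      experiment = character(0), time_min = numeric(0))
  skey <- paste(spots$gene, spots$experiment, sep = "\r")
  for (e in exps) {
    for (g in genes) {
      sel <- skey == paste(g, e, sep = "\r")
      if (!any(sel)) next
      sp <- spots[sel, ]
      gmed <- tapply(sp$green, sp$time_min, stats::median)
      gtimes <- as.numeric(names(gmed))
      if (!0 %in% gtimes || length(gtimes) < 2) next
      gratio <- gmed[gtimes > 0] / gmed[gtimes == 0]
      lr <- abs(log2(cube[g, e, match(gtimes[gtimes > 0], times)]))
      if (stats::quantile(gratio, q) > green_factor &&
          stats::quantile(lr, q) > log2_cut) {
        # duplicate each spot's time-zero green channel across the course
        g0 <- sp$green[sp$time_min == 0][match(sp$spot_index,
                                               sp$spot_index[sp$time_min == 0])]
        ratio <- pmax(sp$red, C) / pmax(g0, C)
        med <- tapply(ratio, sp$time_min, stats::median)
        cube[g, e, match(as.numeric(names(med)), times)] <- as.vector(med)
        flags <- rbind(flags, data.frame(type = "crosstalk", gene = g,
                                         experiment = e,
                                         time_min = NA_real_))
      }
    }
  }
  list(cube = cube, flags = flags)
}

#' Normalize each timecourse to its time-zero value
#'
#' Converts ratios to relative expression `y` with `y = 1` at t = 0 in every
#' gene and experiment.
#'
#' @param cube ratio cube.
#' @return cube of identical shape, first time slice identically 1.
#' @export
normalize_to_t0 <- function(cube) {
  at <- attributes(cube)
  out <- cube / as.vector(cube[, , 1, drop = TRUE])
  attributes(out) <- at
  out
}

#' Subtract the per-class median background signature
#'
#' Both induction systems (GEV and ZEV) carry a characteristic background
#' expression signature, including a mild stress response, shared by all
#' experiments of the class. Because a given gene responds to the induced
#' regulator in only a small minority of experiments, the per-gene median
#' timecourse across the experiments of a class estimates that background
#' and is subtracted (in log space) from every experiment of the class.
#'
#' @param cube normalized cube (y = 1 at t = 0).
#' @param class_map named character vector experiment -> class; defaults to
#'   the cube's `class_map` attribute.
#' @param min_class_size classes with fewer experiments are skipped with a
#'   warning (subtracting the median of a single experiment would zero it
#'   out); default 2.
#' @return list with the normalized `cube` (ratio scale) and `flags` for
#'   skipped classes.
#' @export
subtract_class_median <- function(cube, class_map = NULL,
                                  min_class_size = 2) {
  class_map <- class_map %||% attr(cube, "class_map")
  if (is.null(class_map)) stop("no class map available")
  exps <- dimnames(cube)[[2]]
  flags <- data.frame(type = character(0), gene = character(0),
                      experiment = character(0), time_min = numeric(0))
  lg <- log(cube)
  for (cl in unique(class_map[exps])) {
    members <- exps[class_map[exps] == cl]
    if (length(members) < min_class_size) {
      warning("class ", cl, " has ", length(members),
              " experiment(s); median subtraction skipped")
      flags <- rbind(flags, data.frame(type = "class_median_skipped",
                                       gene = NA_character_,
                                       experiment = members,
                                       time_min = NA_real_))
      next
    }
    med <- apply(lg[, members, , drop = FALSE], c(1, 3), stats::median)
    for (e in members) lg[, e, ] <- lg[, e, ] - med
  }
  out <- exp(lg)
  attributes(out) <- attributes(cube)
  list(cube = out, flags = flags)
}

#' Estimate gene- and array-level noise variance components
#'
#' Robustly estimates the two-component observation noise model
#' `Var(l_it) = sigma_gene_i^2 + sigma_array_t^2` (natural-log scale) from
#' the invariant majority of timecourses, using median absolute deviations.
#' Per-gene and per-array squared MADs are decomposed into the two
#' components by alternating back-fitting of their means.
#'
#' @param lcube natural-log cube with t = 0 excluded from estimation.
#' @param sd_floor lower bound applied to the combined sd.
#' @return list with `gene_var` (per gene), `array_var` (experiment x time,
#'   t > 0 columns), and `sd` (gene x experiment x time array of combined
#'   sds, floored).
#' @keywords internal
estimate_noise_components <- function(lcube, sd_floor = 1e-3) {
  d <- dim(lcube)
  lpost <- lcube[, , -1, drop = FALSE]
  G <- apply(lpost, 1, function(x) stats::mad(x, center = 0))^2
  A <- apply(lpost, c(2, 3), function(x) stats::mad(x, center = 0))^2
  abar <- mean(A) / 2
  for (it in 1:50) {
    gene_var <- pmax(G - abar, 0)
    gbar <- mean(gene_var)
    array_var <- pmax(A - gbar, 0)
    abar <- mean(array_var)
  }
  sd <- array(0, dim = d)
  for (t in 2:d[3]) {
    sd[, , t] <- sqrt(outer(gene_var, array_var[, t - 1L], `+`))
  }
  sd <- pmax(sd, sd_floor)
  list(gene_var = gene_var, array_var = array_var, sd = sd)
}

#' Hard-threshold timecourses consistent with measurement noise
#'
#' Most genes do not respond in a typical induction experiment, so the
#' signal of interest is sparse amid noise. Per timecourse, the statistic
#' `T = sum_t (l_t / sigma_it)^2` over post-zero times is compared with a
#' chi-square null with as many degrees of freedom as post-zero times, with
#' `sigma_it^2 = sigma_gene_i^2 + sigma_array_t^2` estimated robustly (or
#' supplied). P-values are Benjamini-Hochberg corrected and every timecourse
#' not selected at `fdr_q` is set as invariant: log fold change 0 at all
#' times. Selected timecourses are preserved exactly.
#'
#' @param cube cleaned, normalized cube (ratio scale).
#' @param fdr_q Benjamini-Hochberg target (default 0.05).
#' @param noise_params optional list with `gene_var` (per gene) and
#'   `array_var` (experiment x post-zero-time matrix, or scalar); estimated
#'   from the data when NULL.
#' @param sd_floor floor for degenerate sds.
#' @return list with thresholded `cube`, logical matrix `selected`
#'   (gene x experiment), the `padj` matrix, and `selected_fraction`.
#' @export
threshold_noise <- function(cube, fdr_q = 0.05, noise_params = NULL,
                            sd_floor = 1e-3) {
  at <- attributes(cube)
  d <- dim(cube)
  lg <- log(cube)
  if (is.null(noise_params)) {
    np <- estimate_noise_components(lg, sd_floor)
    sd <- np$sd
  } else {
    av <- noise_params$array_var
    if (length(av) == 1) av <- matrix(av, d[2], d[3] - 1L)
    sd <- array(0, dim = d)
    for (t in 2:d[3])
      sd[, , t] <- sqrt(outer(rep_len(noise_params$gene_var, d[1]),
                              av[, t - 1L], `+`))
    sd <- pmax(sd, sd_floor)
  }
  z2 <- (lg / sd)^2
  z2[, , 1] <- 0
  T_stat <- apply(z2, c(1, 2), sum)
  df <- d[3] - 1L
  p <- stats::pchisq(T_stat, df = df, lower.tail = FALSE)
  padj <- matrix(stats::p.adjust(p, method = "BH"), d[1], d[2],
                 dimnames = dimnames(T_stat))
  selected <- padj < fdr_q
  out <- cube
  for (j in seq_len(d[2])) {
    drop_g <- which(!selected[, j])
    if (length(drop_g)) out[drop_g, j, ] <- 1
  }
  attributes(out) <- at
  list(cube = out, selected = selected, padj = padj,
       selected_fraction = mean(selected))
}

#' Run the full raw-to-cleaned-to-thresholded signal chain
#'
#' Applies, in order: spot aggregation with intensity floor, spot
#' disagreement repair, spike repair, crosstalk repair, normalization to
#' t = 0, per-class median background subtraction, and (optionally)
#' noise-model hard-thresholding.
#'
#' @param spots raw spot table.
#' @param class_map named character vector experiment -> class.
#' @param C intensity floor.
#' @param fdr_q threshold FDR; `NA` skips thresholding.
#' @param noise_params optional known noise components for thresholding.
#' @return list with final `cube` (ratio scale, attributes times/class_map),
#'   `flags` (all repair flags), `selected` (NULL if thresholding skipped)
#'   and a per-stage `report`.
#' @export
preprocess_spots <- function(spots, class_map, C = 2, fdr_q = 0.05,
                             noise_params = NULL) {
  stats <- aggregate_spots(spots, C)
  cube <- obs_to_cube(stats)
  r1 <- repair_spot_disagreement(cube, stats)
  r2 <- repair_spike_outliers(r1$cube)
  r3 <- repair_crosstalk(r2$cube, spots, C)
  cube <- normalize_to_t0(r3$cube)
  attr(cube, "class_map") <- class_map
  r4 <- subtract_class_median(cube, class_map)
  cube <- r4$cube
  selected <- NULL
  sel_frac <- NA_real_
  if (!is.na(fdr_q)) {
    th <- threshold_noise(cube, fdr_q, noise_params)
    cube <- th$cube
    selected <- th$selected
    sel_frac <- th$selected_fraction
  }
  flags <- rbind(r1$flags, r2$flags, r3$flags, r4$flags)
  list(cube = cube, flags = flags, selected = selected,
       report = list(
         n_disagreement = sum(r1$flags$type == "disagreement"),
         n_spike = nrow(r2$flags),
         n_crosstalk = nrow(r3$flags),
         selected_fraction = sel_frac))
}
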