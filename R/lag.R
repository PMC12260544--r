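#' Zero-phase bandpass filter of a timeseries
#'
#' Butterworth passband applied forward and backward (`filtfilt`, zero
#' phase) to each node's signal, run by run -- the filter never crosses a
#' run boundary. The band must lie below the Nyquist frequency.
#'
#' @param ts a `timeseries`.
#' @param band_hz increasing two-element passband in Hz.
#' @param order Butterworth order (per direction).
#' @return filtered `timeseries`.
#' @export
bandpass <- function(ts, band_hz = c(0.01, 0.1), order = 2L) {
  stopifnot(inherits(ts, "timeseries"))
  nyq <- 1 / (2 * ts$tr)
  if (band_hz[2L] >= nyq)
    stop(sprintf("band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
                 band_hz[2L], nyq), call. = FALSE)
  if (band_hz[1L] <= 0 || band_hz[1L] >= band_hz[2L])
    stop("band must be an increasing positive pair", call. = FALSE)
  bf <- signal::butter(order, band_hz / nyq, type = "pass")
  out <- ts$values
  for (fr in run_frames(ts)) {
    seg <- ts$values[, fr, drop = FALSE]
    out[, fr] <- t(apply(seg, 1L, function(x) signal::filtfilt(bf, x)))
  }
  timeseries(out, tr = ts$tr, subject_id = ts$subject_id,
             run_boundaries = ts$run_boundaries)
}

#' Lagged delay between two signals
#'
#' Cross-covariance at integer-frame lags within `+/- max_lag_s`; the
#' extremum of |cov| is located and a parabola through it and its two
#' neighbors gives the sub-frame delay. Positive delay means `y` lags `x`.
#' The estimate is invalid (NA, with reason) when the extremum sits at the
#' window edge or when the peak correlation magnitude falls below
#' `min_abs_r`. Anticorrelated pairs (negative extremum) are estimated from
#' the |cov| peak with the sign recorded.
#'
#' @param x,y numeric signals of equal length (>= 3 * max lag frames).
#' @param tr sampling interval, seconds.
#' @param max_lag_s lag search half-width, seconds.
#' @param min_abs_r validity threshold on the peak |correlation|.
#' @return list: `delay_s` (NA when invalid), `peak_r` (signed), `valid`,
#'   `reason`.
#' @export
lagged_delay <- function(x, y, tr, max_lag_s = 8, min_abs_r = 0.1) {
  n <- length(x)
  if (length(y) != n) stop("signals must have equal length", call. = FALSE)
  lmax <- max(1L, as.integer(floor(max_lag_s / tr)))
  if (n < 3L * lmax)
    stop("signals too short for the requested lag window", call. = FALSE)
  x <- x - mean(x); y <- y - mean(y)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0)
    return(list(delay_s = NA_real_, peak_r = NA_real_, valid = FALSE,
                reason = "constant signal"))
  lags <- seq.int(-lmax, lmax)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l)] * y[seq_len(n - l) + l])
    else sum(x[seq_len(n + l) - l] * y[seq_len(n + l)])
  }, numeric(1L)) / denom
  m <- which.max(abs(cc))
  if (abs(cc[m]) < min_abs_r)
    return(list(delay_s = NA_real_, peak_r = cc[m], valid = FALSE,
                reason = "peak correlation below threshold"))
  if (m == 1L || m == length(lags))
    return(list(delay_s = NA_real_, peak_r = cc[m], valid = FALSE,
                reason = "extremum at window edge"))
  s <- sign(cc[m])
  a <- s * cc[m - 1L]; b <- s * cc[m]; c <- s * cc[m + 1L]
  curv <- a - 2 * b + c
  frac <- if (curv < 0) 0.5 * (a - c) / curv else 0
  list(delay_s = (lags[m] + frac) * tr, peak_r = cc[m], valid = TRUE,
       reason = "ok")
}

#' Seed-based lag map
#'
#' Delay of every node's signal relative to the seed subnetwork's mean
#' time course (positive = node later than the seed). Runs are processed
#' separately and combined by a frame-weighted average; nodes invalid in
#' every run are masked.
#'
#' @param ts a `timeseries` (bandpass it first for infraslow lags).
#' @param seed_nodes integer node indices of the seed subnetwork.
#' @param max_lag_s,min_abs_r see [lagged_delay()].
#' @return object of class `lag_map`: `delay_s` per node (NA where masked),
#'   `valid` logical, `seed_nodes`.
#' @export
seed_lag_map <- function(ts, seed_nodes, max_lag_s = 8, min_abs_r = 0.1) {
  stopifnot(inherits(ts, "timeseries"))
  seed_nodes <- unique(as.integer(seed_nodes))
  n <- nrow(ts$values)
  num <- numeric(n); wsum <- numeric(n)
  for (fr in run_frames(ts)) {
    seed <- colMeans(ts$values[seed_nodes, fr, drop = FALSE])
    w <- length(fr)
    for (i in seq_len(n)) {
      res <- lagged_delay(seed, ts$values[i, fr], tr = ts$tr,
                          max_lag_s = max_lag_s, min_abs_r = min_abs_r)
      if (res$valid) {
        num[i] <- num[i] + w * res$delay_s
        wsum[i] <- wsum[i] + w
      }
    }
  }
  delay <- ifelse(wsum > 0, num / pmax(wsum, 1), NA_real_)
  structure(list(delay_s = delay, valid = wsum > 0, seed_nodes = seed_nodes),
            class = "lag_map")
}

#' @export
print.lag_map <- function(x, ...) {
  cat(sprintf("<lag_map> %d nodes (%d valid), seed of %d nodes, mean delay %.3f s\n",
              length(x$delay_s), sum(x$valid), length(x$seed_nodes),
              mean(x$delay_s, na.rm = TRUE)))
  invisible(x)
}

#' Group-level temporal ordering of structures
#'
#' For each subject, lag-map values are averaged over the nodes of each
#' structure of interest and then across that subject's seed maps; each
#' subject's structure means are centered (their mean is zero -- the zero
#' point is arbitrary). A one-way ANOVA across structures (subjects as
#' observations) tests for any ordering, followed by post hoc paired t
#' tests.
#'
#' @param lag_maps_by_subject list (per subject) of lists of `lag_map`s
#'   (one per seed).
#' @param structures named list: structure name -> node indices (may be
#'   per-subject: a list of such lists parallel to subjects).
#' @return object of class `ordering_result`: `means` (centered mean delay
#'   per structure, seconds), `subject_means` (matrix), `anova`
#'   (`stat_result`), `posthoc` (data frame).
#' @export
group_ordering <- function(lag_maps_by_subject, structures) {
  n_sub <- length(lag_maps_by_subject)
  per_subject_structs <- is.list(structures[[1L]]) &&
    !is.numeric(structures[[1L]])
  snames <- if (per_subject_structs) names(structures[[1L]]) else names(structures)
  sm <- matrix(NA_real_, n_sub, length(snames),
               dimnames = list(sprintf("s%02d", seq_len(n_sub)), snames))
  for (s in seq_len(n_sub)) {
    structs <- if (per_subject_structs) structures[[s]] else structures
    per_seed <- vapply(lag_maps_by_subject[[s]], function(lmap)
      vapply(snames, function(nm)
        mean(lmap$delay_s[structs[[nm]]], na.rm = TRUE), numeric(1L)),
      numeric(length(snames)))
    per_seed <- matrix(per_seed, nrow = length(snames))
    means <- rowMeans(per_seed, na.rm = TRUE)
    sm[s, ] <- means - mean(means, na.rm = TRUE)  # zero point is arbitrary
  }
  if (n_sub < 2L) {  # single subject: means only, no group statistics
    return(structure(list(means = colMeans(sm, na.rm = TRUE),
                          subject_means = sm, anova = NULL, posthoc = NULL),
                     class = "ordering_result"))
  }
  long <- data.frame(subject = rep(rownames(sm), times = ncol(sm)),
                     level = rep(colnames(sm), each = nrow(sm)),
                     value = as.vector(sm))
  long <- long[!is.na(long$value), ]
  fit <- stats::lm(value ~ level, data = long)
  an <- stats::anova(fit)
  f <- an[1L, "F value"]; p <- an[1L, "Pr(>F)"]
  if (an[1L, "Sum Sq"] <= 1e-12 * max(sum(an[, "Sum Sq"]), 1e-300)) {
    f <- 0; p <- 1  # identical delays everywhere: no ordering
  }
  anova_res <- structure(list(
    effect = "structure", F = f,
    df = c(an[1L, "Df"], an["Residuals", "Df"]), p = p,
    p_bonferroni = p,
    level_means = colMeans(sm, na.rm = TRUE), degenerate = FALSE),
    class = "stat_result")
  structure(list(means = colMeans(sm, na.rm = TRUE), subject_means = sm,
                 anova = anova_res, posthoc = posthoc_paired_t(sm)),
            class = "ordering_result")
}

#' @export
print.ordering_result <- function(x, ...) {
  ord <- sort(x$means)
  cat("<ordering_result> earliest -> latest:\n")
  cat(sprintf("  %s\n", paste(sprintf("%s (%+.2fs)", names(ord), ord),
                              collapse = " -> ")))
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}
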