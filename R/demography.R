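#' Age-specific mortality from lifespans
#'
#' Central death rates with person-time exposure: within each age bin the
#' hazard estimate is (deaths in bin) / (time lived in the bin by all
#' individuals).  Infinite lifespans (the "never dies" sentinel) contribute
#' exposure but no death event.  Individuals flagged oldest-old — those
#' living longer than the time it takes to fill the next generation, who
#' never reproduce — are excluded unless `include_oldest_old` is set, as in
#' the main mortality-pattern analyses.
#'
#' @param lifespans ages at death (possibly `Inf`).
#' @param bins bin edges covering the data; default 100 uniform bins up to
#'   the largest finite lifespan.
#' @param oldest_old optional logical flags, same length as `lifespans`.
#' @param include_oldest_old keep flagged individuals?
#' @param min_exposure bins with less person-time than this are suppressed.
#' @return a `mortality_curve` data.frame (`time` = bin midpoint, `deaths`,
#'   `exposure`, `hazard`, `log_hazard`), attribute `edges`.
#' @export
estimate_mortality <- function(lifespans, bins = NULL, oldest_old = NULL,
                               include_oldest_old = FALSE,
                               min_exposure = 0) {
  if (length(lifespans) == 0L)
    stop_evohet("no lifespans supplied", "evohet_domain_error")
  if (!is.null(oldest_old) && !include_oldest_old) {
    lifespans <- lifespans[!oldest_old]
    if (length(lifespans) == 0L)
      stop_evohet("no lifespans left after removing the oldest-old",
                  "evohet_domain_error")
  }
  if (!include_oldest_old) lifespans <- lifespans[is.finite(lifespans)]
  if (is.null(bins)) {
    top <- max(lifespans[is.finite(lifespans)])
    bins <- seq(0, top, length.out = 101L)
  }
  nb <- length(bins) - 1L
  left <- bins[-length(bins)]
  right <- bins[-1]
  deaths <- integer(nb)
  exposure <- numeric(nb)
  fin <- is.finite(lifespans)
  d <- lifespans
  for (j in seq_len(nb)) {
    exposure[j] <- sum(pmin(pmax(d - left[j], 0), right[j] - left[j]))
    deaths[j] <- sum(fin & d > left[j] & d <= right[j])
  }
  keep <- exposure > 0 & exposure >= min_exposure
  if (!any(keep))
    warning("all bins suppressed; empty mortality curve", call. = FALSE)
  curve <- data.frame(time = (left + right)[keep] / 2,
                      deaths = deaths[keep], exposure = exposure[keep],
                      hazard = deaths[keep] / exposure[keep])
  curve$log_hazard <- log(curve$hazard)
  class(curve) <- c("mortality_curve", "data.frame")
  attr(curve, "edges") <- bins
  attr(curve, "suppressed") <- sum(!keep)
  curve
}

#' Empirical survival curve
#'
#' Survivor function \eqn{S(t)} = fraction of individuals with lifespan
#' greater than \eqn{t}; equals one minus the empirical CDF.  Simulated
#' lifespans are uncensored; infinite lifespans stay in the risk set at
#' every age.
#'
#' @param lifespans ages at death (possibly `Inf`).
#' @return a `survival_curve` data.frame (`time`, `surv`) starting at
#'   (0, 1), stepping down at each death time.
#' @export
estimate_survival <- function(lifespans) {
  if (length(lifespans) == 0L)
    stop_evohet("no lifespans supplied", "evohet_domain_error")
  tt <- sort(unique(lifespans[is.finite(lifespans)]))
  n <- length(lifespans)
  surv <- vapply(tt, function(t) sum(lifespans > t) / n, numeric(1))
  out <- data.frame(time = c(0, tt), surv = c(1, surv))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Classify the shape of a mortality curve
#'
#' Assigns one of the five qualitative patterns a log-mortality curve can
#' take between its two exponential phases: `kink` (two increasing
#' exponential regimes), `slowdown` (mid-age slope positive but well below
#' the early slope), `plateau` (mid-age slope near zero), `decrease`
#' (negative mid-age slope with a small net drop) and `u_shape` (a drop of
#' at least `delta` log-units followed by recovery).  The log hazard is
#' smoothed with a spline (exposure-weighted when available); the mid-age
#' window is the contiguous region around the minimum of the derivative
#' where the slope falls below `theta1` times the early-phase slope.
#'
#' @param curve a `mortality_curve` (>= 10 reported bins).
#' @param theta0 plateau threshold, as a fraction of the early slope.
#' @param theta1 slowdown threshold, as a fraction of the early slope.
#' @param delta log-hazard drop (in log units) separating `decrease` from
#'   `u_shape`.
#' @param df spline degrees of freedom (`NULL`: chosen by generalized
#'   cross-validation).
#' @return an object of class `shape_label`: list with `label`,
#'   `boundaries` (ages bracketing the mid-age window, possibly empty),
#'   `early_slope`, `mid_slope`, `drop`, and the thresholds used.
#' @export
classify_shape <- function(curve, theta0 = 0.1, theta1 = 0.5, delta = 0.5,
                           df = NULL) {
  keep <- is.finite(curve$log_hazard)
  t <- curve$time[keep]
  y <- curve$log_hazard[keep]
  # Poisson death counts: Var(log hazard) ~ 1/deaths, so weight by deaths
  w <- if (!is.null(curve$deaths)) curve$deaths[keep] else NULL
  if (length(t) < 10L)
    stop_evohet("need at least 10 reported bins to classify a shape",
                "evohet_domain_error")
  # a stiff spline for the slope-regime comparisons ...
  fit_stiff <- smooth.spline(t, y, w = w,
                             df = if (is.null(df)) min(8, length(t) - 2)
                                  else df)
  grid <- seq(min(t), max(t), length.out = 200L)
  yg <- predict(fit_stiff, grid)$y
  dg <- predict(fit_stiff, grid, deriv = 1L)$y
  # ... and a short weighted running mean of the binned values, which
  # resolves the peak-to-valley depth of a U-shape without the variance of
  # an adaptive fit
  k <- min(7L, length(t))
  wr <- if (is.null(w)) rep(1, length(t)) else w
  yr <- vapply(seq_along(t), function(i) {
    j <- max(1L, i - k %/% 2L):min(length(t), i + k %/% 2L)
    sum(y[j] * wr[j]) / sum(wr[j])
  }, numeric(1))

  early <- grid <= min(t) + 0.2 * diff(range(t))
  s_e <- max(mean(dg[early]), 1e-12)

  interior <- seq_along(grid) > 10 & seq_along(grid) < 190
  i_min <- which(interior)[which.min(dg[interior])]

  in_win <- dg < theta1 * s_e
  win <- integer(0)
  if (in_win[i_min]) {
    lo <- i_min; while (lo > 1 && in_win[lo - 1]) lo <- lo - 1
    hi <- i_min; while (hi < length(grid) && in_win[hi + 1]) hi <- hi + 1
    win <- lo:hi
  }
  d_mid <- dg[i_min]
  # peak-to-valley fall of the running-mean curve (running max minus
  # current), excluding the terminal bins
  int_b <- t > min(t) + 0.02 * diff(range(t)) &
    t < max(t) - 0.05 * diff(range(t))
  fall <- cummax(yr) - yr
  fall[!int_b] <- 0
  i_low <- which.max(fall)
  drop <- fall[i_low]
  recovery <- max(yr[i_low:length(t)]) - yr[i_low] >= delta / 2

  label <- if (drop >= delta && recovery) "u_shape"
  else if (d_mid < -theta0 * s_e) "decrease"
  else if (d_mid < theta0 * s_e) "plateau"
  else if (d_mid < theta1 * s_e) "slowdown"
  else "kink"

  structure(list(label = label,
                 boundaries = if (length(win)) grid[range(win)]
                              else numeric(0),
                 early_slope = s_e, mid_slope = d_mid, drop = drop,
                 thresholds = c(theta0 = theta0, theta1 = theta1,
                                delta = delta)),
            class = "shape_label")
}

#' @export
print.shape_label <- function(x, ...) {
  cat(sprintf(
    "<shape_label> %s (early slope %.3g, mid slope %.3g, drop %.2f)\n",
    x$label, x$early_slope, x$mid_slope, x$drop))
  invisible(x)
}

#' Lifespan (or trait) modality
#'
#' Mode count of a kernel density estimate (peaks below a prominence
#' threshold are ignored) together with a dip statistic against
#' unimodality and its bootstrap p-value under a uniform null.
#'
#' @param values numeric sample of at least 100 finite observations.
#' @param bandwidth KDE bandwidth (default Silverman's rule).
#' @param prominence minimal peak prominence, as a fraction of the largest
#'   density value.
#' @param n_boot bootstrap samples for the dip p-value.
#' @param max_n samples larger than this are subsampled (deterministically
#'   given the RNG state) before computing the dip, for speed.
#' @return list with `mode_count`, `modes` (their locations), `dip`,
#'   `p_value`, `n`.
#' @export
lifespan_modality <- function(values, bandwidth = NULL, prominence = 0.05,
                              n_boot = 200L, max_n = 2000L) {
  values <- values[is.finite(values)]
  if (length(values) < 100L)
    stop_evohet("need at least 100 finite observations",
                "evohet_domain_error")
  den <- if (is.null(bandwidth)) density(values) else
    density(values, bw = bandwidth)
  pk <- find_modes(den$y, prominence)
  sub <- if (length(values) > max_n)
    sort(values)[round(seq(1, length(values), length.out = max_n))]
  else values
  dip <- dip_statistic(sub)
  boot <- .cpp_dip_boot(length(sub), as.integer(n_boot))
  list(mode_count = length(pk), modes = den$x[pk], dip = dip,
       p_value = mean(boot >= dip), n = length(values))
}

# indices of prominence-filtered local maxima of a density curve
find_modes <- function(y, prominence) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(peaks) == 0L) peaks <- which.max(y)
  thr <- prominence * max(y)
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    others <- peaks[y[peaks] > y[p]]
    if (length(others) == 0L) { keep[i] <- TRUE; next }
    # prominence: height above the deepest valley separating p from a
    # higher peak
    valleys <- vapply(others, function(q) {
      rng <- if (q < p) q:p else p:q
      min(y[rng])
    }, numeric(1))
    keep[i] <- (y[p] - max(valleys)) >= thr
  }
  peaks[keep]
}

#' Dip statistic
#'
#' Departure of a sample from unimodality: the smallest sup-norm distance
#' between the empirical distribution function and any unimodal
#' distribution function (convex below its mode, concave above it),
#' computed by convex-minorant / concave-majorant band fitting over all
#' candidate mode locations.  Large values indicate multimodality; see
#' [lifespan_modality()] for the bootstrap calibration.
#'
#' @param values numeric sample (>= 2 finite values).
#' @return the dip statistic.
#' @export
dip_statistic <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop_evohet("need at least 2 finite values", "evohet_domain_error")
  .cpp_dip(sort(values))
}

#' Truncate the right tail of a trait distribution or sample
#'
#' Removes mass (or individuals) with trait above `x_max` and renormalizes.
#' Generic over [trait_distribution()] objects, numeric trait samples, and
#' data frames with an `x` column (e.g. the `final` table of
#' [run_evolution()]).
#'
#' @param obj the object to truncate.
#' @param x_max truncation point in (0, 1\].
#' @return the truncated, renormalized object of the same kind.
#' @export
truncate_trait_tail <- function(obj, x_max) {
  check_number(x_max, "x_max", lower = 0, upper = 1)
  if (x_max <= 0) config_error("`x_max` must be > 0")
  UseMethod("truncate_trait_tail")
}

#' @export
truncate_trait_tail.trait_distribution <- function(obj, x_max) {
  mass <- obj$mass
  mass[obj$grid > x_max] <- 0
  if (sum(mass) <= 0)
    stop_evohet("truncation removed all mass", "evohet_domain_error")
  trait_distribution(mass, obj$grid)
}

#' @export
truncate_trait_tail.numeric <- function(obj, x_max) {
  out <- obj[obj <= x_max]
  if (length(out) == 0L)
    stop_evohet("truncation removed all individuals", "evohet_domain_error")
  out
}

#' @export
truncate_trait_tail.data.frame <- function(obj, x_max) {
  out <- obj[obj$x <= x_max, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_evohet("truncation removed all individuals", "evohet_domain_error")
  rownames(out) <- NULL
  out
}
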