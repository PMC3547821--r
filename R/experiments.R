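# Experiment drivers: environment scans, mutation-rate scans, oldest-old
# analysis, stress induction, heat shock, subpopulation analysis.

#' Default calibration of the mortality law to the generation timescale
#'
#' At unit reproduction rate a generation of size N takes about N time units
#' to fill, so hazard rates must be commensurate with 1/N for individual
#' lifespans and the filling period to share a timescale; the defaults
#' therefore fix the dimensionless products `a * N` and `b * N`, and the
#' same transitions occur for other population sizes at correspondingly
#' rescaled rates.  The anchors are family-specific, chosen (the original
#' values are not published) so that the five qualitative mortality shapes
#' appear in order along the `b` grid: the initial mortality `a` sets the
#' floor of the mid-age valley, so it must sit well below the typical death
#' rates (`a * N` = 0.05 for HRM, 0.1 for HTM), and the HTM grid is much
#' narrower because every HTM individual shares the aging rate `b`, leaving
#' a narrow corridor between visible aging (`b * N` not too small) and
#' population collapse (`b * N` too large).
#'
#' @param N population size.
#' @param family `"HRM"` or `"HTM"`.
#' @return `default_a`: the initial mortality; `default_b_grid`: increasing
#'   environment parameters spanning kink, slowdown, plateau, decrease and
#'   U-shape; `default_b`: the mid-grid value (plateau regime).
#' @export
default_a <- function(N, family = c("HRM", "HTM")) {
  family <- match.arg(family)
  (if (family == "HRM") 0.05 else 0.1) / N
}

#' @rdname default_a
#' @export
default_b_grid <- function(N, family = c("HRM", "HTM")) {
  family <- match.arg(family)
  (if (family == "HRM") c(10, 16, 25, 48, 150) else
     c(4.5, 6.8, 7.6, 9, 13)) / N
}

#' @rdname default_a
#' @export
default_b <- function(N, family = c("HRM", "HTM")) {
  default_b_grid(N, family)[3]
}

# pooled final-generation traits as a trait_distribution
final_trait_distribution <- function(result, nbins = 200L) {
  trait_distribution(trait_hist(result$final$x, nbins))
}

# mortality curve of a pooled final-generation lifespan table
evolved_mortality <- function(result, include_oldest_old = FALSE,
                              nbins_age = 100L) {
  w <- result$fill_time / nbins_age
  lf <- result$final$death_time
  oo <- result$final$oldest_old
  keep_lf <- if (include_oldest_old) lf else lf[!oo]
  top <- max(keep_lf[is.finite(keep_lf)])
  bins <- seq(0, top + w, by = w)
  curve <- estimate_mortality(lf, bins = bins, oldest_old = oo,
                              include_oldest_old = include_oldest_old)
  # estimator convention: suppress sparsely observed bins before
  # classification
  curve[curve$exposure >= 1e-3 * max(curve$exposure), , drop = FALSE]
}

scan_provenance <- function(config, hp, extra = list()) {
  c(list(config = config, hazard = hp, seed = config$seed,
         hash = config_hash(list(config, hp, extra))), extra)
}

#' Environment scan
#'
#' Evolves populations to quasi-stationarity for each value of the
#' environment parameter `b` and records the stationary trait distribution,
#' the mortality curve (oldest-old excluded, as in the headline
#' mortality-pattern analyses) and its shape label.  Increasing `b` takes
#' the mortality pattern through the sequence kink, slowdown, plateau,
#' decrease, U-shape, while the stationary trait distribution moves towards
#' maintenance (lower mean trait).
#'
#' @param family `"HRM"` or `"HTM"`.
#' @param config an [evolution_config()].
#' @param b_values increasing environment parameters; default
#'   [default_b_grid()] for `config$N`.
#' @param a initial mortality; default [default_a()].
#' @param method `"stochastic"` (finite populations, [run_evolution()]) or
#'   `"deterministic"` ([find_stationary()]).
#' @param nbins trait-histogram resolution.
#' @param ... passed to [classify_shape()].
#' @return an object of class `scan_result`: list of per-value records
#'   (`b`, `dist`, `curve`, `shape`, `mean_x`, `extinct_fraction`) plus
#'   provenance.
#' @export
scan_environment <- function(family = c("HRM", "HTM"), config,
                             b_values = NULL, a = NULL,
                             method = c("stochastic", "deterministic"),
                             nbins = 50L, ...) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (is.null(b_values)) b_values <- default_b_grid(config$N, family)
  if (is.null(a)) a <- default_a(config$N, family)
  if (any(diff(b_values) <= 0))
    config_error("`b_values` must be increasing")
  records <- lapply(b_values, function(b) {
    hp <- hazard_params(family, a = a, b = b)
    if (method == "stochastic") {
      res <- run_evolution(config, hp, hist_bins = nbins)
      curve <- evolved_mortality(res)
      list(b = b, dist = trait_distribution(res$ensemble_hist[config$G + 1L, ]),
           curve = curve, shape = classify_shape(curve, ...),
           mean_x = mean(res$final$x),
           extinct_fraction = nrow(res$extinctions) / config$replicates,
           result = res)
    } else {
      st <- find_stationary(hp, mutation_kernel(config$pm, config$kernel,
                                                config$kernel_sd),
                            nbins = 200L, T_fill = config$N,
                            maturation = config$maturation)
      tg <- seq(0, config$N, length.out = 201L)[-1]
      curve <- mortality_from_distribution(st$dist, hp, tg)
      list(b = b, dist = st$dist, curve = curve,
           shape = classify_shape(curve, ...),
           mean_x = sum(st$dist$grid * st$dist$mass),
           extinct_fraction = as.numeric(st$extinct), stationary = st)
    }
  })
  structure(list(scan = "b", values = b_values, records = records,
                 family = family, method = method,
                 provenance = scan_provenance(config,
                                              list(family = family, a = a))),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  lab <- vapply(x$records, function(r) r$shape$label, character(1))
  mx <- vapply(x$records, function(r) r$mean_x, numeric(1))
  cat(sprintf("<scan_result> %s over %s (%s)\n", x$family, x$scan, x$method))
  print(data.frame(value = x$values, shape = lab, mean_x = round(mx, 3)))
  invisible(x)
}

#' Shape labels of a scan
#' @param x a `scan_result`.
#' @return character vector of labels, one per scan value.
#' @export
scan_labels <- function(x) {
  vapply(x$records, function(r) r$shape$label, character(1))
}

#' Oldest-old analysis
#'
#' Mortality with and without the oldest-old (individuals alive when the
#' next generation is already full, who never reproduce).  Including them
#' produces the late-age features of medfly mortality, evaluated on the
#' smoothed including-curve: (i) initial increase, (ii) a local maximum,
#' (iii) a U-shape, (iv) a second local maximum strictly higher than the
#' first, (v) a terminal decrease.
#'
#' @param config an [evolution_config()].
#' @param hp a [hazard_params()]; when `NULL`, the mortality law defaults to
#'   the decrease-regime environment (fourth grid cell), where the frail
#'   minority, the main population and the long-lived oldest-old die at
#'   separated ages, as the medfly pattern requires.
#' @param nbins_age age bins per fill time for the excluding curve; the
#'   including curve, which spans several fill times, uses four-fold wider
#'   bins and keeps bins with at least `min_deaths` deaths.
#' @param min_deaths sparse-bin threshold for the including curve.
#' @param df spline degrees of freedom for the feature checks.
#' @return list with `curve_excluding`, `curve_including`, `checklist`
#'   (named logical vector, or `NA` when no oldest-old are present),
#'   `n_oldest_old`, `result`.
#' @export
oldest_old_analysis <- function(config, hp = NULL, nbins_age = 100L,
                                min_deaths = 5L, df = 12) {
  if (is.null(hp))
    hp <- hazard_params("HRM", a = default_a(config$N, "HRM"),
                        b = default_b_grid(config$N, "HRM")[4])
  res <- run_evolution(config, hp)
  n_oo <- sum(res$final$oldest_old)
  curve_ex <- evolved_mortality(res, include_oldest_old = FALSE,
                                nbins_age = nbins_age)
  w_in <- 4 * res$fill_time / nbins_age
  lf <- res$final$death_time
  top <- max(lf[is.finite(lf)])
  curve_in <- estimate_mortality(lf, bins = seq(0, top + w_in, by = w_in),
                                 oldest_old = res$final$oldest_old,
                                 include_oldest_old = TRUE)
  curve_in <- curve_in[is.finite(curve_in$log_hazard) &
                         curve_in$deaths >= min_deaths, , drop = FALSE]
  checklist <- if (n_oo == 0L) NA else medfly_features(curve_in, df = df)
  list(curve_excluding = curve_ex, curve_including = curve_in,
       checklist = checklist, n_oldest_old = n_oo, result = res)
}

# the five medfly features, on a smoothed log-mortality curve
medfly_features <- function(curve, df = 10) {
  keep <- is.finite(curve$log_hazard)
  curve <- curve[keep, , drop = FALSE]
  t <- curve$time
  y <- curve$log_hazard
  w <- if (!is.null(curve$deaths)) curve$deaths else curve$exposure
  fit <- smooth.spline(t, y, w = w, df = min(df, length(t) - 2))
  g <- seq(min(t), max(t), length.out = 400L)
  yg <- predict(fit, g)$y
  dy <- diff(yg)
  sgn <- sign(dy)
  turns <- which(diff(sgn) != 0) + 1L
  maxima <- turns[sgn[turns - 1L] > 0 & sgn[pmin(turns, length(sgn))] < 0]
  minima <- turns[sgn[turns - 1L] < 0 & sgn[pmin(turns, length(sgn))] > 0]
  increase <- mean(dy[seq_len(20)]) > 0
  first_max <- if (length(maxima)) maxima[1] else NA
  has_u <- length(minima) > 0 && !is.na(first_max) &&
    any(minima > first_max)
  second_max <- if (!is.na(first_max) && length(maxima) > 1)
    maxima[maxima > first_max][1] else NA
  higher <- !is.na(second_max) && !is.na(first_max) &&
    yg[second_max] > yg[first_max]
  terminal_dec <- {
    last_peak <- if (length(maxima)) maxima[length(maxima)] else NA
    !is.na(last_peak) && last_peak < length(g) &&
      yg[length(g)] < yg[last_peak]
  }
  c(increase = increase, local_max = !is.na(first_max), u_shape = has_u,
    second_higher_max = higher && !is.na(second_max), decrease = terminal_dec)
}

#' Mutation-rate scan
#'
#' Evolves populations at a fixed environment for increasing mutation
#' probabilities and measures (i) the invariance of the left part of the
#' stationary trait distribution (sup difference of peak-normalized bin
#' densities over \[0, `x_split`\] between any two mutation rates — the
#' shape of the distribution close to zero is set by selection, not by
#' mutation), (ii) the L1 distance of the right tail (raw densities above
#' `x_split`) to the uniform density, which decreases as the mutation rate
#' grows, and (iii) the mortality shape label, which stays unchanged.
#'
#' @param family `"HRM"` or `"HTM"`.
#' @param config an [evolution_config()]; its `pm` is ignored in favour of
#'   `pm_values`.
#' @param pm_values increasing mutation probabilities.
#' @param b environment parameter (default mid-grid).
#' @param a initial mortality (default [default_a()]).
#' @param x_split boundary between the "left part" and the "right tail".
#' @param nbins trait-histogram resolution.
#' @return a `scan_result` over `pm` with `metrics`: `left_invariance`
#'   (sup difference), `tail_to_uniform` (per pm), `labels`.
#' @export
scan_mutation_rate <- function(family = c("HRM", "HTM"), config,
                               pm_values = c(0.01, 0.02, 0.05, 0.1),
                               b = NULL, a = NULL, x_split = 0.3,
                               nbins = 50L) {
  family <- match.arg(family)
  if (is.null(b)) b <- default_b(config$N, family)
  if (is.null(a)) a <- default_a(config$N, family)
  if (any(diff(pm_values) <= 0))
    config_error("`pm_values` must be increasing")
  hp <- hazard_params(family, a = a, b = b)
  records <- lapply(pm_values, function(pm) {
    cfg <- config
    cfg$pm <- pm
    res <- run_evolution(cfg, hp, hist_bins = nbins)
    curve <- evolved_mortality(res)
    list(pm = pm, dist = trait_distribution(res$ensemble_hist[config$G + 1L, ]),
         curve = curve, shape = classify_shape(curve),
         mean_x = mean(res$final$x),
         extinct_fraction = nrow(res$extinctions) / config$replicates)
  })
  dens <- vapply(records, function(r) r$dist$mass * nbins,
                 numeric(nbins))          # bins x pm, density scale
  mids <- (seq_len(nbins) - 0.5) / nbins
  norm_dens <- sweep(dens, 2, apply(dens, 2, max), "/")
  left <- mids <= x_split
  left_invariance <- max(apply(norm_dens[left, , drop = FALSE], 1, max) -
                         apply(norm_dens[left, , drop = FALSE], 1, min))
  tail_to_uniform <- colSums(abs(dens[!left, , drop = FALSE] - 1)) / nbins
  labels <- vapply(records, function(r) r$shape$label, character(1))
  structure(list(scan = "pm", values = pm_values, records = records,
                 family = family, method = "stochastic",
                 metrics = list(left_invariance = left_invariance,
                                tail_to_uniform = tail_to_uniform,
                                labels = labels, x_split = x_split),
                 provenance = scan_provenance(config,
                                              list(family = family, a = a,
                                                   b = b))),
            class = "scan_result")
}

#' Predicted mortality under stress without adaptation
#'
#' Changes the environment parameter `b` while freezing the evolved trait
#' distribution (no re-adaptation of heterogeneity) and computes the
#' resulting population mortality curves, their shape labels, and a
#' sensitivity metric: the mean absolute change of log-hazard over the
#' first half of the age window — where every cell still has the whole
#' population at risk — averaged over the imposed environments.  Re-adaptation is modelled by
#' re-running [scan_environment()] instead.
#'
#' When `t_window` is supplied, each curve is the mortality of the
#' subpopulation dying within that window — the analytic counterpart of
#' estimating mortality from lifespans with the oldest-old excluded, as in
#' the headline mortality-pattern pipeline; curves are then directly
#' comparable with the environment-scan output.
#'
#' @param dist the frozen evolved [trait_distribution()].
#' @param hp0 the [hazard_params()] the distribution evolved under.
#' @param b_new_values environment values to impose (default
#'   `b0 * c(1/4, 1/2, 2, 4)`).
#' @param t_window fill-time horizon for oldest-old-style exclusion
#'   (optional; required for `method = "resample"`).
#' @param t_grid reference age window; default up to `t_window`, or to the
#'   age where the unstressed population survival reaches 1 percent.
#' @param method `"resample"` draws `n_sample` lifespans from the frozen
#'   distribution under each imposed hazard and runs the standard
#'   oldest-old-excluding estimation pipeline (the exact Fig-1-style
#'   treatment, sparse late bins suppressed); `"analytic"` computes exact
#'   mixture hazards.  Uses R's random number stream when resampling.
#' @param n_sample lifespans drawn per environment for `"resample"`.
#' @return list with `baseline` (curve at `b0`), `curves`, `labels`,
#'   `sensitivity`, `b_new_values`.
#' @export
stress_response <- function(dist, hp0, b_new_values = NULL,
                            t_window = NULL, t_grid = NULL,
                            method = c("analytic", "resample"),
                            n_sample = 5e4) {
  method <- match.arg(method)
  if (method == "resample" && is.null(t_window))
    config_error("`t_window` is required for method = \"resample\"")
  if (is.null(b_new_values)) b_new_values <- hp0$b * c(0.25, 0.5, 2, 4)
  if (is.null(t_grid)) {
    if (!is.null(t_window)) {
      t_grid <- seq(0, t_window, length.out = 201L)[-1]
    } else {
      Spop <- function(t) sum(dist$mass *
                                survival_probability(hp0, dist$grid, t))
      top <- stats::uniroot(function(t) Spop(t) - 0.01, c(1e-6, 1e7),
                            extendInt = "downX")$root
      t_grid <- seq(0, top, length.out = 201L)[-1]
    }
  }
  resampled <- function(hp) {
    x <- sample(dist$grid, n_sample, replace = TRUE, prob = dist$mass)
    d <- draw_death_time(hp, x)
    oo <- d > t_window
    if (all(oo)) return(NULL)
    w <- t_window / 100
    top <- max(d[!oo])
    cv <- estimate_mortality(d, bins = seq(0, top + w, by = w),
                             oldest_old = oo, include_oldest_old = FALSE)
    cv[cv$exposure >= 1e-3 * max(cv$exposure), , drop = FALSE]
  }
  curve_for <- function(hp) {
    if (method == "resample") resampled(hp)
    else if (is.null(t_window)) mortality_from_distribution(dist, hp, t_grid)
    else windowed_mortality(dist, hp, t_grid, t_window)
  }
  baseline <- curve_for(hp0)
  curves <- lapply(b_new_values, function(bn)
    curve_for(hazard_params(hp0$family, a = hp0$a, b = bn, k = hp0$k,
                            ext = hp0$ext)))
  labels <- vapply(curves, function(cv)
    if (is.null(cv)) NA_character_ else classify_shape(cv)$label,
    character(1))
  # sensitivity on the exact mixture hazards, over the first half of the
  # age window: there the whole population is still at risk in every cell,
  # so log-mortality changes compare hazard laws rather than the
  # differential attrition they later cause
  t_ref <- t_grid[t_grid <= max(t_grid) / 2]
  base_an <- mortality_from_distribution(dist, hp0, t_ref)
  sens <- mean(vapply(b_new_values, function(bn) {
    cv <- mortality_from_distribution(
      dist, hazard_params(hp0$family, a = hp0$a, b = bn, k = hp0$k,
                          ext = hp0$ext), t_ref)
    n <- min(nrow(cv), nrow(base_an))
    mean(abs(cv$log_hazard[seq_len(n)] - base_an$log_hazard[seq_len(n)]))
  }, numeric(1)))
  list(baseline = baseline, curves = curves, labels = labels,
       sensitivity = sens, b_new_values = b_new_values)
}

# hazard of the subpopulation dying before t_window: deaths density over
# the person-time of individuals that die within the window
windowed_mortality <- function(dist, hp, t_grid, t_window) {
  x <- dist$grid
  S <- exp(-outer(x, t_grid, function(xx, t) cumulative_hazard(hp, xx, t)))
  M <- outer(x, t_grid, function(xx, t) hazard(hp, xx, t))
  ST <- exp(-cumulative_hazard(hp, x, rep(t_window, length(x))))
  den <- as.vector(crossprod(dist$mass, S - ST))
  num <- as.vector(crossprod(dist$mass, M * S))
  ok <- den > 1e-300 & num > 0
  curve <- data.frame(time = t_grid[ok], hazard = num[ok] / den[ok])
  curve$log_hazard <- log(curve$hazard)
  curve$deaths <- num[ok]
  class(curve) <- c("mortality_curve", "data.frame")
  attr(curve, "truncated") <- any(!ok)
  curve
}

#' Survival under an acute stress (heat shock)
#'
#' Population survival of a frozen evolved trait distribution placed under
#' an elevated hazard.  The shock hits an adult cohort: the cohort ages to
#' `age` under the baseline law first (attrition and accumulated aging
#' heterogeneity are both carried into the shock), then survival is
#' measured from the shock onset under the shock law.  Heterogeneous
#' populations show a two-stage decrease — a quick strong fall (the frail
#' die) followed by a slowing down (the robust remain) — quantified as the
#' ratio of the early-window to the late-window log-survival slope; a
#' homogeneous Gompertz cohort shows the opposite ordering (slopes steepen
#' with age), keeping the metric below the threshold.
#'
#' @param dist the frozen evolved [trait_distribution()] (a delta
#'   distribution gives the homogeneous control).
#' @param hp_shock the [hazard_params()] describing the stress.
#' @param hp_baseline the pre-shock [hazard_params()]; needed when
#'   `age > 0`.
#' @param age cohort age at shock onset; default: the age at which a
#'   quarter of the baseline cohort has died (0 when no baseline is given).
#' @param t_grid times since shock onset; default up to the time where
#'   survival reaches 0.1 percent.
#' @param early,late survival ranges defining the two windows.
#' @param threshold slope ratio above which the curve is called two-stage.
#' @return list with `curve` (a `survival_curve` on `t_grid`, time measured
#'   from the shock), `age`, `slope_early`, `slope_late`, `ratio`,
#'   `two_stage`.
#' @export
heat_shock_survival <- function(dist, hp_shock, hp_baseline = NULL,
                                age = NULL, t_grid = NULL,
                                early = c(0.95, 0.5), late = c(0.1, 0.02),
                                threshold = 3) {
  Sbase <- function(t) vapply(t, function(ti)
    sum(dist$mass * survival_probability(hp_baseline, dist$grid, ti)),
    numeric(1))
  if (is.null(age)) {
    age <- if (is.null(hp_baseline)) 0 else
      stats::uniroot(function(t) Sbase(t) - 0.75, c(1e-9, 1e9),
                     extendInt = "downX")$root
  }
  if (age > 0 && is.null(hp_baseline))
    config_error("`hp_baseline` is required when `age` > 0")
  # cohort composition at shock onset
  w <- dist$mass
  if (age > 0)
    w <- w * survival_probability(hp_baseline, dist$grid, age)
  w <- w / sum(w)
  H0 <- cumulative_hazard(hp_shock, dist$grid, rep(age, length(dist$grid)))
  Spop <- function(t) vapply(t, function(ti) {
    H <- cumulative_hazard(hp_shock, dist$grid, rep(age + ti,
                                                    length(dist$grid)))
    sum(w * exp(-(H - H0)))
  }, numeric(1))
  if (is.null(t_grid)) {
    top <- stats::uniroot(function(t) Spop(t) - 0.001, c(1e-6, 1e9),
                          extendInt = "downX")$root
    t_grid <- seq(0, top, length.out = 400L)
  }
  s <- Spop(t_grid)
  curve <- data.frame(time = t_grid, surv = s)
  class(curve) <- c("survival_curve", "data.frame")
  t_at <- function(level)
    approx(rev(s), rev(t_grid), xout = level, ties = "ordered")$y
  slope_in <- function(win) {
    t1 <- t_at(win[1]); t2 <- t_at(win[2])
    (log(win[2]) - log(win[1])) / (t2 - t1)
  }
  se <- slope_in(early)
  sl <- slope_in(late)
  ratio <- abs(se) / abs(sl)
  list(curve = curve, age = age, slope_early = se, slope_late = sl,
       ratio = ratio, two_stage = is.finite(ratio) && ratio > threshold,
       threshold = threshold)
}

#' Subpopulation analysis
#'
#' In the HRM regime with a mid-age plateau, the stationary trait
#' distribution is unimodal while the lifespan distribution is bimodal: the
#' whole right tail of the trait distribution compresses onto a single
#' lifespan peak through the non-linear trait-lifespan relationship, so a
#' bimodal lifespan distribution does not imply two subpopulations in the
#' underlying trait.  Cutting the right trait tail progressively removes
#' the lifespan bimodality.
#'
#' @param config an [evolution_config()].
#' @param hp a [hazard_params()] (default HRM at mid-grid calibration).
#' @param x_max_grid decreasing truncation points (starting at 1 =
#'   untruncated).
#' @param ... passed to [lifespan_modality()].
#' @return list with `trait_modality`, `lifespan_modality`, `truncations`
#'   (data.frame `x_max`, `mode_count`, `dip`, `p_value`), `result`.
#' @export
subpopulation_analysis <- function(config, hp = NULL,
                                   x_max_grid = c(1, 0.8, 0.6, 0.4), ...) {
  if (is.null(hp))
    hp <- hazard_params("HRM", a = default_a(config$N, "HRM"),
                        b = default_b(config$N, "HRM"))
  res <- run_evolution(config, hp)
  fin <- res$final
  trait_mod <- lifespan_modality(fin$x, ...)
  life_mod <- lifespan_modality(fin$death_time, ...)
  rows <- lapply(x_max_grid, function(xm) {
    sub <- truncate_trait_tail(fin, xm)
    m <- lifespan_modality(sub$death_time, ...)
    data.frame(x_max = xm, mode_count = m$mode_count, dip = m$dip,
               p_value = m$p_value, n = m$n)
  })
  list(trait_modality = trait_mod, lifespan_modality = life_mod,
       truncations = do.call(rbind, rows), result = res)
}
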