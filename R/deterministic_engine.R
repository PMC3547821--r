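#' Discretized trait distribution
#'
#' The infinite-population state: nonnegative masses on uniform bin
#' midpoints over \[0, 1\], summing to one.
#'
#' @param mass nonnegative weights; normalized to sum to one.
#' @param grid bin midpoints (default: `length(mass)` uniform bins).
#' @return an object of class `trait_distribution`.
#' @export
trait_distribution <- function(mass, grid = NULL) {
  if (is.null(grid)) {
    n <- length(mass)
    grid <- (seq_len(n) - 0.5) / n
  }
  if (length(grid) != length(mass))
    config_error("`grid` and `mass` lengths differ")
  if (any(mass < 0) || any(!is.finite(mass)))
    config_error("`mass` must be finite and nonnegative")
  if (any(diff(grid) <= 0) || any(grid < 0) || any(grid > 1))
    config_error("`grid` must be strictly increasing within [0, 1]")
  s <- sum(mass)
  if (s <= 0) config_error("`mass` must have positive total")
  structure(list(grid = grid, mass = mass / s), class = "trait_distribution")
}

#' Uniform trait distribution
#' @param nbins number of uniform bins on \[0, 1\].
#' @return a [trait_distribution()].
#' @export
uniform_trait_distribution <- function(nbins = 200L) {
  trait_distribution(rep(1 / nbins, nbins))
}

#' @export
print.trait_distribution <- function(x, ...) {
  m <- sum(x$grid * x$mass)
  cat(sprintf("<trait_distribution> %d bins, mean x = %.4f, max mass = %.4f\n",
              length(x$grid), m, max(x$mass)))
  invisible(x)
}

#' Mutation kernel
#'
#' Mutation model of the deterministic operator: with probability `pm` an
#' offspring trait is redrawn, either uniformly on \[0, 1\] or from a
#' Gaussian centred on the parental trait (sd `sd`) reflected into \[0, 1\].
#'
#' @param pm mutation probability in \[0, 1\].
#' @param type `"uniform_reset"` or `"gaussian"`.
#' @param sd Gaussian kernel standard deviation.
#' @return an object of class `mutation_kernel`.
#' @export
mutation_kernel <- function(pm, type = c("uniform_reset", "gaussian"),
                            sd = 0.3) {
  type <- match.arg(type)
  check_number(pm, "pm", lower = 0, upper = 1)
  check_number(sd, "sd", lower = 0)
  structure(list(pm = pm, type = type, sd = sd), class = "mutation_kernel")
}

# column-stochastic kernel matrix K[i, j] = P(offspring bin i | parent bin j)
kernel_matrix <- function(kernel, grid) {
  n <- length(grid)
  if (kernel$type == "uniform_reset")
    return(matrix(1 / n, n, n))
  edges <- c(0, (grid[-n] + grid[-1]) / 2, 1)
  K <- matrix(0, n, n)
  # fold of N(parent, sd) into [0, 1]: sum the images at 2m + y and 2m - y
  for (j in seq_len(n)) {
    acc <- numeric(n)
    for (m in -3:3) {
      acc <- acc + diff(stats::pnorm(2 * m + edges, grid[j], kernel$sd))
      acc <- acc + rev(diff(stats::pnorm(2 * m - rev(edges), grid[j],
                                         kernel$sd)))
    }
    K[, j] <- acc / sum(acc)
  }
  K
}

#' Within-generation population state
#'
#' Unnormalized density of alive individuals at within-generation time `t`:
#' \eqn{n(x, t) = p(x) S(x, t)} with \eqn{S} the individual survival
#' function.
#'
#' @param dist a [trait_distribution()].
#' @param hp a [hazard_params()].
#' @param t within-generation time (>= 0).
#' @return vector of unnormalized masses on `dist$grid`.
#' @export
within_generation_state <- function(dist, hp, t) {
  check_xt(dist$grid, t)
  dist$mass * survival_probability(hp, dist$grid, t)
}

# survival matrix S[i, j] = S(grid[i], tgrid[j]) and trapezoid weights
det_setup <- function(hp, grid, maturation, T_fill, dt) {
  tgrid <- seq(maturation, maturation + T_fill, by = dt)
  if (tgrid[length(tgrid)] < maturation + T_fill)
    tgrid <- c(tgrid, maturation + T_fill)
  nt <- length(tgrid)
  H <- outer(grid, tgrid, function(x, t) cumulative_hazard(hp, x, t))
  S <- exp(-H)
  wt <- diff(tgrid)
  wt <- c(wt / 2, 0) + c(0, wt / 2)
  list(tgrid = tgrid, S = S, wt = wt)
}

apply_operator_core <- function(mass, grid, setup, kernel, K = NULL) {
  B <- setup$S * grid            # rows scaled by x
  denom <- as.vector(crossprod(mass, B))  # integral of x' n(x', t) over x'
  ok <- denom > .Machine$double.xmin
  extinct <- !all(ok)
  w <- setup$wt
  w[!ok] <- 0
  denom[!ok] <- 1
  influx <- mass * as.vector(B %*% (w / denom))  # selection part, per bin
  total_time <- sum(w)
  if (kernel$pm > 0) {
    mut <- if (kernel$type == "uniform_reset")
      rep(total_time / length(grid), length(grid))
    else as.vector(K %*% influx)
    q <- (1 - kernel$pm) * influx + kernel$pm * mut
  } else q <- influx
  s <- sum(q)
  if (s <= 0) return(list(mass = mass, extinct = TRUE))
  list(mass = q / s, extinct = extinct)
}

#' One generation of the deterministic operator
#'
#' Maps the trait distribution of generation \eqn{g} to generation
#' \eqn{g+1}: offspring are produced at overall unit rate with
#' trait-proportional weights among survivors,
#' \eqn{r(x,t) = x\,n(x,t) / \int x' n(x',t)\,dx'}, accumulated from the
#' maturation delay over a reproduction window of length `T_fill` (the time
#' the stochastic model needs to fill a generation of size N at unit rate),
#' mutated through the kernel, and renormalized.  If the reproductive mass
#' underflows before the window closes the result is flagged extinct.
#'
#' @param dist a [trait_distribution()].
#' @param hp a [hazard_params()].
#' @param kernel a [mutation_kernel()].
#' @param T_fill length of the reproduction window (default 500, matching
#'   the default population size).
#' @param maturation reproduction clock start (>= 0).
#' @param dt time-integration step.
#' @return a [trait_distribution()] with attribute `extinct`.
#' @export
apply_generation_operator <- function(dist, hp, kernel, T_fill = 500,
                                      maturation = 0, dt = 0.1) {
  setup <- det_setup(hp, dist$grid, maturation, T_fill, dt)
  K <- if (kernel$pm > 0 && kernel$type == "gaussian")
    kernel_matrix(kernel, dist$grid) else NULL
  res <- apply_operator_core(dist$mass, dist$grid, setup, kernel, K)
  out <- trait_distribution(res$mass, dist$grid)
  attr(out, "extinct") <- res$extinct
  out
}

#' Quasi-stationary distribution of the deterministic model
#'
#' Iterates the generation operator from a uniform start until the L1
#' distance between consecutive distributions falls below `tol`, or
#' `max_iter` generations are reached (flagged in the diagnostics; the last
#' distribution is still returned).
#'
#' @inheritParams apply_generation_operator
#' @param nbins trait grid resolution.
#' @param start optional starting [trait_distribution()].
#' @param tol L1 convergence tolerance on bin masses.
#' @param max_iter maximum number of operator iterations.
#' @return list with `dist` (the stationary [trait_distribution()]),
#'   `iterations`, `final_distance`, `converged`, `extinct`.
#' @export
find_stationary <- function(hp, kernel, nbins = 200L, T_fill = 500,
                            maturation = 0, dt = 0.1, start = NULL,
                            tol = 1e-8, max_iter = 2000L) {
  dist <- if (is.null(start)) uniform_trait_distribution(nbins) else start
  setup <- det_setup(hp, dist$grid, maturation, T_fill, dt)
  K <- if (kernel$pm > 0 && kernel$type == "gaussian")
    kernel_matrix(kernel, dist$grid) else NULL
  mass <- dist$mass
  d <- Inf
  it <- 0L
  extinct <- FALSE
  while (it < max_iter) {
    res <- apply_operator_core(mass, dist$grid, setup, kernel, K)
    extinct <- extinct || res$extinct
    d <- l1_distance(res$mass, mass)
    mass <- res$mass
    it <- it + 1L
    if (d < tol) break
  }
  list(dist = trait_distribution(mass, dist$grid), iterations = it,
       final_distance = d, converged = d < tol, extinct = extinct)
}

#' Population mortality of a trait mixture
#'
#' Frailty-mixture population hazard of a (frozen) trait distribution:
#' \deqn{\mu_{pop}(t) = \frac{\sum_x \mu(x,t) p(x) S(x,t)}
#'                          {\sum_x p(x) S(x,t)},}
#' the exposure-weighted mean hazard of survivors.  Ages where the surviving
#' mass underflows are dropped and the curve is flagged truncated.
#'
#' @param dist a [trait_distribution()].
#' @param hp a [hazard_params()].
#' @param t_grid increasing ages (>= 0).
#' @return a `mortality_curve` data.frame (`time`, `hazard`, `log_hazard`)
#'   with attribute `truncated`.
#' @export
mortality_from_distribution <- function(dist, hp, t_grid) {
  if (any(diff(t_grid) <= 0) || any(t_grid < 0))
    stop_evohet("`t_grid` must be increasing and >= 0", "evohet_domain_error")
  S <- exp(-outer(dist$grid, t_grid,
                  function(x, t) cumulative_hazard(hp, x, t)))
  M <- outer(dist$grid, t_grid, function(x, t) hazard(hp, x, t))
  den <- as.vector(crossprod(dist$mass, S))
  num <- as.vector(crossprod(dist$mass, M * S))
  ok <- den > 1e-300
  curve <- data.frame(time = t_grid[ok], hazard = num[ok] / den[ok])
  curve$log_hazard <- log(curve$hazard)
  # deaths density: lets the shape classifier weight ages the way an
  # estimated curve weights its bins
  curve$deaths <- num[ok]
  class(curve) <- c("mortality_curve", "data.frame")
  attr(curve, "truncated") <- any(!ok)
  curve
}
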