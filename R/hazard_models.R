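#' Individual mortality law
#'
#' Defines the Gompertz mortality hazard of an individual with
#' resource-allocation trait \eqn{x \in [0,1]}.  Two families implement the
#' two hypotheses about inter-individual differences in aging:
#' \describe{
#'   \item{HRM (heterogeneity in aging rate)}{\eqn{\mu(x,t) = a\,e^{b x^k t}}:
#'     all individuals share the initial mortality \eqn{a} and differ in
#'     their aging rates \eqn{b x^k}.}
#'   \item{HTM (heterogeneity in aging timing)}{\eqn{\mu(x,t) = a x^k e^{b t}}:
#'     all individuals share the aging rate \eqn{b}; a change in \eqn{x}
#'     shifts the log-mortality curve along the time axis by
#'     \eqn{\Delta t = \ln(x_1^k/x_2^k)/b}.}
#' }
#' An age- and trait-independent extrinsic hazard `ext` is added to the
#' intrinsic hazard.
#'
#' @param family `"HRM"` or `"HTM"`.
#' @param a initial mortality rate (per unit time, > 0).
#' @param b environment-biology interaction rate, the baseline Gompertz
#'   slope (per unit time, >= 0).
#' @param k trait exponent (> 0); `k = 1` gives linear dependence on the
#'   trait.
#' @param ext extrinsic age-independent hazard (per unit time, >= 0).
#' @return an object of class `hazard_params`.
#' @examples
#' hp <- hazard_params("HRM", a = 0.001, b = 0.02)
#' hazard(hp, x = 0.5, t = 100)
#' @export
hazard_params <- function(family = c("HRM", "HTM"), a, b, k = 1, ext = 0) {
  family <- match.arg(family)
  check_number(a, "a", lower = 0)
  if (a <= 0) config_error("`a` must be > 0")
  check_number(b, "b", lower = 0)
  check_number(k, "k")
  if (k <= 0) config_error("`k` must be > 0")
  check_number(ext, "ext", lower = 0)
  structure(list(family = family, a = a, b = b, k = k, ext = ext),
            class = "hazard_params")
}

#' @export
print.hazard_params <- function(x, ...) {
  cat(sprintf(
    "<hazard_params> %s: a = %g, b = %g, k = %g, ext = %g\n",
    x$family, x$a, x$b, x$k, x$ext))
  if (x$family == "HRM")
    cat("  mu(x,t) = a * exp(b * x^k * t) + ext\n")
  else
    cat("  mu(x,t) = a * x^k * exp(b * t) + ext\n")
  invisible(x)
}

check_xt <- function(x, t) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_evohet("trait `x` must lie in [0, 1]", "evohet_domain_error")
  if (any(is.na(t)) || any(t < 0))
    stop_evohet("age `t` must be >= 0", "evohet_domain_error")
}

fam_code <- function(hp) if (hp$family == "HRM") 0L else 1L

#' Mortality hazard at a given age
#'
#' Instantaneous death rate of an individual with trait `x` at age `t`,
#' intrinsic hazard plus extrinsic hazard.  Vectorized over `x` and `t`.
#'
#' @param hp a [hazard_params()] object.
#' @param x trait in \[0, 1\].
#' @param t age (>= 0).
#' @return hazard rate(s), per unit time.
#' @export
hazard <- function(hp, x, t) {
  check_xt(x, t)
  xk <- x^hp$k
  mu <- if (hp$family == "HRM") hp$a * exp(hp$b * xk * t)
        else hp$a * xk * exp(hp$b * t)
  mu + hp$ext
}

#' Cumulative hazard
#'
#' Closed-form integral of [hazard()] over age \[0, t\]:
#' HRM: \eqn{a (e^{b x^k t} - 1)/(b x^k) + \mathrm{ext}\, t} (constant-hazard
#' limit \eqn{a t} as \eqn{b x^k \to 0}); HTM:
#' \eqn{a x^k (e^{b t} - 1)/b + \mathrm{ext}\, t} (limit \eqn{a x^k t}).
#'
#' @inheritParams hazard
#' @return dimensionless cumulative hazard(s) H(t) >= 0.
#' @export
cumulative_hazard <- function(hp, x, t) {
  check_xt(x, t)
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  xk <- x^hp$k
  if (hp$family == "HRM") {
    w <- hp$b * xk
    H <- ifelse(w > 0, hp$a * expm1(w * t) / ifelse(w > 0, w, 1), hp$a * t)
  } else {
    H <- if (hp$b > 0)
      ifelse(xk > 0, hp$a * xk * expm1(hp$b * t) / hp$b, 0)
    else hp$a * xk * t
  }
  H + hp$ext * t
}

#' Survival function
#'
#' \eqn{S(t) = \exp(-H(t))} with \eqn{H} the [cumulative_hazard()].
#'
#' @inheritParams hazard
#' @return survival probability(ies) in \[0, 1\].
#' @export
survival_probability <- function(hp, x, t) {
  exp(-cumulative_hazard(hp, x, t))
}

# Exact inverse of the intrinsic cumulative hazard at -log(u); the
# workhorse behind draw_death_time(), exposed internally for tests.
invert_death_time <- function(hp, x, u) {
  n <- max(length(x), length(u))
  x <- rep_len(x, n); u <- rep_len(u, n)
  e <- -log(u)
  xk <- x^hp$k
  if (hp$family == "HRM") {
    w <- hp$b * xk
    ifelse(w > 0, log1p(w * e / hp$a) / ifelse(w > 0, w, 1), e / hp$a)
  } else {
    axk <- hp$a * xk
    out <- rep(Inf, n)
    pos <- axk > 0
    if (hp$b > 0)
      out[pos] <- log1p(hp$b * e[pos] / axk[pos]) / hp$b
    else
      out[pos] <- e[pos] / axk[pos]
    out
  }
}

#' Draw exact death times
#'
#' Inverse-transform sampling of the lifespan distribution: solves
#' \eqn{H(t) = -\ln u} with \eqn{u \sim U(0,1)} using the closed-form
#' inverse of the intrinsic cumulative hazard; with `ext > 0` the returned
#' age is the minimum of the intrinsic draw and an independent exponential
#' draw with rate `ext` (competing hazards).  An HTM individual with
#' \eqn{x = 0} and no extrinsic hazard never dies: the `+Inf` sentinel is a
#' legal value meaning "outlives any horizon".
#'
#' Uses R's global random number stream; call [set.seed()] for
#' reproducibility.
#'
#' @inheritParams hazard
#' @param x vector of traits; one death time is drawn per element.
#' @return vector of ages at death (possibly `Inf`).
#' @export
draw_death_time <- function(hp, x) {
  check_xt(x, t = 0)
  t <- invert_death_time(hp, x, runif(length(x)))
  if (hp$ext > 0) t <- pmin(t, rexp(length(x)) / hp$ext)
  t
}
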