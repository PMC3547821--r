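# Independent oracles used across the suite.

# cumulative hazard by adaptive quadrature of the hazard (oracle for the
# closed forms)
quad_cumhaz <- function(hp, x, t) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    integrate(function(s) hazard(hp, rep(x, length(s)), s), 0, ti,
              rel.tol = 1e-10)$value
  }, numeric(1))
}

# lifetime CDF for Kolmogorov-Smirnov checks
lifetime_cdf <- function(hp, x) {
  function(t) 1 - survival_probability(hp, rep(x, length(t)), pmax(t, 0))
}

# mean lifetime by quadrature of the survival function
quad_mean_lifetime <- function(hp, x, upper = Inf) {
  integrate(function(t) survival_probability(hp, rep(x, length(t)), t), 0,
            upper, rel.tol = 1e-9)$value
}

# ---------------------------------------------------------------------------
# Brute-force dip oracle: bisection on the sup-distance eps, deciding
# feasibility of a unimodal distribution function within the eps-band of the
# ECDF by explicit convex-minorant / concave-majorant construction with a
# jump allowed at the mode.  Only for small samples.
# ---------------------------------------------------------------------------

# greatest convex minorant of points (xx, uu), values at xx
gcm_vals <- function(xx, uu) {
  m <- length(xx)
  if (m == 1) return(uu)
  st <- 1L
  for (j in 2:m) {
    while (length(st) >= 2) {
      a <- st[length(st) - 1]; b <- st[length(st)]
      if ((xx[b] - xx[a]) * (uu[j] - uu[a]) -
          (uu[b] - uu[a]) * (xx[j] - xx[a]) <= 0) st <- st[-length(st)]
      else break
    }
    st <- c(st, j)
  }
  approx(xx[st], uu[st], xout = xx)$y
}

lcm_vals <- function(xx, ll) -gcm_vals(xx, -ll)

dip_oracle <- function(xs, tol = 1e-8) {
  xs <- sort(xs)
  n <- length(xs)
  ux <- unique(xs)
  m <- length(ux)
  cnt <- as.vector(table(factor(xs, levels = ux)))
  Fhi <- cumsum(cnt) / n
  Flo <- c(0, Fhi[-m])

  min_mode_val <- function(xx, up, lo) {
    # smallest feasible convex value at the last point, by bisection
    ok <- function(v) {
      u2 <- up; u2[length(u2)] <- v
      h <- gcm_vals(xx, u2)
      all(h >= lo - 1e-12) && all(diff(h) >= -1e-12)
    }
    if (!ok(up[length(up)])) return(Inf)
    a <- lo[length(lo)]; b <- up[length(up)]
    if (ok(a)) return(a)
    while (b - a > tol) { mid <- (a + b) / 2; if (ok(mid)) b <- mid else a <- mid }
    b
  }
  max_mode_val <- function(xx, up, lo) {
    # largest feasible concave value at the first point
    ok <- function(v) {
      l2 <- lo; l2[1] <- v
      g <- lcm_vals(xx, l2)
      all(g <= up + 1e-12) && all(diff(g) >= -1e-12)
    }
    if (!ok(lo[1])) return(-Inf)
    a <- lo[1]; b <- up[1]
    if (ok(b)) return(b)
    while (b - a > tol) { mid <- (a + b) / 2; if (ok(mid)) a <- mid else b <- mid }
    a
  }
  feasible <- function(eps) {
    lo_all <- Fhi - eps
    up_all <- Flo + eps
    for (j in seq_len(m)) {
      upL <- up_all[seq_len(j)]; loL <- lo_all[seq_len(j)]
      upL[j] <- Flo[j] + eps; loL[j] <- Flo[j] - eps
      upR <- up_all[j:m]; loR <- lo_all[j:m]
      upR[1] <- Fhi[j] + eps; loR[1] <- Fhi[j] - eps
      if (any(loL > upL + 1e-12) || any(loR > upR + 1e-12)) next
      hmin <- min_mode_val(ux[seq_len(j)], upL, loL)
      if (!is.finite(hmin)) next
      gmax <- max_mode_val(ux[j:m], upR, loR)
      if (!is.finite(gmax)) next
      if (hmin <= gmax + 1e-9) return(TRUE)
    }
    FALSE
  }
  a <- 0; b <- 0.5
  while (b - a > tol) { mid <- (a + b) / 2; if (feasible(mid)) b <- mid else a <- mid }
  b
}
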